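# Shared fixture builders; all randomness is seeded by the caller.

# Tiny two-site panel (one cis, one trans) for hand-checkable examples.
toy_panel <- function() {
  haplotype_panel(
    sites = data.frame(position = c(100L, 200L),
                       ref = c("C", "A"), alt = c("T", "G"),
                       orientation = c("cis", "trans")),
    focal_position = 100L, genome_length = 16299L)
}

# Guide read records with explicit fields.
make_reads <- function(cell, guide, mapq = 60, umi = NULL) {
  n <- max(length(cell), length(guide), length(mapq))
  data.frame(cell_barcode = rep_len(cell, n),
             guide_id = rep_len(guide, n),
             mapq = rep_len(mapq, n),
             umi = if (is.null(umi)) sprintf("u%03d", seq_len(n))
                   else rep_len(umi, n),
             read_id = sprintf("r%03d", seq_len(n)),
             stringsAsFactors = FALSE)
}

# Direct transcription of the assignment rule text, used as the
# brute-force oracle: >= min_reads deduplicated reads, and the most
# abundant guide strictly exceeding the dominance fraction of the total.
oracle_assign <- function(counts_vec, min_reads = 2, dominance = 2 / 3) {
  total <- sum(counts_vec)
  if (total < min_reads) return("unassigned")
  top <- max(counts_vec)
  if (sum(counts_vec == top) == 1 && top / total > dominance) "assigned"
  else "ambiguous"
}

# Latent clipped-normal heteroplasmy draw.
draw_latent_h <- function(n, mean = 0.582, sd = 0.113) {
  pmin(1, pmax(0, rnorm(n, mean, sd)))
}
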