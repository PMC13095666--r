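#' Construct a linked-SNV haplotype panel
#'
#' A haplotype panel describes a set of heteroplasmic SNVs on the circular
#' mitochondrial genome that are linked on two haplotypes. Each site is
#' oriented `cis` (alternate allele on the same haplotype as the focal
#' pathogenic variant), `trans` (alternate allele on the opposing
#' haplotype) or `unknown` (orientation not yet inferred). The focal site
#' is cis by definition.
#'
#' @param sites Data frame with columns `position` (1-based), `ref`, `alt`
#'   and optionally `orientation`.
#' @param focal_position Position of the focal pathogenic variant; must
#'   appear in `sites`.
#' @param genome_length Length of the circular mitochondrial genome
#'   (default 16299, mouse mtDNA).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sites, focal_position,
                            genome_length = 16299L) {
  need <- c("position", "ref", "alt")
  miss <- setdiff(need, names(sites))
  if (length(miss)) {
    .stopf("panel table is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(sites$position)) .stopf("duplicated panel positions")
  if (any(sites$position < 1 | sites$position > genome_length)) {
    .stopf("panel positions must lie in [1, %d]", genome_length)
  }
  if (any(sites$ref == sites$alt)) .stopf("ref and alt alleles must differ")
  if (!focal_position %in% sites$position) {
    .stopf("focal position %d is not in the panel", focal_position)
  }
  if (is.null(sites$orientation)) sites$orientation <- "unknown"
  ok <- sites$orientation %in% c("cis", "trans", "unknown")
  if (!all(ok)) .stopf("orientation must be cis, trans or unknown")
  sites$orientation[sites$position == focal_position] <- "cis"
  structure(list(sites = sites, focal_position = as.integer(focal_position),
                 genome_length = as.integer(genome_length)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("Haplotype panel: %d sites, focal m.%d, genome length %d\n",
              nrow(x$sites), x$focal_position, x$genome_length))
  print(x$sites)
  invisible(x)
}

#' Per-site heteroplasmy fraction
#'
#' The alternate-allele fraction `alt / (ref + alt)` at a single variant
#' site; `NA` when the site has zero depth. Vectorized over counts.
#'
#' @param ref_count,alt_count Nonnegative deduplicated read counts.
#' @return Numeric fraction(s) in `[0, 1]`, `NA` at zero depth.
#' @export
site_heteroplasmy <- function(ref_count, alt_count) {
  if (any(ref_count < 0, na.rm = TRUE) || any(alt_count < 0, na.rm = TRUE)) {
    .stopf("allele counts must be nonnegative")
  }
  depth <- ref_count + alt_count
  ifelse(depth > 0, alt_count / depth, NA_real_)
}

#' Infer cis/trans orientation of panel sites from per-cell correlation
#'
#' For each non-focal panel site, computes the Pearson correlation across
#' cells between the site's heteroplasmy fraction and the focal site's,
#' using only cells with at least `min_site_depth` reads at both sites.
#' Sites correlating at `r >= min_abs_r` are oriented `cis`, at
#' `r <= -min_abs_r` `trans`, and otherwise `unknown` (such sites are
#' excluded from combined calling, with a warning).
#'
#' @param counts Data frame of allele counts with columns `cell_barcode`,
#'   `position`, `ref_count`, `alt_count`.
#' @param panel A [haplotype_panel()].
#' @param min_site_depth Minimum per-site depth for a cell to qualify
#'   (default 5).
#' @param min_abs_r Minimum absolute correlation to call an orientation
#'   (default 0.3).
#' @param min_cells Minimum qualifying cells per site (default 10); sites
#'   with fewer are set `unknown`.
#' @return The panel with orientations filled in and a per-site `r`
#'   column added to `panel$sites`.
#' @export
infer_orientations <- function(counts, panel, min_site_depth = 5,
                               min_abs_r = 0.3, min_cells = 10) {
  stopifnot(inherits(panel, "haplotype_panel"))
  .check_fraction(min_abs_r, "min_abs_r", open_lower = TRUE)
  sites <- panel$sites
  focal <- counts[counts$position == panel$focal_position, , drop = FALSE]
  focal_depth <- focal$ref_count + focal$alt_count
  focal <- focal[focal_depth >= min_site_depth, , drop = FALSE]
  focal_h <- site_heteroplasmy(focal$ref_count, focal$alt_count)
  names(focal_h) <- focal$cell_barcode
  sites$r <- NA_real_
  for (i in seq_len(nrow(sites))) {
    pos <- sites$position[i]
    if (pos == panel$focal_position) next
    sub <- counts[counts$position == pos, , drop = FALSE]
    sub <- sub[(sub$ref_count + sub$alt_count) >= min_site_depth, ,
               drop = FALSE]
    common <- intersect(sub$cell_barcode, names(focal_h))
    if (length(common) < min_cells) {
      sites$orientation[i] <- "unknown"
      .warnf("site %d: only %d cells pass depth %g at both sites; orientation unknown",
             pos, length(common), min_site_depth)
      next
    }
    h_site <- site_heteroplasmy(
      sub$ref_count[match(common, sub$cell_barcode)],
      sub$alt_count[match(common, sub$cell_barcode)])
    r <- suppressWarnings(stats::cor(h_site, focal_h[common]))
    sites$r[i] <- r
    sites$orientation[i] <-
      if (is.na(r)) "unknown"
      else if (r >= min_abs_r) "cis"
      else if (r <= -min_abs_r) "trans"
      else "unknown"
    if (sites$orientation[i] == "unknown") {
      .warnf("site %d: |r| = %.3f below %.2f; excluded from combined calling",
             pos, abs(if (is.na(r)) 0 else r), min_abs_r)
    }
  }
  panel$sites <- sites
  panel
}

#' Combined multi-SNV heteroplasmy calls
#'
#' Combines WT and mutant base calls across all oriented panel sites to
#' increase effective coverage: per cell, the focal-haplotype fraction is
#' `h = sum_s f_s / sum_s (ref_s + alt_s)` where `f_s = alt_s` at cis
#' sites and `f_s = ref_s` at trans sites. Cells with zero combined depth
#' are omitted. All panel sites must be oriented cis or trans;
#' `unknown` sites raise an error (drop them or run
#' [infer_orientations()] first).
#'
#' @inheritParams infer_orientations
#' @return Data frame with columns `cell_barcode`, `heteroplasmy`,
#'   `combined_depth`.
#' @export
combined_heteroplasmy <- function(counts, panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  sites <- panel$sites
  if (any(sites$orientation == "unknown")) {
    .stopf("panel has sites with unknown orientation (positions %s)",
           paste(sites$position[sites$orientation == "unknown"],
                 collapse = ", "))
  }
  extra <- setdiff(unique(counts$position), sites$position)
  if (length(extra)) {
    .stopf("counts contain positions absent from the panel: %s",
           paste(extra, collapse = ", "))
  }
  orient <- sites$orientation[match(counts$position, sites$position)]
  focal_reads <- ifelse(orient == "cis", counts$alt_count, counts$ref_count)
  depth <- counts$ref_count + counts$alt_count
  num <- tapply(focal_reads, counts$cell_barcode, sum)
  den <- tapply(depth, counts$cell_barcode, sum)
  keep <- den > 0
  out <- data.frame(cell_barcode = names(den)[keep],
                    heteroplasmy = as.numeric(num[keep] / den[keep]),
                    combined_depth = as.integer(den[keep]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter heteroplasmy calls by combined read depth
#'
#' Retains cells whose combined depth across the panel sites reaches the
#' minimum (inclusive; the conventional confidence cutoff is 20 reads).
#'
#' @param calls Data frame from [combined_heteroplasmy()].
#' @param min_depth Minimum combined depth (default 20).
#' @return Filtered data frame.
#' @export
filter_by_combined_depth <- function(calls, min_depth = 20) {
  calls[calls$combined_depth >= min_depth, , drop = FALSE]
}

#' Pairwise haplotype concordance from long reads
#'
#' Given per-read oriented allele calls (1 = mutant haplotype allele, 0 =
#' WT) at the panel positions, computes for every position pair the
#' percentage of reads covering both positions whose alleles agree (both
#' mutant or both WT) — i.e. match one of the two linked haplotypes.
#'
#' @param read_alleles Data frame with columns `read_id`, `position`,
#'   `allele` (0/1), alleles already oriented to the focal haplotype.
#' @return Data frame with columns `pos1`, `pos2`, `n_reads`,
#'   `concordance_pct`. Reads covering fewer than two positions
#'   contribute to no pair.
#' @export
longread_haplotype_concordance <- function(read_alleles) {
  if (!all(c("read_id", "position", "allele") %in% names(read_alleles))) {
    .stopf("read allele table needs columns read_id, position, allele")
  }
  if (nrow(read_alleles) &&
      !all(read_alleles$allele %in% c(0, 1))) {
    .stopf("alleles must be binary (0 = WT, 1 = mutant)")
  }
  positions <- sort(unique(read_alleles$position))
  # wide matrix: reads x positions, NA where not covered
  m <- matrix(NA_real_, nrow = length(unique(read_alleles$read_id)),
              ncol = length(positions),
              dimnames = list(unique(read_alleles$read_id), positions))
  m[cbind(match(read_alleles$read_id, rownames(m)),
          match(read_alleles$position, positions))] <- read_alleles$allele
  pairs <- if (length(positions) >= 2) utils::combn(length(positions), 2)
           else matrix(integer(), nrow = 2)
  res <- apply(pairs, 2, function(ij) {
    a <- m[, ij[1]]; b <- m[, ij[2]]
    keep <- !is.na(a) & !is.na(b)
    n <- sum(keep)
    data.frame(pos1 = positions[ij[1]], pos2 = positions[ij[2]],
               n_reads = n,
               concordance_pct = if (n) 100 * mean(a[keep] == b[keep])
                                 else NA_real_)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(pos1 = integer(), pos2 = integer(),
                      n_reads = integer(), concordance_pct = numeric())
  }
  rownames(out) <- NULL
  out
}
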