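# Synthetic perturbation-screen cohorts with known ground truth. The
# generator emulates the data layout the analysis consumes: a guide
# library with target genes, per-cell latent heteroplasmy and mtDNA copy
# number, panel allele counts whose depth is proportional to copy
# number, coverage profiles, cell-cycle phase/pseudotime, guide reads
# and long reads.

#' Default linked-SNV panel for a heteroplasmic mouse cohort
#'
#' Seven linked heteroplasmic SNVs on the mouse mitochondrial genome:
#' the focal pathogenic m.5024C>T tRNA-Ala variant plus m.13715C>T on
#' the same haplotype (cis), and five variants on the opposing haplotype
#' (trans).
#'
#' @return A [haplotype_panel()].
#' @export
default_panel <- function() {
  haplotype_panel(
    sites = data.frame(
      position = c(5024L, 13715L, 1781L, 1866L, 3009L, 3823L, 13614L),
      ref = c("C", "C", "C", "A", "G", "T", "C"),
      alt = c("T", "T", "T", "G", "T", "C", "T"),
      orientation = c("cis", "cis", "trans", "trans", "trans", "trans",
                      "trans"),
      stringsAsFactors = FALSE),
    focal_position = 5024L)
}

#' Default guide library for synthetic cohorts
#'
#' A small pooled library: three guides per target gene for a few mtDNA
#' maintenance genes plus nontargeting (NT) controls.
#'
#' @param genes Target gene names (default a depletion-relevant trio
#'   plus two inert targets).
#' @param guides_per_gene Guides per gene (default 3).
#' @param n_nt Number of nontargeting guides (default 3).
#' @return Data frame with columns `guide_id`, `target_gene`.
#' @export
default_guide_library <- function(genes = c("Tfam", "Opa1", "Polg",
                                            "Akap1", "Nnt"),
                                  guides_per_gene = 3, n_nt = 3) {
  lib <- data.frame(
    guide_id = c(unlist(lapply(genes, function(g)
      sprintf("%s-%d", g, seq_len(guides_per_gene)))),
      sprintf("NT-%d", seq_len(n_nt))),
    target_gene = c(rep(genes, each = guides_per_gene),
                    rep("NT", n_nt)),
    stringsAsFactors = FALSE)
  lib
}

# Cell-cycle coverage factor: linear in pseudotime, mean 1 over [0, 2pi).
#' @keywords internal
.cycle_factor <- function(pseudotime) {
  (2 / 3) * (1 + pseudotime / (2 * pi))
}

#' Generate a synthetic perturbation-screen cohort
#'
#' Per cell: a guide is drawn uniformly from the library; the latent
#' mtDNA copy number is `base_cn * depletion_factor(target gene) *`
#' lognormal noise `*` a cell-cycle factor increasing linearly in
#' pseudotime; the latent heteroplasmy is Normal(`het_mean`, `het_sd`)
#' clipped to `[0, 1]` with identical expectation in every group; the
#' combined panel read depth is Poisson(`depth_per_cn * copy number`),
#' split across panel sites by a fixed weight vector; per-site
#' alternate-allele counts are Binomial(site depth, h) at cis sites and
#' Binomial(site depth, 1 - h) at trans sites (the alternate allele of a
#' trans site lies on the non-focal haplotype); mean mtDNA coverage is
#' proportional to copy number.
#'
#' @param n_cells Number of cells.
#' @param guide_library Data frame with `guide_id`, `target_gene`
#'   (default [default_guide_library()]).
#' @param depletion_map Named numeric vector of copy-number depletion
#'   factors in (0, 1] keyed by target gene; genes absent from the map
#'   get factor 1. Every name must be a library target gene.
#' @param het_mean,het_sd Latent heteroplasmy mean and s.d. (defaults
#'   0.582 and 0.113).
#' @param base_cn Baseline mtDNA copy number (default 1750).
#' @param panel A [haplotype_panel()] with orientations set (default
#'   [default_panel()]).
#' @param depth_per_cn Combined panel reads per mtDNA copy (default
#'   60/1750, giving ~60x combined depth at baseline copy number).
#' @param cov_per_cn Mean mtDNA coverage per copy (default 60/1750).
#' @param cn_sdlog Lognormal sdlog of copy-number noise (default 0.35).
#' @param site_weights Multinomial weights splitting depth across panel
#'   sites (default equal).
#' @param seed Optional RNG seed; all stage randomness derives from it.
#' @return List of class `cohort` with elements `counts` (cell x site
#'   allele counts, long format), `coverage`, `metadata`, `truth` and
#'   `panel`.
#' @export
generate_cohort <- function(n_cells, guide_library = default_guide_library(),
                            depletion_map = c(Tfam = 0.25, Opa1 = 0.5,
                                              Polg = 0.4),
                            het_mean = 0.582, het_sd = 0.113,
                            base_cn = 1750, panel = default_panel(),
                            depth_per_cn = 60 / 1750,
                            cov_per_cn = 60 / 1750,
                            cn_sdlog = 0.35, site_weights = NULL,
                            seed = NULL) {
  n_cells <- .check_count(n_cells, "n_cells", min = 1)
  stopifnot(inherits(panel, "haplotype_panel"))
  if (any(panel$sites$orientation == "unknown")) {
    .stopf("panel orientations must be set before simulation")
  }
  unknown <- setdiff(names(depletion_map), guide_library$target_gene)
  if (length(unknown)) {
    .stopf("depletion_map names not in the guide library: %s",
           paste(unknown, collapse = ", "))
  }
  if (length(depletion_map) &&
      any(depletion_map <= 0 | depletion_map > 1)) {
    .stopf("depletion factors must lie in (0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)

  n_sites <- nrow(panel$sites)
  if (is.null(site_weights)) site_weights <- rep(1 / n_sites, n_sites)
  site_weights <- site_weights / sum(site_weights)

  barcode <- sprintf("cell%05d", seq_len(n_cells))
  gi <- sample.int(nrow(guide_library), n_cells, replace = TRUE)
  guide_id <- guide_library$guide_id[gi]
  target_gene <- guide_library$target_gene[gi]
  if (is.null(depletion_map)) depletion_map <- numeric(0)
  depl <- unname(ifelse(target_gene %in% names(depletion_map),
                        depletion_map[target_gene], 1))
  pseudotime <- stats::runif(n_cells, 0, 2 * pi)
  phase <- cut(pseudotime, c(0, 0.5 * pi, pi, 2 * pi),
               labels = c("G1", "S", "G2M"), include.lowest = TRUE)
  true_cn <- base_cn * depl *
    stats::rlnorm(n_cells, meanlog = -cn_sdlog^2 / 2, sdlog = cn_sdlog) *
    .cycle_factor(pseudotime)
  true_h <- pmin(1, pmax(0, stats::rnorm(n_cells, het_mean, het_sd)))
  isr_activation <- pmax(0, 1 - depl)

  total_depth <- stats::rpois(n_cells, depth_per_cn * true_cn)
  # split depth across sites, then draw oriented allele counts
  site_depth <- matrix(0L, nrow = n_cells, ncol = n_sites)
  has_depth <- total_depth > 0
  if (any(has_depth)) {
    site_depth[has_depth, ] <- t(vapply(
      which(has_depth),
      function(i) stats::rmultinom(1, total_depth[i], site_weights)[, 1],
      integer(n_sites)))
  }
  is_cis <- panel$sites$orientation == "cis"
  p_alt <- outer(true_h, rep(1, n_sites))
  p_alt[, !is_cis] <- 1 - p_alt[, !is_cis]
  alt <- matrix(stats::rbinom(n_cells * n_sites,
                              size = as.vector(site_depth),
                              prob = as.vector(p_alt)),
                nrow = n_cells)
  ref <- site_depth - alt

  counts <- data.frame(
    cell_barcode = rep(barcode, times = n_sites),
    position = rep(panel$sites$position, each = n_cells),
    ref_count = as.integer(ref),
    alt_count = as.integer(alt),
    stringsAsFactors = FALSE)
  counts <- counts[counts$ref_count + counts$alt_count > 0, , drop = FALSE]
  counts <- counts[order(counts$cell_barcode, counts$position), ,
                   drop = FALSE]
  rownames(counts) <- NULL

  mean_cov <- cov_per_cn * true_cn
  coverage <- data.frame(
    cell_barcode = barcode,
    total_mt_bases = as.integer(round(mean_cov * panel$genome_length)),
    nuclear_fragments = as.integer(stats::rpois(n_cells, 10000)),
    stringsAsFactors = FALSE)

  metadata <- data.frame(
    cell_barcode = barcode, guide_id = guide_id,
    target_gene = target_gene,
    phase = as.character(phase), pseudotime = pseudotime,
    stringsAsFactors = FALSE)

  truth <- data.frame(
    cell_barcode = barcode, true_h = true_h, true_cn = true_cn,
    guide_id = guide_id, target_gene = target_gene,
    depletion_factor = depl, isr_activation = isr_activation,
    phase = as.character(phase), pseudotime = pseudotime,
    stringsAsFactors = FALSE)

  structure(list(counts = counts, coverage = coverage,
                 metadata = metadata, truth = truth, panel = panel,
                 params = list(n_cells = n_cells, het_mean = het_mean,
                               het_sd = het_sd, base_cn = base_cn,
                               depth_per_cn = depth_per_cn,
                               cov_per_cn = cov_per_cn)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d cells, %d panel sites, %d guide(s)\n",
              x$params$n_cells, nrow(x$panel$sites),
              length(unique(x$metadata$guide_id))))
  invisible(x)
}

#' Generate barcoded guide reads for a cohort
#'
#' Per cell, a Poisson number of reads from the cell's true guide plus
#' ambient reads carrying uniformly random guides; mapping quality is
#' drawn from the supplied distribution, so a controllable fraction of
#' reads falls below the MAPQ filter.
#'
#' @param metadata Cohort metadata (columns `cell_barcode`, `guide_id`).
#' @param reads_per_cell_mean Mean total guide reads per cell (default
#'   6).
#' @param ambient_rate Expected fraction of ambient reads in `[0, 1)`
#'   (default 0.05).
#' @param mapq_values Pool of MAPQ values reads are drawn from (default
#'   90% at 60, 10% at 10).
#' @param guide_pool Guides ambient reads are drawn from (default: all
#'   guides in `metadata`).
#' @param seed Optional RNG seed.
#' @return Data frame of guide read records (`cell_barcode`, `guide_id`,
#'   `mapq`, `umi`, `read_id`).
#' @export
generate_guide_reads <- function(metadata, reads_per_cell_mean = 6,
                                 ambient_rate = 0.05,
                                 mapq_values = c(rep(60L, 9), 10L),
                                 guide_pool = NULL, seed = NULL) {
  .check_fraction(ambient_rate, "ambient_rate", open_upper = TRUE)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(guide_pool)) guide_pool <- unique(metadata$guide_id)
  n <- nrow(metadata)
  n_true <- stats::rpois(n, reads_per_cell_mean * (1 - ambient_rate))
  n_amb <- stats::rpois(n, reads_per_cell_mean * ambient_rate)
  cb <- c(rep(metadata$cell_barcode, n_true),
          rep(metadata$cell_barcode, n_amb))
  gid <- c(rep(metadata$guide_id, n_true),
           sample(guide_pool, sum(n_amb), replace = TRUE))
  n_reads <- length(cb)
  out <- data.frame(
    cell_barcode = cb, guide_id = gid,
    mapq = mapq_values[sample.int(length(mapq_values), n_reads,
                                  replace = TRUE)],
    umi = sprintf("UMI%07d", sample.int(10^7, n_reads, replace = TRUE)),
    read_id = sprintf("read%08d", seq_len(n_reads)),
    stringsAsFactors = FALSE)
  out <- out[order(out$cell_barcode), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Generate synthetic long reads over the panel positions
#'
#' Each read is a full mutant haplotype with probability `true_h` and a
#' full WT haplotype otherwise; each position is then flipped
#' independently with probability `recombination_rate`. Alleles are
#' emitted in the focal-haplotype orientation (mutant = 1).
#'
#' @param n_reads Number of long reads.
#' @param true_h Mutant-haplotype fraction in `[0, 1]`.
#' @param panel A [haplotype_panel()].
#' @param recombination_rate Per-position flip probability in `[0, 1]`
#'   (default 0).
#' @param seed Optional RNG seed.
#' @return Data frame with columns `read_id`, `position`, `allele`.
#' @export
generate_longreads <- function(n_reads, true_h, panel,
                               recombination_rate = 0, seed = NULL) {
  n_reads <- .check_count(n_reads, "n_reads", min = 0)
  .check_fraction(true_h, "true_h")
  .check_fraction(recombination_rate, "recombination_rate")
  if (!is.null(seed)) set.seed(seed)
  positions <- panel$sites$position
  if (n_reads == 0) {
    return(data.frame(read_id = character(), position = integer(),
                      allele = integer(), stringsAsFactors = FALSE))
  }
  hap <- stats::rbinom(n_reads, 1, true_h)
  allele <- matrix(rep(hap, length(positions)), nrow = n_reads)
  flip <- matrix(stats::rbinom(n_reads * length(positions), 1,
                               recombination_rate) == 1,
                 nrow = n_reads)
  allele[flip] <- 1 - allele[flip]
  data.frame(
    read_id = rep(sprintf("lr%06d", seq_len(n_reads)),
                  times = length(positions)),
    position = rep(positions, each = n_reads),
    allele = as.integer(allele),
    stringsAsFactors = FALSE)
}

#' Generate a baseline expression matrix with an ISR module
#'
#' Simple negative-binomial expression baseline for testing the response
#' statistics: gene means are lognormal; a designated module of
#' stress-response (ISR-like) genes is scaled up in cells whose target
#' gene depletes mtDNA, proportional to the cell's ISR activation; a
#' second module tracks mtDNA copy number so that covariate
#' residualization has signal to remove. Counts are log-normalized
#' (log1p of counts per 10k).
#'
#' @param truth Cohort `truth` table from [generate_cohort()].
#' @param n_genes Total genes (default 300).
#' @param n_isr Size of the ISR module (default 30).
#' @param n_cn Size of the copy-number-tracking module (default 30).
#' @param dispersion NB size parameter (default 2).
#' @param seed Optional RNG seed.
#' @return List with `logcounts` (cell x gene matrix) and `gene_info`
#'   (data frame flagging module membership).
#' @export
generate_expression <- function(truth, n_genes = 300, n_isr = 30,
                                n_cn = 30, dispersion = 2, seed = NULL) {
  if (n_isr + n_cn > n_genes) {
    .stopf("module sizes n_isr + n_cn (%d) exceed n_genes (%d)",
           n_isr + n_cn, n_genes)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(truth)
  base_mu <- stats::rlnorm(n_genes, meanlog = 1.5, sdlog = 1)
  module <- rep("baseline", n_genes)
  module[seq_len(n_isr)] <- "isr"
  module[n_isr + seq_len(n_cn)] <- "cn"
  cn_rel <- truth$true_cn / mean(truth$true_cn)
  mu <- outer(rep(1, n), base_mu)
  mu[, module == "isr"] <- mu[, module == "isr"] *
    (1 + 2 * truth$isr_activation)
  mu[, module == "cn"] <- mu[, module == "cn"] * cn_rel
  counts <- matrix(stats::rnbinom(n * n_genes, mu = as.vector(mu),
                                  size = dispersion), nrow = n)
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  logcounts <- log1p(counts / lib * 1e4)
  dimnames(logcounts) <- list(truth$cell_barcode,
                              sprintf("gene%04d", seq_len(n_genes)))
  list(logcounts = logcounts,
       gene_info = data.frame(gene = colnames(logcounts),
                              module = module,
                              stringsAsFactors = FALSE))
}
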