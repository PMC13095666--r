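#' Mean per-cell mtDNA coverage
#'
#' Relative mtDNA copy number is proxied by the mean deduplicated coverage
#' of the mitochondrial genome: total aligned mtDNA bases divided by the
#' genome length. Deliberately not normalized to total ATAC signal, so
#' that cell-cycle-linked coverage trends remain visible; see
#' [normalized_mtdna_coverage()] for an optional normalized value.
#'
#' @param depth Either a per-base depth vector or a single total base
#'   count.
#' @param genome_length Mitochondrial genome length (default 16299,
#'   mouse).
#' @return Mean coverage (a nonnegative fraction).
#' @export
#' @examples
#' mean_mtdna_coverage(162990, 16299)   # 10x
mean_mtdna_coverage <- function(depth, genome_length = 16299) {
  if (genome_length <= 0) .stopf("'genome_length' must be positive")
  if (any(depth < 0)) .stopf("negative depth values")
  sum(as.numeric(depth)) / genome_length
}

#' Coverage normalized to nuclear signal
#'
#' Companion to [mean_mtdna_coverage()]: mtDNA coverage divided by the
#' per-cell nuclear fragment count, for analyses where library-size
#' differences should be removed.
#'
#' @param mean_coverage Per-cell mean mtDNA coverage.
#' @param nuclear_fragments Per-cell nuclear ATAC fragment counts.
#' @return `mean_coverage / nuclear_fragments`, `NA` where fragments are 0.
#' @export
normalized_mtdna_coverage <- function(mean_coverage, nuclear_fragments) {
  ifelse(nuclear_fragments > 0, mean_coverage / nuclear_fragments,
         NA_real_)
}

#' Fold change in coverage after mtDNA enrichment
#'
#' @param cov_pre,cov_post Mean coverage before and after enrichment.
#' @return `cov_post / cov_pre`; `NA` where `cov_pre == 0` (such cells are
#'   flagged, not dropped). Vectorized.
#' @export
enrichment_fold_change <- function(cov_pre, cov_post) {
  if (any(cov_pre < 0) || any(cov_post < 0)) {
    .stopf("coverage values must be nonnegative")
  }
  ifelse(cov_pre > 0, cov_post / cov_pre, NA_real_)
}

#' Pairwise group comparison of mtDNA coverage
#'
#' Compares per-cell mean mtDNA coverage between every pair of groups with
#' two-sided Welch t-tests and Bonferroni correction across pairs.
#' Coverage is optionally log10-transformed first; zero-coverage cells
#' then receive a pseudo-floor of half the smallest nonzero coverage.
#'
#' @param coverage Numeric vector of per-cell mean coverage.
#' @param groups Group label per cell.
#' @param log10_transform Compare on the log10 scale (default `TRUE`).
#' @return List with `tests` (data frame: `group1`, `group2`, `t`, `df`,
#'   `p`, `p_adj`) and `groups` (per-group n, mean and median of the raw
#'   coverage). Groups with fewer than 2 cells are excluded with a
#'   warning.
#' @export
compare_group_depths <- function(coverage, groups, log10_transform = TRUE) {
  stopifnot(length(coverage) == length(groups))
  if (any(coverage < 0)) .stopf("coverage values must be nonnegative")
  groups <- as.character(groups)
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    .warnf("excluding group(s) with < 2 cells: %s",
           paste(small, collapse = ", "))
    keep <- !groups %in% small
    coverage <- coverage[keep]; groups <- groups[keep]
  }
  lv <- sort(unique(groups))
  if (length(lv) < 2) .stopf("need at least 2 groups with >= 2 cells")
  x <- coverage
  if (log10_transform) {
    if (any(x == 0)) {
      floor_val <- min(x[x > 0]) / 2
      x[x == 0] <- floor_val
    }
    x <- log10(x)
  }
  pairs <- utils::combn(lv, 2)
  n_pairs <- ncol(pairs)
  tests <- do.call(rbind, lapply(seq_len(n_pairs), function(k) {
    g1 <- pairs[1, k]; g2 <- pairs[2, k]
    tt <- stats::t.test(x[groups == g1], x[groups == g2],
                        var.equal = FALSE)
    data.frame(group1 = g1, group2 = g2,
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value,
               p_adj = min(1, tt$p.value * n_pairs),
               stringsAsFactors = FALSE)
  }))
  summ <- do.call(rbind, lapply(lv, function(g) {
    v <- coverage[groups == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               median = stats::median(v), stringsAsFactors = FALSE)
  }))
  list(tests = tests, groups = summ)
}
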