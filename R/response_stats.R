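#' Residualize expression against mtDNA copy number
#'
#' Fits, for every gene i, the linear model
#' `expression_i = beta0 + beta1 * covariate + epsilon` by ordinary least
#' squares and returns the residuals as covariate-adjusted expression.
#' With a constant covariate the fit degenerates to intercept-only
#' (residual = value - gene mean) with a warning.
#'
#' @param expr Numeric cell x gene matrix of normalized expression.
#' @param covariate Per-cell mtDNA copy number (or any numeric
#'   covariate); length `nrow(expr)`, all finite.
#' @param log10_covariate Use `log10(covariate)` instead of the linear
#'   scale (default `FALSE`).
#' @return List of class `residual_model` with `beta0`, `beta1` (per
#'   gene) and `residuals` (cell x gene matrix).
#' @export
residualize_expression <- function(expr, covariate,
                                   log10_covariate = FALSE) {
  expr <- as.matrix(expr)
  if (nrow(expr) < 3) .stopf("need at least 3 cells")
  if (length(covariate) != nrow(expr)) {
    .stopf("covariate length (%d) must match the cell count (%d)",
           length(covariate), nrow(expr))
  }
  if (any(!is.finite(covariate))) .stopf("covariate must be finite")
  if (log10_covariate) {
    if (any(covariate <= 0)) {
      .stopf("log10 covariate requires positive values")
    }
    covariate <- log10(covariate)
  }
  if (stats::sd(covariate) == 0) {
    .warnf("constant covariate; falling back to intercept-only residuals")
    mu <- colMeans(expr)
    res <- sweep(expr, 2, mu)
    return(structure(list(beta0 = mu,
                          beta1 = rep(0, ncol(expr)),
                          residuals = res, covariate = covariate),
                     class = "residual_model"))
  }
  X <- cbind(1, covariate)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, expr)          # 2 x genes
  res <- qr.resid(qrX, expr)
  structure(list(beta0 = coefs[1, ], beta1 = coefs[2, ],
                 residuals = res, covariate = covariate),
            class = "residual_model")
}

#' Select the most variable genes
#'
#' Ranks genes by the sample variance of their (residualized) expression
#' and keeps the top k. Ties at the cutoff are broken by gene identifier
#' order, so the selection is deterministic.
#'
#' @param mat Cell x gene matrix (typically residuals from
#'   [residualize_expression()]); must have column names.
#' @param k Number of genes to keep (default 2000). If fewer genes are
#'   available, all are kept with a warning.
#' @return The column subset of `mat` for the selected genes, in
#'   decreasing-variance order.
#' @export
select_top_variable <- function(mat, k = 2000) {
  k <- .check_count(k, "k", min = 1)
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) {
    colnames(mat) <- sprintf("gene%d", seq_len(ncol(mat)))
  }
  v <- .col_vars(mat)
  if (k > ncol(mat)) {
    .warnf("k = %d exceeds the %d available genes; keeping all", k,
           ncol(mat))
    k <- ncol(mat)
  }
  ord <- order(-v, colnames(mat))
  mat[, ord[seq_len(k)], drop = FALSE]
}

#' Principal component scores with a fixed sign convention
#'
#' Eigen-decomposition of the (centered, optionally unit-scaled)
#' covariance of a cell x gene matrix. Loadings are unit-norm and the
#' sign of each component is fixed so that its largest-magnitude loading
#' entry is positive. Zero-variance genes are dropped (with a warning)
#' when scaling is requested.
#'
#' @param mat Cell x gene numeric matrix; >= 2 cells and >= 2 genes.
#' @param n_components Number of components to return (default
#'   `min(dim)`).
#' @param center,scale. Center and unit-scale genes before decomposition
#'   (defaults `TRUE`).
#' @return List of class `pc_result` with `loadings` (gene x component),
#'   `scores` (cell x component) and `explained_variance`.
#' @export
pc_scores <- function(mat, n_components = NULL, center = TRUE,
                      scale. = TRUE) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2 || ncol(mat) < 2) {
    .stopf("need at least 2 cells and 2 genes")
  }
  if (scale.) {
    v <- .col_vars(mat)
    if (any(v == 0)) {
      .warnf("dropping %d zero-variance gene(s) before scaling",
             sum(v == 0))
      mat <- mat[, v > 0, drop = FALSE]
      if (ncol(mat) < 2) .stopf("fewer than 2 genes left after dropping")
    }
  }
  p <- stats::prcomp(mat, center = center, scale. = scale.)
  nc <- if (is.null(n_components)) ncol(p$rotation)
        else min(n_components, ncol(p$rotation))
  load <- p$rotation[, seq_len(nc), drop = FALSE]
  scores <- p$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i_max <- which.max(abs(load[, j]))
    if (load[i_max, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(loadings = load, scores = scores,
                 explained_variance = p$sdev[seq_len(nc)]^2),
            class = "pc_result")
}

#' Compare PC1 scores between perturbation groups and a reference
#'
#' Each group is compared to the reference group with a two-sided
#' rank-based test (Wilcoxon rank-sum for independent groups; set
#' `paired = TRUE` for the signed-rank test on paired scores), with
#' Benjamini-Hochberg adjustment across groups. Groups smaller than 3
#' cells are skipped with a warning.
#'
#' @param scores Per-cell PC1 score.
#' @param groups Group label per cell.
#' @param reference Reference group label (must be nonempty).
#' @param paired Use the paired signed-rank test (default `FALSE`).
#' @return Data frame with columns `group`, `n`, `median_diff`, `p`,
#'   `p_adj`.
#' @export
compare_pc1_groups <- function(scores, groups, reference,
                               paired = FALSE) {
  stopifnot(length(scores) == length(groups))
  groups <- as.character(groups)
  ref <- scores[groups == reference]
  if (!length(ref)) .stopf("reference group '%s' is empty", reference)
  others <- setdiff(unique(groups), reference)
  rows <- lapply(sort(others), function(g) {
    x <- scores[groups == g]
    if (length(x) < 3) {
      .warnf("group '%s' has < 3 cells; skipped", g)
      return(NULL)
    }
    wt <- if (paired) {
      if (length(x) != length(ref)) {
        .warnf("group '%s' not the same size as reference; skipped", g)
        return(NULL)
      }
      suppressWarnings(stats::wilcox.test(x, ref, paired = TRUE))
    } else {
      suppressWarnings(stats::wilcox.test(x, ref))
    }
    data.frame(group = g, n = length(x),
               median_diff = stats::median(x) - stats::median(ref),
               p = wt$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) .stopf("no comparable groups")
  out$p_adj <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}

#' Cell-cycle phase composition test per group
#'
#' For each perturbation group, tests whether its distribution over
#' cell-cycle phases (G1/S/G2M) differs from all other cells with a
#' two-sided chi-squared test on the 2 x 3 contingency table,
#' Benjamini-Hochberg adjusted across groups. Rows where any expected
#' count falls below 1 carry a warning flag.
#'
#' @param phases Per-cell phase label, from `{"G1", "S", "G2M"}`.
#' @param groups Per-cell group label.
#' @return Data frame with per-group phase proportions, `chisq`, `df`,
#'   `p`, `p_adj` and `low_expected` flag.
#' @export
phase_composition_test <- function(phases, groups) {
  stopifnot(length(phases) == length(groups))
  lv <- c("G1", "S", "G2M")
  if (!all(phases %in% lv)) {
    .stopf("phases must be one of %s", paste(lv, collapse = ", "))
  }
  phases <- factor(phases, levels = lv)
  groups <- as.character(groups)
  rows <- lapply(sort(unique(groups)), function(g) {
    ing <- groups == g
    tab <- rbind(table(phases[ing]), table(phases[!ing]))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    props <- as.numeric(tab[1, ] / sum(tab[1, ]))
    data.frame(group = g, n = sum(ing),
               prop_G1 = props[1], prop_S = props[2], prop_G2M = props[3],
               chisq = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, low_expected = any(exp_counts < 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  if (any(out$low_expected)) {
    .warnf("expected count < 1 in group(s): %s",
           paste(out$group[out$low_expected], collapse = ", "))
  }
  rownames(out) <- NULL
  out
}

#' mtDNA coverage trend over cell-cycle phase or pseudotime
#'
#' Per-phase mean coverage with a one-way ANOVA p-value and, when a
#' pseudotime in `[0, 2*pi)` is supplied, per-bin mean coverage over
#' equal-width pseudotime bins.
#'
#' @param coverage Per-cell mean mtDNA coverage.
#' @param phase Optional per-cell phase label (needs >= 2 phases for the
#'   ANOVA; empty phases are dropped).
#' @param pseudotime Optional per-cell cell-cycle position in
#'   `[0, 2*pi)`.
#' @param n_pseudo_bins Number of equal-width pseudotime bins (default
#'   20).
#' @return List with `phase_means` (data frame) and `anova_p` when phase
#'   is given, and `pseudotime_bins` (data frame of bin midpoints and
#'   mean coverage) when pseudotime is given.
#' @export
coverage_phase_trend <- function(coverage, phase = NULL,
                                 pseudotime = NULL, n_pseudo_bins = 20) {
  out <- list()
  if (!is.null(phase)) {
    phase <- as.character(phase)
    keep <- !is.na(phase)
    ph <- phase[keep]; cv <- coverage[keep]
    lv <- unique(ph)
    if (length(lv) < 2) .stopf("need >= 2 cell-cycle phases")
    out$phase_means <- do.call(rbind, lapply(sort(lv), function(p) {
      data.frame(phase = p, n = sum(ph == p), mean_coverage =
                   mean(cv[ph == p]), stringsAsFactors = FALSE)
    }))
    out$anova_p <- stats::oneway.test(cv ~ factor(ph),
                                      var.equal = TRUE)$p.value
  }
  if (!is.null(pseudotime)) {
    if (any(pseudotime < 0 | pseudotime >= 2 * pi)) {
      .stopf("pseudotime must lie in [0, 2*pi)")
    }
    breaks <- seq(0, 2 * pi, length.out = n_pseudo_bins + 1)
    bin <- cut(pseudotime, breaks, include.lowest = TRUE,
               labels = FALSE)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    out$pseudotime_bins <- data.frame(
      bin = seq_len(n_pseudo_bins),
      midpoint = mids,
      n = as.integer(tabulate(bin, n_pseudo_bins)),
      mean_coverage = vapply(seq_len(n_pseudo_bins), function(b) {
        if (any(bin == b)) mean(coverage[bin == b]) else NA_real_
      }, 1))
  }
  if (!length(out)) .stopf("supply 'phase' and/or 'pseudotime'")
  out
}
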