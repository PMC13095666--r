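#' Brown-Forsythe test for equality of group variances
#'
#' Robust variance-equality test: each observation is transformed to its
#' absolute deviation from the group median and a one-way ANOVA F test is
#' run on the transformed values. The statistic W equals that F, with
#' (k - 1, N - k) degrees of freedom. When every transformed value is 0
#' (all groups constant), W = 0 and p = 1.
#'
#' @param groups List of at least two numeric vectors, each with at least
#'   two values.
#' @return List with `W`, `df` (length-2), and `p`.
#' @export
#' @examples
#' brown_forsythe_test(list(rnorm(30), rnorm(30, sd = 3)))
brown_forsythe_test <- function(groups) {
  if (!is.list(groups) || length(groups) < 2) {
    .stopf("'groups' must be a list of >= 2 numeric vectors")
  }
  if (any(vapply(groups, length, 1L) < 2)) {
    .stopf("every group needs >= 2 values")
  }
  z <- lapply(groups, function(g) abs(g - stats::median(g)))
  k <- length(z)
  n_i <- vapply(z, length, 1L)
  n <- sum(n_i)
  zbar_i <- vapply(z, mean, 1)
  zbar <- sum(unlist(z)) / n
  ss_between <- sum(n_i * (zbar_i - zbar)^2)
  ss_within <- sum(vapply(z, function(v) sum((v - mean(v))^2), 1))
  df1 <- k - 1L
  df2 <- n - k
  if (ss_within == 0 && ss_between == 0) {
    return(list(W = 0, df = c(df1, df2), p = 1))
  }
  if (ss_within == 0) {
    return(list(W = Inf, df = c(df1, df2), p = 0))
  }
  W <- (ss_between / df1) / (ss_within / df2)
  list(W = W, df = c(df1, df2),
       p = stats::pf(W, df1, df2, lower.tail = FALSE))
}

#' Holm (step-down Bonferroni) adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "holm"`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, original order.
#' @export
holm_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    .stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "holm")
}

#' Benjamini-Hochberg (step-up) adjustment
#'
#' Thin validated wrapper over [stats::p.adjust()] with `method = "BH"`.
#'
#' @inheritParams holm_adjust
#' @return Adjusted p-values, original order.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    .stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Two-sided empirical p-value against a simulated null
#'
#' Add-one empirical p-value:
#' `p = min(1, 2 * min((1 + #{null <= obs}) / (S + 1),
#'                     (1 + #{null >= obs}) / (S + 1)))`.
#' The add-one correction keeps p strictly positive for any finite number
#' of simulations.
#'
#' @param null Numeric vector of null statistics (length S >= 1).
#' @param observed Observed statistic.
#' @return Empirical p in `(0, 1]`.
#' @export
empirical_two_sided_p <- function(null, observed) {
  s <- length(null)
  if (s < 1) .stopf("empty null distribution")
  lo <- (1 + sum(null <= observed)) / (s + 1)
  hi <- (1 + sum(null >= observed)) / (s + 1)
  min(1, 2 * min(lo, hi))
}

#' Closed-form expected variance of depth-sampled heteroplasmy
#'
#' Law-of-total-variance oracle for binomial read sampling of a latent
#' heteroplasmy h: `Var(h_hat) = Var(h) + E[h(1-h)] * E[1/n]`, where for
#' the plug-in moments `E[h(1-h)] = mean_h * (1 - mean_h) - true_var`.
#'
#' @param true_var Variance of the latent per-cell heteroplasmy.
#' @param mean_h Mean latent heteroplasmy, strictly inside (0, 1).
#' @param depths Vector of per-cell read depths (>= 1).
#' @return Expected sample variance of the depth-sampled heteroplasmy.
#' @export
expected_sampled_variance <- function(true_var, mean_h, depths) {
  .check_fraction(mean_h, "mean_h", open_lower = TRUE, open_upper = TRUE)
  if (true_var < 0) .stopf("'true_var' must be nonnegative")
  if (any(depths < 1)) .stopf("depths must be >= 1")
  true_var + (mean_h * (1 - mean_h) - true_var) * mean(1 / depths)
}

#' Depth-matched binomial bottleneck null for heteroplasmy variance
#'
#' Simulates the heteroplasmy variance expected in a knockdown (KD) group
#' if its cells had the control group's latent heteroplasmy distribution
#' but the KD group's read depths. Per simulation: `n_kd` control cells
#' are drawn without replacement; each is given a depth drawn with
#' replacement from `kd_depths`; a simulated alternative-allele count is
#' drawn as Binomial(depth, control cell's h); the simulated heteroplasmy
#' is count/depth and the sample variance across the `n_kd` cells is
#' recorded. The observed KD variance is then assessed against the null
#' distribution with a two-sided add-one empirical p-value.
#'
#' @param control_h Per-cell heteroplasmy of the control group.
#' @param kd_depths Per-cell combined read depths of the KD group (>= 1).
#' @param observed_variance Observed KD heteroplasmy variance; if `NULL`
#'   no p-value is computed.
#' @param n_kd Number of KD cells to emulate (default
#'   `length(kd_depths)`). Must not exceed the control pool size.
#' @param n_sims Number of simulations S (default 5000).
#' @param seed Optional RNG seed for reproducibility.
#' @return Object of class `bottleneck_null`: list with
#'   `null_variances`, `observed_variance`, `p_empirical`, `n_kd`,
#'   `n_sims`.
#' @export
simulate_bottleneck_null <- function(control_h, kd_depths,
                                     observed_variance = NULL,
                                     n_kd = length(kd_depths),
                                     n_sims = 5000, seed = NULL) {
  n_ctrl <- length(control_h)
  n_kd <- .check_count(n_kd, "n_kd", min = 2)
  n_sims <- .check_count(n_sims, "n_sims", min = 1)
  if (n_kd > n_ctrl) {
    .stopf("n_kd (%d) exceeds the control pool (%d cells)", n_kd, n_ctrl)
  }
  if (any(kd_depths < 1)) .stopf("KD depths must be >= 1")
  if (any(control_h < 0 | control_h > 1)) {
    .stopf("control heteroplasmy values must lie in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  # cells x sims index matrix; each column a without-replacement draw
  idx <- vapply(seq_len(n_sims),
                function(s) sample.int(n_ctrl, n_kd),
                integer(n_kd))
  h <- matrix(control_h[idx], nrow = n_kd)
  d <- matrix(sample(kd_depths, n_kd * n_sims, replace = TRUE),
              nrow = n_kd)
  sim_h <- matrix(stats::rbinom(n_kd * n_sims, size = as.vector(d),
                                prob = as.vector(h)) / as.vector(d),
                  nrow = n_kd)
  null_var <- .col_vars(sim_h)
  p <- if (is.null(observed_variance)) NA_real_
       else empirical_two_sided_p(null_var, observed_variance)
  structure(list(null_variances = null_var,
                 observed_variance = observed_variance,
                 p_empirical = p, n_kd = n_kd, n_sims = n_sims),
            class = "bottleneck_null")
}

#' @export
print.bottleneck_null <- function(x, ...) {
  cat(sprintf(
    "Bottleneck null: %d sims of %d cells; null var %.4g [%.4g, %.4g]\n",
    x$n_sims, x$n_kd, stats::median(x$null_variances),
    stats::quantile(x$null_variances, 0.025),
    stats::quantile(x$null_variances, 0.975)))
  if (!is.null(x$observed_variance)) {
    cat(sprintf("Observed variance %.4g, empirical p = %.4g\n",
                x$observed_variance, x$p_empirical))
  }
  invisible(x)
}

#' Aggregate cells into equal-count depth bins
#'
#' Sorts cells by depth and partitions them into `n_bins` contiguous bins
#' of (as near as possible) equal size, so that per-bin variance
#' estimates are stable. When the cell count is not divisible by
#' `n_bins`, the lowest-depth bins each receive one extra cell.
#'
#' @param depth,h Per-cell combined read depth and heteroplasmy.
#' @param n_bins Number of bins; requires at least `2 * n_bins` cells.
#' @return Data frame with columns `bin`, `n_cells`, `mean_depth`,
#'   `het_variance` (sample variance, n-1 denominator).
#' @export
bin_equal_count <- function(depth, h, n_bins) {
  stopifnot(length(depth) == length(h))
  n_bins <- .check_count(n_bins, "n_bins", min = 1)
  n <- length(depth)
  if (n < 2 * n_bins) {
    .stopf("need at least %d cells for %d bins (got %d)", 2 * n_bins,
           n_bins, n)
  }
  ord <- order(depth)
  depth <- depth[ord]; h <- h[ord]
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins)
  if (extra > 0) sizes[seq_len(extra)] <- base + 1L
  bin <- rep(seq_len(n_bins), times = sizes)
  data.frame(
    bin = seq_len(n_bins),
    n_cells = sizes,
    mean_depth = as.numeric(tapply(depth, bin, mean)),
    het_variance = as.numeric(tapply(h, bin, .sample_var)))
}

# Pinball (check) loss of residuals u at quantile level tau.
#' @keywords internal
.pinball_loss <- function(u, tau) sum(u * (tau - (u < 0)))

#' Quantile regression of variance on inverse depth
#'
#' Fits `Variance = beta0 + beta1 / depth` at each quantile level tau by
#' minimizing the pinball loss. With two parameters the minimizer
#' interpolates two observations, so the exact optimum is found by
#' enumerating all point pairs in (1/depth, variance) space and keeping
#' the candidate with the smallest loss (ties broken by the first pair in
#' enumeration order, which is deterministic).
#'
#' @param bins Data frame from [bin_equal_count()] (columns `mean_depth`,
#'   `het_variance`), or any data frame with those columns; at least 3
#'   rows, all depths positive and not all equal.
#' @param taus Quantile levels (default `c(0.05, 0.95)`).
#' @return Data frame with columns `tau`, `beta0`, `beta1`,
#'   `pinball_loss`.
#' @export
fit_depth_variance_quantiles <- function(bins, taus = c(0.05, 0.95)) {
  if (nrow(bins) < 3) .stopf("need at least 3 bins")
  d <- bins$mean_depth; v <- bins$het_variance
  if (any(d <= 0)) .stopf("depths must be positive")
  x <- 1 / d
  if (length(unique(x)) < 2) {
    .stopf("collinear design: all bin depths equal")
  }
  for (tau in taus) .check_fraction(tau, "tau", open_lower = TRUE,
                                    open_upper = TRUE)
  n <- length(x)
  pairs <- utils::combn(n, 2)
  out <- lapply(taus, function(tau) {
    best <- NULL
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (x[i] == x[j]) next
      b1 <- (v[i] - v[j]) / (x[i] - x[j])
      b0 <- v[i] - b1 * x[i]
      loss <- .pinball_loss(v - b0 - b1 * x, tau)
      if (is.null(best) || loss < best$pinball_loss - 1e-12) {
        best <- list(beta0 = b0, beta1 = b1, pinball_loss = loss)
      }
    }
    data.frame(tau = tau, beta0 = best$beta0, beta1 = best$beta1,
               pinball_loss = best$pinball_loss)
  })
  do.call(rbind, out)
}

#' Predict from a depth-variance quantile fit
#'
#' @param fit One row of the output of [fit_depth_variance_quantiles()],
#'   or a list with `beta0` and `beta1`.
#' @param depth Depths at which to evaluate the fitted curve.
#' @return `beta0 + beta1 / depth`.
#' @export
predict_depth_variance <- function(fit, depth) {
  fit$beta0 + fit$beta1 / depth
}

#' Bootstrap confidence band for the depth-variance quantile fit
#'
#' Resamples bins with replacement, refits each tau, and takes pointwise
#' 2.5/97.5 percentiles of the fitted curves on a depth grid. A bootstrap
#' replicate with a degenerate design (all resampled depths equal) is
#' redrawn, up to 10 attempts.
#'
#' @inheritParams fit_depth_variance_quantiles
#' @param n_boot Number of bootstrap iterations (default 200).
#' @param seed Optional RNG seed.
#' @param depth_grid Depths at which the band is evaluated (default: 50
#'   points spanning the observed bin depths).
#' @return List of class `bootstrap_band` with `depth_grid` and, per tau,
#'   a matrix `band` with rows `lower` and `upper`.
#' @export
bootstrap_variance_band <- function(bins, taus = c(0.05, 0.95),
                                    n_boot = 200, seed = NULL,
                                    depth_grid = NULL) {
  if (nrow(bins) < 3) .stopf("need at least 3 bins")
  n_boot <- .check_count(n_boot, "n_boot", min = 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(depth_grid)) {
    depth_grid <- seq(min(bins$mean_depth), max(bins$mean_depth),
                      length.out = 50)
  }
  n <- nrow(bins)
  curves <- lapply(taus, function(tau) {
    matrix(NA_real_, nrow = n_boot, ncol = length(depth_grid))
  })
  names(curves) <- as.character(taus)
  for (b in seq_len(n_boot)) {
    rep_bins <- NULL
    for (attempt in 1:10) {
      idx <- sample.int(n, n, replace = TRUE)
      cand <- bins[idx, , drop = FALSE]
      if (length(unique(cand$mean_depth)) >= 2) { rep_bins <- cand; break }
    }
    if (is.null(rep_bins)) {
      .stopf("degenerate bootstrap design after 10 redraws")
    }
    fit <- fit_depth_variance_quantiles(rep_bins, taus)
    for (t in seq_along(taus)) {
      curves[[t]][b, ] <- predict_depth_variance(fit[t, ], depth_grid)
    }
  }
  bands <- lapply(curves, function(cm) {
    rbind(lower = apply(cm, 2, stats::quantile, probs = 0.025),
          upper = apply(cm, 2, stats::quantile, probs = 0.975))
  })
  structure(list(depth_grid = depth_grid, taus = taus, bands = bands,
                 n_boot = n_boot),
            class = "bootstrap_band")
}

#' Simulate the accuracy of depth-limited heteroplasmy calls
#'
#' Draws a population of cells with latent heteroplasmy
#' `h ~ Normal(het_mean, het_sd)` clipped to `[0, 1]`, builds each cell's
#' pool of `copy_number` mtDNA molecules with `round(h * copy_number)`
#' mutant copies, and for each sample size draws that many molecules
#' without replacement (hypergeometric sampling) to obtain the sampled
#' heteroplasmy. Reports per sample size the least-squares regression of
#' sampled on true heteroplasmy with its R^2. Passing `depths` switches
#' to matched-population mode: each cell is instead sampled at a depth
#' drawn from the supplied empirical depth distribution (capped at the
#' copy number).
#'
#' @param n_cells Number of simulated cells (default 2000).
#' @param het_mean,het_sd Mean and s.d. of the latent heteroplasmy
#'   (defaults 0.582 and 0.113).
#' @param copy_number mtDNA copies per cell (default 1750).
#' @param sample_sizes Read depths at which to sample each cell (default
#'   `c(5, 20, 50, 100)`); ignored in matched mode.
#' @param depths Optional empirical depth distribution for matched mode.
#' @param seed Optional RNG seed.
#' @return List of class `sampling_accuracy` with `cells` (data frame of
#'   `true_h` plus one sampled column per sample size, or `sampled_h` and
#'   `depth` in matched mode) and `fits` (per sample size: `slope`,
#'   `intercept`, `r_squared`).
#' @export
simulate_sampling_accuracy <- function(n_cells = 2000, het_mean = 0.582,
                                       het_sd = 0.113, copy_number = 1750,
                                       sample_sizes = c(5, 20, 50, 100),
                                       depths = NULL, seed = NULL) {
  .check_fraction(het_mean, "het_mean", open_lower = TRUE,
                  open_upper = TRUE)
  if (het_sd < 0) .stopf("'het_sd' must be nonnegative")
  copy_number <- .check_count(copy_number, "copy_number", min = 1)
  if (is.null(depths) && any(sample_sizes > copy_number)) {
    .stopf("sample size exceeds the molecule pool (%d)", copy_number)
  }
  if (!is.null(seed)) set.seed(seed)
  true_h <- pmin(1, pmax(0, stats::rnorm(n_cells, het_mean, het_sd)))
  n_mut <- round(true_h * copy_number)
  cells <- data.frame(true_h = true_h)
  fits <- NULL
  if (is.null(depths)) {
    for (k in sample_sizes) {
      sampled <- stats::rhyper(n_cells, m = n_mut,
                               n = copy_number - n_mut, k = k) / k
      cells[[paste0("sampled_h_n", k)]] <- sampled
      fit <- stats::lm(sampled ~ true_h)
      fits <- rbind(fits, data.frame(
        sample_size = k,
        intercept = unname(stats::coef(fit)[1]),
        slope = unname(stats::coef(fit)[2]),
        r_squared = summary(fit)$r.squared))
    }
  } else {
    d <- pmin(copy_number,
              pmax(1, sample(depths, n_cells, replace = TRUE)))
    sampled <- stats::rhyper(n_cells, m = n_mut, n = copy_number - n_mut,
                             k = d) / d
    cells$depth <- d
    cells$sampled_h <- sampled
    fit <- stats::lm(sampled ~ true_h)
    fits <- data.frame(sample_size = NA_real_,
                       intercept = unname(stats::coef(fit)[1]),
                       slope = unname(stats::coef(fit)[2]),
                       r_squared = summary(fit)$r.squared)
  }
  structure(list(cells = cells, fits = fits,
                 params = list(n_cells = n_cells, het_mean = het_mean,
                               het_sd = het_sd,
                               copy_number = copy_number)),
            class = "sampling_accuracy")
}
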