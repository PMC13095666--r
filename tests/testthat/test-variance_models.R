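test_that("Brown-Forsythe equals ANOVA on |x - median| and handles degeneracy", {
  # identical spread: W = 0, p = 1
  same <- brown_forsythe_test(list(1:5, 1:5))
  expect_equal(same$W, 0)
  expect_equal(same$p, 1)
  # hand-computed: {0,0,10,10} vs {4,5,5,6} transforms to {5,5,5,5} vs
  # {1,0,0,1}; ANOVA gives F = (40.5/1)/(1/6) = 243
  bf <- brown_forsythe_test(list(c(0, 0, 10, 10), c(4, 5, 5, 6)))
  expect_equal(bf$W, 243)
  expect_equal(bf$df, c(1, 6))
  expect_error(brown_forsythe_test(list(1:5)), "2 numeric")
  expect_error(brown_forsythe_test(list(1:5, 3)), "2 values")
})

test_that("Brown-Forsythe agrees with the independent leveneTest oracle", {
  skip_if_not_installed("car")
  set.seed(71)
  for (i in 1:50) {
    k <- sample(2:4, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(5:15, 1), sd = runif(1, 0.5, 3)))
    got <- brown_forsythe_test(groups)
    y <- unlist(groups)
    g <- factor(rep(seq_len(k), vapply(groups, length, 1L)))
    ora <- car::leveneTest(y, g, center = median)
    expect_equal(got$W, ora$`F value`[1], tolerance = 1e-10)
    expect_equal(got$p, ora$`Pr(>F)`[1], tolerance = 1e-10)
  }
})

test_that("Holm and BH adjustments match their step definitions", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.7), 0.7)
  expect_error(holm_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(-0.1), "\\[0, 1\\]")
  set.seed(72)
  p <- runif(20)
  expect_true(all(holm_adjust(p) >= p))
  expect_true(all(bh_adjust(p) >= p))
  # sorted BH output is monotone nondecreasing
  expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  # Holm's smallest adjusted p equals Bonferroni's smallest
  expect_equal(min(holm_adjust(p)), min(pmin(1, p * length(p))))
})

test_that("two-sided empirical p uses the add-one rule and caps at 1", {
  null <- as.numeric(1:99)
  expect_equal(empirical_two_sided_p(null, 0), 0.02)
  expect_equal(empirical_two_sided_p(null, 50), 1)
  expect_equal(empirical_two_sided_p(rep(3, 10), 3), 1)
  expect_error(empirical_two_sided_p(numeric(0), 1), "empty")
})

test_that("closed-form sampled variance follows the law of total variance", {
  expect_equal(expected_sampled_variance(0, 0.5, rep(10, 5)), 0.025)
  expect_equal(expected_sampled_variance(0.01, 0.6, rep(1e9, 3)), 0.01,
               tolerance = 1e-6)
  expect_error(expected_sampled_variance(0.01, 0, 10), "mean_h")
  expect_error(expected_sampled_variance(0.01, 1, 10), "mean_h")
})

test_that("bottleneck null: infinite-depth limit, closed-form mean, determinism", {
  set.seed(73)
  ctrl <- draw_latent_h(400)
  # near-infinite depth: null variance is just subsampling variance
  bn_inf <- simulate_bottleneck_null(ctrl, kd_depths = rep(1e6, 100),
                                     n_kd = 100, n_sims = 300, seed = 1)
  expect_equal(mean(bn_inf$null_variances), var(ctrl), tolerance = 0.02)
  # closed-form oracle within 3 Monte-Carlo standard errors
  depths <- rpois(200, 25) + 1
  bn <- simulate_bottleneck_null(ctrl, depths, n_kd = 200,
                                 n_sims = 2000, seed = 2)
  expected <- expected_sampled_variance(var(ctrl), mean(ctrl), depths)
  mc_se <- sd(bn$null_variances) / sqrt(bn$n_sims)
  expect_lt(abs(mean(bn$null_variances) - expected), 3 * mc_se)
  # reproducibility
  bn_a <- simulate_bottleneck_null(ctrl, depths, n_sims = 100, seed = 9)
  bn_b <- simulate_bottleneck_null(ctrl, depths, n_sims = 100, seed = 9)
  bn_c <- simulate_bottleneck_null(ctrl, depths, n_sims = 100, seed = 10)
  expect_identical(bn_a$null_variances, bn_b$null_variances)
  expect_false(identical(bn_a$null_variances, bn_c$null_variances))
  expect_error(simulate_bottleneck_null(ctrl[1:10], depths, n_kd = 20),
               "control pool")
  expect_error(simulate_bottleneck_null(ctrl, c(0, depths)), ">= 1")
})

test_that("equal-count binning sorts by depth and spreads remainders low", {
  set.seed(74)
  d <- runif(100, 5, 100); h <- runif(100)
  b <- bin_equal_count(d, h, 10)
  expect_equal(b$n_cells, rep(10L, 10))
  expect_true(all(diff(b$mean_depth) > 0))
  b2 <- bin_equal_count(runif(103, 5, 100), runif(103), 10)
  expect_equal(b2$n_cells, c(11L, 11L, 11L, rep(10L, 7)))
  b3 <- bin_equal_count(d, rep(0.5, 100), 10)
  expect_equal(b3$het_variance, rep(0, 10))
  expect_error(bin_equal_count(d[1:15], h[1:15], 10), "at least 20")
})

test_that("quantile fit recovers exact 1/depth laws and orders tau curves", {
  d <- c(5, 10, 20, 50, 100)
  bins <- data.frame(mean_depth = d, het_variance = 0.01 + 0.2 / d)
  fit <- fit_depth_variance_quantiles(bins, taus = c(0.05, 0.5, 0.95))
  expect_equal(fit$beta0, rep(0.01, 3), tolerance = 1e-10)
  expect_equal(fit$beta1, rep(0.2, 3), tolerance = 1e-10)
  expect_equal(fit$pinball_loss, rep(0, 3), tolerance = 1e-12)
  expect_error(fit_depth_variance_quantiles(
    data.frame(mean_depth = rep(10, 5), het_variance = 1:5)),
    "collinear")
  expect_error(fit_depth_variance_quantiles(bins[1:2, ]), "3 bins")
  # heteroscedastic bins: the 95th-percentile curve dominates the 5th
  set.seed(75)
  d2 <- runif(100, 5, 100)
  v2 <- 0.01 + 0.25 / d2 + rnorm(100, 0, 0.02 + 0.1 / d2)
  bins2 <- data.frame(mean_depth = d2, het_variance = v2)
  fit2 <- fit_depth_variance_quantiles(bins2)
  grid <- seq(5, 100, length.out = 40)
  expect_true(all(predict_depth_variance(fit2[fit2$tau == 0.95, ], grid) >=
                    predict_depth_variance(fit2[fit2$tau == 0.05, ], grid)))
})

test_that("quantile fit attains the grid-search optimum on random instances", {
  set.seed(76)
  for (i in 1:3) {
    d <- runif(20, 5, 80)
    v <- 0.02 + 0.3 / d + rnorm(20, 0, 0.05 / sqrt(d))
    bins <- data.frame(mean_depth = d, het_variance = v)
    fit <- fit_depth_variance_quantiles(bins, taus = 0.5)
    x <- 1 / d
    b0s <- fit$beta0 + seq(-0.02, 0.02, length.out = 60)
    b1s <- fit$beta1 + seq(-0.1, 0.1, length.out = 60)
    grid_loss <- outer(b0s, b1s, Vectorize(function(b0, b1)
      sum((v - b0 - b1 * x) * (0.5 - ((v - b0 - b1 * x) < 0)))))
    expect_lte(fit$pinball_loss, min(grid_loss) + 1e-10)
  }
})

test_that("bootstrap band collapses on noise-free bins and is seed-deterministic", {
  d <- c(5, 8, 12, 20, 40, 80)
  bins <- data.frame(mean_depth = d, het_variance = 0.015 + 0.3 / d)
  band <- bootstrap_variance_band(bins, taus = 0.5, n_boot = 50, seed = 3)
  bw <- band$bands[["0.5"]]["upper", ] - band$bands[["0.5"]]["lower", ]
  expect_true(all(bw < 1e-10))
  set.seed(77)
  noisy <- data.frame(mean_depth = d,
                      het_variance = 0.015 + 0.3 / d + rnorm(6, 0, 0.01))
  b1 <- bootstrap_variance_band(noisy, n_boot = 40, seed = 4)
  b2 <- bootstrap_variance_band(noisy, n_boot = 40, seed = 4)
  b3 <- bootstrap_variance_band(noisy, n_boot = 40, seed = 5)
  expect_identical(b1$bands, b2$bands)
  expect_false(identical(b1$bands, b3$bands))
  for (tau in names(b1$bands)) {
    expect_true(all(b1$bands[[tau]]["lower", ] <=
                      b1$bands[[tau]]["upper", ]))
  }
})

test_that("sampling the whole molecule pool reproduces true heteroplasmy", {
  acc <- simulate_sampling_accuracy(n_cells = 200, copy_number = 500,
                                    sample_sizes = 500, seed = 78)
  # sampled h equals round(h * N) / N: within half a molecule of truth
  expect_lte(max(abs(acc$cells$sampled_h_n500 - acc$cells$true_h)),
             0.5 / 500)
  expect_gt(acc$fits$r_squared, 0.9999)
  expect_error(simulate_sampling_accuracy(copy_number = 50,
                                          sample_sizes = 100),
               "exceeds")
})

test_that("matched-population mode samples each cell at an empirical depth", {
  set.seed(79)
  acc <- simulate_sampling_accuracy(n_cells = 500,
                                    depths = rpois(2000, 40) + 1,
                                    seed = 79)
  expect_true(all(c("depth", "sampled_h") %in% names(acc$cells)))
  expect_true(all(acc$cells$depth >= 1))
  expect_equal(nrow(acc$fits), 1)
  expect_gt(acc$fits$r_squared, 0.3)
})
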