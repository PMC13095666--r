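test_that("site heteroplasmy is the alt fraction, NA at zero depth", {
  expect_equal(site_heteroplasmy(3, 1), 0.25)
  expect_equal(site_heteroplasmy(0, 7), 1)
  expect_true(is.na(site_heteroplasmy(0, 0)))
  expect_error(site_heteroplasmy(-1, 2), "nonnegative")
})

test_that("combined heteroplasmy counts focal-haplotype reads at oriented sites", {
  pan <- haplotype_panel(
    data.frame(position = c(1L, 2L, 3L), ref = c("C", "C", "G"),
               alt = c("T", "T", "A"),
               orientation = c("cis", "cis", "trans")),
    focal_position = 1L)
  cts <- data.frame(cell_barcode = "c1", position = c(1L, 2L, 3L),
                    ref_count = c(2L, 1L, 6L), alt_count = c(8L, 4L, 4L))
  out <- combined_heteroplasmy(cts, pan)
  expect_equal(out$heteroplasmy, (8 + 4 + 6) / 25)
  expect_equal(out$combined_depth, 25L)
  # all-cis pure alt
  pan2 <- haplotype_panel(
    data.frame(position = 1:2, ref = "C", alt = "T", orientation = "cis"),
    focal_position = 1L)
  cts2 <- data.frame(cell_barcode = "c1", position = 1:2,
                     ref_count = 0L, alt_count = 5L)
  expect_equal(combined_heteroplasmy(cts2, pan2)$heteroplasmy, 1)
  # single cis site reduces to site_heteroplasmy
  pan1 <- haplotype_panel(
    data.frame(position = 1L, ref = "C", alt = "T", orientation = "cis"),
    focal_position = 1L)
  cts1 <- data.frame(cell_barcode = "c1", position = 1L,
                     ref_count = 3L, alt_count = 1L)
  expect_equal(combined_heteroplasmy(cts1, pan1)$heteroplasmy,
               site_heteroplasmy(3, 1))
  # unknown site in counts is an error
  bad <- rbind(cts, data.frame(cell_barcode = "c1", position = 99L,
                               ref_count = 1L, alt_count = 1L))
  expect_error(combined_heteroplasmy(bad, pan), "absent from the panel")
})

test_that("flipping every orientation maps h to 1 - h exactly", {
  set.seed(21)
  pan <- default_panel()
  co <- generate_cohort(80, depletion_map = NULL, seed = 21)
  h1 <- combined_heteroplasmy(co$counts, pan)
  flipped <- pan
  flipped$sites$orientation <- ifelse(pan$sites$orientation == "cis",
                                      "trans", "cis")
  h2 <- combined_heteroplasmy(co$counts, flipped)
  expect_equal(h2$heteroplasmy, 1 - h1$heteroplasmy)
  # combined h equals the depth-weighted mean of per-site oriented fractions
  one_cell <- co$counts[co$counts$cell_barcode ==
                          co$counts$cell_barcode[1], ]
  ori <- pan$sites$orientation[match(one_cell$position,
                                     pan$sites$position)]
  f <- ifelse(ori == "cis",
              site_heteroplasmy(one_cell$ref_count, one_cell$alt_count),
              1 - site_heteroplasmy(one_cell$ref_count,
                                    one_cell$alt_count))
  d <- one_cell$ref_count + one_cell$alt_count
  expect_equal(h1$heteroplasmy[h1$cell_barcode ==
                                 one_cell$cell_barcode[1]],
               sum(f * d) / sum(d))
})

test_that("orientation inference recovers cis/trans from per-cell correlation", {
  set.seed(31)
  pan <- default_panel()
  n <- 60
  h <- draw_latent_h(n)
  cb <- sprintf("c%03d", seq_len(n))
  depth <- 40L
  mk_site <- function(pos, p) {
    alt <- rbinom(n, depth, p)
    data.frame(cell_barcode = cb, position = pos,
               ref_count = depth - alt, alt_count = alt)
  }
  cts <- rbind(mk_site(5024L, h), mk_site(13715L, h),
               mk_site(1781L, 1 - h), mk_site(1866L, 1 - h),
               mk_site(3009L, 1 - h), mk_site(3823L, 1 - h),
               mk_site(13614L, 1 - h))
  pan$sites$orientation <- "unknown"
  pan$sites$orientation[pan$sites$position == 5024] <- "cis"
  got <- infer_orientations(cts, pan)
  expect_equal(got$sites$orientation,
               default_panel()$sites$orientation)
  # independent noise at a site gives |r| < threshold -> unknown
  noise <- cts
  noise$alt_count[noise$position == 13715] <-
    rbinom(n, depth, runif(n))
  noise$ref_count[noise$position == 13715] <-
    depth - noise$alt_count[noise$position == 13715]
  expect_warning(got2 <- infer_orientations(noise, pan), "excluded")
  expect_equal(got2$sites$orientation[got2$sites$position == 13715],
               "unknown")
  # too few qualifying cells -> unknown with warning
  tiny <- cts[cts$cell_barcode %in% cb[1:5], ]
  ws <- capture_warnings(got3 <- infer_orientations(tiny, pan))
  expect_true(all(grepl("cells pass", ws)) && length(ws) > 0)
  expect_true(all(got3$sites$orientation[
    got3$sites$position != 5024] == "unknown"))
})

test_that("depth filter keeps cells at or above the cutoff", {
  calls <- data.frame(cell_barcode = c("a", "b", "c"),
                      heteroplasmy = 0.5,
                      combined_depth = c(5L, 20L, 35L))
  expect_equal(nrow(filter_by_combined_depth(calls, 20)), 2)
  expect_equal(filter_by_combined_depth(calls, 0), calls)
  calls$combined_depth <- 19L
  expect_equal(nrow(filter_by_combined_depth(calls, 20)), 0)
})

test_that("combined calls sharpen with depth on cohorts with one true fraction", {
  set.seed(41)
  pan <- default_panel()
  rmse_at <- function(depth_per_cn) {
    co <- generate_cohort(300, depletion_map = NULL,
                          depth_per_cn = depth_per_cn, cn_sdlog = 0,
                          seed = 41)
    calls <- combined_heteroplasmy(co$counts, pan)
    truth <- co$truth$true_h[match(calls$cell_barcode,
                                   co$truth$cell_barcode)]
    sqrt(mean((calls$heteroplasmy - truth)^2))
  }
  expect_lt(rmse_at(100 / 1750), rmse_at(5 / 1750))
})

test_that("long-read concordance tallies oriented allele agreement per pair", {
  # 2 full-mutant + 2 full-WT reads: perfect linkage at every pair
  mk_read <- function(id, alleles, positions = c(10L, 20L, 30L)) {
    data.frame(read_id = id, position = positions, allele = alleles)
  }
  reads <- rbind(mk_read("m1", c(1, 1, 1)), mk_read("m2", c(1, 1, 1)),
                 mk_read("w1", c(0, 0, 0)), mk_read("w2", c(0, 0, 0)))
  cc <- longread_haplotype_concordance(reads)
  expect_true(all(cc$concordance_pct == 100))
  # one discordant read at (10, 20) drops that pair to 4/5
  reads2 <- rbind(reads, mk_read("x1", c(1, 0, 1)))
  cc2 <- longread_haplotype_concordance(reads2)
  expect_equal(cc2$concordance_pct[cc2$pos1 == 10 & cc2$pos2 == 20], 80)
  expect_equal(cc2$concordance_pct[cc2$pos1 == 10 & cc2$pos2 == 30], 100)
  # a read covering one position contributes to no pair
  reads3 <- rbind(reads, data.frame(read_id = "s1", position = 10L,
                                    allele = 1))
  expect_equal(longread_haplotype_concordance(reads3)$n_reads,
               rep(4L, 3))
})

test_that("shuffled alleles give the independence concordance in closed form", {
  set.seed(51)
  n <- 4000
  q1 <- 0.7; q2 <- 0.4
  reads <- data.frame(
    read_id = rep(sprintf("r%04d", 1:n), 2),
    position = rep(c(1L, 2L), each = n),
    allele = c(rbinom(n, 1, q1), rbinom(n, 1, q2)))
  cc <- longread_haplotype_concordance(reads)
  expected <- 100 * (q1 * q2 + (1 - q1) * (1 - q2))
  expect_equal(cc$concordance_pct, expected, tolerance = 0.05)
})
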