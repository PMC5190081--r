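test_that("control filtering conserves counts and preserves order", {
  set.seed(8)
  pl <- make_platform(platform_spec(1000, 5, control_fraction = 0.1), seed = 8)
  m <- matrix(rnorm(1000 * 3), 1000, 3,
              dimnames = list(pl$probe_id, paste0("s", 1:3)))
  cnm <- copy_number_matrix(m, pl)
  kept <- filter_controls(cnm)
  expect_equal(nrow(kept$values), sum(!pl$is_control))  # brute-force tally
  expect_equal(nrow(kept$values) + sum(pl$is_control), 1000)
  expect_identical(kept$annotation$probe_id,
                   pl$probe_id[!pl$is_control])
  # no controls: identity
  pl0 <- tiny_platform(100, 2)
  cnm0 <- copy_number_matrix(matrix(0, 100, 2,
                                    dimnames = list(pl0$probe_id, c("a", "b"))),
                             pl0)
  expect_identical(filter_controls(cnm0)$values, cnm0$values)
})

test_that("background correction is element-wise subtraction", {
  pl <- tiny_platform(50, 1)
  set.seed(2)
  mk <- function() matrix(runif(50 * 2, 0, 1000), 50, 2,
                          dimnames = list(pl$probe_id, c("s1", "s2")))
  fg_t <- mk(); bg_t <- mk() / 10; fg_r <- mk(); bg_r <- mk() / 10
  raw <- raw_intensity(fg_t, bg_t, fg_r, bg_r, pl)
  corr <- background_correct(raw)
  expect_identical(corr$fg_test, fg_t - bg_t)   # oracle subtraction
  expect_identical(corr$fg_ref, fg_r - bg_r)
  # fg == bg everywhere -> all zero
  z <- background_correct(raw_intensity(bg_t, bg_t, bg_r, bg_r, pl))
  expect_true(all(z$fg_test == 0) && all(z$fg_ref == 0))
})

test_that("log2 ratios follow the floored formula", {
  pl <- tiny_platform(4, 1)
  mk <- function(v) matrix(v, 4, 1, dimnames = list(pl$probe_id, "s"))
  # background correction drives the third test signal negative
  raw <- background_correct(
    raw_intensity(mk(c(500, 1000, 0, 0)), mk(c(0, 0, 3, 0)),
                  mk(c(500, 500, 64, 128)), mk(0), pl))
  r <- compute_log2_ratio(raw, floor = 1)$values[, 1]
  expect_equal(unname(r), c(0, 1, log2(1 / 64), log2(1 / 128)))
  expect_true(all(is.finite(r)))
  expect_error(compute_log2_ratio(raw, floor = 0), "positive")
})

test_that("median normalization centers, is exact for shifts, and idempotent", {
  pl <- tiny_platform(201, 1)
  set.seed(3)
  v <- rnorm(201)
  m <- copy_number_matrix(cbind(s1 = v - median(v), s2 = v + 0.3), pl)
  norm <- normalize_median(m)
  expect_equal(norm$values[, "s1"], m$values[, "s1"])  # already centered
  expect_equal(norm$values[, "s2"], m$values[, "s2"] - median(m$values[, "s2"]))
  expect_lt(max(abs(apply(norm$values, 2, median))), 1e-12)
  expect_equal(normalize_median(norm)$values, norm$values)
})

test_that("cellularity correction inverts the mixing model", {
  # c = 1 is the identity
  sim <- tiny_cohort(noise_sd = 0, cellularity = c(1, 1))
  expect_equal(correct_cellularity(sim$matrix, rep(1, 10))$values,
               sim$matrix$values)
  # single-copy loss at c = 0.5: observed log2(0.75), corrected -1
  pl <- tiny_platform(10, 1)
  obs <- matrix(log2(0.5 * 0.5 + 0.5), 10, 1, dimnames = list(pl$probe_id, "s"))
  expect_equal(obs[1, 1], log2(0.75))
  corr <- correct_cellularity(copy_number_matrix(obs, pl), 0.5)
  expect_equal(unname(corr$values[, 1]), rep(-1, 10))
  # deep loss where 2^x <= 1 - c lands on the finite floor branch
  deep <- copy_number_matrix(matrix(log2(0.2), 10, 1,
                                    dimnames = list(pl$probe_id, "s")), pl)
  out <- correct_cellularity(deep, 0.7, floor = 0.05)  # 0.2 <= 1 - 0.7
  expect_true(all(is.finite(out$values)))
  expect_equal(unname(out$values[1, 1]), log2(0.05 * 0.2))
  expect_error(correct_cellularity(deep, 1.5), "0, 1")
})

test_that("mix-then-correct is the identity across the cellularity range", {
  for (cc in c(0.35, 0.6, 1)) {
    sim <- tiny_cohort(n_per_group = 3, noise_sd = 0,
                       cellularity = c(cc, cc), seed = 21)
    corr <- correct_cellularity(sim$matrix, sim$truth$cellularity)
    expect_lt(max(abs(corr$values - sim$truth$log2)), 1e-9)
  }
})

test_that("low-cellularity samples are rejected with a warning", {
  sim <- tiny_cohort(n_per_group = 3, noise_sd = 0, cellularity = c(1, 1))
  cells <- c(0.2, rep(0.8, 5))
  expect_warning(out <- correct_cellularity(sim$matrix, cells),
                 "cellularity < 0.3")
  expect_equal(ncol(out$values), 5)
  expect_false("g1_01" %in% colnames(out$values))
})

test_that("MAD is shift-invariant, scales with noise, and uses residuals", {
  pl <- tiny_platform(2000, 2)
  set.seed(4)
  noise <- rnorm(2000, sd = 0.2)
  m <- copy_number_matrix(cbind(s1 = noise, s2 = noise + 5), pl)
  qr <- compute_mad(m)
  expect_equal(qr$mad[1], qr$mad[2])                   # location invariance
  m2 <- copy_number_matrix(cbind(s1 = 3 * noise, s2 = noise), pl)
  expect_equal(compute_mad(m2)$mad[1], 3 * qr$mad[1])  # linear in sd
  # constant profile
  mc <- copy_number_matrix(cbind(s = rep(0.7, 2000)), pl)
  expect_equal(compute_mad(mc)$mad, 0)
  # residual form removes true structure
  step <- c(rep(0, 1000), rep(2, 1000))
  m3 <- copy_number_matrix(cbind(s = step + noise), pl)
  seg_true <- as_segmented_matrix(cbind(s = step), pl)
  expect_lt(abs(compute_mad(m3, seg_true)$mad - 0.2), 0.02)
  expect_gt(compute_mad(m3, method = "raw")$mad, 0.5)
  expect_error(compute_mad(m3, as_segmented_matrix(cbind(s = 0), tiny_platform(1, 1))),
               "dimension")
})

test_that("full raw-table preprocessing recovers true ratios", {
  sim <- tiny_cohort(n_per_group = 3, noise_sd = 0, cellularity = c(0.6, 0.6))
  raw <- raw_from_log2(sim$matrix$values, sim$platform)
  m <- preprocess_raw(raw, cellularity = sim$truth$cellularity)
  # medians are re-zeroed, so compare against median-centered truth
  truth <- sweep(sim$truth$log2, 2, apply(sim$truth$log2, 2, median))
  skew <- apply(sim$matrix$values, 2, median)  # shift removed by normalization
  corr_truth <- correct_cellularity(
    copy_number_matrix(sweep(sim$matrix$values, 2, skew), sim$platform),
    sim$truth$cellularity)
  expect_equal(m$values, corr_truth$values, tolerance = 1e-9)
  expect_true(all(is.finite(m$values)))
})
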