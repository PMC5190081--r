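test_that("nearest-neighbour distances match the all-pairs oracle", {
  expect_equal(nn_distances(matrix(c(0, 1, 2, 4, 8), ncol = 1)),
               c(1, 1, 1, 2, 4))
  # duplicates give a zero distance
  expect_equal(min(nn_distances(matrix(c(0, 0, 5), ncol = 1))), 0)
  set.seed(12)
  X <- matrix(rnorm(100), 20, 5)
  oracle <- vapply(1:20, function(i) {
    min(vapply(setdiff(1:20, i),
               function(j) sqrt(sum((X[i, ] - X[j, ])^2)), numeric(1)))
  }, numeric(1))
  expect_equal(unname(nn_distances(X)), oracle)
  expect_error(nn_distances(matrix(1, 1, 3)), "at least 2")
})

test_that("the full Kozachenko-Leonenko formula is evaluated correctly", {
  x <- c(0, 1, 2, 4, 8)
  res <- estimate_entropy(matrix(x, ncol = 1), estimator = "full_kl")
  rho <- c(1, 1, 1, 2, 4)
  gamma <- 0.57721566490153286
  H_hand <- mean(log(rho)) + log(4) + gamma + log(2)  # V_1 = 2
  expect_equal(res$H, H_hand, tolerance = 1e-12)
  expect_equal(res$h_i, log(rho) + log(4) + gamma + log(2))
  expect_equal(res$constants$log_Vd, log(2))
  # H is exactly the mean of the per-sample terms, both estimators
  expect_equal(res$H, mean(res$h_i))
  resn <- estimate_entropy(matrix(x, ncol = 1))
  expect_equal(resn$H, mean(resn$h_i))
  expect_equal(resn$h_i, log(rho) + log(4))
})

test_that("identical rows are floored at tie_epsilon deterministically", {
  X <- matrix(1, 4, 3)
  expect_warning(res <- estimate_entropy(X, tie_epsilon = 1e-8), "tie_epsilon")
  expect_equal(res$H, log(1e-8 / sqrt(3)) + log(3))
  expect_error(estimate_entropy(X, tie_epsilon = 0), "positive")
  expect_error(estimate_entropy(matrix(c(1, Inf), 2, 1)), "non-finite")
})

test_that("entropy obeys the location and scale laws", {
  set.seed(13)
  X <- matrix(rnorm(15 * 8), 15, 8)
  d <- ncol(X)
  shifted <- sweep(X, 2, runif(d, -5, 5), "+")
  for (est in c("normalized", "full_kl")) {
    H0 <- estimate_entropy(X, est)$H
    expect_equal(estimate_entropy(shifted, est)$H, H0, tolerance = 1e-9)
  }
  s <- 3.7
  expect_lt(abs(estimate_entropy(s * X)$H -
                  (estimate_entropy(X)$H + log(s))), 1e-9)
  expect_lt(abs(estimate_entropy(s * X, "full_kl")$H -
                  (estimate_entropy(X, "full_kl")$H + d * log(s))), 1e-9)
})

test_that("per-sample contributions behave as whole-cohort neighbourhoods", {
  set.seed(14)
  X <- matrix(rnorm(10 * 6), 10, 6,
              dimnames = list(paste0("s", 1:10), NULL))
  z <- per_sample_entropy(X, normalization = "cohort_zscore")
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  # an outlier sample has the largest contribution
  X2 <- rbind(X, outlier = rep(40, 6))
  h2 <- per_sample_entropy(X2)
  expect_equal(names(which.max(h2)), "outlier")
  # duplicating a sample collapses both copies' contributions
  h1 <- suppressWarnings(per_sample_entropy(X))
  X3 <- rbind(X, dup = X[1, ])
  expect_warning(h3 <- per_sample_entropy(X3), "tie_epsilon")
  expect_lt(h3["s1"], h1["s1"])
  expect_lt(h3["dup"], h1["s1"])
})

test_that("small two-group tests are enumerated exhaustively and match an oracle", {
  set.seed(15)
  X <- matrix(rnorm(6 * 4), 6, 4)
  labels <- rep(c("a", "b"), each = 3)
  res <- entropy_permutation_test(X, labels, B = 50, seed = 1)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$B, choose(6, 3))
  # oracle: enumerate every split, computing each group's entropy through
  # the standalone estimator rather than the test's distance-matrix path
  splits <- utils::combn(6, 3)
  T_all <- apply(splits, 2, function(idx) {
    estimate_entropy(X[idx, , drop = FALSE])$H -
      estimate_entropy(X[-idx, , drop = FALSE])$H
  })
  T_obs <- estimate_entropy(X[1:3, ])$H - estimate_entropy(X[4:6, ])$H
  expect_equal(res$T_obs, T_obs)
  expect_equal(res$p, mean(abs(T_all) >= abs(T_obs) - 1e-12))
  expect_equal(unname(res$H_by_group["a"] - res$H_by_group["b"]), res$T_obs)
})

test_that("Monte-Carlo permutation p-values are seeded and in (0, 1]", {
  set.seed(16)
  X <- matrix(rnorm(24 * 5), 24, 5)
  labels <- rep(c("a", "b"), each = 12)  # choose(24,12) >> exhaustive limit
  r1 <- entropy_permutation_test(X, labels, B = 99, seed = 7)
  r2 <- entropy_permutation_test(X, labels, B = 99, seed = 7)
  expect_equal(r1$method, "monte_carlo")
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0)
  expect_lte(r1$p, 1)
  expect_error(entropy_permutation_test(X, rep("a", 24), B = 10), "two groups")
  expect_error(entropy_permutation_test(X, c("a", rep("b", 23)), B = 10),
               "at least 2")
})

test_that("per-chromosome testing localizes a planted signal and applies BH", {
  pl <- make_platform(platform_spec(1000, n_chromosomes = 5), seed = 1)
  a_sh <- chr1_architecture(40, 0.15, seed = 2, chrom_len = 200)
  a_di <- chr1_architecture(40, 1.0, seed = 3, chrom_len = 200)
  sim <- simulate_cohort(pl, list(sh = a_sh, di = a_di), 10, noise_sd = 0.25,
                         cellularity_range = c(1, 1), seed = 4)
  tab <- per_chromosome_entropy(sim$matrix, sim$truth$group, B = 499, seed = 5)
  expect_equal(nrow(tab), 5)
  expect_equal(tab$chrom[which.min(tab$p)], "chr1")
  # BH oracle: step-up computed directly from the reported p-values
  ord <- order(tab$p, decreasing = TRUE)
  q_hand <- numeric(5)
  q_hand[ord] <- cummin(tab$p[ord] * 5 / rank(tab$p)[ord])
  expect_equal(tab$q, pmin(q_hand, 1))
  expect_identical(tab$significant, tab$q < 0.1)
})

test_that("chromosomes with fewer than 2 probes are skipped with a warning", {
  ann <- as_probe_annotation(data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    start = c(1, 100, 200, 300, 1), end = c(61, 161, 261, 361, 61),
    probe_id = paste0("P", 1:5), is_control = FALSE))
  set.seed(17)
  m <- copy_number_matrix(matrix(rnorm(5 * 8), 5, 8,
                                 dimnames = list(ann$probe_id, paste0("s", 1:8))),
                          ann)
  expect_warning(tab <- per_chromosome_entropy(m, rep(c("a", "b"), 4), B = 19),
                 "chr2")
  expect_equal(tab$chrom, "chr1")
})

test_that("PCA dispersion separates tight from spread groups", {
  set.seed(18)
  tight <- matrix(rnorm(8 * 30, sd = 1), 8, 30)
  spread <- matrix(rnorm(8 * 30, sd = 4), 8, 30)
  disp <- pca_dispersion(rbind(tight, spread), rep(c("t", "s"), each = 8))
  expect_gt(disp$hull_area_per_group[["s"]], disp$hull_area_per_group[["t"]])
  expect_true(all(diff(disp$variance_explained) <= 0))
  expect_lte(sum(disp$variance_explained), 1 + 1e-12)
})

test_that("degenerate point clouds give zero hull area", {
  X <- matrix(1, 6, 4)
  w <- capture_warnings(disp <- pca_dispersion(X, rep(c("a", "b"), 3)))
  expect_length(w, 2)  # one per degenerate group
  expect_match(w, "hull area", all = TRUE)
  expect_equal(unname(disp$hull_area_per_group), c(0, 0))
  expect_true(all(abs(disp$scores) < 1e-9))
})
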