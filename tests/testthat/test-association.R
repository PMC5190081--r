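make_clinical <- function(time, event, arm = "A", cellularity = 0.6) {
  df <- data.frame(sample_id = paste0("s", seq_along(time)), arm = arm,
                   time_years = time, event = event,
                   cellularity = cellularity, stringsAsFactors = FALSE)
  class(df) <- c("clinical_table", "data.frame")
  df
}

test_that("Cox fit recovers a simulated hazard ratio and rejects no-event data", {
  set.seed(20)
  x <- rnorm(300)
  tm <- rexp(300, rate = 0.3 * exp(log(1.8) * x))
  cn <- rexp(300, rate = 0.05)
  clin <- make_clinical(pmin(tm, cn), as.integer(tm <= cn))
  fit <- fit_cox(x, clin)
  expect_true(fit$ci_low <= 1.8 && 1.8 <= fit$ci_high)
  expect_true(fit$ci_low <= fit$HR && fit$HR <= fit$ci_high)
  expect_gt(fit$HR, 0)
  expect_error(fit_cox(x, make_clinical(tm, rep(0L, 300))), "no events")
  expect_error(fit_cox(x[1:5], clin), "align")
})

test_that("the treatment-interaction term is reported when requested", {
  set.seed(21)
  x <- rnorm(200)
  arm <- rep(c("CS", "S"), 100)
  tm <- rexp(200, 0.3 * exp(0.5 * x))
  clin <- make_clinical(pmin(tm, 8), as.integer(tm <= 8), arm = arm)
  fit <- fit_cox(x, clin, interaction = TRUE)
  expect_true(is.numeric(fit$interaction_p) && fit$interaction_p > 0)
})

test_that("median split sends ties low and balances sizes", {
  g <- group_by_entropy(c(1, 2, 3, 4), "median")
  expect_equal(as.character(g$groups), c("low", "low", "high", "high"))
  for (n in 3:30) {
    set.seed(n)
    gg <- group_by_entropy(rnorm(n), "median")
    expect_lte(abs(diff(table(gg$groups))), 1)
    expect_equal(length(gg$groups), n)  # exhaustive partition
  }
  # a value equal to the median goes to the low group
  gt <- group_by_entropy(c(1, 2, 2, 5, 9), "median")
  expect_equal(sum(gt$groups == "low"), 3)
  expect_error(group_by_entropy(rep(1, 5)), "equal")
})

test_that("tertile merging follows the requested or survival-driven pair", {
  g <- group_by_entropy(1:9, "tertile_merge", merge = "low_mid")
  expect_equal(as.integer(table(g$groups)), c(6L, 3L))
  expect_equal(as.character(g$groups[7:9]), rep("high", 3))
  g2 <- group_by_entropy(1:9, "tertile_merge", merge = "mid_high")
  expect_equal(as.integer(table(g2$groups)), c(3L, 6L))
  # auto: survival identical for T1/T2 but much worse for T3 -> merge low_mid
  time <- c(rep(5, 3), rep(5.2, 3), rep(0.5, 3))
  clin <- make_clinical(time, rep(1L, 9))
  ga <- group_by_entropy(1:9, "tertile_merge", clinical = clin)
  expect_equal(ga$merged_pair, "low_mid")
  expect_error(group_by_entropy(1:2, "tertile_merge", merge = "low_mid"),
               "at least 3")
})

test_that("log-rank agrees with the direct O-E/V computation", {
  # two groups, all events: {1,2,3} vs {4,5,6}
  clin <- make_clinical(c(1, 2, 3, 4, 5, 6), rep(1L, 6))
  groups <- factor(rep(c("g1", "g2"), each = 3))
  res <- km_logrank(groups, clin)
  # oracle: loop over distinct death times with the standard moments
  times <- 1:6
  O1 <- 3; E1 <- 0; V <- 0
  at_risk <- data.frame(t = clin$time_years, g = groups)
  for (t in times) {
    n <- sum(at_risk$t >= t)
    n1 <- sum(at_risk$t >= t & at_risk$g == "g1")
    d <- sum(at_risk$t == t)
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq_hand <- (O1 - E1)^2 / V
  expect_equal(res$chisq, chisq_hand, tolerance = 1e-9)
  expect_equal(res$p, pchisq(chisq_hand, 1, lower.tail = FALSE))
  expect_equal(res$table$median, c(2, 5))
})

test_that("a group compared against its duplicate gives log-rank p = 1", {
  time <- c(0.5, 1.2, 3.1, 4.4, 6.0)
  event <- c(1L, 1L, 0L, 1L, 0L)
  clin <- make_clinical(c(time, time), c(event, event))
  res <- km_logrank(factor(rep(c("a", "b"), each = 5)), clin)
  expect_lt(res$chisq, 1e-9)
  expect_equal(res$p, 1, tolerance = 1e-6)
  expect_error(km_logrank(factor(rep("a", 10)), clin), "2 non-empty")
})

test_that("covariate association statistic and permutation p behave", {
  # identical level-wise multisets: statistic exactly 0
  e <- c(1, 2, 3, 1, 2, 3)
  lev <- rep(c("x", "y"), each = 3)
  res <- covariate_association(e, lev, B = 99, seed = 1)
  expect_equal(res$statistic, 0)
  expect_equal(res$type, "mean_difference")
  # planted 1-sd shift between two levels of 20 is detected
  set.seed(22)
  hits <- vapply(1:40, function(r) {
    e2 <- c(rnorm(20), rnorm(20, mean = 1))
    covariate_association(e2, rep(c("a", "b"), each = 20),
                          B = 199, seed = r)$p < 0.05
  }, logical(1))
  expect_gte(sum(hits), 36)
  # >2 levels use the F-ratio; NA levels are dropped
  e3 <- rnorm(30)
  lev3 <- rep(c("1", "2", "3"), 10)
  res3 <- covariate_association(e3, lev3, B = 99, seed = 2)
  expect_equal(res3$type, "f_ratio")
  lev3[1:2] <- NA
  expect_silent(covariate_association(e3, lev3, B = 19, seed = 3))
  expect_error(covariate_association(e3, rep("z", 30), B = 9), "levels")
})

test_that("null covariate permutation p-values are calibrated", {
  set.seed(23)
  rej <- vapply(1:400, function(r) {
    covariate_association(rnorm(24), rep(c("a", "b"), 12),
                          B = 99, seed = 1000 + r)$p <= 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)
})

test_that("the cellularity confounder model isolates the group effect", {
  set.seed(24)
  n <- 120
  g <- rep(c("CS", "S"), each = n / 2)
  cellularity <- runif(n, 0.3, 0.9)
  # exact linear data: coefficients recovered to 1e-9
  e_exact <- 0.7 * (g == "S") + 2 * cellularity + 1
  fit <- suppressWarnings(cellularity_confounder_model(e_exact, g, cellularity))
  expect_lt(abs(fit$group_effect - 0.7), 1e-9)
  expect_lt(abs(fit$cellularity_effect - 2), 1e-9)
  # entropy driven only by cellularity: adjusted group effect ~ 0
  cell2 <- c(runif(n / 2, 0.3, 0.5), runif(n / 2, 0.7, 0.9))  # confounded
  e_conf <- 3 * cell2 + rnorm(n, sd = 0.05)
  fit2 <- cellularity_confounder_model(e_conf, g, cell2)
  expect_lt(abs(fit2$group_effect), 3 * fit2$se)
  # constant cellularity: flagged, term dropped
  expect_warning(fit3 <- cellularity_confounder_model(e_exact, g, rep(0.5, n)),
                 "constant")
  expect_false(fit3$cellularity_defined)
  expect_error(cellularity_confounder_model(e_exact[1:5], g, cellularity),
               "aligned")
})

test_that("probe matching is tolerance-bounded, one-to-one and symmetric", {
  a <- tiny_platform(50, 2, seed = 1)
  expect_equal(nrow(match_probes(a, a, 100)), 50)
  expect_true(all(match_probes(a, a, 100)$distance_bp == 0))
  b <- a
  b$start <- b$start + 400; b$end <- b$end + 400
  m_in <- match_probes(a, b, tolerance_bp = 1000)
  expect_equal(nrow(m_in), 50)
  expect_equal(nrow(match_probes(a, b, tolerance_bp = 100)), 0)
  # symmetry: swapping arguments gives the same pair set
  set.seed(25)
  c_ann <- tiny_platform(30, 2, seed = 2)
  c_ann$start <- c_ann$start + sample(-300:300, 30, replace = TRUE)
  c_ann$end <- pmax(c_ann$end + 600, c_ann$start + 1)
  ab <- match_probes(a, c_ann, 500)
  ba <- match_probes(c_ann, a, 500)
  expect_equal(nrow(ab), nrow(ba))
  expect_setequal(paste(ab$index_a, ab$index_b),
                  paste(ba$index_b, ba$index_a))
})

test_that("the mean aberration profile averages across samples", {
  pl <- tiny_platform(20, 1)
  vals <- cbind(s1 = rep(0, 20), s2 = rep(1, 20))
  rownames(vals) <- pl$probe_id
  prof <- mean_aberration_profile(as_segmented_matrix(vals, pl))
  expect_equal(prof$mean_value, rep(0.5, 20))
  expect_equal(prof$probe_id, pl$probe_id)
})
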