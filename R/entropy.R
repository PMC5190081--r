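#' Nearest-neighbour distances between samples
#'
#' Euclidean distance from each row of `X` to its nearest other row — the
#' substrate of the nearest-neighbour entropy estimator.
#'
#' @param X Numeric samples x features matrix with at least two rows.
#' @return Numeric vector `rho` of length `nrow(X)`.
#' @export
nn_distances <- function(X) {
  X <- as_sample_matrix(X)
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 samples")
  D <- as.matrix(dist(X))
  diag(D) <- Inf
  rho <- apply(D, 1L, min)
  names(rho) <- rownames(X)
  rho
}

# Per-sample entropy contributions from nearest-neighbour distances.
# Shared by the estimator and by the permutation machinery (which reuses a
# precomputed distance matrix).
entropy_terms <- function(rho, n, d, estimator, tie_epsilon = 1e-8,
                          warn_ties = TRUE) {
  n_tied <- sum(rho < tie_epsilon)
  if (n_tied > 0L) {
    if (warn_ties) {
      warning(n_tied, " nearest-neighbour distance(s) below tie_epsilon = ",
              tie_epsilon, "; floored to keep log finite")
    }
    rho <- pmax(rho, tie_epsilon)
  }
  if (estimator == "full_kl") {
    log_Vd <- (d / 2) * log(pi) - lgamma(d / 2 + 1)
    h <- d * log(rho) + log(n - 1) + EULER_GAMMA + log_Vd
    constants <- list(log_Vd = log_Vd, gamma = EULER_GAMMA, log_nm1 = log(n - 1))
  } else {
    h <- log(rho / sqrt(d)) + log(n - 1)
    constants <- list(log_Vd = NA_real_, gamma = NA_real_, log_nm1 = log(n - 1))
  }
  list(h = h, rho = rho, constants = constants)
}

#' Estimate the differential entropy of a sample group
#'
#' Nearest-neighbour (1-NN) estimation of the differential entropy of the
#' distribution the rows of `X` are drawn from. Two variants are provided:
#'
#' * `"full_kl"` — the Kozachenko-Leonenko estimator with all constants,
#'   `h_i = d log(rho_i) + log(n - 1) + gamma + log V_d`, where `V_d =
#'   pi^(d/2) / Gamma(d/2 + 1)` is the unit-ball volume and `gamma` the
#'   Euler-Mascheroni constant. Consistent for the true differential
#'   entropy; intended for validation at low dimension, since the constants
#'   diverge as `d` grows to genomic scale.
#' * `"normalized"` (default) — a dimension-stabilized variant,
#'   `h_i = log(rho_i / sqrt(d)) + log(n - 1)`, which drops the unit-ball
#'   term and the `d` multiplier and measures distances per-dimension. Used
#'   for all cohort analyses; group contrasts are unaffected by the choice
#'   because both variants differ only by monotone per-dimension rescaling.
#'
#' In both cases the group estimate is `H = mean(h_i)` exactly, so `h_i` is
#' the contribution of sample `i` (large when the sample is far from its
#' nearest neighbouring profile). Duplicate rows give `rho_i = 0`; such
#' distances are floored at `tie_epsilon` with a warning to keep the
#' logarithm finite.
#'
#' @param X Numeric samples x features matrix (or a package container,
#'   transposed automatically).
#' @param estimator `"normalized"` or `"full_kl"`.
#' @param tie_epsilon Positive floor for zero nearest-neighbour distances.
#' @return An `entropy_result`: list with `H` (nats), `h_i`, `n`, `d`,
#'   `rho_i`, `estimator`, `constants`, `normalization`.
#' @examples
#' X <- matrix(rnorm(5000), ncol = 1)
#' estimate_entropy(X, estimator = "full_kl")$H  # ~ 0.5 * log(2 * pi * exp(1))
#' @export
estimate_entropy <- function(X, estimator = c("normalized", "full_kl"),
                             tie_epsilon = 1e-8) {
  estimator <- match.arg(estimator)
  if (!is.numeric(tie_epsilon) || tie_epsilon <= 0) {
    stop("'tie_epsilon' must be positive")
  }
  X <- as_sample_matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples")
  if (!all(is.finite(X))) stop("input contains non-finite values")
  n <- nrow(X)
  d <- ncol(X)
  rho <- nn_distances(X)
  terms <- entropy_terms(rho, n, d, estimator, tie_epsilon)
  structure(
    list(H = mean(terms$h), h_i = terms$h, n = n, d = d, rho_i = terms$rho,
         estimator = estimator, constants = terms$constants,
         normalization = "raw"),
    class = "entropy_result"
  )
}

#' Per-sample DNA copy number entropy contributions
#'
#' Computes each sample's entropy contribution with neighbours drawn from
#' the whole cohort, so one value is reported per case against the common
#' background. `"cohort_zscore"` additionally centers and scales the
#' contributions to mean 0, sd 1 across the cohort ("normalised" entropy).
#'
#' @param cohort A `segmented_matrix`, `copy_number_matrix` or samples x
#'   features matrix.
#' @param normalization `"raw"` or `"cohort_zscore"`.
#' @param estimator,tie_epsilon Passed to [estimate_entropy()].
#' @return Named numeric vector of per-sample entropy values.
#' @export
per_sample_entropy <- function(cohort, normalization = c("raw", "cohort_zscore"),
                               estimator = "normalized", tie_epsilon = 1e-8) {
  normalization <- match.arg(normalization)
  res <- estimate_entropy(cohort, estimator = estimator,
                          tie_epsilon = tie_epsilon)
  h <- res$h_i
  X <- as_sample_matrix(cohort)
  if (!is.null(rownames(X))) names(h) <- rownames(X)
  if (normalization == "cohort_zscore") h <- (h - mean(h)) / sd(h)
  h
}

# Within-group entropy from a precomputed full distance matrix. 'idx' are
# the member indices; the estimator constants use the group size.
group_entropy_from_dist <- function(D, idx, d, estimator, tie_epsilon) {
  m <- length(idx)
  sub <- D[idx, idx, drop = FALSE]
  diag(sub) <- Inf
  rho <- apply(sub, 1L, min)
  mean(entropy_terms(rho, m, d, estimator, tie_epsilon, warn_ties = FALSE)$h)
}

#' Permutation test of the entropy difference between two groups
#'
#' The test statistic is `T = H(group 1) - H(group 2)`, each entropy
#' computed within its group. Group labels are permuted while group sizes
#' are held fixed; when the number of distinct label arrangements
#' `choose(n, n1)` is at most `exhaustive_limit` the null distribution is
#' enumerated exhaustively, otherwise `B` Monte-Carlo permutations are drawn
#' and the two-sided p-value uses the add-one correction
#' `p = (1 + #\{|T_perm| >= |T_obs|\}) / (B + 1)`.
#'
#' @param X A `segmented_matrix`, `copy_number_matrix` or samples x features
#'   matrix.
#' @param labels Two-group factor (or coercible) of length `nrow`.
#' @param B Number of Monte-Carlo permutations.
#' @param seed Integer seed for the Monte-Carlo draw.
#' @param estimator,tie_epsilon Passed to the entropy estimator.
#' @param exhaustive_limit Enumerate all arrangements when their number does
#'   not exceed this.
#' @return A `perm_test_result`: list with `T_obs`, `B` (permutations
#'   actually used), `p`, `seed`, `sidedness`, `method`
#'   (`"exhaustive"` or `"monte_carlo"`), `H_by_group`.
#' @export
entropy_permutation_test <- function(X, labels, B = 999L, seed = 1L,
                                     estimator = "normalized",
                                     tie_epsilon = 1e-8,
                                     exhaustive_limit = 20000) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("'labels' must define exactly two groups")
  Xs <- as_sample_matrix(X)
  n <- nrow(Xs)
  if (length(labels) != n) stop("'labels' length must match the sample count")
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("both groups need at least 2 samples")
  if (B < 1L) stop("'B' must be >= 1")

  d <- ncol(Xs)
  D <- as.matrix(dist(Xs))
  idx1 <- which(labels == levels(labels)[1])
  idx2 <- which(labels == levels(labels)[2])
  H1 <- group_entropy_from_dist(D, idx1, d, estimator, tie_epsilon)
  H2 <- group_entropy_from_dist(D, idx2, d, estimator, tie_epsilon)
  T_obs <- H1 - H2
  n1 <- length(idx1)

  stat_for <- function(members1) {
    members2 <- setdiff(seq_len(n), members1)
    group_entropy_from_dist(D, members1, d, estimator, tie_epsilon) -
      group_entropy_from_dist(D, members2, d, estimator, tie_epsilon)
  }

  n_arrangements <- choose(n, n1)
  if (n_arrangements <= exhaustive_limit) {
    combs <- utils::combn(n, n1)
    T_perm <- apply(combs, 2L, stat_for)
    # observed split is one of the enumerated arrangements
    p <- mean(abs(T_perm) >= abs(T_obs) - 1e-12)
    method <- "exhaustive"
    B_used <- ncol(combs)
  } else {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    T_perm <- vapply(seq_len(B),
                     function(b) stat_for(sample.int(n, n1)), numeric(1))
    p <- (1 + sum(abs(T_perm) >= abs(T_obs) - 1e-12)) / (B + 1)
    method <- "monte_carlo"
    B_used <- B
  }
  structure(
    list(T_obs = T_obs, B = B_used, p = p, seed = seed,
         sidedness = "two-sided", method = method,
         H_by_group = stats::setNames(c(H1, H2), levels(labels))),
    class = "perm_test_result"
  )
}

#' Per-chromosome entropy group comparison with FDR control
#'
#' Runs [entropy_permutation_test()] on each chromosome's probe subset and
#' adjusts the per-chromosome p-values by Benjamini-Hochberg; chromosomes
#' with adjusted `q < fdr` are flagged significant. Chromosomes with fewer
#' than 2 probes are skipped with a warning.
#'
#' @param X A `segmented_matrix` or `copy_number_matrix` (the probe
#'   annotation supplies the chromosome of each probe).
#' @param labels Two-group factor.
#' @param B,seed,estimator,tie_epsilon Passed to the per-chromosome tests;
#'   each chromosome gets its own child seed derived from `seed`.
#' @param fdr Significance threshold on the BH-adjusted q-value.
#' @return data.frame with columns `chrom`, `n_probes`, `T_obs`, `p`, `q`,
#'   `significant`.
#' @export
per_chromosome_entropy <- function(X, labels, B = 999L, seed = 1L,
                                   estimator = "normalized",
                                   tie_epsilon = 1e-8, fdr = 0.1) {
  ann <- annotation_of(X)
  if (is.null(ann)) stop("'X' must carry a probe annotation")
  idx_by_chrom <- chrom_index(ann)
  values <- X$values
  chroms <- names(idx_by_chrom)
  seeds <- derive_seeds(seed, length(chroms))
  rows <- vector("list", length(chroms))
  for (i in seq_along(chroms)) {
    probes <- idx_by_chrom[[chroms[i]]]
    if (length(probes) < 2L) {
      warning("chromosome '", chroms[i], "' has < 2 probes; skipped")
      next
    }
    res <- entropy_permutation_test(t(values[probes, , drop = FALSE]), labels,
                                    B = B, seed = seeds[i],
                                    estimator = estimator,
                                    tie_epsilon = tie_epsilon)
    rows[[i]] <- data.frame(chrom = chroms[i], n_probes = length(probes),
                            T_obs = res$T_obs, p = res$p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out$q <- p.adjust(out$p, method = "BH")
  out$significant <- out$q < fdr
  rownames(out) <- NULL
  out
}

#' Inter-tumor dispersion in principal-component space
#'
#' Projects the (column-centered) profile matrix on its first two principal
#' components and summarizes each group's spread as the area of the convex
#' hull of its scores — the smaller the hull, the more similar the group's
#' copy-number profiles.
#'
#' @param X A `segmented_matrix`, `copy_number_matrix` or samples x features
#'   matrix.
#' @param labels Group factor of length `nrow`.
#' @return A `dispersion_result`: list with `scores` (samples x 2),
#'   `hull_area_per_group`, `variance_explained` (first two proportions)
#'   and `labels`.
#' @export
pca_dispersion <- function(X, labels) {
  Xs <- as_sample_matrix(X)
  labels <- as.factor(labels)
  if (length(labels) != nrow(Xs)) stop("'labels' length must match sample count")
  pc <- prcomp(Xs, center = TRUE, scale. = FALSE, rank. = 2L)
  scores <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(scores) < 2L) {
    scores <- cbind(scores, matrix(0, nrow(scores), 2L - ncol(scores)))
  }
  colnames(scores) <- c("PC1", "PC2")
  total_var <- sum(pc$sdev^2)
  ve <- if (total_var > 0) (pc$sdev^2 / total_var)[1:2] else c(0, 0)
  ve[is.na(ve)] <- 0
  areas <- vapply(levels(labels), function(g) {
    convex_hull_area(scores[labels == g, , drop = FALSE])
  }, numeric(1))
  structure(
    list(scores = scores, hull_area_per_group = areas,
         variance_explained = ve, labels = labels),
    class = "dispersion_result"
  )
}

# Shoelace area of the convex hull of 2-D points; 0 (with a warning) when
# fewer than 3 distinct points are available.
convex_hull_area <- function(pts) {
  pts <- unique(round(pts, 12))
  if (nrow(pts) < 3L) {
    warning("fewer than 3 distinct points; hull area set to 0")
    return(0)
  }
  h <- grDevices::chull(pts[, 1], pts[, 2])
  xy <- pts[h, , drop = FALSE]
  x <- xy[, 1]; y <- xy[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}
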