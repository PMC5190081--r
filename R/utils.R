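#' @keywords internal
"_PACKAGE"

#' @useDynLib cnentropy, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median mad sd quantile rbinom rnorm runif rexp
#'   prcomp dist p.adjust lm coef vcov pchisq pnorm
NULL

# Euler-Mascheroni constant used by the Kozachenko-Leonenko estimator.
EULER_GAMMA <- 0.57721566490153286

#' Derive independent child seeds from one root seed
#'
#' All stochastic stages of the pipeline draw their own seed from a single
#' root seed so that sub-stages are individually reproducible: rerunning one
#' stage with its recorded child seed gives the same output as running it
#' inside the full pipeline.
#'
#' @param seed Integer root seed.
#' @param n Number of child seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Coerce the containers used across the package to a samples x features
# matrix, the orientation the entropy estimator works in. Plain matrices are
# taken to be samples x features already; package containers store
# probes x samples and are transposed.
as_sample_matrix <- function(x) {
  if (inherits(x, c("copy_number_matrix", "segmented_matrix"))) {
    t(x$values)
  } else if (is.matrix(x)) {
    x
  } else {
    stop("expected a matrix, copy_number_matrix or segmented_matrix")
  }
}

# Annotation carried by a container, or NULL for plain matrices.
annotation_of <- function(x) {
  if (inherits(x, c("copy_number_matrix", "segmented_matrix"))) x$annotation else NULL
}

stop_if_not_scalar_prob <- function(x, name, open_left = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      x > 1 || x < 0 || (open_left && x == 0)) {
    stop(sprintf("'%s' must be a single proportion in %s0, 1]",
                 name, if (open_left) "(" else "["), call. = FALSE)
  }
  invisible(x)
}
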