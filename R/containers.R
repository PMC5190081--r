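#' Construct a copy number matrix
#'
#' The central data container: a probes x samples matrix of log2 ratios
#' tied to a probe annotation. Provenance flags record which preprocessing
#' steps have been applied.
#'
#' @param values Numeric probes x samples matrix of log2 ratios; rownames
#'   are probe ids, colnames are sample ids.
#' @param annotation A `probe_annotation` with one row per matrix row.
#' @param provenance Named list of logical flags (e.g. `background_corrected`,
#'   `normalized`, `cellularity_corrected`).
#' @return An object of class `copy_number_matrix`.
#' @export
copy_number_matrix <- function(values, annotation, provenance = list()) {
  annotation <- as_probe_annotation(annotation)
  values <- as.matrix(values)
  if (nrow(values) != nrow(annotation)) {
    stop("matrix has ", nrow(values), " rows but annotation has ",
         nrow(annotation), " probes")
  }
  if (is.null(rownames(values))) rownames(values) <- annotation$probe_id
  structure(
    list(values = values, annotation = annotation,
         sample_ids = colnames(values), provenance = provenance),
    class = "copy_number_matrix"
  )
}

#' @export
print.copy_number_matrix <- function(x, ...) {
  cat("copy_number_matrix:", nrow(x$values), "probes x",
      ncol(x$values), "samples\n")
  flags <- names(Filter(isTRUE, x$provenance))
  if (length(flags)) cat("  provenance:", paste(flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.copy_number_matrix <- function(x) dim(x$values)

#' @export
print.segmented_matrix <- function(x, ...) {
  cat("segmented_matrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples;", nrow(x$segments), "segments\n")
  invisible(x)
}

#' @export
dim.segmented_matrix <- function(x) dim(x$values)

#' @export
print.truth_set <- function(x, ...) {
  cat("truth_set:", nrow(x$state), "probes x", ncol(x$state), "samples\n")
  cat("  groups:", paste(sprintf("%s=%d", names(table(x$group)),
                                 table(x$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("entropy_result (%s): H = %.6f nats, n = %d, d = %d\n",
              x$estimator, x$H, x$n, x$d))
  invisible(x)
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("permutation test (%s): T = %.6f, p = %.4g (B = %d, %s)\n",
              x$method, x$T_obs, x$p, x$B, x$sidedness))
  invisible(x)
}
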