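#' Construct a raw two-channel intensity table
#'
#' Holds foreground and background median intensities for the test (tumor)
#' and reference (matched normal) channels, one matrix each, probes x
#' samples, tied to a probe annotation. This is the tabular shape emitted
#' by standard feature-extraction software.
#'
#' @param fg_test,bg_test,fg_ref,bg_ref Nonnegative numeric probes x samples
#'   matrices of equal dimension.
#' @param annotation A `probe_annotation` with one row per probe.
#' @return An object of class `raw_intensity`.
#' @export
raw_intensity <- function(fg_test, bg_test, fg_ref, bg_ref, annotation) {
  annotation <- as_probe_annotation(annotation)
  mats <- list(fg_test = as.matrix(fg_test), bg_test = as.matrix(bg_test),
               fg_ref = as.matrix(fg_ref), bg_ref = as.matrix(bg_ref))
  dims <- unique(lapply(mats, dim))
  if (length(dims) != 1L) stop("all four intensity matrices must share a dimension")
  if (dims[[1]][1] != nrow(annotation)) {
    stop("intensity matrices and annotation disagree on probe count")
  }
  if (any(vapply(mats, function(m) any(m < 0, na.rm = TRUE), logical(1)))) {
    stop("raw intensities must be nonnegative")
  }
  structure(c(mats, list(annotation = annotation,
                         sample_ids = colnames(mats$fg_test),
                         background_corrected = FALSE)),
            class = "raw_intensity")
}

#' Remove control spots
#'
#' Drops every probe flagged as a control in the annotation, preserving the
#' original probe order. Works on raw intensity tables and on log2-ratio
#' matrices alike.
#'
#' @param x A `raw_intensity` or `copy_number_matrix`.
#' @return The same type of object restricted to non-control probes.
#' @export
filter_controls <- function(x) UseMethod("filter_controls")

#' @export
filter_controls.raw_intensity <- function(x) {
  if (is.null(x$annotation$is_control)) stop("annotation has no 'is_control' flag")
  keep <- !x$annotation$is_control
  out <- x
  for (f in c("fg_test", "bg_test", "fg_ref", "bg_ref")) {
    out[[f]] <- x[[f]][keep, , drop = FALSE]
  }
  out$annotation <- x$annotation[keep, , drop = FALSE]
  rownames(out$annotation) <- NULL
  out
}

#' @export
filter_controls.copy_number_matrix <- function(x) {
  if (is.null(x$annotation$is_control)) stop("annotation has no 'is_control' flag")
  keep <- !x$annotation$is_control
  ann <- x$annotation[keep, , drop = FALSE]
  rownames(ann) <- NULL
  copy_number_matrix(x$values[keep, , drop = FALSE], ann,
                     provenance = c(x$provenance, list(controls_removed = TRUE)))
}

#' Background-correct both channels
#'
#' Subtracts background median intensities from foreground median
#' intensities, per channel. Corrected signals may be negative; they are
#' clipped at a positive floor later, at the ratio step.
#'
#' @param raw A `raw_intensity`.
#' @return A `raw_intensity` whose `fg_*` slots hold the corrected signals
#'   (backgrounds are zeroed) and with `background_corrected = TRUE`.
#' @export
background_correct <- function(raw) {
  stopifnot(inherits(raw, "raw_intensity"))
  out <- raw
  out$fg_test <- raw$fg_test - raw$bg_test
  out$fg_ref <- raw$fg_ref - raw$bg_ref
  out$bg_test[] <- 0
  out$bg_ref[] <- 0
  out$background_corrected <- TRUE
  out
}

#' Compute log2 tumor/normal ratios
#'
#' `r = log2(max(test, floor) / max(reference, floor))`. The floor keeps the
#' ratio finite when background correction has driven a signal to zero or
#' below.
#'
#' @param corrected A background-corrected `raw_intensity`.
#' @param floor Positive intensity floor (default 1 intensity unit).
#' @return A [copy_number_matrix()] of log2 ratios.
#' @export
compute_log2_ratio <- function(corrected, floor = 1) {
  stopifnot(inherits(corrected, "raw_intensity"))
  if (!is.numeric(floor) || floor <= 0) stop("'floor' must be positive")
  r <- log2(pmax(corrected$fg_test, floor) / pmax(corrected$fg_ref, floor))
  copy_number_matrix(r, corrected$annotation,
                     provenance = list(
                       background_corrected = isTRUE(corrected$background_corrected)))
}

#' Median-normalize each sample
#'
#' Shifts every sample's log2 ratios so its median is zero, removing
#' sample-level intensity offsets. Idempotent.
#'
#' @param m A `copy_number_matrix`.
#' @return The normalized matrix.
#' @export
normalize_median <- function(m) {
  stopifnot(inherits(m, "copy_number_matrix"))
  med <- apply(m$values, 2, median, na.rm = TRUE)
  out <- m
  out$values <- sweep(m$values, 2, med, "-")
  out$provenance$normalized <- TRUE
  out
}

#' Correct log2 ratios for tumor cellularity
#'
#' An observed ratio from a sample with tumor-cell fraction `c` is a mix of
#' tumor and diploid normal signal: `2^x = c * 2^t + (1 - c)`. The
#' correction inverts the mix, `x_corr = log2(max((2^x - (1 - c)) / c,
#' floor * 2^x))`; the floor branch keeps the result finite for deep losses
#' where the de-mixed intensity would be nonpositive. `c = 1` is the
#' identity. Samples below `min_cellularity` are dropped with a warning,
#' since their signal is too diluted to de-mix reliably.
#'
#' @param m A `copy_number_matrix` or `segmented_matrix`.
#' @param cellularity One tumor-cell proportion in (0, 1] per sample.
#' @param floor Positive relative floor for the clipped branch.
#' @param min_cellularity Samples with cellularity below this are removed.
#' @return Same type as `m`, corrected (possibly with fewer samples).
#' @export
correct_cellularity <- function(m, cellularity, floor = 0.05,
                                min_cellularity = 0.3) {
  if (!inherits(m, c("copy_number_matrix", "segmented_matrix"))) {
    stop("'m' must be a copy_number_matrix or segmented_matrix")
  }
  if (length(cellularity) != ncol(m$values)) {
    stop("need one cellularity per sample")
  }
  if (any(cellularity <= 0) || any(cellularity > 1)) {
    stop("cellularity must be in (0, 1]")
  }
  if (!is.numeric(floor) || floor <= 0) stop("'floor' must be positive")

  low <- cellularity < min_cellularity
  if (any(low)) {
    warning(sum(low), " sample(s) with cellularity < ", min_cellularity,
            " removed: ", paste(colnames(m$values)[low], collapse = ", "))
    m$values <- m$values[, !low, drop = FALSE]
    if (inherits(m, "segmented_matrix")) {
      m$segments <- m$segments[m$segments$sample_id %in% colnames(m$values), ,
                               drop = FALSE]
    }
    m$sample_ids <- colnames(m$values)
    cellularity <- cellularity[!low]
  }

  intens <- 2^m$values
  demixed <- sweep(sweep(intens, 2, 1 - cellularity, "-"), 2, cellularity, "/")
  out <- m
  out$values <- log2(pmax(demixed, floor * intens))
  if (inherits(m, "segmented_matrix")) {
    # segment means must stay consistent with per-probe corrected values
    out$segments <- recompute_segment_means(out)
  } else {
    out$provenance$cellularity_corrected <- TRUE
  }
  out
}

#' Per-sample noise estimate (scaled MAD)
#'
#' For each sample, `MAD = 1.4826 * median(|x - median(x)|)` where `x` is
#' the probe-minus-segment residual when a segmentation is supplied, and the
#' raw log2 ratio otherwise. The 1.4826 factor makes the MAD of Gaussian
#' noise estimate its standard deviation, so MAD is a robust technical
#' quality score that ignores genuine copy-number structure when residuals
#' are used.
#'
#' @param m A `copy_number_matrix`.
#' @param segmented Optional `segmented_matrix` of identical dimension.
#' @param method `"residual"` (default when `segmented` is given),
#'   `"raw"` (ignore the segmentation), or `"diff"` (scaled MAD of
#'   lag-1 probe differences divided by sqrt(2), segmentation-free).
#' @return A `quality_report` data.frame with columns `sample_id`, `mad`,
#'   `n_probes`.
#' @export
compute_mad <- function(m, segmented = NULL,
                        method = c("residual", "raw", "diff")) {
  stopifnot(inherits(m, "copy_number_matrix"))
  method <- match.arg(method)
  x <- m$values
  if (method == "residual") {
    if (is.null(segmented)) {
      method <- "raw"
    } else {
      if (!identical(dim(segmented$values), dim(x))) {
        stop("segmented matrix dimension does not match")
      }
      x <- x - segmented$values
    }
  }
  mads <- if (method == "diff") {
    apply(x, 2, function(v) mad(diff(v)) / sqrt(2))
  } else {
    apply(x, 2, mad)
  }
  out <- data.frame(sample_id = colnames(m$values), mad = unname(mads),
                    n_probes = nrow(x), stringsAsFactors = FALSE)
  class(out) <- c("quality_report", "data.frame")
  out
}

#' Full preprocessing of a raw intensity table
#'
#' Chains control-spot removal, background correction, log2 ratio
#' computation, per-sample median normalization and (optionally)
#' cellularity correction.
#'
#' @param raw A `raw_intensity`.
#' @param cellularity Optional per-sample tumor-cell proportions; when
#'   supplied, cellularity correction is applied.
#' @param floor Intensity floor for the ratio step.
#' @param min_cellularity Exclusion threshold for low-cellularity samples.
#' @return A preprocessed `copy_number_matrix`.
#' @export
preprocess_raw <- function(raw, cellularity = NULL, floor = 1,
                           min_cellularity = 0.3) {
  m <- normalize_median(compute_log2_ratio(background_correct(filter_controls(raw)),
                                           floor = floor))
  if (!is.null(cellularity)) {
    m <- correct_cellularity(m, cellularity, min_cellularity = min_cellularity)
  }
  m
}
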