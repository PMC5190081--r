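# Plain-text table I/O: BED-like probe annotations, probe x sample
# matrices, segment tables and clinical tables, all TSV. Numeric fields are
# written with 17 significant digits so write -> read round-trips exactly.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a probe annotation as BED-like TSV
#'
#' Columns: `chrom`, `start`, `end`, `probe_id`, `is_control`.
#'
#' @param ann A `probe_annotation`.
#' @param path File path.
#' @return `read_probe_annotation` returns a `probe_annotation`;
#'   `write_probe_annotation` returns `path` invisibly.
#' @export
write_probe_annotation <- function(ann, path) {
  ann <- as_probe_annotation(ann)
  df <- data.frame(chrom = ann$chrom, start = ann$start, end = ann$end,
                   probe_id = ann$probe_id,
                   is_control = as.integer(ann$is_control))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_annotation
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("chrom", "start", "end", "probe_id")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(df$end <= df$start)
  if (length(bad)) {
    stop("annotation file '", path, "' has end <= start at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))  # +1 for header
  }
  if (!is.null(df$is_control)) df$is_control <- as.logical(df$is_control)
  as_probe_annotation(df)
}

#' Write / read a probes x samples matrix as TSV
#'
#' First column `probe_id`, one column per sample; values at full precision.
#'
#' @param m A matrix, `copy_number_matrix` or `segmented_matrix`.
#' @param path File path.
#' @param annotation Optional `probe_annotation` to attach on read; when
#'   supplied, `read_matrix_tsv` returns a `copy_number_matrix`.
#' @return `read_matrix_tsv` returns a matrix (or `copy_number_matrix`);
#'   `write_matrix_tsv` returns `path` invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  values <- if (inherits(m, c("copy_number_matrix", "segmented_matrix"))) {
    m$values
  } else {
    as.matrix(m)
  }
  df <- data.frame(probe_id = rownames(values),
                   apply(values, 2, fmt_num),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path, annotation = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") {
    stop("matrix file '", path, "' must have 'probe_id' as first column")
  }
  values <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(values)) {
    bad <- which(!stats::complete.cases(suppressWarnings(
      matrix(as.numeric(values), nrow(values)))))
    stop("matrix file '", path, "' has non-numeric values at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  rownames(values) <- df$probe_id
  if (!is.null(annotation)) copy_number_matrix(values, annotation) else values
}

#' Write the segment table of a segmented matrix
#'
#' @param seg A `segmented_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(seg, path) {
  stopifnot(inherits(seg, "segmented_matrix"))
  s <- seg$segments
  s$mean <- fmt_num(s$mean)
  utils::write.table(s, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

clinical_required_cols <- c("sample_id", "arm", "time_years", "event")

#' Write / read a clinical table as TSV
#'
#' Required columns: `sample_id`, `arm`, `time_years`, `event`; optional
#' pathology covariates (`mandard`, `pT`, `pN`, `differentiation`,
#' `cellularity`) are carried through when present.
#'
#' @param clinical A `clinical_table` data.frame.
#' @param path File path.
#' @return `read_clinical` returns a `clinical_table`; `write_clinical`
#'   returns `path` invisibly.
#' @export
write_clinical <- function(clinical, path) {
  missing <- setdiff(clinical_required_cols, names(clinical))
  if (length(missing)) {
    stop("clinical table is missing column(s): ", paste(missing, collapse = ", "))
  }
  df <- as.data.frame(clinical)
  df$time_years <- fmt_num(df$time_years)
  if (!is.null(df$cellularity)) df$cellularity <- fmt_num(df$cellularity)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clinical
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(clinical_required_cols, names(df))
  if (length(missing)) {
    stop("clinical file '", path, "' is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- which(!is.finite(df$time_years) | df$time_years < 0)
  if (length(bad)) {
    stop("clinical file '", path, "' has invalid survival times at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  bad <- which(!df$event %in% c(0L, 1L))
  if (length(bad)) {
    stop("clinical file '", path, "' has invalid event indicators at line(s): ",
         paste(utils::head(bad + 1L, 5), collapse = ", "))
  }
  class(df) <- c("clinical_table", "data.frame")
  df
}
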