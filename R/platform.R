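#' Describe a synthetic aCGH platform
#'
#' A platform specification captures the geometry of an oligonucleotide
#' aCGH array: how many probes it carries, how they are spread over
#' chromosomes, the genomic spacing between consecutive probes, and the
#' fraction of features that are non-genomic control spots. The defaults
#' emulate a dense custom array with probes evenly spaced at roughly 17 kb
#' over 22 autosomes; the full-scale 180,880-feature geometry is supported
#' but the package default elsewhere is a 10,000-probe desk-scale platform.
#'
#' @param n_probes Total number of array features (controls included).
#' @param n_chromosomes Number of autosomes probes are spread over.
#' @param spacing_bp Distance in base pairs between consecutive probe starts
#'   within a chromosome.
#' @param control_fraction Proportion of features flagged as control spots.
#'   Controls carry no genomic signal and are removed during preprocessing.
#' @return An object of class `platform_spec`.
#' @seealso [make_platform()]
#' @export
platform_spec <- function(n_probes, n_chromosomes = 22L, spacing_bp = 17000,
                          control_fraction = 0) {
  n_probes <- as.integer(n_probes)
  n_chromosomes <- as.integer(n_chromosomes)
  if (is.na(n_probes) || n_probes < 1L) stop("'n_probes' must be a positive count")
  if (is.na(n_chromosomes) || n_chromosomes < 1L) {
    stop("'n_chromosomes' must be a positive count")
  }
  if (!is.numeric(spacing_bp) || spacing_bp <= 0) {
    stop("'spacing_bp' must be a positive length in bp")
  }
  stop_if_not_scalar_prob(control_fraction, "control_fraction")
  if (control_fraction >= 1) stop("'control_fraction' must be < 1")
  if (n_probes < n_chromosomes) stop("'n_probes' must be >= 'n_chromosomes'")
  structure(
    list(n_probes = n_probes, n_chromosomes = n_chromosomes,
         spacing_bp = spacing_bp, control_fraction = control_fraction),
    class = "platform_spec"
  )
}

#' Generate the probe annotation of a synthetic platform
#'
#' Probes are partitioned near-evenly across chromosomes (the first
#' `n_probes %% n_chromosomes` chromosomes receive one extra probe) and laid
#' out with strictly increasing start positions at the requested spacing.
#' Exactly `round(control_fraction * n_probes)` features are flagged as
#' control spots, at seed-dependent positions, so the control count is
#' reproducible for any seed.
#'
#' @param spec A [platform_spec()].
#' @param seed Integer seed governing control-spot placement.
#' @return A `probe_annotation` data.frame with columns `chrom`, `start`,
#'   `end`, `probe_id`, `is_control`, ordered by chromosome then position.
#' @examples
#' ann <- make_platform(platform_spec(1000, control_fraction = 0.05), seed = 1)
#' table(ann$is_control)
#' @export
make_platform <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "platform_spec"))
  per_chrom <- rep(spec$n_probes %/% spec$n_chromosomes, spec$n_chromosomes)
  extra <- spec$n_probes %% spec$n_chromosomes
  if (extra > 0L) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L

  chrom <- rep(paste0("chr", seq_len(spec$n_chromosomes)), per_chrom)
  local_idx <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  start <- (local_idx - 1L) * spec$spacing_bp + 1
  probe_len <- min(60, spec$spacing_bp)  # in-situ oligo length, <= spacing

  n_ctrl <- round(spec$control_fraction * spec$n_probes)
  is_control <- logical(spec$n_probes)
  if (n_ctrl > 0L) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
    is_control[sample.int(spec$n_probes, n_ctrl)] <- TRUE
  }

  ann <- data.frame(
    chrom = chrom,
    start = start,
    end = start + probe_len,
    probe_id = sprintf("P%06d", seq_len(spec$n_probes)),
    is_control = is_control,
    stringsAsFactors = FALSE
  )
  class(ann) <- c("probe_annotation", "data.frame")
  ann
}

#' Validate a probe annotation table
#'
#' @param ann A data.frame with columns `chrom`, `start`, `end`, `probe_id`
#'   and (optionally) `is_control`.
#' @return The annotation, with class `probe_annotation`, invisibly checked.
#' @export
as_probe_annotation <- function(ann) {
  required <- c("chrom", "start", "end", "probe_id")
  missing <- setdiff(required, names(ann))
  if (length(missing)) {
    stop("annotation is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad <- which(ann$end <= ann$start)
  if (length(bad)) {
    stop("annotation has end <= start at row(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(ann$is_control)) ann$is_control <- FALSE
  if (!inherits(ann, "probe_annotation")) {
    class(ann) <- c("probe_annotation", class(ann))
  }
  ann
}

# Chromosome-local 0-based probe index ranges, in annotation order.
chrom_index <- function(ann) {
  split(seq_len(nrow(ann)), factor(ann$chrom, levels = unique(ann$chrom)))
}
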