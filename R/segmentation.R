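#' Segment a single copy-number profile
#'
#' Recursive binary segmentation in the circular-binary-segmentation style:
#' at each window the breakpoint maximizing the two-sample pooled-t
#' statistic is found (leftmost maximizer on ties), its significance is
#' assessed by permuting probe positions within the window, and the split is
#' accepted when the permutation p-value `(1 + exceedances) / (n_perm + 1)`
#' is below `alpha`; the procedure then recurses on both flanks. A constant
#' window is never split, and a zero-variance step (noiseless data) always
#' is, so noiseless profiles are recovered exactly.
#'
#' @param x Numeric vector of log2 ratios of one sample on one chromosome.
#' @param alpha Significance level for accepting a split.
#' @param min_width Minimum segment width in probes (>= 2).
#' @param n_perm Number of within-window permutations.
#' @param seed Optional integer seed; segmentation is deterministic given it.
#' @return data.frame with columns `start_idx`, `end_idx` (0-based,
#'   half-open, chromosome-local) and `mean`, tiling the profile.
#' @examples
#' x <- c(rep(0, 50), rep(1, 50)) + rnorm(100, sd = 0.1)
#' segment_profile(x, seed = 1)
#' @export
segment_profile <- function(x, alpha = 0.01, min_width = 3L, n_perm = 1000L,
                            seed = NULL) {
  if (length(x) < 1L) stop("empty profile")
  if (!all(is.finite(x))) stop("profile contains non-finite values")
  if (min_width < 2L) stop("'min_width' must be >= 2")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(as.integer(seed))
  }
  breaks <- .cbs_breakpoints(as.numeric(x), alpha, as.integer(min_width),
                             as.integer(n_perm))
  bounds <- c(0L, breaks, length(x))
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  means <- vapply(seq_along(start),
                  function(i) mean(x[(start[i] + 1L):end[i]]), numeric(1))
  data.frame(start_idx = start, end_idx = end, mean = means)
}

#' Segment every sample of a cohort, chromosome by chromosome
#'
#' Applies [segment_profile()] independently to each (sample, chromosome)
#' profile and assembles the piecewise-constant matrix: every probe carries
#' its segment mean. Segments never span chromosome boundaries.
#'
#' @param m A `copy_number_matrix`.
#' @param alpha,min_width,n_perm Passed to [segment_profile()].
#' @param seed Integer seed; profiles are visited in a fixed order so the
#'   whole cohort segmentation is deterministic given it.
#' @return A `segmented_matrix`: list with `values` (probes x samples matrix
#'   of segment means), `segments` (data.frame `sample_id`, `chrom`,
#'   `start_idx`, `end_idx`, `mean`; indices chromosome-local, 0-based,
#'   half-open) and `annotation`.
#' @export
segment_cohort <- function(m, alpha = 0.01, min_width = 3L, n_perm = 1000L,
                           seed = 1L) {
  stopifnot(inherits(m, "copy_number_matrix"))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  idx_by_chrom <- chrom_index(m$annotation)
  values <- m$values
  seg_list <- vector("list", ncol(values) * length(idx_by_chrom))
  k <- 0L
  for (j in seq_len(ncol(values))) {
    sid <- colnames(values)[j]
    for (ch in names(idx_by_chrom)) {
      rows <- idx_by_chrom[[ch]]
      segs <- tryCatch(
        segment_profile(values[rows, j], alpha = alpha, min_width = min_width,
                        n_perm = n_perm),
        error = function(e) stop("sample '", sid, "', chromosome '", ch,
                                 "': ", conditionMessage(e), call. = FALSE))
      for (i in seq_len(nrow(segs))) {
        values[rows[(segs$start_idx[i] + 1L):segs$end_idx[i]], j] <- segs$mean[i]
      }
      k <- k + 1L
      seg_list[[k]] <- cbind(sample_id = sid, chrom = ch, segs,
                             stringsAsFactors = FALSE)
    }
  }
  structure(
    list(values = values,
         segments = do.call(rbind, seg_list[seq_len(k)]),
         annotation = m$annotation,
         params = list(alpha = alpha, min_width = min_width,
                       n_perm = n_perm, seed = seed)),
    class = "segmented_matrix"
  )
}

#' Construct a segmented matrix from known segment boundaries
#'
#' Mainly useful for building ground-truth segmentations in simulations.
#'
#' @param values Probes x samples matrix of piecewise-constant values.
#' @param annotation Matching `probe_annotation`.
#' @return A `segmented_matrix` whose segments are the maximal runs of equal
#'   value within each chromosome.
#' @export
as_segmented_matrix <- function(values, annotation) {
  annotation <- as_probe_annotation(annotation)
  values <- as.matrix(values)
  stopifnot(nrow(values) == nrow(annotation))
  idx_by_chrom <- chrom_index(annotation)
  seg_list <- list()
  for (j in seq_len(ncol(values))) {
    for (ch in names(idx_by_chrom)) {
      v <- values[idx_by_chrom[[ch]], j]
      runs <- rle(v)
      end <- cumsum(runs$lengths)
      start <- c(0L, end[-length(end)])
      seg_list[[length(seg_list) + 1L]] <- data.frame(
        sample_id = colnames(values)[j], chrom = ch,
        start_idx = start, end_idx = end, mean = runs$values,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(values = values, segments = do.call(rbind, seg_list),
                 annotation = annotation),
            class = "segmented_matrix")
}

# Recompute segment means from the (possibly transformed) per-probe values;
# used after probe-wise transforms that preserve within-segment constancy.
recompute_segment_means <- function(seg) {
  idx_by_chrom <- chrom_index(seg$annotation)
  s <- seg$segments
  keep <- s$sample_id %in% colnames(seg$values)
  s <- s[keep, , drop = FALSE]
  for (i in seq_len(nrow(s))) {
    rows <- idx_by_chrom[[s$chrom[i]]][(s$start_idx[i] + 1L):s$end_idx[i]]
    s$mean[i] <- mean(seg$values[rows, s$sample_id[i]])
  }
  rownames(s) <- NULL
  s
}
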