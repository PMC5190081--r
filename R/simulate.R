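#' Define an aberration architecture for one simulated patient group
#'
#' An architecture is a pool of candidate copy-number segments plus a rule
#' for how individual tumors draw from it. The `concentration` dial controls
#' inter-tumor heterogeneity: each group first restricts the candidate pool
#' to a fraction `concentration` of its segments (drawn once per group), and
#' every tumor in the group then draws its aberrations from that restricted
#' pool. A small shared pool makes tumors reuse the same genomic locations
#' (homogeneous group, low copy number entropy); with `concentration = 1`
#' tumors draw from the full dispersed pool (heterogeneous group, high
#' entropy).
#'
#' @param candidate_segments data.frame with columns `chrom`, `start_idx`,
#'   `end_idx` (chromosome-local 0-based half-open probe indices) and
#'   `state`, the integer copy state relative to diploid
#'   (loss = -1, neutral = 0, gain = +1, amplification = +2).
#' @param concentration Proportion in (0, 1] of the candidate pool available
#'   to each tumor of the group.
#' @param segments_per_tumor Number of segments each tumor draws.
#' @return An object of class `aberration_architecture`.
#' @export
aberration_architecture <- function(candidate_segments, concentration = 1,
                                    segments_per_tumor = 5L) {
  required <- c("chrom", "start_idx", "end_idx", "state")
  missing <- setdiff(required, names(candidate_segments))
  if (length(missing)) {
    stop("candidate_segments missing column(s): ", paste(missing, collapse = ", "))
  }
  if (any(candidate_segments$end_idx <= candidate_segments$start_idx)) {
    stop("candidate segments must have end_idx > start_idx (half-open)")
  }
  if (!all(candidate_segments$state %in% c(-1L, 0L, 1L, 2L))) {
    stop("copy states must be in {-1, 0, 1, 2}")
  }
  stop_if_not_scalar_prob(concentration, "concentration", open_left = TRUE)
  segments_per_tumor <- as.integer(segments_per_tumor)
  if (is.na(segments_per_tumor) || segments_per_tumor < 1L) {
    stop("'segments_per_tumor' must be a positive count")
  }
  structure(
    list(candidate_segments = candidate_segments,
         concentration = concentration,
         segments_per_tumor = segments_per_tumor),
    class = "aberration_architecture"
  )
}

#' Draw a random candidate-segment pool on a platform
#'
#' Convenience generator of an [aberration_architecture()]: candidate
#' segments are placed uniformly over the non-control probes of the
#' platform, with lengths drawn uniformly from `len_range` (in probes) and
#' copy states drawn uniformly from `states`.
#'
#' @param platform A `probe_annotation` from [make_platform()].
#' @param n_candidates Size of the candidate pool.
#' @param len_range Length-2 integer vector: min and max segment length in
#'   probes.
#' @param states Integer copy states to draw from.
#' @param concentration,segments_per_tumor Passed to
#'   [aberration_architecture()].
#' @param seed Integer seed.
#' @return An `aberration_architecture`.
#' @export
sample_architecture <- function(platform, n_candidates, len_range = c(30L, 120L),
                                states = c(-1L, 1L), concentration = 1,
                                segments_per_tumor = 5L, seed = 1L) {
  platform <- as_probe_annotation(platform)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  sizes <- vapply(chrom_index(platform), length, integer(1))
  chroms <- names(sizes)[sizes >= len_range[1]]
  if (!length(chroms)) stop("no chromosome is long enough for 'len_range'")
  segs <- lapply(seq_len(n_candidates), function(i) {
    ch <- sample(chroms, 1L)
    n_ch <- sizes[[ch]]
    len <- sample(seq(len_range[1], min(len_range[2], n_ch)), 1L)
    start <- sample.int(n_ch - len + 1L, 1L) - 1L
    data.frame(chrom = ch, start_idx = start, end_idx = start + len,
               state = sample(states, 1L), stringsAsFactors = FALSE)
  })
  aberration_architecture(do.call(rbind, segs), concentration = concentration,
                          segments_per_tumor = segments_per_tumor)
}

#' Simulate an aCGH cohort with known ground truth
#'
#' Each sample is built in three steps. (1) Its integer copy-state vector is
#' assembled by drawing `segments_per_tumor` segments from the group's
#' (concentration-restricted) candidate pool; when drawn segments overlap on
#' a chromosome the later draw overwrites the earlier on the overlap.
#' Control probes always keep state 0. (2) The noiseless tumor log2 ratio is
#' `log2((2 + state) / 2)`. (3) The observed ratio mixes tumor with admixed
#' normal cells at the sample's cellularity `c` (drawn uniformly from
#' `cellularity_range`) and adds probe-level Gaussian noise:
#' `r = log2(c * 2^true + (1 - c)) + N(0, noise_sd)`.
#'
#' With `noise_sd = 0` and `cellularity_range = c(1, 1)` the observed matrix
#' equals the true log2 matrix exactly. The default `noise_sd` of 0.33 is
#' chosen so that the per-sample scaled MAD of a flat profile sits in the
#' 0.33-0.34 range typical of a good-quality two-channel hybridization.
#'
#' @param platform A `probe_annotation`.
#' @param arch_by_group Named list of [aberration_architecture()], one per
#'   group; names become group labels.
#' @param n_per_group Samples per group (scalar or one count per group).
#' @param noise_sd Probe-level Gaussian noise standard deviation.
#' @param cellularity_range Interval within (0, 1] the per-sample tumor-cell
#'   fraction is drawn from.
#' @param seed Integer root seed; per-stage child seeds are derived from it.
#' @return List with elements `matrix` (a [copy_number_matrix()] of observed
#'   ratios) and `truth` (a `truth_set` with `state`, `log2`, `cellularity`,
#'   `group`).
#' @export
simulate_cohort <- function(platform, arch_by_group, n_per_group,
                            noise_sd = 0.33, cellularity_range = c(0.3, 0.9),
                            seed = 1L) {
  platform <- as_probe_annotation(platform)
  if (is.null(names(arch_by_group)) || any(names(arch_by_group) == "")) {
    stop("'arch_by_group' must be a named list of architectures")
  }
  if (!all(vapply(arch_by_group, inherits, logical(1), "aberration_architecture"))) {
    stop("every element of 'arch_by_group' must be an aberration_architecture")
  }
  n_groups <- length(arch_by_group)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, n_groups)
  n_per_group <- as.integer(n_per_group)
  if (any(is.na(n_per_group)) || any(n_per_group < 1L)) stop("empty groups are not allowed")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(cellularity_range) != 2L || any(cellularity_range <= 0) ||
      any(cellularity_range > 1) || cellularity_range[1] > cellularity_range[2]) {
    stop("'cellularity_range' must be an interval within (0, 1]")
  }

  idx_by_chrom <- chrom_index(platform)
  for (g in names(arch_by_group)) {
    cs <- arch_by_group[[g]]$candidate_segments
    if (!all(cs$chrom %in% names(idx_by_chrom))) {
      stop("architecture for group '", g, "' references chromosomes absent from the platform")
    }
    sizes <- vapply(idx_by_chrom, length, integer(1))
    if (any(cs$end_idx > sizes[cs$chrom])) {
      stop("architecture for group '", g, "' has segments beyond chromosome bounds")
    }
  }

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  seeds <- derive_seeds(seed, 3L)

  n_probes <- nrow(platform)
  n_total <- sum(n_per_group)
  group <- rep(names(arch_by_group), n_per_group)
  sample_ids <- unlist(lapply(seq_len(n_groups), function(g) {
    sprintf("%s_%02d", names(arch_by_group)[g], seq_len(n_per_group[g]))
  }), use.names = FALSE)

  # Stage 1: copy states per sample.
  set.seed(seeds[1])
  state <- matrix(0L, n_probes, n_total, dimnames = list(platform$probe_id, sample_ids))
  col <- 0L
  for (g in seq_len(n_groups)) {
    arch <- arch_by_group[[g]]
    pool_n <- max(1L, ceiling(arch$concentration * nrow(arch$candidate_segments)))
    pool <- arch$candidate_segments[
      sample.int(nrow(arch$candidate_segments), pool_n), , drop = FALSE]
    for (s in seq_len(n_per_group[g])) {
      col <- col + 1L
      draw <- pool[sample.int(nrow(pool), arch$segments_per_tumor,
                              replace = arch$segments_per_tumor > nrow(pool)), ,
                   drop = FALSE]
      for (k in seq_len(nrow(draw))) {     # later draw overwrites on overlap
        rows <- idx_by_chrom[[draw$chrom[k]]][(draw$start_idx[k] + 1L):draw$end_idx[k]]
        state[rows, col] <- draw$state[k]
      }
    }
  }
  state[platform$is_control, ] <- 0L

  true_log2 <- log2((2 + state) / 2)

  # Stage 2: cellularity mixing.
  set.seed(seeds[2])
  cellularity <- runif(n_total, cellularity_range[1], cellularity_range[2])
  names(cellularity) <- sample_ids
  mixed <- log2(sweep(2^true_log2, 2, cellularity, "*") +
                  rep(1 - cellularity, each = n_probes))

  # Stage 3: probe noise.
  set.seed(seeds[3])
  observed <- mixed
  if (noise_sd > 0) {
    observed <- observed + matrix(rnorm(n_probes * n_total, sd = noise_sd),
                                  n_probes, n_total)
  }

  truth <- structure(
    list(state = state, log2 = true_log2, cellularity = cellularity,
         group = stats::setNames(group, sample_ids)),
    class = "truth_set"
  )
  m <- copy_number_matrix(observed, platform,
                          provenance = list(simulated = TRUE,
                                            noise_sd = noise_sd))
  list(matrix = m, truth = truth)
}

#' Simulate survival outcomes under a proportional-hazards model
#'
#' Event times are exponential with hazard
#' `baseline_rate * exp(log_hr_beta * covariate)`; censoring times are
#' independent exponential with rate `censor_rate`. With
#' `selection = "short_long"` the cohort is restricted to short-term
#' survivors (death within 1 year) and long-term survivors (3 or more years
#' of follow-up), emulating an extreme-survivor case selection.
#'
#' @param truth A `truth_set` from [simulate_cohort()].
#' @param entropy_like_covariate Per-sample numeric covariate driving the
#'   hazard (typically a per-sample entropy contribution).
#' @param log_hr_beta Log hazard ratio per unit covariate.
#' @param baseline_rate,censor_rate Positive exponential rates (per year).
#' @param selection `"none"` or `"short_long"`.
#' @param seed Integer seed.
#' @return A `clinical_table` data.frame with columns `sample_id`, `arm`,
#'   `time_years`, `event` (1 = death from cancer, 0 = censored), `mandard`
#'   (tumor regression grade, NA outside the first arm), `pT`, `pN`,
#'   `differentiation`, `cellularity`. Rows kept by `selection` only.
#' @export
simulate_survival <- function(truth, entropy_like_covariate, log_hr_beta,
                              baseline_rate = 0.25, censor_rate = 0.05,
                              selection = c("none", "short_long"), seed = 1L) {
  selection <- match.arg(selection)
  stopifnot(inherits(truth, "truth_set"))
  n <- length(truth$group)
  if (length(entropy_like_covariate) != n) {
    stop("'entropy_like_covariate' must have one value per sample")
  }
  if (baseline_rate <= 0 || censor_rate <= 0) stop("rates must be positive")

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  hazard <- baseline_rate * exp(log_hr_beta * entropy_like_covariate)
  t_event <- rexp(n, rate = hazard)
  t_cens <- rexp(n, rate = censor_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  arms <- unique(truth$group)
  mandard <- ifelse(truth$group == arms[1], sample(3:5, n, replace = TRUE), NA_integer_)
  clin <- data.frame(
    sample_id = names(truth$group),
    arm = unname(truth$group),
    time_years = time,
    event = event,
    mandard = mandard,
    pT = sample(paste0("pT", 1:4), n, replace = TRUE, prob = c(.1, .2, .5, .2)),
    pN = sample(c("pN0", "pN1"), n, replace = TRUE),
    differentiation = sample(c("well", "moderate", "poor"), n, replace = TRUE),
    cellularity = unname(truth$cellularity),
    stringsAsFactors = FALSE
  )
  if (selection == "short_long") {
    keep <- (clin$time_years < 1 & clin$event == 1L) | clin$time_years >= 3
    clin <- clin[keep, , drop = FALSE]
    rownames(clin) <- NULL
  }
  class(clin) <- c("clinical_table", "data.frame")
  clin
}
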