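# Small fixture builders shared across tests; everything is generated in
# code under fixed seeds.

tiny_platform <- function(n_probes = 500L, n_chromosomes = 5L,
                          control_fraction = 0, seed = 1L) {
  make_platform(platform_spec(n_probes, n_chromosomes,
                              control_fraction = control_fraction),
                seed = seed)
}

tiny_cohort <- function(n_per_group = 5L, n_probes = 500L,
                        n_chromosomes = 5L, noise_sd = 0, cellularity = c(1, 1),
                        concentration = c(1, 1), seed = 1L) {
  pl <- tiny_platform(n_probes, n_chromosomes, seed = seed)
  sds <- derive_seeds(seed, 3)
  archs <- list(
    g1 = sample_architecture(pl, 20, len_range = c(10, 30),
                             concentration = concentration[1],
                             segments_per_tumor = 4, seed = sds[1]),
    g2 = sample_architecture(pl, 20, len_range = c(10, 30),
                             concentration = concentration[2],
                             segments_per_tumor = 4, seed = sds[2])
  )
  sim <- simulate_cohort(pl, archs, n_per_group = n_per_group,
                         noise_sd = noise_sd, cellularity_range = cellularity,
                         seed = sds[3])
  sim$platform <- pl
  sim
}

# Cohort whose true segments are disjoint, well separated and wide, so a
# noiseless segmentation can recover them exactly (overlap resolution in
# the generic generator may leave fragments narrower than min_width, which
# no minimum-width segmentation can isolate).
disjoint_cohort <- function(n_per_group = 4L, noise_sd = 0, seed = 1L) {
  pl <- tiny_platform(500, 5, seed = seed)  # 100 probes per chromosome
  cand <- data.frame(
    chrom = rep(paste0("chr", 1:5), each = 3),
    start_idx = rep(c(10L, 40L, 70L), 5),
    end_idx = rep(c(30L, 60L, 90L), 5),
    state = rep(c(-1L, 1L, 2L), 5))
  arch <- aberration_architecture(cand, concentration = 1,
                                  segments_per_tumor = 4L)
  sim <- simulate_cohort(pl, list(g1 = arch, g2 = arch), n_per_group,
                         noise_sd = noise_sd, cellularity_range = c(1, 1),
                         seed = seed)
  sim$platform <- pl
  sim
}

# Architecture whose candidate pool lives entirely on chr1.
chr1_architecture <- function(n_candidates, concentration, seed,
                              chrom_len = 200L, len_range = c(10L, 25L),
                              segments_per_tumor = 6L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  len <- sample(len_range[1]:len_range[2], n_candidates, replace = TRUE)
  st <- vapply(len, function(l) sample.int(chrom_len - l, 1L) - 1L, integer(1))
  aberration_architecture(
    data.frame(chrom = "chr1", start_idx = st, end_idx = st + len,
               state = sample(c(-1L, 1L), n_candidates, replace = TRUE)),
    concentration = concentration, segments_per_tumor = segments_per_tumor)
}

# Raw intensity table realizing given true log2 ratios with chosen
# backgrounds, for preprocessing round-trips.
raw_from_log2 <- function(log2_ratios, annotation, ref_level = 1000,
                          bg = 100) {
  fg_ref <- matrix(ref_level + bg, nrow(log2_ratios), ncol(log2_ratios),
                   dimnames = dimnames(log2_ratios))
  fg_test <- ref_level * 2^log2_ratios + bg
  bgm <- matrix(bg, nrow(log2_ratios), ncol(log2_ratios))
  raw_intensity(fg_test, bgm, fg_ref, bgm, annotation)
}
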