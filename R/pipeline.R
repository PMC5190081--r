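# End-to-end orchestration: simulate -> preprocess -> segment -> entropy ->
# associate, driven by a nested-list configuration that round-trips through
# YAML.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    genome_build = "synthetic",
    input = list(annotation = NULL, matrix = NULL, clinical = NULL,
                 cellularity = NULL),
    simulate = list(
      enabled = TRUE,
      n_probes = 10000L, n_chromosomes = 22L, spacing_bp = 17000,
      control_fraction = 0.036,
      n_per_group = 20L,
      groups = list(
        CS_like = list(concentration = 0.1),
        S_like = list(concentration = 1.0)
      ),
      n_candidates = 100L, segments_per_tumor = 8L,
      seg_len_range = c(30L, 120L),
      noise_sd = 0.33, cellularity_range = c(0.3, 0.9),
      survival = list(log_hr_beta = log(1.8), baseline_rate = 0.25,
                      censor_rate = 0.05, selection = "none")
    ),
    preprocess = list(enabled = TRUE, floor = 1, min_cellularity = 0.3,
                      cellularity_correction = TRUE),
    segment = list(enabled = TRUE, alpha = 0.01, min_width = 3L,
                   n_perm = 1000L),
    entropy = list(enabled = TRUE, estimator = "normalized", B = 999L,
                   per_chromosome = TRUE, fdr = 0.1,
                   normalization = "cohort_zscore"),
    associate = list(enabled = TRUE, grouping = "median",
                     interaction = FALSE, B = 999L)
  )
}

check_config_keys <- function(config, template, prefix = "") {
  unknown <- setdiff(names(config), names(template))
  if (length(unknown)) {
    stop("unknown config key: ", prefix, unknown[1], call. = FALSE)
  }
  for (k in names(config)) {
    if (is.list(template[[k]]) && !is.null(names(template[[k]])) &&
        is.list(config[[k]]) && k != "groups") {
      check_config_keys(config[[k]], template[[k]], paste0(prefix, k, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(user, template) {
  for (k in names(user)) {
    if (is.list(user[[k]]) && is.list(template[[k]]) &&
        !is.null(names(template[[k]])) && k != "groups") {
      template[[k]] <- merge_config(user[[k]], template[[k]])
    } else {
      template[k] <- list(user[[k]])  # assign via [ so NULL is preserved
    }
  }
  template
}

#' Build a validated pipeline configuration
#'
#' Starts from the package defaults (a desk-scale two-arm synthetic study)
#' and overrides them with the supplied named values; unknown keys are
#' rejected with the offending key named, so typos fail loudly.
#'
#' @param ... Named overrides, nested lists allowed (e.g.
#'   `segment = list(alpha = 0.05)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  template <- default_pipeline_config()
  check_config_keys(user, template)
  cfg <- merge_config(user, template)
  if (is.null(cfg$seed)) stop("config must carry an explicit 'seed'")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline configuration as YAML
#'
#' The file form round-trips losslessly through [pipeline_config()]
#' validation.
#'
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `read_pipeline_config` returns a validated `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for config files")
  }
  yaml::write_yaml(unclass(config), path, precision = 17)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required for config files")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load inputs),
#' preprocess, segment, entropy, associate — and returns a run report with
#' per-stage record counts, the parameters and child seed each stage used,
#' any warnings, and (when `output_dir` is set) the paths and MD5 digests
#' of every written artifact. Reruns with the same configuration are
#' bit-identical.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_report`: list with `stages` (per-stage records),
#'   `results` (in-memory objects: matrix, truth, segmented, entropy,
#'   tests, dispersion, survival models) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- derive_seeds(config$seed, 6L)
  out_dir <- config$output_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  stages <- list()
  results <- list()
  emit <- function(obj, writer, file) {
    if (is.null(out_dir)) return(NULL)
    path <- file.path(out_dir, file)
    writer(obj, path)
    stats::setNames(as.character(tools::md5sum(path)), path)
  }
  record <- function(name, n_records, params, outputs = NULL, warnings = character()) {
    stages[[name]] <<- list(stage = name, n_records = n_records,
                            params = params, outputs = outputs,
                            warnings = warnings)
  }

  # ---- stage 1: simulate or load -------------------------------------
  if (isTRUE(config$simulate$enabled)) {
    sc <- config$simulate
    platform <- make_platform(
      platform_spec(sc$n_probes, sc$n_chromosomes, sc$spacing_bp,
                    sc$control_fraction),
      seed = seeds[1])
    arch_seeds <- derive_seeds(seeds[1], length(sc$groups))
    archs <- lapply(seq_along(sc$groups), function(i) {
      g <- sc$groups[[i]]
      sample_architecture(platform, n_candidates = sc$n_candidates,
                          len_range = sc$seg_len_range,
                          concentration = g$concentration,
                          segments_per_tumor = sc$segments_per_tumor,
                          seed = arch_seeds[i])
    })
    names(archs) <- names(sc$groups)
    sim <- simulate_cohort(platform, archs, n_per_group = sc$n_per_group,
                           noise_sd = sc$noise_sd,
                           cellularity_range = sc$cellularity_range,
                           seed = seeds[2])
    m <- sim$matrix
    results$truth <- sim$truth
    cellularity <- sim$truth$cellularity
    group_labels <- sim$truth$group
    outs <- c(emit(platform, write_probe_annotation, "annotation.tsv"),
              emit(m, write_matrix_tsv, "observed_log2.tsv"))
    record("simulate", ncol(m$values),
           params = c(sc[c("n_probes", "n_chromosomes", "noise_sd")],
                      list(seed = seeds[2])),
           outputs = outs)
  } else {
    inp <- config$input
    if (is.null(inp$annotation) || is.null(inp$matrix)) {
      stop("simulation disabled and no input annotation/matrix configured")
    }
    ann <- read_probe_annotation(inp$annotation)
    m <- read_matrix_tsv(inp$matrix, annotation = ann)
    clin <- if (!is.null(inp$clinical)) read_clinical(inp$clinical) else NULL
    cellularity <- if (!is.null(clin)) clin$cellularity else NULL
    group_labels <- if (!is.null(clin)) stats::setNames(clin$arm, clin$sample_id) else NULL
    results$clinical <- clin
    record("load", ncol(m$values), params = inp[!vapply(inp, is.null, TRUE)])
  }
  results$matrix <- m
  results$observed <- m

  # ---- stage 2: preprocess -------------------------------------------
  if (isTRUE(config$preprocess$enabled)) {
    pc <- config$preprocess
    warns <- character()
    m <- withCallingHandlers({
      m2 <- filter_controls(m)
      m2 <- normalize_median(m2)
      if (isTRUE(pc$cellularity_correction) && !is.null(cellularity)) {
        m2 <- correct_cellularity(m2, cellularity,
                                  min_cellularity = pc$min_cellularity)
      }
      m2
    }, warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
    keep <- colnames(m$values)
    if (!is.null(group_labels)) group_labels <- group_labels[keep]
    if (!is.null(cellularity)) cellularity <- cellularity[keep]
    qr <- compute_mad(m)
    results$matrix <- m
    results$quality <- qr
    record("preprocess", nrow(m$values),
           params = pc[c("floor", "min_cellularity", "cellularity_correction")],
           outputs = c(emit(m, write_matrix_tsv, "preprocessed_log2.tsv")),
           warnings = warns)
  }

  # ---- stage 3: segment ----------------------------------------------
  if (isTRUE(config$segment$enabled)) {
    sg <- config$segment
    seg <- segment_cohort(m, alpha = sg$alpha, min_width = sg$min_width,
                          n_perm = sg$n_perm, seed = seeds[3])
    results$segmented <- seg
    results$quality <- compute_mad(m, segmented = seg)
    record("segment", nrow(seg$segments),
           params = c(sg[c("alpha", "min_width", "n_perm")],
                      list(seed = seeds[3])),
           outputs = c(emit(seg, write_matrix_tsv, "segmented_log2.tsv"),
                       emit(seg, write_segments_tsv, "segments.tsv")))
    entropy_input <- seg
  } else {
    entropy_input <- m
  }

  # ---- stage 4: entropy ----------------------------------------------
  if (isTRUE(config$entropy$enabled)) {
    ec <- config$entropy
    h <- per_sample_entropy(entropy_input, normalization = ec$normalization,
                            estimator = ec$estimator)
    results$entropy <- h
    outs <- NULL
    if (!is.null(out_dir)) {
      path <- file.path(out_dir, "entropy.tsv")
      utils::write.table(
        data.frame(sample_id = names(h), entropy = fmt_num(h)),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
      outs <- stats::setNames(as.character(tools::md5sum(path)), path)
    }
    if (!is.null(group_labels)) {
      results$group_test <- entropy_permutation_test(
        entropy_input, group_labels, B = ec$B, seed = seeds[4],
        estimator = ec$estimator)
      if (isTRUE(ec$per_chromosome)) {
        results$per_chromosome <- per_chromosome_entropy(
          entropy_input, group_labels, B = ec$B, seed = seeds[4],
          estimator = ec$estimator, fdr = ec$fdr)
      }
      results$dispersion <- pca_dispersion(entropy_input, group_labels)
    }
    record("entropy", length(h),
           params = c(ec[c("estimator", "B", "normalization")],
                      list(seed = seeds[4])),
           outputs = outs)
  }

  # ---- stage 5: associate --------------------------------------------
  if (isTRUE(config$associate$enabled) && !is.null(results$entropy)) {
    ac <- config$associate
    if (is.null(results$clinical) && isTRUE(config$simulate$enabled)) {
      sv <- config$simulate$survival
      truth_kept <- results$truth
      keep <- names(results$entropy)
      truth_kept$group <- truth_kept$group[keep]
      truth_kept$cellularity <- truth_kept$cellularity[keep]
      results$clinical <- simulate_survival(
        truth_kept, results$entropy, log_hr_beta = sv$log_hr_beta,
        baseline_rate = sv$baseline_rate, censor_rate = sv$censor_rate,
        selection = sv$selection, seed = seeds[5])
    }
    clin <- results$clinical
    if (!is.null(clin) && nrow(clin) >= 4L && sum(clin$event) >= 1L) {
      h <- results$entropy[clin$sample_id]
      results$cox <- fit_cox(h, clin, interaction = isTRUE(ac$interaction))
      grp <- group_by_entropy(h, method = ac$grouping, clinical = clin)
      results$grouping <- grp
      results$km <- km_logrank(grp, clin)
      if (!is.null(clin$cellularity) && !is.null(group_labels)) {
        results$confounder <- cellularity_confounder_model(
          h, group_labels[clin$sample_id], clin$cellularity)
      }
      record("associate", nrow(clin),
             params = c(ac[c("grouping", "interaction")],
                        list(seed = seeds[5])),
             outputs = c(emit(clin, write_clinical, "clinical.tsv")))
    } else {
      record("associate", 0L, params = list(),
             warnings = "clinical table too small for survival modeling")
    }
  }

  structure(list(stages = stages, results = results, config = config),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline_report:", length(x$stages), "stages\n")
  for (s in x$stages) {
    cat(sprintf("  %-10s records: %-6d %s\n", s$stage, s$n_records,
                if (length(s$warnings)) paste0("(", length(s$warnings),
                                               " warning(s))") else ""))
  }
  invisible(x)
}
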