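#' @importFrom survival coxph survfit survdiff Surv
NULL

#' Cox proportional-hazards fit of survival on entropy
#'
#' Fits the partial likelihood of cancer-specific survival on the
#' continuous per-patient entropy value, optionally adding the treatment
#' arm and an arm x entropy interaction term. The hazard ratio is per unit
#' of entropy; the 95% confidence interval and p-value are Wald-based.
#'
#' @param entropy Per-patient numeric vector, aligned with `clinical` rows.
#' @param clinical A `clinical_table` (needs `time_years`, `event`, and
#'   `arm` when `interaction = TRUE`).
#' @param interaction Include treatment arm and its interaction with
#'   entropy.
#' @return A `survival_model_result`: list with `HR`, `ci_low`, `ci_high`,
#'   `p` (for the entropy term), `interaction_p` (when requested), `n`,
#'   `events`, and the underlying `coxph` fit.
#' @export
fit_cox <- function(entropy, clinical, interaction = FALSE) {
  if (length(entropy) != nrow(clinical)) {
    stop("'entropy' must align with the clinical rows")
  }
  if (sum(clinical$event) < 1L) stop("no events in the clinical table")
  df <- data.frame(time = clinical$time_years, event = clinical$event,
                   entropy = entropy)
  if (interaction) {
    df$arm <- factor(clinical$arm)
    fit <- coxph(Surv(time, event) ~ entropy * arm, data = df)
  } else {
    fit <- coxph(Surv(time, event) ~ entropy, data = df)
  }
  sm <- summary(fit)
  co <- sm$coefficients["entropy", ]
  ci <- sm$conf.int["entropy", ]
  res <- list(HR = unname(co["exp(coef)"]),
              ci_low = unname(ci["lower .95"]),
              ci_high = unname(ci["upper .95"]),
              p = unname(co["Pr(>|z|)"]),
              n = sm$n, events = sm$nevent, fit = fit)
  if (interaction) {
    inter_row <- grep(":", rownames(sm$coefficients), value = TRUE)
    res$interaction_p <- unname(sm$coefficients[inter_row, "Pr(>|z|)"])
  }
  structure(res, class = "survival_model_result")
}

#' @export
print.survival_model_result <- function(x, ...) {
  cat(sprintf("Cox PH: HR %.3f (95%% CI %.3f-%.3f), p = %.4g, n = %d, events = %d\n",
              x$HR, x$ci_low, x$ci_high, x$p, x$n, x$events))
  if (!is.null(x$interaction_p)) {
    cat(sprintf("  treatment interaction p = %.4g\n", x$interaction_p))
  }
  invisible(x)
}

#' Group patients by their entropy values
#'
#' Two dichotomization procedures:
#'
#' * `"median"` — split at the sample median; values equal to the median go
#'   to the low-entropy group, so group sizes never differ by more than 1.
#' * `"tertile_merge"` — order patients by entropy, form three equal-sized
#'   groups (remainders go to the lower tertiles first), then merge the two
#'   adjacent groups whose Kaplan-Meier curves overlap the most,
#'   operationalized as the adjacent pair with the larger pairwise log-rank
#'   p-value. Requires `clinical` unless `merge` names the pair explicitly.
#'
#' @param entropy Per-patient numeric values.
#' @param method `"median"` or `"tertile_merge"`.
#' @param clinical Clinical table, needed for `merge = "auto"`.
#' @param merge For `tertile_merge`: `"auto"`, `"low_mid"` or `"mid_high"`.
#' @return A `grouping_result`: list with `groups` (factor `low`/`high`),
#'   `cutpoints`, `method`, and `merged_pair` for tertile merging.
#' @export
group_by_entropy <- function(entropy, method = c("median", "tertile_merge"),
                             clinical = NULL,
                             merge = c("auto", "low_mid", "mid_high")) {
  method <- match.arg(method)
  merge <- match.arg(merge)
  if (length(unique(entropy)) < 2L) stop("all entropy values are equal")
  n <- length(entropy)

  if (method == "median") {
    cut <- median(entropy)
    groups <- factor(ifelse(entropy <= cut, "low", "high"),
                     levels = c("low", "high"))
    return(structure(list(groups = groups, cutpoints = cut, method = method),
                     class = "grouping_result"))
  }

  if (n < 3L) stop("tertile_merge needs at least 3 patients")
  ord <- order(entropy)
  base <- n %/% 3L
  sizes <- rep(base, 3L)
  extra <- n %% 3L
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  tert <- integer(n)
  tert[ord] <- rep(1:3, sizes)
  tert <- factor(tert, labels = c("T1", "T2", "T3"))

  if (merge == "auto") {
    if (is.null(clinical)) stop("'clinical' is required for merge = 'auto'")
    p_lm <- pairwise_logrank_p(clinical, tert, c("T1", "T2"))
    p_mh <- pairwise_logrank_p(clinical, tert, c("T2", "T3"))
    merge <- if (p_lm >= p_mh) "low_mid" else "mid_high"
  }
  groups <- if (merge == "low_mid") {
    factor(ifelse(tert %in% c("T1", "T2"), "low", "high"),
           levels = c("low", "high"))
  } else {
    factor(ifelse(tert == "T1", "low", "high"), levels = c("low", "high"))
  }
  bounds <- cumsum(sizes)
  cutpoints <- sort(entropy)[bounds[-3]]
  structure(list(groups = groups, cutpoints = cutpoints, method = method,
                 merged_pair = merge, tertiles = tert),
            class = "grouping_result")
}

pairwise_logrank_p <- function(clinical, groups, pair) {
  keep <- groups %in% pair
  df <- data.frame(time = clinical$time_years[keep],
                   event = clinical$event[keep],
                   g = droplevels(groups[keep]))
  sd <- survdiff(Surv(time, event) ~ g, data = df)
  pchisq(sd$chisq, df = 1, lower.tail = FALSE)
}

#' Kaplan-Meier curves and log-rank test for entropy groups
#'
#' Product-limit survival estimates per group with median survival and its
#' 95% confidence interval, plus the log-rank test of any group difference.
#'
#' @param groups A `grouping_result` (or a factor).
#' @param clinical A `clinical_table` aligned with the grouping.
#' @return A `km_result`: list with `fit` (a `survfit`), `table`
#'   (data.frame `group`, `n`, `events`, `median`, `ci_low`, `ci_high`),
#'   `chisq`, `p`.
#' @export
km_logrank <- function(groups, clinical) {
  g <- if (inherits(groups, "grouping_result")) groups$groups else as.factor(groups)
  if (length(g) != nrow(clinical)) stop("groups must align with clinical rows")
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 non-empty groups")
  df <- data.frame(time = clinical$time_years, event = clinical$event, g = g)
  fit <- survfit(Surv(time, event) ~ g, data = df, conf.type = "log-log")
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list("all", names(tab)))
  sd <- survdiff(Surv(time, event) ~ g, data = df)
  p <- pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  out_tab <- data.frame(
    group = sub("^g=", "", rownames(tab)),
    n = tab[, "records"], events = tab[, "events"],
    median = tab[, "median"],
    ci_low = tab[, grep("LCL", colnames(tab))],
    ci_high = tab[, grep("UCL", colnames(tab))],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(fit = fit, table = out_tab, chisq = sd$chisq, p = p),
            class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("log-rank chisq = %.3f, p = %.4g\n", x$chisq, x$p))
  invisible(x)
}

#' Permutation association between entropy and a categorical covariate
#'
#' For a two-level covariate the statistic is the difference in mean entropy
#' between levels (two-sided); for more levels it is the ANOVA-style ratio
#' of between-level to within-level mean squares. The p-value comes from `B`
#' permutations of the entropy values across patients, with the add-one
#' correction.
#'
#' @param entropy Per-patient numeric values.
#' @param covariate Categorical covariate (>= 2 levels with >= 2 patients
#'   each); `NA` levels are dropped with their patients.
#' @param B Number of permutations.
#' @param seed Integer seed.
#' @return List with `statistic`, `p`, `B`, `levels`, `type`
#'   (`"mean_difference"` or `"f_ratio"`).
#' @export
covariate_association <- function(entropy, covariate, B = 999L, seed = 1L) {
  keep <- !is.na(covariate)
  entropy <- entropy[keep]
  covariate <- droplevels(as.factor(covariate[keep]))
  sizes <- table(covariate)
  if (nlevels(covariate) < 2L || any(sizes < 2L)) {
    stop("need >= 2 covariate levels with >= 2 patients each")
  }
  two_level <- nlevels(covariate) == 2L
  stat_fun <- if (two_level) {
    function(e) diff(rev(tapply(e, covariate, mean)))  # level1 - level2
  } else {
    function(e) {
      grand <- mean(e)
      means <- tapply(e, covariate, mean)
      ssb <- sum(sizes * (means - grand)^2)
      ssw <- sum((e - means[covariate])^2)
      dfb <- nlevels(covariate) - 1L
      dfw <- length(e) - nlevels(covariate)
      if (ssw == 0) Inf else (ssb / dfb) / (ssw / dfw)
    }
  }
  obs <- unname(stat_fun(entropy))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  perm <- vapply(seq_len(B), function(b) stat_fun(sample(entropy)), numeric(1))
  p <- if (two_level) {
    (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (B + 1)
  } else {
    (1 + sum(perm >= obs - 1e-12)) / (B + 1)
  }
  list(statistic = obs, p = p, B = B, levels = levels(covariate),
       type = if (two_level) "mean_difference" else "f_ratio")
}

#' Linear model of entropy on group with cellularity as confounder
#'
#' Fits `entropy ~ group + cellularity` by least squares and reports the
#' group effect adjusted for tumor cellularity, guarding against the
#' concern that apparent entropy differences merely reflect differing
#' tumor-cell content.
#'
#' @param entropy Per-patient numeric values.
#' @param group_label Two-level grouping (e.g. treatment arm).
#' @param cellularity Per-patient tumor-cell proportions.
#' @return List with `group_effect`, `se`, `p`, `cellularity_effect`,
#'   `cellularity_defined` (FALSE when cellularity is constant and its term
#'   drops out), and the `lm` fit.
#' @export
cellularity_confounder_model <- function(entropy, group_label, cellularity) {
  n <- length(entropy)
  if (length(group_label) != n || length(cellularity) != n) {
    stop("'entropy', 'group_label' and 'cellularity' must be aligned")
  }
  g <- as.factor(group_label)
  if (nlevels(g) != 2L) stop("'group_label' must have exactly two levels")
  cell_ok <- sd(cellularity) > 0
  if (!cell_ok) {
    warning("cellularity is constant; its coefficient is undefined and dropped")
    fit <- lm(entropy ~ g)
  } else {
    fit <- lm(entropy ~ g + cellularity)
  }
  sm <- summary(fit)$coefficients
  grow <- rownames(sm)[startsWith(rownames(sm), "g")]
  list(group_effect = unname(sm[grow, "Estimate"]),
       se = unname(sm[grow, "Std. Error"]),
       p = unname(sm[grow, "Pr(>|t|)"]),
       cellularity_effect = if (cell_ok) unname(sm["cellularity", "Estimate"]) else NA_real_,
       cellularity_defined = cell_ok,
       fit = fit)
}

#' Match probes between two platforms by genomic position
#'
#' Pairs probes of two annotations one-to-one within each chromosome by
#' greedy nearest-midpoint matching: candidate pairs within `tolerance_bp`
#' are sorted by distance (ties broken by genomic position) and accepted
#' while both probes are unused. The pairing is symmetric in its arguments.
#'
#' @param annotA,annotB Probe annotations (same genome build assumed).
#' @param tolerance_bp Maximum midpoint distance for a match.
#' @return data.frame with columns `index_a`, `index_b`, `distance_bp`.
#' @export
match_probes <- function(annotA, annotB, tolerance_bp) {
  annotA <- as_probe_annotation(annotA)
  annotB <- as_probe_annotation(annotB)
  if (tolerance_bp < 0) stop("'tolerance_bp' must be nonnegative")
  posA <- (annotA$start + annotA$end) / 2
  posB <- (annotB$start + annotB$end) / 2
  out <- list()
  for (ch in intersect(unique(annotA$chrom), unique(annotB$chrom))) {
    ia <- which(annotA$chrom == ch)
    ib <- which(annotB$chrom == ch)
    pb_ord <- ib[order(posB[ib])]
    pb <- posB[pb_ord]
    # candidate pairs within tolerance via a window scan on sorted B
    cand <- list()
    for (a in ia) {
      lo <- findInterval(posA[a] - tolerance_bp, pb) + 1L
      hi <- findInterval(posA[a] + tolerance_bp, pb)
      if (hi >= lo) {
        j <- pb_ord[lo:hi]
        cand[[length(cand) + 1L]] <- data.frame(
          index_a = a, index_b = j, distance_bp = abs(posA[a] - posB[j]))
      }
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    pa_c <- posA[cand$index_a]; pb_c <- posB[cand$index_b]
    cand <- cand[order(cand$distance_bp, pmin(pa_c, pb_c), pmax(pa_c, pb_c)), ,
                 drop = FALSE]
    used_a <- logical(nrow(annotA)); used_b <- logical(nrow(annotB))
    for (i in seq_len(nrow(cand))) {
      a <- cand$index_a[i]; b <- cand$index_b[i]
      if (!used_a[a] && !used_b[b]) {
        used_a[a] <- TRUE; used_b[b] <- TRUE
        out[[length(out) + 1L]] <- cand[i, ]
      }
    }
  }
  if (!length(out)) {
    return(data.frame(index_a = integer(), index_b = integer(),
                      distance_bp = numeric()))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$index_a), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Mean segmented copy-number profile across samples
#'
#' @param seg A `segmented_matrix` (or `copy_number_matrix`).
#' @return data.frame with the probe annotation columns plus `mean_value`,
#'   the per-probe arithmetic mean across samples.
#' @export
mean_aberration_profile <- function(seg) {
  if (!inherits(seg, c("segmented_matrix", "copy_number_matrix"))) {
    stop("'seg' must be a segmented_matrix or copy_number_matrix")
  }
  cbind(as.data.frame(seg$annotation),
        mean_value = rowMeans(seg$values))
}
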