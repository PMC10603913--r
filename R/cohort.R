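#' Per-subject summary of vitals and pressure load
#'
#' Arithmetic mean and sd of each vital channel over its valid samples, plus
#' the mean total pressure load, one row per subject. Subjects without a
#' single valid sample in any channel are excluded with a warning.
#'
#' @param dataset A `cohort_dataset`.
#' @param preprocess Run [preprocess_vitals()] on each subject first
#'   (default `TRUE`).
#' @param bounds,qconfig Preprocessing parameters.
#' @return A data frame with columns `subject_id`, `group`,
#'   `<ch>_mean`/`<ch>_sd` for spo2/hr/temp, and `mean_pressure_load`.
#' @export
subject_means <- function(dataset, preprocess = TRUE,
                          bounds = range_bounds(),
                          qconfig = quality_config()) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  rows <- list()
  for (s in dataset$subjects) {
    v <- s$vitals
    if (preprocess) v <- preprocess_vitals(v, bounds, qconfig)$series
    any_valid <- FALSE
    row <- list(subject_id = s$profile$subject_id, group = s$profile$group)
    for (ch in VITAL_CHANNELS) {
      vals <- v[[ch]][v[[paste0(ch, "_valid")]]]
      row[[paste0(ch, "_mean")]] <- if (length(vals)) mean(vals) else NA_real_
      row[[paste0(ch, "_sd")]] <- if (length(vals)) stats::sd(vals) else
        NA_real_
      any_valid <- any_valid || length(vals) > 0
    }
    row$mean_pressure_load <- if (length(s$pressure$sum_load)) {
      mean(s$pressure$sum_load)
    } else NA_real_
    if (!any_valid) {
      warning("subject ", s$profile$subject_id,
              " has no valid data; excluded")
      next
    }
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  do.call(rbind, rows)
}

#' Welch's unequal-variances t-test
#'
#' Two-sided test of equal means with the Welch statistic and the
#' Welch-Satterthwaite degrees of freedom; significance is flagged at
#' `alpha` (default 0.001, the level used for all group comparisons).
#'
#' @param a,b Numeric vectors of per-subject means, each of length >= 2.
#' @param alpha Significance level for the flag.
#' @return A list of class `group_comparison`: `mean_a`, `sd_a`, `n_a`,
#'   `mean_b`, `sd_b`, `n_b`, `t`, `df`, `p`, `significant`.
#' @export
welch_test <- function(a, b, alpha = 0.001) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 subjects")
  }
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  if (va + vb == 0) {               # two constant groups: degenerate test
    tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    df <- NA_real_
    p <- if (mean(a) == mean(b)) 1 else 0
  } else {
    tstat <- (mean(a) - mean(b)) / sqrt(va + vb)
    df <- (va + vb)^2 /
      (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(mean_a = mean(a), sd_a = stats::sd(a), n_a = length(a),
                 mean_b = mean(b), sd_b = stats::sd(b), n_b = length(b),
                 t = tstat, df = df, p = p, significant = p < alpha),
            class = "group_comparison")
}

cohort_channels <- function() {
  c(paste0(VITAL_CHANNELS, "_mean"), "mean_pressure_load")
}

#' Patient-vs-control comparison per channel
#'
#' Welch tests of patient vs control per-subject means for SpO2, HR, skin
#' temperature, and mean pressure load.
#'
#' @param summaries Output of [subject_means()].
#' @param alpha Significance level.
#' @return A data frame with one row per channel: group means/sds, `t`,
#'   `df`, `p`, `significant`.
#' @export
compare_groups <- function(summaries, alpha = 0.001) {
  rows <- lapply(cohort_channels(), function(ch) {
    w <- welch_test(summaries[[ch]][summaries$group == "patient"],
                    summaries[[ch]][summaries$group == "control"], alpha)
    data.frame(channel = sub("_mean$", "", ch), stratifier = "group",
               mean_a = w$mean_a, sd_a = w$sd_a, mean_b = w$mean_b,
               sd_b = w$sd_b, t = w$t, df = w$df, p = w$p,
               significant = w$significant)
  })
  do.call(rbind, rows)
}

#' Stratify patients on a preexisting-condition flag
#'
#' Splits the patient subjects on one condition flag (e.g. a PU surgery
#' prior to the study) and runs a Welch test per channel, including the mean
#' pressure load. Group A has the condition, group B does not.
#'
#' @param dataset A `cohort_dataset`.
#' @param condition One of `diabetes`, `immobile`, `paraplegic`, `prior_pu`,
#'   `prior_pu_surgery`.
#' @param summaries Optional precomputed [subject_means()] (recomputed
#'   otherwise).
#' @param alpha Significance level.
#' @param ... Passed to [subject_means()].
#' @return A data frame as in [compare_groups()], `stratifier` set to the
#'   condition.
#' @export
stratify_by_condition <- function(dataset, condition, summaries = NULL,
                                  alpha = 0.001, ...) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  if (is.null(summaries)) summaries <- subject_means(dataset, ...)
  patients <- summaries[summaries$group == "patient", , drop = FALSE]
  flags <- vapply(patients$subject_id, function(id) {
    dataset$subjects[[id]]$profile$conditions[[condition]]
  }, logical(1))
  if (all(flags) || !any(flags)) {
    stop("empty stratum: condition '", condition,
         "' is constant across patients")
  }
  rows <- lapply(cohort_channels(), function(ch) {
    w <- welch_test(patients[[ch]][flags], patients[[ch]][!flags], alpha)
    data.frame(channel = sub("_mean$", "", ch), stratifier = condition,
               mean_a = w$mean_a, sd_a = w$sd_a, mean_b = w$mean_b,
               sd_b = w$sd_b, t = w$t, df = w$df, p = w$p,
               significant = w$significant)
  })
  do.call(rbind, rows)
}
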