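#' Early-warning predictor configuration
#'
#' The predictor compares the trailing one-hour rolling mean of tissue SpO2
#' with the expanding mean of all patient data available at that time,
#' `diffSpO2 = rolling - expanding`, and flags a warning when the difference
#' falls to the threshold or below. The rolling mean is only computed when at
#' least `min_valid_frac` of the SpO2 samples in the window are valid.
#'
#' @param window Rolling-window length in minutes (default 60).
#' @param min_valid_frac Minimum valid fraction in the window, inclusive
#'   (default 0.9).
#' @param thres Warning threshold in percentage points (default -3; a
#'   decline, so negative).
#' @param warmup Minutes from series start before the expanding mean is
#'   trusted (default 120); earlier states are `undefined`.
#' @param merge_gap Warn runs separated by at most this many minutes of
#'   non-warn state merge into one alarm (default 60).
#' @return An object of class `predictor_config`.
#' @export
predictor_config <- function(window = 60, min_valid_frac = 0.9, thres = -3,
                             warmup = 120, merge_gap = 60) {
  if (window <= 0) stop("window must be > 0")
  if (min_valid_frac <= 0 || min_valid_frac > 1) {
    stop("min_valid_frac must lie in (0, 1]")
  }
  structure(list(window = window, min_valid_frac = min_valid_frac,
                 thres = thres, warmup = warmup, merge_gap = merge_gap),
            class = "predictor_config")
}

#' Validity-gated rolling mean of SpO2
#'
#' Right-aligned window of `config$window` minutes ending at (and including)
#' each timestamp: the mean of the valid SpO2 values in the window, absent
#' (`NA`) when the valid fraction is below `min_valid_frac` or the window
#' underruns the series start. Forward-filled values count as valid.
#'
#' @param series A gridded [vital_series()].
#' @param config A [predictor_config()].
#' @return Numeric vector aligned with `series$t`.
#' @export
rolling_mean_spo2 <- function(series, config = predictor_config()) {
  stopifnot(inherits(series, "vital_series"))
  interval <- series_interval(series)
  w <- round(config$window / interval)
  n <- nrow(series)
  out <- rep(NA_real_, n)
  if (n == 0 || w < 1) return(out)
  valid <- series$spo2_valid
  vals <- ifelse(valid, series$spo2, 0)
  cv <- cumsum(as.numeric(valid))
  cx <- cumsum(vals)
  i <- seq_len(n)
  ok <- i >= w
  nv <- cv - c(rep(0, w), cv)[i]
  sx <- cx - c(rep(0, w), cx)[i]
  defined <- ok & (nv / w >= config$min_valid_frac) & nv > 0
  out[defined] <- sx[defined] / nv[defined]
  out
}

#' Expanding mean of SpO2
#'
#' The mean of all valid SpO2 values from the series start up to and
#' including each timestamp; absent before `warmup` minutes have elapsed or
#' while no valid value has been seen.
#'
#' @param series A gridded [vital_series()].
#' @param config A [predictor_config()].
#' @return Numeric vector aligned with `series$t`.
#' @export
expanding_mean_spo2 <- function(series, config = predictor_config()) {
  stopifnot(inherits(series, "vital_series"))
  n <- nrow(series)
  out <- rep(NA_real_, n)
  if (n == 0) return(out)
  valid <- series$spo2_valid
  cv <- cumsum(as.numeric(valid))
  cx <- cumsum(ifelse(valid, series$spo2, 0))
  defined <- cv > 0 & (series$t - series$t[1]) >= config$warmup
  out[defined] <- cx[defined] / cv[defined]
  out
}

#' Compute the predictor trace: diffSpO2 and warn/normal state
#'
#' `diff = rolling - expanding` wherever both are defined; the state is
#' `warn` when `diff <= thres` (inclusive), `normal` when defined and above
#' the threshold, and `undefined` elsewhere.
#'
#' @param series A preprocessed [vital_series()].
#' @param config A [predictor_config()].
#' @return A data frame of class `predictor_trace`: `t`, `rolling_mean`,
#'   `expanding_mean`, `diff`, `state`.
#' @export
diff_and_state <- function(series, config = predictor_config()) {
  rolling <- rolling_mean_spo2(series, config)
  expanding <- expanding_mean_spo2(series, config)
  d <- rolling - expanding
  state <- ifelse(is.na(d), "undefined",
                  ifelse(d <= config$thres, "warn", "normal"))
  out <- data.frame(t = series$t, rolling_mean = rolling,
                    expanding_mean = expanding, diff = d, state = state)
  attr(out, "subject_id") <- attr(series, "subject_id")
  attr(out, "interval") <- series_interval(series)
  class(out) <- c("predictor_trace", "data.frame")
  out
}

#' Merge warn states into alarm events
#'
#' Maximal runs of `warn` become alarm intervals; runs separated by at most
#' `merge_gap` minutes of non-warn state are merged. Intervals are half-open
#' `[start, end)` minutes.
#'
#' @param trace A `predictor_trace` from [diff_and_state()].
#' @param config A [predictor_config()].
#' @return A list of class `alarm_summary`: `subject_id`, `alarm_intervals`
#'   (data frame `start`, `end`), `n_alarms`.
#' @export
alarm_events <- function(trace, config = predictor_config()) {
  interval <- attr(trace, "interval") %||% 1
  warn <- trace$state == "warn"
  r <- rle(warn)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ws <- which(r$values)
  if (length(ws) == 0) {
    iv <- data.frame(start = numeric(), end = numeric())
  } else {
    s <- trace$t[starts[ws]]
    e <- trace$t[ends[ws]] + interval
    merged_s <- s[1]; merged_e <- e[1]
    out_s <- numeric(); out_e <- numeric()
    for (i in seq_along(s)[-1]) {
      if (s[i] - merged_e <= config$merge_gap) {
        merged_e <- e[i]
      } else {
        out_s <- c(out_s, merged_s); out_e <- c(out_e, merged_e)
        merged_s <- s[i]; merged_e <- e[i]
      }
    }
    iv <- data.frame(start = c(out_s, merged_s), end = c(out_e, merged_e))
  }
  structure(list(subject_id = attr(trace, "subject_id") %||% "s",
                 alarm_intervals = iv, n_alarms = nrow(iv)),
            class = "alarm_summary")
}

#' Run the predictor over a cohort
#'
#' Preprocesses each subject's vitals (unless `preprocess = FALSE`), computes
#' the predictor trace and the merged alarm summary. Deterministic given its
#' inputs and invariant to subject order.
#'
#' @param dataset A `cohort_dataset` from [generate_cohort()].
#' @param config A [predictor_config()].
#' @param bounds A [range_bounds()].
#' @param qconfig A [quality_config()].
#' @param preprocess Run [preprocess_vitals()] first (default `TRUE`).
#' @return A named list of `alarm_summary` objects, one per subject.
#' @export
evaluate_cohort <- function(dataset, config = predictor_config(),
                            bounds = range_bounds(),
                            qconfig = quality_config(), preprocess = TRUE) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  out <- lapply(dataset$subjects, function(s) {
    v <- s$vitals
    if (preprocess) v <- preprocess_vitals(v, bounds, qconfig)$series
    alarm_events(diff_and_state(v, config), config)
  })
  names(out) <- names(dataset$subjects)
  out
}
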