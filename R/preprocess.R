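#' Physical range bounds per vital channel
#'
#' Out-of-range sensor values are deleted (blanked and invalidated) before
#' any analysis. The defaults are adult physiological plausibility bounds;
#' both ends are inclusive.
#'
#' @param spo2,hr,temp Length-2 `(low, high)` inclusive bounds.
#' @return An object of class `range_bounds`.
#' @export
range_bounds <- function(spo2 = c(70, 100), hr = c(30, 220),
                         temp = c(25, 45)) {
  b <- list(spo2 = spo2, hr = hr, temp = temp)
  for (ch in names(b)) {
    if (length(b[[ch]]) != 2 || b[[ch]][1] >= b[[ch]][2]) {
      stop("bounds for ", ch, " must be (low, high) with low < high")
    }
  }
  structure(b, class = "range_bounds")
}

#' Quality/segmentation configuration
#'
#' @param ffill_max Maximum forward-fill span in minutes (default 5).
#' @param quality_threshold Strict lower bound on the data-quality factor for
#'   a timestamp to be relevant; default 2/3, i.e. at least two of the three
#'   vital channels valid.
#' @param min_section_length Minimum section length in minutes; default 60 so
#'   a one-hour rolling window fits inside any section.
#' @return An object of class `quality_config`.
#' @export
quality_config <- function(ffill_max = 5, quality_threshold = 2 / 3,
                           min_section_length = 60) {
  if (ffill_max < 0) stop("ffill_max must be >= 0")
  if (quality_threshold < 0 || quality_threshold > 1) {
    stop("quality_threshold must lie in [0, 1]")
  }
  structure(list(ffill_max = ffill_max, quality_threshold = quality_threshold,
                 min_section_length = min_section_length),
            class = "quality_config")
}

#' Re-grid raw records onto a complete, equally spaced timeline
#'
#' Builds the full grid from the first to the last observed timestamp at
#' `interval` spacing; missing timestamps become blank records flagged
#' invalid, and duplicate timestamps collapse to the last record seen.
#'
#' @param raw A data frame with column `t` (minutes) and any of the channel
#'   value/validity columns of [vital_series()] (missing flag columns default
#'   to "valid iff non-blank").
#' @param interval Grid spacing in minutes.
#' @param subject_id Identifier carried on the result.
#' @return A [vital_series()] on the complete grid.
#' @export
normalize_timeline <- function(raw, interval = 1, subject_id = "s") {
  if (interval <= 0) stop("interval must be > 0")
  if (inherits(raw, "vital_series")) subject_id <- attr(raw, "subject_id")
  raw <- as.data.frame(raw)
  if (nrow(raw) == 0) {
    return(vital_series(numeric(0), interval = interval,
                        subject_id = subject_id))
  }
  if (!"t" %in% names(raw)) stop("raw records must carry a 't' column")
  tnum <- suppressWarnings(as.numeric(raw$t))
  if (anyNA(tnum)) {
    stop("unparsable timestamp in row ", which(is.na(tnum))[1])
  }
  off <- (tnum - tnum[1]) / interval
  if (any(abs(off - round(off)) > 1e-8)) {
    stop("timestamp off the ", interval, "-min grid in row ",
         which(abs(off - round(off)) > 1e-8)[1])
  }
  grid_t <- seq(min(tnum), max(tnum), by = interval)
  ## duplicate timestamps: the last record wins, so match against reversed rows
  ridx <- rev(seq_len(nrow(raw)))
  idx <- ridx[match(round((grid_t - tnum[1]) / interval), round(off[ridx]))]

  pick_num <- function(col) {
    if (col %in% names(raw)) as.numeric(raw[[col]])[idx] else
      rep(NA_real_, length(idx))
  }
  pick_flag <- function(col, values) {
    if (col %in% names(raw)) {
      f <- as.logical(raw[[col]])[idx]
      f[is.na(f)] <- FALSE
      f
    } else !is.na(values)
  }
  spo2 <- pick_num("spo2"); hr <- pick_num("hr"); temp <- pick_num("temp")
  vital_series(grid_t, spo2 = spo2, hr = hr, temp = temp,
               spo2_valid = pick_flag("spo2_valid", spo2) & !is.na(spo2),
               hr_valid = pick_flag("hr_valid", hr) & !is.na(hr),
               temp_valid = pick_flag("temp_valid", temp) & !is.na(temp),
               spo2_filled = pick_flag("spo2_filled", NA) & !is.na(idx),
               hr_filled = pick_flag("hr_filled", NA) & !is.na(idx),
               temp_filled = pick_flag("temp_filled", NA) & !is.na(idx),
               interval = interval, subject_id = subject_id)
}

#' Delete out-of-range sensor values
#'
#' Values outside the (inclusive) physical bounds become blank and invalid;
#' channels are treated independently and in-range values are untouched.
#' Idempotent.
#'
#' @param series A [vital_series()].
#' @param bounds A [range_bounds()].
#' @return The cleaned series.
#' @export
remove_out_of_range <- function(series, bounds = range_bounds()) {
  stopifnot(inherits(series, "vital_series"), inherits(bounds, "range_bounds"))
  for (ch in VITAL_CHANNELS) {
    v <- series[[ch]]
    bad <- !is.na(v) & (v < bounds[[ch]][1] | v > bounds[[ch]][2])
    series[[ch]][bad] <- NA_real_
    series[[paste0(ch, "_valid")]][bad] <- FALSE
    series[[paste0(ch, "_filled")]][bad] <- FALSE
  }
  series
}

#' Forward-fill short dropouts
#'
#' Each blank run following a valid value is filled with that value for at
#' most `ffill_max` minutes. Filled records are flagged valid and marked
#' `*_filled`; anything beyond the cap, and leading blanks, stay blank.
#' Applying the operation twice equals applying it once.
#'
#' @param series A gridded [vital_series()].
#' @param ffill_max Maximum fill span in minutes.
#' @return The filled series.
#' @export
forward_fill <- function(series, ffill_max = 5) {
  stopifnot(inherits(series, "vital_series"))
  if (ffill_max < 0) stop("ffill_max must be >= 0")
  interval <- series_interval(series)
  max_steps <- floor(ffill_max / interval)
  n <- nrow(series)
  if (n == 0 || max_steps == 0) return(series)
  for (ch in VITAL_CHANNELS) {
    vcol <- paste0(ch, "_valid")
    fcol <- paste0(ch, "_filled")
    valid <- series[[vcol]]
    vals <- series[[ch]]
    ## index of the most recent originally-valid sample at or before i
    src <- ifelse(valid & !series[[fcol]], seq_len(n), NA_integer_)
    src <- cummax_na(src)
    fill <- !valid & !is.na(src) & (seq_len(n) - src) <= max_steps
    series[[ch]][fill] <- vals[src[fill]]
    series[[vcol]][fill] <- TRUE
    series[[fcol]][fill] <- TRUE
  }
  validate_vital_series(series)
  series
}

## running last non-NA index
cummax_na <- function(x) {
  notna <- !is.na(x)
  idx <- cumsum(notna)
  out <- rep(NA_integer_, length(x))
  if (any(notna)) out[idx > 0] <- x[notna][idx[idx > 0]]
  out
}

#' Data-quality factor
#'
#' The fraction of valid vital channels (SpO2, HR, temperature) at each
#' requested timestamp: one of 0, 1/3, 2/3, 1. Forward-filled values count as
#' valid.
#'
#' @param series A [vital_series()].
#' @param t Minutes on the grid; default the whole grid.
#' @return Numeric vector of fractions, one per `t`.
#' @export
quality_factor <- function(series, t = series$t) {
  stopifnot(inherits(series, "vital_series"))
  idx <- match(t, series$t)
  if (anyNA(idx)) stop("timestamp off the series grid: ", t[is.na(idx)][1])
  (as.numeric(series$spo2_valid[idx]) + as.numeric(series$hr_valid[idx]) +
      as.numeric(series$temp_valid[idx])) / 3
}

#' Segment a series into relevant sections
#'
#' Maximal runs of consecutive timestamps whose data-quality factor is
#' strictly greater than the threshold; runs shorter than
#' `min_section_length` minutes are discarded. Sections are half-open
#' `[t_start, t_end)` intervals, disjoint and ordered.
#'
#' @param series A [vital_series()] (after [forward_fill()]).
#' @param config A [quality_config()].
#' @return A data frame with columns `subject_id`, `t_start`, `t_end`,
#'   `length`.
#' @export
segment_sections <- function(series, config = quality_config()) {
  stopifnot(inherits(series, "vital_series"),
            inherits(config, "quality_config"))
  interval <- series_interval(series)
  empty <- data.frame(subject_id = character(), t_start = numeric(),
                      t_end = numeric(), length = numeric())
  if (nrow(series) == 0) return(empty)
  ok <- quality_factor(series) > config$quality_threshold
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & (r$lengths * interval >= config$min_section_length)
  if (!any(keep)) return(empty)
  data.frame(subject_id = attr(series, "subject_id") %||% "s",
             t_start = series$t[starts[keep]],
             t_end = series$t[ends[keep]] + interval,
             length = r$lengths[keep] * interval)
}

#' Summary statistics of section lengths
#'
#' @param sections Output of [segment_sections()] (possibly row-bound over
#'   subjects).
#' @return A list with `count`, `mean_length`, `median_length` (lengths `NA`
#'   when there are no sections).
#' @export
section_stats <- function(sections) {
  n <- nrow(sections)
  list(count = n,
       mean_length = if (n) mean(sections$length) else NA_real_,
       median_length = if (n) stats::median(sections$length) else NA_real_)
}

#' Run the fixed preprocessing pipeline on one vital series
#'
#' Grid completion, out-of-range deletion, capped forward fill, then
#' quality-thresholded segmentation — in that order.
#'
#' @param series A [vital_series()] or raw record data frame.
#' @param bounds A [range_bounds()].
#' @param config A [quality_config()].
#' @param interval Grid interval for [normalize_timeline()].
#' @return A list with the cleaned `series` and its `sections`.
#' @export
preprocess_vitals <- function(series, bounds = range_bounds(),
                              config = quality_config(), interval = 1) {
  s <- normalize_timeline(series, interval = interval)
  s <- remove_out_of_range(s, bounds)
  s <- forward_fill(s, config$ffill_max)
  list(series = s, sections = segment_sections(s, config))
}
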