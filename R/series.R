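#' @keywords internal
"_PACKAGE"

## Vital channels recorded by the sensor node (per-minute grid).
VITAL_CHANNELS <- c("spo2", "hr", "temp")

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Construct a per-minute vital-sign series
#'
#' A `vital_series` is a data frame on a strictly increasing, equally spaced
#' time grid (minutes since subject start). Each channel (SpO2 in %, heart
#' rate in bpm, skin temperature in degrees C) carries a value column, a
#' validity flag and a `*_filled` flag marking values imputed by
#' [forward_fill()]. A blank (`NA`) value is never flagged valid.
#'
#' @param t Integer-valued minutes, strictly increasing, equally spaced.
#' @param spo2,hr,temp Numeric channel values; `NA` means blank.
#' @param spo2_valid,hr_valid,temp_valid Logical validity flags.
#' @param spo2_filled,hr_filled,temp_filled Logical forward-fill markers.
#' @param interval Grid spacing in minutes (default inferred from `t`, or 1).
#' @param subject_id Opaque subject identifier.
#' @param start POSIXct wall-clock time of `t = 0` (used only for CSV export).
#' @return An object of class `vital_series` (a data frame).
#' @export
vital_series <- function(t, spo2 = NA_real_, hr = NA_real_, temp = NA_real_,
                         spo2_valid = !is.na(spo2), hr_valid = !is.na(hr),
                         temp_valid = !is.na(temp),
                         spo2_filled = FALSE, hr_filled = FALSE,
                         temp_filled = FALSE,
                         interval = NULL, subject_id = "s",
                         start = as.POSIXct("2023-01-01", tz = "UTC")) {
  n <- length(t)
  df <- data.frame(
    t = as.numeric(t),
    spo2 = rep_len(as.numeric(spo2), n),
    spo2_valid = rep_len(as.logical(spo2_valid), n),
    spo2_filled = rep_len(as.logical(spo2_filled), n),
    hr = rep_len(as.numeric(hr), n),
    hr_valid = rep_len(as.logical(hr_valid), n),
    hr_filled = rep_len(as.logical(hr_filled), n),
    temp = rep_len(as.numeric(temp), n),
    temp_valid = rep_len(as.logical(temp_valid), n),
    temp_filled = rep_len(as.logical(temp_filled), n)
  )
  if (is.null(interval)) {
    interval <- if (n >= 2) df$t[2] - df$t[1] else 1
  }
  attr(df, "interval") <- interval
  attr(df, "subject_id") <- subject_id
  attr(df, "start") <- start
  class(df) <- c("vital_series", "data.frame")
  validate_vital_series(df)
  df
}

validate_vital_series <- function(x) {
  stopifnot(is.data.frame(x))
  n <- nrow(x)
  if (n >= 2) {
    d <- diff(x$t)
    if (any(d <= 0)) stop("vital_series: t must be strictly increasing")
    if (any(abs(d - d[1]) > 1e-9)) {
      stop("vital_series: t must be equally spaced")
    }
  }
  for (ch in VITAL_CHANNELS) {
    bad <- is.na(x[[ch]]) & x[[paste0(ch, "_valid")]]
    if (any(bad)) stop("vital_series: blank ", ch, " flagged valid")
  }
  invisible(x)
}

#' @export
print.vital_series <- function(x, ...) {
  cat(sprintf("<vital_series> subject %s: %d records, %g-min grid [%g, %g]\n",
              attr(x, "subject_id"), nrow(x), attr(x, "interval"),
              if (nrow(x)) min(x$t) else NA, if (nrow(x)) max(x$t) else NA))
  for (ch in VITAL_CHANNELS) {
    cat(sprintf("  %-4s valid %5.1f%%\n", ch,
                100 * mean(x[[paste0(ch, "_valid")]])))
  }
  invisible(x)
}

series_interval <- function(x) attr(x, "interval") %||% 1

#' Construct a pressure-grid frame series
#'
#' Frames of a force-sensitive element grid (5x5 for the hip/sacral foil,
#' 12 rows x 4 columns for the insole) sampled every `interval` minutes.
#' `sum_load` is, exactly, the element sum of each frame.
#'
#' @param t Frame times in minutes, strictly increasing.
#' @param grid Numeric array `n x rows x cols` of non-negative force readings
#'   (arbitrary calibrated units).
#' @param interval Frame spacing in minutes (default 5).
#' @param subject_id Opaque subject identifier.
#' @param weight Subject weight in kg (used by the insole analysis), or `NA`.
#' @param shoe_group Optional insole group label
#'   (`"orthopedic"`, `"regular"`, `"control"`).
#' @return An object of class `pressure_series`.
#' @export
pressure_series <- function(t, grid, interval = 5, subject_id = "s",
                            weight = NA_real_, shoe_group = NA_character_) {
  stopifnot(length(dim(grid)) == 3, dim(grid)[1] == length(t))
  if (any(grid < 0)) stop("pressure_series: readings must be >= 0")
  if (length(t) >= 2 && any(diff(t) <= 0)) {
    stop("pressure_series: t must be strictly increasing")
  }
  structure(
    list(t = as.numeric(t), grid = grid,
         sum_load = apply(grid, 1, sum)),
    interval = interval, subject_id = subject_id, weight = weight,
    shoe_group = shoe_group,
    class = "pressure_series"
  )
}

#' @export
print.pressure_series <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<pressure_series> subject %s: %d frames of %dx%d elements, %g-min grid\n",
    attr(x, "subject_id"), d[1], d[2], d[3], attr(x, "interval")))
  invisible(x)
}

#' Total-load series of a pressure recording on its native grid
#'
#' @param x A `pressure_series`.
#' @return A data frame with columns `t` and `sum_load`.
#' @export
sum_load_series <- function(x) {
  stopifnot(inherits(x, "pressure_series"))
  data.frame(t = x$t, sum_load = x$sum_load)
}

#' Upsample the total-load series to a 1-min grid by forward filling
#'
#' The pressure foil samples every 5 minutes; event windows and the
#' temperature response are analysed on the common 1-min vitals grid, so each
#' frame value is held until the next frame (a step interpolation bounded by
#' the native interval).
#'
#' @param x A `pressure_series`.
#' @param interval Target grid spacing in minutes (default 1).
#' @return A data frame with columns `t`, `sum_load` on the target grid.
#' @export
upsample_sum_load <- function(x, interval = 1) {
  stopifnot(inherits(x, "pressure_series"))
  if (length(x$t) == 0) return(data.frame(t = numeric(), sum_load = numeric()))
  native <- series_interval(x)
  tt <- seq(min(x$t), max(x$t) + native - interval, by = interval)
  idx <- findInterval(tt, x$t)
  data.frame(t = tt, sum_load = x$sum_load[idx])
}
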