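## Peak detection on the smoothed, z-scored total-load series.
##
## Definitions follow the standard DSP convention also used by the study's
## toolchain: a peak is a sample whose two direct neighbours are smaller; a
## run of equal samples returns its middle index (lower middle when the run
## has even length). Candidates are then filtered by minimum distance
## (keeping the higher-prominence peak on conflict), minimum prominence, and
## width-at-half-prominence bounds; the surviving width is the event's
## duration proxy.

#' Peak-filter configuration
#'
#' @param min_distance Minimum spacing between retained peaks, minutes.
#' @param min_prominence Minimum peak prominence, in units of the (z-scored)
#'   input.
#' @param width_min,width_max Bounds on the width at half prominence,
#'   minutes.
#' @return An object of class `peak_config`.
#' @export
peak_config <- function(min_distance = 10, min_prominence = 1,
                        width_min = 5, width_max = 120) {
  if (min_distance < 1) stop("min_distance must be >= 1 sample")
  if (min_prominence <= 0) stop("min_prominence must be > 0")
  structure(list(min_distance = min_distance,
                 min_prominence = min_prominence,
                 width_min = width_min, width_max = width_max),
            class = "peak_config")
}

#' Local maxima with plateau handling
#'
#' @param x Numeric series.
#' @return Integer indices of all local maxima; for a plateau of equal
#'   values the (lower-)middle index is returned.
#' @export
local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2
  while (i < n) {
    if (x[i - 1] < x[i]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j < n && x[j + 1] < x[i]) {
        out <- c(out, (i + j) %/% 2)
        i <- j
      } else {
        i <- j
      }
    }
    i <- i + 1
  }
  out
}

#' Peak prominence
#'
#' The vertical distance between the peak and its higher base: on each side
#' the minimum is taken between the peak and the nearest sample exceeding the
#' peak height (or the series border), and the prominence is the peak height
#' minus the larger of the two minima.
#'
#' @param x Numeric series.
#' @param peaks Integer peak indices.
#' @return A list with `prominence`, `left_base`, `right_base` vectors.
#' @export
peak_prominence <- function(x, peaks) {
  n <- length(x)
  prom <- numeric(length(peaks))
  lb <- integer(length(peaks))
  rb <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    h <- x[p]
    i <- p; left_min <- h; lbase <- p
    while (i > 1 && x[i - 1] <= h) {
      i <- i - 1
      if (x[i] < left_min) { left_min <- x[i]; lbase <- i }
    }
    i <- p; right_min <- h; rbase <- p
    while (i < n && x[i + 1] <= h) {
      i <- i + 1
      if (x[i] < right_min) { right_min <- x[i]; rbase <- i }
    }
    prom[k] <- h - max(left_min, right_min)
    lb[k] <- lbase
    rb[k] <- rbase
  }
  list(prominence = prom, left_base = lb, right_base = rb)
}

#' Peak width at a fraction of the prominence
#'
#' Width of each peak measured where the series crosses
#' `height - rel_height * prominence`, with linear interpolation between
#' samples and evaluation bounded by the peak's bases.
#'
#' @param x Numeric series.
#' @param peaks Integer peak indices.
#' @param prom Output of [peak_prominence()] for the same peaks.
#' @param rel_height Fraction of the prominence (default 0.5).
#' @return Numeric widths in samples.
#' @export
peak_width <- function(x, peaks, prom = peak_prominence(x, peaks),
                       rel_height = 0.5) {
  widths <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    height <- x[p] - rel_height * prom$prominence[k]
    i <- p
    while (i > prom$left_base[k] && x[i] > height) i <- i - 1
    left_ip <- i
    if (x[i] < height) {
      left_ip <- i + (height - x[i]) / (x[i + 1] - x[i])
    }
    i <- p
    while (i < prom$right_base[k] && x[i] > height) i <- i + 1
    right_ip <- i
    if (x[i] < height) {
      right_ip <- i - (height - x[i]) / (x[i - 1] - x[i])
    }
    widths[k] <- right_ip - left_ip
  }
  widths
}

#' Detect pressure-load events
#'
#' Rising events are peaks of the (smoothed, z-scored) total-load series;
#' falling events are peaks of the negated series. Candidates are filtered by
#' minimum distance (conflicts resolved in favour of the higher prominence),
#' minimum prominence, and width bounds. The retained width at half
#' prominence serves as the event's duration.
#'
#' @param x Numeric series, smoothed and z-scored.
#' @param t Sample times in minutes (default a 1-min grid from 0).
#' @param config A [peak_config()].
#' @param direction `"rising"`, `"falling"`, or `"both"`.
#' @return A data frame of events: `t_peak`, `direction`, `prominence`,
#'   `width` (minutes), `cluster` (`NA` until clustered), sorted by `t_peak`.
#' @export
detect_events <- function(x, t = seq_along(x) - 1, config = peak_config(),
                          direction = c("rising", "falling", "both")) {
  direction <- match.arg(direction)
  if (direction == "both") {
    ev <- rbind(detect_events(x, t, config, "rising"),
                detect_events(x, t, config, "falling"))
    return(ev[order(ev$t_peak), , drop = FALSE])
  }
  empty <- data.frame(t_peak = numeric(), direction = character(),
                      prominence = numeric(), width = numeric(),
                      cluster = integer())
  if (length(x) < 3) return(empty)
  sig <- if (direction == "falling") -x else x
  peaks <- local_maxima(sig)
  if (length(peaks) == 0) return(empty)
  interval <- if (length(t) >= 2) t[2] - t[1] else 1
  prom <- peak_prominence(sig, peaks)
  width <- peak_width(sig, peaks, prom) * interval

  ## distance filter: greedily keep in order of decreasing prominence
  keep <- rep(TRUE, length(peaks))
  ord <- order(-prom$prominence, peaks)
  for (k in ord) {
    if (!keep[k]) next
    conflict <- keep & abs(t[peaks] - t[peaks[k]]) < config$min_distance
    conflict[k] <- FALSE
    drop <- conflict & (prom$prominence < prom$prominence[k] |
                          (prom$prominence == prom$prominence[k] &
                             seq_along(peaks) > k))
    keep[drop] <- FALSE
  }
  keep <- keep & prom$prominence >= config$min_prominence
  keep <- keep & width >= config$width_min & width <= config$width_max
  out <- data.frame(t_peak = t[peaks[keep]],
                    direction = rep(direction, sum(keep)),
                    prominence = prom$prominence[keep],
                    width = width[keep],
                    cluster = rep(NA_integer_, sum(keep)))
  out[order(out$t_peak), , drop = FALSE]
}

#' Assign an event width to the reported duration bins
#'
#' Events are reported in three duration classes: 20 min, 40 min, and
#' longer than 55 min, assigned by the nearest bin.
#'
#' @param width Event widths in minutes.
#' @return A factor with levels `"20"`, `"40"`, `">55"`.
#' @export
duration_bin <- function(width) {
  cut(width, breaks = c(-Inf, 30, 47.5, Inf), labels = c("20", "40", ">55"))
}
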