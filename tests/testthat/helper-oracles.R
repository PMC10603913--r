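# Naive reference implementations used as independent oracles.
# All are deliberately written as plain loops over the definitions.

make_random_vitals <- function(n, seed, p_blank = 0.3, interval = 1) {
  set.seed(seed)
  mk <- function() {
    v <- round(stats::runif(n, 85, 99), 1)
    v[stats::runif(n) < p_blank] <- NA
    v
  }
  spo2 <- mk(); hr <- mk() - 20; temp <- mk() - 60
  vital_series(seq(0, by = interval, length.out = n),
               spo2 = spo2, hr = hr, temp = temp, interval = interval)
}

naive_ffill <- function(series, ffill_max) {
  out <- series
  interval <- attr(series, "interval")
  for (ch in c("spo2", "hr", "temp")) {
    vcol <- paste0(ch, "_valid"); fcol <- paste0(ch, "_filled")
    last_src <- NA
    for (i in seq_len(nrow(series))) {
      if (series[[vcol]][i] && !series[[fcol]][i]) {
        last_src <- i
      } else if (!series[[vcol]][i] && !is.na(last_src) &&
                 (i - last_src) * interval <= ffill_max) {
        out[[ch]][i] <- series[[ch]][last_src]
        out[[vcol]][i] <- TRUE
        out[[fcol]][i] <- TRUE
      }
    }
  }
  out
}

naive_range <- function(series, bounds) {
  out <- series
  for (ch in c("spo2", "hr", "temp")) {
    for (i in seq_len(nrow(series))) {
      v <- series[[ch]][i]
      if (!is.na(v) && (v < bounds[[ch]][1] || v > bounds[[ch]][2])) {
        out[[ch]][i] <- NA
        out[[paste0(ch, "_valid")]][i] <- FALSE
        out[[paste0(ch, "_filled")]][i] <- FALSE
      }
    }
  }
  out
}

naive_sections <- function(ok, t, interval, threshold_len) {
  res <- list()
  i <- 1
  n <- length(ok)
  while (i <= n) {
    if (ok[i]) {
      j <- i
      while (j < n && ok[j + 1]) j <- j + 1
      len <- (j - i + 1) * interval
      if (len >= threshold_len) {
        res[[length(res) + 1]] <- c(t[i], t[j] + interval, len)
      }
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  res
}

# --- brute-force peak detector oracle ---------------------------------------

bf_local_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  for (i in 2:(n - 1)) {
    if (x[i - 1] < x[i]) {
      j <- i
      while (j < n && x[j + 1] == x[i]) j <- j + 1
      if (j <= n - 1 && x[j + 1] < x[i]) out <- c(out, (i + j) %/% 2)
    }
  }
  out
}

bf_prominence_one <- function(x, p) {
  n <- length(x)
  h <- x[p]
  left_stop <- 0
  for (j in (p - 1):1) if (j >= 1 && x[j] > h) { left_stop <- j; break }
  right_stop <- n + 1
  if (p < n) for (j in (p + 1):n) if (x[j] > h) { right_stop <- j; break }
  left_min <- min(x[max(1, left_stop + 1):p])
  right_min <- min(x[p:min(n, right_stop - 1)])
  lb <- max(which(x[max(1, left_stop + 1):p] == left_min)) +
    max(1, left_stop + 1) - 1
  # base = position of the minimum closest to the peak on each side
  rb <- min(which(x[p:min(n, right_stop - 1)] == right_min)) + p - 1
  list(prom = h - max(left_min, right_min), lb = lb, rb = rb)
}

bf_width_one <- function(x, p, pr, rel_height = 0.5) {
  height <- x[p] - rel_height * pr$prom
  i <- p
  while (i > pr$lb && x[i] > height) i <- i - 1
  left_ip <- i
  if (x[i] < height) left_ip <- i + (height - x[i]) / (x[i + 1] - x[i])
  i <- p
  while (i < pr$rb && x[i] > height) i <- i + 1
  right_ip <- i
  if (x[i] < height) right_ip <- i - (height - x[i]) / (x[i - 1] - x[i])
  right_ip - left_ip
}

bf_detect <- function(x, t = seq_along(x) - 1, config = peak_config(),
                      direction = "rising") {
  sig <- if (direction == "falling") -x else x
  if (length(sig) < 3) return(data.frame(t_peak = numeric(),
                                         prominence = numeric(),
                                         width = numeric()))
  peaks <- bf_local_maxima(sig)
  if (!length(peaks)) return(data.frame(t_peak = numeric(),
                                        prominence = numeric(),
                                        width = numeric()))
  interval <- if (length(t) >= 2) t[2] - t[1] else 1
  prs <- lapply(peaks, function(p) bf_prominence_one(sig, p))
  prom <- vapply(prs, `[[`, 0, "prom")
  width <- mapply(function(p, pr) bf_width_one(sig, p, pr),
                  peaks, prs) * interval
  # distance filter: greedy by decreasing prominence (ties: earlier peak)
  keep <- rep(TRUE, length(peaks))
  ord <- order(-prom, peaks)
  for (k in ord) {
    if (!keep[k]) next
    for (m in seq_along(peaks)) {
      if (m == k || !keep[m]) next
      if (abs(t[peaks[m]] - t[peaks[k]]) < config$min_distance) {
        if (prom[m] < prom[k] || (prom[m] == prom[k] && m > k)) {
          keep[m] <- FALSE
        }
      }
    }
  }
  keep <- keep & prom >= config$min_prominence &
    width >= config$width_min & width <= config$width_max
  out <- data.frame(t_peak = t[peaks[keep]], prominence = prom[keep],
                    width = width[keep])
  out[order(out$t_peak), , drop = FALSE]
}

# enumerate all series of length n over values 0..(k-1)
all_series <- function(n, k = 3) {
  grid <- do.call(expand.grid, rep(list(0:(k - 1)), n))
  unname(as.matrix(grid))
}

welch_by_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
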