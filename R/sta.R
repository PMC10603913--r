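## Event windows, duration clustering and spike-triggered averaging.
##
## Around each detected pressure event a 61-sample window is cut from 5 min
## before to 55 min after the event on the common 1-min grid. Windows are
## clustered on their (per-window rescaled) pressure trajectories with
## k-means, and for each cluster the skin-temperature response is summarised
## by spike-triggered averaging relative to the sample one minute before the
## event.

#' Extract event windows
#'
#' One window per event that lies fully inside both series; a temperature
#' gap (blank or invalid sample) anywhere inside a window disqualifies it.
#' Pressure is expected on the 1-min grid (see [upsample_sum_load()]),
#' smoothed and z-scored.
#'
#' @param events Data frame from [detect_events()].
#' @param pressure Data frame with columns `t`, `value`: the processed
#'   total-load series on the 1-min grid.
#' @param temp Data frame with columns `t`, `value`: skin temperature in
#'   degrees C with `NA` at gaps, or a [vital_series()].
#' @param pre,post Window extent in minutes before/after the event.
#' @return A list of windows, each with `event` (one-row data frame),
#'   `rel_time`, `pressure_traj`, `temp_traj`; the number of excluded events
#'   is carried in attribute `n_excluded`.
#' @export
extract_windows <- function(events, pressure, temp, pre = 5, post = 55) {
  if (inherits(temp, "vital_series")) {
    temp <- data.frame(t = temp$t,
                       value = ifelse(temp$temp_valid, temp$temp, NA_real_))
  }
  rel <- seq(-pre, post)
  windows <- list()
  excluded <- 0L
  for (i in seq_len(nrow(events))) {
    tt <- events$t_peak[i] + rel
    ip <- match(tt, pressure$t)
    it <- match(tt, temp$t)
    if (anyNA(ip) || anyNA(it) || anyNA(temp$value[it])) {
      excluded <- excluded + 1L
      next
    }
    windows[[length(windows) + 1L]] <- list(
      event = events[i, , drop = FALSE],
      rel_time = rel,
      pressure_traj = pressure$value[ip],
      temp_traj = temp$value[it])
  }
  attr(windows, "n_excluded") <- excluded
  windows
}

## per-window rescaling ("input scaling"): each trajectory to mean 0, var 1
scale_window <- function(x) {
  s <- pop_sd(x)
  if (s == 0) numeric(length(x)) else (x - mean(x)) / s
}

window_feature_matrix <- function(windows) {
  do.call(rbind, lapply(windows, function(w) scale_window(w$pressure_traj)))
}

#' Cluster event windows by their pressure trajectory
#'
#' Each window's pressure trajectory is rescaled to zero mean and unit
#' variance and flattened into a feature vector; k-means with Euclidean
#' distance is run for every candidate `k` (multiple restarts under the
#' seed), and `K` is chosen by the elbow method, operationalised as the
#' maximum second difference of the within-cluster inertia over the
#' candidates. With a single candidate that `k` is used directly.
#'
#' @param windows List from [extract_windows()].
#' @param k_candidates Integer candidate cluster counts (default `2:6`).
#' @param seed Integer seed controlling all restarts.
#' @param nstart Restarts per `k` (default 10).
#' @return A list of class `cluster_result`: `K`, `labels` (1-based),
#'   `centers` (`K x 61` matrix in scaled space), `inertia_by_k`.
#' @export
cluster_windows <- function(windows, k_candidates = 2:6, seed = 1L,
                            nstart = 10) {
  n <- length(windows)
  if (n == 0) stop("no windows to cluster")
  X <- window_feature_matrix(windows)
  n_distinct <- nrow(unique(X))
  k_max <- min(n - 1, n_distinct)        # stats::kmeans needs k < n
  usable <- k_candidates[k_candidates == 1 | k_candidates <= k_max]
  if (length(usable) < length(k_candidates)) {
    warning("skipping k beyond the usable window count (", k_max, ")")
  }
  if (length(usable) == 0) stop("fewer windows than every candidate k")
  fits <- list()
  inertia <- numeric(length(usable))
  for (j in seq_along(usable)) {
    set.seed(seed + usable[j])
    fits[[j]] <- stats::kmeans(X, centers = usable[j], nstart = nstart,
                               iter.max = 100)
    inertia[j] <- fits[[j]]$tot.withinss
  }
  names(inertia) <- usable
  if (length(usable) >= 3) {
    d2 <- diff(inertia, differences = 2)    # values for interior candidates
    K <- usable[which.max(d2) + 1]
  } else {
    K <- usable[1]
  }
  fit <- fits[[match(K, usable)]]
  structure(list(K = K, labels = fit$cluster, centers = fit$centers,
                 inertia_by_k = inertia),
            class = "cluster_result")
}

#' Spike-triggered average of the temperature response
#'
#' For every window the relative temperature is the trajectory minus its
#' value at the reference sample (one minute before the event, rel_time -1);
#' the STA is the pointwise mean of these relative trajectories. Pearson and
#' Spearman correlations are computed between the cluster's pressure centre
#' and the STA over the shared time axis (`NA` when either is constant).
#'
#' @param windows Windows of one cluster (non-empty list).
#' @param center Optional pressure centre trajectory; defaults to the
#'   pointwise mean of the windows' rescaled pressure trajectories.
#' @return A list: `rel_time`, `sta` (degrees C, zero at the reference
#'   index), `n`, `pearson_r`, `spearman_rho`, `center`.
#' @export
spike_triggered_average <- function(windows, center = NULL) {
  if (length(windows) == 0) stop("empty cluster")
  rel <- windows[[1]]$rel_time
  ref <- match(-1, rel)
  if (is.na(ref)) stop("reference sample (rel_time -1) not in the window")
  relmat <- do.call(rbind, lapply(windows, function(w)
    w$temp_traj - w$temp_traj[ref]))
  sta <- colMeans(relmat)
  if (is.null(center)) {
    center <- colMeans(window_feature_matrix(windows))
  }
  pr <- if (pop_sd(sta) == 0 || pop_sd(center) == 0) NA_real_ else
    stats::cor(center, sta)
  sr <- if (pop_sd(sta) == 0 || pop_sd(center) == 0) NA_real_ else
    stats::cor(center, sta, method = "spearman")
  list(rel_time = rel, sta = sta, n = length(windows),
       pearson_r = pr, spearman_rho = sr, center = center)
}

#' STA per cluster
#'
#' @param windows List from [extract_windows()].
#' @param clusters A `cluster_result` from [cluster_windows()].
#' @return A list with one [spike_triggered_average()] entry per non-empty
#'   cluster, named by cluster label.
#' @export
sta_by_cluster <- function(windows, clusters) {
  out <- list()
  for (k in seq_len(clusters$K)) {
    members <- windows[clusters$labels == k]
    if (length(members) == 0) next
    out[[as.character(k)]] <-
      spike_triggered_average(members, center = clusters$centers[k, ])
  }
  out
}
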