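# Helper: build a clean pressure+temperature pair with boxcar events of the
# given durations, on the 1-min grid, plus the window list.
make_event_world <- function(durations, amplitude = 50, gap = 60,
                             temp_gain = 0, temp_lag = 0, seed = 1,
                             noise = 0) {
  set.seed(seed)
  onsets <- 30 + c(0, cumsum(utils::head(durations, -1) +
                               utils::head(rep(gap, length(durations)), -1)))
  total <- max(onsets + durations) + 120
  t <- 0:(total - 1)
  load <- rep(0, total)
  for (i in seq_along(durations)) {
    load[t >= onsets[i] & t < onsets[i] + durations[i]] <- amplitude
  }
  if (noise > 0) load <- load + rnorm(total, 0, noise)
  proc <- zscore(smooth_series(load))
  z <- zscore(load)
  if (temp_lag > 0) {       # first-order lag, as in the stream generator
    a <- 1 - exp(-1 / temp_lag)
    z <- as.numeric(stats::filter(a * z, 1 - a, method = "recursive",
                                  init = z[1]))
  }
  temp <- 36 + temp_gain * z
  list(t = t, load = load,
       pressure = data.frame(t = t, value = proc),
       temp = data.frame(t = t, value = temp),
       onsets = onsets, durations = durations)
}

test_that("extract_windows cuts the documented -5..+55 min window", {
  w <- make_event_world(c(30))
  ev <- data.frame(t_peak = 100, direction = "rising", prominence = 2,
                   width = 30, cluster = NA_integer_)
  wins <- extract_windows(ev, w$pressure, w$temp)
  expect_length(wins, 1)
  expect_equal(wins[[1]]$rel_time, -5:55)
  expect_length(wins[[1]]$pressure_traj, 61)
  expect_equal(wins[[1]]$pressure_traj,
               w$pressure$value[w$pressure$t %in% 95:155])
})

test_that("extract_windows excludes boundary and gap windows", {
  w <- make_event_world(c(30))
  ev <- data.frame(t_peak = c(3, 100, max(w$t) - 10),
                   direction = "rising", prominence = 2, width = 30,
                   cluster = NA_integer_)
  wins <- extract_windows(ev, w$pressure, w$temp)
  expect_length(wins, 1)
  expect_equal(attr(wins, "n_excluded"), 2L)
  # a temperature gap inside the window disqualifies it
  temp_gap <- w$temp
  temp_gap$value[temp_gap$t == 120] <- NA
  expect_length(extract_windows(ev[2, ], w$pressure, temp_gap), 0)
  # count identity: windows = events - exclusions
  expect_equal(length(wins) + attr(wins, "n_excluded"), nrow(ev))
})

test_that("k = 1 cluster centre is the pointwise mean of scaled windows", {
  w <- make_event_world(c(20, 40, 20, 40), gap = 70)
  ev <- detect_events(w$pressure$value, w$t,
                      peak_config(min_distance = 10, min_prominence = 0.5,
                                  width_min = 5, width_max = 120))
  wins <- extract_windows(ev, w$pressure, w$temp)
  cl <- cluster_windows(wins, k_candidates = 1, seed = 1)
  expect_equal(cl$K, 1)
  scaled <- do.call(rbind, lapply(wins, function(x)
    (x$pressure_traj - mean(x$pressure_traj)) /
      sqrt(mean((x$pressure_traj - mean(x$pressure_traj))^2))))
  expect_equal(as.numeric(cl$centers[1, ]), colMeans(scaled),
               tolerance = 1e-9)
})

test_that("clustering recovers well-separated duration classes", {
  durations <- rep(c(20, 40), each = 8)
  w <- make_event_world(sample(durations), gap = 70, seed = 3)
  ev <- detect_events(w$pressure$value, w$t)
  wins <- extract_windows(ev, w$pressure, w$temp)
  expect_gte(length(wins), 14)
  cl <- cluster_windows(wins, k_candidates = 2, seed = 1)
  # ground truth from the generator's schedule: nearest event midpoint
  truth <- vapply(wins, function(x) {
    mids <- w$onsets + w$durations / 2
    w$durations[which.min(abs(x$event$t_peak - mids))]
  }, 0)
  for (k in 1:2) {
    expect_length(unique(truth[cl$labels == k]), 1)   # pure clusters
  }
  # reproducibility under the seed
  cl2 <- cluster_windows(wins, k_candidates = 2, seed = 1)
  expect_identical(cl$labels, cl2$labels)
})

test_that("inertia decreases in k and the elbow picks the true K", {
  set.seed(40)
  durations <- sample(rep(c(20, 40, 60), each = 10))
  w <- make_event_world(durations, gap = 70, seed = 4)
  ev <- detect_events(w$pressure$value, w$t)
  wins <- extract_windows(ev, w$pressure, w$temp)
  cl <- cluster_windows(wins, k_candidates = 2:6, seed = 2)
  expect_true(all(diff(cl$inertia_by_k) <= 1e-8))
  expect_equal(cl$K, 3)
  # three windows, only two distinct shapes (noise-free duplicates):
  # candidate ks above the distinct count are skipped with a warning
  truth <- vapply(wins, function(x) {
    mids <- w$onsets + w$durations / 2
    w$durations[which.min(abs(x$event$t_peak - mids))]
  }, 0)
  idx <- c(which(truth == 20)[1:2], which(truth == 40)[1])
  expect_warning(cl_small <- cluster_windows(wins[idx], k_candidates = 2:6,
                                             seed = 1), "skipping")
  expect_equal(cl_small$K, 2)
})

test_that("STA is zero at the reference sample and averages correctly", {
  w <- make_event_world(c(20, 20, 20), gap = 70, temp_gain = 0.5)
  ev <- detect_events(w$pressure$value, w$t)
  wins <- extract_windows(ev, w$pressure, w$temp)
  st <- spike_triggered_average(wins)
  ref_idx <- match(-1, st$rel_time)
  expect_identical(st$sta[ref_idx], 0)
  expect_equal(st$n, length(wins))
  # single window: STA equals that window's relative trajectory
  st1 <- spike_triggered_average(wins[1])
  expect_equal(st1$sta, wins[[1]]$temp_traj - wins[[1]]$temp_traj[ref_idx])
  expect_error(spike_triggered_average(list()), "empty")
})

test_that("constant-temperature windows give zero STA and absent correlations", {
  w <- make_event_world(c(20, 20), gap = 70, temp_gain = 0)
  ev <- detect_events(w$pressure$value, w$t)
  wins <- extract_windows(ev, w$pressure, w$temp)
  st <- spike_triggered_average(wins)
  expect_true(all(st$sta == 0))
  expect_true(is.na(st$pearson_r))
  expect_true(is.na(st$spearman_rho))
})

test_that("with positive coupling the STA tracks the pressure centre", {
  # instantaneous coupling: STA is an affine image of the pressure centre
  durations <- rep(c(20, 40), each = 6)
  w <- make_event_world(sample(durations), gap = 70, temp_gain = 0.5,
                        seed = 5)
  ev <- detect_events(w$pressure$value, w$t)
  wins <- extract_windows(ev, w$pressure, w$temp)
  cl <- cluster_windows(wins, k_candidates = 2, seed = 1)
  for (st in sta_by_cluster(wins, cl)) {
    expect_gt(st$pearson_r, 0.9)
  }

  # lagged coupling (the generator's model): the event trigger is the load
  # peak (plateau middle), so while the event persists the temperature is
  # still climbing toward its asymptote on both sides of the reference --
  # the STA must be higher just after the trigger than at the window start
  wl <- make_event_world(sample(durations), gap = 70, temp_gain = 0.5,
                         temp_lag = 5, seed = 6)
  evl <- detect_events(wl$pressure$value, wl$t)
  winsl <- extract_windows(evl, wl$pressure, wl$temp)
  cll <- cluster_windows(winsl, k_candidates = 2, seed = 1)
  for (st in sta_by_cluster(winsl, cll)) {
    expect_gt(st$sta[match(5, st$rel_time)], st$sta[match(-5, st$rel_time)])
    expect_gt(st$pearson_r, 0.5)
  }
})
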