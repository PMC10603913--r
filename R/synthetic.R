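## Cohort vital-sign parameters: across-subject mean and between-subject sd
## of per-subject means for each group (SpO2 %, HR bpm, skin temp deg C).
DEFAULT_GROUP_PARAMS <- list(
  patient = list(spo2 = c(mean = 91.3, sd = 2.9),
                 hr   = c(mean = 70.2, sd = 10.8),
                 temp = c(mean = 36.0, sd = 0.7)),
  control = list(spo2 = c(mean = 98.5, sd = 0.9),
                 hr   = c(mean = 57.4, sd = 7.0),
                 temp = c(mean = 35.3, sd = 0.4))
)

#' Subject profile
#'
#' Metadata for one monitored subject. Control subjects are healthy: all
#' condition flags must be `FALSE`. Diagnosis events are (minute, result)
#' pairs from the Phillips finger test; a positive test ends participation,
#' so at most one positive event is allowed and times must be strictly
#' increasing.
#'
#' @param subject_id Opaque identifier.
#' @param group `"patient"` or `"control"`.
#' @param age Years.
#' @param height cm.
#' @param weight kg, must be positive.
#' @param conditions Named logical vector with elements `diabetes`,
#'   `immobile`, `paraplegic`, `prior_pu`, `prior_pu_surgery`.
#' @param diagnosis_events Data frame with columns `t` (minutes) and
#'   `result` (`"positive"`/`"negative"`), or `NULL`.
#' @param shoe_group Optional insole study arm
#'   (`"orthopedic"`, `"regular"`, `"control"`).
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group = c("patient", "control"),
                            age = 70, height = 172, weight = 80,
                            conditions = NULL, diagnosis_events = NULL,
                            shoe_group = NA_character_) {
  group <- match.arg(group)
  flags <- c(diabetes = FALSE, immobile = FALSE, paraplegic = FALSE,
             prior_pu = FALSE, prior_pu_surgery = FALSE)
  if (!is.null(conditions)) {
    if (is.null(names(conditions)) ||
        !all(names(conditions) %in% names(flags))) {
      stop("unknown condition flag: ",
           paste(setdiff(names(conditions), names(flags)), collapse = ", "))
    }
    flags[names(conditions)] <- as.logical(conditions)
  }
  if (weight <= 0) stop("weight must be > 0")
  if (group == "control" && any(flags)) {
    stop("control subjects must have all condition flags FALSE")
  }
  if (!is.null(diagnosis_events)) {
    stopifnot(all(c("t", "result") %in% names(diagnosis_events)))
    if (is.unsorted(diagnosis_events$t, strictly = TRUE)) {
      stop("diagnosis event times must be strictly increasing")
    }
    if (sum(diagnosis_events$result == "positive") > 1) {
      stop("at most one positive finger test (study exit on positive)")
    }
  }
  structure(list(subject_id = subject_id, group = group, age = age,
                 height = height, weight = weight, conditions = flags,
                 diagnosis_events = diagnosis_events,
                 shoe_group = shoe_group),
            class = "subject_profile")
}

#' Synthetic-stream generator configuration
#'
#' The generator emits what the sensor system records: per-minute vitals with
#' validity flags and gap structure, and 5-min pressure-grid frames carrying
#' scheduled load events. Vital noise is mean-reverting (first-order
#' autoregressive); skin temperature additionally follows the z-scored total
#' pressure load through a linear gain with first-order lag, so a rising load
#' raises temperature after a short delay.
#'
#' @param duration Recording length in minutes.
#' @param vitals_interval,pressure_interval Sampling grids in minutes.
#' @param grid_shape Pressure foil `(rows, cols)`; 5x5 for hip/sacral.
#' @param group_params Per-group `{mean, sd}` for SpO2/HR/temp; the `sd` is
#'   the marginal (within-subject, stationary AR) sd of emitted values, so a
#'   long recording's sample mean converges to the configured mean.
#' @param between_sd Additional between-subject sd of per-subject mean
#'   levels (default 0; cohort heterogeneity then comes from the
#'   condition-linked contrasts only).
#' @param ar_tau Autocorrelation time constant of the vital noise, minutes.
#' @param invalid_fraction Long-run fraction of invalid samples per channel.
#' @param invalid_burst_mean Mean length of an invalid burst, minutes.
#' @param gap_rate Per-minute rate of missing-timestamp gap starts.
#' @param gap_mean_length Mean gap length in minutes.
#' @param events Explicit event schedule: data frame with `onset`, `duration`
#'   (minutes) and `amplitude` (added total load, a.u.); `NULL` for an
#'   automatic schedule.
#' @param event_durations,event_jitter,event_gap_mean,event_amplitude
#'   Automatic schedule: durations cycled with uniform `+/- event_jitter`
#'   minutes, exponential inter-event gaps of mean `event_gap_mean`, and the
#'   added total load per event.
#' @param baseline_level,baseline_noise_sd Per-element resting load and noise.
#' @param temp_gain Temperature gain, degrees C per z-unit of load.
#' @param temp_lag First-order lag of the temperature response, minutes.
#' @param surgery_spo2_offset,surgery_temp_offset Mean contrasts linked to a
#'   prior PU surgery (subgroup difference; applied mean-preservingly).
#' @param prevalence Named condition prevalences for sampled patient profiles.
#' @param seed Default seed used when an operation is not given one.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(duration = 5000,
                             vitals_interval = 1, pressure_interval = 5,
                             grid_shape = c(5, 5),
                             group_params = DEFAULT_GROUP_PARAMS,
                             between_sd = c(spo2 = 0, hr = 0, temp = 0),
                             ar_tau = 30,
                             invalid_fraction = c(spo2 = 0.25, hr = 0.25,
                                                  temp = 0.02),
                             invalid_burst_mean = 5,
                             gap_rate = 0.002, gap_mean_length = 10,
                             events = NULL,
                             event_durations = c(20, 40, 60),
                             event_jitter = 2,
                             event_gap_mean = 90,
                             event_amplitude = 50,
                             baseline_level = 2, baseline_noise_sd = 0.3,
                             temp_gain = 0.5, temp_lag = 5,
                             surgery_spo2_offset = -2.2,
                             surgery_temp_offset = -0.7,
                             prevalence = c(diabetes = 0.25, immobile = 0.5,
                                            paraplegic = 0.1, prior_pu = 0.3,
                                            prior_pu_surgery = 0.3),
                             seed = 1L) {
  cfg <- as.list(environment())
  if (duration <= 0) stop("duration must be positive")
  if (duration %% vitals_interval != 0 || duration %% pressure_interval != 0) {
    stop("sampling intervals must divide the duration")
  }
  if (any(invalid_fraction < 0 | invalid_fraction >= 1)) {
    stop("invalid_fraction must lie in [0, 1)")
  }
  sds <- c(between_sd, vapply(group_params, function(g)
    vapply(g, function(p) p[["sd"]], 0), numeric(3)))
  if (any(sds < 0)) stop("sds must be >= 0")
  if (!is.null(events)) {
    stopifnot(all(c("onset", "duration", "amplitude") %in% names(events)))
  }
  structure(cfg, class = "generator_config")
}

## Two-state Markov validity flags: stationary invalid fraction f with mean
## invalid burst length L. Simulated as alternating geometric run lengths.
markov_valid_flags <- function(n, f, burst_mean) {
  if (n == 0) return(logical(0))
  if (f <= 0) return(rep(TRUE, n))
  p_iv <- 1 / burst_mean                 # invalid -> valid
  p_vi <- f / ((1 - f) * burst_mean)     # valid -> invalid
  p_vi <- min(p_vi, 1)
  state <- stats::runif(1) >= f          # TRUE = valid
  out <- logical(n)
  i <- 1
  while (i <= n) {
    p <- if (state) p_vi else p_iv
    len <- 1 + stats::rgeom(1, p)
    len <- min(len, n - i + 1)
    out[i:(i + len - 1)] <- state
    i <- i + len
    state <- !state
  }
  out
}

auto_event_schedule <- function(config) {
  onset <- 30
  rows <- list()
  k <- 0
  repeat {
    dur <- sample(config$event_durations, 1) +
      stats::runif(1, -config$event_jitter, config$event_jitter)
    if (onset + dur + 60 > config$duration) break
    k <- k + 1
    rows[[k]] <- data.frame(onset = onset, duration = dur,
                            amplitude = config$event_amplitude)
    gap <- max(15, stats::rexp(1, 1 / config$event_gap_mean))
    onset <- onset + dur + gap
  }
  if (k == 0) {
    return(data.frame(onset = numeric(), duration = numeric(),
                      amplitude = numeric()))
  }
  do.call(rbind, rows)
}

## Stationary AR(1) noise: sd `sigma`, time constant `tau` minutes.
ar1_noise <- function(n, sigma, tau, interval) {
  if (sigma == 0 || n == 0) return(numeric(n))
  phi <- exp(-interval / tau)
  innov <- stats::rnorm(n, 0, sigma * sqrt(1 - phi^2))
  x0 <- stats::rnorm(1, 0, sigma)
  as.numeric(stats::filter(innov, phi, method = "recursive", init = x0))
}

subject_channel_mean <- function(profile, config, ch) {
  par <- config$group_params[[profile$group]]
  if (is.null(par)) stop("no parameter set for group '", profile$group, "'")
  mu <- par[[ch]][["mean"]] + stats::rnorm(1, 0, config$between_sd[[ch]])
  if (profile$group == "patient") {
    off <- switch(ch, spo2 = config$surgery_spo2_offset,
                  temp = config$surgery_temp_offset, 0)
    prev <- config$prevalence[["prior_pu_surgery"]]
    mu <- mu + (as.numeric(profile$conditions[["prior_pu_surgery"]]) - prev) *
      off
  }
  mu
}

#' Generate one subject's sensor streams
#'
#' Emits the vital and pressure series the sensor system would record for one
#' subject: AR(1) mean-reverting vitals around subject-level means drawn from
#' the group parameters, pressure frames carrying the scheduled load events on
#' a central 3x3 sub-block of the foil, temperature coupled to the lagged
#' z-scored total load, and burst-structured validity flags plus blank gap
#' minutes. Fully reproducible from the seed.
#'
#' @param profile A [subject_profile()].
#' @param config A [generator_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A list with elements `vitals` ([vital_series()]) and `pressure`
#'   ([pressure_series()]), plus the realised `events` schedule.
#' @export
generate_subject <- function(profile, config = generator_config(),
                             seed = config$seed) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(config, "generator_config"))
  if (is.null(config$group_params[[profile$group]])) {
    stop("no parameter set for group '", profile$group, "'")
  }
  set.seed(seed)
  vi <- config$vitals_interval
  pi_ <- config$pressure_interval
  tv <- seq(0, config$duration - vi, by = vi)
  tp <- seq(0, config$duration - pi_, by = pi_)
  nv <- length(tv)
  np <- length(tp)
  rows <- config$grid_shape[1]
  cols <- config$grid_shape[2]

  events <- config$events
  if (is.null(events)) events <- auto_event_schedule(config)

  ## pressure frames: baseline + noise + event load on a central 3x3 block
  grid <- array(pmax(0, config$baseline_level +
                          stats::rnorm(np * rows * cols,
                                       0, config$baseline_noise_sd)),
                dim = c(np, rows, cols))
  br <- block_indices(rows)
  bc <- block_indices(cols)
  per_el <- 1 / (length(br) * length(bc))
  if (nrow(events)) {
    for (i in seq_len(nrow(events))) {
      in_ev <- tp >= events$onset[i] & tp < events$onset[i] + events$duration[i]
      if (any(in_ev)) {
        grid[in_ev, br, bc] <- grid[in_ev, br, bc] +
          events$amplitude[i] * per_el
      }
    }
  }
  pressure <- pressure_series(tp, grid, interval = pi_,
                              subject_id = profile$subject_id,
                              weight = profile$weight,
                              shoe_group = profile$shoe_group)

  ## subject-level channel means, then AR(1) noise around them
  mu <- vapply(VITAL_CHANNELS, subject_channel_mean, 0,
               profile = profile, config = config)
  pars <- config$group_params[[profile$group]]
  vals <- list()
  for (ch in VITAL_CHANNELS) {
    vals[[ch]] <- mu[[ch]] +
      ar1_noise(nv, pars[[ch]][["sd"]], config$ar_tau, vi)
  }

  ## temperature follows the lagged z-scored load (rising load -> warming)
  sl <- pressure$sum_load
  if (np > 1 && stats::sd(sl) > 0) {
    z <- (sl - mean(sl)) / pop_sd(sl)
    zv <- z[pmin(np, findInterval(tv, tp))]
    a <- 1 - exp(-vi / config$temp_lag)
    lagged <- as.numeric(stats::filter(a * zv, 1 - a,
                                       method = "recursive", init = zv[1]))
    vals$temp <- vals$temp + config$temp_gain * lagged
  }
  vals$spo2 <- pmin(100, pmax(0, vals$spo2))
  vals$hr <- pmax(0, vals$hr)

  ## validity bursts per channel, plus whole-record gap minutes
  valid <- lapply(VITAL_CHANNELS, function(ch)
    markov_valid_flags(nv, config$invalid_fraction[[ch]],
                       config$invalid_burst_mean))
  names(valid) <- VITAL_CHANNELS
  gap <- if (config$gap_rate > 0) {
    markov_valid_flags(nv,
                       f = min(0.99, config$gap_rate * config$gap_mean_length /
                                 (1 + config$gap_rate * config$gap_mean_length)),
                       burst_mean = config$gap_mean_length)
  } else rep(TRUE, nv)
  for (ch in VITAL_CHANNELS) {
    valid[[ch]] <- valid[[ch]] & gap
    vals[[ch]][!valid[[ch]]] <- NA_real_
  }

  vitals <- vital_series(tv, spo2 = vals$spo2, hr = vals$hr, temp = vals$temp,
                         spo2_valid = valid$spo2, hr_valid = valid$hr,
                         temp_valid = valid$temp,
                         interval = vi, subject_id = profile$subject_id)
  attr(vitals, "gap") <- !gap
  list(vitals = vitals, pressure = pressure, events = events)
}

## central block of up to 3 indices on an axis of length n
block_indices <- function(n) {
  k <- min(3, n)
  start <- floor((n - k) / 2) + 1
  start:(start + k - 1)
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Inject a PU-like SpO2 decline episode
#'
#' Superimposes the early-warning pattern seen before a diagnosed stage-one
#' PU: the SpO2 level declines linearly by `drop` percentage points over
#' `decline_duration` minutes starting at `onset`, holds the depressed level
#' for `hold_duration` minutes, then returns to baseline. Noise and validity
#' structure are preserved; other channels are untouched.
#'
#' @param vitals A [vital_series()].
#' @param onset Episode start, minutes.
#' @param drop Decline depth in percentage points (>= 0).
#' @param decline_duration Length of the linear decline, minutes.
#' @param hold_duration Length of the depressed plateau, minutes.
#' @return A modified copy of `vitals`.
#' @export
inject_pu_episode <- function(vitals, onset, drop, decline_duration = 90,
                              hold_duration = 60) {
  stopifnot(inherits(vitals, "vital_series"))
  if (drop < 0) stop("drop must be >= 0")
  end <- onset + decline_duration + hold_duration
  if (nrow(vitals) == 0 || end > max(vitals$t)) {
    stop("episode exceeds the series")
  }
  t <- vitals$t
  delta <- numeric(length(t))
  in_decline <- t >= onset & t <= onset + decline_duration
  delta[in_decline] <- -drop * (t[in_decline] - onset) / decline_duration
  in_hold <- t > onset + decline_duration & t < end
  delta[in_hold] <- -drop
  out <- vitals
  out$spo2 <- ifelse(is.na(out$spo2), NA_real_,
                     pmin(100, pmax(0, out$spo2 + delta)))
  validate_vital_series(out)
  out
}

#' Generate a synthetic cohort
#'
#' Samples patient/control profiles (condition flags at the configured
#' prevalences; controls healthy) and generates each subject's streams with a
#' per-subject seed derived deterministically from the master seed.
#'
#' @param n_patients,n_controls Subject counts (>= 0).
#' @param config A [generator_config()].
#' @param seed Master seed.
#' @return A `cohort_dataset`: list with `subjects` (each a list of
#'   `profile`, `vitals`, `pressure`), `config` and `seed`.
#' @export
generate_cohort <- function(n_patients, n_controls,
                            config = generator_config(), seed = config$seed) {
  stopifnot(n_patients >= 0, n_controls >= 0)
  set.seed(seed)
  n <- n_patients + n_controls
  groups <- rep(c("patient", "control"), c(n_patients, n_controls))
  ids <- c(sprintf("P%03d", seq_len(n_patients)),
           sprintf("C%03d", seq_len(n_controls)))
  sub_seeds <- if (n) sample.int(.Machine$integer.max - 1, n) else integer(0)
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    if (groups[i] == "patient") {
      flags <- stats::runif(length(config$prevalence)) < config$prevalence
      names(flags) <- names(config$prevalence)
      ## a prior surgery implies a prior PU
      if (flags[["prior_pu_surgery"]]) flags[["prior_pu"]] <- TRUE
      profiles[[i]] <- subject_profile(
        ids[i], "patient",
        age = round(stats::rnorm(1, 70, 10)),
        height = round(stats::rnorm(1, 172, 9)),
        weight = max(40, round(stats::rnorm(1, 82, 15))),
        conditions = flags)
    } else {
      profiles[[i]] <- subject_profile(
        ids[i], "control",
        age = round(stats::rnorm(1, 35, 10)),
        height = round(stats::rnorm(1, 175, 9)),
        weight = max(45, round(stats::rnorm(1, 72, 10))))
    }
  }
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    streams <- generate_subject(profiles[[i]], config, seed = sub_seeds[i])
    subjects[[i]] <- list(profile = profiles[[i]], vitals = streams$vitals,
                          pressure = streams$pressure,
                          events = streams$events)
  }
  names(subjects) <- ids
  structure(list(subjects = subjects, config = config, seed = seed),
            class = "cohort_dataset")
}

#' @export
print.cohort_dataset <- function(x, ...) {
  groups <- vapply(x$subjects, function(s) s$profile$group, "")
  cat(sprintf("<cohort_dataset> %d subjects (%d patients, %d controls)\n",
              length(groups), sum(groups == "patient"),
              sum(groups == "control")))
  invisible(x)
}

#' Generate a synthetic insole recording
#'
#' Emulates the foot-study variant of the sensor: a 12-row x 4-column
#' pressure foil worn in a shoe by an ambulatory subject. Load is
#' weight-proportional and distributed anatomically (most at the heel, least
#' at the midfoot); walking produces occasional high-pressure frames.
#' Orthopedic shoes attenuate peak frames and slightly reduce the mean load,
#' the pattern the insole comparison is designed to detect.
#'
#' @param profile A [subject_profile()] with `shoe_group` set.
#' @param duration Minutes of recording.
#' @param interval Frame interval in minutes.
#' @param seed Integer seed.
#' @param peak_attenuation Multiplier on peak-frame load for the orthopedic
#'   group (< 1).
#' @param mean_attenuation Multiplier on resting load for the orthopedic
#'   group.
#' @return A [pressure_series()] with a 12x4 grid, carrying the subject
#'   weight and shoe group.
#' @export
generate_insole_subject <- function(profile, duration = 1440, interval = 5,
                                    seed = 1L, peak_attenuation = 0.6,
                                    mean_attenuation = 0.9) {
  stopifnot(inherits(profile, "subject_profile"),
            profile$shoe_group %in% c("orthopedic", "regular", "control"))
  set.seed(seed)
  t <- seq(0, duration - interval, by = interval)
  n <- length(t)
  ## row shares, toe row first: forefoot carries ~40%, midfoot ~10%,
  ## rearfoot/heel ~50% of standing load
  row_share <- c(rep(0.40 / 5, 5), rep(0.10 / 3, 3), rep(0.50 / 4, 4))
  ortho <- identical(profile$shoe_group, "orthopedic")
  base <- profile$weight * 0.5 * (if (ortho) mean_attenuation else 1)
  activity <- stats::rgamma(n, shape = 4, rate = 4)      # mean 1
  spike <- stats::runif(n) < 0.05
  spike_mult <- ifelse(spike, 3 * (if (ortho) peak_attenuation else 1), 1)
  frame_load <- base * activity * spike_mult
  grid <- array(0, dim = c(n, 12, 4))
  for (r in 1:12) {
    share <- row_share[r] / 4
    grid[, r, ] <- pmax(0, frame_load * share *
                             (1 + stats::rnorm(n * 4, 0, 0.1)))
  }
  pressure_series(t, grid, interval = interval,
                  subject_id = profile$subject_id, weight = profile$weight,
                  shoe_group = profile$shoe_group)
}
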