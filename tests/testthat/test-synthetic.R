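noise_free_config <- function(duration = 600, mean_spo2 = 98.5, ...) {
  gp <- DEFAULT_GROUP_PARAMS
  for (g in names(gp)) for (ch in names(gp[[g]])) gp[[g]][[ch]]["sd"] <- 0
  gp$control$spo2["mean"] <- mean_spo2
  generator_config(duration = duration, group_params = gp,
                   invalid_fraction = c(spo2 = 0, hr = 0, temp = 0),
                   gap_rate = 0, baseline_noise_sd = 0, temp_gain = 0,
                   events = data.frame(onset = numeric(),
                                       duration = numeric(),
                                       amplitude = numeric()), ...)
}

test_that("degenerate noise-free generation emits the exact configured mean", {
  s <- generate_subject(subject_profile("C1", "control"),
                        noise_free_config(), seed = 5)
  expect_true(all(s$vitals$spo2 == 98.5))
  expect_true(all(s$vitals$spo2_valid))
  expect_equal(nrow(s$vitals), 600)
  expect_true(all(s$pressure$sum_load == 2 * 25))
})

test_that("generation is bit-identical under a repeated seed", {
  p <- subject_profile("P1", "patient", conditions = c(immobile = TRUE))
  cfg <- generator_config(duration = 1000)
  a <- generate_subject(p, cfg, seed = 11)
  b <- generate_subject(p, cfg, seed = 11)
  expect_identical(a$vitals, b$vitals)
  expect_identical(a$pressure$grid, b$pressure$grid)
  expect_identical(a$events, b$events)
})

test_that("long patient series recovers the configured SpO2 mean", {
  # law-of-large-numbers check; band = 2x the AR-adjusted Monte-Carlo SE
  # (tau = 30 min -> effective n ~ 167 over 10,000 min, SE ~ 0.22)
  cfg <- generator_config(duration = 10000)
  s <- generate_subject(subject_profile("P1", "patient"), cfg, seed = 1)
  got <- mean(s$vitals$spo2[s$vitals$spo2_valid])
  phi <- exp(-1 / 30)
  se <- 2.9 / sqrt(10000 * (1 - phi) / (1 + phi))
  expect_lt(abs(got - 91.3), 2 * se)
})

test_that("generated streams respect physical ranges and flag consistency", {
  for (seed in 1:3) {
    cfg <- generator_config(duration = 1500, seed = seed)
    s <- generate_subject(subject_profile("P1", "patient",
                                          conditions = c(prior_pu = TRUE)),
                          cfg, seed = seed)
    v <- s$vitals
    expect_true(all(is.na(v$spo2) | (v$spo2 >= 0 & v$spo2 <= 100)))
    expect_true(all(s$pressure$grid >= 0))
    expect_equal(s$pressure$sum_load, apply(s$pressure$grid, 1, sum))
    for (ch in c("spo2", "hr", "temp")) {
      expect_false(any(is.na(v[[ch]]) & v[[paste0(ch, "_valid")]]))
    }
    f <- cfg$invalid_fraction[["spo2"]]
    expect_lt(abs(mean(!v$spo2_valid) - f), 0.15)  # burst noise is coarse
  }
})

test_that("positive temperature coupling yields positive lagged correlation", {
  cfg <- generator_config(duration = 4000, temp_gain = 0.5,
                          invalid_fraction = c(spo2 = 0, hr = 0, temp = 0),
                          gap_rate = 0)
  s <- generate_subject(subject_profile("P1", "patient"), cfg, seed = 2)
  up <- upsample_sum_load(s$pressure)
  n <- min(nrow(up), nrow(s$vitals))
  lag <- 5
  r <- cor(up$sum_load[1:(n - lag)], s$vitals$temp[(1 + lag):n])
  expect_gt(r, 0.2)
})

test_that("inject_pu_episode reproduces the documented decline exactly", {
  s <- generate_subject(subject_profile("C1", "control",),
                        noise_free_config(mean_spo2 = 94), seed = 1)$vitals
  out <- inject_pu_episode(s, onset = 100, drop = 7, decline_duration = 90,
                           hold_duration = 60)
  expect_equal(out$spo2[out$t == 190], 87)           # 94 -> 87 over 1.5 h
  # closed-form piecewise-linear oracle, pointwise
  oracle <- vapply(s$t, function(t) {
    if (t < 100) 94
    else if (t <= 190) 94 - 7 * (t - 100) / 90
    else if (t < 250) 87
    else 94
  }, 0)
  expect_equal(out$spo2, oracle, tolerance = 1e-12)
  expect_identical(out$hr, s$hr)
  expect_identical(out$temp, s$temp)
})

test_that("inject_pu_episode edge cases", {
  s <- generate_subject(subject_profile("C1", "control"),
                        noise_free_config(duration = 300), seed = 1)$vitals
  expect_identical(inject_pu_episode(s, 50, 0, 90, 60)$spo2, s$spo2)
  expect_error(inject_pu_episode(s, 200, 5, 90, 60), "exceeds")
  expect_error(inject_pu_episode(s, 50, -1, 90, 60), ">= 0")
})

test_that("generate_cohort bookkeeping and parameter recovery", {
  empty <- generate_cohort(0, 0, generator_config(duration = 100), seed = 1)
  expect_length(empty$subjects, 0)

  small <- generate_cohort(3, 2, generator_config(duration = 120), seed = 1)
  ids <- names(small$subjects)
  expect_length(unique(ids), 5)
  groups <- vapply(small$subjects, function(s) s$profile$group, "")
  expect_equal(sum(groups == "patient"), 3)
  expect_equal(sum(groups == "control"), 2)

  ds <- generate_cohort(15, 15, generator_config(duration = 1000), seed = 3)
  sm <- subject_means(ds, preprocess = FALSE)
  d <- mean(sm$spo2_mean[sm$group == "control"]) -
    mean(sm$spo2_mean[sm$group == "patient"])
  expect_lt(abs(d - (98.5 - 91.3)), 1)
})

test_that("profile invariants are enforced", {
  expect_error(subject_profile("x", "control",
                               conditions = c(diabetes = TRUE)),
               "control")
  expect_error(subject_profile("x", "patient", weight = 0), "weight")
  expect_error(subject_profile("x", "patient", diagnosis_events =
    data.frame(t = c(10, 5), result = c("negative", "negative"))),
    "increasing")
  expect_error(subject_profile("x", "patient", diagnosis_events =
    data.frame(t = c(5, 10), result = c("positive", "positive"))),
    "one positive")
  expect_error(generate_subject(
    structure(list(subject_id = "x", group = "other",
                   conditions = c(prior_pu_surgery = FALSE)),
              class = "subject_profile"),
    generator_config(duration = 100)), "parameter set")
  expect_error(generator_config(duration = 0), "positive")
  expect_error(generator_config(duration = 101), "divide")
  expect_error(generator_config(invalid_fraction = c(spo2 = 1.2, hr = 0,
                                                     temp = 0)),
               "invalid_fraction")
})
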