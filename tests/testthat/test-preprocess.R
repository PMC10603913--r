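test_that("normalize_timeline fills missing timestamps with blanks", {
  raw <- data.frame(t = c(0, 1, 3), spo2 = c(95, 96, 97))
  out <- normalize_timeline(raw)
  expect_equal(out$t, 0:3)
  expect_true(is.na(out$spo2[3]))
  expect_false(out$spo2_valid[3])
  expect_equal(out$spo2[c(1, 2, 4)], c(95, 96, 97))

  # identity on an already-complete grid, existing values never altered
  s <- make_random_vitals(50, seed = 1)
  out2 <- normalize_timeline(s)
  expect_equal(out2$spo2, s$spo2)
  expect_equal(out2$t, s$t)
})

test_that("normalize_timeline on a random subset restores the complement", {
  set.seed(2)
  full_t <- 0:99
  keep <- sort(sample(full_t, 60))
  keep <- union(0, union(keep, 99))
  raw <- data.frame(t = keep, spo2 = 90 + seq_along(keep) * 0.01)
  out <- normalize_timeline(raw)
  expect_equal(out$t, full_t)
  expect_equal(out$t[is.na(out$spo2)], setdiff(full_t, keep))
})

test_that("normalize_timeline handles duplicates and bad input", {
  raw <- data.frame(t = c(0, 1, 1, 2), spo2 = c(90, 91, 92, 93))
  expect_equal(normalize_timeline(raw)$spo2, c(90, 92, 93))  # last wins
  expect_error(normalize_timeline(data.frame(t = c(0, "x"), spo2 = 1:2)),
               "row 2")
  expect_equal(nrow(normalize_timeline(data.frame(t = numeric(),
                                                  spo2 = numeric()))), 0)
})

test_that("remove_out_of_range blanks only out-of-range values", {
  s <- vital_series(0:2, spo2 = c(101, 91.3, 69), hr = c(70.2, 25, 100),
                    temp = c(36, 50, 36.5))
  out <- remove_out_of_range(s)
  expect_true(is.na(out$spo2[1]) && !out$spo2_valid[1])
  expect_equal(out$spo2[2], 91.3)
  expect_true(is.na(out$spo2[3]))
  expect_true(is.na(out$hr[2]))
  expect_equal(out$hr[1], 70.2)
  expect_true(is.na(out$temp[2]))
  expect_identical(remove_out_of_range(out), out)   # idempotent
})

test_that("remove_out_of_range matches the naive loop oracle", {
  for (seed in 1:3) {
    s <- make_random_vitals(300, seed = seed)
    s$spo2 <- s$spo2 + sample(c(0, 30, -40), 300, replace = TRUE)
    s$spo2_valid <- !is.na(s$spo2)
    b <- range_bounds()
    expect_equal(remove_out_of_range(s, b), naive_range(s, b))
  }
})

test_that("forward_fill caps at the configured span", {
  s <- vital_series(0:9, spo2 = c(95, rep(NA, 7), 96, NA))
  out <- forward_fill(s, 5)
  expect_equal(out$spo2, c(95, rep(95, 5), NA, NA, 96, 96))
  expect_equal(out$spo2_valid, c(TRUE, rep(TRUE, 5), FALSE, FALSE, TRUE, TRUE))
  expect_equal(out$spo2_filled,
               c(FALSE, rep(TRUE, 5), FALSE, FALSE, FALSE, TRUE))
})

test_that("forward_fill identities and idempotence", {
  s <- make_random_vitals(100, seed = 3, p_blank = 0)
  expect_identical(forward_fill(s, 5), s)          # nothing to fill
  s2 <- make_random_vitals(200, seed = 4)
  once <- forward_fill(s2, 5)
  expect_identical(forward_fill(once, 5), once)    # idempotent
  # leading blanks never filled
  s3 <- vital_series(0:4, spo2 = c(NA, NA, 95, NA, NA))
  expect_true(all(is.na(forward_fill(s3, 5)$spo2[1:2])))
})

test_that("forward_fill matches the naive scan oracle", {
  for (seed in 5:8) {
    s <- make_random_vitals(250, seed = seed, p_blank = 0.4)
    expect_equal(forward_fill(s, 5), naive_ffill(s, 5))
    expect_equal(forward_fill(s, 2), naive_ffill(s, 2))
  }
})

test_that("quality_factor counts valid channels, filled included", {
  s <- vital_series(0:3,
                    spo2 = c(95, NA, NA, 95), hr = c(70, 70, NA, NA),
                    temp = c(36, 36, 36, NA))
  expect_equal(quality_factor(s), c(1, 2 / 3, 1 / 3, 1 / 3))
  expect_error(quality_factor(s, t = 99), "off the series grid")
  filled <- forward_fill(s, 5)
  expect_equal(quality_factor(filled), c(1, 1, 1, 1))
  # a channel that is always valid bounds the factor from below
  s2 <- make_random_vitals(100, seed = 9, p_blank = 0.6)
  s2$temp <- 36; s2$temp_valid <- TRUE
  expect_true(all(quality_factor(s2) >= 1 / 3))
})

test_that("segment_sections follows the strict-threshold run rule", {
  mk <- function(q) {
    # build a series whose quality factor per timestamp is q (0 or 1)
    vital_series(seq_along(q) - 1,
                 spo2 = ifelse(q == 1, 95, NA), hr = ifelse(q == 1, 70, NA),
                 temp = ifelse(q == 1, 36, NA))
  }
  s <- mk(rep(1, 20))
  sec <- segment_sections(s, quality_config(min_section_length = 5))
  expect_equal(nrow(sec), 1)
  expect_equal(c(sec$t_start, sec$t_end, sec$length), c(0, 20, 20))

  s2 <- mk(c(1, 1, 0, 1, 1, 1))
  sec2 <- segment_sections(s2, quality_config(min_section_length = 2))
  expect_equal(sec2$t_start, c(0, 3))
  expect_equal(sec2$t_end, c(2, 6))

  # strict inequality: threshold 1 excludes any timestamp below quality 1
  s3 <- vital_series(0:5, spo2 = c(95, 95, NA, 95, 95, 95),
                     hr = 70, temp = 36)
  sec3 <- segment_sections(s3, quality_config(quality_threshold = 1,
                                              min_section_length = 1))
  expect_false(any(vapply(seq_len(nrow(sec3)), function(i)
    2 >= sec3$t_start[i] && 2 < sec3$t_end[i], TRUE)))
})

test_that("segment_sections matches a run-length oracle on random input", {
  for (seed in 1:3) {
    s <- make_random_vitals(400, seed = seed, p_blank = 0.35)
    cfg <- quality_config(min_section_length = 10)
    sec <- segment_sections(s, cfg)
    ok <- quality_factor(s) > cfg$quality_threshold
    oracle <- naive_sections(ok, s$t, 1, 10)
    expect_equal(nrow(sec), length(oracle))
    for (i in seq_along(oracle)) {
      expect_equal(c(sec$t_start[i], sec$t_end[i], sec$length[i]),
                   oracle[[i]])
    }
  }
})

test_that("section_stats arithmetic", {
  one <- data.frame(length = 100)
  expect_equal(section_stats(one)[c("mean_length", "median_length")],
               list(mean_length = 100, median_length = 100))
  three <- data.frame(length = c(100, 200, 1200))
  st <- section_stats(three)
  expect_equal(st$mean_length, 500)
  expect_equal(st$median_length, 200)
  expect_equal(section_stats(three[0, , drop = FALSE])$count, 0)
  expect_true(is.na(section_stats(three[0, , drop = FALSE])$mean_length))
})

test_that("preprocess_vitals applies the fixed stage order", {
  # out-of-range value must be deleted before filling, and the filled value
  # must then count as valid for segmentation
  s <- vital_series(0:9, spo2 = c(95, 101, NA, NA, 95, 95, 95, 95, 95, 95),
                    hr = 70, temp = 36)
  out <- preprocess_vitals(s)
  expect_equal(out$series$spo2[2], 95)         # filled from t=0, not 101
  expect_true(out$series$spo2_filled[2])
  expect_equal(quality_factor(out$series), rep(1, 10))
})
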