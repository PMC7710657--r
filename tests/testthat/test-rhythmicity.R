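cosine_series <- function(n_days = 5, bin_width = 30, period_h = 24,
                          base = 50, amp = 40) {
  n <- n_days * 1440 / bin_width
  t_h <- (seq_len(n) - 1) * bin_width / 60
  counts <- round(base + amp * cos(2 * pi * t_h / period_h))
  activity_series("cos", "2020-01-01 00:00", counts, bin_width = bin_width)
}

test_that("autocorrelogram matches the O(N^2) direct-sum oracle", {
  # pure 24 h cosine over 5 days at 30-min bins
  s <- cosine_series()
  ac <- autocorrelogram(s, max_lag_hours = 48)
  expect_equal(ac$acf[1], 1)
  oracle <- acf_direct_sum(as.numeric(s$counts), max_lag = 96)
  expect_equal(ac$acf, oracle, tolerance = 1e-9)
  expect_equal(ac$acf[49], oracle[49], tolerance = 1e-9)  # lag 24 h
  expect_true(all(ac$acf >= -1 - 1e-12 & ac$acf <= 1 + 1e-12))
  # seeded white noise, bin-for-bin
  set.seed(41)
  w <- random_series(n_days = 5, bin_width = 30, lambda = 20)
  acw <- autocorrelogram(w, max_lag_hours = 48)
  expect_equal(acw$acf, acf_direct_sum(as.numeric(w$counts), 96),
               tolerance = 1e-9)
})

test_that("autocorrelogram rejects constant or too-short series", {
  const <- activity_series("c", "2020-01-01 00:00", rep(3L, 240),
                           bin_width = 30)
  expect_error(autocorrelogram(const), "constant")
  short <- random_series(n_days = 2, bin_width = 30)
  expect_error(autocorrelogram(short, max_lag_hours = 48), "too short")
})

test_that("rhythm_statistic selects the circadian peak and classifies by RS", {
  s <- cosine_series()
  r <- rhythm_statistic(autocorrelogram(s))
  expect_s3_class(r, "rhythmicity_result")
  expect_lt(abs(r$estimated_period_hours - 24), 0.51)
  expect_equal(r$confidence_line, 2 / sqrt(240))
  expect_equal(r$rs, r$peak_height / (2 / sqrt(240)))
  expect_equal(r$label, "rhythmic")
  # boundary: RS exactly at threshold is arrhythmic (inclusive); n chosen so
  # the confidence line (2/16) and the peak are exact binary fractions
  n <- 256
  acf_flat <- rep(0, 97)
  acf_flat[1] <- 1
  acf_flat[49] <- 0.1875                   # = 1.5 * 2/sqrt(256), RS = 1.5
  rb <- rhythm_statistic(acf_flat, n_bins = n, bin_width = 30)
  expect_identical(rb$rs, 1.5)
  expect_equal(rb$label, "arrhythmic")
  acf_flat[49] <- 1.5000001 * 2 / sqrt(n)
  expect_equal(rhythm_statistic(acf_flat, n_bins = n, bin_width = 30)$label,
               "rhythmic")
  expect_error(rhythm_statistic(autocorrelogram(s, max_lag_hours = 24),
                                search_window = c(18, 30)),
               "search window")
})

test_that("rhythmicity wrapper maps a constant series to flagged arrhythmic", {
  const <- activity_series("c", "2020-01-01 00:00", rep(2L, 7200))
  r <- rhythmicity(const)
  expect_equal(r$label, "arrhythmic")
  expect_true(r$constant_series)
  expect_equal(r$rs, 0)
})

test_that("RS is invariant to affine rescaling of the counts", {
  set.seed(42)
  sim <- simulate_forager(forager_params(amplitude = 0.6, seed = 99,
                                         n_days_dd = 0))
  base <- rhythmicity(sim$series)$rs
  for (i in 1:5) {
    a <- sample(2:9, 1); b <- sample(0:20, 1)
    scaled <- sim$series
    scaled$counts <- a * scaled$counts + as.integer(b)
    expect_equal(rhythmicity(scaled)$rs, base, tolerance = 1e-9)
  }
})

test_that("RS grows with modulation amplitude (fixed seeds, amplitude grid)", {
  amps <- c(0, 0.3, 0.6, 0.9)
  mean_rs <- vapply(amps, function(a) {
    mean(vapply(1:5, function(sd)
      rhythmicity(simulate_forager(
        forager_params(amplitude = a, seed = sd, n_days_dd = 0,
                       sleep_onset_rate_day = 0,
                       sleep_onset_rate_night = 0))$series)$rs, 1))
  }, 1)
  expect_true(all(diff(mean_rs) > 0))
})

test_that("arrhythmic_proportion reports percentage and n", {
  mk <- function(lab) structure(list(label = lab),
                                class = "rhythmicity_result")
  res <- c(replicate(3, mk("arrhythmic"), simplify = FALSE),
           replicate(7, mk("rhythmic"), simplify = FALSE))
  p <- arrhythmic_proportion(res)
  expect_equal(p$percent, 30)
  expect_equal(p$n, 10)
  expect_equal(arrhythmic_proportion(replicate(4, mk("rhythmic"),
                                               simplify = FALSE))$percent, 0)
  expect_error(arrhythmic_proportion(list()), "empty")
})
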