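test_that("detect_sleep_bouts finds maximal zero runs at the threshold", {
  s <- activity_series("b", "2020-01-01 00:00", c(2L, 0L, 0L, 0L, 0L, 0L, 3L))
  b <- detect_sleep_bouts(s)
  expect_equal(nrow(b), 1L)
  expect_equal(b$duration, 5L)
  expect_equal(b$start_index, 2L)
  # run of 4 is below the default threshold
  s4 <- activity_series("b", "2020-01-01 00:00", c(1L, 0L, 0L, 0L, 0L, 1L, 1L))
  expect_equal(nrow(detect_sleep_bouts(s4)), 0L)
  # a fully inactive day is one maximal 1440-min bout
  sz <- activity_series("b", "2020-01-01 00:00", rep(0L, 1440))
  bz <- detect_sleep_bouts(sz)
  expect_equal(bz$duration, 1440L)
  # 1-min bins are mandatory
  s30 <- activity_series("b", "2020-01-01 00:00", rep(0L, 48), bin_width = 30)
  expect_error(detect_sleep_bouts(s30), "1-min")
  expect_error(detect_sleep_bouts(s, threshold = 0), ">= 1")
})

test_that("bouts are non-overlapping, deterministic and threshold-monotone", {
  set.seed(51)
  for (i in 1:5) {
    counts <- rpois(2880, 0.3)
    s <- activity_series("b", "2020-01-01 00:00", counts)
    b <- detect_sleep_bouts(s)
    expect_identical(b, detect_sleep_bouts(s))  # idempotent
    if (nrow(b) > 1) {
      ends <- b$start_index + b$duration - 1L
      expect_true(all(b$start_index[-1] > ends[-nrow(b)] + 1L))
    }
    # maximality: neighbours of each bout are active or absent
    for (j in seq_len(nrow(b))) {
      lo <- b$start_index[j] - 1L
      hi <- b$start_index[j] + b$duration[j]
      if (lo >= 1) expect_gt(counts[lo], 0)
      if (hi <= length(counts)) expect_gt(counts[hi], 0)
    }
    tot <- vapply(c(3, 5, 10, 30), function(th)
      sum(detect_sleep_bouts(s, th)$duration), 1)
    expect_true(all(diff(tot) <= 0))            # non-increasing in threshold
  }
})

test_that("summarize_sleep counts episodes at onset and splits minutes", {
  sched <- light_schedule(1, 0)
  # one 10-min bout fully inside the day
  s <- activity_series("b", "2020-01-01 00:00",
                       c(rep(1L, 100), rep(0L, 10), rep(1L, 1330)))
  sl <- summarize_sleep(detect_sleep_bouts(s), sched)
  expect_equal(sl$total_sleep_day, 10)
  expect_equal(sl$bouts_day, 1L)
  expect_equal(sl$total_sleep_night, 0)
  expect_equal(sl$bouts_night, 0L)
  expect_true(is.na(sl$mean_bout_night))
  # 20-min bout starting 10 min before lights-off: initiated in day,
  # minutes split 10 day / 10 night (hand-enumerated apportioning)
  cnt <- rep(1L, 1440); cnt[711:730] <- 0L
  s2 <- activity_series("b", "2020-01-01 00:00", cnt)
  sl2 <- summarize_sleep(detect_sleep_bouts(s2), sched)
  expect_equal(sl2$bouts_day, 1L)
  expect_equal(sl2$bouts_night, 0L)
  expect_equal(sl2$total_sleep_day, 10)
  expect_equal(sl2$total_sleep_night, 10)
  expect_equal(sl2$mean_bout_day, 20)
  # conservation: per-phase minutes sum to total detected in-regime sleep
  expect_equal(sl2$total_sleep_day + sl2$total_sleep_night,
               sum(detect_sleep_bouts(s2)$duration))
  # 30-min profile sums to the daily total
  expect_length(sl2$profile, 48L)
  expect_true(all(sl2$profile >= 0 & sl2$profile <= 30))
  expect_equal(sum(sl2$profile), 20)
})

test_that("misaligned bouts are rejected", {
  sched <- light_schedule(1, 0)
  s <- activity_series("b", "2020-01-02 00:00", c(rep(0L, 10), rep(1L, 10)))
  expect_error(summarize_sleep(detect_sleep_bouts(s), sched), "misaligned")
})

test_that("detected sleep equals generator ground truth exactly", {
  for (sd in c(7, 77, 777)) {
    sim <- simulate_forager(forager_params(seed = sd,
                                           sleep_onset_rate_day = 0.01,
                                           sleep_onset_rate_night = 0.03))
    b <- detect_sleep_bouts(sim$series, 5)
    r <- rle(sim$truth$sleep_state)
    true_runs <- r$lengths[r$values & r$lengths >= 5]
    expect_identical(nrow(b), length(true_runs))
    expect_identical(sum(b$duration), sum(true_runs))
    expect_identical(b$duration, as.integer(true_runs))
  }
})

test_that("phase_activity averages per day and matches a brute-force sum", {
  sched <- light_schedule(1, 0)
  s <- activity_series("b", "2020-01-01 00:00", rep(1L, 1440))
  pa <- phase_activity(s, sched)
  expect_equal(unname(pa["day"]), 720)
  expect_equal(unname(pa["night"]), 720)
  # all activity in the photophase
  cnt <- c(rep(2L, 720), rep(0L, 720))
  pa2 <- phase_activity(activity_series("b", "2020-01-01 00:00", cnt), sched)
  expect_equal(unname(pa2["night"]), 0)
  expect_true(is.na(pa2["subjective_day"]))
  # random series against per-bin oracle over LD + DD
  set.seed(52)
  sched2 <- default_schedule(2, 1)
  s3 <- random_series(n_days = 3)
  pa3 <- phase_activity(s3, sched2)
  ph <- phase_of(bin_times(s3) + 30, sched2)
  expect_equal(unname(pa3["day"]), sum(s3$counts[ph == "day"]) / 2)
  expect_equal(unname(pa3["night"]), sum(s3$counts[ph == "night"]) / 2)
  expect_equal(unname(pa3["subjective_day"]),
               sum(s3$counts[ph == "subjective_day"]))
  # trailing partial day is excluded and reported
  s4 <- activity_series("b", "2020-01-01 00:00", rep(1L, 1440 + 100))
  pa4 <- phase_activity(s4, sched2)
  expect_true(attr(pa4, "excluded_partial_day"))
  expect_equal(unname(pa4["day"]), 720)
})
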