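test_that("activity_series enforces its invariants", {
  expect_error(activity_series("b", "2020-01-01 00:00", c(1L, -1L)),
               "non-negative")
  expect_error(activity_series("b", "2020-01-01 00:00", c(1.5, 2)),
               "non-negative integers")
  expect_error(activity_series("b", "2020-01-01 00:00", integer(0)),
               "at least one bin")
  expect_error(activity_series("b", "2020-01-01 00:00", 1L, bin_width = 7),
               "divide 1440")
  s <- activity_series("b", "2020-01-01 00:00", 0:3, bin_width = 30)
  expect_s3_class(s, "activity_series")
  expect_equal(as.numeric(diff(bin_times(s))), rep(30, 3))
})

test_that("phase_of maps LD and DD timestamps per the half-open convention", {
  sched <- light_schedule(2, 2, lights_on_clock = 0,
                          reference_start = "2020-01-01 00:00")
  t0 <- as.POSIXct("2020-01-01 00:00", tz = "UTC")
  expect_equal(phase_of(t0 + 60, sched), "day")           # 1 min after lights-on
  expect_equal(phase_of(t0 + 720 * 60, sched), "night")   # exactly lights-off
  expect_equal(phase_of(t0, sched), "day")                # exactly lights-on
  # 6 h after extrapolated lights-on on a DD day
  expect_equal(phase_of(t0 + (2 * 1440 + 360) * 60, sched), "subjective_day")
  expect_equal(phase_of(t0 + (3 * 1440 + 800) * 60, sched), "subjective_night")
  expect_error(phase_of(t0 - 60, sched), "outside")
  expect_error(phase_of(t0 + 4 * 1440 * 60, sched), "outside")
})

test_that("phase_of respects a non-midnight lights-on and 24 h periodicity", {
  sched <- light_schedule(3, 0, lights_on_clock = 6 * 60,
                          reference_start = "2020-01-01 00:00")
  t0 <- as.POSIXct("2020-01-01 00:00", tz = "UTC")
  expect_equal(phase_of(t0 + 6 * 3600, sched), "day")
  expect_equal(phase_of(t0 + 5 * 3600, sched), "night")   # pre-dawn scotophase
  expect_equal(phase_of(t0 + 18 * 3600, sched), "night")
  # periodic with period 1440 min within the LD block
  mins <- sample.int(1440, 50) - 1L
  expect_equal(phase_of(t0 + mins * 60, sched),
               phase_of(t0 + (mins + 1440) * 60, sched))
})

test_that("rebin sums groups, conserves totals and rejects ragged tails", {
  s <- activity_series("b", "2020-01-01 00:00", rep(1L, 60))
  expect_equal(rebin(s, 30)$counts, c(30L, 30L))
  expect_identical(rebin(s, 1), s)
  s59 <- activity_series("b", "2020-01-01 00:00", rep(1L, 59))
  expect_error(rebin(s59, 30), "ragged tail")
  expect_error(rebin(rebin(s, 30), 45), "not a multiple")
  # conservation property over random series and widths
  set.seed(11)
  for (i in 1:10) {
    bw <- sample(c(1, 2, 5, 10), 1)
    s <- random_series(n_days = sample(1:3, 1), bin_width = bw)
    nw <- bw * sample(c(2, 3, 6), 1)
    r <- rebin(s, nw)
    expect_identical(sum(r$counts), sum(s$counts))
    expect_identical(r$start_time, s$start_time)
  }
})

test_that("slice_phase partitions the series exactly across the four phases", {
  sched <- default_schedule(2, 2)
  set.seed(21)
  s <- random_series(n_days = 4, bin_width = 30)
  slices <- lapply(c("day", "night", "subjective_day", "subjective_night"),
                   function(p) slice_phase(s, sched, p))
  tot <- sum(vapply(slices, function(sl) sum(unlist(sl)), 1))
  expect_identical(tot, as.numeric(sum(s$counts)))
  # one LD day, phase = day: 720 min of bins starting at lights-on
  d1 <- slice_phase(s, sched, "day")
  expect_equal(length(d1), 2L)               # two LD days recorded
  expect_equal(length(d1[[1]]), 24L)         # 720 min / 30-min bins
  expect_equal(names(d1[[1]])[1], "2020-01-01 00:00")
  # two DD days of subjective night, each 720 min
  sn <- slice_phase(s, sched, "subjective_night")
  expect_equal(lengths(sn), c("3" = 24L, "4" = 24L))
  # brute-force per-bin check of membership
  for (p in c("day", "subjective_night")) {
    manual <- sum(s$counts[phase_of(bin_times(s) + 15 * 60, sched) == p])
    expect_identical(sum(unlist(slice_phase(s, sched, p))), manual)
  }
})

test_that("slice_phase flags regime-incompatible phases", {
  sched_ld <- light_schedule(3, 0)
  s <- random_series(n_days = 3, bin_width = 30)
  out <- slice_phase(s, sched_ld, "subjective_day")
  expect_length(out, 0)
  expect_true(attr(out, "incompatible_phase"))
})

test_that("read_schedule parses a YAML schedule config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("entrain_days: 4", "dd_days: 2", 'lights_on_clock: "06:00"',
               'reference_start: "2020-03-01 00:00"'), f)
  sc <- read_schedule(f)
  expect_equal(sc$entrain_days, 4L)
  expect_equal(sc$dd_days, 2L)
  expect_equal(sc$lights_on_clock, 360L)
})
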