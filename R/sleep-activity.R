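#' Detect sleep bouts from sustained inactivity
#'
#' Any maximal run of consecutive zero-count minutes of at least `threshold`
#' minutes (default 5, the conventional insect-sleep proxy) is scored as a
#' sleep bout. Bouts are maximal — the minutes immediately before and after a
#' bout are active or absent — so they never overlap, and detection is
#' deterministic.
#'
#' @param series An `activity_series` at 1-min bins. Coarser series cannot be
#'   used: rebinning cannot recover within-bin inactivity runs, so 1-min
#'   input is required.
#' @param threshold Minimum run length, minutes (integer ≥ 1; default 5).
#' @return A data.frame of class `sleep_bouts` with columns `start_index`
#'   (1-based minute), `start_time` (`POSIXct`) and `duration` (minutes),
#'   in chronological order. Zero rows if no run reaches the threshold.
#' @examples
#' s <- activity_series("bee01", "2020-01-01 00:00",
#'                      c(2L, 0L, 0L, 0L, 0L, 0L, 3L))
#' detect_sleep_bouts(s)
#' @export
detect_sleep_bouts <- function(series, threshold = 5) {
  stopifnot(inherits(series, "activity_series"))
  if (series$bin_width != 1L)
    stop("sleep scoring requires 1-min bins; this series has ",
         series$bin_width, "-min bins and rebinning cannot restore the ",
         "lost within-bin detail - supply the original 1-min recording")
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 1L) stop("'threshold' must be >= 1 min")
  r <- rle(series$counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= threshold
  out <- data.frame(start_index = starts[keep],
                    start_time = series$start_time + 60 * (starts[keep] - 1L),
                    duration = r$lengths[keep])
  class(out) <- c("sleep_bouts", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "subject_id") <- series$subject_id
  out
}

#' Summarize sleep bouts by circadian phase
#'
#' Each bout is COUNTED as an episode in the phase where it was initiated
#' (its first minute), while its MINUTES are apportioned to the phases they
#' actually occupy, so per-phase totals always sum to the total detected
#' sleep. By default only the LD (entrained) days are analyzed, mirroring
#' day/night sleep figures; set `regime = "dd"` to analyze the DD block using
#' the subjective phases in the day/night slots.
#'
#' @param bouts A `sleep_bouts` data.frame from [detect_sleep_bouts()].
#' @param schedule A `light_schedule` aligned with the series the bouts came
#'   from.
#' @param regime `"ld"` (default) or `"dd"`: which block of the schedule to
#'   summarize.
#' @param profile_bin_width Width of the time-of-day profile bins, minutes
#'   (default 30, giving 48 bins).
#' @return Object of class `sleep_summary`: totals (min) and episode counts
#'   per phase, mean bout length per phase (`NA` when a phase has no bouts),
#'   the mean time-of-day sleep profile (min asleep per profile bin per day),
#'   and `n_days` analyzed.
#' @export
summarize_sleep <- function(bouts, schedule, regime = c("ld", "dd"),
                            profile_bin_width = 30) {
  regime <- match.arg(regime)
  stopifnot(inherits(bouts, "sleep_bouts"), inherits(schedule, "light_schedule"))
  n_days <- if (regime == "ld") schedule$entrain_days else schedule$dd_days
  if (n_days == 0L)
    stop("schedule has no ", toupper(regime), " days to summarize")
  want <- if (regime == "ld") c("day", "night")
          else c("subjective_day", "subjective_night")
  nb <- 1440L %/% as.integer(profile_bin_width)
  profile <- numeric(nb)
  tot <- c(day = 0, night = 0)
  n_ep <- c(day = 0L, night = 0L)
  durs <- list(day = numeric(0), night = numeric(0))
  ref <- as.numeric(schedule$reference_start)
  total_min <- schedule_minutes(schedule)
  for (i in seq_len(nrow(bouts))) {
    t0 <- bouts$start_time[i]
    off0 <- (as.numeric(t0) - ref) / 60
    if (off0 < 0 || off0 + bouts$duration[i] > total_min)
      stop("bout ", i, " extends outside the schedule window; ",
           "bouts and schedule are misaligned")
    mins <- t0 + 60 * (seq_len(bouts$duration[i]) - 1L)
    ph <- phase_of(mins, schedule)
    ph_start <- ph[1]
    if (ph_start %in% want) {
      slot <- if (ph_start %in% c("day", "subjective_day")) "day" else "night"
      n_ep[slot] <- n_ep[slot] + 1L
      durs[[slot]] <- c(durs[[slot]], bouts$duration[i])
    }
    in_regime <- ph %in% want
    if (any(in_regime)) {
      slots <- ifelse(ph[in_regime] %in% c("day", "subjective_day"),
                      "day", "night")
      tt <- table(slots)
      tot[names(tt)] <- tot[names(tt)] + as.numeric(tt)
      tod <- (as.numeric(mins[in_regime]) %/% 60) %% 1440
      bin <- tod %/% as.integer(profile_bin_width) + 1L
      tb <- table(bin)
      profile[as.integer(names(tb))] <- profile[as.integer(names(tb))] +
        as.numeric(tb)
    }
  }
  structure(
    list(total_sleep_day = unname(tot["day"]),
         total_sleep_night = unname(tot["night"]),
         bouts_day = unname(n_ep["day"]),
         bouts_night = unname(n_ep["night"]),
         mean_bout_day = if (length(durs$day)) mean(durs$day) else NA_real_,
         mean_bout_night = if (length(durs$night)) mean(durs$night) else NA_real_,
         profile = profile / n_days,
         profile_bin_width = as.integer(profile_bin_width),
         n_days = n_days, regime = regime,
         subject_id = attr(bouts, "subject_id")),
    class = "sleep_summary")
}

#' @export
print.sleep_summary <- function(x, ...) {
  cat(sprintf("<sleep_summary> %s, %s block (%d days)\n",
              x$subject_id %||% "?", toupper(x$regime), x$n_days))
  cat(sprintf("  day:   %g min in %d episodes (mean %s min)\n",
              x$total_sleep_day, x$bouts_day,
              if (is.na(x$mean_bout_day)) "NA" else sprintf("%.1f", x$mean_bout_day)))
  cat(sprintf("  night: %g min in %d episodes (mean %s min)\n",
              x$total_sleep_night, x$bouts_night,
              if (is.na(x$mean_bout_night)) "NA" else sprintf("%.1f", x$mean_bout_night)))
  invisible(x)
}

#' Mean per-day activity by circadian phase
#'
#' For each phase present in the schedule, total counts falling in that phase
#' divided by the number of complete days in the corresponding block — the
#' per-subject quantity behind day/night activity comparisons. A trailing
#' partial day is excluded from the analysis and reported via the
#' `excluded_partial_day` attribute.
#'
#' @param series An `activity_series` covering at least one full schedule day.
#' @param schedule A `light_schedule`.
#' @return Named numeric vector with entries `day`, `night`,
#'   `subjective_day`, `subjective_night` (mean counts per day; `NA` for
#'   phases absent from the regime), with attributes `n_days_ld`,
#'   `n_days_dd` and `excluded_partial_day`.
#' @export
phase_activity <- function(series, schedule) {
  stopifnot(inherits(series, "activity_series"), inherits(schedule, "light_schedule"))
  ref <- as.numeric(schedule$reference_start) / 60
  s0 <- as.numeric(series$start_time) / 60 - ref
  n_min <- length(series$counts) * series$bin_width
  full_days <- floor((s0 + n_min) / 1440) - ceiling(s0 / 1440)
  if (full_days < 1L)
    stop("series must cover at least one full schedule day")
  excluded <- (s0 + n_min) %% 1440 != 0
  end_min <- (floor((s0 + n_min) / 1440)) * 1440
  mid <- bin_times(series) + 30 * series$bin_width
  offs <- as.numeric(mid) / 60 - ref
  keep <- offs >= ceiling(s0 / 1440) * 1440 & offs < end_min
  ph <- phase_of(mid[keep], schedule)
  counts <- series$counts[keep]
  day_idx <- floor(offs[keep] / 1440)
  n_ld <- length(unique(day_idx[day_idx < schedule$entrain_days]))
  n_dd <- length(unique(day_idx[day_idx >= schedule$entrain_days]))
  out <- c(day = NA_real_, night = NA_real_,
           subjective_day = NA_real_, subjective_night = NA_real_)
  for (p in c("day", "night")) {
    if (n_ld > 0) out[p] <- sum(counts[ph == p]) / n_ld
  }
  for (p in c("subjective_day", "subjective_night")) {
    if (n_dd > 0) out[p] <- sum(counts[ph == p]) / n_dd
  }
  attr(out, "n_days_ld") <- n_ld
  attr(out, "n_days_dd") <- n_dd
  attr(out, "excluded_partial_day") <- excluded
  out
}
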