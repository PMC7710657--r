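#' Construct a light schedule
#'
#' Describes the lighting regime of a recording: a block of 12 h:12 h
#' light:dark (LD) entrainment days followed by a block of constant-darkness
#' (DD) days. During DD the photophase is extrapolated from the LD lights-on
#' time, defining the subjective day (the 12 h that were lit during
#' entrainment) and subjective night.
#'
#' @param entrain_days Number of LD days at the start of the recording.
#' @param dd_days Number of DD days following the LD block.
#' @param lights_on_clock Clock time of lights-on, in minutes after midnight
#'   (default 0: lights-on at midnight of each schedule day).
#' @param photoperiod Lit minutes per day; fixed at 720 (12 h) for all
#'   analyses in scope.
#' @param reference_start `POSIXct` (or string) midnight-aligned timestamp at
#'   which schedule day 1 begins.
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule(5, 5, reference_start = "2020-01-01 00:00")
#' phase_of(as.POSIXct("2020-01-01 06:00", tz = "UTC"), sched)
#' @export
light_schedule <- function(entrain_days, dd_days = 0L, lights_on_clock = 0L,
                           photoperiod = 720L,
                           reference_start = "2020-01-01 00:00") {
  entrain_days <- as.integer(entrain_days)
  dd_days <- as.integer(dd_days)
  lights_on_clock <- as.integer(lights_on_clock)
  photoperiod <- as.integer(photoperiod)
  if (entrain_days < 0L || dd_days < 0L || entrain_days + dd_days < 1L)
    stop("schedule must cover at least one day")
  if (photoperiod != 720L)
    stop("only 12 h:12 h photoperiods (720 min) are supported")
  if (lights_on_clock < 0L || lights_on_clock >= 1440L)
    stop("'lights_on_clock' must be in [0, 1440) minutes after midnight")
  reference_start <- as_minute_time(reference_start)
  if (minutes_after_midnight(reference_start) != 0L)
    stop("'reference_start' must fall on a midnight (00:00)")
  structure(
    list(entrain_days = entrain_days, dd_days = dd_days,
         lights_on_clock = lights_on_clock, photoperiod = photoperiod,
         reference_start = reference_start),
    class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("<light_schedule> %d LD + %d DD days from %s\n",
              x$entrain_days, x$dd_days,
              format(x$reference_start, "%Y-%m-%d", tz = "UTC")))
  cat(sprintf("  lights on %02d:%02d for %d min (12:12)\n",
              x$lights_on_clock %/% 60, x$lights_on_clock %% 60, x$photoperiod))
  invisible(x)
}

#' Read a light schedule from a YAML configuration file
#'
#' Expected keys: `entrain_days`, `dd_days`, `lights_on_clock` (minutes after
#' midnight or `"HH:MM"`), `reference_start`.
#'
#' @param path Path to a YAML file.
#' @return A `light_schedule`.
#' @export
read_schedule <- function(path) {
  cfg <- yaml::read_yaml(path)
  lo <- cfg$lights_on_clock %||% 0L
  if (is.character(lo)) {
    hm <- as.integer(strsplit(lo, ":", fixed = TRUE)[[1]])
    lo <- hm[1] * 60L + hm[2]
  }
  light_schedule(entrain_days = cfg$entrain_days %||% 0L,
                 dd_days = cfg$dd_days %||% 0L,
                 lights_on_clock = lo,
                 reference_start = cfg$reference_start %||% "2020-01-01 00:00")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

minutes_after_midnight <- function(t) {
  as.integer((as.numeric(t) %/% 60) %% 1440)
}

schedule_minutes <- function(schedule) {
  1440L * (schedule$entrain_days + schedule$dd_days)
}

#' Map timestamps to circadian phase
#'
#' Returns `"day"`/`"night"` for timestamps in the LD block and
#' `"subjective_day"`/`"subjective_night"` for timestamps in the DD block,
#' where the subjective photophase extrapolates the LD lights-on time. Phase
#' intervals are half-open `[lights_on, lights_off)`: a boundary timestamp
#' belongs to the phase it begins.
#'
#' @param t `POSIXct` vector of timestamps (minute resolution).
#' @param schedule A `light_schedule`.
#' @return Character vector of phase labels, same length as `t`.
#' @export
phase_of <- function(t, schedule) {
  stopifnot(inherits(schedule, "light_schedule"))
  if (is.character(t))
    t <- as.POSIXct(t, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
  mins <- as.numeric(t) %/% 60 - as.numeric(schedule$reference_start) %/% 60
  total <- schedule_minutes(schedule)
  if (any(mins < 0 | mins >= total))
    stop("timestamp outside the scheduled recording window (",
         format(schedule$reference_start, "%Y-%m-%d %H:%M", tz = "UTC"),
         " + ", total, " min)")
  day_idx <- mins %/% 1440          # 0-based schedule day
  tod <- mins %% 1440
  lit <- ((tod - schedule$lights_on_clock) %% 1440) < schedule$photoperiod
  in_dd <- day_idx >= schedule$entrain_days
  out <- ifelse(in_dd,
                ifelse(lit, "subjective_day", "subjective_night"),
                ifelse(lit, "day", "night"))
  out
}

#' Slice a series into per-day subseries of one phase
#'
#' For each recorded day of the schedule, extracts the bins whose midpoint
#' maps to the requested phase. The four phase slices over all LD and DD days
#' partition the series: concatenating them reconstitutes every bin exactly
#' once.
#'
#' @param series An `activity_series` aligned to `schedule` (its bins must lie
#'   within the schedule window).
#' @param schedule A `light_schedule`.
#' @param phase One of `"day"`, `"night"`, `"subjective_day"`,
#'   `"subjective_night"`.
#' @return A list with one element per schedule day on which the phase occurs;
#'   each element is an integer vector of counts (bin left-edge times as
#'   names). If the phase is incompatible with the regime (e.g. a subjective
#'   phase requested for an LD-only schedule) the result is an empty list with
#'   attribute `incompatible_phase = TRUE`.
#' @export
slice_phase <- function(series, schedule,
                        phase = c("day", "night", "subjective_day",
                                  "subjective_night")) {
  phase <- match.arg(phase)
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "light_schedule"))
  subjective <- phase %in% c("subjective_day", "subjective_night")
  if ((subjective && schedule$dd_days == 0L) ||
      (!subjective && schedule$entrain_days == 0L)) {
    out <- list()
    attr(out, "incompatible_phase") <- TRUE
    return(out)
  }
  mid <- bin_times(series) + 30 * series$bin_width   # bin midpoints
  ph <- phase_of(mid, schedule)
  day_idx <- as.integer((as.numeric(mid) %/% 60 -
                         as.numeric(schedule$reference_start) %/% 60) %/% 1440) + 1L
  keep <- ph == phase
  if (!any(keep)) return(list())
  counts <- series$counts[keep]
  names(counts) <- format(bin_times(series)[keep], "%Y-%m-%d %H:%M", tz = "UTC")
  split(counts, day_idx[keep])
}
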