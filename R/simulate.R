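#' Parameters for a simulated forager
#'
#' Defines the statistical structure of one synthetic subject: an
#' inhomogeneous Poisson count process whose rate is sinusoidally modulated
#' around the clock, gated by a two-state sleep/wake process with
#' phase-dependent sleep-onset hazard and geometrically distributed bout
#' durations. While asleep the count rate is exactly zero, so sleep bouts are
#' recoverable from the counts without error.
#'
#' @param period_hours Endogenous period tau, hours (default 24).
#' @param amplitude Relative modulation depth of the awake count rate, in
#'   `[0, 1]`; 0 gives a homogeneous Poisson process.
#' @param base_rate Expected counts per minute while awake, at zero
#'   modulation.
#' @param acrophase_hours Clock time (hours after midnight of day 1) of peak
#'   activity; default 6, the middle of a photophase with lights-on at
#'   midnight.
#' @param sleep_onset_rate_day,sleep_onset_rate_night Per-minute wake-to-sleep
#'   hazards during the (subjective) day and night.
#' @param mean_bout_min Mean sleep-bout duration, minutes (geometric; the
#'   per-minute wake-up probability is `1/mean_bout_min`).
#' @param n_days_ld,n_days_dd Days of LD entrainment and of constant darkness
#'   to simulate (defaults 5 + 5).
#' @param seed Integer seed making the subject fully reproducible.
#' @return A list of class `forager_params`.
#' @export
forager_params <- function(period_hours = 24, amplitude = 0.8,
                           base_rate = 2, acrophase_hours = 6,
                           sleep_onset_rate_day = 0.004,
                           sleep_onset_rate_night = 0.02,
                           mean_bout_min = 20,
                           n_days_ld = 5, n_days_dd = 5, seed = 1L) {
  if (period_hours <= 0) stop("'period_hours' must be positive")
  if (amplitude < 0 || amplitude > 1) stop("'amplitude' must be in [0, 1]")
  if (base_rate < 0 || sleep_onset_rate_day < 0 || sleep_onset_rate_night < 0)
    stop("rates must be non-negative")
  if (mean_bout_min < 1) stop("'mean_bout_min' must be >= 1")
  if (n_days_ld < 0 || n_days_dd < 0 || n_days_ld + n_days_dd < 1)
    stop("must simulate at least one day")
  structure(
    list(period_hours = period_hours, amplitude = amplitude,
         base_rate = base_rate, acrophase_hours = acrophase_hours,
         sleep_onset_rate_day = sleep_onset_rate_day,
         sleep_onset_rate_night = sleep_onset_rate_night,
         mean_bout_min = mean_bout_min,
         n_days_ld = as.integer(n_days_ld), n_days_dd = as.integer(n_days_dd),
         seed = as.integer(seed)),
    class = "forager_params")
}

#' Treatment presets for the synthetic generator
#'
#' Named parameter sets emulating the direction of the treatment effects seen
#' in neonicotinoid-exposed foragers: relative to `control`, the
#' `imidacloprid_10` preset has reduced rate amplitude, a lower awake base
#' rate and an elevated daytime sleep-onset hazard with unchanged mean bout
#' length (so daytime sleep rises through more episodes, not longer ones);
#' `imidacloprid_1` is intermediate. The numeric values are generator
#' conventions versioned in `inst/extdata/treatment_presets.yaml`, not
#' measurements.
#'
#' @param name One of `"control"`, `"imidacloprid_1"`, `"imidacloprid_10"`.
#' @param ... Overrides passed on to [forager_params()] (e.g. `seed`,
#'   `n_days_dd`).
#' @return A `forager_params` object.
#' @export
treatment_preset <- function(name, ...) {
  path <- system.file("extdata", "treatment_presets.yaml",
                      package = "actirhythm", mustWork = TRUE)
  presets <- yaml::read_yaml(path)
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  args <- utils::modifyList(presets[[name]], list(...))
  do.call(forager_params, args)
}

#' Simulate one forager
#'
#' Generates a per-minute `activity_series` over `n_days_ld + n_days_dd`
#' schedule days (lights on at midnight) together with the ground truth used
#' to validate downstream analyses. Sleep/wake evolves minute-by-minute:
#' an awake subject falls asleep with the phase-appropriate hazard and a
#' sleeping subject wakes with probability `1/mean_bout_min`. Awake minutes
#' draw counts from a zero-truncated Poisson law with rate
#' `base_rate * (1 + amplitude * cos(2*pi*(t - acrophase)/tau))`; sleeping
#' minutes are exactly zero. Truncation makes every awake minute visibly
#' active, so zero-count runs coincide exactly with the simulated sleep
#' state and bout recovery can be validated without error; the mean awake
#' count is `rate / (1 - exp(-rate))`. The same seed always yields the same
#' subject.
#'
#' @param params A `forager_params`.
#' @param subject_id Subject id for the series (default `"sim"`).
#' @param start_time Midnight-aligned start (default `"2020-01-01 00:00"`).
#' @return A list with `series` (the `activity_series`), `truth` (class
#'   `ground_truth`: `sleep_state` per minute, `true_period`,
#'   `true_amplitude`, `params`) and `schedule` (the matching
#'   `light_schedule`).
#' @examples
#' sim <- simulate_forager(forager_params(seed = 42))
#' sim$series
#' @export
simulate_forager <- function(params, subject_id = "sim",
                             start_time = "2020-01-01 00:00") {
  stopifnot(inherits(params, "forager_params"))
  schedule <- light_schedule(params$n_days_ld, params$n_days_dd,
                             lights_on_clock = 0L,
                             reference_start = start_time)
  n_min <- 1440L * (params$n_days_ld + params$n_days_dd)
  t_h <- (seq_len(n_min) - 1L) / 60       # hours since start (midnight)
  rate <- params$base_rate *
    (1 + params$amplitude *
       cos(2 * pi * (t_h - params$acrophase_hours) / params$period_hours))
  lit <- (t_h %% 24) < 12                  # photophase / subjective photophase
  onset <- ifelse(lit, params$sleep_onset_rate_day,
                  params$sleep_onset_rate_night)
  p_wake <- 1 / params$mean_bout_min
  with_seed(params$seed, {
    asleep <- logical(n_min)
    state <- FALSE
    u <- stats::runif(n_min)
    for (i in seq_len(n_min)) {
      state <- if (state) u[i] >= p_wake else u[i] < onset[i]
      asleep[i] <- state
    }
    counts <- integer(n_min)
    awake <- !asleep
    # inverse-CDF draw from the zero-truncated Poisson: u uniform on
    # (P(X=0), 1) so qpois never returns 0 (requires rate > 0)
    rw <- rate[awake]
    if (any(rw <= 0)) stop("awake count rate must be positive everywhere")
    p0 <- exp(-rw)
    counts[awake] <- stats::qpois(p0 + stats::runif(sum(awake)) * (1 - p0), rw)
  })
  series <- activity_series(subject_id, start_time, counts, bin_width = 1L)
  truth <- structure(
    list(sleep_state = asleep, true_period = params$period_hours,
         true_amplitude = params$amplitude, params = params),
    class = "ground_truth")
  list(series = series, truth = truth, schedule = schedule)
}

#' Simulate a cohort of foragers
#'
#' Draws `n` independent subjects from the same parameter set, with
#' per-subject seeds derived deterministically from a master seed, so the
#' whole cohort reproduces exactly under the same call.
#'
#' @param n Number of subjects (>= 1).
#' @param params A `forager_params`, or a preset name understood by
#'   [treatment_preset()].
#' @param seed Master seed for the cohort.
#' @param id_prefix Prefix for subject ids (`"<prefix>01"` ...).
#' @param start_time Passed to [simulate_forager()].
#' @return A list of `n` elements as returned by [simulate_forager()].
#' @export
simulate_cohort <- function(n, params, seed = 1L, id_prefix = "bee",
                            start_time = "2020-01-01 00:00") {
  if (n < 1L) stop("'n' must be >= 1")
  if (is.character(params)) params <- treatment_preset(params)
  stopifnot(inherits(params, "forager_params"))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  ids <- sprintf("%s%02d", id_prefix, seq_len(n))
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- seeds[i]
    simulate_forager(p, subject_id = ids[i], start_time = start_time)
  })
}

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}
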