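#' Analyze one subject end-to-end
#'
#' Runs the full single-subject pipeline: rhythmicity separately on the LD
#' and DD blocks (30-min analysis bins), 1-min sleep scoring on the LD block,
#' and per-phase mean daily activity.
#'
#' @param series A 1-min `activity_series` aligned to `schedule`.
#' @param schedule A `light_schedule`.
#' @param rs_threshold,search_window,analysis_bin_width,max_lag_hours
#'   Rhythmicity settings (see [rhythmicity()]).
#' @param sleep_threshold Sleep-bout threshold in minutes (default 5).
#' @return One-row data.frame of per-subject metrics (RS, classification and
#'   period per regime; mean daily activity per phase; LD sleep totals,
#'   episode counts and mean bout lengths).
#' @export
analyze_subject <- function(series, schedule,
                            rs_threshold = 1.5, search_window = c(18, 30),
                            analysis_bin_width = 30, max_lag_hours = 48,
                            sleep_threshold = 5) {
  stopifnot(inherits(series, "activity_series"),
            inherits(schedule, "light_schedule"))
  n_ld_min <- 1440L * schedule$entrain_days
  n_min <- length(series$counts) * series$bin_width
  res <- list(subject_id = series$subject_id)
  rhy <- function(counts, t0) {
    s <- activity_series(series$subject_id, t0, counts,
                         bin_width = series$bin_width,
                         modality = series$modality)
    # short regime blocks: shrink the max lag to half the data, but never
    # below the top of the peak-search window
    hours <- length(counts) * series$bin_width / 60
    ml <- max(search_window[2], min(max_lag_hours, hours / 2))
    rhythmicity(s, analysis_bin_width = analysis_bin_width,
                max_lag_hours = ml,
                search_window = search_window, rs_threshold = rs_threshold)
  }
  if (schedule$entrain_days > 0L && n_min >= n_ld_min) {
    r <- rhy(series$counts[seq_len(n_ld_min %/% series$bin_width)],
             series$start_time)
    res$rs_ld <- r$rs; res$label_ld <- r$label
    res$period_ld <- r$estimated_period_hours
  } else {
    res$rs_ld <- NA_real_; res$label_ld <- NA_character_
    res$period_ld <- NA_real_
  }
  if (schedule$dd_days > 0L && n_min > n_ld_min) {
    dd_idx <- (n_ld_min %/% series$bin_width + 1L):length(series$counts)
    r <- rhy(series$counts[dd_idx], series$start_time + 60 * n_ld_min)
    res$rs_dd <- r$rs; res$label_dd <- r$label
    res$period_dd <- r$estimated_period_hours
  } else {
    res$rs_dd <- NA_real_; res$label_dd <- NA_character_
    res$period_dd <- NA_real_
  }
  act <- phase_activity(series, schedule)
  res$activity_day <- unname(act["day"])
  res$activity_night <- unname(act["night"])
  res$activity_subj_day <- unname(act["subjective_day"])
  res$activity_subj_night <- unname(act["subjective_night"])
  if (series$bin_width == 1L && schedule$entrain_days > 0L) {
    sl <- summarize_sleep(detect_sleep_bouts(series, sleep_threshold),
                          schedule, regime = "ld")
    res$sleep_day <- sl$total_sleep_day / sl$n_days
    res$sleep_night <- sl$total_sleep_night / sl$n_days
    res$sleep_bouts_day <- sl$bouts_day / sl$n_days
    res$sleep_bouts_night <- sl$bouts_night / sl$n_days
    res$mean_bout_day <- sl$mean_bout_day
    res$mean_bout_night <- sl$mean_bout_night
  } else {
    res[c("sleep_day", "sleep_night", "sleep_bouts_day", "sleep_bouts_night",
          "mean_bout_day", "mean_bout_night")] <- NA_real_
  }
  as.data.frame(res, stringsAsFactors = FALSE)
}

#' Run the full cohort pipeline
#'
#' Orchestrates the whole analysis: simulate or read cohorts, analyze every
#' subject (rhythmicity per regime, sleep, phase activity), compute
#' group-level statistics, and write a results bundle — per-subject results
#' CSV, group summary text, actogram matrix CSVs (one representative subject
#' per group) and a log of parameters, seeds and exclusions. Reruns with the
#' same configuration produce byte-identical CSV output.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Keys:
#' \describe{
#'   \item{groups}{Named list; each entry is either
#'     `list(preset = "<name>", n = <int>)` /
#'     `list(params = <forager_params fields>, n = <int>)` for simulation, or
#'     `list(file = "<path>", dialect = "canonical_csv"|"dam_tsv")` for
#'     recorded data.}
#'   \item{schedule}{For file input: `entrain_days`, `dd_days`,
#'     `lights_on_clock`, `reference_start`. Ignored for simulated groups
#'     (the generator defines its own schedule).}
#'   \item{seed}{Master seed for simulated groups (default 1).}
#'   \item{out_dir}{Output directory (created if missing).}
#'   \item{rs_threshold, search_window, analysis_bin_width, max_lag_hours,
#'     sleep_threshold}{Analysis settings with the usual defaults.}
#' }
#' @param seed Optional override of `config$seed`.
#' @param out_dir Optional override of `config$out_dir`.
#' @return Invisibly, a list with `results` (per-subject data.frame),
#'   `comparisons` (list of `group_comparison`), `arrhythmic` (per-group,
#'   per-regime percentages) and `files` (paths written).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$groups) || !length(config$groups))
    stop("config must define a non-empty 'groups' list")
  seed <- seed %||% config$seed %||% 1L
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop("config must name an 'out_dir'")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opts <- list(
    rs_threshold = config$rs_threshold %||% 1.5,
    search_window = unlist(config$search_window %||% c(18, 30)),
    analysis_bin_width = config$analysis_bin_width %||% 30,
    max_lag_hours = config$max_lag_hours %||% 48,
    sleep_threshold = config$sleep_threshold %||% 5)
  log_lines <- c(
    sprintf("actirhythm %s pipeline run",
            as.character(utils::packageVersion("actirhythm"))),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("rs_threshold: %g; search_window: %g-%g h; analysis bins: %g min",
            opts$rs_threshold, opts$search_window[1], opts$search_window[2],
            opts$analysis_bin_width),
    sprintf("sleep threshold: %g min; max acf lag: %g h",
            opts$sleep_threshold, opts$max_lag_hours))
  results <- list(); actos <- list()
  gnames <- names(config$groups)
  if (is.null(gnames)) stop("groups must be named")
  for (gi in seq_along(config$groups)) {
    g <- config$groups[[gi]]; gname <- gnames[gi]
    if (!is.null(g$file)) {
      if (!file.exists(g$file)) stop("group '", gname, "': input file not found: ", g$file)
      sers <- read_monitor(g$file, dialect = g$dialect %||% "canonical_csv",
                           modality = g$modality %||% "locomotion")
      sc <- config$schedule
      if (is.null(sc)) stop("file input requires a 'schedule' config block")
      schedule <- light_schedule(sc$entrain_days %||% 0L, sc$dd_days %||% 0L,
                                 lights_on_clock = sc$lights_on_clock %||% 0L,
                                 reference_start = sc$reference_start %||%
                                   "2020-01-01 00:00")
      subs <- lapply(sers, function(s) list(series = s, schedule = schedule))
      log_lines <- c(log_lines, sprintf("group %s: %d subjects from %s",
                                        gname, length(subs), g$file))
    } else {
      params <- if (!is.null(g$preset)) treatment_preset(g$preset)
                else do.call(forager_params, g$params)
      n <- g$n %||% 20L
      gseed <- (as.integer(seed) + 7919L * gi) %% .Machine$integer.max
      subs <- simulate_cohort(n, params, seed = gseed,
                              id_prefix = paste0(gname, "_bee"))
      log_lines <- c(log_lines,
                     sprintf("group %s: simulated n = %d (%s), group seed %d",
                             gname, n, g$preset %||% "custom params", gseed))
    }
    rows <- lapply(subs, function(sb)
      cbind(group = gname,
            do.call(analyze_subject, c(list(sb$series, sb$schedule), opts))))
    results[[gname]] <- do.call(rbind, rows)
    actos[[gname]] <- actogram_matrix(subs[[1]]$series)
  }
  results <- do.call(rbind, results)
  rownames(results) <- NULL

  arrhythmic <- list()
  for (regime in c("ld", "dd")) {
    col <- paste0("label_", regime)
    if (all(is.na(results[[col]]))) next
    arrhythmic[[regime]] <- vapply(gnames, function(g) {
      lab <- results[[col]][results$group == g]
      100 * sum(lab == "arrhythmic", na.rm = TRUE) / sum(!is.na(lab))
    }, 1)
  }
  comparisons <- list()
  metric_cols <- c("rs_ld", "rs_dd", "activity_day", "activity_night",
                   "activity_subj_day", "activity_subj_night",
                   "sleep_day", "sleep_night",
                   "sleep_bouts_day", "sleep_bouts_night",
                   "mean_bout_day", "mean_bout_night")
  for (m in metric_cols) {
    vals <- split(results[[m]], results$group)[gnames]
    vals <- lapply(vals, function(v) v[!is.na(v)])
    if (length(vals) < 2L || any(vapply(vals, length, 1L) < 2L)) next
    comparisons[[m]] <- if (length(vals) >= 3L) one_way_anova_tukey(vals)
                        else two_sample_t(vals[[1]], vals[[2]],
                                          labels = names(vals))
  }

  files <- character(0)
  f <- file.path(out_dir, "results.csv")
  export_results_table(results, f); files <- c(files, f)
  for (g in names(actos)) {
    f <- file.path(out_dir, paste0("actogram_", g, ".csv"))
    utils::write.csv(unclass(actos[[g]]), f, row.names = TRUE)
    files <- c(files, f)
  }
  f <- file.path(out_dir, "group_summary.txt")
  con <- file(f, "w")
  for (regime in names(arrhythmic)) {
    writeLines(sprintf("arrhythmic %% (%s): %s", toupper(regime),
                       paste(sprintf("%s = %.1f%%", gnames,
                                     arrhythmic[[regime]][gnames]),
                             collapse = ", ")), con)
  }
  for (m in names(comparisons)) {
    writeLines(paste0("\n== ", m, " =="), con)
    writeLines(utils::capture.output(print(comparisons[[m]])), con)
  }
  close(con); files <- c(files, f)
  f <- file.path(out_dir, "run_log.txt")
  writeLines(log_lines, f); files <- c(files, f)

  invisible(list(results = results, comparisons = comparisons,
                 arrhythmic = arrhythmic, actograms = actos, files = files))
}
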