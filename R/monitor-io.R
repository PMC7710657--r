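#' Read activity data from a monitor file
#'
#' Two dialects are supported. `"canonical_csv"` is a long-format CSV with a
#' mandatory header `subject_id,timestamp,count` (ISO-8601 timestamps at
#' minute resolution). `"dam_tsv"` is a DAM-style tab-separated file, one row
#' per reading: index, date (`"d b y"`, e.g. `1 Jan 20`), time (`HH:MM:SS`),
#' a status column (1 = OK; other rows are skipped), then 32 integer channel
#' columns. Timestamps must advance with a constant step per channel; the
#' step is taken as the bin width.
#'
#' @param path Path to the file.
#' @param dialect `"canonical_csv"` or `"dam_tsv"`.
#' @param channel_map For `dam_tsv`: named character vector mapping channel
#'   columns to subject ids, e.g. `c("3" = "bee07")`. If `NULL`, every
#'   channel with at least one non-zero count is read and named
#'   `"ch<nn>"`.
#' @param modality Modality recorded in the returned series.
#' @return A named list of [activity_series] objects, one per channel/subject.
#' @export
read_monitor <- function(path, dialect = c("canonical_csv", "dam_tsv"),
                         channel_map = NULL,
                         modality = c("locomotion", "foraging_trips")) {
  dialect <- match.arg(dialect)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("monitor file not found: ", path)
  switch(dialect,
         canonical_csv = read_canonical_csv(path, modality),
         dam_tsv = read_dam_tsv(path, channel_map, modality))
}

read_canonical_csv <- function(path, modality) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "timestamp", "count")
  if (!all(need %in% names(df)))
    stop("canonical CSV must have header columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) stop("canonical CSV contains no data rows")
  bad <- which(is.na(suppressWarnings(as.numeric(df$count))) | df$count < 0)
  if (length(bad))
    stop("negative or non-numeric count at line ", bad[1] + 1L,  # +1 header
         " of ", path)
  df$line <- seq_len(nrow(df)) + 1L
  out <- lapply(split(df, df$subject_id), function(d) {
    ts <- as.POSIXct(d$timestamp, tz = "UTC",
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                    "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M"))
    if (anyNA(ts))
      stop("unparseable timestamp at line ", d$line[which(is.na(ts))[1]],
           " of ", path)
    step <- diff(as.numeric(ts)) / 60
    if (length(step)) {
      if (any(step <= 0))
        stop("timestamps not strictly increasing at line ",
             d$line[which(step <= 0)[1] + 1L], " of ", path)
      if (any(step != step[1]))
        stop("inconsistent timestamp step (gap) at line ",
             d$line[which(step != step[1])[1] + 1L], " of ", path)
      bw <- as.integer(step[1])
    } else bw <- 1L
    activity_series(d$subject_id[1], ts[1], as.integer(d$count),
                    bin_width = bw, modality = modality)
  })
  out[order(names(out))]
}

read_dam_tsv <- function(path, channel_map, modality) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 36L)
    stop("DAM-style file must have 36 tab-separated columns (index, date, ",
         "time, status, 32 channels); found ", ncol(df))
  names(df) <- c("index", "date", "time", "status", sprintf("ch%02d", 1:32))
  keep <- df$status == 1L
  if (!any(keep)) stop("no rows with OK status (status == 1) in ", path)
  lines <- which(keep)
  df <- df[keep, , drop = FALSE]
  ts <- parse_dam_datetime(df$date, df$time)
  if (anyNA(ts))
    stop("unparseable date/time at line ", lines[which(is.na(ts))[1]], " of ", path)
  step <- diff(as.numeric(ts)) / 60
  if (length(step) && any(step != step[1]))
    stop("inconsistent timestamp step (gap) at line ",
         lines[which(step != step[1])[1] + 1L], " of ", path)
  bw <- if (length(step)) as.integer(step[1]) else 1L
  chans <- as.matrix(df[, 5:36, drop = FALSE])
  if (any(chans < 0))
    stop("negative count at line ", lines[which(rowSums(chans < 0) > 0)[1]],
         " of ", path)
  if (is.null(channel_map)) {
    active <- which(colSums(chans) > 0)
    channel_map <- stats::setNames(sprintf("ch%02d", active), active)
  }
  idx <- as.integer(names(channel_map))
  out <- lapply(seq_along(idx), function(i)
    activity_series(unname(channel_map[i]), ts[1], chans[, idx[i]],
                    bin_width = bw, modality = modality))
  names(out) <- unname(channel_map)
  out[order(names(out))]
}

# English month abbreviations regardless of locale
parse_dam_datetime <- function(date, time) {
  parts <- strsplit(date, " ", fixed = TRUE)
  ok <- lengths(parts) == 3L
  d <- m <- y <- rep(NA_integer_, length(date))
  d[ok] <- as.integer(vapply(parts[ok], `[`, "", 1L))
  m[ok] <- match(vapply(parts[ok], `[`, "", 2L), month.abb)
  y[ok] <- as.integer(vapply(parts[ok], `[`, "", 3L)) + 2000L
  out <- as.POSIXct(sprintf("%04d-%02d-%02d %s", y, m, d, time),
                    tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  out[!ok] <- NA
  out
}

#' Write activity series to a monitor file
#'
#' The canonical CSV dialect writes one row per subject per bin. The DAM
#' dialect writes one row per bin with the series laid out on consecutive
#' channel columns (unused channels are zero); it requires all series to
#' share `start_time`, length and bin width, as a real monitor would.
#' `read_monitor(write_series(x))` reproduces `x` exactly (counts,
#' timestamps, subject ids) when the returned channel map is passed back.
#'
#' @param series_list Non-empty list of [activity_series] with identical bin
#'   width.
#' @param path Output file path.
#' @param dialect `"canonical_csv"` or `"dam_tsv"`.
#' @return Invisibly, for `dam_tsv` the channel map needed to recover subject
#'   ids on re-reading; for `canonical_csv`, `path`.
#' @export
write_series <- function(series_list, path,
                         dialect = c("canonical_csv", "dam_tsv")) {
  dialect <- match.arg(dialect)
  if (!length(series_list)) stop("cannot write an empty series collection")
  stopifnot(all(vapply(series_list, inherits, TRUE, "activity_series")))
  bw <- vapply(series_list, function(s) s$bin_width, 1L)
  if (length(unique(bw)) != 1L)
    stop("all series must share one bin width; found: ",
         paste(sort(unique(bw)), collapse = ", "))
  if (dialect == "canonical_csv") {
    rows <- do.call(rbind, lapply(series_list, function(s)
      data.frame(subject_id = s$subject_id,
                 timestamp = format(bin_times(s), "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                 count = s$counts, stringsAsFactors = FALSE)))
    utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
    return(invisible(path))
  }
  if (length(series_list) > 32L)
    stop("DAM dialect holds at most 32 channels")
  n <- vapply(series_list, function(s) length(s$counts), 1L)
  st <- vapply(series_list, function(s) as.numeric(s$start_time), 1)
  if (length(unique(n)) != 1L || length(unique(st)) != 1L)
    stop("DAM dialect requires all series to share start_time and length")
  ts <- bin_times(series_list[[1]])
  chans <- matrix(0L, nrow = n[1], ncol = 32L)
  for (i in seq_along(series_list)) chans[, i] <- series_list[[i]]$counts
  df <- data.frame(index = seq_len(n[1]),
                   date = sprintf("%d %s %02d",
                                  as.integer(format(ts, "%d", tz = "UTC")),
                                  month.abb[as.integer(format(ts, "%m", tz = "UTC"))],
                                  as.integer(format(ts, "%Y", tz = "UTC")) %% 100L),
                   time = format(ts, "%H:%M:%S", tz = "UTC"),
                   status = 1L)
  df <- cbind(df, as.data.frame(chans))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(stats::setNames(
    vapply(series_list, function(s) s$subject_id, ""),
    as.character(seq_along(series_list))))
}

#' Export a per-subject results table as CSV
#'
#' Writes one row per subject/condition with a stable column order and fixed
#' numeric precision, so identical inputs yield byte-identical files. Missing
#' metrics are rendered as empty fields, never dropped columns.
#'
#' @param rows A data.frame of per-subject metric records.
#' @param path Output CSV path.
#' @param digits Decimal places used for floating-point columns.
#' @return Invisibly, `path`.
#' @export
export_results_table <- function(rows, path, digits = 4) {
  stopifnot(is.data.frame(rows))
  out <- rows
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf(paste0("%.", digits, "f"), out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    } else {
      v <- as.character(out[[j]])
      v[is.na(v)] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}
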