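#' Construct an activity series
#'
#' An `activity_series` holds one subject's binned activity counts: beam-break
#' counts for an isolated forager in a monitor tube, or foraging-trip events
#' for a forager observed at the colony entrance. Bins are contiguous,
#' non-overlapping and of constant width; the width must divide 1440 min so
#' that day boundaries always fall on bin boundaries.
#'
#' @param subject_id Character scalar identifying the subject.
#' @param start_time `POSIXct` timestamp of the first bin's left edge
#'   (minute resolution; seconds are dropped). A string in
#'   `"YYYY-MM-DD HH:MM"` form (UTC) is accepted.
#' @param counts Vector of non-negative integer counts, one per bin.
#' @param bin_width Bin width in minutes; a positive integer dividing 1440.
#' @param modality `"locomotion"` (beam breaks) or `"foraging_trips"`
#'   (one count per trip event).
#' @return An object of class `activity_series`.
#' @examples
#' s <- activity_series("bee01", "2020-01-01 00:00", rpois(1440, 1))
#' s
#' @export
activity_series <- function(subject_id, start_time, counts, bin_width = 1L,
                            modality = c("locomotion", "foraging_trips")) {
  modality <- match.arg(modality)
  if (!is.character(subject_id) || length(subject_id) != 1L || is.na(subject_id))
    stop("'subject_id' must be a single non-NA string")
  start_time <- as_minute_time(start_time)
  bin_width <- as.integer(bin_width)
  if (length(bin_width) != 1L || is.na(bin_width) || bin_width < 1L)
    stop("'bin_width' must be a positive integer number of minutes")
  if (1440L %% bin_width != 0L)
    stop("'bin_width' (", bin_width, ") must divide 1440 so day boundaries align")
  if (length(counts) < 1L)
    stop("'counts' must contain at least one bin")
  if (anyNA(counts))
    stop("'counts' must not contain NA")
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers")
  structure(
    list(subject_id = subject_id,
         start_time = start_time,
         bin_width = bin_width,
         counts = as.integer(counts),
         modality = modality),
    class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat(sprintf("<activity_series> %s (%s)\n", x$subject_id, x$modality))
  cat(sprintf("  %d bins of %d min from %s (%.2f days)\n",
              length(x$counts), x$bin_width,
              format(x$start_time, "%Y-%m-%d %H:%M", tz = "UTC"),
              length(x$counts) * x$bin_width / 1440))
  cat(sprintf("  total counts: %d; mean/bin: %.3f\n",
              sum(x$counts), mean(x$counts)))
  invisible(x)
}

#' @export
length.activity_series <- function(x) length(x$counts)

#' Bin left-edge timestamps of an activity series
#'
#' @param series An `activity_series`.
#' @return `POSIXct` vector, one timestamp per bin (left edge).
#' @export
bin_times <- function(series) {
  stopifnot(inherits(series, "activity_series"))
  series$start_time + 60 * series$bin_width * (seq_along(series$counts) - 1L)
}

#' Rebin an activity series to a coarser bin width
#'
#' Counts are summed within consecutive groups of bins; the total count is
#' conserved and `start_time` is unchanged. Used to move between the 1-min
#' resolution required by sleep scoring and the 30-min resolution used for
#' rhythmicity analysis.
#'
#' @param series An `activity_series`.
#' @param new_width Target bin width in minutes; a positive multiple of the
#'   current width, and the series length must be an exact multiple of the
#'   ratio (no ragged tail).
#' @return A new `activity_series` at `new_width` minutes.
#' @examples
#' s <- activity_series("bee01", "2020-01-01 00:00", rep(1L, 60))
#' rebin(s, 30)$counts  # two bins of 30
#' @export
rebin <- function(series, new_width) {
  stopifnot(inherits(series, "activity_series"))
  new_width <- as.integer(new_width)
  if (length(new_width) != 1L || is.na(new_width) || new_width < 1L)
    stop("'new_width' must be a positive integer")
  if (new_width %% series$bin_width != 0L)
    stop("'new_width' (", new_width, ") is not a multiple of the current bin width (",
         series$bin_width, ")")
  ratio <- new_width %/% series$bin_width
  if (ratio == 1L) return(series)
  n <- length(series$counts)
  if (n %% ratio != 0L)
    stop("series length (", n, " bins) is not a multiple of the rebin ratio (",
         ratio, "); drop the ragged tail before rebinning")
  grp <- rep(seq_len(n %/% ratio), each = ratio)
  out <- series
  out$counts <- as.integer(rowsum(series$counts, grp))
  out$bin_width <- new_width
  out
}

# Parse/normalise a timestamp to minute resolution POSIXct UTC.
as_minute_time <- function(t) {
  if (is.character(t))
    t <- as.POSIXct(t, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (!inherits(t, "POSIXct"))
    stop("timestamp must be POSIXct or a 'YYYY-MM-DD HH:MM' string")
  if (length(t) != 1L || is.na(t)) stop("timestamp must be a single non-NA time")
  attr(t, "tzone") <- "UTC"
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}
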