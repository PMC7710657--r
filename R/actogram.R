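#' Actogram matrix
#'
#' Builds the day-by-day raster behind actogram plots: one row per recording
#' day, one column per time-of-day bin. With `double_plot = TRUE` each row
#' shows day i concatenated with day i + 1 (the last row padded with NA), the
#' conventional layout for spotting phase drift across days. Rendering is a
#' thin layer over this matrix (see [plot_actogram()]).
#'
#' @param series An `activity_series` spanning at least one full day from its
#'   start; a trailing partial day is dropped with a message.
#' @param bin_width Column bin width in minutes (default 30).
#' @param double_plot Double-plot the days (default TRUE).
#' @return Integer matrix of class `actogram_matrix` with one row per day;
#'   `1440/bin_width` columns (doubled when double-plotted). Row names are
#'   `"day1"` ...; the `bin_width` and `double_plot` attributes record the
#'   layout.
#' @export
actogram_matrix <- function(series, bin_width = 30, double_plot = TRUE) {
  stopifnot(inherits(series, "activity_series"))
  per_day <- 1440L %/% series$bin_width
  d <- length(series$counts) %/% per_day
  if (d < 1L) stop("series must span at least one full day")
  if (length(series$counts) %% per_day != 0L) {
    message("dropping trailing partial day (",
            length(series$counts) %% per_day, " bins)")
    series$counts <- series$counts[seq_len(d * per_day)]
  }
  s <- rebin(series, bin_width)
  nc <- 1440L %/% as.integer(bin_width)
  m <- matrix(s$counts, nrow = d, ncol = nc, byrow = TRUE)
  if (double_plot) {
    nxt <- rbind(m[-1, , drop = FALSE], matrix(NA_integer_, 1L, nc))
    m <- cbind(m, nxt)
  }
  rownames(m) <- paste0("day", seq_len(d))
  structure(m, class = c("actogram_matrix", "matrix"),
            bin_width = as.integer(bin_width), double_plot = double_plot,
            subject_id = series$subject_id)
}

#' Plot an actogram matrix
#'
#' Base-graphics raster of an [actogram_matrix()]: days run top to bottom,
#' time of day left to right, darker cells meaning more counts.
#'
#' @param m An `actogram_matrix`.
#' @param main Plot title (defaults to the subject id).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `m`.
#' @export
plot_actogram <- function(m, main = attr(m, "subject_id"), ...) {
  stopifnot(inherits(m, "actogram_matrix"))
  z <- t(unclass(m))[, rev(seq_len(nrow(m))), drop = FALSE]
  graphics::image(z, col = grDevices::grey.colors(64, start = 1, end = 0),
                  axes = FALSE, main = main, ...)
  graphics::box()
  invisible(m)
}
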