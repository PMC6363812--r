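#' Build a fluorescence histogram
#'
#' Half-open bins `[e_i, e_{i+1})` over the (log-)fluorescence range of the
#' data; the last bin is closed so every in-range event is counted exactly
#' once.
#'
#' @param events An [event_table()].
#' @param n_bins Number of bins (default 512, a typical cytometer
#'   resolution).
#' @param scale `"log"` (default) or `"linear"` binning.
#' @return Object of class `"fl_histogram"`: `bin_edges` (fluorescence
#'   a.u.), `counts`, `scale`.
#' @export
build_histogram <- function(events, n_bins = 512L, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  events <- as_event_table(events)
  if (nrow(events) < 1L) stop_fmt("need at least one event")
  x <- if (scale == "log") log(events$fl3) else events$fl3
  rng <- range(x)
  if (diff(rng) <= 0) rng <- rng + c(-1, 1) * max(abs(rng[1L]) * 1e-6, 1e-6)
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  counts <- tabulate(idx, nbins = n_bins)
  structure(list(
    bin_edges = if (scale == "log") exp(edges) else edges,
    counts = counts,
    scale = scale
  ), class = "fl_histogram")
}

#' @export
print.fl_histogram <- function(x, ...) {
  cat(sprintf("Fluorescence histogram: %d bins (%s scale), %d events, range [%.4g, %.4g] a.u.\n",
              length(x$counts), x$scale, sum(x$counts),
              min(x$bin_edges), max(x$bin_edges)))
  invisible(x)
}

#' @export
plot.fl_histogram <- function(x, ...) {
  mids <- sqrt(x$bin_edges[-1L] * x$bin_edges[-length(x$bin_edges)])
  graphics::plot(mids, x$counts, type = "h", log = if (x$scale == "log") "x" else "",
                 xlab = "PI fluorescence (a.u.)", ylab = "nuclei", ...)
  invisible(x)
}
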