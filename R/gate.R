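#' Gate debris on side scatter
#'
#' Debris (nuclear fragments, cytoplasmic particles) shows up as a heavy
#' right-hand tail in side scatter.  An event is gated out when its side
#' scatter exceeds a robust threshold (Q3 + `gate_k` IQR) *and* its
#' fluorescence lies off every provisional fluorescence peak, so that
#' genuinely granular nuclei sitting on a peak are never removed.  The gate
#' never removes more than `max_gate_fraction` of the events: beyond that
#' the gate is relaxed to the worst offenders and a warning is issued.
#'
#' @param events An [event_table()].
#' @param gate_k IQR multiplier for the side-scatter threshold (default 3).
#' @param max_gate_fraction Hard cap on the gated fraction (default 0.2).
#' @param bw_factor Kernel bandwidth factor for the provisional peak scan.
#' @return List with `events` (retained rows), `gated_fraction` and
#'   `threshold`.
#' @export
gate_debris <- function(events, gate_k = 3, max_gate_fraction = 0.2,
                        bw_factor = 0.5) {
  events <- as_event_table(events)
  n <- nrow(events)
  if (n == 0L) stop_fmt("cannot gate an empty event table")
  ssc <- events$ssc
  q <- unname(quantile(ssc, c(0.25, 0.75)))
  threshold <- q[2L] + gate_k * (q[2L] - q[1L])

  logf <- log(events$fl3)
  peaks <- tryCatch(detect_peaks(events, bw_factor = bw_factor),
                    error = function(e) NULL)
  on_peak <- rep(FALSE, n)
  if (!is.null(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      w <- 3 * max(peaks$sd_log[i], 0.02)
      on_peak <- on_peak | abs(logf - log(peaks$position[i])) <= w
    }
  }
  gated <- ssc > threshold & !on_peak
  if (mean(gated) > max_gate_fraction) {
    allowed <- floor(max_gate_fraction * n)
    idx <- which(gated)
    keep_gated <- idx[order(ssc[idx], decreasing = TRUE)][seq_len(allowed)]
    gated <- rep(FALSE, n)
    gated[keep_gated] <- TRUE
    warning(sprintf(
      "debris gate would remove %.1f%% of events; relaxed to the cap of %.0f%%",
      100 * length(idx) / n, 100 * max_gate_fraction))
  }
  list(events = events[!gated, , drop = FALSE],
       gated_fraction = mean(gated),
       threshold = threshold)
}
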