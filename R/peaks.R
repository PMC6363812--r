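#' Detect fluorescence peaks
#'
#' Peaks are local maxima of a Gaussian-kernel density of log fluorescence
#' (bandwidth: Silverman's rule scaled by `bw_factor`).  Each candidate's
#' prominence is measured against the highest saddle separating it from
#' taller peaks; candidates whose prominence mass (prominence times the
#' half-prominence width, approximately the event mass in the peak) falls
#' below `min_prominence_fraction` of the events are discarded, and of two
#' peaks closer than `min_separation_ratio` in fluorescence only the more
#' massive is kept.  Positions are refined as the mean fluorescence of the
#' events inside the half-prominence window.
#'
#' @param events An [event_table()].
#' @param bw_factor Bandwidth scale on Silverman's rule (default 0.5).
#' @param n_grid Density grid size.
#' @param min_prominence_fraction Minimum prominence mass as a fraction of
#'   all events (default 0.005).
#' @param min_separation_ratio Minimum fluorescence ratio between retained
#'   peaks (default 1.25).
#' @param min_prominence_ratio Minimum prominence as a fraction of the
#'   peak's own density height (default 0.5).  A genuine cluster rises from
#'   near-zero valleys (ratio about 1); low-relief ripples riding on a
#'   continuous plateau stay well below it.
#' @param max_peak_width Maximum half-prominence window width in log
#'   fluorescence (default 0.35).  Genuine clusters are narrow (FWHM about
#'   2.35 times the log-SD, so about 0.2 at a 8\% CV); broad plateaus such
#'   as a continuous polyploid-fragment chain are rejected here and handled
#'   by [detect_polyploid_chain()] instead.
#' @return Data frame sorted by position: `position` (a.u.), `prominence`
#'   (density units), `mass` (event fraction in the half-prominence
#'   window), `sd_log` (robust SD of log fluorescence in the window),
#'   `height`, `lo`, `hi` (window bounds, a.u.).
#' @export
detect_peaks <- function(events, bw_factor = 0.5, n_grid = 512L,
                         min_prominence_fraction = 0.005,
                         min_separation_ratio = 1.25,
                         min_prominence_ratio = 0.5,
                         max_peak_width = 0.35) {
  events <- as_event_table(events)
  n <- nrow(events)
  if (n < 1L) stop_fmt("no peak found: empty event table")
  logf <- log(events$fl3)
  if (sd(logf) < 1e-12) {
    return(data.frame(position = exp(logf[1L]), prominence = Inf, mass = 1,
                      sd_log = 0, height = Inf,
                      lo = exp(logf[1L]), hi = exp(logf[1L])))
  }
  bw <- bw.nrd0(logf) * bw_factor
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3
  d <- density(logf, bw = bw, n = n_grid,
               from = min(logf) - 3 * bw, to = max(logf) + 3 * bw)
  x <- d$x
  y <- d$y
  k <- length(y)
  cand <- which(y[-c(1L, k)] > y[-c(k - 1L, k)] &
                  y[-c(1L, k)] >= y[-c(1L, 2L)]) + 1L
  if (!length(cand)) stop_fmt("no peak found in fluorescence density")

  peak_row <- function(p) {
    side_base <- function(idx_seq) {
      if (!length(idx_seq)) return(y[p])
      m <- y[p]
      for (j in idx_seq) {
        if (y[j] > y[p]) break
        if (y[j] < m) m <- y[j]
      }
      m
    }
    base_l <- side_base(rev(seq_len(p - 1L)))
    base_r <- side_base(seq(p + 1L, k))
    prom <- y[p] - max(base_l, base_r)
    level <- y[p] - prom / 2
    lo <- p
    while (lo > 1L && y[lo - 1L] >= level) lo <- lo - 1L
    hi <- p
    while (hi < k && y[hi + 1L] >= level) hi <- hi + 1L
    sel <- logf >= x[lo] & logf <= x[hi]
    c(prom = prom, prom_mass = prom * (x[hi] - x[lo]),
      mass = mean(sel), lo = x[lo], hi = x[hi],
      pos = if (any(sel)) mean(events$fl3[sel]) else exp(x[p]),
      sd_log = if (sum(sel) > 1L) {
        s <- mad(logf[sel])
        if (s > 0) s else sd(logf[sel])
      } else bw,
      height = y[p])
  }
  rows <- t(vapply(cand, peak_row, numeric(8L)))
  keep <- rows[, "prom_mass"] >= min_prominence_fraction &
    rows[, "prom"] >= min_prominence_ratio * rows[, "height"] &
    (rows[, "hi"] - rows[, "lo"]) <= max_peak_width
  rows <- rows[keep, , drop = FALSE]
  if (!nrow(rows)) stop_fmt("no peak found above the prominence threshold")
  rows <- rows[order(rows[, "pos"]), , drop = FALSE]
  # enforce minimum separation: drop the less massive of close pairs
  repeat {
    if (nrow(rows) < 2L) break
    ratios <- rows[-1L, "pos"] / rows[-nrow(rows), "pos"]
    close <- which(ratios < min_separation_ratio)
    if (!length(close)) break
    i <- close[1L]
    drop_i <- if (rows[i, "prom_mass"] < rows[i + 1L, "prom_mass"]) i else i + 1L
    rows <- rows[-drop_i, , drop = FALSE]
  }
  data.frame(position = rows[, "pos"], prominence = rows[, "prom"],
             mass = rows[, "mass"], sd_log = rows[, "sd_log"],
             height = rows[, "height"], lo = rows[, "lo"],
             hi = rows[, "hi"])
}

#' Assign detected peaks to the ploidy doubling ladder
#'
#' Starting from the most populous peak, the ladder is walked in both
#' directions, accepting each neighbouring peak whose position ratio to the
#' previously accepted peak lies in `ladder_window` (default \[1.6, 2.3\],
#' bracketing observed under-replicated ratios).  The lowest chained peak
#' is anchored as 2Cx, unless `expect_haploid` is set and that lowest peak
#' sits at about half the position of the next (ratio in
#' `haploid_window`) with smaller mass, in which case it is 1Cx.  Peaks
#' outside every window are left unclassified.  If the two most massive
#' peaks have near-equal mass (within 5%) and are not reconciled by the
#' ladder, the anchor is ambiguous and an error names both candidates;
#' analysts resolve such cases with the reference sample.
#'
#' @param peaks A peak table from [detect_peaks()].
#' @param ladder_window Acceptance window for adjacent-position ratios.
#' @param expect_haploid Whether a 1Cx cluster may be present (e.g. male
#'   gonad).
#' @param haploid_window Downward ratio window identifying a 1Cx peak.
#' @return Object of class `"ploidy_ladder"`: `peaks` (accepted, with a
#'   `level` column in Cx units), `unassigned`, `anchor_level`.
#' @export
assign_ploidy <- function(peaks, ladder_window = c(1.6, 2.3),
                          expect_haploid = FALSE,
                          haploid_window = c(1.7, 2.3)) {
  if (is.null(peaks) || nrow(peaks) < 1L) stop_fmt("need at least one peak")
  peaks <- peaks[order(peaks$position), , drop = FALSE]
  np <- nrow(peaks)
  start <- which.max(peaks$mass)
  acc <- start
  cur <- start
  while (cur < np) {
    ratios <- peaks$position[(cur + 1L):np] / peaks$position[cur]
    ok <- which(ratios >= ladder_window[1L] & ratios <= ladder_window[2L])
    if (!length(ok)) break
    nxt <- cur + ok[which.min(abs(log(ratios[ok] / 2)))]
    acc <- c(acc, nxt)
    cur <- nxt
  }
  cur <- start
  while (cur > 1L) {
    ratios <- peaks$position[cur] / peaks$position[1:(cur - 1L)]
    ok <- which(ratios >= ladder_window[1L] & ratios <= ladder_window[2L])
    if (!length(ok)) break
    prv <- ok[which.min(abs(log(ratios[ok] / 2)))]
    acc <- c(acc, prv)
    cur <- prv
  }
  acc <- sort(unique(acc))

  ord <- order(peaks$mass, decreasing = TRUE)
  if (np >= 2L && peaks$mass[ord[2L]] >= 0.95 * peaks$mass[ord[1L]] &&
      !all(ord[1:2] %in% acc))
    stop_fmt("ambiguous 2Cx anchor: peaks at %.4g and %.4g a.u. have near-equal mass",
             peaks$position[ord[1L]], peaks$position[ord[2L]])

  anchor_level <- 2
  if (expect_haploid && length(acc) >= 2L) {
    r <- peaks$position[acc[2L]] / peaks$position[acc[1L]]
    if (r >= haploid_window[1L] && r <= haploid_window[2L] &&
        peaks$mass[acc[1L]] < peaks$mass[acc[2L]])
      anchor_level <- 1
  }
  assigned <- peaks[acc, , drop = FALSE]
  assigned$level <- anchor_level * 2^(seq_along(acc) - 1L)
  structure(list(peaks = assigned,
                 unassigned = peaks[setdiff(seq_len(np), acc), , drop = FALSE],
                 anchor_level = anchor_level),
            class = "ploidy_ladder")
}
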