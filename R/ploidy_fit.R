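#' Per-cluster statistics for an assigned ploidy ladder
#'
#' Attributes every event to the nearest accepted cluster in
#' log-fluorescence, provided it lies within `window_sd` robust SDs of the
#' peak; remaining events are unclassified (this is what keeps continuous
#' chain material out of the cluster means, so the 2Cx mean used for
#' calibration stays uncontaminated).  Cluster fractions are computed over
#' classified events.
#'
#' @param events An [event_table()] (post-gating).
#' @param ladder A `"ploidy_ladder"` from [assign_ploidy()].
#' @param window_sd Attribution window half-width in robust SDs (default 3).
#' @return List with `clusters` (level, mean_fi, sd_fi, sd_log, count,
#'   fraction, cv), `assignment` (per-event cluster index, NA when
#'   unclassified), `n_classified`.
#' @export
cluster_stats <- function(events, ladder, window_sd = 3) {
  events <- as_event_table(events)
  stopifnot(inherits(ladder, "ploidy_ladder"))
  pk <- ladder$peaks
  logf <- log(events$fl3)
  centres <- log(pk$position)
  sds <- pmax(pk$sd_log, 1e-3)
  dist <- abs(outer(logf, centres, "-"))
  nearest <- max.col(-dist, ties.method = "first")
  within <- dist[cbind(seq_along(logf), nearest)] <=
    window_sd * sds[nearest]
  assignment <- ifelse(within, nearest, NA_integer_)
  n_classified <- sum(within)
  clusters <- do.call(rbind, lapply(seq_len(nrow(pk)), function(j) {
    sel <- which(assignment == j)
    fl <- events$fl3[sel]
    m <- if (length(sel)) mean(fl) else NA_real_
    s <- if (length(sel) > 1L) sd(fl) else 0
    data.frame(level = pk$level[j], mean_fi = m, sd_fi = s,
               sd_log = sds[j], count = length(sel),
               fraction = length(sel) / max(n_classified, 1L),
               cv = if (is.na(m) || m <= 0) NA_real_ else 100 * s / m)
  }))
  clusters <- clusters[order(clusters$level), , drop = FALSE]
  rownames(clusters) <- NULL
  list(clusters = clusters, assignment = assignment,
       n_classified = n_classified)
}

#' Detect a continuous polyploid-fragment chain above 8Cx
#'
#' A chain (breakage products of extremely polyploid nuclei, as seen in
#' larval salivary gland) fills the valleys between would-be 16Cx and 32Cx
#' positions.  Detection requires (i) at least 2% of events above the 8Cx
#' cluster and (ii) for two consecutive octaves above 8Cx, the inter-peak
#' valley density never falling below `valley_fraction` of the density at
#' the octave's upper ladder position.  Chain mass is the fraction of
#' events above the 8Cx attribution window that belong to no cluster.
#'
#' @param events Post-gate [event_table()].
#' @param clusters Cluster table from [cluster_stats()].
#' @param assignment Per-event cluster index from [cluster_stats()].
#' @param valley_fraction Valley-to-peak density floor (default 0.2).
#' @param bw_factor Kernel bandwidth factor.
#' @param min_chain_mass Minimum above-8Cx event fraction (default 0.02).
#' @return List with `detected` and `mass`.
#' @export
detect_polyploid_chain <- function(events, clusters, assignment,
                                   valley_fraction = 0.2, bw_factor = 0.5,
                                   min_chain_mass = 0.02) {
  events <- as_event_table(events)
  i8 <- which(clusters$level == 8)
  if (!length(i8) || is.na(clusters$mean_fi[i8]))
    return(list(detected = FALSE, mass = 0))
  c8 <- clusters$mean_fi[i8]
  sd8 <- max(clusters$sd_log[i8], 1e-3)
  logf <- log(events$fl3)
  upper8 <- log(c8) + 3 * sd8
  above <- logf > upper8 & is.na(assignment)
  mass <- mean(above)
  frac_above <- mean(logf > log(c8) + log(1.25))
  if (frac_above < min_chain_mass)
    return(list(detected = FALSE, mass = mass))

  bw <- bw.nrd0(logf) * bw_factor
  if (!is.finite(bw) || bw <= 0) bw <- 1e-3
  d <- density(logf, bw = bw, n = 1024L,
               from = min(logf) - 3 * bw, to = max(logf) + 3 * bw)
  dens_at <- function(lo, hi, f) {
    sel <- d$x >= lo & d$x <= hi
    if (!any(sel)) return(NA_real_)
    f(d$y[sel])
  }
  ok <- logical(2L)
  for (k in 1:2) {
    lo <- log(c8) + (k - 1) * log(2)
    hi <- lo + log(2)
    valley <- dens_at(lo + log(1.25), hi - log(1.25), min)
    peak <- dens_at(hi - log(1.35), hi + log(1.15), max)
    ok[k] <- is.finite(valley) && is.finite(peak) &&
      valley >= valley_fraction * peak
  }
  list(detected = all(ok), mass = mass)
}

#' Fit a ploidy profile to a listmode event table
#'
#' The central estimator: gates debris on side scatter ([gate_debris()]),
#' detects fluorescence peaks ([detect_peaks()]), assigns them to the
#' 2Cx/4Cx/... doubling ladder ([assign_ploidy()]), computes per-cluster
#' statistics ([cluster_stats()]) and checks for a continuous
#' polyploid-fragment chain ([detect_polyploid_chain()]).  It is the
#' computational stand-in for interactive gating in vendor acquisition
#' software: a deterministic, reproducible rule replaces analyst judgement.
#'
#' @param events An [event_table()] (or data.frame with `fl3`, `ssc`).
#' @param expect_haploid Whether a 1Cx cluster may be present.
#' @param gate Apply the side-scatter debris gate first (default TRUE).
#' @param gate_k,max_gate_fraction Debris-gate parameters, see
#'   [gate_debris()].
#' @param bw_factor,min_prominence_fraction,min_separation_ratio Peak
#'   detection parameters, see [detect_peaks()].
#' @param ladder_window Ladder acceptance window, see [assign_ploidy()].
#' @param window_sd Attribution window, see [cluster_stats()].
#' @param valley_fraction Chain-detection valley floor.
#' @param keep_events Store the post-gate events in the fit (needed by
#'   `residuals` and `plot`).
#' @return Object of class `"ploidy_fit"` with components `clusters`
#'   (level, mean_fi, sd_fi, count, fraction, cv), `anchor_level`,
#'   `chain_detected`, `chain_mass`, `gated_fraction`,
#'   `unclassified_fraction`, `n_events`, `peaks`, `ladder` and (optionally)
#'   `events`/`assignment`.
#' @examples
#' tpl <- template_library()$dmel_adult_head
#' fit <- ploidy_fit(generate_sample(tpl, 5000, seed = 1))
#' coef(fit)
#' summary(fit)
#' @export
ploidy_fit <- function(events, expect_haploid = FALSE, gate = TRUE,
                       gate_k = 3, max_gate_fraction = 0.2,
                       bw_factor = 0.5, min_prominence_fraction = 0.005,
                       min_separation_ratio = 1.25,
                       ladder_window = c(1.6, 2.3), window_sd = 3,
                       valley_fraction = 0.2, keep_events = TRUE) {
  cl <- match.call()
  events <- as_event_table(events)
  n_input <- nrow(events)
  if (n_input == 0L) stop_fmt("cannot fit an empty event table")
  gated_fraction <- 0
  if (gate) {
    g <- gate_debris(events, gate_k = gate_k,
                     max_gate_fraction = max_gate_fraction,
                     bw_factor = bw_factor)
    events <- g$events
    gated_fraction <- g$gated_fraction
  }
  peaks <- detect_peaks(events, bw_factor = bw_factor,
                        min_prominence_fraction = min_prominence_fraction,
                        min_separation_ratio = min_separation_ratio)
  ladder <- assign_ploidy(peaks, ladder_window = ladder_window,
                          expect_haploid = expect_haploid)
  cs <- cluster_stats(events, ladder, window_sd = window_sd)
  chain <- detect_polyploid_chain(events, cs$clusters, cs$assignment,
                                  valley_fraction = valley_fraction,
                                  bw_factor = bw_factor)
  structure(list(
    clusters = cs$clusters,
    anchor_level = ladder$anchor_level,
    chain_detected = chain$detected,
    chain_mass = chain$mass,
    gated_fraction = gated_fraction,
    unclassified_fraction = 1 - cs$n_classified / nrow(events),
    n_events = n_input,
    n_gated = n_input - nrow(events),
    n_classified = cs$n_classified,
    peaks = peaks,
    ladder = ladder,
    events = if (keep_events) events else NULL,
    assignment = if (keep_events) cs$assignment else NULL,
    call = cl
  ), class = "ploidy_fit")
}

#' @export
print.ploidy_fit <- function(x, ...) {
  cat(sprintf("Ploidy profile: %d cluster(s), anchor %dCx, %d events\n",
              nrow(x$clusters), x$anchor_level, x$n_events))
  tab <- x$clusters
  tab$mean_fi <- round(tab$mean_fi, 2)
  tab$sd_fi <- round(tab$sd_fi, 2)
  tab$fraction <- round(tab$fraction, 4)
  tab$cv <- round(tab$cv, 2)
  print(tab[, c("level", "mean_fi", "sd_fi", "count", "fraction", "cv")],
        row.names = FALSE)
  cat(sprintf("gated %.2f%% | unclassified %.2f%% | chain %s (mass %.3f)\n",
              100 * x$gated_fraction, 100 * x$unclassified_fraction,
              if (x$chain_detected) "detected" else "absent", x$chain_mass))
  invisible(x)
}

#' @export
summary.ploidy_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ploidy_fit")
}

#' @export
print.summary.ploidy_fit <- function(x, ...) {
  print(x$fit)
  pk <- x$fit$ladder$unassigned
  if (nrow(pk))
    cat(sprintf("unassigned peak(s) at %s a.u.\n",
                paste(signif(pk$position, 4), collapse = ", ")))
  invisible(x)
}

#' @export
coef.ploidy_fit <- function(object, ...) {
  setNames(object$clusters$mean_fi, paste0(object$clusters$level, "Cx"))
}

#' @export
as.data.frame.ploidy_fit <- function(x, ...) {
  x$clusters[, c("level", "mean_fi", "sd_fi", "count", "fraction", "cv")]
}

#' Classify new events against a fitted ploidy profile
#'
#' @param object A `"ploidy_fit"`.
#' @param newdata An [event_table()]; defaults to the fit's stored events.
#' @param ... Unused.
#' @return Factor of cluster labels (`"2Cx"`, ...) with `"unclassified"`.
#' @export
predict.ploidy_fit <- function(object, newdata = NULL, ...) {
  events <- as_event_table(newdata %||% object$events)
  logf <- log(events$fl3)
  centres <- log(object$clusters$mean_fi)
  sds <- pmax(object$clusters$sd_log, 1e-3)
  dist <- abs(outer(logf, centres, "-"))
  nearest <- max.col(-dist, ties.method = "first")
  within <- dist[cbind(seq_along(logf), nearest)] <= 3 * sds[nearest]
  labels <- c(paste0(object$clusters$level, "Cx"), "unclassified")
  factor(ifelse(within, labels[nearest], "unclassified"), levels = labels)
}

#' @export
residuals.ploidy_fit <- function(object, ...) {
  if (is.null(object$events))
    stop_fmt("fit was built with keep_events = FALSE")
  logf <- log(object$events$fl3)
  centres <- log(object$clusters$mean_fi)
  ifelse(is.na(object$assignment), NA_real_,
         logf - centres[object$assignment])
}

#' Simulate events from a fitted ploidy profile
#'
#' Draws from the fitted log-normal mixture (cluster fractions, means and
#' CVs); side scatter is drawn from the empirical post-gate distribution.
#'
#' @param object A `"ploidy_fit"`.
#' @param nsim Number of tables to simulate.
#' @param seed Integer seed.
#' @param n_events Events per table (default: the fitted event count).
#' @param ... Unused.
#' @return A list of [event_table()]s (length `nsim`), or a single table
#'   when `nsim = 1`.
#' @export
simulate.ploidy_fit <- function(object, nsim = 1, seed = 1L,
                                n_events = object$n_events, ...) {
  cl <- object$clusters[object$clusters$count > 0, , drop = FALSE]
  sdlogs <- sqrt(log(1 + (cl$cv / 100)^2))
  ssc_pool <- if (!is.null(object$events)) object$events$ssc else 100
  out <- with_seed(seed, lapply(seq_len(nsim), function(i) {
    comp <- sample(seq_len(nrow(cl)), n_events, replace = TRUE,
                   prob = cl$fraction)
    fl <- exp(rnorm(n_events, log(cl$mean_fi[comp]) - sdlogs[comp]^2 / 2,
                    sdlogs[comp]))
    ssc <- sample(ssc_pool, n_events, replace = TRUE)
    event_table(fl, ssc, paste0(cl$level[comp], "Cx"))
  }))
  if (nsim == 1) out[[1L]] else out
}

#' @export
plot.ploidy_fit <- function(x, breaks = 120, ...) {
  if (is.null(x$events))
    stop_fmt("fit was built with keep_events = FALSE")
  logf <- log10(x$events$fl3)
  h <- graphics::hist(logf, breaks = breaks, plot = FALSE)
  graphics::plot(h, freq = TRUE, xlab = "log10 PI fluorescence (a.u.)",
                 ylab = "nuclei", main = "Ploidy profile", border = NA,
                 col = "grey80", ...)
  at <- log10(x$clusters$mean_fi)
  graphics::abline(v = at, col = "firebrick", lty = 2)
  graphics::mtext(paste0(x$clusters$level, "Cx"), side = 3, at = at,
                  cex = 0.8, col = "firebrick")
  invisible(x)
}
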