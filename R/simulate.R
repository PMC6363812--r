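#' Event tables
#'
#' An event table is the raw unit of analysis: one row per nucleus with the
#' PI fluorescence channel `fl3` (a.u., strictly positive) and the side
#' scatter channel `ssc` (a.u., non-negative).  Synthetic tables carry a
#' `true_label` column naming the generating component (`"2Cx"`, `"4Cx"`,
#' ..., `"debris"`, `"chain"`).
#'
#' @param fl3 Fluorescence values (a.u.).
#' @param ssc Side scatter values (a.u.).
#' @param true_label Optional generating-component labels.
#' @return A `data.frame` of class `"event_table"`.
#' @export
event_table <- function(fl3 = numeric(), ssc = numeric(), true_label = NULL) {
  if (length(fl3) != length(ssc))
    stop_fmt("fl3 and ssc must have equal length")
  if (length(fl3) && (!all(is.finite(fl3)) || any(fl3 <= 0)))
    stop_fmt("fluorescence must be finite and strictly positive")
  if (length(ssc) && (!all(is.finite(ssc)) || any(ssc < 0)))
    stop_fmt("side scatter must be finite and non-negative")
  df <- data.frame(fl3 = as.numeric(fl3), ssc = as.numeric(ssc))
  if (!is.null(true_label)) {
    if (length(true_label) != length(fl3))
      stop_fmt("true_label must match fl3 in length")
    df$true_label <- as.character(true_label)
  }
  class(df) <- c("event_table", "data.frame")
  df
}

as_event_table <- function(x) {
  if (inherits(x, "event_table")) return(x)
  if (!is.data.frame(x) || !all(c("fl3", "ssc") %in% names(x)))
    stop_fmt("expected an event table with fl3 and ssc columns")
  event_table(x$fl3, x$ssc, if ("true_label" %in% names(x)) x$true_label)
}

#' Simulate a listmode cytometry sample from a tissue template
#'
#' Draws `n_events` nuclei component-wise: a multinomial allocation over the
#' template's ploidy classes, debris and chain components, then per-class
#' log-normal fluorescence around the class centre with the template's CV
#' (the class centre is the log-normal median, so CV and centre are exact).
#' Strengthening interference replaces a fraction of each class by a
#' positively shifted contaminant with a heavy right side-scatter tail;
#' weakening shifts a fraction of the classes above 2Cx downward.  Debris is
#' log-uniform below/around the lowest class centre with heavy-tailed
#' scatter; chain events are log-uniform from the 8Cx centre to 1.3 times
#' the 32Cx-equivalent position.  Identical `(template, n_events, seed)`
#' give identical output; the caller's RNG state is untouched.
#'
#' @param template A [tissue_template()].
#' @param n_events Number of events to draw (>= 0).
#' @param seed Integer seed.
#' @return An [event_table()] with `true_label`.
#' @examples
#' tpl <- template_library()$dmel_adult_head
#' ev <- generate_sample(tpl, 1000, seed = 1)
#' table(ev$true_label)
#' @export
generate_sample <- function(template, n_events, seed = 1L) {
  stopifnot(inherits(template, "tissue_template"))
  if (!is.numeric(n_events) || length(n_events) != 1L || is.na(n_events) ||
      n_events < 0)
    stop_fmt("n_events must be a single non-negative number")
  n_events <- as.integer(n_events)
  if (n_events == 0L)
    return(event_table(numeric(), numeric(), character()))

  tpl <- template
  sp <- tpl$scatter_params
  comp_names <- c(paste0(tpl$class_levels, "Cx"), "debris", "chain")
  probs <- c((1 - tpl$debris_fraction - tpl$chain_fraction) *
               tpl$class_proportions,
             tpl$debris_fraction, tpl$chain_fraction)
  sdlog <- sqrt(log(1 + tpl$peak_cv^2))
  c_min <- tpl$class_centres[1L]
  c8 <- if (8 %in% tpl$class_levels)
    unname(tpl$class_centres[match(8, tpl$class_levels)]) else NA_real_

  with_seed(seed, {
    comp <- sample(comp_names, n_events, replace = TRUE, prob = probs)
    fl <- numeric(n_events)
    ssc <- numeric(n_events)
    for (i in seq_along(tpl$class_levels)) {
      idx <- which(comp == comp_names[i])
      ni <- length(idx)
      if (!ni) next
      centre <- unname(tpl$class_centres[i])
      affected <- switch(tpl$interference,
                         none = FALSE,
                         strengthening = TRUE,
                         weakening = tpl$class_levels[i] > 2)
      contam <- if (isTRUE(affected))
        runif(ni) < tpl$interference_weight else rep(FALSE, ni)
      shift <- if (tpl$interference == "weakening")
        1 - tpl$interference_skew else 1 + tpl$interference_skew
      mu <- ifelse(contam, log(centre * shift), log(centre))
      fl[idx] <- exp(rnorm(ni, mu, sdlog))
      s <- exp(rnorm(ni, sp$main_meanlog, sp$main_sdlog))
      if (tpl$interference == "strengthening" && any(contam))
        s[contam] <- exp(rnorm(sum(contam), sp$tail_meanlog, sp$tail_sdlog))
      ssc[idx] <- s
    }
    idx <- which(comp == "debris")
    if (length(idx)) {
      fl[idx] <- exp(runif(length(idx), log(0.1 * c_min), log(1.2 * c_min)))
      ssc[idx] <- exp(rnorm(length(idx), sp$debris_meanlog, sp$debris_sdlog))
    }
    idx <- which(comp == "chain")
    if (length(idx)) {
      fl[idx] <- exp(runif(length(idx), log(c8), log(1.3 * 4 * c8)))
      ssc[idx] <- exp(rnorm(length(idx), sp$main_meanlog, sp$main_sdlog))
    }
    event_table(fl, ssc, comp)
  })
}
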