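# Statistical comparisons used in flow-cytometric genome-size surveys.
# Summary-statistic variants (anova_from_summary, two_sample_t) operate on
# printed means/SEs/ns, recovering the within-group variance as n * se^2.

#' One-sample t-test of an adjacent-cluster ratio against 2.0
#'
#' Full genome doubling at each endocycle predicts adjacent-cluster
#' fluorescence ratios of exactly 2.0; under-replication pushes them below.
#' Given a replicate mean ratio with its SE, this computes the two-sided
#' one-sample Student t-test against the expected ratio (df = n - 1).
#'
#' @param mean_ratio Mean adjacent-cluster ratio across replicates.
#' @param se Standard error of the mean ratio (> 0).
#' @param n Number of replicates (>= 2).
#' @param expected Null ratio (default 2.0).
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' ratio_t_test(1.66, 0.050, 3)  # p ~ 0.021
#' @export
ratio_t_test <- function(mean_ratio, se, n, expected = 2.0) {
  if (!is.finite(se) || se <= 0) stop_fmt("se must be positive")
  if (n < 2L) stop_fmt("need n >= 2")
  t <- (mean_ratio - expected) / se
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), df = n - 1))
}

#' Chi-square comparison of ploidy-class composition
#'
#' Pearson chi-square on the 2 x L table of per-level nucleus counts from
#' two samples.  Level sets are aligned by name (absent levels padded with
#' zero); levels whose expected count falls below 1 are merged into the
#' adjacent higher level before testing.
#'
#' @param counts_a,counts_b Per-level counts, named by level (e.g.
#'   `c("2" = 90, "4" = 10)`); unnamed vectors are aligned positionally.
#' @return List with `chi2`, `df`, `p`, and the pooled `table` tested.
#' @export
composition_chisq <- function(counts_a, counts_b) {
  if (is.null(names(counts_a)) && is.null(names(counts_b))) {
    L <- max(length(counts_a), length(counts_b))
    counts_a <- c(counts_a, rep(0, L - length(counts_a)))
    counts_b <- c(counts_b, rep(0, L - length(counts_b)))
    names(counts_a) <- names(counts_b) <- as.character(seq_len(L))
  } else {
    lev <- sort(suppressWarnings(as.numeric(
      union(names(counts_a), names(counts_b)))))
    if (any(is.na(lev)))
      lev <- union(names(counts_a), names(counts_b))
    lev <- as.character(lev)
    counts_a <- setNames(counts_a[lev], lev)
    counts_b <- setNames(counts_b[lev], lev)
    counts_a[is.na(counts_a)] <- 0
    counts_b[is.na(counts_b)] <- 0
  }
  if (sum(counts_a) == 0 || sum(counts_b) == 0)
    stop_fmt("each sample needs a non-zero total count")
  m <- rbind(a = counts_a, b = counts_b)
  # pooling: merge levels with expected count < 1 into the adjacent higher level
  repeat {
    if (ncol(m) < 2L) stop_fmt("fewer than 2 levels remain after pooling")
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    low <- which(apply(expected < 1, 2L, any))
    if (!length(low)) break
    j <- low[1L]
    tgt <- if (j < ncol(m)) j + 1L else j - 1L
    m[, tgt] <- m[, tgt] + m[, j]
    m <- m[, -j, drop = FALSE]
  }
  res <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(chi2 = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, table = m)
}

#' One-way ANOVA with Fisher's LSD compact letter display
#'
#' Standard one-way ANOVA over per-group replicate values, followed by
#' Fisher's least-significant-difference test: the pairwise threshold is
#' `t(1 - alpha/2, df_within) * sqrt(MSW * (1/n_i + 1/n_j))`, and groups
#' are summarised by shared letters ('a' at the smallest mean) via the
#' insert-and-absorb algorithm.  When every value is identical the F = 0
#' path assigns a single shared letter.
#'
#' @param groups Named list of numeric replicate vectors (>= 2 groups,
#'   each n >= 2).
#' @param alpha LSD significance level (default 0.05).
#' @return Object of class `"anova_lsd"`: `F`, `df_between`, `df_within`,
#'   `p`, `ms_within`, `lsd` (threshold for the first group pair),
#'   `letters`, `means`, `ses`, `ns`, `alpha`.
#' @export
anova_lsd <- function(groups, alpha = 0.05) {
  if (length(groups) < 2L) stop_fmt("need at least 2 groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop_fmt("each group needs at least 2 replicates")
  if (is.null(names(groups)))
    names(groups) <- paste0("group", seq_along(groups))
  means <- vapply(groups, mean, numeric(1))
  vars <- vapply(groups, function(v) stats::var(v), numeric(1))
  anova_core(means, vars, ns, alpha)
}

#' One-way ANOVA reconstructed from summary statistics
#'
#' Exactly reproduces [anova_lsd()] on any raw data realising the supplied
#' group means and SEs: the within-group variance is recovered as
#' `n * se^2`, the within sum of squares is pooled by degrees of freedom
#' and the between sum of squares is taken about the weighted grand mean.
#' This is the tool for re-deriving F statistics and LSD letters from
#' published tables that print only means and SEs.
#'
#' @param means Group means.
#' @param ses Group standard errors of the mean.
#' @param ns Group sizes (>= 2).
#' @param labels Optional group labels.
#' @param alpha LSD significance level.
#' @return An `"anova_lsd"` object, as [anova_lsd()].
#' @export
anova_from_summary <- function(means, ses, ns, labels = NULL, alpha = 0.05) {
  k <- length(means)
  if (length(ses) != k || length(ns) != k)
    stop_fmt("means, ses and ns must have equal length")
  if (any(ns < 2L)) stop_fmt("each group needs n >= 2")
  if (is.null(labels)) labels <- names(means) %||% paste0("group", seq_len(k))
  anova_core(setNames(means, labels), ns * ses^2, ns, alpha)
}

anova_core <- function(means, vars, ns, alpha) {
  k <- length(means)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * vars)
  df_b <- k - 1L
  df_w <- N - k
  msw <- ssw / df_w
  f <- if (ssw == 0 && ssb == 0) 0 else if (ssw == 0) Inf else (ssb / df_b) / msw
  p <- if (is.finite(f)) pf(f, df_b, df_w, lower.tail = FALSE) else 0
  tcrit <- qt(1 - alpha / 2, df_w)
  sig <- matrix(FALSE, k, k)
  if (msw > 0) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      lsd_ij <- tcrit * sqrt(msw * (1 / ns[i] + 1 / ns[j]))
      sig[i, j] <- sig[j, i] <- abs(means[i] - means[j]) >= lsd_ij
    }
  }
  letters <- lsd_letters(means, sig)
  structure(list(
    F = f, df_between = df_b, df_within = df_w, p = p,
    ms_within = msw,
    lsd = tcrit * sqrt(msw * (1 / ns[1L] + 1 / ns[2L])),
    letters = letters, means = means,
    ses = sqrt(vars / ns), ns = ns, alpha = alpha
  ), class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.2f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  tab <- data.frame(group = names(x$means), mean = round(x$means, 4),
                    se = signif(x$ses, 3), n = x$ns,
                    letters = x$letters[names(x$means)])
  print(tab, row.names = FALSE)
  cat(sprintf("Fisher's LSD (first pair, alpha = %.2f): %.4g\n",
              x$alpha, x$lsd))
  invisible(x)
}

#' Pooled two-sample t-test from summary statistics
#'
#' Pooled-variance Student t with df = n1 + n2 - 2; within-group variances
#' are recovered from the SEs as `n * se^2`.  Matches `t.test(...,
#' var.equal = TRUE)` on any raw data realising the summaries.
#'
#' @param mean1,se1,n1 First sample summary.
#' @param mean2,se2,n2 Second sample summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @examples
#' two_sample_t(394, 2.42, 6, 430, 1.78, 5)  # t ~ -11.5, df = 9
#' @export
two_sample_t <- function(mean1, se1, n1, mean2, se2, n2) {
  if (n1 < 2L || n2 < 2L) stop_fmt("need n >= 2 in both samples")
  v1 <- n1 * se1^2
  v2 <- n2 * se2^2
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
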