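#' Estimate a C-value against an internal reference standard
#'
#' Genome size follows directly from the stoichiometry of PI staining: the
#' sample's haploid DNA content equals the ratio of the sample and
#' reference 2Cx peak mean fluorescences times the reference C-value.  The
#' estimate is invariant to joint rescaling of both fluorescence inputs
#' (detector gain) and linear in the reference C-value.
#'
#' @param sample_2cx_mean_fi Mean fluorescence of the sample 2Cx peak (a.u.).
#' @param reference_2cx_mean_fi Mean fluorescence of the reference 2Cx peak.
#' @param reference_c_pg Reference C-value in pg (default 0.18, the
#'   *D. melanogaster* standard).
#' @return Sample C-value in pg.
#' @examples
#' estimate_c_value(223.89, 100)   # ~0.403 pg
#' @export
estimate_c_value <- function(sample_2cx_mean_fi, reference_2cx_mean_fi,
                             reference_c_pg = 0.18) {
  if (any(!is.finite(sample_2cx_mean_fi)) || any(sample_2cx_mean_fi <= 0) ||
      any(!is.finite(reference_2cx_mean_fi)) || any(reference_2cx_mean_fi <= 0) ||
      !is.finite(reference_c_pg) || reference_c_pg <= 0)
    stop_fmt("all fluorescence and C-value inputs must be positive")
  sample_2cx_mean_fi / reference_2cx_mean_fi * reference_c_pg
}

#' Convert picograms of DNA to megabases
#'
#' Uses the standard constant 1 pg = 978 Mb.  Computation stays in full
#' precision; genome sizes are conventionally printed as integer Mb, so
#' round at the presentation layer (e.g. `round(pg_to_mb(0.403))` gives
#' 394).
#'
#' @param pg DNA content in pg (>= 0).
#' @param pg_per_mb Conversion constant (Mb per pg).
#' @return Unrounded Mb.
#' @export
pg_to_mb <- function(pg, pg_per_mb = 978) {
  if (any(!is.finite(pg)) || any(pg < 0)) stop_fmt("pg must be non-negative")
  pg * pg_per_mb
}

#' Aggregate replicate C-values
#'
#' Mean and standard error (sample SD with n-1 denominator over sqrt(n))
#' across replicate C-value estimates, in pg and Mb, plus the range of the
#' per-sample 2Cx peak CVs as a staining-quality summary.
#'
#' @param per_replicate_pg Replicate C-values in pg (length >= 2).
#' @param per_replicate_cv_pct Optional per-replicate 2Cx peak CVs (%).
#' @param pg_per_mb Conversion constant.
#' @param species,tissue Labels carried into the estimate.
#' @return Object of class `"cvalue_estimate"`: `per_replicate_pg`,
#'   `mean_pg`, `se_pg`, `mean_mb`, `se_mb`, `cv_range_pct`, `n`,
#'   `species`, `tissue`.
#' @export
aggregate_replicates <- function(per_replicate_pg, per_replicate_cv_pct = NULL,
                                 pg_per_mb = 978, species = NA_character_,
                                 tissue = NA_character_) {
  n <- length(per_replicate_pg)
  if (n < 2L)
    stop_fmt("need at least 2 replicates (SE undefined for n = %d)", n)
  if (any(!is.finite(per_replicate_pg)) || any(per_replicate_pg <= 0))
    stop_fmt("replicate C-values must be positive")
  mean_pg <- mean(per_replicate_pg)
  se_pg <- sd(per_replicate_pg) / sqrt(n)
  cvr <- if (is.null(per_replicate_cv_pct)) c(NA_real_, NA_real_)
  else range(per_replicate_cv_pct)
  structure(list(
    per_replicate_pg = per_replicate_pg,
    mean_pg = mean_pg, se_pg = se_pg,
    mean_mb = mean_pg * pg_per_mb, se_mb = se_pg * pg_per_mb,
    cv_range_pct = cvr, n = n,
    species = species, tissue = tissue
  ), class = "cvalue_estimate")
}

#' @export
print.cvalue_estimate <- function(x, ...) {
  lab <- paste(stats::na.omit(c(x$species, x$tissue)), collapse = " / ")
  if (nzchar(lab)) cat(lab, "\n")
  cat(sprintf("  n = %d replicates\n", x$n))
  cat(sprintf("  C-value: %.3f pg (SE %.5f pg)\n", x$mean_pg, x$se_pg))
  cat(sprintf("  Genome size: %d Mb (SE %.2f Mb)\n",
              round(x$mean_mb), x$se_mb))
  if (all(is.finite(x$cv_range_pct)))
    cat(sprintf("  2Cx peak CV range: %.2f-%.2f%%\n",
                x$cv_range_pct[1L], x$cv_range_pct[2L]))
  invisible(x)
}

# 2Cx mean fluorescence of a fitted profile (calibration quantity).
fit_2cx_mean <- function(fit) {
  i <- which(fit$clusters$level == 2)
  if (!length(i)) stop_fmt("fitted profile has no 2Cx cluster")
  fit$clusters$mean_fi[i]
}
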