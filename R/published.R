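# Bundled summary tables from the Helicoverpa endopolyploidy and
# genome-size survey that this package's statistical reconstructions
# operate on.  Raw per-nucleus data were never published; these printed
# means/SEs/ns are therefore the inputs to the summary-statistic tests.

#' Adjacent-cluster fluorescence ratio summaries
#'
#' Mean, SE and published two-sided p-value (vs the expected 2.0) of the
#' adjacent-cluster fluorescence ratios for the *D. melanogaster* adult
#' head reference and six *H. armigera* larval tissues, three replicates
#' each.
#'
#' @return Data frame: `sample`, `step` (e.g. `"4Cx/2Cx"`), `n`, `ratio`,
#'   `se`, `p_published`.
#' @export
helicoverpa_ratio_summary <- function() {
  rows <- list(
    c("dmel_adult_head", "4Cx/2Cx", 1.94, 0.019, 0.088),
    c("dmel_adult_head", "8Cx/4Cx", 1.66, 0.050, 0.021),
    c("harm_head", "4Cx/2Cx", 1.94, 0.015, 0.048),
    c("harm_head", "8Cx/4Cx", 1.93, 0.012, 0.026),
    c("harm_head", "16Cx/8Cx", 1.85, 0.012, 0.006),
    c("harm_head", "32Cx/16Cx", 1.79, 0.005, 0),
    c("harm_hemolymph", "4Cx/2Cx", 1.99, 0.009, 0.268),
    c("harm_hemolymph", "8Cx/4Cx", 1.91, 0.014, 0.025),
    c("harm_salivary_gland", "4Cx/2Cx", 1.81, 0.016, 0.007),
    c("harm_salivary_gland", "8Cx/4Cx", 1.94, 0.018, 0.080),
    c("harm_male_gonad", "2Cx/1Cx", 2.17, 0.069, 0.127),
    c("harm_male_gonad", "4Cx/2Cx", 1.89, 0.038, 0.104),
    c("harm_male_gonad", "8Cx/4Cx", 1.78, 0.043, 0.037),
    c("harm_midgut", "4Cx/2Cx", 1.95, 0.005, 0.008),
    c("harm_midgut", "8Cx/4Cx", 1.84, 0.013, 0.007),
    c("harm_midgut", "16Cx/8Cx", 1.85, 0.023, 0.022),
    c("harm_midgut", "32Cx/16Cx", 1.71, 0.006, 0),
    c("harm_malpighian_tubules", "4Cx/2Cx", 1.82, 0.031, 0.029),
    c("harm_malpighian_tubules", "8Cx/4Cx", 1.93, 0.058, 0.329))
  data.frame(sample = vapply(rows, `[`, character(1), 1L),
             step = vapply(rows, `[`, character(1), 2L),
             n = 3L,
             ratio = as.numeric(vapply(rows, `[`, character(1), 3L)),
             se = as.numeric(vapply(rows, `[`, character(1), 4L)),
             p_published = as.numeric(vapply(rows, `[`, character(1), 5L)))
}

#' Per-tissue C-value summaries for *H. armigera*
#'
#' Mean C-value (pg), SE, 2Cx-peak CV range and published LSD letter for
#' the six larval tissues, three replicates each.
#'
#' @return Data frame: `tissue`, `n`, `c_value_pg`, `se_pg`, `cv_lo`,
#'   `cv_hi`, `letter_published`.
#' @export
helicoverpa_tissue_summary <- function() {
  data.frame(
    tissue = c("head", "hemolymph", "salivary_gland", "male_gonad",
               "midgut", "malpighian_tubules"),
    n = 3L,
    c_value_pg = c(0.402, 0.381, 0.415, 0.465, 0.451, 0.469),
    se_pg = c(0.00187, 0.00225, 0.00129, 0.0239, 0.0149, 0.0401),
    cv_lo = c(3.69, 3.23, 6.22, 7.5, 6.31, 4.93),
    cv_hi = c(6.44, 6.17, 8.87, 10.2, 7.68, 9.20),
    letter_published = c("ab", "a", "abc", "c", "bc", "c"))
}

#' Species genome-size summaries
#'
#' Larval-head genome sizes of *H. armigera* and *H. assulta*: C-value
#' (pg), genome size (Mb, at 978 Mb/pg), SE (Mb) and 2Cx-peak CV range.
#'
#' @return Data frame: `species`, `n`, `c_value_pg`, `genome_mb`, `se_mb`,
#'   `cv_lo`, `cv_hi`.
#' @export
helicoverpa_genome_summary <- function() {
  data.frame(
    species = c("H_armigera", "H_assulta"),
    n = c(6L, 5L),
    c_value_pg = c(0.403, 0.440),
    genome_mb = c(394, 430),
    se_mb = c(2.42, 1.78),
    cv_lo = c(3.69, 2.69),
    cv_hi = c(6.73, 5.68))
}
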