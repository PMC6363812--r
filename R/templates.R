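#' Construct a tissue template for the synthetic event generator
#'
#' A tissue template holds the generative parameters of one tissue phenotype:
#' its endopolyploidy ladder (which Cx classes are present and in what
#' proportions), the fluorescence of the 2Cx class centre, the per-doubling
#' under-replication factors, peak dispersion, debris and polyploid-fragment
#' ("chain") loads, and optional fluorescence interference.
#'
#' Class centres follow the doubling ladder: the centre of the 2Cx class is
#' `base_2cx_intensity`, and each step up the ladder multiplies the centre by
#' the corresponding `under_replication` factor (expected at or below the
#' ideal 2.0; full doubling would give exactly 2).  A 1Cx class, when
#' present, sits at `base_2cx_intensity` divided by its step factor.
#'
#' @param name Template label.
#' @param class_levels Ordered ploidy multipliers in Cx units, each level
#'   double the previous (e.g. `c(2, 4, 8)`; may start at 1).  Level 2 must
#'   be present.
#' @param class_proportions Simplex weights over `class_levels` (sum to 1).
#' @param base_2cx_intensity Fluorescence (a.u.) of the 2Cx class centre.
#' @param under_replication Per-step centre ratios, one per adjacent pair of
#'   levels (e.g. the 4Cx/2Cx and 8Cx/4Cx ratios).  Dimensionless.
#' @param peak_cv Within-class coefficient of variation of fluorescence
#'   (fraction, e.g. 0.05).
#' @param debris_fraction Fraction of events drawn from a debris component
#'   (broad sub-2Cx fluorescence, heavy right side-scatter tail).
#' @param interference `"none"`, `"strengthening"` (positive-skew
#'   contamination of the peaks plus a heavy right side-scatter tail) or
#'   `"weakening"` (downward shift of the peaks above 2Cx, left skew).
#' @param interference_skew Relative centre shift of the contaminant
#'   component (fraction of the class centre).
#' @param interference_weight Mixing weight of the contaminant within each
#'   affected class.
#' @param chain_fraction Fraction of events drawn from a continuous
#'   polyploid-fragment chain, log-uniform from the 8Cx centre to 1.3 times
#'   the 32Cx-equivalent position.  Requires level 8 in `class_levels`.
#' @param scatter_params Location/scale (meanlog/sdlog) of side scatter for
#'   the main, debris and strengthening-tail components.
#'
#' @return An object of class `"tissue_template"`.
#' @seealso [template_library()], [generate_sample()]
#' @export
tissue_template <- function(name, class_levels, class_proportions,
                            base_2cx_intensity, under_replication,
                            peak_cv = 0.05, debris_fraction = 0,
                            interference = c("none", "strengthening", "weakening"),
                            interference_skew = 0.15,
                            interference_weight = 0.2,
                            chain_fraction = 0,
                            scatter_params = list()) {
  interference <- match.arg(interference)
  sp <- utils::modifyList(list(
    main_meanlog = log(100), main_sdlog = 0.3,
    debris_meanlog = log(1000), debris_sdlog = 0.8,
    tail_meanlog = log(400), tail_sdlog = 0.6), scatter_params)

  if (!is.numeric(class_levels) || length(class_levels) < 1L)
    stop_fmt("class_levels must be a non-empty numeric vector")
  if (is.unsorted(class_levels, strictly = TRUE))
    stop_fmt("class_levels must be strictly increasing")
  if (!all(abs(diff(log2(class_levels)) - 1) < 1e-9))
    stop_fmt("class_levels must double at each step")
  if (!(2 %in% class_levels))
    stop_fmt("class_levels must contain the 2Cx level")
  if (length(class_proportions) != length(class_levels))
    stop_fmt("class_proportions must match class_levels in length")
  if (any(class_proportions < 0) || abs(sum(class_proportions) - 1) > 1e-9)
    stop_fmt("class_proportions must be non-negative and sum to 1")
  if (!is.numeric(base_2cx_intensity) || base_2cx_intensity <= 0)
    stop_fmt("base_2cx_intensity must be positive")
  if (length(under_replication) != max(length(class_levels) - 1L, 0L))
    stop_fmt("under_replication needs one factor per adjacent level pair")
  if (length(under_replication) && any(under_replication <= 1))
    stop_fmt("under_replication factors must exceed 1")
  if (peak_cv <= 0) stop_fmt("peak_cv must be positive")
  if (debris_fraction < 0 || chain_fraction < 0 ||
      debris_fraction + chain_fraction > 1)
    stop_fmt("debris_fraction + chain_fraction must lie in [0, 1]")
  if (chain_fraction > 0 && !(8 %in% class_levels))
    stop_fmt("a chain component requires an 8Cx level")

  centres <- ladder_centres(class_levels, base_2cx_intensity, under_replication)

  structure(list(
    name = name,
    class_levels = as.numeric(class_levels),
    class_proportions = as.numeric(class_proportions),
    base_2cx_intensity = as.numeric(base_2cx_intensity),
    under_replication = as.numeric(under_replication),
    peak_cv = peak_cv,
    debris_fraction = debris_fraction,
    interference = interference,
    interference_skew = interference_skew,
    interference_weight = interference_weight,
    chain_fraction = chain_fraction,
    scatter_params = sp,
    class_centres = centres
  ), class = "tissue_template")
}

# Class centres from the 2Cx base and the per-step ratio factors.
ladder_centres <- function(class_levels, base, under_replication) {
  i2 <- match(2, class_levels)
  k <- length(class_levels)
  centres <- numeric(k)
  centres[i2] <- base
  if (i2 < k) for (i in seq(i2 + 1L, k))
    centres[i] <- centres[i - 1L] * under_replication[i - 1L]
  if (i2 > 1L) for (i in seq(i2 - 1L, 1L))
    centres[i] <- centres[i + 1L] / under_replication[i]
  stopifnot(!is.unsorted(centres, strictly = TRUE))
  setNames(centres, paste0(class_levels, "Cx"))
}

#' @export
print.tissue_template <- function(x, ...) {
  cat(sprintf("Tissue template '%s'\n", x$name))
  tab <- data.frame(level = paste0(x$class_levels, "Cx"),
                    proportion = x$class_proportions,
                    centre_au = round(unname(x$class_centres), 2))
  print(tab, row.names = FALSE)
  cat(sprintf("peak CV %.3f | debris %.2f | chain %.2f | interference %s\n",
              x$peak_cv, x$debris_fraction, x$chain_fraction, x$interference))
  invisible(x)
}

#' Built-in library of tissue templates
#'
#' Eight templates covering the adult-head internal reference of
#' *Drosophila melanogaster* (0.18 pg; three classes at 88.8/8.3/2.8%),
#' six larval tissues of *Helicoverpa armigera* and the larval head of
#' *H. assulta*.  Class proportions follow the published composition of each
#' tissue where a figure is available (2Cx shares of 43.2% for head, 54.9%
#' for salivary gland and 43.0% for Malpighian tubules; a 61.4% 4Cx mode
#' with 16.2% at 8Cx for male gonad; a 37.9% 16Cx mode dropping to 4.2% at
#' 32Cx for midgut; an upward 2Cx-to-8Cx trend for hemolymph), and the
#' remaining classes are filled to preserve those trends.  Under-replication
#' factors are the published adjacent-cluster fluorescence ratios.  Base 2Cx
#' intensities place each tissue at its measured C-value relative to the
#' reference at 100 a.u.; peak CVs sit mid-way through each tissue's
#' published CV range.  The salivary gland carries a 15% polyploid-fragment
#' chain; tissues with reported fluorescence-strengthening debris
#' (salivary gland, male gonad, midgut, Malpighian tubules) default to
#' strengthening interference and hemolymph to weakening.
#'
#' @return Named list of [tissue_template()] objects:
#'   `dmel_adult_head`, `harm_head`, `harm_hemolymph`, `harm_salivary_gland`,
#'   `harm_male_gonad`, `harm_midgut`, `harm_malpighian_tubules`, `hass_head`.
#' @export
template_library <- function() {
  ref_base <- 100
  base_for <- function(pg) ref_base * pg / 0.18
  lib <- list(
    dmel_adult_head = tissue_template(
      "dmel_adult_head",
      class_levels = c(2, 4, 8),
      class_proportions = c(0.888, 0.083, 0.028) / 0.999,
      base_2cx_intensity = ref_base,
      under_replication = c(1.94, 1.66),
      peak_cv = 0.04, debris_fraction = 0.02),
    harm_head = tissue_template(
      "harm_head",
      class_levels = c(2, 4, 8, 16, 32),
      class_proportions = c(0.432, 0.280, 0.170, 0.080, 0.038),
      base_2cx_intensity = base_for(0.403),
      under_replication = c(1.94, 1.93, 1.85, 1.79),
      peak_cv = 0.05, debris_fraction = 0.03),
    harm_hemolymph = tissue_template(
      "harm_hemolymph",
      class_levels = c(2, 4, 8),
      class_proportions = c(0.20, 0.33, 0.47),
      base_2cx_intensity = base_for(0.381),
      under_replication = c(1.99, 1.91),
      peak_cv = 0.045, debris_fraction = 0.02,
      interference = "weakening"),
    harm_salivary_gland = tissue_template(
      "harm_salivary_gland",
      class_levels = c(2, 4, 8),
      class_proportions = c(0.549, 0.280, 0.171),
      base_2cx_intensity = base_for(0.415),
      under_replication = c(1.81, 1.94),
      peak_cv = 0.07, debris_fraction = 0.03,
      chain_fraction = 0.15,
      interference = "strengthening"),
    harm_male_gonad = tissue_template(
      "harm_male_gonad",
      class_levels = c(1, 2, 4, 8),
      class_proportions = c(0.030, 0.194, 0.614, 0.162),
      base_2cx_intensity = base_for(0.465),
      under_replication = c(2.17, 1.89, 1.78),
      peak_cv = 0.08, debris_fraction = 0.05,
      interference = "strengthening"),
    harm_midgut = tissue_template(
      "harm_midgut",
      class_levels = c(2, 4, 8, 16, 32),
      class_proportions = c(0.120, 0.180, 0.279, 0.379, 0.042),
      base_2cx_intensity = base_for(0.451),
      under_replication = c(1.95, 1.84, 1.85, 1.71),
      peak_cv = 0.06, debris_fraction = 0.05,
      interference = "strengthening"),
    harm_malpighian_tubules = tissue_template(
      "harm_malpighian_tubules",
      class_levels = c(2, 4, 8),
      class_proportions = c(0.43, 0.31, 0.26),
      base_2cx_intensity = base_for(0.469),
      under_replication = c(1.82, 1.93),
      peak_cv = 0.06, debris_fraction = 0.04,
      interference = "strengthening"),
    hass_head = tissue_template(
      "hass_head",
      class_levels = c(2, 4, 8, 16, 32),
      class_proportions = c(0.450, 0.270, 0.170, 0.075, 0.035),
      base_2cx_intensity = base_for(0.440),
      under_replication = c(1.94, 1.93, 1.85, 1.79),
      peak_cv = 0.042, debris_fraction = 0.02)
  )
  lib
}

#' Drop interference and optional components from a template
#'
#' Convenience for clean-recovery experiments: returns a copy of the
#' template with `interference = "none"`; debris and chain loads are kept
#' unless also zeroed.
#'
#' @param template A [tissue_template()].
#' @param drop_debris,drop_chain Also zero the debris / chain fraction.
#' @return A `"tissue_template"`.
#' @export
template_without_interference <- function(template, drop_debris = FALSE,
                                          drop_chain = FALSE) {
  stopifnot(inherits(template, "tissue_template"))
  tissue_template(
    name = template$name,
    class_levels = template$class_levels,
    class_proportions = template$class_proportions,
    base_2cx_intensity = template$base_2cx_intensity,
    under_replication = template$under_replication,
    peak_cv = template$peak_cv,
    debris_fraction = if (drop_debris) 0 else template$debris_fraction,
    interference = "none",
    chain_fraction = if (drop_chain) 0 else template$chain_fraction,
    scatter_params = template$scatter_params)
}
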