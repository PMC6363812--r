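---
title: "Genome size and endopolyploidy from flow cytometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome size and endopolyploidy from flow cytometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowploidy)
```

## The measurement model

Propidium iodide (PI) intercalates DNA stoichiometrically, so the
fluorescence of a stained nucleus is proportional to its DNA content up to
an instrument gain.  A tissue that endoreduplicates therefore produces a
*ladder* of fluorescence clusters at the 2Cx, 4Cx, 8Cx, ... DNA levels
(Cx = the basic genome copy unit; male germ cells add a 1Cx rung).  Two
facts shape everything this package does:

* **Gain is arbitrary.**  Absolute fluorescence means nothing; only ratios
  do.  Genome size is obtained by co-analysing an internal reference
  standard of known C-value and forming

  $$\hat C_\text{sample} \;=\;
    \frac{\bar F_{2Cx,\text{sample}}}{\bar F_{2Cx,\text{ref}}}
    \times C_\text{ref},$$

  with $C_\text{ref} = 0.18$ pg for the *Drosophila melanogaster*
  adult-head standard, and $1\,\mathrm{pg} = 978$ Mb for unit conversion
  (`estimate_c_value()`, `pg_to_mb()`).  The estimator is homogeneous of
  degree 0 in joint rescaling of the two fluorescence means and of degree
  1 in $C_\text{ref}$.

* **Endocycles under-replicate.**  Each endoreduplication round would
  double fluorescence exactly if the whole genome were copied; in practice
  heterochromatic fractions are skipped, so adjacent-cluster ratios fall
  at or below 2.0 (observed range here roughly 1.66–2.17).  The package
  treats these per-step ratios as first-class parameters
  (`under_replication` in templates; `ratio_t_test()` for inference).

Within a cluster, fluorescence noise is multiplicative (staining,
focusing, optics), so clusters are modelled log-normal.  We parameterise
by the class *centre* (the log-normal median) and the coefficient of
variation: `sdlog = sqrt(log(1 + cv^2))` and `meanlog = log(centre)`.
With this convention the configured centre and CV are exact moments, which
is what makes closed-form oracle tests possible.

## What the synthetic generator emulates — and what it does not

`generate_sample()` draws events component-wise: a multinomial allocation
over the ploidy classes plus optional debris and chain components, then
per-class log-normal fluorescence.  The eight bundled templates
(`template_library()`) encode the study conditions:

* class proportions follow the published composition of each tissue
  (e.g. 88.8/8.3/2.8% for the reference head; the 61.4% 4Cx mode of male
  gonad; the 37.9% 16Cx mode of midgut dropping to 4.2% at 32Cx); where a
  tissue's full composition was not printed, the remaining classes fill
  in the published trend;
* under-replication factors are the published adjacent-cluster ratios;
* base 2Cx intensities place every tissue at its measured C-value with the
  reference at 100 a.u., so end-to-end calibration has a known truth;
* per-class CVs sit mid-way through each tissue's published CV range;
* per-sample size defaults to 20,000 events — the published work does not
  state per-sample event counts, and 10–20k nuclei is routine for insect
  tissue preparations;
* debris (2–5% by tissue) has broad sub-2Cx fluorescence and a
  heavy-tailed side-scatter distribution, producing the right-hand
  scatter tails typical of granular preparations;
* *strengthening* interference (salivary gland, male gonad, midgut,
  Malpighian tubules) mixes a positively shifted contaminant (weight 0.2,
  shift +15%) into each peak with a heavy scatter tail — the
  right-skewed/shouldered peaks of debris-rich tissues; *weakening*
  (hemolymph) shifts a contaminant of the above-2Cx peaks downward;
* salivary gland carries a 15% *chain*: fragments of extremely polyploid
  nuclei spread log-uniformly from the 8Cx centre to 1.3 times the
  32Cx-equivalent position.  Log-uniform is the least-informative choice
  for a positive quantity known only to span "8Cx to beyond 32Cx".

Not emulated: instrument optics (spectral overlap, compensation), cell
cycle substructure (S-phase bridges between G1 and G2), doublets/pulse
shape, and day effects in staining.  Passing recovery tests on this
generator therefore demonstrates that the *deconvolution and calibration
logic* is correct under the assumed mixture model — not that real
instrument data are free of those artefacts.

All randomness flows from one explicit seed through `with_seed()`; the
same `(template, n, seed)` is bit-identical and the caller's RNG stream is
untouched.

## Deconvolution: replacing interactive gating with a rule

Vendor software leaves gating to the analyst.  `ploidy_fit()` replaces
that judgement with a deterministic sequence, each step exposed and
testable on its own:

1. **Debris gate** (`gate_debris()`): remove events whose side scatter
   exceeds Q3 + 3·IQR *and* whose fluorescence lies off every provisional
   peak.  The conjunction protects genuinely granular nuclei sitting on a
   peak.  The gate never removes more than 20% of events; past that it is
   relaxed to the worst offenders with a warning.  Whether published 2Cx
   means were computed before or after such exclusion is not stated
   anywhere we could check, so both the multiplier and the cap are
   parameters, not constants.
2. **Peak detection** (`detect_peaks()`): Gaussian-kernel density of log
   fluorescence, bandwidth = Silverman's rule × 0.5 (half-Silverman,
   because the mixture is strongly multimodal and full Silverman
   oversmooths minor rungs).  Local maxima are filtered three ways: the
   *prominence mass* (prominence × half-prominence width, approximately
   the event mass in the peak) must exceed 0.5% of events; the prominence
   must be at least half the peak's own height (genuine clusters rise
   from near-zero valleys, ratio ≈ 1, while ripples riding a continuous
   chain plateau stay below ≈ 0.3); and the half-prominence window must be
   narrower than 0.35 log units (a cluster at 8% CV has FWHM ≈ 0.19).
   Positions are refined as the mean fluorescence of events in the
   half-prominence window.
3. **Ladder assignment** (`assign_ploidy()`): starting from the most
   populous peak, the ladder is walked in *both* directions, accepting
   neighbours whose position ratio lies in [1.6, 2.3] (bracketing all
   observed under-replicated ratios with margin).  The lowest chained peak
   is anchored as 2Cx.  Anchoring the most populous peak itself would
   misidentify tissues whose composition rises with ploidy — hemolymph
   peaks at 8Cx and male gonad at 4Cx — which is why the anchor is the
   ladder's foot, not its mode.  With `expect_haploid`, a lowest peak at
   roughly half the next position ([1.7, 2.3]) and smaller mass is called
   1Cx.  Two near-equal-mass anchor candidates (within 5%) that the
   ladder cannot reconcile raise an error rather than a guess: flow
   analysts resolve that situation with the reference sample.
4. **Cluster statistics** (`cluster_stats()`): events join the nearest
   cluster in log fluorescence if within 3 robust SDs of its peak;
   everything else is unclassified.  Fractions are reported over
   classified events (so they are comparable to class proportions of the
   discrete mixture), and counts conserve exactly:
   classified + unclassified = post-gate events, gated + post-gate =
   input events.
5. **Chain detection** (`detect_polyploid_chain()`): a chain is declared
   when at least 2% of events lie above the 8Cx cluster and, across two
   consecutive octaves above 8Cx, the inter-peak valley density never
   falls below 20% of the density at the octave's upper ladder position.
   Discrete 16Cx/32Cx clusters produce near-zero valleys and fail the
   floor; a continuous chain keeps valley ≈ peak.  Chain events are
   excluded from every cluster, keeping the 2Cx calibration mean
   uncontaminated.

### Numerical choices and degenerate inputs

Half-open attribution and histogram bins `[lo, hi)` with the last bin
closed; log-space attribution (multiplicative noise); ties in
nearest-cluster distance break to the lower cluster; a zero-variance
event set short-circuits to a single exact peak; an empty table, a
featureless (flat) density and a missing reference are explicit errors,
not silent results.  Default histogram resolution is 512 bins over the
log range, mirroring typical cytometer resolution.

## Statistical reconstructions from printed summaries

Raw per-nucleus and per-replicate data for the original survey were never
deposited, so the package includes summary-statistic variants that operate
on printed tables (bundled as `helicoverpa_ratio_summary()`,
`helicoverpa_tissue_summary()`, `helicoverpa_genome_summary()`):

* `ratio_t_test(mean, se, n)` — two-sided one-sample t vs 2.0 with
  df = n − 1.  Two-sided is not a guess: the printed p = 0.021 for ratio
  1.66, SE 0.050, n = 3 equals the two-sided df = 2 value exactly
  (closed form: $p = 1 - |t|/\sqrt{2 + t^2}$).
* `anova_from_summary(means, ses, ns)` — recovers within-group variance
  as $n \cdot se^2$, pools by df, and is provably identical to
  `anova_lsd()` on any raw data realising those summaries (tested by
  construction).  Letters come from the insert-and-absorb compact letter
  display with 'a' at the smallest mean, matching the published
  convention (hemolymph = a), plus a cover-repair pass so that sharing a
  letter is exactly equivalent to a non-significant LSD difference.
* `two_sample_t(...)` — pooled-variance t, df = n1 + n2 − 2.
* `composition_chisq()` — Pearson chi-square over aligned level sets,
  with levels of expected count < 1 merged into the adjacent higher
  level.  The original survey's chi-square statistics cannot be
  reproduced because per-class *counts* were never printed (only
  percentages); the function exists for new data.

No multiple-testing correction is applied anywhere, matching the
reporting style of the reconstructed survey.  ANOVA/LSD runs on the pg
scale; F and the letter partition are scale-invariant, so the choice is
cosmetic.

One quantification of the rounding floor: rebuilding the tissue ANOVA
from the printed means/SEs gives

```{r anova}
t2 <- helicoverpa_tissue_summary()
rec <- anova_from_summary(t2$c_value_pg, t2$se_pg, t2$n, labels = t2$tissue)
rec
```

The raw-data F was printed as 3.29; the reconstruction lands within one
unit in the second decimal because the printed inputs are themselves
rounded to 3 significant figures.  The letter partition is recovered
exactly.

## Worked example

```{r pipeline}
lib <- template_library()
ref <- ploidy_fit(generate_sample(lib$dmel_adult_head, 20000, seed = 1))
smp <- ploidy_fit(generate_sample(lib$harm_head, 20000, seed = 2))
smp
c_pg <- estimate_c_value(coef(smp)[["2Cx"]], coef(ref)[["2Cx"]])
round(pg_to_mb(c_pg))
```

`demo_paper(seed)` wraps the whole study design: all eight templates,
three replicates each, full pipeline, plus the printed-summary
reconstructions.

## Problem sizes, tolerances and known limitations

The package's own test conditions are 20,000 events per sample and five
seeds per template — enough for per-class binomial noise (≈ 0.35
percentage points SD at a 50% class) to sit well inside the ±2 pp
recovery tolerance, while keeping a full recovery sweep under a few
seconds.  Recovery checks run on interference-free template copies: the
interference components are *designed* to bias peaks (that is the
phenomenon they emulate), so they are exercised by direction-of-effect
tests instead.

Known limitations:

* The salivary-gland chain overlaps the 8Cx attribution window by
  construction (its support starts at the 8Cx centre), inflating the 8Cx
  cluster by 1–2 pp and its mean by ≈ 1%.  This is a property of the
  declared chain model, not an estimator defect; the calibration quantity
  (2Cx) is unaffected.
* Anchoring assumes the ladder's foot is visible.  A sample whose 2Cx
  class fell below the prominence floor would shift every label by one
  octave; the reference-sample workflow (and the ambiguity error) is the
  guard.
* Reference pairing is a single shared reference intensity per
  calibration group (the mean over reference replicates); per-day
  pairing, if replicate-to-day mappings exist, can be expressed by
  splitting groups.
* Chain detection needs an 8Cx cluster and two octaves of headroom;
  profiles truncated below that return `FALSE` rather than guessing.
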