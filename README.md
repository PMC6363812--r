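# flowploidy

Genome size (C-value) and endopolyploidy estimation from propidium-iodide
flow cytometry, for entomologists and cytogenomicists who calibrate
fluorescence against an internal reference standard.

Endoreduplicating tissues produce a ladder of fluorescence clusters at the
2Cx, 4Cx, 8Cx, ... DNA levels.  Because detector gain is arbitrary, genome
size comes from the ratio of 2Cx peak means against a co-analysed standard
of known C-value:

    C_sample = (F̄_2Cx,sample / F̄_2Cx,reference) × C_reference

with C_reference = 0.18 pg (*Drosophila melanogaster* adult head) and
1 pg = 978 Mb.  Adjacent-cluster ratios below the ideal 2.0 quantify
under-replication in endocycles.

The package provides:

* `ploidy_fit()` — the central estimator: side-scatter debris gating,
  kernel-density peak detection, doubling-ladder assignment (2Cx anchored
  at the ladder's foot, optional 1Cx), per-cluster statistics, and
  detection of the continuous polyploid-fragment "chain" seen in larval
  salivary gland.  Classed S3 object with `print`, `summary`, `coef`,
  `plot`, `predict`, `residuals` and `simulate` methods.
* `estimate_c_value()`, `pg_to_mb()`, `aggregate_replicates()` — reference
  calibration, unit conversion, replicate aggregation with SE and CV range.
* `ratio_t_test()`, `composition_chisq()`, `anova_lsd()`,
  `anova_from_summary()`, `two_sample_t()` — the survey statistics,
  including summary-statistic variants that rebuild F statistics, pooled
  t-tests and Fisher's-LSD letter partitions from printed means/SEs.
* `template_library()` / `generate_sample()` — a synthetic listmode
  generator for eight tissue phenotypes (reference head, six *Helicoverpa
  armigera* larval tissues, *H. assulta* head) with configurable
  under-replication, debris, fluorescence interference and chain load, so
  the whole pipeline is testable without instrument data.
* `read_events()` / `write_events()` (documented CSV dialect; minimal FCS
  3.1 adapter), `read_run_config()` (YAML manifests), `run_pipeline()`,
  `demo_paper()`, and a thin CLI at `inst/cli/flowploidy.R`.

## Worked example

```r
library(flowploidy)
lib <- template_library()
ref <- ploidy_fit(generate_sample(lib$dmel_adult_head, 20000, seed = 1))
smp <- ploidy_fit(generate_sample(lib$harm_head, 20000, seed = 2))
smp
#> Ploidy profile: 5 cluster(s), anchor 2Cx, 20000 events
#>  level mean_fi  sd_fi count fraction   cv
#>      2  224.19  10.85  8325   0.4334 4.84
#>      4  434.38  21.27  5353   0.2787 4.90
#>      8  840.21  40.61  3294   0.1715 4.83
#>     16 1554.76  74.02  1504   0.0783 4.76
#>     32 2786.41 130.72   732   0.0381 4.69
#> gated 2.83% | unclassified 1.17% | chain absent (mass 0.002)

c_pg <- estimate_c_value(coef(smp)[["2Cx"]], coef(ref)[["2Cx"]])
round(c_pg, 3)        # 0.403  -- C-value in pg
round(pg_to_mb(c_pg)) # 395    -- genome size in Mb
```

The five clusters are the 2Cx-32Cx endopolyploidy ladder of the larval
head; `fraction` is each cluster's share of classified nuclei, `cv` the
peak quality metric, and the calibrated C-value (0.403 pg, i.e. ~394 Mb;
this single seed pair rounds to 395) matches the configured truth.  `demo_paper(seed = 1)` runs the full eight-tissue study design
(three replicates each) and appends the printed-summary reconstructions
(tissue ANOVA F(5,12) ≈ 3.28–3.29 with letter partition
a/ab/abc/bc/c/c, species comparison t(9) ≈ −11.5, and all
adjacent-ratio t-tests).

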