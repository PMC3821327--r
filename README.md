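# vocfinger

Urine-headspace volatile organic compound (VOC) fingerprinting for
distinguishing **bile acid diarrhoea (BAD)** from **ulcerative colitis
(UC)** and **healthy controls**.

Chronic diarrhoea caused by excess colonic bile acids is common but
under-diagnosed, because the gold-standard SeHCAT retention scan is
expensive nuclear imaging. Gut dysbiosis in BAD alters the fermentation
products that end up as volatiles in urine headspace, so the disease leaves
a chemical fingerprint that cheap gas-phase instruments can read. This
package implements the complete analysis workflow for three such
instruments, plus a synthetic cohort generator that emulates all of them so
the entire pipeline is testable without patient data:

* **FAIMS** (field asymmetric ion mobility spectrometry): each scan is a
  pair of dispersion matrices — ion current over 51 dispersion-field (DF)
  settings (0–90 %) × 512 compensation-voltage (CV) steps (+6 → −6 V), one
  per polarity, 26,112 points each.
* **Electronic nose**: 18 metal-oxide resistive sensors sampled at 1 Hz for
  180 s per injection, three injections per sample.
* **GC-MS**: peak tables (retention time + fragmentation spectrum) screened
  for the two candidate BAD markers, 2-propanol (~1.71 min) and acetamide
  (~2.05 min).

## The method

For the FAIMS route, both polarity matrices are concatenated into a single
vector *x* ∈ ℝ⁵²²²⁴ and transformed with an orthonormal multilevel
Daubechies-4 wavelet (periodic, depth 9). For every wavelet coefficient the
two scatter statistics

* class scatter (within): `(Σᵢ σᵢ)²`, where `σᵢ` is the standard deviation
  of the coefficient within class *i*,
* between-class scatter: `(σ_μ)² / (Σᵢ σᵢ)²`, where `σ_μ` is the standard
  deviation of the per-class means,

are computed, and coefficients with `within < t_w` and `between > t_b` are
selected. The two thresholds span a 2-D parameter space that is explored on
a grid; every cell is scored by full leave-one-out reclassification
(regularized Fisher LDA projection + k-nearest-neighbour vote, selection
and LDA refit per fold so the held-out sample never informs its own
classifier). Cells whose accuracy exceeds the chance null
`mean = Σ p_c²`, `sd = √(mean(1−mean)/n)` by more than **three standard
deviations** form the robust region; its best cell supplies the variables
for the final report, which includes per-class accuracy and the collapsed
binary **BAM vs non-BAM** accuracy. The e-nose route uses the per-sensor
maximum resistance change `max_t |R_s(t) − baseline_s|` as its 18-feature
fingerprint and the same LOOCV machinery with replicate-grouped hold-out.

## Worked example

```r
library(vocfinger)

cfg <- cohort_config(n_per_group = c(BAD = 7, UC = 7, CONTROL = 7),
                     effect_size = 2, noise_sd = 0.5, seed = 11)
cohort   <- generate_cohort(cfg)
features <- faims_feature_matrix(cohort$faims_scans)
grid     <- explore_threshold_grid(features, cohort$manifest$group,
                                   n_within = 8, n_between = 8)
grid
#> <threshold_grid_result> 8 x 8 grid, 12 defined cell(s), 12 robust
#>   best accuracy 1.000 (chance 0.333 + 3 sd = 0.642)
find_robust_region(grid)
#> <robust_region> accuracy 1.000 at (within < 4.022, between > 2.144), 12 variable(s)

enose_classify(cohort$enose_records, cohort$manifest$group)
#> <classification_report>
#>   overall accuracy: 0.905
#>   BAM vs non-BAM:  0.952
#>   BAD      0.857
#>   CONTROL  0.857
#>   UC       1.000

detect_markers(cohort$gcms_tables[["BAD_001"]])
#> <marker_report> 6 hit(s) (rt window 0.050 min, min similarity 0.80)
#> ...
#> 6       2.060379                       Acetamide  1.0000000  0.009378876
```

Reading the output: the synthetic 21-sample cohort with a moderate planted
effect is perfectly reclassified from its FAIMS wavelet features inside a
robust threshold region (accuracy 1.0 ≫ chance 0.333 + 3 × 0.103); the
noisier 18-sensor e-nose fingerprint reaches 90.5 % three-class and 95.2 %
BAM-vs-non-BAM accuracy; and the BAD sample's GC-MS table triggers the
acetamide marker near 2.05 min, which control tables never do.

## Command line

```sh
vocfinger simulate  --out cohort/ --n_bad 23 --n_uc 42 --n_control 45 --seed 1
vocfinger faims-run --manifest cohort/manifest.json --grid 20x20 --k 3 --out report/
vocfinger enose-run --manifest cohort/manifest.json --mode absolute --out report/
vocfinger gcms-scan --table cohort/BAD_001_gcms.tsv --out report/
vocfinger report    --report report/enose_report.json
```

The launcher script lives at
`system.file("cli", "vocfinger", package = "vocfinger")`; `--config
file.yaml` supplies defaults that individual flags override.

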