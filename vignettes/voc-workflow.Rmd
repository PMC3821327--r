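---
title: "Classifying urine-headspace VOC profiles: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying urine-headspace VOC profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocfinger)
```

## The problem and the data model

Bile acid diarrhoea (BAD) arises when bile acids escape reabsorption and
reach the colon; the resulting shift in gut fermentation alters the
volatile organic compounds (VOCs) found in urine headspace. The package
classifies urine samples into BAD, ulcerative colitis (UC) and healthy
controls from three instrument modalities:

* a FAIMS scan per sample: two 51 × 512 dispersion matrices (positive and
  negative polarity) of ion current over dispersion field (0–90 %, 51
  settings) × compensation voltage (+6 → −6 V, 512 steps), 26,112 points
  per polarity;
* three e-nose injections per sample: 18 metal-oxide sensor resistance
  traces, 180 s at 1 Hz, plus a pre-injection baseline;
* a GC-MS peak table per sample: retention times with base-peak-999
  mass spectra.

## The FAIMS pipeline

Each scan's two matrices are concatenated row-major by dispersion-field
line into a 52,224-element vector and transformed with a multilevel
Daubechies-4 wavelet. Per coefficient, with `sigma_i` the within-class
standard deviation and `sigma_mu` the standard deviation of the class
means, the pipeline computes the class scatter `(sum_i sigma_i)^2` and the
between-class scatter ratio `(sigma_mu)^2 / (sum_i sigma_i)^2`, then
selects coefficients below a within-threshold and above a
between-threshold. The two thresholds are explored on a grid; every cell is
scored by leave-one-out LDA + KNN reclassification, and cells beating the
chance null by more than three standard deviations form the *robust
region* whose best cell supplies the final variable set.

### Numerical and design choices

**Wavelet.** Only the wavelet family (Daubechies-4) is fixed by the
workflow's provenance; the boundary rule and depth are this package's
choices. We use the orthonormal filter pair with periodic (circular)
boundary handling and depth 9, because 52,224 halves evenly exactly nine
times (down to 102 approximation coefficients). Orthonormality preserves
length and energy (Parseval holds to 1e−9 in the tests), which keeps
coefficient indices stable and makes the scatter statistics comparable
across cells. Signals whose length is not divisible by `2^depth` are
refused with advice to reduce the depth rather than silently padded.

**Standard deviations** use the n−1 denominator throughout: per-class
sample sizes are small (as few as 5 in tests, 23 in the emulated cohort),
where the denominator choice is material.

**Degenerate scatter conventions.** A coefficient constant everywhere gets
`within = 0, between = 0` so it can never be selected; one constant within
each class but differing between classes gets `between = +Inf` so it passes
any finite threshold. Both follow from reading `0/0` as "no evidence" and
`x/0, x > 0` as "perfect separation".

**Selection direction.** The source description says variables "below this
threshold" for both statistics, but a *large* between-class scatter ratio
indicates a discriminative variable, so the literal reading would select
the least informative coefficients. The default is `within < t_w` AND
`between > t_b`; both directions are configurable
(`select_variables(..., within_dir, between_dir)`) and the ambiguity is
documented here rather than silently resolved.

**Threshold grids.** The within axis uses 20 empirical quantiles
(2.5 %, 7.5 %, …, 97.5 %). For the between axis, linear quantiles turned
out to be unusable: with 52,224 variables and a selection cap of
`min(n − C, 500)`, even the most selective linear-quantile corner cell
selects > 100 variables (measured: 170 on a 21-sample cohort), so *every*
cell is capped and no robust region can exist. The between axis therefore
places thresholds at log-spaced upper-tail exceedance fractions, from 50 %
down to about two variables, which covers the full range of usable
selection sizes regardless of scale. This is the one place the package's
defaults deviate from a linear-quantile convention, and it is forced by the
dimensionality.

**Selection cap.** Cells selecting more than `min(n − C, 500)` variables
are marked *undefined* (with a reason) rather than scored: LDA with more
variables than samples is dominated by the ridge term and its accuracy
would be an artifact of the regularizer. Undefined cells can never be
robust.

**LDA.** Regularized Fisher discriminant: the pooled within-class
covariance gets `1e-6 × mean(diag(W))` added to its diagonal, keeping the
fit well-posed when the selected-variable count approaches the sample
count, and making duplicated variables harmless. Eigenvector signs follow a
fixed convention (first non-negligible loading positive), so fits are
bit-reproducible.

**KNN.** `k = 3` by default — odd, to reduce three-class vote ties; the
workflow's provenance does not state k. Classification happens in the
LDA-projected space (`knn_space = "raw"` is available). Vote ties are
broken by the nearest neighbour among the tied classes, and exact distance
ties by lexicographic label order, so predictions are invariant to
training-set row order.

**Leave-one-out discipline.** Scatter statistics, variable selection and
the LDA fit are recomputed for every fold from the retained samples only.
In the grid search this is done efficiently by downdating per-class
sufficient statistics (counts, sums, sums of squares) rather than
recomputing from the raw matrix. Replicated measurements (the three e-nose
injections) are held out *together* and vote by majority on their sample's
label, avoiding the pseudo-replication that ungrouped hold-out of
technical replicates would cause; the ungrouped variant remains available
by passing per-row groups.

**Chance null.** The analytic prior-proportional model:
`mean = sum_c p_c^2`, `sd = sqrt(mean (1 − mean) / n)`. For the emulated
cohort (23/42/45) this gives mean ≈ 0.357. A permutation null (≥ 200 label
reshuffles) is retained as a cross-check and agrees with the analytic mean
within Monte-Carlo error; the analytic version is the default because it
is deterministic and the robustness rule only needs its first two moments.

## The e-nose pipeline

The feature is the per-sensor maximum absolute resistance change from the
pre-injection baseline, `max_t |R_s(t) − baseline_s|`. Metal-oxide sensors
can rise or fall depending on the analyte/dopant combination, hence the
absolute value; signed and baseline-relative variants are exposed as modes.
Exploratory PCA (column-centered, unscaled by default) is provided;
classification reuses the LOOCV machinery with replicate grouping.
Averaging replicates at the feature level is offered but not default,
matching the three-injections-per-sample protocol.

## GC-MS marker detection

The packaged reference set contains seven urinary-headspace peaks with
their printed retention times and base-peak-999 spectra, including the two
candidate BAD markers: isopropyl alcohol (1.714 min) and acetamide
(2.051 min). A table entry is a hit when its retention time falls within
`rt_window` (default 0.05 min) of a reference *and* the cosine similarity
over the m/z union is at least `min_similarity` (default 0.8). Cosine
similarity on base-peak-normalized intensities is the standard open
surrogate for a proprietary library search; it is symmetric and invariant
to uniform intensity rescaling, so the 999-normalization convention does
not affect scores.

## The synthetic cohort generator

The generator's defaults state the emulated world: group sizes 23/42/45,
three e-nose replicates per sample, one FAIMS scan and one GC-MS table per
sample.

* **FAIMS**: intensities are a shared background of 2-D Gaussian "plumes"
  on the (CV, DF) grid plus four designated group-differential plumes
  whose amplitudes (and, for one plume, CV centers) differ by group and
  scale with `effect_size`, plus i.i.d. Gaussian pixel noise (`noise_sd`,
  default 0.5). Gaussian bumps are the simplest shape reproducing the
  visual plume of a real dispersion plot with controllable overlap, and a
  sparse set of differential plumes is what makes variable selection
  meaningful.
* **e-nose**: each trace is baseline + amplitude ×
  `(1 − exp(−t/τ_rise)) · exp(−t/τ_decay)` (normalized to peak 1), with
  group-specific amplitude offsets on four designated sensors.
* **GC-MS**: reference spectra are planted verbatim; the two markers
  appear only in BAD tables, at configurable centers (defaults 1.714 and
  2.051 min) with uniform retention-time jitter (default ±0.01 min).

Biological versus technical variance is not specified by the emulated
study, so both are free parameters: `bio_sd` (default 0.1) jitters plume
and sensor amplitudes per *sample*, `noise_sd` acts per *measurement*.
Every record's RNG seed derives deterministically from
`(cohort seed, sample id, replicate)`, so cohorts are reproducible record
by record, and RNG consumption is group-independent, so `effect_size = 0`
removes group structure entirely.

**What a green test establishes — and what it does not.** The generator
emulates class-dependent signal, replicate structure and i.i.d. noise. It
deliberately does not model real urine chemistry, humidity or temperature
effects, sensor drift, or the multi-month batch structure of real
acquisition campaigns. Passing tests therefore establish that the
*algorithms* are correct and calibrated (no leakage, chance-level behaviour
under the null, signal recovery when signal exists) — not that any
particular clinical accuracy would be attained on patients. The original
cohort's accuracies were computed on data that were never deposited and
are not reproducible; the test suite replaces them with property-based
substitutes: oracle equivalence on small instances, null calibration
(≥ 18/20 seeds within 3 SD of chance), signal recovery (median accuracy
≥ 0.9 and a robust region at `effect_size = 2`, `noise_sd = 0.5`), exact
wavelet/energy identities and a hand-computed scatter example.

## Known limitations

* The threshold-grid search scores `O(grid cells × samples)` LDA fits;
  at the default 20 × 20 grid and 110 samples this is minutes of CPU, and
  the tests use smaller grids and cohorts for speed.
* Pooled analysis only: measurement batches are not modelled or corrected.
* KNN tie-breaking beyond the documented rules (e.g. equal distance *and*
  equal label) falls back to label order — irrelevant for continuous
  features, visible only on constructed integer data.
* The GC-MS route flags markers in peak tables; it does not pick peaks
  from raw chromatograms or quantify concentrations.
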