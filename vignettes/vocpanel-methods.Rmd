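---
title: "Methods: term-effect subtraction, screening, and SVM panel search for urinary VOC studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: term-effect subtraction, screening, and SVM panel search}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocpanel)
```

# The study design and data model

`vocpanel` targets a four-group, two-timepoint volatile-metabolomics design:
two rodent tumor models (call them A and B), each with a tumor-injected and a
placebo-injected group of the same size, urine sampled per animal at an early
period and again at the terminal period, and a fixed list of GC/MS
total-ion-chromatogram peaks quantified by height in every sample. The
central data object, `VocStudy`, is a `SummarizedExperiment` with peaks in
rows, one column per (animal, timepoint) measurement, and
`sample_id`/`model`/`condition`/`timepoint` in `colData`. Validity enforces
the balance assumptions the downstream statistics rely on: equal group
sizes, both timepoints per animal, one shared peak list.

Working on the log scale is assumed throughout: peak heights are positive
and multiplicative noise is the norm for GC/MS intensities, so the
preprocessing chain is `log(height + 1)` followed by per-sample row-mean
centering (an overall-intensity, i.e. dilution, correction).

# Term-effect subtraction

Urine composition drifts between the early and terminal collection periods
in *all* animals — the term effect. Because every animal is measured at both
timepoints, the per-animal difference

$$R_{sp} = tH_{sp} - eH_{sp}$$

(terminal minus early processed height of peak $p$ in animal $s$) cancels
every animal-specific and stage-shared additive component on the log scale:
for placebo animals $R$ estimates the term effect alone, for tumor animals
the term plus tumor effect. Two properties are tested explicitly: adding a
per-animal constant to both stages leaves $R$ unchanged, and a stage-wide
per-peak shift (the term effect itself) disappears after the subsequent
per-peak z-scoring. When a stage has repeated collections, each cell takes
the per-animal maximum height across collections before subtraction.

`normalizeSubtracted()` z-scores each peak column over the pooled analysis
set of one model (tumor + placebo animals), using the population (1/n)
standard deviation; zero-variance columns become all-zero with a warning.
The scope — per model, pooled over both conditions — matches how normalized
intensities are displayed and fed to the classifier.

# Univariate screening

The screen is a two-sided two-sample test per peak between tumor and placebo
$R$ values at a stringent raw threshold, default $\alpha = 10^{-4}$.
Welch's $t$ is the default (robust to unequal variances; the pooled-variance
$t$ and Wilcoxon are selectable). Deliberately, **no multiple-testing
correction** is applied: the design this package mirrors controlled false
positives through the severity of the raw threshold
($47 \times 10^{-4} \approx 0.005$ expected false positives per screen), and
the screening report carries raw p-values so any correction can be applied
downstream if wanted.

# Two-way ANOVA interaction screening

Tumor-model specificity is assessed per peak with the balanced two-factor
model $y = \mu + \alpha_i + \beta_j + (\alpha\beta)_{ij} + \epsilon$,
condition × tumor model, on the normalized subtracted values pooled over all
four groups. Only the balanced 2×2 layout is implemented — it is the study's
design, and it admits the exact closed-form decomposition from cell means

$$SS_A = 2n\sum_i(\bar y_{i\cdot} - \bar y)^2,\qquad
  SS_{AB} = n\sum_{ij}(\bar y_{ij} - \bar y_{i\cdot} - \bar y_{\cdot j} + \bar y)^2,$$

with $F = MS_{\mathrm{effect}}/MS_{\mathrm{err}}$ on $(1, N-4)$ df, which is
exactly testable against a least-squares fit (the test suite checks
agreement with `anova(lm(...))` to $10^{-8}$ relative on 100 random
instances). Unbalanced layouts are rejected rather than approximated; no
Type-II/III machinery is provided. Peaks are flagged at a loose 0.05 and a
strict 0.002 interaction threshold; the strict list is the "model-specific"
call, the loose list is reported for context.

# The classifier

The soft-margin SVM minimizes $\tfrac12\|w\|^2 + C\sum_i \xi_i$ in the
feature space induced by the Gaussian kernel. The kernel convention
matters: here

$$k(x, x') = \exp(-\sigma\,\|x - x'\|^2),$$

with $\sigma$ multiplying the squared distance — the `rbfdot` convention of
the kernlab library — and the default $\sigma = 0.9$ is interpreted under
that convention. $C$ defaults to 1 and is exposed everywhere; no kernel
other than the RBF is offered, and multi-class problems are out of scope.

Training solves the dual by sequential minimal optimization (compiled,
`src/smo.cpp`): first-order selection of the most violating index, second-
order (maximal guaranteed decrease) selection of its partner, analytic
two-variable steps, stopping when the KKT violation falls below `tol`
(default $10^{-4}$). Two numerical details are deliberate:

* bound membership in the working-set selection uses a tolerance of
  $10^{-12} C$, because a clipped step can leave a dual coefficient one
  rounding error away from a bound and exact comparisons would then reselect
  the same zero-progress pair forever;
* a decision value of exactly 0 is assigned to the positive class, with a
  warning.

The tests verify the KKT conditions on random problems and compare the dual
objective with an independent interior-point QP solution (`kernlab::ipop`)
to $10^{-6}$; the solver itself agrees to ~$10^{-11}$.

For the descriptive two-dimensional view (`scoreSpaceClassify()`), samples
are projected onto the first two principal components (covariance PCA,
centering only, loading signs fixed so the largest-magnitude entry is
positive) and the SVM is trained on the scores. Panel evaluation, in
contrast, trains on the (standardized) peak values directly — per-subset PCA
would be ill-defined for one-peak panels. An optional Platt-style sigmoid on
decision values (`plattScale()`) supports class-probability backgrounds in
score plots; nothing in the pipeline consumes it.

# Evaluation protocols and the panel search

`makeFolds()` partitions each class separately into $k$ folds of near-equal
size (25 animals, $k = 10$: five folds of 3 and five of 2, i.e. sub-samples
of 1–3 animals); fold $j$ of one class is tested together with fold $j$ of
the other, so test folds almost always contain both classes. If a test fold
still lacks a class, that fold contributes nothing to the undefined rate —
the value is excluded from the mean with a note, never counted as 0.
Metrics are averaged over folds and reported in percent with
$\mathrm{SEM} = \mathrm{sd}/\sqrt{k}$, the "98 ± 2" convention. The hold-out
protocol draws 13 training and 12 test animals per class per seed; transfer
trains on all animals of one model and tests on all of the other, with
standardization fitted on the training model only.

By default all preprocessing inside a protocol is **leak-free**: centering
and scaling are fitted on the training folds only. A `pooledMode` switch
instead fits them once on the pooled data — the original analysis appears to
have projected all samples together — and is provided for reproduction
studies; the default stays leak-free.

`exhaustiveSearch()` enumerates all $2^p - 1$ non-empty subsets of the
candidate peaks in lexicographic order ($2047$ for 11 candidates) and ranks
them by mean accuracy (desc), then subset size (asc), then mean sensitivity
(desc), then lexicographic panel identity. The tie-break chain beyond
accuracy is this package's convention — some rule is needed to make ranked
output deterministic, and smaller panels are preferred as cheaper assays.
More than 20 candidates are refused (the subset count doubles per peak)
unless forced. No greedy or heuristic selection is offered: exhaustive
enumeration over a screened candidate set *is* the method.

# The synthetic-study generator

`simulateStudy()` draws the log intensity of peak $p$ for animal $s$ in
group $(m, c)$ at timepoint $t$ as

$$\mu_p + \tau_p[t{=}\mathrm{late}]
  + (\delta_p + \gamma_{pm})[t{=}\mathrm{late},\, c{=}\mathrm{tumor}]
  + \varepsilon,\qquad \varepsilon \sim N(0, \sigma_p^2)\ \text{i.i.d.},$$

returning linear-scale intensities $e^{\text{log-intensity}}$. The defaults
define the emulated study conditions and were chosen once, by design:

* **47 peaks, 25 animals per group, two models** — the emulated design.
* **$\sigma_p = 0.5$** log-scale noise: a mid-range coefficient of variation
  (~50%) for untargeted GC/MS peak heights.
* **11 differential peaks with $|\delta_p| = 3\sigma_p$, 9 down- and 2
  up-regulated** — predominant down-regulation with a minority of
  up-regulated peaks. The $3\sigma$ magnitude makes the per-peak Welch
  power at $\alpha = 10^{-4}$ about 0.999 ($R$ has noise sd
  $\sqrt2\sigma$, so the standardized effect is $3/\sqrt2 = 2.12$ and the
  $t$ noncentrality $2.12\sqrt{25/2} = 7.5$ against a critical value of
  ~4.3), hence full 11-peak recovery in ≳99% of studies — a regime where
  screening *should* succeed, so failures indicate defects.
* **4 interaction peaks with $|\gamma_{pm}| = 1.1$, sum-to-zero across
  models** (so $\delta_p$ stays the shared tumor effect, mirroring the
  ANOVA parameterization). The interaction-F noncentrality is
  $n\gamma^2/(2\sigma^2) \approx 60$, putting strict-threshold recovery
  near 1 while null peaks pass at the nominal 0.002 rate.
* **$\mu_p$ and $\tau_p$ smooth deterministic patterns** (sinusoids across
  the peak index): varied baselines and a nonzero shared term effect without
  extra random-number plumbing; equal designs therefore mean equal effect
  specifications.
* The default differential and interaction peak sets are disjoint, so
  ground-truth roles are unambiguous; in real data (and optionally here) a
  peak can carry both.
* The printed cubic growth fits (`growthCurve()`) and the caliper
  tumor-volume formula (`tumorVolume()`, coefficient 3.14 exactly as used in
  the protocol, not $\pi$) are provided to schedule early/late effect
  magnitudes; no per-day longitudinal samples are simulated, since the
  chemistry was analyzed at two timepoints only.

`simulateTic()` renders heights as Gaussian peaks over a constant baseline
with optional white noise; `simulateStudyTics()` does so for every
measurement of a study at a default spacing (0.8 min) ≫ peak width
(0.05 min), so window detection and max-height quantification recover the
planted heights exactly on noise-free traces.

**What the generator does not emulate:** retention-time drift and warping,
co-eluting peaks, heteroscedastic or heavy-tailed noise, missing peaks,
batch effects, and any dilution (overall-intensity) variation between
samples. Passing tests therefore demonstrate the pipeline's correctness and
power under its stated statistical assumptions, not robustness to those
real-data complications — the chromatogram module deliberately excludes
alignment and deconvolution.

One consequence is worth spelling out. The per-sample row-mean correction
exists to remove dilution variation. Simulated data contain none, but the
correction still subtracts each sample's mean *signal*: with 9 down- and 2
up-regulated peaks of 47, tumor samples' late row means shift by about
$-0.22$, which attenuates the planted $3\sigma$ effects by ~15% and drops
the probability of recovering all 11 peaks from ~0.99 to ~0.8. The
power-recovery checks in the test suite and `scripts/acceptance.R` therefore
run the screen on log-scale subtracted values with the dilution correction
disabled (`correctIntensity = FALSE`) — that is the configuration in which
the planted $|\delta|/\sigma = 3$ condition means what it says — while the
pipeline default keeps the correction on, as real GC/MS data require.

# Numerical choices and degenerate inputs

* Peak windows are half-open $[start, end)$ on the retention-time grid, so
  boundary grid points are never double-counted; windows extend to midpoints
  between adjacent centers and `minSeparation` beyond the flanking centers.
  Near-coincident maxima are merged keeping the higher one. A window with no
  grid points scores 0 with a warning; an all-flat trace set yields an empty
  window list, not an error.
* Log transform is natural log with offset 1 (zeros map to 0); both are
  configurable.
* Z-scoring uses the population sd; a column `(1, 2, 3)` becomes
  `(-1.2247, 0, 1.2247)`.
* Welch p-values come from `stats::t.test`; ANOVA tail probabilities from
  `pf()`; PCA from `stats::prcomp` with a deterministic sign convention.
* All randomness (simulation, fold plans, hold-out splits) flows through
  explicit seeds, restored afterwards so library code never perturbs the
  caller's RNG stream; equal seeds give bit-identical studies, plans and
  reports.
* Errors are classed (`vocpanel_config_error`, `vocpanel_data_error`) and
  the CLI maps them to exit codes 2 and 3.

The test suite and acceptance script run the power and recovery checks at
the design's own sizes (25 animals/group, 47 peaks, 100 screening seeds, 20
exhaustive-search seeds, 2047 panels × 10 folds each) — a few minutes of
compute in total, dominated by the ~400,000 SMO fits of the search checks.

# Known limitations

* Only two-class problems; only the RBF (and implicitly linear-in-scores)
  kernel; no probability calibration beyond the cosmetic Platt sigmoid.
* Only balanced 2×2 ANOVA; unbalanced data are rejected.
* The univariate screen and the search's accuracy ranking ignore correlation
  between peaks; a panel of highly correlated peaks can rank above a more
  complementary one when their CV accuracies tie.
* With 1–3 animals per fold, per-fold sensitivity/specificity are coarse
  (0/50/100%), so fold SEMs are large for small panels; the hold-out
  protocol gives smoother estimates.
* Pooled mode reproduces a project-all-samples-at-once workflow but is
  optimistically biased; leak-free mode is the default and the two are
  never mixed within a report.
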