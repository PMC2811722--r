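# vocpanel

Discovering diagnostic panels of urinary volatile organic compounds (VOCs)
from GC/MS peak tables in case/control rodent tumor studies.

## The problem

Tumor growth alters an animal's volatile metabolome. In a flank-tumor study
design, urine is sampled from tumor-bearing and placebo-injected mice of two
tumor models at an early period (shortly after injection) and again at the
terminal period, headspace volatiles are profiled by GC/MS, and a fixed set
of total-ion-chromatogram peaks — shared by every animal — is quantified by
peak height. The analytical challenge is that peak intensities drift between
the two collection periods for reasons unrelated to the tumor (age, season,
husbandry): the *term effect*. `vocpanel` implements the full discovery
pipeline for this design:

1. **Chromatogram quantification** — peak windows detected simultaneously on
   the point-wise mean trace of all samples; per-window maximum height;
   `log(x + 1)` transform; per-sample row-mean intensity correction.
2. **Term-effect removal** — per animal and peak,
   `R_i = tH_i − eH_i` (terminal minus early height), so placebo animals
   carry the term effect alone and tumor animals carry term + tumor effect;
   `R` is then z-scored per peak.
3. **Univariate screening** — two-sided Welch *t* per peak between tumor and
   placebo at a stringent raw threshold (default `p < 1e-4`; no
   multiple-testing correction, by design).
4. **Model-specificity screening** — per peak, balanced two-way ANOVA
   `R ~ condition * tumor model`; a significant interaction (`p < 0.002`
   after a loose `p < 0.05` pass) flags peaks that respond differently in
   the two tumor models.
5. **Classification** — soft-margin SVM with Gaussian kernel
   `k(x, x′) = exp(−σ‖x − x′‖²)`, σ = 0.9, trained on the first two PCA
   scores for the descriptive score-space view, or on peak values directly
   for panel evaluation. Performance is reported as sensitivity
   `tp/(tp+fn)`, specificity `tn/(tn+fp)`, accuracy `(tp+tn)/n`, and the
   ROC-space point `(1−sp, se)`.
6. **Exhaustive panel search** — every non-empty subset of the screened
   candidate peaks (2047 panels for 11 candidates) evaluated by 10-fold
   cross-validation (per-class folds of 1–3 animals), 13/12 hold-out
   splits, or cross-model transfer (train on model A, test on model B),
   ranked by mean accuracy.

A seeded synthetic-study generator reproduces the design's statistical
structure (4 groups × 25 animals × 2 timepoints × 47 peaks, log-normal
noise, predominant tumor-associated down-regulation, a shared term effect,
and model-specific interaction peaks), so the whole pipeline is testable
without instrument data. Raw chromatograms can be emulated as Gaussian peaks
over a baseline and re-quantified end to end.

## Worked example

```r
library(vocpanel)

study <- simulateStudy(studyDesign(nPerGroup = 25, nPeaks = 47, seed = 1))
study
#> VocStudy: 47 peaks, 100 animals, 2 tumor model(s), 2 timepoints
#>   planted: 11 differential, 4 interaction peak(s); seed 1

R <- normalizeSubtracted(subtractTermEffect(study, tumorModel = "A"))
scr <- screenPeaks(R, alpha = 1e-4)
head(scr[, c("peak", "meanTumor", "meanPlacebo", "statistic", "p")], 4)
#>  peak meanTumor meanPlacebo statistic        p
#>   P42     0.822      -0.822     10.01 3.33e-13
#>   P18    -0.757       0.757     -8.02 2.18e-10
#>   P38     0.728      -0.728      7.35 3.05e-09
#>   P01     0.718      -0.718      7.15 5.64e-09

cls <- scoreSpaceClassify(R)   # PCA scores + RBF SVM
cls$metrics
#> confusion: tp=25 fn=0 tn=25 fp=0
#>   sensitivity 1 | specificity 1 | accuracy 1 | error rate 0

sr <- exhaustiveSearch(subtractedValues(R), sampleConditions(R),
                       candidates = head(selectedPeaks(scr), 11), seed = 1)
head(sr$results[, 1:6], 3)
#>        panel size accuracy accuracySem sensitivity sensitivitySem
#>  P01+P18+P42    3      100           0         100              0
#>  P01+P22+P29    3      100           0         100              0
#>  P01+P26+P29    3      100           0         100              0
```

The screening table lists per-peak class means of the normalized subtracted
values (negative `meanTumor` = down-regulated following tumor development),
the Welch statistic and raw p-value. The search table reports each panel's
cross-validated accuracy/sensitivity/specificity in percent with SEM over
folds — the `98 ± 2` presentation convention.

`runPipeline(runConfig(...))` chains every stage and writes one CSV per
report plus a JSON echo of the configuration;
`inst/scripts/vocpanel.R` exposes the same stages as shell subcommands.

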