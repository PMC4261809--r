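---
title: "Methods: longitudinal case-control microbiome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal case-control microbiome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seroscan)
```

# The problem

In longitudinal infant-cohort studies of islet autoimmunity, stool is
collected roughly monthly from genetically at-risk children, 16S rRNA
amplicons are sequenced, and the question is whether any taxon's relative
abundance diverges between children who later seroconvert (cases) and
those who do not (controls) — and, if so, *when*. Three features of such
data break naive testing:

* **Compositionality and depth**: read counts are proportions of an
  arbitrary sequencing depth; samples must be rarefied to a common depth
  before fractions are comparable.
* **Measurement reliability**: technical-replicate variance explodes at
  low relative abundance, so taxa below a reliability cutoff cannot be
  measured meaningfully — yet they must still count toward multiplicity
  correction.
* **Repeated measures**: subjects contribute unequal numbers of samples,
  and a subject's samples are correlated; any test pooling samples is
  exposed to pseudo-replication.

`seroscan` implements the full pipeline — preprocessing, two
differential-abundance routes, a sliding age-window scan, cross-platform
species calibration, qPCR concordance, and subject-aware prediction —
together with a synthetic-cohort generator so every stage can be tested
end to end without restricted data.

# Preprocessing

The order is fixed: depth filter → rarefaction → relative abundance →
rank aggregation → abundance cutoff.

* Samples under **10,000 reads** are excluded (strict `<`), then each
  remaining sample is subsampled once, without replacement, to exactly
  10,000 reads. The subsample is an exact multivariate hypergeometric
  draw implemented as a chain of univariate hypergeometric draws, so the
  cost is independent of depth and the draw is reproducible from the
  seed. A single draw (rather than averaging many) keeps downstream
  counts integral and the provenance simple; the seed is recorded.
* Fractions are kept on the 0–1 scale internally; per-sample sums are
  exact to 1e-9 and aggregation to phylum/genus/species preserves mass
  exactly. Unresolved lineage levels aggregate into explicit
  `unclassified-<parent>` buckets rather than disappearing.
* The **reliability cutoff** is derived from technical replicates:
  within-replicate-group CVs are binned on a 20-point log-spaced
  abundance grid, smoothed by an isotonic non-increasing fit (replicate
  noise falls with abundance), and the cutoff is the smallest bin whose
  smoothed CV is at or below the dispersion threshold (default 0.3).
  With the default noise model this lands at ~1% relative abundance.
  Retention uses the **median across samples** of a taxon's relative
  abundance (robust, and matching how dominant-taxon figures are
  drawn); the pre-filter taxon count `m_total` is carried forward for
  multiplicity correction.

# Differential abundance

Two routes are computed per taxon and rank, and each is
Benjamini–Hochberg adjusted as if `m_total` hypotheses had been tested
(untested, below-cutoff taxa counted at p = 1). A taxon is significant
when either adjusted p falls below `alpha` (default 0.001).

**Across all samples.** The Mann–Whitney U test (exact enumeration when
both groups have ≤ 8 observations without ties; mid-rank, tie-corrected
normal approximation with continuity correction otherwise) applied to a
**balanced bootstrap**: each of 100 iterations draws exactly
`per_subject_k` samples per subject (default 1, with replacement when a
subject has fewer), and the reported p is the mean over iterations. One
draw per subject makes every iteration an independent-units test: with
subject-level random effects present, resampling many samples per
subject preserves pseudo-replication and we measured severe
anticonservatism under the null for abundant taxa, so k = 1 is the
default even though it caps attainable significance at the
subjects-only sample size.

**Across age.** Logistic regression of case status on abundance, age
(both standardized) and their interaction, tested by a 1-df
likelihood-ratio chi-square against the no-interaction model. Main
effects are kept in both models (standard hierarchy). On
(quasi-)separation both models are refitted with Firth's penalized
likelihood and the result is flagged. This route retains the full sample
size and is the one that detects a transient, age-localized divergence
at very small p; in null simulations its per-taxon error is calibrated.

LOESS trajectories (degree 1, tricube weights, span 0.75 by default)
with pointwise standard errors are provided for display, and categorical
covariate balance (delivery mode, breast-feeding duration bins,
antibiotic courses) is checked by contingency chi-square without
continuity correction, with a warning flag when expected cells drop
below 5.

# Sliding window scan

Samples are sorted by age; from each start position (advanced by 10
sorted samples) a contiguous run is extended until it holds 98 samples
*after* truncating every subject to its 2 samples nearest the window's
age midpoint. Windows with fewer than 20 case or 20 control subjects
are discarded. Within a window each subject collapses to a per-taxon
median profile; case and control profile sets are compared by a
bootstrap-averaged Mann–Whitney test in which each of 100 iterations
draws `min(n_case, n_control)` subjects per group with replacement,
equalizing group sampling frequency. Windows are flagged at 0.05 and
0.01 unadjusted — the scan is a localization display, not a discovery
procedure, and the discovery-level claim comes from the differential
module; an FDR option across windows exists but is off by default. Age
intervals are half-open `[start, end)` in days; months are days/30.44.

The minimum-p window localizes a transient effect: the bootstrap
averaging is what makes this work, because windows where separation is
incomplete mix saturated and non-saturated iterations and so rank above
windows at the true peak.

# Species calibration and absolute abundance

Short coarse-platform reads resolve only a merged two-species group;
a 93-sample fine-platform subset resolves the two species. Per species,
pseudo-counts (`fraction × 10,000`, the rarefaction depth) are
regressed on `log(group fraction)` with a log-link Poisson GLM,
observations weighted proportionally to group abundance (normalized to
mean 1) because replicate variance falls with abundance; both deviance
R² (1 − residual/null deviance) and squared Pearson correlation are
reported, along with the pooled species share of the group. Fits are
per species (the post-hoc check verifies shares sum to ~1); predictions
are clipped to `[0, group]` and jointly rescaled if their sum would
exceed the group fraction. In the noiseless proportional limit the fit
is exact (share recovered exactly, deviance R² = 1).

qPCR triplicates are QC'd by coefficient of variation (default
threshold 0.3 — chosen so that a realistic minority of samples fails,
as in the emulated study where 6 of 28 were discarded; no numeric
threshold was printed). Concordance of copy number with relative
abundance uses a log-link **quasi-Poisson** regression: copy-number
data are overdispersed by orders of magnitude relative to Poisson, and
the quasi-likelihood dispersion is what keeps the slope test calibrated
(verified by permutation). Concordance is declared when the slope is
positive with p < 0.01.

# Seroconversion prediction

The feature is one taxon's per-subject median abundance over an age
window (default 186–368 days, i.e. 6.1–12.1 months). Cross-validation
is subject-aware throughout — no subject's data ever informs its own
prediction:

* **Per-subject scores** come from leave-one-subject-out folds
  (logistic regression on the remaining subjects), reported as the
  predicted probability minus the training fold's case prevalence.
  The centering removes the leave-one-out prevalence artifact (holding
  out a case lowers the training prevalence and would otherwise depress
  every case's score).
* **AUC** is estimated by leave-pair-out cross-validation: every
  case–control subject pair is held out jointly, the model refitted,
  and the pair scored by whether the case outranks the control (ties
  ½). Pooled leave-one-out scores carry a well-known pessimistic AUC
  bias (we measured null means near 0.38 at this cohort size, because
  each fold's fitted slope is anticorrelated with its held-out label);
  the pairwise estimator is unbiased under the null, with mean ½ on
  null cohorts. The pooled estimator remains available as
  `auc_method = "pooled"`.
* The AUC standard error uses the Hanley–McNeil formula, and
  significance is the 1-df likelihood-ratio chi-square of the
  full-data logistic fit. A permutation p for the AUC can be obtained
  by rerunning on permuted labels.

`scan_prediction_windows()` repeats this over the sliding windows and
flags whether the best window's upper age bound precedes the cohort's
median seroconversion age.

# The synthetic cohort generator

The generator's defaults *are* the emulated study conditions; they are
design parameters, not tuning knobs.

* **Cohort**: 29 cases, 47 controls; first sample at ~150 days (clipped
  to 4–6 months); gaps normal (36, 11) days truncated at ≥ 14;
  per-subject follow-up ends uniformly on 331–803 days. The attrition
  makes the three printed design facts mutually consistent — ~947
  samples, a 36-day mean interval, and a 4–6-month-to-2.2-year
  envelope imply 12.5 samples per subject, which a full-length
  schedule cannot produce. Three samples are forced below 10,000 reads
  to exercise the depth filter. Case seroconversion ages are normal
  (16.8, 10.9) months truncated above the subject's first sample age
  (the SD back-calculates a standard error of 2.03 months at n = 29).
* **Composition**: 20 species across five phyla, Dirichlet-multinomial
  with total concentration 1/0.075 ≈ 13.3 — chosen so the per-sample
  spike-fraction SD at the case peak is ~0.10, the value implied by a
  printed peak-window mean of 17.3% with SE 0.02 at the realized
  per-window case count. A per-subject log-normal random effect
  (sd 0.5 on concentrations, mean-corrected) induces the
  subject-level correlation that makes bootstrap balancing matter; a
  second-order correction keeps the spike taxon's marginal mean at its
  target despite the nonlinear renormalization. Read depths are
  log-normal with arithmetic mean 357,581 (sdlog 0.5).
* **Spike trajectory**: both groups share a logistic colonization
  curve from 0.1% to a 20% plateau whose midpoint is placed so
  controls sit at exactly 0.18% at the 231-day peak; cases add a
  Gaussian bloom (σ = 35 days) reaching 17.3% at the peak. The
  case–control difference therefore peaks exactly at 231 days
  (7.6 months) and vanishes as controls colonize. The width is the one
  genuinely free shape parameter; it was fixed by requiring the
  generator's own design properties — the species group stays above
  the 1% retention cutoff, and the scan's minimum-p window localizes
  the injected peak in ≥ 90% of simulations. Wider blooms (σ ≥ 45 d)
  fail localization because rank tests saturate once cases separate
  completely from near-zero controls, letting the minimum drift early.
* **Replicates** draw from a sample's empirical composition perturbed
  by log-normal noise with sd `3·sqrt(1e-4/p)` — calibrated so the
  replicate CV crosses 0.3 at ~1% relative abundance at the 10,000-read
  depth, and depth-invariant so the derived cutoff is scale-consistent.
* **Fine platform / qPCR**: the merged group splits binomially at a
  0.75 species share; qPCR copies are relative abundance × log-normal
  total load with log-normal triplicate noise.

What the generator does **not** emulate: OTU-picking and chimera error,
primer bias, true compositional interactions between taxa (taxa other
than the spike differ only through closure), within-subject temporal
autocorrelation beyond the subject random effect, and any dependence of
covariates on case status (covariates are balanced by construction
unless an imbalance is injected). Passing tests therefore demonstrate
the statistical machinery under the study's declared structure, not
performance on raw sequencing artifacts.

# Numerical choices and degenerate inputs

* Exact Mann–Whitney switches on at ≤ 8 per group without ties; ties
  use mid-ranks with the tie-corrected variance and continuity
  correction.
* Benjamini–Hochberg is computed by the step-up formula directly;
  `m_total` inflation enters through the denominator ranks.
* Zero-total samples are an error for relative abundance; rarefaction
  below depth is an error directing the caller to the depth filter
  (the pipeline cannot run stages out of order).
* Constant-abundance taxa make the age interaction inestimable and
  error out (the pipeline records them as `NA` and judges the taxon on
  the all-samples route).
* Window ties in `locate_peak()` resolve to the earliest window.
* Master seed discipline: every stage derives named child seeds
  (FNV-1a hash of a stream label folded with the seed), so per-taxon
  and per-window results are independent of iteration order and
  enabling one stage never perturbs another's randomness.

# Problem sizes used in the test suite

Monte-Carlo checks in the package's tests use 50 simulated cohorts at
the full design size (76 subjects, ~950 samples, 20 taxa) for the
calibration and recovery properties, 200 reduced cohorts for the
oversampling demonstration, and oracle enumerations at n ≤ 6–8 for
exactness checks. These sizes put Monte-Carlo standard errors well
below the margins being asserted while keeping the default test run in
the minutes range.

# Known limitations

* The balanced bootstrap with k = 1 bounds attainable significance by
  the number of subjects; transient effects that never produce a
  marginal (all-ages) shift are detected by the interaction route
  instead.
* The window scan reports unadjusted flags; treat the p-track as a
  localization display.
* Leave-pair-out AUC costs one model fit per case-control pair; for
  the univariate logistic used here that is negligible, but it would
  grow for richer models.
* The calibration assumes the fine platform measures the same
  underlying composition (the generator's split is binomial from the
  same counts); platform-specific primer bias would enter the share
  estimate directly.
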