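---
title: "Deriving and validating tumor-stroma microenvironment signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and validating tumor-stroma microenvironment signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muenvsig)
```

## The model

Paracrine signaling from activated stroma changes tumor-cell transcription.
The analysis implemented here captures that change *in vitro* — breast
cancer cell lines of three molecular subtypes treated with conditioned
medium from cancer-associated fibroblasts (CAF) versus normal fibroblasts
(NAF) — and transfers it to clinical tumors as a correlation score. A tumor
whose mean-centered expression of the signature genes has Spearman
correlation above zero with the CAF-treated reference centroid is called
microenvironment-positive (μENV+); the prognostic value of that dichotomy
for distant-metastasis-free survival is then assessed within the tumor's
own subtype.

Five statistical components carry the analysis, and each is implemented in
this package rather than delegated (established packages — `limma`,
`survival`, `fgsea`, `mclust` — appear only as independent oracles in the
test suite):

1. **Moderated-t class comparison.** Per gene, a linear model
   `expression ~ condition + cell_line` is fitted to the CAF-CM and NAF-CM
   arrays of one subtype. Cell line enters as a fixed blocking factor: the
   comparison the signature needs is "CAF vs NAF within subtype", and
   blocking absorbs between-line baseline differences (pooling is available
   via `block_cell_line = FALSE`). Serum-free control arrays are excluded
   from this contrast. Residual variances are shrunk toward a
   scaled-inverse-chi-square prior whose parameters (d₀, s₀²) are estimated
   by matching the empirical mean and variance of log s² to their
   digamma/trigamma expressions, inverting the trigamma equation by Newton
   iteration; d₀ is clipped to [0.1, 10⁶] and values above 10⁵ are flagged
   effectively infinite. DE calls require p < 10⁻⁴ *and* natural-scale fold
   change outside (0.67, 1.5), all inequalities strict — a fold change of
   exactly 1.5 is not called.

2. **Preranked enrichment.** Gene sets are scored on the moderated-t
   ranking with the weighted-KS statistic (weight 1 by default; weight 0
   reduces to classical KS). The null is gene-set permutation — random
   same-size sets from the ranked universe — which is the matching null for
   a preranked analysis; NES normalizes by the mean absolute null score of
   matching sign, and FDR pools the sign-matched normalized null scores
   across sets. Rank ties are broken by gene id so runs are reproducible.

3. **Signature and scoring.** The centroid is the mean centered expression
   of the DE genes over the subtype's CAF-treated arrays, with the
   cell-line collection centered across *all* its arrays (all subtypes and
   conditions); each cohort is centered within itself. Scoring uses
   Spearman correlation, making calls invariant to any strictly increasing
   transform of a tumor's profile. Dichotomization is strict at zero; ρ
   exactly 0 is negative. A minimum overlap of 10 genes between signature
   and cohort is enforced — below that, a rank correlation over so few
   points is too unstable to dichotomize. A zero-variance tumor profile
   leaves ρ undefined; such samples are reported negative with a warning
   rather than dropped, so subtype cohorts stay complete.

4. **Subtype gating.** Cohorts are partitioned on the *ESR1* and *ERBB2*
   reporter rows: ERBB2 above its cut is HER2+ regardless of ESR1;
   otherwise ESR1 above its cut is ER+/HER2−, else ER−/HER2−. The cuts are
   estimated by a two-component normal-mixture EM (10 seeded restarts,
   component-sd floor) with the threshold at the posterior-membership
   crossing between the component means. Degenerate fits — a component
   weight under 0.02, or no density dip between the components (the dip
   ratio exceeding 0.9 indicates a unimodal shape) — raise an error
   advising a manual threshold rather than returning a meaningless cut.

5. **Survival.** Kaplan–Meier with Greenwood variance, the two-group
   log-rank test, and Cox regression by Newton–Raphson on the partial
   likelihood with Efron tie handling (Breslow available; the Breslow-mode
   score test at β = 0 equals the log-rank statistic without ties, which
   the tests exploit as a cross-module identity). Wald intervals and
   p-values are reported, matching the (HR, CI, p) style of clinical
   tables; a likelihood-ratio p is also available. The proportional-hazards
   assumption is checked with the Grambsch–Therneau test: Schoenfeld
   residuals (Efron-averaged within tied times), scaled by the fit's
   covariance, regressed on g(t).

## Time-varying effects

The multivariable model includes a GGI-by-time interaction because the
Genomic Grade Index violates proportional hazards. The interaction is
implemented generally: follow-up is episode-split at the distinct event
times and the interaction column x·g(t) is evaluated at each episode's stop
time, so the same engine fits any time-varying coefficient.

The functional form of g is a genuine design choice — the source analyses
name the term without defining it. This package uses **g(t) = log(max(t, 1
month))** for the fitted interaction, the Schoenfeld transform, *and* the
generator, for two reasons. First, keeping the three identical makes
diagnostics, remediation and simulation self-consistent: what the generator
plants is exactly what the fitter can recover. Second, the floor at one
month is required for the generative model to be proper: with a strongly
negative interaction coefficient (the planted multivariable world uses
log(0.112) ≈ −2.19), an unfloored log-time hazard h(t) ∝ t^(−2.19) has a
divergent cumulative hazard at t → 0, which would force every GGI-high
patient to an immediate event. With the floor, GGI-high patients carry a
large early hazard that plateaus — a burst-then-cure shape whose cumulative
hazard is bounded, so some GGI-high patients never event. A practical
consequence, visible in the tests, is that GGI-high events are few; in
about 1 fit in 3 at n = 297 the two GGI terms are weakly identified and the
partial likelihood plateaus along one direction. The Cox engine handles
this the way the field's reference implementation does: capped Newton
steps, plateau-as-convergence, and a warning that the drifting coefficient
may be infinite. Erroring instead would discard a third of simulated
cohorts and select against exactly the seeds with rare GGI events.

"Ten-year" quantities use administrative censoring at 120 months before
fitting (`ten_year = TRUE`); a landmark analysis would be the alternative
reading, but censoring is the conservative choice and is applied uniformly.

## What the generators emulate

`simulate_cellline_experiment()` reproduces the design of the treatment
experiment: 3 subtypes × 3 lines × 3 conditions (CAF-CM, NAF-CM, serum-free
control) × 3 replicates = 81 arrays over 22,000 gene-level probes. At that
gene count the expected number of null genes passing p = 10⁻⁴ is 2.2 per
contrast, which the null-simulation tests verify. Gene-wise variances are
drawn from the scaled-inverse-chi-square prior implied by (d₀ = 4,
s₀² = 0.04) — typical bead-array moderation parameters — so the
moderated-t model is exactly well-specified and prior recovery can be
tested. Planted DE counts default to 69/114/10 (luminal/HER2/basal) with
80% upregulated *within each subtype block*, planted |log2FC| uniform on
[1, 2.5], per-(gene, line) offsets of sd 0.2 to make the blocking factor
meaningful, and detection p-values under 0.01 for expressed genes (95% of
genes; planted DE genes always).

`simulate_cohort()` emulates a pooled clinical collection: subtype mix
(default 55/15/30%), latent activation fractions 0.43/0.64/0.79 per
subtype, bimodal reporter rows with ≥ 5 pooled-sd separation (the observed
clinical distributions are strongly bimodal, and at that separation the
mixture threshold misclassifies under 2% of samples), and per-gene noise sd
0.35 — a typical log2 residual spread for array cohorts. Activated tumors
recapitulate the in-vitro response *proportionally*: each signature gene
moves by `effect_size` (default 1) times its centroid value. The
proportional imprint matters: a uniform per-gene shift makes all signature
genes move identically, and for a small same-direction signature the
centroid correlation would then carry no rank information at all — an
early version of the generator had exactly that defect, exposed by a
truth-recovery test on the 10-gene basal signature. Survival times come
from an exponential baseline (closed-form inversion; proportional hazards
holds exactly except for the deliberately time-varying GGI term) scaled by
exp(Σβx); independent exponential dropout (rate 0.003/month) plus
administrative censoring at 180 months; the baseline rate can be tuned to
an expected event count by numeric integration over the enumerated
covariate patterns (`tune_baseline_hazard()`). Treated-cohort analogues
(tamoxifen/chemotherapy collections, where μENV status carries no signal)
are simulated by attenuating the μENV coefficient toward zero
(`muenv_attenuation`).

What the generators do **not** emulate: probe-level bead data, platform
batch structure, correlated gene–gene noise, immune/stromal admixture in
the bulk profile, or informative censoring. Passing tests therefore
demonstrate that the estimators recover what the model plants — not that
the biological signatures would validate in new clinical data.

## Calibration facts the tests pin down

- A cohort with no activation signal (activated fraction 0, or effect size
  0) is classified μENV-positive at ~50%: mean-centering makes ρ > 0 a
  median split under the null. The same logic underlies the
  subtype-specificity control — scoring a cohort with another subtype's
  signature gives ~50% positives and a Cox interval that covers HR 1.
- With default settings, classification agrees with the latent activation
  state for ≥ 99% of samples on the 69-gene luminal signature and ~98% on
  the 10-gene basal signature.
- Hazard-ratio recovery is reported as the geometric mean across seeds
  (averaging log HR): the arithmetic mean of a ratio estimator at ~53
  events carries a Jensen bias of roughly +0.2 that reflects the averaging
  convention rather than the estimator.

## Numerical choices

- Zero residual variance is floored at 10⁻¹² with a warning (relevant only
  for noise-free simulations).
- Quantile normalization resolves rank ties by averaging the two adjacent
  rank means; on tie-free data it is exactly idempotent.
- Probe collapse breaks residual ties lexicographically by probe id.
- Newton–Raphson convergence: |Δ log-likelihood| < 10⁻⁹, at most 100
  iterations, steps capped at 3 per component, step-halving with a
  ridge fallback for ill-conditioned information matrices.
- The mixture EM floors component sds at 10⁻³ of the data sd so a
  component cannot collapse onto a single point.
- GSEA permutation p-values use an add-one correction, (1 + #{null ≥
  obs})/(1 + #{null, matching sign}).

## Problem sizes

The test suite and acceptance script scale simulations to what the checks
need: hazard-ratio recovery uses 297-patient cohorts (the size of the
multivariable clinical table, ~53 events) over 200–1000 seeds;
positive-rate calibration uses cohorts of 600–1000; null calibrations use
20,000-gene matrices (DE), 500–800-gene rankings (GSEA) and 300-patient
cohorts over 500 seeds (Schoenfeld size). Cell-line simulations for
signature derivation run at the full 22,000 genes where the chance-DE
expectation matters and at 300–3000 genes where only the planted blocks are
exercised.

## Known limitations

- The detection filter precedes normalization in `run_pipeline()`; the
  original order is not documented and the statistics downstream depend
  only on relative values, but the choice is a convention, not a fact.
- Robust spline normalization is platform-specific and is replaced by
  ordinary quantile normalization — deterministic, rank-preserving, and
  sufficient for the rank-based scoring downstream.
- Whether the original Spearman scoring used all DE genes or
  direction-weighted subsets is not stated; all DE genes with their
  centroid values are used here.
- The bimodal-threshold estimator operationalizes "cuts defined from the
  bimodal distribution"; the original cut values were never printed, so
  agreement can only be checked on synthetic mixtures.
- Firth penalization for separated Cox fits, competing risks, frailty
  terms, and leading-edge extraction for GSEA are out of scope.
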