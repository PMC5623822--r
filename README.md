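# muenvsig

Subtype-specific tumor–stroma microenvironment signatures for breast cancer.

## The problem

Most prognostic gene expression signatures for breast cancer read out
tumor-intrinsic programs. This package implements a complementary idea:
profile what the *stroma does to the tumor cell*. Breast cancer cell lines of
the three major molecular subtypes (luminal/ER+, HER2+, basal-like) are
exposed to conditioned medium from cancer-associated fibroblasts (CAF) versus
normal fibroblasts (NAF); the genes a subtype's lines modulate specifically
under CAF medium define that subtype's **microenvironment (μENV) signature**.
A clinical tumor is then called **μENV-positive** when its expression profile
correlates positively with the CAF-treated reference centroid, and μENV
status is evaluated as a prognostic factor for distant-metastasis-free
survival (DMFS) within the matching subtype.

The package is aimed at computational biologists who want to run, extend, or
stress-test this kind of signature pipeline. Because the original clinical
collections are external microarray cohorts, the package ships seeded
synthetic-data generators that emulate every input — the cell-line treatment
experiment, cohorts with bimodal *ESR1*/*ERBB2* reporters, a latent
stromal-activation state imprinted on signature genes, and survival outcomes
with planted hazard ratios — so each stage is testable by parameter recovery.

## The method

1. **Preprocessing** — quantile normalization, detection-p filtering
   (p < 0.01 in ≥ 1 sample), probe→gene collapse by detection rate then IQR.
2. **Class comparison** — per-gene linear model `expression ~ condition +
   cell_line` (CAF-CM vs NAF-CM within subtype), empirical-Bayes variance
   moderation: s̃² = (d₀s₀² + d·s²)/(d₀ + d), t = β̂/(s̃·c) on d₀ + d df,
   with (d₀, s₀²) estimated by matching the moments of log s² to
   digamma/trigamma expressions. DE genes satisfy p < 10⁻⁴ and FC > 1.5 or
   FC < 0.67 (strict).
3. **Enrichment** — preranked GSEA on the moderated-t ranking:
   weighted-KS enrichment score, gene-set permutation null, sign-matched NES
   and pooled-null FDR.
4. **Signature & scoring** — centroid = mean centered expression of DE genes
   in the subtype's CAF-treated lines; per-tumor score = Spearman ρ between
   centroid and the tumor's mean-centered profile; μENV-positive ⇔ ρ > 0.
   Cohort subtype gating uses bimodal thresholds on the *ESR1*/*ERBB2*
   reporters (two-component normal mixture, posterior crossing).
5. **Survival** — Kaplan–Meier, log-rank, Cox proportional hazards
   (Newton–Raphson on the Efron partial likelihood, counting-process data),
   a GGI-by-time interaction via episode splitting with g(t) = log(max(t, 1
   month)), and Grambsch–Therneau Schoenfeld-residual diagnostics.

All of steps 2–5 are implemented in-package; `limma`, `fgsea`, `survival`
and `mclust` serve only as independent cross-checks in the test suite.

## Worked example

```r
library(muenvsig)

# 1. cell-line experiment (22,000 genes, 9 lines x 3 conditions x 3 reps)
sim <- simulate_cellline_experiment(cellline_sim_config(seed = 1))
em  <- filter_probes(quantile_normalize(sim$matrix))

# 2. moderated-t contrast and DE calling for the luminal subtype
ct <- fit_linear_contrast(em, sim$design, "luminal")
de <- call_de(ct, de_thresholds())
nrow(de)
#> [1] 67        # 69 genes were planted

# 3. signature and cohort scoring
sig <- build_signature(de, mean_center(em), sim$design, "luminal")
sig
#> MuEnvSignature (luminal): 67 genes (54 up, 13 down)

cohort <- simulate_cohort(
  cohort_sim_config(n_patients = 600,
                    subtype_fracs = c(luminal = 1, HER2 = 0, basal = 0),
                    hazard_coefs = c(muenv = log(2.546)),
                    target_events = 107, seed = 2),
  sig)
calls <- classify_muenv(mean_center(cohort$matrix), sig)
mean(calls$status == "positive")
#> [1] 0.427     # planted activation fraction: 0.43

# 4. prognosis of the dichotomized muENV status
fit <- cox_fit(data.frame(muenv = as.integer(calls$status == "positive")),
               cohort$annotation$time_months, cohort$annotation$event)
fit
#> Cox fit (efron ties): n = 600, events = 110, loglik = -655.316
#>   term   beta     se    hr ci_low ci_high   wald_p
#>  muenv 0.9184 0.1964 2.505  1.705   3.681 2.92e-06
```

The recovered hazard ratio (2.505, 95% CI 1.71–3.68) matches the planted
HR of 2.546: tumors scored μENV-positive carry a ~2.5-fold higher hazard of
distant metastasis in this luminal cohort. `run_pipeline()` (or
`inst/scripts/muenv-pipeline.R` from a shell) chains every stage and writes
per-stage TSV artifacts plus a JSON run manifest.

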