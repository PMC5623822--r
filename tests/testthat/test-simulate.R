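test_that("cell-line simulator emits the designed dimensions and is deterministic", {
  cfg <- cellline_sim_config(seed = 2)
  sim <- simulate_cellline_experiment(cfg)
  # 3 subtypes x 3 lines x 3 conditions x 3 replicates = 81 arrays
  expect_equal(dim(sim$matrix$values), c(22000, 81))
  expect_equal(nrow(sim$design), 81)
  expect_false(is.null(sim$matrix$detection_p))
  expect_equal(nrow(sim$truth$planted_de), 69 + 114 + 10)

  sim2 <- simulate_cellline_experiment(cfg)
  expect_identical(sim$matrix$values, sim2$matrix$values)
  expect_identical(sim$truth$planted_de, sim2$truth$planted_de)
})

test_that("planted DE genes are always detected and shifts sit in the right cells", {
  sim <- small_sim(seed = 91, n_genes = 500, noise_scale = 0)
  planted <- sim$truth$planted_de
  # detection: planted genes pass the filter
  expect_true(all(planted$gene_id %in%
                    rownames(filter_probes(sim$matrix)$values)))
  # at zero noise the CAF-vs-NAF difference equals the planted log2fc
  for (k in sample(nrow(planted), 10)) {
    g <- planted$gene_id[k]; st <- planted$subtype[k]
    d <- sim$design
    caf <- d$sample_id[d$subtype == st & d$condition == "CAF_CM"]
    naf <- d$sample_id[d$subtype == st & d$condition == "NAF_CM"]
    obs <- mean(sim$matrix$values[g, caf]) - mean(sim$matrix$values[g, naf])
    expect_equal(obs, planted$true_log2fc[k], tolerance = 1e-10)
    # other subtypes untouched
    caf_other <- d$sample_id[d$subtype != st & d$condition == "CAF_CM"]
    naf_other <- d$sample_id[d$subtype != st & d$condition == "NAF_CM"]
    expect_equal(mean(sim$matrix$values[g, caf_other]) -
                   mean(sim$matrix$values[g, naf_other]), 0,
                 tolerance = 1e-10)
  }
})

test_that("null cell-line simulation: chance DE near n_genes x 1e-4", {
  counts <- vapply(1:12, function(s) {
    sim <- simulate_cellline_experiment(cellline_sim_config(
      n_genes = 20000, de_counts = c(luminal = 0, HER2 = 0, basal = 0),
      seed = 700 + s))
    ct <- fit_linear_contrast(sim$matrix, sim$design, "luminal")
    sum(ct$p < 1e-4)
  }, numeric(1))
  # expected 2 per run; mean over 12 runs within broad Poisson bounds
  expect_gt(mean(counts), 0.5)
  expect_lt(mean(counts), 5)
})

test_that("cohort simulator is deterministic and records coherent truth", {
  sim <- small_sim(seed = 95, n_genes = 400)
  sig <- signature_from_truth(sim$truth, "luminal")
  cfg <- one_subtype_cohort("luminal", n = 150, seed = 5)
  co1 <- simulate_cohort(cfg, sig)
  co2 <- simulate_cohort(cfg, sig)
  expect_identical(co1$matrix$values, co2$matrix$values)
  expect_identical(co1$annotation, co2$annotation)
  expect_equal(nrow(co1$annotation), 150)
  expect_true(all(co1$annotation$time_months > 0))
  expect_true(all(co1$annotation$event %in% 0:1))
  expect_true(all(sig$genes$gene_id %in% rownames(co1$matrix$values)))
  # raw covariates consistent with the binary truth
  d <- dichotomize_covariates(co1$annotation)
  expect_equal(d$age_hi, co1$truth$covariates$age_hi)
  expect_equal(d$size_hi, co1$truth$covariates$size_hi)
  expect_equal(d$ggi_hi, co1$truth$covariates$ggi_hi)
})

test_that("reporter bimodality: recovered cuts misclassify under 2% of subtype truth", {
  sim <- small_sim(seed = 97, n_genes = 400)
  sigs <- lapply(setNames(c("luminal", "HER2", "basal"),
                          c("luminal", "HER2", "basal")),
                 function(st) signature_from_truth(sim$truth, st))
  cfg <- cohort_sim_config(n_patients = 600, n_genes = 400, seed = 9)
  co <- simulate_cohort(cfg, sigs)
  esr1_cut <- bimodal_threshold(co$matrix$values["ESR1", ], seed = 1)
  erbb2_cut <- bimodal_threshold(co$matrix$values["ERBB2", ], seed = 1)
  st <- assign_subtype(co$matrix, as.numeric(esr1_cut),
                       as.numeric(erbb2_cut))
  expect_lt(mean(st != co$truth$subtype_truth), 0.02)
  expect_gt(attr(esr1_cut, "strength"), 4)
})

test_that("event-count tuning hits the target on average across seeds", {
  sim <- small_sim(seed = 99, n_genes = 300)
  sig <- signature_from_truth(sim$truth, "luminal")
  lam <- tune_baseline_hazard(53, 297, c(muenv = log(2.546)),
                              p_muenv = 0.43)
  evs <- vapply(1:100, function(s) {
    cfg <- one_subtype_cohort("luminal", n = 297, seed = 800 + s,
                              baseline_hazard = lam,
                              hazard_coefs = c(muenv = log(2.546)))
    sum(simulate_cohort(cfg, sig)$annotation$event)
  }, numeric(1))
  expect_equal(mean(evs), 53, tolerance = 0.06)
})

test_that("no activation signal means coin-flip classification, both null directions", {
  sim <- small_sim(seed = 101, n_genes = 300)
  sig <- signature_from_truth(sim$truth, "luminal")
  # activated fraction 0: no imprint anywhere
  co0 <- simulate_cohort(one_subtype_cohort(
    "luminal", n = 500, seed = 11,
    activated_frac = c(luminal = 0, HER2 = 0.64, basal = 0.79)), sig)
  call0 <- classify_muenv(mean_center(co0$matrix), sig)
  expect_gt(mean(call0$status == "positive"), 0.35)
  expect_lt(mean(call0$status == "positive"), 0.65)
  # effect size 0: latent state exists but leaves no trace in expression
  co1 <- simulate_cohort(one_subtype_cohort("luminal", n = 500, seed = 12,
                                            effect_size = 0), sig)
  call1 <- classify_muenv(mean_center(co1$matrix), sig)
  agree <- mean((call1$status == "positive") ==
                  (co1$truth$latent_state == "activated"))
  expect_lt(abs(agree - 0.5), 0.12)
  # but the planted hazard is still recovered from the latent labels
  f <- cox_fit(data.frame(muenv = co1$truth$covariates$muenv),
               co1$annotation$time_months, co1$annotation$event)
  expect_gt(f$terms$hr, 1.5)
})

test_that("default effect size: classification agrees with the latent state", {
  sim <- small_sim(seed = 103, n_genes = 500,
                   de_counts = c(luminal = 69, HER2 = 114, basal = 10))
  for (st in c("luminal", "basal")) {
    sig <- signature_from_truth(sim$truth, st)
    co <- simulate_cohort(one_subtype_cohort(st, n = 400, seed = 13), sig)
    call <- classify_muenv(mean_center(co$matrix), sig)
    agree <- mean((call$status == "positive") ==
                    (co$truth$latent_state == "activated"))
    expect_gte(agree, 0.9)
  }
})

test_that("treatment attenuation nulls the muENV hazard association", {
  sim <- small_sim(seed = 107, n_genes = 300)
  sig <- signature_from_truth(sim$truth, "luminal")
  co <- simulate_cohort(one_subtype_cohort(
    "luminal", n = 600, seed = 17, muenv_attenuation = 0,
    treatment = "tam", hazard_coefs = c(muenv = log(2.546))), sig)
  expect_true(all(co$annotation$treatment == "tam"))
  f <- cox_fit(data.frame(muenv = co$truth$covariates$muenv),
               co$annotation$time_months, co$annotation$event)
  expect_true(f$terms$ci_low < 1 && f$terms$ci_high > 1)
})

test_that("subtype-specificity: cross-signature scoring is null (rate and survival)", {
  sim <- small_sim(seed = 109, n_genes = 500,
                   de_counts = c(luminal = 40, HER2 = 40, basal = 15))
  sig_lum <- signature_from_truth(sim$truth, "luminal")
  sig_her2 <- signature_from_truth(sim$truth, "HER2")
  covered <- logical(50)
  rates <- numeric(50)
  for (s in 1:50) {
    co <- simulate_cohort(one_subtype_cohort(
      "luminal", n = 300, seed = 400 + s,
      hazard_coefs = c(muenv = log(2.546))),
      list(luminal = sig_lum, HER2 = sig_her2))
    call <- classify_muenv(mean_center(co$matrix), sig_her2)
    rates[s] <- mean(call$status == "positive")
    muenv <- as.integer(call$status == "positive")
    f <- try(cox_fit(data.frame(muenv = muenv), co$annotation$time_months,
                     co$annotation$event), silent = TRUE)
    covered[s] <- if (inherits(f, "try-error")) NA
                  else f$terms$ci_low < 1 && f$terms$ci_high > 1
  }
  expect_lt(abs(mean(rates) - 0.5), 0.12)
  expect_gte(mean(covered, na.rm = TRUE), 0.9)
})
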