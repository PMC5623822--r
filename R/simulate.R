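#' Configuration for the cell-line treatment simulator
#'
#' Defaults emulate the design of the conditioned-medium experiment: nine
#' breast cancer cell lines (three per subtype) treated with CAF-CM, NAF-CM
#' or serum-free control medium in biological triplicate, profiled on a
#' bead-array style platform with ~22,000 gene-level probes. Planted DE
#' counts per subtype default to 69 (luminal), 114 (HER2) and 10 (basal),
#' with 80% of DE genes upregulated. Gene-wise residual variances are drawn
#' from the scaled-inverse-chi-square prior implied by `(d0, s0_sq)` so the
#' moderated-t hierarchical model is well-specified.
#'
#' @param n_genes Number of gene rows (default 22,000, at which the
#'   expected chance DE count at p = 1e-4 is 2.2; reducible for fast tests).
#' @param lines_per_subtype Cell lines per subtype (default 3).
#' @param replicates Biological replicates per line and condition
#'   (default 3, must be >= 2).
#' @param de_counts Named planted DE counts per subtype.
#' @param frac_up Fraction of planted DE genes that are upregulated
#'   (default 0.8).
#' @param lfc_range Range of planted |log2 fold change| (default 1 to 2.5).
#' @param d0,s0_sq Variance-prior parameters (default d0 = 4, s0_sq = 0.04).
#' @param noise_scale Multiplier on the per-gene residual sd (0 gives a
#'   noise-free matrix for truth-recovery checks).
#' @param line_sd SD of per-gene cell-line offsets (biological blocking
#'   structure removed by the blocked contrast).
#' @param baseline_mean,baseline_sd Distribution of per-gene baseline log2
#'   intensity.
#' @param frac_expressed Fraction of genes emitted as detected (detection
#'   p < 0.01 in all samples); the rest fail the detection filter. Planted
#'   DE genes are always expressed.
#' @param seed Integer seed.
#' @return A `CellLineSimConfig` list.
#' @export
cellline_sim_config <- function(n_genes = 22000, lines_per_subtype = 3,
                                replicates = 3,
                                de_counts = c(luminal = 69, HER2 = 114,
                                              basal = 10),
                                frac_up = 0.8, lfc_range = c(1, 2.5),
                                d0 = 4, s0_sq = 0.04, noise_scale = 1,
                                line_sd = 0.2, baseline_mean = 7,
                                baseline_sd = 1.5, frac_expressed = 0.95,
                                seed = 1) {
  stopifnot(replicates >= 2, sum(de_counts) <= n_genes,
            frac_up >= 0, frac_up <= 1, all(lfc_range >= log2(1.5)))
  structure(list(n_genes = n_genes, lines_per_subtype = lines_per_subtype,
                 replicates = replicates, de_counts = de_counts,
                 frac_up = frac_up, lfc_range = lfc_range, d0 = d0,
                 s0_sq = s0_sq, noise_scale = noise_scale, line_sd = line_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 frac_expressed = frac_expressed, seed = seed),
            class = "CellLineSimConfig")
}

#' Simulate the cell-line conditioned-medium experiment
#'
#' Emits a log2 expression matrix (with detection p-values), the experiment
#' design, and the ground truth. Planted DE genes are shifted by their true
#' log2 fold change in the CAF-CM samples of their own subtype only.
#' Identical config and seed give bit-identical output.
#'
#' @param cfg A [cellline_sim_config()].
#' @return List with `matrix` ([ExpressionMatrix()]), `design` (data.frame:
#'   `sample_id`, `cell_line`, `subtype`, `condition`, `replicate`) and
#'   `truth` (list with `planted_de` data.frame, `expressed` gene ids,
#'   `config`, `seed`).
#' @export
simulate_cellline_experiment <- function(cfg = cellline_sim_config()) {
  stopifnot(inherits(cfg, "CellLineSimConfig"))
  set.seed(cfg$seed)
  subtypes <- names(cfg$de_counts)
  conditions <- c("CAF_CM", "NAF_CM", "CTRL")
  lines <- unlist(lapply(subtypes, function(s)
    paste0(s, "_line", seq_len(cfg$lines_per_subtype))))
  line_subtype <- rep(subtypes, each = cfg$lines_per_subtype)
  design <- expand.grid(replicate = seq_len(cfg$replicates),
                        condition = conditions, cell_line = lines,
                        stringsAsFactors = FALSE)
  design$subtype <- line_subtype[match(design$cell_line, lines)]
  design$sample_id <- paste(design$cell_line, design$condition,
                            design$replicate, sep = ".")
  design <- design[, c("sample_id", "cell_line", "subtype", "condition",
                       "replicate")]
  n_s <- nrow(design)
  genes <- sprintf("G%05d", seq_len(cfg$n_genes))

  # planted DE assignment: disjoint gene blocks per subtype
  n_de <- sum(cfg$de_counts)
  de_gene <- genes[seq_len(n_de)]
  de_subtype <- rep(subtypes, cfg$de_counts)
  # the up/down mix holds within every subtype block, not just globally
  dir_sign <- unlist(lapply(cfg$de_counts, function(k) {
    s <- rep(-1, k)
    if (k > 0) s[sample.int(k, round(cfg$frac_up * k))] <- 1
    s
  }), use.names = FALSE)
  lfc <- dir_sign * stats::runif(n_de, cfg$lfc_range[1], cfg$lfc_range[2])
  planted <- data.frame(gene_id = de_gene, subtype = de_subtype,
                        true_log2fc = lfc,
                        direction = ifelse(lfc > 0, "up", "down"),
                        stringsAsFactors = FALSE)

  mu <- stats::rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  # scaled-inverse-chi-square prior: s2_g = d0*s0^2 / chi2_{d0}
  s2_g <- cfg$d0 * cfg$s0_sq / stats::rchisq(cfg$n_genes, df = cfg$d0)
  sd_g <- sqrt(s2_g) * cfg$noise_scale

  vals <- matrix(mu, nrow = cfg$n_genes, ncol = n_s)
  line_eff <- matrix(stats::rnorm(cfg$n_genes * length(lines),
                                  sd = cfg$line_sd),
                     nrow = cfg$n_genes)
  vals <- vals + line_eff[, match(design$cell_line, lines)]
  caf_cols <- which(design$condition == "CAF_CM")
  for (i in seq_len(n_de)) {
    cols <- caf_cols[design$subtype[caf_cols] == de_subtype[i]]
    vals[i, cols] <- vals[i, cols] + lfc[i]
  }
  vals <- vals + matrix(stats::rnorm(cfg$n_genes * n_s, sd = rep(sd_g, n_s)),
                        nrow = cfg$n_genes)
  dimnames(vals) <- list(genes, design$sample_id)

  expressed <- rep(TRUE, cfg$n_genes)
  n_unexpr <- round((1 - cfg$frac_expressed) * cfg$n_genes)
  if (n_unexpr > 0) {
    candidates <- setdiff(seq_len(cfg$n_genes), seq_len(n_de))
    expressed[sample(candidates, min(n_unexpr, length(candidates)))] <- FALSE
  }
  dp <- matrix(stats::runif(cfg$n_genes * n_s, 0.01, 1),
               nrow = cfg$n_genes)
  dp[expressed, ] <- stats::runif(sum(expressed) * n_s, 0, 0.009)
  dimnames(dp) <- dimnames(vals)

  list(matrix = ExpressionMatrix(vals, detection_p = dp,
                                 platform = "synthetic-beadarray"),
       design = design,
       truth = list(planted_de = planted, expressed = genes[expressed],
                    config = cfg, seed = cfg$seed))
}

#' Signature object from simulator ground truth
#'
#' Builds the planted subtype signature directly from a
#' [simulate_cellline_experiment()] truth record: the planted DE genes with
#' their directions, and the planted log2 fold changes as the centroid
#' reference levels. Useful for calibration studies that need the exact
#' imprinted signature rather than one re-derived through the DE pipeline.
#'
#' @param truth The `truth` element of a simulation result.
#' @param subtype Subtype label.
#' @return A `MuEnvSignature`.
#' @export
signature_from_truth <- function(truth, subtype) {
  pd <- truth$planted_de[truth$planted_de$subtype == subtype, , drop = FALSE]
  if (!nrow(pd)) stop("no planted DE genes for subtype ", subtype)
  structure(list(subtype = subtype,
                 genes = data.frame(gene_id = pd$gene_id,
                                    direction = pd$direction,
                                    stringsAsFactors = FALSE),
                 centroid = stats::setNames(pd$true_log2fc, pd$gene_id),
                 provenance = list(source = "simulation ground truth",
                                   seed = truth$seed)),
            class = "MuEnvSignature")
}

#' Configuration for the clinical-cohort simulator
#'
#' Defaults emulate a pooled node-negative untreated collection: subtype mix
#' with latent microenvironment-activation fractions of 0.43 (luminal/
#' ER+HER2-), 0.64 (HER2+) and 0.79 (basal/ER-HER2-); bimodal ESR1/ERBB2
#' reporter rows; activated tumors carrying the subtype signature imprint;
#' and distant-metastasis-free survival driven by planted log-hazard
#' coefficients with an optional GGI-by-time interaction (g(t) =
#' [g_logtime()]).
#'
#' @param n_patients Cohort size.
#' @param subtype_fracs Named subtype fractions (must sum to 1).
#' @param activated_frac Named latent activation fraction per subtype.
#' @param effect_size Multiplier on the signature centroid applied to a
#'   subtype's signature genes in activated samples (default 1: activated
#'   tumors recapitulate the in-vitro response gene-for-gene).
#' @param noise_sd Per-gene residual sd on the log2 scale (default 0.35).
#' @param n_genes Total gene rows (signature genes + reporters + filler).
#' @param esr1_mix,erbb2_mix Two-component normal mixture parameters for
#'   the reporter rows: list(mu = c(neg, pos), sd = c(neg, pos)).
#' @param hazard_coefs Named log-hazard coefficients among `muenv`,
#'   `age_hi`, `size_hi`, `ggi_hi`, `ggi_gtime`.
#' @param covariate_prev Prevalence of each binary clinical covariate
#'   (default 0.5).
#' @param baseline_hazard Events per month for the reference patient; when
#'   NULL it is tuned with [tune_baseline_hazard()] to hit `target_events`.
#' @param target_events Expected number of events to tune the baseline to
#'   (used when `baseline_hazard` is NULL; default 53 per 297 luminal
#'   patients scaled to `n_patients`).
#' @param censor_rate Rate of the independent exponential dropout process
#'   (default 0.003 / month).
#' @param horizon Administrative censoring horizon in months (default 180).
#' @param muenv_attenuation Multiplier on the `muenv` coefficient, a knob
#'   for emulating treated collections where the association is nulled
#'   (default 1 = untreated).
#' @param treatment Treatment label recorded in the annotation.
#' @param seed Integer seed.
#' @return A `CohortSimConfig` list.
#' @export
cohort_sim_config <- function(n_patients = 826,
                              subtype_fracs = c(luminal = 0.55, HER2 = 0.15,
                                                basal = 0.30),
                              activated_frac = c(luminal = 0.43,
                                                 HER2 = 0.64, basal = 0.79),
                              effect_size = 1, noise_sd = 0.35,
                              n_genes = 2000,
                              esr1_mix = list(mu = c(6, 11),
                                              sd = c(0.8, 0.8)),
                              erbb2_mix = list(mu = c(7, 12),
                                               sd = c(0.8, 0.8)),
                              hazard_coefs = c(muenv = log(2.546)),
                              covariate_prev = 0.5,
                              baseline_hazard = NULL, target_events = NULL,
                              censor_rate = 0.003, horizon = 180,
                              muenv_attenuation = 1, treatment = "none",
                              seed = 1) {
  stopifnot(abs(sum(subtype_fracs) - 1) < 1e-8,
            all(activated_frac >= 0), all(activated_frac <= 1),
            all(names(subtype_fracs) %in% names(activated_frac)))
  structure(list(n_patients = n_patients, subtype_fracs = subtype_fracs,
                 activated_frac = activated_frac, effect_size = effect_size,
                 noise_sd = noise_sd, n_genes = n_genes,
                 esr1_mix = esr1_mix, erbb2_mix = erbb2_mix,
                 hazard_coefs = hazard_coefs,
                 covariate_prev = covariate_prev,
                 baseline_hazard = baseline_hazard,
                 target_events = target_events, censor_rate = censor_rate,
                 horizon = horizon, muenv_attenuation = muenv_attenuation,
                 treatment = treatment, seed = seed),
            class = "CohortSimConfig")
}

# Cumulative hazard at time t for baseline lambda, linear predictor eta and
# time-interaction exponent a (hazard ~ t^a for t > 1, constant below).
# All arguments recycle against each other.
cum_hazard <- function(t, lambda, eta, a) {
  n <- max(length(t), length(lambda), length(eta), length(a))
  t <- rep_len(t, n); a <- rep_len(a, n)
  base <- rep_len(lambda, n) * exp(rep_len(eta, n))
  tc <- pmax(t, 1)  # integral of s^a from 1 to t, guarded below t = 1
  inner <- ifelse(abs(a + 1) < 1e-12, log(tc), (tc^(a + 1) - 1) / (a + 1))
  ifelse(t <= 1, base * t, base * (1 + inner))
}

# Inverse of cum_hazard in t for a draw u = -log(U); Inf when the bounded
# cumulative hazard is never reached (a < -1 tail plateau).
inv_cum_hazard <- function(u, lambda, eta, a) {
  n <- max(length(u), length(lambda), length(eta), length(a))
  u <- rep_len(u, n); a <- rep_len(a, n)
  base <- rep_len(lambda, n) * exp(rep_len(eta, n))
  m <- u / base - 1
  val <- 1 + m * (a + 1)
  tail_t <- ifelse(abs(a + 1) < 1e-12, exp(m),
                   ifelse(val <= 0, Inf, val^(1 / (a + 1))))
  ifelse(u <= base, u / base, tail_t)
}

#' Tune the baseline hazard to an expected event count
#'
#' Solves for the exponential baseline rate at which the expected number of
#' observed events (accounting for the planted covariate effects, the
#' independent censoring process and the administrative horizon) equals
#' `target_events`. Expectation is computed by numeric integration over the
#' enumerated binary covariate patterns.
#'
#' @param target_events Desired expected event count.
#' @param n_patients Cohort size.
#' @param hazard_coefs Named log-hazard coefficients (see
#'   [cohort_sim_config()]).
#' @param p_muenv Probability of the latent activation indicator.
#' @param covariate_prev Prevalence of the other binary covariates.
#' @param censor_rate,horizon Censoring parameters.
#' @return Baseline hazard (events/month).
#' @export
tune_baseline_hazard <- function(target_events, n_patients, hazard_coefs,
                                 p_muenv, covariate_prev = 0.5,
                                 censor_rate = 0.003, horizon = 180) {
  covs <- c("muenv", "age_hi", "size_hi", "ggi_hi")
  active <- covs[covs %in% names(hazard_coefs) | covs == "muenv"]
  grid <- do.call(expand.grid, stats::setNames(
    rep(list(c(0, 1)), length(active)), active))
  prob <- rep(1, nrow(grid))
  for (cv in active) {
    pcv <- if (cv == "muenv") p_muenv else covariate_prev
    prob <- prob * ifelse(grid[[cv]] == 1, pcv, 1 - pcv)
  }
  coef_of <- function(nm) if (nm %in% names(hazard_coefs))
    hazard_coefs[[nm]] else 0
  eta <- as.matrix(grid) %*% vapply(active, coef_of, numeric(1L))
  a_pat <- if ("ggi_gtime" %in% names(hazard_coefs) && "ggi_hi" %in% active)
    grid$ggi_hi * hazard_coefs[["ggi_gtime"]] else rep(0, nrow(grid))

  tgrid <- seq(0, horizon, length.out = 4001)
  tmid <- (tgrid[-1] + tgrid[-length(tgrid)]) / 2
  expected <- function(lambda) {
    tot <- 0
    for (k in seq_len(nrow(grid))) {
      H <- cum_hazard(tgrid, lambda, eta[k], a_pat[k])
      Hm <- cum_hazard(tmid, lambda, eta[k], a_pat[k])
      # P(event in interval, not yet censored) ~ dH * S_T(mid) * S_C(mid)
      tot <- tot + prob[k] *
        sum(diff(H) * exp(-Hm) * exp(-censor_rate * tmid))
    }
    tot * n_patients
  }
  obj <- function(loglam) expected(exp(loglam)) - target_events
  exp(stats::uniroot(obj, c(log(1e-8), log(1)), tol = 1e-10)$root)
}

#' Simulate a clinical cohort with latent microenvironment activation
#'
#' Generates per-patient subtype and latent activation state, a log2
#' expression matrix in which activated samples carry the subtype
#' signature's imprint (each signature gene shifted by `effect_size` along
#' its DE direction) and bimodal ESR1/ERBB2 reporter rows, clinical
#' covariates, and survival outcomes drawn from an exponential baseline
#' scaled by the planted log-hazard coefficients (with the GGI-by-time
#' interaction entering the hazard as `t^(ggi_gtime)` for t > 1 month,
#' i.e. g(t) = [g_logtime()]).
#'
#' @param cfg A [cohort_sim_config()].
#' @param signatures A [build_signature()] result, or a named list of them
#'   keyed by subtype (subtypes without a signature receive no imprint).
#' @return List with `matrix` ([ExpressionMatrix()]), `annotation`
#'   (data.frame: `sample_id`, `time_months`, `event`, `age_years`,
#'   `size_cm`, `ggi`, `treatment`) and `truth` (list with `latent_state`,
#'   `subtype_truth`, `hazard_coefs`, `baseline_hazard`, `covariates`,
#'   `seed`).
#' @export
simulate_cohort <- function(cfg, signatures) {
  stopifnot(inherits(cfg, "CohortSimConfig"))
  if (inherits(signatures, "MuEnvSignature"))
    signatures <- stats::setNames(list(signatures), signatures$subtype)
  stopifnot(is.list(signatures), !is.null(names(signatures)))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  ids <- sprintf("P%05d", seq_len(n))
  subtype <- sample(names(cfg$subtype_fracs), n, replace = TRUE,
                    prob = cfg$subtype_fracs)
  activated <- stats::rbinom(n, 1L,
                             cfg$activated_frac[subtype]) == 1L

  sig_genes <- unique(unlist(lapply(signatures, function(s) s$genes$gene_id)))
  if (length(sig_genes) + 2L > cfg$n_genes)
    stop("n_genes too small for the signature genes plus reporter rows")
  filler <- sprintf("BG%05d", seq_len(cfg$n_genes - length(sig_genes) - 2L))
  genes <- c(sig_genes, "ESR1", "ERBB2", filler)

  mu <- stats::rnorm(length(genes), 7, 1)
  vals <- matrix(mu, nrow = length(genes), ncol = n)
  dimnames(vals) <- list(genes, ids)
  for (st in names(signatures)) {
    sig <- signatures[[st]]
    # activated tumors recapitulate the in-vitro response proportionally:
    # each signature gene moves by effect_size times its centroid level
    shift <- cfg$effect_size * unname(sig$centroid[sig$genes$gene_id])
    cols <- which(subtype == st & activated)
    if (length(cols))
      vals[sig$genes$gene_id, cols] <-
        vals[sig$genes$gene_id, cols] + shift
  }
  vals <- vals + matrix(stats::rnorm(length(genes) * n, sd = cfg$noise_sd),
                        nrow = length(genes))
  # reporter rows from the configured mixtures, conditioned on true subtype
  esr1_pos <- subtype == "luminal" |
    (subtype == "HER2" & stats::runif(n) < 0.5)
  erbb2_pos <- subtype == "HER2"
  draw_mix <- function(pos, mix)
    stats::rnorm(n, mix$mu[pos + 1L], mix$sd[pos + 1L])
  vals["ESR1", ] <- draw_mix(as.integer(esr1_pos), cfg$esr1_mix)
  vals["ERBB2", ] <- draw_mix(as.integer(erbb2_pos), cfg$erbb2_mix)

  # clinical covariates: binary truths with consistent raw backfill
  need <- function(nm) nm %in% names(cfg$hazard_coefs)
  age_hi <- stats::rbinom(n, 1L, cfg$covariate_prev)
  size_hi <- stats::rbinom(n, 1L, cfg$covariate_prev)
  ggi_hi <- stats::rbinom(n, 1L, cfg$covariate_prev)
  age <- ifelse(age_hi == 1, stats::runif(n, 51, 78),
                stats::runif(n, 28, 50))
  size <- ifelse(size_hi == 1, stats::runif(n, 2.1, 5),
                 stats::runif(n, 0.5, 2.0))
  ggi <- ifelse(ggi_hi == 1, stats::runif(n, 0.05, 3),
                stats::runif(n, -3, -0.05))

  coefs <- cfg$hazard_coefs
  if ("muenv" %in% names(coefs))
    coefs[["muenv"]] <- coefs[["muenv"]] * cfg$muenv_attenuation
  lambda <- cfg$baseline_hazard
  if (is.null(lambda)) {
    target <- if (!is.null(cfg$target_events)) cfg$target_events
              else round(53 / 297 * n)
    lambda <- tune_baseline_hazard(
      target, n, coefs, p_muenv = mean(cfg$activated_frac[subtype]),
      covariate_prev = cfg$covariate_prev, censor_rate = cfg$censor_rate,
      horizon = cfg$horizon)
  }
  coef_of <- function(nm) if (need(nm)) coefs[[nm]] else 0
  eta <- coef_of("muenv") * as.integer(activated) +
    coef_of("age_hi") * age_hi + coef_of("size_hi") * size_hi +
    coef_of("ggi_hi") * ggi_hi
  a_i <- if (need("ggi_gtime")) coefs[["ggi_gtime"]] * ggi_hi else rep(0, n)

  for (attempt in 1:10) {
    u <- -log(stats::runif(n))
    t_event <- inv_cum_hazard(u, lambda, eta, a_i)
    cens <- pmin(stats::rexp(n, rate = cfg$censor_rate), cfg$horizon)
    time <- pmin(t_event, cens)
    event <- as.integer(t_event <= cens)
    time <- pmax(time, 1e-6)
    if (sum(event) >= 1L) break
    if (attempt == 10L)
      stop("all draws censored after 10 attempts; ",
           "increase baseline_hazard or target_events")
  }

  ann <- data.frame(sample_id = ids, time_months = time, event = event,
                    age_years = age, size_cm = size, ggi = ggi,
                    treatment = cfg$treatment, stringsAsFactors = FALSE)
  truth <- list(latent_state = stats::setNames(
                  ifelse(activated, "activated", "quiescent"), ids),
                subtype_truth = stats::setNames(subtype, ids),
                hazard_coefs = coefs, baseline_hazard = lambda,
                covariates = data.frame(sample_id = ids,
                                        muenv = as.integer(activated),
                                        age_hi = age_hi, size_hi = size_hi,
                                        ggi_hi = ggi_hi,
                                        stringsAsFactors = FALSE),
                seed = cfg$seed)
  list(matrix = ExpressionMatrix(vals, platform = "synthetic-affy"),
       annotation = ann, truth = truth)
}
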