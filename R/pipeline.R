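#' Pipeline configuration
#'
#' Bundles the settings of an end-to-end run: simulate the cell-line
#' experiment, preprocess, call DE per subtype, run preranked GSEA, build
#' signatures, simulate a cohort, assign subtypes from the bimodal
#' reporters, score and dichotomize, and evaluate prognosis.
#'
#' @param cellline A [cellline_sim_config()].
#' @param cohort A [cohort_sim_config()].
#' @param thresholds DE thresholds from [de_thresholds()].
#' @param gmt_path Optional GMT file for the enrichment stage; when NULL a
#'   collection is assembled from the planted DE sets plus random sets.
#' @param n_perm GSEA permutations (default 1000).
#' @param gsea_weight GSEA weight (default 1).
#' @param min_overlap Minimum signature/cohort gene overlap for scoring.
#' @param subtype_cuts `"auto"` to estimate reporter thresholds with
#'   [bimodal_threshold()], or a named numeric `c(esr1 = ..., erbb2 = ...)`.
#' @param covariates Covariates for the multivariable Cox model (subset of
#'   `age`, `size`, `ggi`); NULL for univariable only.
#' @param tt_var Covariate receiving a time-interaction term (e.g.
#'   `"ggi_hi"`), or NULL.
#' @param ten_year Apply 120-month administrative censoring before fitting.
#' @param cross_signatures If TRUE, additionally score each subtype cohort
#'   with the other subtypes' signatures (negative control).
#' @param seed Master seed for every stochastic stage.
#' @return A `PipelineConfig` list.
#' @export
pipeline_config <- function(cellline = cellline_sim_config(),
                            cohort = cohort_sim_config(),
                            thresholds = de_thresholds(),
                            gmt_path = NULL, n_perm = 1000, gsea_weight = 1,
                            min_overlap = 10, subtype_cuts = "auto",
                            covariates = c("age", "size", "ggi"),
                            tt_var = NULL, ten_year = FALSE,
                            cross_signatures = FALSE, seed = 1) {
  structure(list(cellline = cellline, cohort = cohort,
                 thresholds = thresholds, gmt_path = gmt_path,
                 n_perm = n_perm, gsea_weight = gsea_weight,
                 min_overlap = min_overlap, subtype_cuts = subtype_cuts,
                 covariates = covariates, tt_var = tt_var,
                 ten_year = ten_year, cross_signatures = cross_signatures,
                 seed = seed),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> preprocess (quantile normalization, detection
#' filter) -> moderated-t DE -> preranked GSEA -> signature construction ->
#' cohort simulation -> subtype assignment -> scoring -> survival analysis,
#' writing per-stage TSV artifacts, a JSON run manifest and a log under
#' `out_dir`. Identical config and seed give byte-identical tables. Stage
#' errors abort with the stage name; partial outputs are retained next to
#' a `FAILED` marker file.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory stage results (`signatures`,
#'   `calls`, `cox_fits`, ...) and `manifest`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), out_dir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  log_con <- file(log_path, "w")
  warnings_seen <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    writeLines(msg, log_con); message(msg)
  }
  stage <- function(name, expr) {
    say("stage: ", name)
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        writeLines(paste("FAILED at stage", name, ":", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
        close(log_con)
        stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
             call. = FALSE)
      }),
      warning = function(w) {
        warnings_seen <<- c(warnings_seen,
                            paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  cfg$cellline$seed <- cfg$seed
  cfg$cohort$seed <- cfg$seed + 1L

  sim <- stage("simulate-celllines",
               simulate_cellline_experiment(cfg$cellline))
  em <- stage("preprocess", {
    m <- quantile_normalize(sim$matrix)
    filter_probes(m)
  })
  subtypes <- names(cfg$cellline$de_counts)

  contrasts <- list(); de_sets <- list(); signatures <- list()
  gsea_tabs <- list()
  centered_cl <- mean_center(em)
  for (st in subtypes) {
    ct <- stage(paste0("de-", st),
                fit_linear_contrast(em, sim$design, st))
    contrasts[[st]] <- ct
    de <- call_de(ct, cfg$thresholds)
    de_sets[[st]] <- de
    write_contrast_tsv(ct, file.path(out_dir,
                                     paste0("contrast_", st, ".tsv")),
                       cfg$thresholds)
    utils::write.table(de, file.path(out_dir, paste0("de_", st, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    collection <- stage(paste0("gsea-collection-", st), {
      if (!is.null(cfg$gmt_path)) read_gmt(cfg$gmt_path)
      else synthetic_collection(sim, seed = cfg$seed)
    })
    gs <- stage(paste0("gsea-", st), {
      ranked <- rank_genes(stats::setNames(ct$t_mod, ct$gene_id))
      gsea_preranked(ranked, collection, n_perm = cfg$n_perm,
                     weight = cfg$gsea_weight, seed = cfg$seed)
    })
    gsea_tabs[[st]] <- gs
    utils::write.table(gs, file.path(out_dir, paste0("gsea_", st, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    sig <- stage(paste0("signature-", st),
                 build_signature(de, centered_cl, sim$design, st,
                                 provenance = list(
                                   p_cut = cfg$thresholds$p_cut,
                                   fc_low = cfg$thresholds$fc_low,
                                   fc_high = cfg$thresholds$fc_high,
                                   contrast = paste0("CAF_vs_NAF_", st),
                                   seed = cfg$seed)))
    signatures[[st]] <- sig
    write_signature_tsv(sig, file.path(out_dir,
                                       paste0("signature_", st, ".tsv")))
  }

  cohort <- stage("simulate-cohort", simulate_cohort(cfg$cohort, signatures))
  cuts <- stage("subtype-cuts", {
    if (identical(cfg$subtype_cuts, "auto"))
      c(esr1 = as.numeric(bimodal_threshold(
          cohort$matrix$values["ESR1", ], seed = cfg$seed)),
        erbb2 = as.numeric(bimodal_threshold(
          cohort$matrix$values["ERBB2", ], seed = cfg$seed)))
    else cfg$subtype_cuts
  })
  subtype_call <- stage("subtype-assign",
                        assign_subtype(cohort$matrix, cuts[["esr1"]],
                                       cuts[["erbb2"]]))
  utils::write.table(
    data.frame(sample_id = names(subtype_call), subtype = subtype_call),
    file.path(out_dir, "subtype_assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  centered_cohort <- mean_center(cohort$matrix)
  ann <- cohort$annotation
  dich <- dichotomize_covariates(ann)
  calls <- list(); km_tabs <- list(); cox_fits <- list()
  score_pairs <- lapply(subtypes, function(st) c(st, st))
  if (cfg$cross_signatures)
    score_pairs <- c(score_pairs, unlist(lapply(subtypes, function(a)
      lapply(setdiff(subtypes, a), function(b) c(a, b))), recursive = FALSE))
  for (pair in score_pairs) {
    st_cohort <- pair[1]; st_sig <- pair[2]
    tag <- if (st_cohort == st_sig) st_cohort
           else paste0(st_cohort, "_vs_", st_sig, "sig")
    samples <- names(subtype_call)[subtype_call == st_cohort]
    if (length(samples) < 2L) next
    sub_em <- ExpressionMatrix(
      centered_cohort$values[, samples, drop = FALSE])
    call <- stage(paste0("score-", tag),
                  classify_muenv(sub_em, signatures[[st_sig]],
                                 min_overlap = cfg$min_overlap))
    calls[[tag]] <- call
    utils::write.table(call, file.path(out_dir,
                                       paste0("muenv_calls_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    idx <- match(call$sample_id, ann$sample_id)
    time <- ann$time_months[idx]; event <- ann$event[idx]
    muenv <- as.integer(call$status == "positive")
    if (length(unique(muenv)) < 2L || sum(event) < 2L) {
      say("skipping survival for ", tag, " (degenerate grouping)")
      next
    }
    km <- stage(paste0("km-", tag),
                km_estimate(time, event, ifelse(muenv == 1, "muENV+",
                                                "muENV-")))
    km_tabs[[tag]] <- km
    utils::write.table(km, file.path(out_dir, paste0("km_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    fits <- list()
    fits$univariable <- stage(paste0("cox-uni-", tag),
      cox_fit(data.frame(muenv = muenv), time, event,
              ten_year = cfg$ten_year))
    if (!is.null(cfg$covariates) && st_cohort == st_sig) {
      covtab <- data.frame(muenv = muenv)
      for (cv in cfg$covariates)
        covtab[[paste0(cv, "_hi")]] <- dich[[paste0(cv, "_hi")]][idx]
      fits$multivariable <- stage(paste0("cox-multi-", tag),
        cox_fit(covtab, time, event, tt_var = cfg$tt_var,
                ten_year = cfg$ten_year))
      sch <- stage(paste0("schoenfeld-", tag),
                   schoenfeld_test(fits$multivariable))
      write_coxfit_tsv(fits$multivariable,
                       file.path(out_dir, paste0("cox_multi_", tag, ".tsv")),
                       schoenfeld = sch)
    }
    write_coxfit_tsv(fits$univariable,
                     file.path(out_dir, paste0("cox_uni_", tag, ".tsv")))
    cox_fits[[tag]] <- fits
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("muenvsig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    subtype_cuts = as.list(cuts),
    de_counts = lapply(de_sets, nrow),
    warnings = warnings_seen)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  close(log_con)
  invisible(list(celllines = sim, contrasts = contrasts, de = de_sets,
                 gsea = gsea_tabs, signatures = signatures, cohort = cohort,
                 subtype_cuts = cuts, subtypes = subtype_call,
                 calls = calls, km = km_tabs, cox_fits = cox_fits,
                 manifest = manifest))
}

# Deterministic fingerprint of the config (structure + values).
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  # small rolling hash; avoids a digest dependency
  v <- utf8ToInt(as.character(s))
  h <- 0
  for (ch in v) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Assemble a gene-set collection from the simulated experiment
#'
#' Builds a collection containing each subtype's planted DE gene set (the
#' positive controls expected to enrich) plus random background sets drawn
#' from the simulated universe, for exercising the enrichment stage when no
#' external GMT is supplied.
#'
#' @param sim Result of [simulate_cellline_experiment()].
#' @param n_random Number of random background sets (default 50).
#' @param size_range Size range of the random sets.
#' @param seed Integer seed.
#' @return Named list of gene-id vectors.
#' @export
synthetic_collection <- function(sim, n_random = 50,
                                 size_range = c(15, 100), seed = 1) {
  set.seed(seed)
  genes <- rownames(sim$matrix$values)
  planted <- split(sim$truth$planted_de$gene_id,
                   sim$truth$planted_de$subtype)
  out <- stats::setNames(planted, paste0("PLANTED_", names(planted)))
  for (i in seq_len(n_random)) {
    sz <- sample(size_range[1]:size_range[2], 1L)
    out[[sprintf("RANDOM_%03d", i)]] <- sample(genes, sz)
  }
  out
}
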