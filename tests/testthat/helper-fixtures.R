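# Shared fixture builders; everything is generated in code at test time.

toy_matrix <- function(values, genes = NULL, samples = NULL, dp = NULL) {
  m <- matrix(values, nrow = if (is.null(genes)) 1 else length(genes))
  rownames(m) <- genes %||% paste0("g", seq_len(nrow(m)))
  colnames(m) <- samples %||% paste0("s", seq_len(ncol(m)))
  ExpressionMatrix(m, detection_p = dp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small cell-line experiment reused across DE/signature tests.
small_sim <- function(seed = 11, n_genes = 2000,
                      de_counts = c(luminal = 20, HER2 = 25, basal = 10),
                      ...) {
  simulate_cellline_experiment(cellline_sim_config(
    n_genes = n_genes, de_counts = de_counts, seed = seed, ...))
}

# Preprocessed matrix + signatures derived through the full DE path.
derived_signatures <- function(sim) {
  em <- filter_probes(quantile_normalize(sim$matrix))
  centered <- mean_center(em)
  sigs <- list()
  for (st in names(sim$truth$config$de_counts)) {
    de <- call_de(fit_linear_contrast(em, sim$design, st))
    if (nrow(de))
      sigs[[st]] <- build_signature(de, centered, sim$design, st)
  }
  sigs
}

# One-subtype cohort config shorthand.
one_subtype_cohort <- function(subtype, n = 400, seed = 1, n_genes = 300,
                               ...) {
  fr <- stats::setNames(c(0, 0, 0), c("luminal", "HER2", "basal"))
  fr[subtype] <- 1
  cohort_sim_config(n_patients = n, subtype_fracs = fr, n_genes = n_genes,
                    seed = seed, ...)
}
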