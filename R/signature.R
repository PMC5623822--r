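#' Mean-center an expression matrix
#'
#' Subtracts from every gene its average signal over all samples of the
#' collection, removing between-platform magnitude differences before
#' centroid correlation scoring. Each collection (cell-line compendium,
#' clinical cohort) is centered within itself.
#'
#' @param em An [ExpressionMatrix()] with at least 2 samples.
#' @return The centered [ExpressionMatrix()].
#' @export
mean_center <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (ncol(em$values) < 2L)
    stop("mean-centering requires at least 2 samples")
  out <- em$values - rowMeans(em$values)
  ExpressionMatrix(out, detection_p = em$detection_p, platform = em$platform)
}

#' Build a subtype-specific microenvironment signature
#'
#' The signature's reference centroid is the mean centered expression of the
#' DE genes over the CAF-CM-treated samples of the subtype's cell lines. The
#' input matrix must already be centered over the *full* cell-line
#' collection (all subtypes and conditions) so centroid values are relative
#' to the platform average.
#'
#' @param de data.frame with columns `gene_id`, `direction` (from
#'   [call_de()]).
#' @param centered_em The mean-centered cell-line [ExpressionMatrix()].
#' @param design Experiment design (see [fit_linear_contrast()]).
#' @param subtype Subtype label.
#' @param provenance Optional list stored with the signature (thresholds,
#'   contrast id, ...).
#' @return Object of class `MuEnvSignature`: list with `subtype`, `genes`
#'   (data.frame gene_id/direction), `centroid` (named numeric), and
#'   `provenance`.
#' @export
build_signature <- function(de, centered_em, design, subtype,
                            provenance = list()) {
  stopifnot(inherits(centered_em, "ExpressionMatrix"))
  if (!nrow(de)) stop("no genes pass thresholds; cannot build a signature")
  miss <- setdiff(de$gene_id, rownames(centered_em$values))
  if (length(miss))
    stop("DE gene(s) absent from matrix: ", paste(miss, collapse = ", "))
  caf <- design$sample_id[design$subtype == subtype &
                            design$condition == "CAF_CM"]
  if (!length(caf))
    stop("no CAF_CM samples of subtype ", subtype, " in the design")
  sub <- centered_em$values[de$gene_id, caf, drop = FALSE]
  centroid <- rowMeans(sub)
  structure(list(subtype = subtype,
                 genes = de[, c("gene_id", "direction")],
                 centroid = centroid,
                 provenance = provenance),
            class = "MuEnvSignature")
}

#' @export
print.MuEnvSignature <- function(x, ...) {
  cat(sprintf("MuEnvSignature (%s): %d genes (%d up, %d down)\n",
              x$subtype, nrow(x$genes), sum(x$genes$direction == "up"),
              sum(x$genes$direction == "down")))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tie ranks; errors on constant input,
#' where the rank correlation is undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for a constant vector")
  stats::cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
}

#' Score and dichotomize cohort samples against a signature
#'
#' For every sample, computes the Spearman correlation between the signature
#' centroid (restricted to genes present in the cohort) and the sample's
#' centered expression over the same genes. Samples with rho strictly above
#' zero are microenvironment-positive; rho of exactly 0 is negative. A
#' constant (zero-variance) sample vector leaves rho undefined: the sample
#' is reported negative with a warning rather than dropped, keeping cohort
#' partitions complete.
#'
#' @param centered_em The mean-centered cohort [ExpressionMatrix()].
#' @param sig A [build_signature()] result.
#' @param min_overlap Minimum number of shared genes required (default 10;
#'   below this rank correlation is too unstable to dichotomize).
#' @return data.frame of class `MuEnvCall`: `sample_id`, `rho`, `status`
#'   (`positive`/`negative`), `n_genes_used`.
#' @export
classify_muenv <- function(centered_em, sig, min_overlap = 10) {
  stopifnot(inherits(centered_em, "ExpressionMatrix"),
            inherits(sig, "MuEnvSignature"))
  shared <- intersect(names(sig$centroid), rownames(centered_em$values))
  if (length(shared) < min_overlap) {
    missing <- setdiff(names(sig$centroid), shared)
    stop("only ", length(shared), " signature gene(s) found in the cohort ",
         "(need >= ", min_overlap, ")",
         if (length(missing)) paste0("; missing from cohort: ",
                                     paste(missing, collapse = ", "))
         else "; the signature itself has fewer genes than the floor")
  }
  centroid <- sig$centroid[shared]
  sub <- centered_em$values[shared, , drop = FALSE]
  rho <- vapply(seq_len(ncol(sub)), function(j) {
    x <- sub[, j]
    if (stats::sd(x) == 0) {
      warning("sample ", colnames(sub)[j],
              " has constant expression over signature genes; ",
              "rho undefined, reported negative")
      return(NA_real_)
    }
    spearman_rho(centroid, x)
  }, numeric(1L))
  status <- ifelse(!is.na(rho) & rho > 0, "positive", "negative")
  out <- data.frame(sample_id = colnames(sub), rho = rho, status = status,
                    n_genes_used = length(shared), stringsAsFactors = FALSE)
  class(out) <- c("MuEnvCall", "data.frame")
  out
}

# Log-likelihood of a two-component univariate normal mixture.
mix_loglik <- function(x, w, mu, sd) {
  sum(log(w[1] * stats::dnorm(x, mu[1], sd[1]) +
            w[2] * stats::dnorm(x, mu[2], sd[2])))
}

#' Data-driven threshold from a bimodal distribution
#'
#' Fits a two-component normal mixture by EM (10 seeded random restarts)
#' and returns the point between the component means where the posterior
#' membership probability crosses 0.5. Intended for dichotomizing strongly
#' bimodal reporter expression (ESR1, ERBB2). A bimodality-strength score
#' (component separation over pooled sd) is attached, and degenerate fits
#' (a vanishing component, or no density dip between the means) raise an
#' error advising a manual threshold.
#'
#' @param values Numeric vector, length >= 20.
#' @param n_restarts Number of EM restarts (default 10).
#' @param seed Integer seed for the restarts.
#' @return Numeric threshold, with attributes `strength` (separation /
#'   pooled sd), `means`, `sds`, `weights`.
#' @export
bimodal_threshold <- function(values, n_restarts = 10, seed = 1) {
  stopifnot(length(values) >= 20L)
  x <- as.numeric(values)
  sd_floor <- max(1e-3 * stats::sd(x), 1e-8)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    mu <- sort(sample(x, 2L))
    sd2 <- rep(stats::sd(x) / 2, 2L)
    w <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in 1:500) {
      d1 <- w[1] * stats::dnorm(x, mu[1], sd2[1])
      d2 <- w[2] * stats::dnorm(x, mu[2], sd2[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      g <- d1 / tot
      n1 <- sum(g); n2 <- length(x) - n1
      if (n1 < 1e-8 || n2 < 1e-8) break
      w <- c(n1, n2) / length(x)
      mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
      sd2 <- c(sqrt(sum(g * (x - mu[1])^2) / n1),
               sqrt(sum((1 - g) * (x - mu[2])^2) / n2))
      sd2 <- pmax(sd2, sd_floor)
      ll <- mix_loglik(x, w, mu, sd2)
      if (is.finite(ll) && abs(ll - ll_old) < 1e-8 * (abs(ll_old) + 1)) break
      ll_old <- ll
    }
    ll <- mix_loglik(x, w, mu, sd2)
    if (is.null(best) || (is.finite(ll) && ll > best$ll))
      best <- list(w = w, mu = mu, sd = sd2, ll = ll)
  }
  ord <- order(best$mu)
  w <- best$w[ord]; mu <- best$mu[ord]; s <- best$sd[ord]
  if (min(w) < 0.02)
    stop("degenerate mixture fit (component weight ",
         signif(min(w), 3), " < 0.02); set the threshold manually")
  mixd <- function(t) w[1] * stats::dnorm(t, mu[1], s[1]) +
    w[2] * stats::dnorm(t, mu[2], s[2])
  # posterior crossing: solve w1 f1(t) = w2 f2(t) between the means
  fdiff <- function(t) log(w[1]) + stats::dnorm(t, mu[1], s[1], log = TRUE) -
    log(w[2]) - stats::dnorm(t, mu[2], s[2], log = TRUE)
  if (mu[2] - mu[1] < 1e-10 || fdiff(mu[1]) * fdiff(mu[2]) > 0)
    stop("degenerate mixture fit (no posterior crossing between the means); ",
         "set the threshold manually")
  thr <- stats::uniroot(fdiff, c(mu[1], mu[2]), tol = 1e-10)$root
  strength <- (mu[2] - mu[1]) / sqrt((s[1]^2 + s[2]^2) / 2)
  dip_ratio <- mixd(thr) / min(mixd(mu[1]), mixd(mu[2]))
  if (dip_ratio > 0.9)
    stop("degenerate mixture fit (no density dip between components; ",
         "the distribution looks unimodal); set the threshold manually")
  structure(thr, strength = strength, means = mu, sds = s, weights = w,
            dip_ratio = dip_ratio)
}

#' Assign molecular subtype from ESR1/ERBB2 reporter expression
#'
#' Partition rule: samples with ERBB2 reporter expression above `erbb2_cut`
#' are HER2 regardless of ESR1; of the rest, ESR1 above `esr1_cut` gives
#' luminal (ER+/HER2-) and the remainder basal (ER-/HER2-). The partition is
#' exhaustive and disjoint. Cuts can be set manually or estimated with
#' [bimodal_threshold()].
#'
#' @param em Cohort [ExpressionMatrix()] containing both reporter rows.
#' @param esr1_cut,erbb2_cut Thresholds on the reporter rows.
#' @param esr1_reporter,erbb2_reporter Row ids of the reporters (gene
#'   symbols for symbol-level matrices; probeset ids such as `205225_at` /
#'   `216836_at` are honored when present).
#' @return Named character vector (sample id -> `luminal`/`HER2`/`basal`).
#' @export
assign_subtype <- function(em, esr1_cut, erbb2_cut,
                           esr1_reporter = "ESR1", erbb2_reporter = "ERBB2") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  for (rep_id in c(esr1_reporter, erbb2_reporter))
    if (!rep_id %in% rownames(em$values))
      stop("reporter row ", rep_id, " missing from the matrix")
  esr1 <- em$values[esr1_reporter, ]
  erbb2 <- em$values[erbb2_reporter, ]
  out <- ifelse(erbb2 > erbb2_cut, "HER2",
                ifelse(esr1 > esr1_cut, "luminal", "basal"))
  stats::setNames(out, colnames(em$values))
}

#' Write a signature as TSV plus JSON provenance
#'
#' @param sig A `MuEnvSignature`.
#' @param path Output TSV path (`gene_id`, `direction`, `centroid_value`);
#'   a `.json` sidecar with subtype and provenance is written alongside.
#' @export
write_signature_tsv <- function(sig, path) {
  stopifnot(inherits(sig, "MuEnvSignature"))
  out <- data.frame(gene_id = sig$genes$gene_id,
                    direction = sig$genes$direction,
                    centroid_value = unname(sig$centroid[sig$genes$gene_id]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(subtype = sig$subtype, n_genes = nrow(sig$genes),
         provenance = sig$provenance),
    paste0(sub("\\.tsv$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a signature written by [write_signature_tsv()]
#'
#' @param path TSV path.
#' @param subtype Subtype label (read from the JSON sidecar when present).
#' @return A `MuEnvSignature`.
#' @export
read_signature_tsv <- function(path, subtype = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- paste0(sub("\\.tsv$", "", path), ".json")
  prov <- list()
  if (is.null(subtype) && file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    subtype <- meta$subtype
    prov <- if (!is.null(meta$provenance)) as.list(meta$provenance) else list()
  }
  structure(list(subtype = subtype,
                 genes = tab[, c("gene_id", "direction")],
                 centroid = stats::setNames(tab$centroid_value, tab$gene_id),
                 provenance = prov),
            class = "MuEnvSignature")
}
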