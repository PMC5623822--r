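#' Invert the trigamma function
#'
#' Solves `trigamma(x) = y` for `x > 0` by Newton iteration on a
#' well-conditioned reparameterization. Used by the empirical-Bayes variance
#' prior estimator.
#'
#' @param y Positive numeric vector.
#' @return x such that `trigamma(x) = y`, elementwise.
#' @keywords internal
trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    if (yi < 1e-6) return(1 / yi)
    x <- 0.5 + 1 / yi
    for (i in 1:50) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, 2L)
      x <- x + dif
      if (abs(dif / x) < 1e-10) break
    }
    x
  }, numeric(1L))
}

#' Estimate the variance prior by method of moments
#'
#' Fits the scaled-inverse-chi-square prior of the hierarchical variance
#' model: residual variances `s2` on `df` degrees of freedom are assumed
#' s2 | sigma2 ~ sigma2 * chi2_df / df with sigma2 drawn from the prior
#' (d0, s0^2). The moments of log(s2) are matched to their
#' digamma/trigamma expressions and the trigamma equation inverted
#' numerically.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (scalar).
#' @return List with `d0` (prior df, clipped to \[0.1, 1e6\] and flagged
#'   `infinite` when above 1e5), and `s0_sq` (prior variance).
#' @export
fit_var_prior <- function(s2, df) {
  stopifnot(length(df) == 1L, df > 0, all(s2 > 0))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e) * (length(e) - 1) / length(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- 1e6
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    d0 <- min(max(d0, 0.1), 1e6)
  }
  infinite <- d0 > 1e5
  s0_sq <- if (infinite) exp(mean(e))
           else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq, infinite = infinite)
}

#' Fit the CAF-vs-NAF contrast with empirical-Bayes moderation
#'
#' For every gene fits the linear model `expression ~ condition + cell_line`
#' on the CAF-CM and NAF-CM samples of one subtype (serum-free controls are
#' excluded from this contrast), then shrinks the residual variances toward
#' the prior estimated by [fit_var_prior()] and forms moderated t-statistics
#'
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d_g s^2)/(d_0 + d_g), \quad
#'       t = \beta / (\tilde s \, c)}
#'
#' with `c` the standard-error multiplier of the condition contrast and
#' two-tailed p-values on `d0 + dg` degrees of freedom.
#'
#' @param em An [ExpressionMatrix()] (log2 scale).
#' @param design data.frame with columns `sample_id`, `cell_line`, `subtype`,
#'   `condition` (values `CAF_CM`, `NAF_CM`, `CTRL`), `replicate`.
#' @param subtype Subtype whose cell lines enter the contrast.
#' @param block_cell_line Include cell line as a fixed blocking factor
#'   (default TRUE); set FALSE to pool replicates across lines.
#' @return A data.frame of class `ContrastResult` with one row per gene:
#'   `gene_id`, `log2fc`, `fc`, `avg_expr`, `s2`, `t_mod`, `p`; attributes
#'   `d0`, `s0_sq`, `df_residual`, `df_total`, `se_multiplier`, `subtype`.
#' @export
fit_linear_contrast <- function(em, design, subtype, block_cell_line = TRUE) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  sel <- design$subtype == subtype & design$condition %in% c("CAF_CM", "NAF_CM")
  d <- design[sel, , drop = FALSE]
  if (sum(d$condition == "CAF_CM") < 2L || sum(d$condition == "NAF_CM") < 2L)
    stop("need >= 2 CAF_CM and >= 2 NAF_CM samples of subtype ", subtype)
  miss <- setdiff(d$sample_id, colnames(em$values))
  if (length(miss))
    stop("design samples absent from matrix: ", paste(miss, collapse = ", "))
  Y <- em$values[, d$sample_id, drop = FALSE]
  cond <- factor(d$condition, levels = c("NAF_CM", "CAF_CM"))
  if (block_cell_line && length(unique(d$cell_line)) > 1L) {
    X <- stats::model.matrix(~ cond + factor(d$cell_line))
  } else {
    X <- stats::model.matrix(~ cond)
  }
  df_resid <- nrow(X) - ncol(X)
  if (df_resid < 2L)
    stop("fewer than 2 residual degrees of freedom")
  XtXi <- solve(crossprod(X))
  coef_idx <- 2L  # condCAF_CM
  B <- Y %*% X %*% XtXi            # genes x p coefficient matrix
  resid <- Y - B %*% t(X)
  s2 <- rowSums(resid^2) / df_resid
  n_floored <- sum(s2 < 1e-12)
  if (n_floored > 0L) {
    warning(n_floored, " gene(s) with zero residual variance; floored at 1e-12")
    s2 <- pmax(s2, 1e-12)
  }
  prior <- fit_var_prior(s2, df_resid)
  s2_post <- (prior$d0 * prior$s0_sq + df_resid * s2) / (prior$d0 + df_resid)
  cmult <- sqrt(XtXi[coef_idx, coef_idx])
  log2fc <- B[, coef_idx]
  t_mod <- log2fc / (sqrt(s2_post) * cmult)
  df_total <- prior$d0 + df_resid
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  res <- data.frame(gene_id = rownames(Y), log2fc = log2fc, fc = 2^log2fc,
                    avg_expr = rowMeans(Y), s2 = s2, s2_post = s2_post,
                    t_mod = t_mod, p = p, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "d0") <- prior$d0
  attr(res, "s0_sq") <- prior$s0_sq
  attr(res, "d0_infinite") <- prior$infinite
  attr(res, "df_residual") <- df_resid
  attr(res, "df_total") <- df_total
  attr(res, "se_multiplier") <- cmult
  attr(res, "subtype") <- subtype
  class(res) <- c("ContrastResult", "data.frame")
  res
}

#' Moderated t-statistic from its components
#'
#' Pure helper implementing the shrinkage formula used by
#' [fit_linear_contrast()]: posterior variance
#' `(d0*s0_sq + dg*s2)/(d0 + dg)`, `t = log2fc/(s_tilde * se_multiplier)`,
#' and a two-tailed p on `d0 + dg` df. In the `d0 = Inf` limit the statistic
#' reduces to `log2fc/(s0 * se_multiplier)` with a normal reference.
#'
#' @param log2fc Effect estimate(s).
#' @param s2 Residual variance(s).
#' @param dg Residual degrees of freedom.
#' @param d0,s0_sq Prior degrees of freedom and variance.
#' @param se_multiplier Contrast standard-error multiplier from the design.
#' @return List with `s2_post`, `t_mod`, `p`, `df_total`.
#' @export
moderated_t <- function(log2fc, s2, dg, d0, s0_sq, se_multiplier) {
  if (is.infinite(d0)) {
    s2_post <- rep_len(s0_sq, length(log2fc))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s0_sq + dg * s2) / (d0 + dg)
    df_total <- d0 + dg
  }
  t_mod <- log2fc / (sqrt(s2_post) * se_multiplier)
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod))
       else 2 * stats::pt(-abs(t_mod), df = df_total)
  list(s2_post = s2_post, t_mod = t_mod, p = p, df_total = df_total)
}

#' Default DE thresholds
#'
#' Dual gate used throughout: two-tailed p-value below `p_cut` combined with
#' a biological fold-change cutoff on the natural scale.
#'
#' @param p_cut Two-tailed p-value threshold (default 1e-4, strict).
#' @param fc_low,fc_high Fold-change gates on the natural scale (defaults
#'   0.67 and 1.5, both strict).
#' @return List of thresholds.
#' @export
de_thresholds <- function(p_cut = 1e-4, fc_low = 0.67, fc_high = 1.5) {
  stopifnot(p_cut > 0, p_cut < 1, fc_low > 0, fc_low < 1, fc_high > 1)
  list(p_cut = p_cut, fc_low = fc_low, fc_high = fc_high)
}

#' Call differentially expressed genes
#'
#' A gene is DE iff `p < p_cut` and its natural-scale fold change exceeds
#' `fc_high` or falls below `fc_low` (all inequalities strict; a fold change
#' of exactly 1.5 is not called).
#'
#' @param contrast A `ContrastResult` from [fit_linear_contrast()].
#' @param thresholds From [de_thresholds()].
#' @return data.frame with columns `gene_id`, `direction` (`up`/`down`),
#'   `log2fc`, `p`. May have zero rows.
#' @export
call_de <- function(contrast, thresholds = de_thresholds()) {
  stopifnot(inherits(contrast, "ContrastResult"))
  fc <- 2^contrast$log2fc
  de <- contrast$p < thresholds$p_cut &
    (fc > thresholds$fc_high | fc < thresholds$fc_low)
  out <- data.frame(
    gene_id = contrast$gene_id[de],
    direction = ifelse(fc[de] > thresholds$fc_high, "up", "down"),
    log2fc = contrast$log2fc[de],
    p = contrast$p[de],
    stringsAsFactors = FALSE)
  out[order(out$p, out$gene_id), , drop = FALSE]
}

#' Write a contrast result as TSV
#'
#' @param contrast A `ContrastResult`.
#' @param path Output path.
#' @param thresholds Thresholds used to fill the `de_flag`/`direction`
#'   columns.
#' @export
write_contrast_tsv <- function(contrast, path, thresholds = de_thresholds()) {
  fc <- 2^contrast$log2fc
  de <- contrast$p < thresholds$p_cut &
    (fc > thresholds$fc_high | fc < thresholds$fc_low)
  out <- data.frame(gene_id = contrast$gene_id, log2fc = contrast$log2fc,
                    fc = fc, avg_expr = contrast$avg_expr,
                    t_mod = contrast$t_mod, p = contrast$p,
                    de_flag = as.integer(de),
                    direction = ifelse(de & fc > 1, "up",
                                       ifelse(de, "down", "")))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
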