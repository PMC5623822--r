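#' Rank genes by a statistic, descending, ties broken by gene id
#'
#' @param stats Named numeric vector (names = gene ids).
#' @return Named numeric vector sorted for use with [enrichment_score()].
#' @export
rank_genes <- function(stats) {
  stopifnot(!is.null(names(stats)), !anyDuplicated(names(stats)))
  stats[order(-stats, names(stats), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list: genes in the set increment the running sum by
#' `|stat|^weight / N_R` (`N_R` = sum of `|stat|^weight` over set members),
#' genes outside decrement it by `1/(N - N_hits)`. The enrichment score is
#' the running-sum value of maximal absolute deviation from zero, signed.
#'
#' @param ranked Named numeric vector sorted in decreasing order (see
#'   [rank_genes()]).
#' @param geneset Character vector of gene ids; must intersect the list and
#'   must not cover it entirely.
#' @param weight Exponent on `|stat|` (default 1; 0 gives the classical KS
#'   statistic).
#' @return List with `es` and the full `running_sum` vector (length = list
#'   length).
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  n <- length(ranked)
  hit <- names(ranked) %in% geneset
  n_hits <- sum(hit)
  if (n_hits == 0L) stop("gene set has no overlap with the ranked list")
  if (n_hits == n) stop("gene set covers the entire ranked list")
  w <- abs(ranked)^weight
  nr <- sum(w[hit])
  if (nr == 0) stop("all hit statistics are zero at this weight")
  step <- ifelse(hit, w / nr, -1 / (n - n_hits))
  running <- cumsum(step)
  es <- running[which.max(abs(running))]
  list(es = es, running_sum = running)
}

# ES from hit positions only, O(set size); equivalent to enrichment_score()
# but avoids materializing the full running sum inside permutation loops.
# Extremes occur at peaks (just after a hit) and troughs (just before one).
es_from_positions <- function(pos, w_all, n) {
  s <- length(pos)
  pos <- sort.int(pos)
  wh <- w_all[pos]
  nr <- sum(wh)
  if (nr == 0) return(0)
  miss_dec <- 1 / (n - s)
  cum_hit <- cumsum(wh / nr)
  k <- seq_len(s)
  peaks <- cum_hit - (pos - k) * miss_dec          # just after hit k
  troughs <- c(0, cum_hit[-s]) - (pos - k) * miss_dec  # just before hit k
  hi <- max(peaks)
  lo <- min(troughs)
  if (abs(hi) >= abs(lo)) hi else lo
}

#' Preranked gene set enrichment analysis with permutation FDR
#'
#' Computes the weighted-KS enrichment score of every set against the ranked
#' list, builds a null distribution per set from random same-size gene sets
#' drawn from the ranked universe (gene-set permutation), normalizes scores
#' by the mean absolute null score of matching sign (NES), and derives
#' one-sided permutation p-values and an FDR q-value by pooling the
#' sign-matched normalized null scores across sets.
#'
#' @param ranked Named numeric vector sorted decreasing (see [rank_genes()]).
#' @param collection Named list of gene-id vectors (see [read_gmt()]).
#' @param n_perm Number of permutations per set (>= 100, default 1000).
#' @param weight ES weight (default 1).
#' @param seed Integer seed; results are deterministic given the seed.
#' @return data.frame with one row per scored set: `set_name`, `size_used`,
#'   `es`, `nes`, `p_perm`, `fdr_q`, `direction`. Sets with no overlap are
#'   skipped with a warning.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000, weight = 1,
                           seed = 1) {
  if (!length(collection)) stop("empty gene-set collection")
  stopifnot(n_perm >= 100)
  n <- length(ranked)
  genes <- names(ranked)
  w_all <- abs(ranked)^weight

  overlap <- lapply(collection, function(g) which(genes %in% g))
  sizes <- lengths(overlap)
  skip <- sizes == 0L | sizes == n
  if (any(skip)) {
    warning("skipping ", sum(skip),
            " set(s) with empty or complete overlap: ",
            paste(names(collection)[skip], collapse = ", "))
    overlap <- overlap[!skip]
    sizes <- sizes[!skip]
  }
  if (!length(overlap)) stop("no scorable gene sets in the collection")

  es_obs <- vapply(overlap, es_from_positions, numeric(1L),
                   w_all = w_all, n = n)

  set.seed(seed)
  uniq_sizes <- sort(unique(sizes))
  null_by_size <- lapply(uniq_sizes, function(s) {
    vapply(seq_len(n_perm), function(i)
      es_from_positions(sample.int(n, s), w_all, n), numeric(1L))
  })
  names(null_by_size) <- as.character(uniq_sizes)

  norm_mean <- function(null_es, sign_pos) {
    sel <- if (sign_pos) null_es[null_es >= 0] else -null_es[null_es < 0]
    if (!length(sel)) return(NA_real_)
    mean(sel)
  }

  nes <- p_perm <- numeric(length(es_obs))
  nes_null_pool <- vector("list", length(es_obs))
  for (i in seq_along(es_obs)) {
    null_es <- null_by_size[[as.character(sizes[i])]]
    pos_mean <- norm_mean(null_es, TRUE)
    neg_mean <- norm_mean(null_es, FALSE)
    if (es_obs[i] >= 0) {
      nes[i] <- if (is.na(pos_mean)) NA_real_ else es_obs[i] / pos_mean
      npos <- sum(null_es >= 0)
      p_perm[i] <- (1 + sum(null_es >= es_obs[i])) / (1 + npos)
    } else {
      nes[i] <- if (is.na(neg_mean)) NA_real_ else -(-es_obs[i]) / neg_mean
      nneg <- sum(null_es < 0)
      p_perm[i] <- (1 + sum(null_es <= es_obs[i])) / (1 + nneg)
    }
    # normalized null for the FDR pool (same normalization as the observed)
    nn <- null_es
    nn[nn >= 0] <- if (is.na(pos_mean)) NA_real_ else nn[nn >= 0] / pos_mean
    nn[nn < 0] <- if (is.na(neg_mean)) NA_real_ else nn[nn < 0] / neg_mean
    nes_null_pool[[i]] <- nn[is.finite(nn)]
  }
  pool <- unlist(nes_null_pool, use.names = FALSE)

  fdr_q <- vapply(seq_along(nes), function(i) {
    if (!is.finite(nes[i])) return(NA_real_)
    if (nes[i] >= 0) {
      denom_null <- sum(pool >= 0)
      num <- if (denom_null) sum(pool >= nes[i]) / denom_null else 0
      denom_obs_n <- sum(nes >= 0, na.rm = TRUE)
      den <- if (denom_obs_n) sum(nes >= nes[i], na.rm = TRUE) / denom_obs_n else 1
    } else {
      denom_null <- sum(pool < 0)
      num <- if (denom_null) sum(pool <= nes[i]) / denom_null else 0
      denom_obs_n <- sum(nes < 0, na.rm = TRUE)
      den <- if (denom_obs_n) sum(nes <= nes[i], na.rm = TRUE) / denom_obs_n else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1L))

  data.frame(set_name = names(overlap), size_used = as.integer(sizes),
             es = es_obs, nes = nes, p_perm = p_perm, fdr_q = fdr_q,
             direction = ifelse(es_obs >= 0, "positive", "negative"),
             row.names = NULL, stringsAsFactors = FALSE)
}
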