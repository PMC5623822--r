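#' Default time transform for time-interaction terms
#'
#' Natural log of time in months, floored at one month so the implied
#' hazard stays proper near the time origin. Used for both the fitted
#' GGI-by-time interaction and the Schoenfeld-residual transform, keeping
#' diagnostics and remediation consistent.
#'
#' @param t Time in months.
#' @return log(max(t, 1)).
#' @export
g_logtime <- function(t) log(pmax(t, 1))

#' Dichotomize clinical covariates
#'
#' Cutoffs used throughout the prognosis analysis, all strict: age above 50
#' years, tumor size above 2 cm, Genomic Grade Index above 0.
#'
#' @param ann Clinical annotation data.frame with columns among `age_years`,
#'   `size_cm`, `ggi` (plus `sample_id`).
#' @param covariates Which dichotomized covariates to produce.
#' @return data.frame with `sample_id` and 0/1 columns `age_hi`, `size_hi`,
#'   `ggi_hi` as requested.
#' @export
dichotomize_covariates <- function(ann,
                                   covariates = c("age", "size", "ggi")) {
  out <- data.frame(sample_id = ann$sample_id, stringsAsFactors = FALSE)
  src <- c(age = "age_years", size = "size_cm", ggi = "ggi")
  cut <- c(age = 50, size = 2, ggi = 0)
  for (cv in covariates) {
    col <- src[[cv]]
    if (is.null(ann[[col]]))
      stop("annotation is missing column `", col, "`")
    out[[paste0(cv, "_hi")]] <- as.integer(ann[[col]] > cut[[cv]])
  }
  out
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Optional group labels (one curve per group).
#' @return data.frame with columns `group`, `time` (distinct event times),
#'   `n_risk`, `n_event`, `surv`, `var` (Greenwood), `se`. With all-censored
#'   input the curve is identically 1 (zero rows of events).
#' @export
km_estimate <- function(time, event, group = NULL) {
  stopifnot(all(time > 0), all(event %in% c(0, 1)))
  if (is.null(group)) group <- rep("all", length(time))
  if (any(table(factor(group)) == 0L) || length(time) == 0L)
    stop("empty group")
  out <- lapply(split(seq_along(time), group), function(idx) {
    ti <- time[idx]; ev <- event[idx]
    et <- sort(unique(ti[ev == 1]))
    if (!length(et))
      return(data.frame(time = numeric(0), n_risk = integer(0),
                        n_event = integer(0), surv = numeric(0),
                        var = numeric(0), se = numeric(0)))
    n_risk <- vapply(et, function(t) sum(ti >= t), integer(1L))
    n_event <- vapply(et, function(t) sum(ti == t & ev == 1), integer(1L))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- surv^2 * cumsum(n_event / (n_risk * (n_risk - n_event)))
    gw[n_risk == n_event] <- 0  # S = 0; Greenwood sum degenerate there
    data.frame(time = et, n_risk = n_risk, n_event = n_event, surv = surv,
               var = gw, se = sqrt(gw))
  })
  res <- do.call(rbind, Map(function(g, d)
    cbind(data.frame(group = rep(g, nrow(d)), stringsAsFactors = FALSE), d),
    names(out), out))
  rownames(res) <- NULL
  res
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic with hypergeometric variance at each distinct
#' event time.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param group Two-level group labels.
#' @return List with `chi2`, `p` (1 df), `observed`, `expected` (for the
#'   first group level), `var`.
#' @export
logrank_test <- function(time, event, group) {
  g <- factor(group)
  if (nlevels(g) != 2L) stop("log-rank test requires exactly two groups")
  if (sum(event) == 0L) stop("no events observed")
  et <- sort(unique(time[event == 1]))
  o <- e <- v <- 0
  in1 <- g == levels(g)[1L]
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & in1)
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1L)
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- (o - e)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1L, lower.tail = FALSE),
       observed = o, expected = e, var = v)
}

# Core Cox partial-likelihood engine for counting-process data (start, stop].
# Returns beta, var, loglik, score chi2 at beta = 0, and per-event-time
# sufficient statistics reused by the Schoenfeld residuals.
cox_engine <- function(start, stop, event, X, ties = c("efron", "breslow"),
                       max_iter = 100, tol = 1e-9) {
  ties <- match.arg(ties)
  n <- length(stop); p <- ncol(X)
  et <- sort(unique(stop[event == 1]))
  n_et <- length(et)
  # cumulative-sum machinery: S(t) = sum_{start < t} - sum_{stop < t}
  ord_stop <- order(stop, method = "radix")
  ord_start <- order(start, method = "radix")
  stop_s <- stop[ord_stop]; start_s <- start[ord_start]
  k_stop <- findInterval(et, stop_s, left.open = TRUE)   # #{stop < t}
  k_start <- findInterval(et, start_s, left.open = TRUE) # #{start < t}
  risk_sum <- function(v) {
    cs_stop <- c(0, cumsum(v[ord_stop]))
    cs_start <- c(0, cumsum(v[ord_start]))
    cs_start[k_start + 1L] - cs_stop[k_stop + 1L]
  }
  death_rows <- split(which(event == 1),
                      match(stop[event == 1], et))
  d_t <- lengths(death_rows)[as.character(seq_len(n_et))]
  d_t[is.na(d_t)] <- 0L
  death_idx <- unlist(death_rows, use.names = FALSE)
  # Efron expansion: one (event time, l/d) pair per death
  tidx <- rep(seq_len(n_et), d_t)
  frac <- if (ties == "efron")
    unlist(lapply(d_t, function(d) seq_len(d) - 1L), use.names = FALSE) /
      rep(pmax(d_t, 1L), d_t)
  else rep(0, sum(d_t))

  # symmetric p x p storage
  ut <- which(upper.tri(matrix(0, p, p), diag = TRUE))
  ui <- ((ut - 1L) %% p) + 1L
  uj <- ((ut - 1L) %/% p) + 1L

  eval_at <- function(beta, want_info = TRUE) {
    eta <- drop(X %*% beta)
    r <- exp(eta)
    S0 <- risk_sum(r)
    S1 <- vapply(seq_len(p), function(j) risk_sum(X[, j] * r),
                 numeric(n_et))
    S1 <- matrix(S1, nrow = n_et)
    s0d <- vapply(seq_len(n_et), function(k) {
      rows <- death_rows[[as.character(k)]]
      if (is.null(rows)) 0 else sum(r[rows])
    }, numeric(1L))
    s1d <- vapply(seq_len(p), function(j)
      vapply(seq_len(n_et), function(k) {
        rows <- death_rows[[as.character(k)]]
        if (is.null(rows)) 0 else sum(X[rows, j] * r[rows])
      }, numeric(1L)), numeric(n_et))
    s1d <- matrix(s1d, nrow = n_et)
    den <- S0[tidx] - frac * s0d[tidx]
    num <- S1[tidx, , drop = FALSE] - frac * s1d[tidx, , drop = FALSE]
    ll <- sum(eta[death_idx]) - sum(log(den))
    grad <- colSums(X[death_idx, , drop = FALSE]) - colSums(num / den)
    info <- NULL
    if (want_info) {
      S2u <- vapply(seq_along(ut), function(m)
        risk_sum(X[, ui[m]] * X[, uj[m]] * r), numeric(n_et))
      S2u <- matrix(S2u, nrow = n_et)
      s2du <- vapply(seq_along(ut), function(m)
        vapply(seq_len(n_et), function(k) {
          rows <- death_rows[[as.character(k)]]
          if (is.null(rows)) 0
          else sum(X[rows, ui[m]] * X[rows, uj[m]] * r[rows])
        }, numeric(1L)), numeric(n_et))
      s2du <- matrix(s2du, nrow = n_et)
      info <- matrix(0, p, p)
      for (m in seq_along(ut)) {
        term <- sum((S2u[tidx, m] - frac * s2du[tidx, m]) / den -
                      num[, ui[m]] * num[, uj[m]] / den^2)
        info[ui[m], uj[m]] <- term
        info[uj[m], ui[m]] <- term
      }
    }
    list(ll = ll, grad = grad, info = info, S0 = S0, S1 = S1,
         s0d = s0d, s1d = s1d)
  }

  beta <- rep(0, p)
  at0 <- eval_at(beta)
  score_chi2 <- drop(t(at0$grad) %*% solve(at0$info, at0$grad))
  cur <- at0
  iter_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    step <- tryCatch(solve(cur$info, cur$grad),
                     error = function(e)
                       solve(cur$info + diag(1e-8 * (1 + diag(cur$info)),
                                             p), cur$grad))
    # cap the step so a flat likelihood direction cannot explode
    if (max(abs(step)) > 3) step <- step * 3 / max(abs(step))
    halv <- 0
    plateau <- FALSE
    repeat {
      cand <- beta + step
      nxt <- eval_at(cand)
      if (is.finite(nxt$ll) && nxt$ll >= cur$ll - 1e-12) break
      step <- step / 2
      halv <- halv + 1
      if (halv > 30) { plateau <- TRUE; nxt <- cur; cand <- beta; break }
    }
    delta <- nxt$ll - cur$ll
    beta <- cand
    cur <- nxt
    iter_trace <- c(iter_trace, cur$ll)
    if (plateau || abs(delta) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stop("Cox fit did not converge in ", max_iter, " iterations; ",
         "loglik trace: ", paste(signif(iter_trace, 6), collapse = ", "))
  if (any(abs(beta) > 10))
    warning("partial likelihood is monotone in some direction; ",
            "coefficient(s) ",
            paste(colnames(X)[abs(beta) > 10], collapse = ", "),
            " may be infinite (their Wald statistics are unreliable)")
  var <- solve(cur$info)
  list(beta = beta, var = var, loglik = cur$ll, loglik_null = at0$ll,
       score_chi2 = score_chi2, iter = it,
       et = et, d_t = d_t, death_rows = death_rows,
       eval_at = eval_at)
}

# Split right-censored records into counting-process episodes at the
# distinct event times, evaluating the time-interaction column tt_var * g(t)
# at each episode's stop time. Trailing censored pieces containing no event
# time are dropped (they never contribute to a risk set).
split_episodes <- function(time, event, X, tt_var, g) {
  et <- sort(unique(time[event == 1]))
  k <- findInterval(time, et)  # number of event times <= time_i
  keep <- k > 0L
  idx <- rep(which(keep), k[keep])
  pos <- unlist(lapply(k[keep], seq_len), use.names = FALSE)
  stop_new <- et[pos]
  start_new <- c(0, et)[pos]
  event_new <- as.integer(event[idx] == 1 & stop_new == time[idx])
  Xn <- X[idx, , drop = FALSE]
  tt_col <- Xn[, tt_var] * g(stop_new)
  Xn <- cbind(Xn, tt_col)
  colnames(Xn)[ncol(Xn)] <- paste0(tt_var, ":gtime")
  list(start = start_new, stop = stop_new, event = event_new, X = Xn,
       id = idx)
}

#' Cox proportional-hazards regression
#'
#' Newton-Raphson maximization of the partial likelihood with Efron
#' handling of tied event times (Breslow available). A time-interaction
#' term for one covariate is supported via episode splitting at the
#' distinct event times, adding a column `x * g(t)` evaluated per risk set
#' (default `g` = [g_logtime()]). Wald confidence intervals and p-values
#' are computed from the observed information.
#'
#' @param covariates data.frame or matrix of numeric covariates (each must
#'   vary).
#' @param time Positive follow-up times in months.
#' @param event 0/1 event indicators (>= 1 event required).
#' @param tt_var Optional name of one covariate column to also enter as a
#'   time interaction `x * g(t)`.
#' @param g Time transform for the interaction (default [g_logtime()]).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param ten_year If TRUE, follow-up is administratively censored at 120
#'   months before fitting (10-year analysis).
#' @return Object of class `SurvivalFit`: list with `terms` (data.frame:
#'   `term`, `beta`, `se`, `hr`, `ci_low`, `ci_high`, `wald_p`), `loglik`,
#'   `loglik_null`, `lr_p` (likelihood-ratio test), `score_chi2` (score
#'   test at beta = 0), `n`, `n_events`, `ties`, `iter`, plus the fitted
#'   engine data reused by [schoenfeld_test()].
#' @export
cox_fit <- function(covariates, time, event, tt_var = NULL, g = g_logtime,
                    ties = c("efron", "breslow"), ten_year = FALSE) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  stopifnot(all(time > 0), all(event %in% c(0, 1)),
            nrow(X) == length(time))
  if (ten_year) {
    event <- ifelse(time > 120, 0, event)
    time <- pmin(time, 120)
  }
  if (sum(event) < 1L) stop("at least one event is required")
  const <- apply(X, 2L, function(v) length(unique(v)) < 2L)
  if (any(const))
    stop("covariate(s) do not vary: ",
         paste(colnames(X)[const], collapse = ", "))
  if (!is.null(tt_var)) {
    if (!tt_var %in% colnames(X)) stop("unknown tt covariate: ", tt_var)
    dat <- split_episodes(time, event, X, tt_var, g)
  } else {
    dat <- list(start = rep(0, length(time)), stop = time, event = event,
                X = X, id = seq_along(time))
  }
  eng <- cox_engine(dat$start, dat$stop, dat$event, dat$X, ties = ties)
  se <- sqrt(diag(eng$var))
  terms <- data.frame(term = colnames(dat$X), beta = eng$beta, se = se,
                      hr = exp(eng$beta),
                      ci_low = exp(eng$beta - 1.96 * se),
                      ci_high = exp(eng$beta + 1.96 * se),
                      wald_p = 2 * stats::pnorm(-abs(eng$beta / se)),
                      row.names = NULL, stringsAsFactors = FALSE)
  lr <- 2 * (eng$loglik - eng$loglik_null)
  structure(list(terms = terms, loglik = eng$loglik,
                 loglik_null = eng$loglik_null,
                 lr_p = stats::pchisq(lr, df = ncol(dat$X),
                                      lower.tail = FALSE),
                 score_chi2 = eng$score_chi2,
                 n = length(time), n_events = sum(event), ties = ties,
                 iter = eng$iter, g = g, tt_var = tt_var,
                 engine = eng, data = dat),
            class = "SurvivalFit")
}

#' @export
print.SurvivalFit <- function(x, ...) {
  cat(sprintf("Cox fit (%s ties): n = %d, events = %d, loglik = %.3f\n",
              x$ties, x$n, x$n_events, x$loglik))
  print(transform(x$terms, hr = signif(hr, 4), ci_low = signif(ci_low, 4),
                  ci_high = signif(ci_high, 4), wald_p = signif(wald_p, 3),
                  beta = signif(beta, 4), se = signif(se, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Grambsch-Therneau test: Schoenfeld residuals (Efron-averaged within tied
#' event times) are scaled by the fit's covariance and regressed on a
#' transform of event time (default the same [g_logtime()] used for fitted
#' time interactions). Reports a 1-df chi-square p-value per covariate and
#' a global test.
#'
#' @param fit A [cox_fit()] result with >= 2 events.
#' @param transform Time transform (default the fit's `g`).
#' @return data.frame with `term`, `chi2`, `df`, `p`; the final row is the
#'   global test.
#' @export
schoenfeld_test <- function(fit, transform = NULL) {
  stopifnot(inherits(fit, "SurvivalFit"))
  if (fit$n_events < 2L) stop("need >= 2 events for the Schoenfeld test")
  if (is.null(transform)) transform <- fit$g
  eng <- fit$engine
  dat <- fit$data
  p <- ncol(dat$X)
  at <- eng$eval_at(fit$terms$beta, want_info = FALSE)
  # Efron-averaged risk-weighted covariate mean per event time
  resid <- NULL
  gt <- NULL
  for (k in seq_along(eng$et)) {
    rows <- eng$death_rows[[as.character(k)]]
    if (is.null(rows)) next
    d <- length(rows)
    frac <- (seq_len(d) - 1L) / d
    if (fit$ties == "breslow") frac <- rep(0, d)
    xbar_l <- vapply(seq_len(d), function(l)
      (at$S1[k, ] - frac[l] * at$s1d[k, ]) /
        (at$S0[k] - frac[l] * at$s0d[k]), numeric(p))
    xbar <- if (p == 1L) mean(xbar_l) else rowMeans(matrix(xbar_l, nrow = p))
    res_k <- sweep(dat$X[rows, , drop = FALSE], 2L, xbar)
    resid <- rbind(resid, res_k)
    gt <- c(gt, rep(transform(eng$et[k]), d))
  }
  d_tot <- nrow(resid)
  V <- solve(eng$eval_at(fit$terms$beta)$info)
  xx <- gt - mean(gt)
  w <- drop(crossprod(xx, resid))              # 1 x p
  wV <- drop(w %*% V)
  chi2 <- d_tot * wV^2 / (diag(V) * sum(xx^2))
  global <- d_tot * drop(w %*% V %*% w) / sum(xx^2)
  out <- data.frame(term = c(colnames(dat$X), "GLOBAL"),
                    chi2 = c(chi2, global),
                    df = c(rep(1L, p), p),
                    stringsAsFactors = FALSE)
  out$p <- stats::pchisq(out$chi2, df = out$df, lower.tail = FALSE)
  out
}

#' Write Cox fit results as TSV (plus JSON)
#'
#' @param fit A `SurvivalFit`.
#' @param path Output TSV path; a `.json` sidecar with fit metadata is
#'   written alongside.
#' @param schoenfeld Optional result of [schoenfeld_test()] merged in as a
#'   `schoenfeld_p` column.
#' @export
write_coxfit_tsv <- function(fit, path, schoenfeld = NULL) {
  out <- fit$terms
  if (!is.null(schoenfeld))
    out$schoenfeld_p <- schoenfeld$p[match(out$term, schoenfeld$term)]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = fit$n, n_events = fit$n_events, ties = fit$ties,
         loglik = fit$loglik, lr_p = fit$lr_p, iterations = fit$iter),
    paste0(sub("\\.tsv$", "", path), ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
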