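test_that("covariate dichotomization uses strict cutoffs", {
  ann <- data.frame(sample_id = paste0("p", 1:6),
                    age_years = c(50, 50.1, 49, 70, 50, 51),
                    size_cm = c(2.0, 2.1, 1.0, 3.0, 2.0, 2.00001),
                    ggi = c(0, 0.01, -1, 2, -0.0001, 0))
  d <- dichotomize_covariates(ann)
  expect_equal(d$age_hi, c(0, 1, 0, 1, 0, 1))
  expect_equal(d$size_hi, c(0, 1, 0, 1, 0, 1))
  expect_equal(d$ggi_hi, c(0, 1, 0, 1, 0, 0))
  expect_error(dichotomize_covariates(ann[, 1:3], covariates = "ggi"),
               "ggi")
})

test_that("Kaplan-Meier matches the product-limit hand computation", {
  km <- km_estimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km$time, c(2, 6))
  expect_equal(km$surv, c(2 / 3, 0))
  expect_equal(km$n_risk, c(3L, 1L))
  # all censored: no event rows, S identically 1
  expect_equal(nrow(km_estimate(c(1, 2, 3), c(0, 0, 0))), 0)
  # no censoring: 1 - S is the empirical CDF at event times
  set.seed(10)
  tt <- sort(sample(1:100, 20))
  km2 <- km_estimate(tt, rep(1, 20))
  expect_equal(1 - km2$surv, ecdf(tt)(km2$time))
  # monotone nonincreasing, nonnegative Greenwood variance
  set.seed(11)
  t3 <- rexp(50); e3 <- rbinom(50, 1, 0.6)
  km3 <- km_estimate(t3, e3)
  expect_true(all(diff(km3$surv) <= 1e-12))
  expect_true(all(km3$var >= 0))
})

test_that("Kaplan-Meier agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(14)
  tt <- round(rexp(80, 0.05), 1) + 0.1
  ev <- rbinom(80, 1, 0.7)
  g <- rep(c("A", "B"), 40)
  own <- km_estimate(tt, ev, g)
  ref <- summary(survival::survfit(survival::Surv(tt, ev) ~ g))
  for (lev in c("A", "B")) {
    o <- own[own$group == lev, ]
    r <- which(ref$strata == paste0("g=", lev) & ref$n.event > 0)
    expect_equal(o$surv, ref$surv[r], tolerance = 1e-12)
    fin <- is.finite(ref$std.err[r])  # survfit reports NaN se where S = 0
    expect_equal(o$se[fin], ref$std.err[r][fin], tolerance = 1e-9)
  }
})

test_that("log-rank test: hand example, symmetry, and survdiff agreement", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(lr$observed - lr$expected, 7 / 6, tolerance = 1e-12)
  expect_equal(lr$var, 17 / 36, tolerance = 1e-12)
  expect_equal(lr$chi2, (7 / 6)^2 / (17 / 36), tolerance = 1e-12)
  expect_equal(lr$chi2, 2.8824, tolerance = 1e-4)

  # identical groups: chi2 = 0, p = 1
  t0 <- c(1, 3, 5, 1, 3, 5); e0 <- c(1, 0, 1, 1, 0, 1)
  same <- logrank_test(t0, e0, rep(c("a", "b"), each = 3))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  skip_if_not_installed("survival")
  set.seed(15)
  tt <- rexp(100, 0.1 * exp(0.5 * rep(0:1, 50)))
  ev <- rbinom(100, 1, 0.8)
  g <- rep(0:1, 50)
  own <- logrank_test(tt, ev, g)
  ref <- survival::survdiff(survival::Surv(tt, ev) ~ g)
  expect_equal(own$chi2, ref$chisq, tolerance = 1e-9)
})

test_that("Cox score test at beta 0 reproduces the log-rank chi-square without ties", {
  set.seed(16)
  tt <- rexp(60); ev <- rbinom(60, 1, 0.75); g <- rbinom(60, 1, 0.5)
  fit <- cox_fit(data.frame(g = g), tt, ev, ties = "breslow")
  lr <- logrank_test(tt, ev, g)
  expect_equal(fit$score_chi2, lr$chi2, tolerance = 1e-9)
})

test_that("Cox fit maximizes the Efron partial likelihood (grid-search oracle)", {
  # interleaved groups: the likelihood has an interior maximum
  tt <- 1:6; ev <- rep(1, 6); x <- c(1, 0, 1, 0, 1, 0)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  # brute-force partial likelihood on a fine grid (no ties -> Efron = exact)
  pl <- function(b) {
    eta <- b * x
    sum(vapply(which(ev == 1), function(i) {
      risk <- tt >= tt[i]
      eta[i] - log(sum(exp(eta[risk])))
    }, numeric(1)))
  }
  grid <- seq(-4, 4, by = 1e-3)
  best <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(fit$terms$beta, best, tolerance = 1e-3)
})

test_that("Cox fit matches survival::coxph with Efron ties and covariates", {
  skip_if_not_installed("survival")
  set.seed(42)
  n <- 250
  x1 <- rbinom(n, 1, 0.5); x2 <- rnorm(n)
  t0 <- rexp(n, 0.02 * exp(0.7 * x1 - 0.3 * x2))
  cens <- pmin(rexp(n, 0.01), 120)
  tt <- round(pmin(t0, cens), 1) + 0.1  # induce ties
  ev <- as.integer(t0 <= cens)
  fit <- cox_fit(data.frame(x1 = x1, x2 = x2), tt, ev)
  ref <- survival::coxph(survival::Surv(tt, ev) ~ x1 + x2, ties = "efron")
  expect_equal(fit$terms$beta, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$terms$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)
  expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-8)
})

test_that("time-interaction episode splitting matches a survSplit-based coxph oracle", {
  skip_if_not_installed("survival")
  set.seed(7)
  n <- 200
  x <- rbinom(n, 1, 0.5); z <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.02 * exp(0.6 * x))
  cens <- pmin(rexp(n, 0.008), 150)
  time <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  fit <- cox_fit(data.frame(x = x, z = z), time, ev, tt_var = "z")
  # independent split: survival::survSplit at the event times, covariate
  # z * log(max(t, 1)) evaluated at each episode's stop time
  dat <- data.frame(time = time, ev = ev, x = x, z = z)
  cuts <- sort(unique(time[ev == 1]))
  Surv <- survival::Surv  # survSplit requires a bare Surv() on the LHS
  sp <- survival::survSplit(Surv(time, ev) ~ ., data = dat, cut = cuts)
  sp$zt <- sp$z * log(pmax(sp$time, 1))
  ref <- survival::coxph(
    survival::Surv(tstart, time, ev) ~ x + z + zt, data = sp,
    ties = "efron")
  expect_equal(fit$terms$beta, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(fit$terms$se, unname(sqrt(diag(vcov(ref)))), tolerance = 1e-8)
})

test_that("null covariate: beta near 0 and CI covers HR 1", {
  set.seed(19)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  t0 <- rexp(n, 0.02)
  cens <- pmin(rexp(n, 0.01), 120)
  tt <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  fit <- cox_fit(data.frame(x = x), tt, ev)
  expect_lt(abs(fit$terms$beta), 0.3)
  expect_true(fit$terms$ci_low < 1 && fit$terms$ci_high > 1)
})

test_that("hazard ratio recovery: true HR 2 with censoring, across seeds", {
  set.seed(23)
  hrs <- vapply(1:40, function(s) {
    set.seed(3000 + s)
    n <- 800
    x <- rbinom(n, 1, 0.5)
    t0 <- rexp(n, 0.01 * exp(log(2) * x))
    cens <- rexp(n, 0.0045)  # ~30% censoring
    tt <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
    cox_fit(data.frame(x = x), tt, ev)$terms$hr
  }, numeric(1))
  expect_gt(mean(hrs), 1.9)
  expect_lt(mean(hrs), 2.1)
})

test_that("ten-year flag applies administrative censoring at 120 months", {
  set.seed(29)
  n <- 300
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.005); ev <- rbinom(n, 1, 0.9)
  fit <- cox_fit(data.frame(x = x), tt, ev, ten_year = TRUE)
  manual_ev <- ifelse(tt > 120, 0, ev)
  expect_equal(fit$n_events, sum(manual_ev))
})

test_that("Schoenfeld test calibration: ~5% rejection under proportional hazards", {
  set.seed(31)
  pvals <- vapply(1:150, function(s) {
    set.seed(5000 + s)
    n <- 150
    x <- rbinom(n, 1, 0.5)
    t0 <- rexp(n, 0.02 * exp(0.5 * x))
    cens <- pmin(rexp(n, 0.008), 150)
    tt <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
    fit <- cox_fit(data.frame(x = x), tt, ev)
    schoenfeld_test(fit)$p[1]
  }, numeric(1))
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.12)
  # p-values roughly uniform under the null
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("Schoenfeld test detects a planted time-decaying effect", {
  set.seed(37)
  rejections <- vapply(1:30, function(s) {
    set.seed(6000 + s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    # piecewise-constant approximation of beta(t) = 1 - 0.5 log t
    tt <- numeric(n); ev <- integer(n)
    for (i in 1:n) {
      t_cur <- 0
      repeat {
        seg <- min(2, 180 - t_cur)
        b <- 1 - 0.5 * log(pmax(t_cur + 1, 1))
        haz <- 0.01 * exp(b * x[i])
        draw <- rexp(1, haz)
        if (draw < seg) { tt[i] <- t_cur + draw; ev[i] <- 1L; break }
        t_cur <- t_cur + seg
        if (t_cur >= 180) { tt[i] <- 180; ev[i] <- 0L; break }
      }
    }
    tt <- pmax(tt, 0.01)
    fit <- cox_fit(data.frame(x = x), tt, ev)
    schoenfeld_test(fit)$p[1] < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.8)
})

test_that("Schoenfeld p-values track survival::cox.zph", {
  skip_if_not_installed("survival")
  set.seed(41)
  n <- 300
  x <- rbinom(n, 1, 0.5); z <- rnorm(n)
  t0 <- rexp(n, 0.02 * exp(0.4 * x + 0.3 * z))
  cens <- pmin(rexp(n, 0.008), 150)
  tt <- pmin(t0, cens); ev <- as.integer(t0 <= cens)
  fit <- cox_fit(data.frame(x = x, z = z), tt, ev)
  own <- schoenfeld_test(fit)
  ref <- survival::cox.zph(
    survival::coxph(survival::Surv(tt, ev) ~ x + z, ties = "efron"),
    transform = function(t) log(pmax(t, 1)))
  # same averaged-variance family of tests; allow approximation differences
  expect_equal(own$p[1:2], ref$table[1:2, "p"], tolerance = 0.15,
               ignore_attr = TRUE)
})
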