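test_that("KM estimator matches hand-computed product-limit tables", {
  km <- km_curve(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))

  km_cens <- km_curve(c(2, 5, 9), c(0, 0, 0))
  expect_true(all(km_cens$surv == 1))

  # 6 subjects: deaths at 1, 3, 5, 6; censored at 2, 4
  km6 <- km_curve(c(1, 2, 3, 4, 5, 6), c(1, 0, 1, 0, 1, 1))
  death_rows <- km6$n_event > 0
  expect_equal(km6$surv[death_rows], c(5 / 6, 5 / 6 * 3 / 4, 5 / 6 * 3 / 4 * 1 / 2, 0))
  expect_true(all(diff(km6$surv) <= 1e-12))
  expect_equal(km_surv_at(km6, 0), 1)
  expect_equal(km_surv_at(km6, 3.5), 5 / 6 * 3 / 4)
})

test_that("log-rank matches a hand-computed O/E/V table and is null for identical groups", {
  # A: death 1, death 3, censored 5; B: death 2, censored 4, death 6
  lr <- logrank_test(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 0, 1), rep(c("A", "B"), each = 3))
  expect_equal(lr$chi2, (2 - 1.4)^2 / 0.74, tolerance = 1e-10)
  expect_equal(lr$p, pchisq((2 - 1.4)^2 / 0.74, 1, lower.tail = FALSE))

  tt <- c(1, 2, 3, 4, 5)
  ee <- c(1, 0, 1, 1, 0)
  lr0 <- logrank_test(c(tt, tt), c(ee, ee), rep(1:2, each = 5))
  expect_lt(lr0$chi2, 1e-10)
  expect_error(logrank_test(tt, ee, rep(1, 5)), class = "pyroscore_config_error")
  # relabeling invariance
  lr_a <- logrank_test(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 0, 1), rep(c("A", "B"), each = 3))
  lr_b <- logrank_test(c(1, 3, 5, 2, 4, 6), c(1, 1, 0, 1, 0, 1), rep(c("B", "A"), each = 3))
  expect_equal(lr_a$chi2, lr_b$chi2)
})

test_that("asymptotic log-rank p agrees with a permutation p on mid-size data", {
  set.seed(1)
  n <- 60
  grp <- rep(1:2, each = n / 2)
  tt <- rexp(n, rate = ifelse(grp == 1, 1, 1.6))
  ee <- rbinom(n, 1, 0.8)
  obs <- logrank_test(tt, ee, grp)
  perm_chi <- replicate(1000, logrank_test(tt, ee, sample(grp))$chi2)
  p_perm <- mean(perm_chi >= obs$chi2)
  expect_lt(abs(p_perm - obs$p), 0.05)
})

test_that("the optimal cutpoint splits perfectly ordered survival with a strong test", {
  score <- c(-(5:1), 1:5)
  tt <- c(1:5, 101:105)
  ee <- rep(1, 10)
  cut <- optimal_cutpoint(score, tt, ee, min_frac = 0.1)
  # the low-score side of the selected cut contains only early deaths
  expect_true(all(tt[score <= cut$cutpoint] <= 5))
  expect_gt(cut$chi2, qchisq(0.999, 1))
  expect_gte(cut$n_low, 1)
  expect_gte(cut$n_high, 1)
  expect_error(optimal_cutpoint(rep(1, 10), tt, ee), class = "pyroscore_data_error")
  # ties broken toward the lower cut
  flat <- optimal_cutpoint(rep(c(0, 1), each = 5), rep(tt, 1), ee, min_frac = 0.2)
  expect_equal(flat$cutpoint, 0.5)
})

test_that("a planted hazard threshold is recovered to high partition agreement", {
  agree <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 300
    score <- c(runif(n / 2, -2, -0.25), runif(n / 2, 0.25, 2))
    tt <- rexp(n, rate = ifelse(score > 0, 0.1, 0.3))
    ee <- rbinom(n, 1, 0.85)
    cut <- optimal_cutpoint(score, tt, ee)
    mean((score > cut$cutpoint) == (score > 0))
  })
  expect_gte(mean(agree >= 0.9), 0.9)
})

test_that("the naive cutpoint p-value is anti-conservative under the null", {
  ps <- sapply(1:40, function(s) {
    set.seed(400 + s)
    n <- 80
    optimal_cutpoint(rnorm(n), rexp(n, 0.1), rbinom(n, 1, 0.8))$p_naive
  })
  # selection inflates the type-I error well beyond the nominal level
  expect_gt(mean(ps < 0.05), 0.10)
})

test_that("Cox fit recovers a planted binary effect and is duplication-invariant", {
  betas <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 500
    x <- rbinom(n, 1, 0.5)
    tt <- rexp(n, rate = 0.05 * exp(-1.0 * x))
    cens <- rexp(n, rate = 0.02)
    cl <- data.frame(time = pmin(tt, cens), event = as.integer(tt <= cens), x = x)
    cox_fit(cl, "x")$coef$beta
  })
  expect_lt(abs(mean(betas) + 1.0), 0.15)

  set.seed(99)
  n <- 150
  cl <- data.frame(
    time = rexp(n, 0.1), event = rbinom(n, 1, 0.7), x = rnorm(n)
  )
  # duplication invariance of the partial likelihood (Breslow ties: the
  # duplicated copies create ties, which Efron's correction treats differently)
  f1 <- cox_fit(cl, "x", ties = "breslow")
  f2 <- cox_fit(rbind(cl, cl), "x", ties = "breslow")
  expect_equal(f2$coef$beta, f1$coef$beta, tolerance = 1e-6)
  expect_error(cox_fit(transform(cl, x = 1), "x"), class = "pyroscore_data_error")
})

test_that("null covariates give small estimates and uniform Wald p-values", {
  ps <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    n <- 120
    cl <- data.frame(time = rexp(n, 0.1), event = rbinom(n, 1, 0.8), x = rnorm(n))
    cox_fit(cl, "x")$coef$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("absolute risk from the Breslow baseline behaves like 1 - KM in a null model", {
  set.seed(2)
  n <- 500
  cl <- data.frame(time = rexp(n, 0.08), event = rbinom(n, 1, 0.8), x = rnorm(n))
  fit <- cox_fit(cl, "x") # x is pure noise, so the fitted effect is ~0
  t0 <- 10
  risk0 <- risk_at_t(fit, data.frame(x = 0), t0) # lp = 0 -> 1 - S0(t)
  km_ref <- 1 - km_surv_at(km_curve(cl$time, cl$event), t0)
  expect_lt(abs(risk0 - km_ref), 0.02)
  # monotone in the linear predictor
  set.seed(3)
  cl2 <- data.frame(time = rexp(200, 0.1), event = rep(1, 200), x = rnorm(200))
  fit2 <- cox_fit(cl2, "x")
  nd <- data.frame(x = c(-1, 0, 1) * sign(fit2$coef$beta))
  expect_true(all(diff(risk_at_t(fit2, nd, t = 8)) > 0))
})

test_that("NRI and IDI vanish for identical models and match a hand-computed fixture", {
  tt <- c(1, 2, 3, 4, 6, 7, 8, 9, 10, 11)
  ee <- rep(1, 10)
  r_old <- c(.5, .4, .6, .3, .5, .2, .6, .4, .3, .2)
  r_new <- c(.6, .5, .5, .4, .4, .3, .5, .3, .2, .3)
  same <- reclassification_metrics(r_old, r_old, tt, ee, t = 5)
  expect_identical(same$nri, 0)
  expect_identical(same$idi, 0)
  rc <- reclassification_metrics(r_old, r_new, tt, ee, t = 5)
  expect_equal(rc$nri, 5 / 6, tolerance = 1e-12)
  expect_equal(rc$idi, 0.05 + 0.2 / 6, tolerance = 1e-12)
  # antisymmetry under swapping old/new
  rev_rc <- reclassification_metrics(r_new, r_old, tt, ee, t = 5)
  expect_equal(rev_rc$nri, -rc$nri)
  expect_equal(rev_rc$idi, -rc$idi)
  # perfect upgrade: risk_new = event indicator, risk_old flat
  ind <- as.numeric(tt <= 5)
  up <- reclassification_metrics(rep(0.5, 10), ind, tt, ee, t = 5)
  expect_equal(up$nri, 2)
  expect_equal(up$idi, 1)
  expect_error(reclassification_metrics(r_old, r_new, tt, ee, t = 0.5),
    class = "pyroscore_data_error")
})

test_that("concordance is 1 for perfectly anti-concordant risk and 0.5 for noise", {
  tt <- 1:20
  expect_equal(concordance_index(rev(tt), tt, rep(1, 20)), 1)
  set.seed(4)
  cvals <- replicate(20, {
    n <- 200
    concordance_index(rnorm(n), rexp(n, 0.1), rbinom(n, 1, 0.8))
  })
  expect_lt(abs(mean(cvals) - 0.5), 0.05)
  expect_error(concordance_index(rnorm(5), 1:5, rep(0, 5)), class = "pyroscore_data_error")
  # invariant to monotone transforms of risk
  set.seed(5)
  r <- runif(50)
  tt2 <- rexp(50, 0.1)
  ee2 <- rbinom(50, 1, 0.8)
  expect_equal(
    concordance_index(r, tt2, ee2),
    concordance_index(qlogis(r), tt2, ee2)
  )
})

test_that("time-dependent AUC reduces to the Mann-Whitney AUC without censoring", {
  set.seed(6)
  n <- 80
  tt <- rexp(n, 0.1)
  ee <- rep(1, n)
  risk <- -tt + rnorm(n, sd = 3)
  t0 <- median(tt)
  auc <- time_dependent_auc(risk, tt, ee, t0)
  oracle <- mw_auc(risk[tt <= t0], risk[tt > t0])
  expect_equal(auc, oracle, tolerance = 1e-12)
  expect_equal(time_dependent_auc(as.numeric(tt <= t0), tt, ee, t0), 1)
  # monotone-transform invariance
  expect_equal(time_dependent_auc(exp(risk / 3), tt, ee, t0), auc)
})

test_that("decision curves honor the treat-all / treat-none reference geometry", {
  set.seed(7)
  n <- 300
  tt <- rexp(n, 0.1)
  ee <- rep(1, n)
  risk <- pmin(pmax(1 - exp(-0.1 * tt) + rnorm(n, sd = 0.1), 0), 1)
  t0 <- 8
  prev <- 1 - km_surv_at(km_curve(tt, ee), t0)
  dc <- decision_curve(risk, tt, ee, t0, thresholds = c(0.01, prev, 0.6))
  expect_true(all(dc$nb_none == 0))
  expect_equal(dc$nb_all[2], 0, tolerance = 1e-12)
  expect_equal(dc$nb_all[1], prev - (1 - prev) * 0.01 / 0.99, tolerance = 1e-12)
  expect_lt(abs(dc$nb_all[1] - prev), 0.02) # p_t -> 0 limit
})

test_that("nomogram points self-normalize and respect effect signs", {
  set.seed(8)
  n <- 300
  x <- runif(n, 2, 6)
  tt <- rexp(n, 0.05 * exp(0.5 * x))
  cl <- data.frame(time = tt, event = rep(1, n), x = x)
  fit <- cox_fit(cl, "x")
  nom <- nomogram_points(fit)
  pts <- nom$points[, "x"]
  expect_equal(unname(pts), 100 * (x - min(x)) / (max(x) - min(x)), tolerance = 1e-10)
  # two covariates: monotone in each, with the right sign
  z <- rnorm(n)
  cl2 <- data.frame(time = rexp(n, 0.05 * exp(0.5 * x - 0.7 * z)), event = rep(1, n), x = x, z = z)
  fit2 <- cox_fit(cl2, c("x", "z"))
  nom2 <- nomogram_points(fit2)
  expect_gt(cor(nom2$points[, "x"], x), 0.999)
  expect_lt(cor(nom2$points[, "z"], z), -0.999)
  expect_true(all(nom2$points >= -1e-10))
  # total points map to a risk consistent with risk_at_t
  tot <- rowSums(nom2$points)
  expect_equal(nom2$total_to_risk(tot, 5), risk_at_t(fit2, t = 5), tolerance = 1e-10)
})
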