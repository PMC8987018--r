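# Survival stratification and model-improvement statistics: KM, log-rank,
# maximally-selected cutpoint, Cox PH (via the survival package) with a
# Breslow baseline, IPCW reclassification metrics (continuous NRI, IDI),
# Harrell's C, cumulative/dynamic time-dependent AUC, decision curves and
# nomogram points.

check_surv_input <- function(times, events) {
  if (length(times) != length(events)) stop_data("times and events differ in length")
  if (any(times <= 0)) stop_data("survival times must be > 0")
  if (!all(events %in% c(0, 1))) stop_data("event indicator must be 0/1")
  invisible(NULL)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimator; `S(0) = 1` with right-continuous steps at event
#' times.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @return A `km_curve` data frame with columns `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, covering every distinct observed time.
#' @export
km_curve <- function(times, events) {
  check_surv_input(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, surv = fit$surv
  )
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a KM curve at arbitrary times
#'
#' @param km A [km_curve()] (or any data frame with `time` and `surv`).
#' @param t Times at which to evaluate S(t); `S = 1` before the first step.
#' @return Numeric vector of survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  f <- stats::stepfun(km$time, c(1, km$surv), right = FALSE)
  f(t)
}

#' Log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over distinct event times; p from chi-square with (groups - 1) df.
#'
#' @param times Positive follow-up times.
#' @param events 0/1 event indicators.
#' @param groups Group labels (>= 2 groups, each nonempty).
#' @return List with `chi2`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop_config("log-rank needs >= 2 groups")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Optimal survival cutpoint by maximally selected log-rank
#'
#' Evaluates the log-rank chi-square at every candidate cut (midpoints of
#' consecutive distinct score values) whose resulting smaller group holds at
#' least `min_frac` of the samples, and returns the cut maximizing the
#' statistic (ties toward the lower cut). The reported p-value is the naive
#' chi-square p of the selected split and is anti-conservative because of
#' the selection; it is labelled `p_naive`.
#'
#' @param score Numeric per-sample score with >= 2 distinct values.
#' @param times,events Survival outcome.
#' @param min_frac Minimum fraction of samples on each side of the cut.
#' @return List with `cutpoint`, `chi2`, `p_naive`, `n_low`, `n_high`.
#' @export
optimal_cutpoint <- function(score, times, events, min_frac = 0.1) {
  check_surv_input(times, events)
  us <- sort(unique(score))
  if (length(us) < 2L) stop_data("score is constant; no cutpoint exists")
  cuts <- (us[-1] + us[-length(us)]) / 2
  n <- length(score)
  keep <- vapply(cuts, function(cc) {
    nl <- sum(score <= cc)
    nl >= min_frac * n && (n - nl) >= min_frac * n
  }, logical(1))
  cuts <- cuts[keep]
  if (!length(cuts)) stop_data("no candidate cut satisfies the minimum group fraction")
  chi2s <- vapply(cuts, function(cc) {
    logrank_test(times, events, score > cc)$chi2
  }, numeric(1))
  best <- which.max(chi2s) # first maximum = lowest cut on ties
  cut <- cuts[best]
  list(
    cutpoint = cut, chi2 = chi2s[best],
    p_naive = stats::pchisq(chi2s[best], 1L, lower.tail = FALSE),
    n_low = sum(score <= cut), n_high = sum(score > cut)
  )
}

#' Cox proportional-hazards fit
#'
#' Maximum partial likelihood with Efron tie handling; per-covariate hazard
#' ratios with Wald confidence intervals, plus the Breslow baseline
#' cumulative hazard needed for absolute risk prediction.
#'
#' @param clinical Data frame with `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names.
#' @param ties Tie handling for the partial likelihood: `"efron"` (default)
#'   or `"breslow"`.
#' @return A `CoxModel` list: `coef` table (beta, HR, CI, Wald p), `loglik`,
#'   `baseline` (Breslow cumulative hazard at covariate value zero), the
#'   fitted `survival::coxph` object, and the design matrix used.
#' @export
cox_fit <- function(clinical, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv_input(clinical$time, clinical$event)
  missing <- setdiff(covariates, names(clinical))
  if (length(missing)) stop_data("covariates absent from clinical table: %s", paste(missing, collapse = ", "))
  Xd <- as.matrix(clinical[, covariates, drop = FALSE])
  if (!is.numeric(Xd)) stop_data("covariates must be numeric")
  if (any(apply(Xd, 2L, function(x) length(unique(x)) == 1L))) {
    stop_data("constant covariate in Cox design")
  }
  if (sum(clinical$event) < length(covariates)) {
    stop_data("fewer events than covariates")
  }
  fit <- survival::coxph(
    survival::Surv(clinical$time, clinical$event) ~ Xd,
    ties = ties, control = survival::coxph.control(iter.max = 100L, eps = 1e-10)
  )
  if (!is.null(fit$info) && isTRUE(fit$info$flag > 0)) stop_data("Cox fit did not converge")
  if (any(!is.finite(fit$coefficients)) || any(abs(fit$coefficients) > 50)) {
    stop_data("Cox fit did not converge (possible separation)")
  }
  beta <- unname(fit$coefficients)
  se <- sqrt(diag(fit$var))
  zq <- stats::qnorm(0.975)
  coef_tab <- data.frame(
    covariate = covariates, beta = beta, se = se, hr = exp(beta),
    ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
    p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  lp <- as.vector(Xd %*% beta) # uncentered linear predictor
  base <- breslow_baseline(clinical$time, clinical$event, lp)
  structure(
    list(
      coef = coef_tab, loglik = fit$loglik[2L], baseline = base,
      fit = fit, covariates = covariates, design = Xd,
      time = clinical$time, event = clinical$event, lp = lp
    ),
    class = "CoxModel"
  )
}

# Breslow estimator of the baseline cumulative hazard at covariate value 0:
# H0(t) = sum over event times tj <= t of d_j / sum_{i at risk} exp(lp_i).
breslow_baseline <- function(times, events, lp) {
  et <- sort(unique(times[events == 1]))
  elp <- exp(lp)
  dH <- vapply(et, function(tj) {
    sum(events == 1 & times == tj) / sum(elp[times >= tj])
  }, numeric(1))
  data.frame(time = et, cumhaz = cumsum(dH))
}

#' Absolute risk at a horizon from a Cox model
#'
#' `risk = 1 - S0(t)^exp(lp)` with the Breslow baseline survival
#' `S0 = exp(-H0)`; with all linear predictors zero this reduces to
#' `1 - S0(t)`, which agrees with the KM estimate in a null model.
#'
#' @param model A `CoxModel` from [cox_fit()].
#' @param newdata Optional data frame holding the model covariates; default
#'   is the training data.
#' @param t Horizon (scalar).
#' @return Numeric vector of per-subject event risks in [0, 1].
#' @export
risk_at_t <- function(model, newdata = NULL, t) {
  lp <- if (is.null(newdata)) {
    model$lp
  } else {
    as.vector(as.matrix(newdata[, model$covariates, drop = FALSE]) %*% model$coef$beta)
  }
  H0 <- if (nrow(model$baseline) == 0L) 0 else {
    f <- stats::stepfun(model$baseline$time, c(0, model$baseline$cumhaz), right = FALSE)
    f(t)
  }
  1 - exp(-H0 * exp(lp))
}

# IPCW weights for horizon-t event status: cases (event before or at t) get
# 1/G(T-), controls (followed beyond t) get 1/G(t), censored-before-t get 0.
# G is the KM estimator of the censoring distribution.
ipcw_status <- function(times, events, t) {
  km_c <- km_curve(times, 1 - events)
  Gt <- max(km_surv_at(km_c, t), 1e-10)
  case <- times <= t & events == 1
  control <- times > t
  w <- numeric(length(times))
  w[case] <- 1 / pmax(km_surv_at(km_c, times[case] * (1 - 1e-12)), 1e-10)
  w[control] <- 1 / Gt
  list(case = case, control = control, w = w)
}

#' Continuous NRI and IDI at a horizon
#'
#' Category-free net reclassification improvement and integrated
#' discrimination improvement for replacing `risk_old` by `risk_new`, with
#' horizon-t case/control status under censoring handled by inverse
#' probability of censoring weights (KM of the censoring distribution).
#' NRI = (P(up|case) - P(down|case)) + (P(down|control) - P(up|control));
#' IDI = (mean risk_new - mean risk_old | cases) - (same | controls).
#'
#' @param risk_old,risk_new Per-subject risks in [0, 1].
#' @param times,events Survival outcome.
#' @param t Horizon within follow-up.
#' @return List with `nri`, `idi`, and the weighted case/control counts.
#' @export
reclassification_metrics <- function(risk_old, risk_new, times, events, t) {
  check_surv_input(times, events)
  if (any(risk_old < 0 | risk_old > 1 | risk_new < 0 | risk_new > 1)) {
    stop_data("risks must lie in [0, 1]")
  }
  if (!any(times <= t & events == 1)) stop_data("no events before the horizon t")
  st <- ipcw_status(times, events, t)
  up <- risk_new > risk_old
  down <- risk_new < risk_old
  wcase <- st$w * st$case
  wctrl <- st$w * st$control
  p_up_case <- sum(wcase * up) / sum(wcase)
  p_down_case <- sum(wcase * down) / sum(wcase)
  p_up_ctrl <- sum(wctrl * up) / sum(wctrl)
  p_down_ctrl <- sum(wctrl * down) / sum(wctrl)
  nri <- (p_up_case - p_down_case) + (p_down_ctrl - p_up_ctrl)
  idi <- (sum(wcase * (risk_new - risk_old)) / sum(wcase)) -
    (sum(wctrl * (risk_new - risk_old)) / sum(wctrl))
  list(
    nri = nri, idi = idi,
    n_case = sum(st$case), n_control = sum(st$control)
  )
}

#' Harrell's concordance index
#'
#' Probability, over usable (event-anchored) pairs, that the subject with
#' the shorter survival carries the higher risk; risk ties count 0.5.
#'
#' @param risk Per-subject risk scores (higher = worse prognosis).
#' @param times,events Survival outcome.
#' @return Concordance in [0, 1].
#' @export
concordance_index <- function(risk, times, events) {
  check_surv_input(times, events)
  cc <- survival::concordance(survival::Surv(times, events) ~ risk, reverse = TRUE)
  npairs <- sum(cc$count[c("concordant", "discordant", "tied.x")])
  if (npairs == 0) stop_data("no usable pairs (all observations censored?)")
  unname(cc$concordance)
}

#' Cumulative/dynamic time-dependent AUC
#'
#' IPCW-weighted probability that a case by the horizon (event time <= t)
#' outranks a control (followed beyond t); risk ties count 0.5. With no
#' censoring this is exactly the Mann-Whitney AUC of cases vs controls.
#'
#' @param risk Per-subject risk scores.
#' @param times,events Survival outcome.
#' @param t Horizon.
#' @return AUC in [0, 1].
#' @export
time_dependent_auc <- function(risk, times, events, t) {
  check_surv_input(times, events)
  st <- ipcw_status(times, events, t)
  ci <- which(st$case)
  cj <- which(st$control)
  if (!length(ci) || !length(cj)) stop_data("need both cases and controls at the horizon")
  wi <- st$w[ci]
  wj <- st$w[cj]
  gt <- outer(risk[ci], risk[cj], ">") + 0.5 * outer(risk[ci], risk[cj], "==")
  sum((wi %o% wj) * gt) / (sum(wi) * sum(wj))
}

#' Decision curve (net benefit) at a horizon
#'
#' `NB(p) = TP/n - FP/n * p / (1 - p)` across threshold probabilities `p`,
#' where a subject is "treated" when their predicted risk exceeds the
#' threshold and the event probability among the treated is estimated by KM
#' within that risk stratum (respecting censoring). Treat-all and
#' treat-none reference curves are included; treat-all crosses zero at the
#' event prevalence.
#'
#' @param risk Per-subject risks in [0, 1].
#' @param times,events Survival outcome.
#' @param t Horizon.
#' @param thresholds Grid of threshold probabilities in (0, 1).
#' @return Data frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(risk, times, events, t,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  check_surv_input(times, events)
  n <- length(risk)
  km_all <- km_curve(times, events)
  prev <- 1 - km_surv_at(km_all, t)
  nb_model <- vapply(thresholds, function(p) {
    treated <- risk >= p
    if (!any(treated)) return(0)
    ev <- if (sum(treated) == n) prev else {
      1 - km_surv_at(km_curve(times[treated], events[treated]), t)
    }
    frac <- mean(treated)
    frac * ev - frac * (1 - ev) * p / (1 - p)
  }, numeric(1))
  data.frame(
    threshold = thresholds,
    nb_model = nb_model,
    nb_all = prev - (1 - prev) * thresholds / (1 - thresholds),
    nb_none = 0
  )
}

#' Nomogram point table for a Cox model
#'
#' Each covariate's points scale its log-hazard contribution to 0..100 for
#' the covariate with the largest effect range:
#' `points(x) = 100 * |beta| * (x - x_ref) / max_j(|beta_j| * range_j)`,
#' with `x_ref` the covariate value of lowest risk, so points are
#' non-negative and increase with hazard. Total points map back to the
#' linear predictor (and hence to [risk_at_t()]).
#'
#' @param model A `CoxModel` from [cox_fit()].
#' @return List with `points` (per-subject per-covariate point matrix),
#'   `scale` (points per unit log-hazard), `lp_ref`, and
#'   `total_to_risk(total_points, t)` mapping totals to event risk.
#' @export
nomogram_points <- function(model) {
  Xd <- model$design
  beta <- model$coef$beta
  rng <- apply(Xd, 2L, range)
  eff_range <- abs(beta) * (rng[2L, ] - rng[1L, ])
  max_eff <- max(eff_range)
  if (max_eff == 0) stop_data("all covariates have zero effect range")
  x_ref <- ifelse(beta >= 0, rng[1L, ], rng[2L, ])
  # beta * (x - x_ref) is >= 0 by choice of x_ref
  pts <- 100 * sweep(Xd, 2L, x_ref) *
    matrix(beta, nrow(Xd), length(beta), byrow = TRUE) / max_eff
  colnames(pts) <- model$covariates
  lp_ref <- sum(beta * x_ref)
  model_env <- model
  total_to_risk <- function(total_points, t) {
    lp <- lp_ref + total_points * max_eff / 100
    H0 <- if (nrow(model_env$baseline) == 0L) 0 else {
      f <- stats::stepfun(model_env$baseline$time, c(0, model_env$baseline$cumhaz), right = FALSE)
      f(t)
    }
    1 - exp(-H0 * exp(lp))
  }
  list(points = pts, scale = 100 / max_eff, lp_ref = lp_ref, total_to_risk = total_to_risk)
}
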