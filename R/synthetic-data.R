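#' Configuration of a synthetic tumor cohort
#'
#' Defines the planted structure of a simulated meta-cohort: `k_true` latent
#' expression patterns, a correlated panel of pathway genes driving the
#' clustering, two signature modules (a prognosis-favorable module whose
#' expression rises with the latent score and an unfavorable module that
#' falls with it), proportional-hazards survival driven by the latent score
#' (optionally together with an ordinal stage covariate), additive batch
#' structure and iid Gaussian noise on the log2 scale.
#'
#' @param n_samples Number of samples (>= 3 * `k_true`).
#' @param n_genes Total number of genes; must accommodate panel + modules.
#' @param k_true Number of latent expression patterns.
#' @param panel_size Number of correlated pathway-panel genes.
#' @param module_sizes Length-2 integer vector: sizes of the favorable and
#'   unfavorable signature modules.
#' @param effect_size Separation of planted effects in within-cluster SD
#'   units (noise SD is 1 on the log2 scale).
#' @param beta_score Planted log-hazard per unit of the standardized latent
#'   score. Negative values make a high score protective.
#' @param beta_stage Planted log-hazard per unit of the ordinal stage
#'   covariate (stage is negatively correlated with the latent score).
#' @param censor_rate Target fraction of censored subjects in [0, 1).
#' @param n_batches Number of sub-cohort batches.
#' @param batch_shift SD of the per-gene additive batch offsets (batch 1 is
#'   the reference and gets no shift).
#' @param batch_scale If `TRUE`, batches also get mild per-gene scale
#'   effects; default location-only.
#' @param seed RNG seed.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_samples = 300L, n_genes = 2000L, k_true = 3L,
                          panel_size = 24L, module_sizes = c(60L, 15L),
                          effect_size = 1.2, beta_score = -1.0,
                          beta_stage = 0.4, censor_rate = 0.3,
                          n_batches = 2L, batch_shift = 1.0,
                          batch_scale = FALSE, seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
    k_true = as.integer(k_true), panel_size = as.integer(panel_size),
    module_sizes = as.integer(module_sizes), effect_size = effect_size,
    beta_score = beta_score, beta_stage = beta_stage,
    censor_rate = censor_rate, n_batches = as.integer(n_batches),
    batch_shift = batch_shift, batch_scale = isTRUE(batch_scale),
    seed = as.integer(seed)
  )
  if (cfg$n_samples < 3L * cfg$k_true) {
    stop_config("n_samples (%d) must be >= 3 * k_true (%d)", cfg$n_samples, 3L * cfg$k_true)
  }
  if (length(cfg$module_sizes) != 2L || any(cfg$module_sizes < 1L)) {
    stop_config("module_sizes must be two positive counts")
  }
  if (cfg$panel_size + sum(cfg$module_sizes) > cfg$n_genes) {
    stop_config("panel_size + module sizes exceed n_genes")
  }
  if (cfg$censor_rate < 0 || cfg$censor_rate >= 1) stop_config("censor_rate must be in [0, 1)")
  if (cfg$k_true < 1L || cfg$n_batches < 1L) stop_config("k_true and n_batches must be >= 1")
  class(cfg) <- "CohortConfig"
  cfg
}

# Exponential censoring rate tuned by bisection so that, for the drawn event
# times and censoring quantiles, the realised censored fraction (including
# administrative censoring at tau) hits the target as closely as possible.
censoring_rate_for <- function(event_time, u, target, tau) {
  frac <- function(rate) {
    cens <- if (rate <= 0) rep(Inf, length(u)) else -log(u) / rate
    mean(pmin(cens, tau) < event_time)
  }
  base <- frac(0)
  if (target <= base) return(0)
  lo <- 1e-8
  hi <- 1
  while (frac(hi) < target && hi < 1e6) hi <- hi * 2
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (frac(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Expression is built on the log2 scale as baseline gene means plus
#' cluster-level panel offsets, module effects proportional to the latent
#' score, per-batch additive shifts, and iid N(0, 1) noise. Survival times
#' follow an exponential proportional-hazards model with linear predictor
#' `beta_score * z(latent) + beta_stage * (stage - mean(stage))`; censoring
#' combines an administrative cap with an exponential censoring time whose
#' rate is tuned by bisection to the requested `censor_rate`. The output is
#' bitwise reproducible for a fixed config.
#'
#' @param config A [cohort_config()].
#' @param scale Output scale: `"log2"` (default) or `"fpkm"` (`2^x`), to
#'   exercise the FPKM -> TPM path.
#' @return A list with `expression` ([expression_matrix()]), `clinical`
#'   (data.frame: sample_id, time, event, stage, mycn, age_group, sex,
#'   batch), and `truth` (list: cluster_labels, favorable_genes,
#'   unfavorable_genes, panel_genes, latent_score, batch_labels, gene_ids).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 30, n_genes = 200, seed = 7))
#' dim(cohort$expression)
#' @export
generate_cohort <- function(config = cohort_config(), scale = c("log2", "fpkm")) {
  if (!inherits(config, "CohortConfig")) config <- do.call(cohort_config, config)
  scale <- match.arg(scale)
  set.seed(config$seed)
  n <- config$n_samples
  g <- config$n_genes
  k <- config$k_true

  gene_ids <- sprintf("gene_%04d", seq_len(g))
  sample_ids <- sprintf("sample_%03d", seq_len(n))
  panel <- gene_ids[seq_len(config$panel_size)]
  fav <- gene_ids[config$panel_size + seq_len(config$module_sizes[1L])]
  unf <- gene_ids[config$panel_size + config$module_sizes[1L] + seq_len(config$module_sizes[2L])]

  cluster <- rep(seq_len(k), length.out = n)
  # Cluster activation levels, centered and unit-spaced: for k = 3 these are
  # (1, 0, -1); they drive both the panel offsets and the latent score.
  u_levels <- rev(seq_len(k)) - (k + 1) / 2
  u <- u_levels[cluster]
  latent <- u + 0.5 * stats::rnorm(n)

  base_mean <- stats::rnorm(g, mean = 7, sd = 1.5)
  X <- matrix(base_mean, nrow = g, ncol = n) + matrix(stats::rnorm(g * n), g, n)
  dimnames(X) <- list(gene_ids, sample_ids)

  es <- config$effect_size
  if (es != 0) {
    # Panel genes share the cluster activation -> correlated panel + separable clusters.
    X[panel, ] <- X[panel, ] + es * matrix(u, length(panel), n, byrow = TRUE)
    X[fav, ] <- X[fav, ] + es * matrix(latent, length(fav), n, byrow = TRUE)
    X[unf, ] <- X[unf, ] - es * matrix(latent, length(unf), n, byrow = TRUE)
  }

  batch <- rep(seq_len(config$n_batches), length.out = n)
  if (config$n_batches > 1L && config$batch_shift != 0) {
    for (b in seq(2L, config$n_batches)) {
      delta <- stats::rnorm(g, mean = 0, sd = config$batch_shift)
      mult <- if (config$batch_scale) exp(stats::rnorm(g, 0, 0.1)) else rep(1, g)
      idx <- batch == b
      X[, idx] <- X[, idx] * mult + delta
    }
  }

  # Clinical covariates; stage is an ordinal 1..4 negatively tied to the score.
  z_latent <- as.vector(base::scale(latent))
  stage_prop <- -z_latent + 0.8 * stats::rnorm(n)
  stage <- as.integer(cut(stage_prop,
    breaks = stats::quantile(stage_prop, c(0, .25, .5, .75, 1)),
    include.lowest = TRUE, labels = FALSE
  ))
  mycn <- stats::rbinom(n, 1L, stats::plogis(-z_latent))
  age_group <- stats::rbinom(n, 1L, stats::plogis(-0.5 * z_latent))
  sex <- stats::rbinom(n, 1L, 0.5)

  lp <- config$beta_score * z_latent + config$beta_stage * (stage - mean(stage))
  lambda0 <- log(2) / 36 # baseline median survival 36 study units (months)
  event_time <- stats::rexp(n, rate = lambda0 * exp(lp))
  # administrative close-out at the 99th percentile of event times, so the
  # exponential censoring component can reach any requested censor_rate
  tau <- unname(stats::quantile(event_time, 0.99))
  u_cens <- stats::runif(n)
  rate_c <- censoring_rate_for(event_time, u_cens, config$censor_rate, tau)
  cens_time <- pmin(if (rate_c <= 0) rep(Inf, n) else -log(u_cens) / rate_c, tau)
  time <- pmin(event_time, cens_time)
  event <- as.integer(event_time <= cens_time)
  time <- pmax(time, 1e-4)

  clinical <- data.frame(
    sample_id = sample_ids, time = time, event = event,
    stage = stage, mycn = mycn, age_group = age_group, sex = sex,
    batch = batch, stringsAsFactors = FALSE
  )
  truth <- list(
    cluster_labels = stats::setNames(cluster, sample_ids),
    favorable_genes = fav, unfavorable_genes = unf, panel_genes = panel,
    latent_score = stats::setNames(latent, sample_ids),
    batch_labels = stats::setNames(batch, sample_ids),
    gene_ids = gene_ids
  )
  expr <- if (scale == "fpkm") expression_matrix(2^X, "fpkm") else expression_matrix(X, "log2")
  list(expression = expr, clinical = clinical, truth = truth, config = config)
}

#' Build gene-set fixtures from planted modules
#'
#' Returns the two planted signature modules as named sets plus `n_decoy`
#' random sets drawn without replacement from the gene universe, with sizes
#' matched (alternately) to the two modules.
#'
#' @param truth The `truth` element of [generate_cohort()].
#' @param n_decoy Number of decoy sets (>= 0).
#' @param seed RNG seed for decoy sampling.
#' @return Named list of character vectors (a gene-set collection).
#' @export
generate_genesets <- function(truth, n_decoy = 5L, seed = 1L) {
  if (n_decoy < 0L) stop_config("n_decoy must be >= 0")
  if (!length(truth$favorable_genes) || !length(truth$unfavorable_genes)) {
    stop_config("truth gene lists must be nonempty")
  }
  sets <- list(
    favorable_module = truth$favorable_genes,
    unfavorable_module = truth$unfavorable_genes
  )
  if (n_decoy > 0L) {
    set.seed(derive_seed(seed, 17L))
    sizes <- rep(lengths(sets), length.out = n_decoy)
    for (i in seq_len(n_decoy)) {
      sets[[sprintf("decoy_%02d", i)]] <- sample(truth$gene_ids, sizes[i])
    }
  }
  sets
}

#' Simulate binary therapy-response labels from the latent score
#'
#' Response is Bernoulli with success probability
#' `plogis(logit_slope * z(latent_score))`, emulating an immune-checkpoint
#' response endpoint that is positively linked to the latent score.
#'
#' @param truth The `truth` element of [generate_cohort()].
#' @param logit_slope Log-odds of response per SD of latent score.
#' @param seed RNG seed.
#' @return Named integer vector of 0/1 response labels.
#' @export
generate_response_labels <- function(truth, logit_slope = 1.0, seed = 1L) {
  ls <- truth$latent_score
  if (is.null(ls)) stop_config("truth must contain latent_score")
  set.seed(derive_seed(seed, 29L))
  z <- as.vector(base::scale(ls))
  stats::setNames(stats::rbinom(length(z), 1L, stats::plogis(logit_slope * z)), names(ls))
}
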