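# End-to-end orchestration: simulate -> preprocess -> cluster -> derive ->
# score -> survive -> enrich, with TSV/JSON artifacts and a hashed manifest.

#' Default pipeline configuration
#'
#' A nested list of stage parameters for [run_pipeline()], defaulting to
#' the synthetic study conditions: a 2,000-gene, 300-sample cohort with 3
#' latent patterns, consensus clustering on the pathway panel over k = 2..6
#' with 1,000 resampling iterations, |log2FC| > 1 and BH q < 0.05
#' differential-expression thresholds, Boruta de-redundancy, PC1-difference
#' scoring, and survival evaluation at 36- and 60-month horizons.
#'
#' @param seed Global seed fanned out to every stochastic stage.
#' @param overrides Named list merged over the defaults (one level deep).
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, overrides = list()) {
  cfg <- list(
    seed = as.integer(seed),
    cohort = list(),          # passed to cohort_config(); seed filled from global
    cluster = list(k_range = 2:6, n_iter = 1000L, p_item = 0.8),
    degs = list(lfc_thresh = 1, alpha = 0.05, combine = "intersection"),
    boruta = list(max_iter = 100L, alpha = 0.01, num_trees = 500L),
    survive = list(horizons = c(36, 60), covariates = c("stage", "mycn", "age_group", "sex"), min_frac = 0.1),
    enrich = list(n_decoy = 5L, ssgsea_alpha = 0.25, gsea_n_perm = 1000L)
  )
  for (nm in names(overrides)) {
    if (is.list(overrides[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      cfg[[nm]] <- overrides[[nm]]
    }
  }
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read a clinical table from TSV
#'
#' Requires `sample_id`, `time` (> 0) and `event` (0/1) columns; any other
#' covariate columns are passed through untouched.
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop_data("clinical file not found: %s", path)
  df <- utils::read.table(
    path, header = TRUE, sep = "\t", quote = "", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  need <- c("sample_id", "time", "event")
  missing <- setdiff(need, names(df))
  if (length(missing)) stop_data("clinical table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(df$time <= 0)) stop_data("clinical times must be > 0")
  if (!all(df$event %in% c(0, 1))) stop_data("event column must be 0/1")
  if (anyDuplicated(df$sample_id)) stop_data("duplicated sample_id in clinical table")
  df
}

write_tsv <- function(df, path, comment = "# pyroscore table v1") {
  con <- file(path, "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(comment, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Drop samples present in only one of expression/clinical, with a message.
join_cohort <- function(expr, clinical) {
  common <- intersect(sample_ids(expr), clinical$sample_id)
  dropped <- length(sample_ids(expr)) + nrow(clinical) - 2L * length(common)
  if (dropped > 0L) {
    warning(sprintf("%d sample(s) present in only one of expression/clinical; dropped", dropped))
  }
  if (length(common) < 3L) stop_data("fewer than 3 samples shared by expression and clinical")
  list(
    expr = expression_matrix(expr$values[, common, drop = FALSE], expr$scale),
    clinical = clinical[match(common, clinical$sample_id), , drop = FALSE]
  )
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading of supplied TSVs),
#' preprocessing (FPKM->TPM->log2 where needed, batch adjustment,
#' z-scoring), consensus clustering of the pathway panel with PAC-driven
#' choice of k, derivation of the signed signatures (pairwise moderated-t
#' DEGs, Boruta, good/bad-prognosis split oriented by median survival),
#' PC1-difference scoring, survival evaluation (optimal cutpoint, log-rank,
#' uni-/multivariable Cox, NRI/IDI, C-index, time-dependent AUC, decision
#' curves) and gene-set enrichment (ORA of the signatures, preranked GSEA
#' on the score-correlation ranking, ssGSEA). Every intermediate table is
#' written to `outdir` together with a manifest (parameters, seed, content
#' hashes) and a summary report. Any stage error aborts with the stage
#' name.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @param expression_path,clinical_path Optional TSV inputs; when `NULL`
#'   (default) a synthetic cohort is generated from `config$cohort`.
#' @return Invisibly, a list with the summary report and the paths of all
#'   artifacts.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir,
                         expression_path = NULL, clinical_path = NULL) {
  if (!inherits(config, "PipelineConfig")) stop_config("config must be a PipelineConfig")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = c("pyroscore_pipeline_error", "pyroscore_error")
      ))
    })
  }

  ## simulate / load ---------------------------------------------------------
  truth <- NULL
  sim <- stage("simulate", function() {
    if (!is.null(expression_path)) {
      if (is.null(clinical_path) || !file.exists(clinical_path)) {
        stop_data("clinical.tsv not found: %s", clinical_path %||% "<missing>")
      }
      list(
        expression = read_expression(expression_path, scale = "fpkm"),
        clinical = read_clinical(clinical_path), truth = NULL,
        config = NULL
      )
    } else {
      ccfg <- do.call(cohort_config, c(config$cohort, list(seed = derive_seed(config$seed, 1L))))
      generate_cohort(ccfg, scale = "fpkm")
    }
  })
  truth <- sim$truth
  joined <- join_cohort(sim$expression, sim$clinical)
  expr_raw <- joined$expr
  clinical <- joined$clinical
  paths$expression <- file.path(outdir, "expression.tsv")
  write_expression(expr_raw, paths$expression)
  paths$clinical <- file.path(outdir, "clinical.tsv")
  write_tsv(clinical, paths$clinical)
  if (!is.null(truth)) {
    paths$truth <- file.path(outdir, "truth.json")
    jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  }

  ## preprocess --------------------------------------------------------------
  pre <- stage("preprocess", function() {
    m <- expr_raw
    if (m$scale == "fpkm") m <- fpkm_to_tpm(m)
    if (m$scale %in% c("fpkm", "tpm")) m <- log2_transform(m)
    if ("batch" %in% names(clinical) && length(unique(clinical$batch)) > 1L) {
      m <- batch_adjust(m, stats::setNames(clinical$batch, clinical$sample_id))
    }
    list(log2 = m, z = zscore_genes(m))
  })
  paths$expression_z <- file.path(outdir, "expression_zscore.tsv")
  write_expression(pre$z, paths$expression_z)

  ## cluster -----------------------------------------------------------------
  panel <- if (!is.null(truth)) truth$panel_genes else {
    top_variable_genes(pre$log2, min(24L, nrow(pre$log2$values)))
  }
  clu <- stage("cluster", function() {
    panel_z <- expression_matrix(pre$z$values[panel, , drop = FALSE], "zscore")
    sel <- select_k(panel_z,
      k_range = config$cluster$k_range, n_iter = config$cluster$n_iter,
      p_item = config$cluster$p_item, seed = derive_seed(config$seed, 2L)
    )
    labels <- cluster_from_consensus(sel$consensus[[as.character(sel$k_star)]])
    list(sel = sel, labels = labels)
  })
  paths$labels <- file.path(outdir, "labels.tsv")
  write_tsv(data.frame(sample_id = names(clu$labels), cluster = clu$labels), paths$labels)
  paths$pac <- file.path(outdir, "pac.tsv")
  write_tsv(data.frame(k = as.integer(names(clu$sel$pac)), pac = clu$sel$pac), paths$pac)

  ## derive signatures -------------------------------------------------------
  der <- stage("derive-signatures", function() {
    degs <- pairwise_degs(pre$log2, clu$labels,
      lfc_thresh = config$degs$lfc_thresh, alpha = config$degs$alpha,
      combine = config$degs$combine
    )
    if (length(degs) < 2L) stop_data("fewer than 2 DEGs survive the pairwise thresholds")
    sub <- expression_matrix(pre$z$values[degs, , drop = FALSE], "zscore")
    bor <- boruta_select(sub, clu$labels,
      max_iter = config$boruta$max_iter, alpha = config$boruta$alpha,
      seed = derive_seed(config$seed, 3L), num_trees = config$boruta$num_trees
    )
    keep <- union(bor$confirmed, bor$tentative_resolved)
    if (length(keep) < 2L) stop_data("Boruta retained fewer than 2 genes")
    fav <- favorable_clusters_by_survival(clu$labels, clinical)
    sig <- split_signatures(pre$z, clu$labels, keep, fav)
    list(degs = degs, boruta = bor, favorable = fav, sig = sig)
  })
  paths$degs <- file.path(outdir, "degs.tsv")
  write_tsv(data.frame(gene = as.character(der$degs)), paths$degs)
  paths$signatures <- file.path(outdir, "signatures.json")
  jsonlite::write_json(list(gppg = der$sig$gppg, bppg = der$sig$bppg),
    paths$signatures, auto_unbox = FALSE)

  ## score -------------------------------------------------------------------
  scores <- stage("score", function() compute_pyroscore(pre$z, der$sig))
  paths$scores <- file.path(outdir, "scores.tsv")
  write_tsv(as.data.frame(scores), paths$scores)

  ## survive -----------------------------------------------------------------
  surv <- stage("survive", function() {
    sc <- scores$pyroscore[match(clinical$sample_id, scores$sample_id)]
    clinical$pyroscore <- as.vector(base::scale(sc))
    covs <- intersect(config$survive$covariates, names(clinical))
    covs <- covs[vapply(covs, function(v) length(unique(clinical[[v]])) > 1L, logical(1))]
    cut <- optimal_cutpoint(sc, clinical$time, clinical$event,
      min_frac = config$survive$min_frac)
    lr <- logrank_test(clinical$time, clinical$event, sc > cut$cutpoint)
    uni <- lapply(c("pyroscore", covs), function(v) cox_fit(clinical, v)$coef)
    multi <- cox_fit(clinical, c("pyroscore", covs))
    old_model <- cox_fit(clinical, covs)
    horizons <- config$survive$horizons
    eval_h <- lapply(horizons, function(h) {
      r_old <- risk_at_t(old_model, t = h)
      r_new <- risk_at_t(multi, t = h)
      rc <- reclassification_metrics(r_old, r_new, clinical$time, clinical$event, h)
      list(
        horizon = h, nri = rc$nri, idi = rc$idi,
        auc_old = time_dependent_auc(r_old, clinical$time, clinical$event, h),
        auc_new = time_dependent_auc(r_new, clinical$time, clinical$event, h),
        dca = decision_curve(r_new, clinical$time, clinical$event, h)
      )
    })
    list(
      cutpoint = cut, logrank = lr, cox_uni = do.call(rbind, uni),
      cox_multi = multi, old_model = old_model,
      cindex_new = concordance_index(multi$lp, clinical$time, clinical$event),
      cindex_old = concordance_index(old_model$lp, clinical$time, clinical$event),
      horizons = eval_h, nomogram = nomogram_points(multi)
    )
  })
  paths$cox_uni <- file.path(outdir, "cox_univariate.tsv")
  write_tsv(surv$cox_uni, paths$cox_uni)
  paths$cox_multi <- file.path(outdir, "cox_multivariate.tsv")
  write_tsv(surv$cox_multi$coef, paths$cox_multi)
  paths$eval <- file.path(outdir, "eval_report.json")
  jsonlite::write_json(
    list(
      cutpoint = surv$cutpoint[c("cutpoint", "chi2", "p_naive")],
      logrank = surv$logrank,
      cindex = list(old = surv$cindex_old, new = surv$cindex_new),
      horizons = lapply(surv$horizons, function(h) h[c("horizon", "nri", "idi", "auc_old", "auc_new")])
    ),
    paths$eval, auto_unbox = TRUE, digits = NA
  )

  ## enrich ------------------------------------------------------------------
  enr <- stage("enrich", function() {
    sets <- if (!is.null(truth)) {
      generate_genesets(truth, n_decoy = config$enrich$n_decoy, seed = derive_seed(config$seed, 4L))
    } else {
      list(gppg = der$sig$gppg, bppg = der$sig$bppg)
    }
    ora <- ora_analysis(der$sig$gppg, sets, gene_ids(pre$z))
    sc <- scores$pyroscore[match(sample_ids(pre$z), scores$sample_id)]
    rank_stat <- apply(pre$z$values, 1L, function(g) stats::cor(g, sc, method = "spearman"))
    gsea <- lapply(sets, function(s) {
      gsea_preranked(rank_stat, s,
        n_perm = config$enrich$gsea_n_perm, seed = derive_seed(config$seed, 5L))
    })
    ssg <- ssgsea_scores(pre$z, sets, alpha = config$enrich$ssgsea_alpha)
    list(sets = sets, ora = ora, gsea = gsea, ssgsea = ssg)
  })
  paths$genesets <- file.path(outdir, "genesets.gmt")
  write_gmt(enr$sets, paths$genesets)
  paths$ora <- file.path(outdir, "ora.tsv")
  write_tsv(enr$ora, paths$ora)
  paths$ssgsea <- file.path(outdir, "ssgsea.tsv")
  write_tsv(data.frame(set = rownames(enr$ssgsea), enr$ssgsea, check.names = FALSE), paths$ssgsea)

  ## manifest + summary ------------------------------------------------------
  summary <- list(
    seed = config$seed,
    n_samples = ncol(pre$z$values), n_genes = nrow(pre$z$values),
    selected_k = clu$sel$k_star, pac = as.list(clu$sel$pac),
    n_degs = length(der$degs),
    n_gppg = length(der$sig$gppg), n_bppg = length(der$sig$bppg),
    cutpoint = surv$cutpoint$cutpoint, logrank_p = surv$logrank$p,
    cox_multi = surv$cox_multi$coef,
    cindex = list(old = surv$cindex_old, new = surv$cindex_new),
    horizons = lapply(surv$horizons, function(h) h[c("horizon", "nri", "idi", "auc_old", "auc_new")])
  )
  paths$summary <- file.path(outdir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE, digits = NA)
  hashes <- vapply(paths[setdiff(names(paths), "manifest")], function(p) {
    unname(tools::md5sum(p))
  }, character(1))
  manifest <- list(
    package_version = as.character(utils::packageVersion("pyroscore")),
    seed = config$seed,
    parameters = unclass(config),
    artifacts = as.list(hashes)
  )
  paths$manifest <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

  invisible(list(
    summary = summary, paths = paths, labels = clu$labels, signatures = der$sig,
    scores = scores, truth = truth, survival = surv, enrichment = enr
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
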