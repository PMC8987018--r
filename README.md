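# pyroscore

Pyroptosis — gasdermin-mediated inflammatory cell death — shapes the tumor
immune microenvironment, and in pediatric neuroblastoma its gene network
carries prognostic information. `pyroscore` is an R package for analysts who
want to reproduce that style of analysis end to end on their own cohorts:
discover expression patterns driven by a pyroptosis gene panel, derive
signed prognostic signatures from those patterns, summarize each tumor in a
single score, and quantify how much that score improves clinical risk
models.

The pipeline:

1. **Preprocess** — FPKM → TPM (columns sum to 10^6), `log2(x+1)`,
   empirical-Bayes batch adjustment across sub-cohorts, gene-wise z-scores.
2. **Cluster** — resampling consensus clustering of samples on the panel
   genes (Euclidean distance, Ward linkage), with the number of clusters
   chosen by the proportion of ambiguous clustering,
   `PAC = F(0.9) − F(0.1)` over the off-diagonal consensus entries (minimum
   PAC wins).
3. **Derive signatures** — genes separating *every* cluster pair
   (moderated-t with empirical-Bayes variance shrinkage, |log2FC| > 1, BH
   q < 0.05), de-redundanced by Boruta shadow-feature selection, then split
   into good-prognosis (GPPG) and bad-prognosis (BPPG) sets by association
   sign with the survival-favorable clusters.
4. **Score** — per sample,
   `pyroscore = PC1(GPPG submatrix) − PC1(BPPG submatrix)`,
   each term the sample's first-principal-component coordinate over one
   signature, sign-anchored to the signature's mean expression.
5. **Evaluate** — maximally-selected log-rank cutpoint, Kaplan–Meier and
   log-rank tests, uni-/multivariable Cox (Efron ties, Breslow baseline),
   continuous NRI and IDI with IPCW handling of censoring, Harrell's C,
   time-dependent (cumulative/dynamic) AUC, decision curves, nomogram
   points. Gene-set tooling (hypergeometric ORA, preranked GSEA, ssGSEA)
   annotates the signatures.

Real cohorts of this kind live in external repositories, so the package
ships a synthetic-cohort generator (`generate_cohort()`) that plants
cluster structure, favorable/unfavorable signature modules, a latent score
driving proportional-hazards survival next to a correlated stage covariate,
batch structure, and therapy-response labels — every stage of the pipeline
is tested against that ground truth.

## Worked example

```r
library(pyroscore)

cohort <- generate_cohort(cohort_config(seed = 1))   # 2000 genes x 300 samples
z      <- zscore_genes(cohort$expression)

panel  <- expression_matrix(z$values[cohort$truth$panel_genes, ], "zscore")
sel    <- select_k(panel, k_range = 2:6, n_iter = 250, seed = 1)
round(sel$pac, 3)
#>     2     3     4     5     6
#> 0.469 0.059 0.212 0.241 0.181     # PAC is minimized at k = 3
labels <- cluster_from_consensus(sel$consensus[[as.character(sel$k_star)]])

degs <- pairwise_degs(cohort$expression, labels)     # 88 genes pass all pairs
sig  <- split_signatures(z, labels, degs,
                         favorable_clusters_by_survival(labels, cohort$clinical))
length(sig$gppg); length(sig$bppg)
#> [1] 74
#> [1] 14

sv <- compute_pyroscore(z, sig)
head(sv, 3)
#>    sample_id   pc1_gppg  pc1_bppg  pyroscore
#> 1 sample_001  5.6393666 -0.788038   6.427405
#> 2 sample_002  0.4512938 -0.577553   1.028847
#> 3 sample_003 -8.7503409  4.623823 -13.374163

cl <- cohort$clinical
cl$pyroscore <- as.vector(scale(sv$pyroscore[match(cl$sample_id, sv$sample_id)]))
cox_fit(cl, c("pyroscore", "stage"))$coef[, c("covariate", "hr", "ci_low", "ci_high", "p")]
#>   covariate    hr ci_low ci_high        p
#> 1 pyroscore 0.378  0.296   0.482 4.05e-15
#> 2     stage 1.505  1.219   1.858 1.41e-04
```

A one-SD increase in pyroscore carries a hazard ratio of 0.38 — a strong
protective effect that remains significant beside the correlated stage
covariate, i.e. the score behaves as an independent prognostic factor in
this cohort. Adding the score to a stage-only risk model reclassifies
substantially at the 36-month horizon:

```r
old <- cox_fit(cl, "stage"); new <- cox_fit(cl, c("stage", "pyroscore"))
reclassification_metrics(risk_at_t(old, t = 36), risk_at_t(new, t = 36),
                         cl$time, cl$event, 36)[c("nri", "idi")]
#> $nri [1] 0.773      $idi [1] 0.085
time_dependent_auc(risk_at_t(new, t = 36), cl$time, cl$event, 36)
#> [1] 0.887
```

`run_pipeline(pipeline_config(seed = 1), "out/")` runs all of the above
plus enrichment in one call, writing every intermediate table, a summary
and a content-hashed manifest (two runs with the same seed are
byte-identical). A thin command-line wrapper with per-stage subcommands
(`simulate`, `preprocess`, `cluster`, `derive-signatures`, `score`,
`survive`, `enrich`, `run-all`) lives at `inst/scripts/pyroscore-cli`.

## Documentation

Function documentation lives in the roxygen comments under `R/`; the
methods vignette (`vignettes/pyroscore-methods.Rmd`) describes the model,
its assumptions, the synthetic-data design, numerical choices and known
limitations.
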