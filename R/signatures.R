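# Derivation of the signed prognostic signatures: moderated-t differential
# expression between cluster pairs, BH correction, intersection of per-pair
# hits, Boruta shadow-feature de-redundancy, and the good-/bad-prognosis
# split by association sign.

# Inverse of trigamma by Newton iteration (monotone decreasing function).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

# Moment-match a scaled F distribution to observed gene-wise variances on
# the log scale: returns the prior df d0 and prior variance s0^2.
fit_f_prior <- function(s2, df) {
  s2 <- pmax(s2, 1e-12)
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (!is.finite(evar) || evar <= 0) {
    return(list(df_prior = Inf, var_prior = exp(ebar)))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(df_prior = d0, var_prior = s0)
}

#' Moderated two-group t-test across genes
#'
#' Gene-wise two-group comparison with empirical-Bayes variance shrinkage:
#' the pooled residual variance of each gene is shrunk toward a prior
#' variance `s0^2` with prior degrees of freedom `d0`, both estimated by
#' moment-matching a scaled F distribution to the observed variances. The
#' moderated statistic is `log2FC / (s_post * sqrt(1/nA + 1/nB))` on
#' `d + d0` degrees of freedom. `prior_df = 0` disables shrinkage and
#' recovers the ordinary pooled-variance t-test exactly.
#'
#' @param X An [expression_matrix()] on the log2 (or z-score) scale.
#' @param groupA,groupB Sample ids (or column indices) of the two groups,
#'   each of size >= 2. `log2FC` is mean(A) - mean(B).
#' @param prior_df Optional override of the prior degrees of freedom;
#'   `NULL` (default) estimates it from the data.
#' @return Data frame with one row per gene: `gene`, `log2FC`, `t_mod`,
#'   `p`, `q` (BH-adjusted), plus attributes `df_prior` and `var_prior`.
#' @export
moderated_t <- function(X, groupA, groupB, prior_df = NULL) {
  m <- as_expr(X)
  V <- m$values
  a <- if (is.character(groupA)) match(groupA, sample_ids(m)) else as.integer(groupA)
  b <- if (is.character(groupB)) match(groupB, sample_ids(m)) else as.integer(groupB)
  if (anyNA(a) || anyNA(b)) stop_data("group contains unknown sample ids")
  nA <- length(a)
  nB <- length(b)
  if (nA < 2L || nB < 2L) stop_data("each group needs >= 2 samples")
  XA <- V[, a, drop = FALSE]
  XB <- V[, b, drop = FALSE]
  mA <- rowMeans(XA)
  mB <- rowMeans(XB)
  df <- nA + nB - 2L
  ssA <- rowSums((XA - mA)^2)
  ssB <- rowSums((XB - mB)^2)
  s2 <- (ssA + ssB) / df
  if (is.null(prior_df)) {
    prior <- fit_f_prior(s2, df)
  } else if (prior_df == 0) {
    prior <- list(df_prior = 0, var_prior = mean(s2))
  } else {
    prior <- list(df_prior = prior_df, var_prior = fit_f_prior(s2, df)$var_prior)
  }
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$var_prior, length(s2))
  } else if (d0 == 0) {
    s2
  } else {
    (d0 * prior$var_prior + df * s2) / (d0 + df)
  }
  lfc <- mA - mB
  se <- sqrt(s2_post * (1 / nA + 1 / nB))
  tmod <- ifelse(se > 0, lfc / se, 0)
  df_total <- if (is.infinite(d0)) Inf else df + d0
  p <- 2 * stats::pt(abs(tmod), df = df_total, lower.tail = FALSE)
  p[se == 0 & lfc == 0] <- 1
  out <- data.frame(
    gene = rownames(V), log2FC = lfc, t_mod = tmod, p = p,
    q = bh_adjust(p), row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "df_prior") <- d0
  attr(out, "var_prior") <- prior$var_prior
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of adjusted p-values (q-values), same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_data("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genes differential in every cluster pair
#'
#' For each unordered pair of clusters, runs [moderated_t()] with BH
#' correction; a gene hits a pair when `|log2FC| > lfc_thresh` and
#' `q < alpha`. Returns the combination of the per-pair hit sets —
#' intersection by default (a gene must separate every pair), or union.
#'
#' @param X An `ExpressionMatrix` (log2 scale).
#' @param labels Cluster labels, one per sample (or named by sample id).
#' @param lfc_thresh Absolute log2 fold-change threshold (default 1).
#' @param alpha BH-adjusted significance threshold (default 0.05).
#' @param combine `"intersection"` (default) or `"union"` of per-pair hits.
#' @return Character vector of gene ids; attribute `per_pair` holds the
#'   per-pair hit lists.
#' @export
pairwise_degs <- function(X, labels, lfc_thresh = 1, alpha = 0.05,
                          combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  m <- as_expr(X)
  labels <- align_labels(labels, sample_ids(m))
  cl <- sort(unique(labels))
  if (length(cl) < 2L) stop_data("need >= 2 clusters")
  if (any(table(labels) < 2L)) stop_data("every cluster needs >= 2 samples")
  pairs <- utils::combn(cl, 2L, simplify = FALSE)
  hits <- lapply(pairs, function(pr) {
    de <- moderated_t(m, which(labels == pr[1L]), which(labels == pr[2L]))
    de$gene[abs(de$log2FC) > lfc_thresh & de$q < alpha]
  })
  names(hits) <- vapply(pairs, paste, character(1), collapse = "_vs_")
  out <- if (combine == "intersection") Reduce(intersect, hits) else Reduce(union, hits)
  out <- out[order(match(out, gene_ids(m)))]
  attr(out, "per_pair") <- hits
  out
}

align_labels <- function(labels, sids) {
  if (!is.null(names(labels))) {
    if (!all(sids %in% names(labels))) stop_data("labels missing for some samples")
    labels <- labels[sids]
  } else if (length(labels) != length(sids)) {
    stop_data("labels must have one entry per sample")
  }
  unname(labels)
}

#' Boruta all-relevant feature selection
#'
#' Each iteration appends a permuted "shadow" copy of every feature, fits a
#' random-forest classifier (500 trees, sqrt(p) candidate features per
#' split), and scores a hit for every real feature whose importance exceeds
#' the maximum shadow importance. Features whose hit counts are
#' significantly above (below) Binomial(iters, 0.5) — two-sided binomial
#' test, BH-corrected across undecided features at level `alpha` — are
#' confirmed (rejected, and dropped from later iterations). The loop stops
#' at `max_iter` or when nothing is tentative; remaining tentative features
#' are resolved by comparing their median importance to the median of the
#' per-iteration maximum shadow importances.
#'
#' @param X An `ExpressionMatrix` or genes x samples matrix; features are
#'   genes.
#' @param target Class labels, one per sample (or named by sample id).
#' @param max_iter Maximum number of iterations.
#' @param alpha Two-sided significance level for the binomial decisions.
#' @param seed RNG seed (controls permutations and forests).
#' @param num_trees Trees per forest.
#' @return List with character vectors `confirmed`, `tentative`, `rejected`
#'   and the final `hit_counts` / `n_iter` bookkeeping.
#' @export
boruta_select <- function(X, target, max_iter = 100L, alpha = 0.01, seed = 1L,
                          num_trees = 500L) {
  m <- as_expr(X)
  V <- m$values
  if (any(!is.finite(V))) stop_data("non-finite values in feature matrix")
  target <- align_labels(target, sample_ids(m))
  target <- as.factor(target)
  if (nlevels(target) < 2L) stop_data("need >= 2 classes")
  if (any(table(target) < 5L)) stop_data("need >= 5 samples per class")
  feats <- rownames(V)
  dat <- t(V) # samples x features
  active <- rep(TRUE, length(feats)) # not yet rejected
  decided <- rep(NA, length(feats)) # NA = tentative, TRUE = confirmed, FALSE = rejected
  hits <- integer(length(feats))
  imp_hist <- vector("list", length(feats))
  shadow_max_hist <- numeric(0)
  set.seed(derive_seed(seed, 3L))
  n <- nrow(dat)
  iter <- 0L
  while (iter < max_iter && any(is.na(decided) & active)) {
    iter <- iter + 1L
    use <- which(active)
    real <- dat[, use, drop = FALSE]
    shadow <- apply(real, 2L, sample)
    colnames(shadow) <- paste0("shadow_", colnames(real))
    df <- as.data.frame(cbind(real, shadow))
    fit <- ranger::ranger(
      x = df, y = target, num.trees = num_trees,
      mtry = max(1L, floor(sqrt(ncol(df)))), importance = "impurity",
      seed = derive_seed(seed, 100L + iter), num.threads = 1L
    )
    imp <- fit$variable.importance
    imp_real <- imp[seq_along(use)]
    imp_shadow_max <- max(imp[-seq_along(use)])
    shadow_max_hist <- c(shadow_max_hist, imp_shadow_max)
    hit_now <- imp_real > imp_shadow_max
    hits[use] <- hits[use] + as.integer(hit_now)
    for (j in seq_along(use)) {
      imp_hist[[use[j]]] <- c(imp_hist[[use[j]]], imp_real[j])
    }
    if (iter >= 5L) {
      und <- which(is.na(decided) & active)
      p_two <- vapply(hits[und], function(h) {
        min(1, 2 * min(stats::pbinom(h, iter, 0.5), stats::pbinom(h - 1L, iter, 0.5, lower.tail = FALSE)))
      }, numeric(1))
      q <- bh_adjust(p_two)
      up <- q < alpha & hits[und] > iter / 2
      down <- q < alpha & hits[und] < iter / 2
      decided[und[up]] <- TRUE
      decided[und[down]] <- FALSE
      active[und[down]] <- FALSE
    }
  }
  # Tentative resolution: median importance vs median of max-shadow importances.
  tent <- which(is.na(decided))
  med_shadow <- stats::median(shadow_max_hist)
  resolved <- vapply(tent, function(j) {
    stats::median(imp_hist[[j]]) > med_shadow
  }, logical(1))
  list(
    confirmed = feats[which(decided %in% TRUE)],
    tentative = feats[tent],
    tentative_resolved = feats[tent[resolved]],
    rejected = feats[which(decided %in% FALSE)],
    hit_counts = stats::setNames(hits, feats),
    n_iter = iter
  )
}

#' Split selected genes into signed prognosis signatures
#'
#' Per gene, the association statistic is the difference between its mean
#' z-scored expression in the favorable clusters and in the remaining
#' clusters. Positive genes form the good-prognosis set (GPPGs), negative
#' ones the bad-prognosis set (BPPGs); an exact zero goes to the GPPGs with
#' a warning.
#'
#' @param X An `ExpressionMatrix`; z-scored internally if not already.
#' @param labels Cluster labels per sample.
#' @param genes Genes to split (must be present in `X`).
#' @param favorable_clusters Nonempty strict subset of the cluster labels
#'   regarded as prognosis-favorable (see [favorable_clusters_by_survival()]).
#' @return List of class `SignaturePair`: `gppg`, `bppg`, and the named
#'   `association_stat` vector.
#' @export
split_signatures <- function(X, labels, genes, favorable_clusters) {
  m <- as_expr(X)
  if (m$scale != "zscore") m <- zscore_genes(m)
  labels <- align_labels(labels, sample_ids(m))
  cl <- unique(labels)
  if (!length(favorable_clusters) || !all(favorable_clusters %in% cl) ||
    length(setdiff(cl, favorable_clusters)) == 0L) {
    stop_config("favorable_clusters must be a nonempty strict subset of the cluster labels")
  }
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing)) stop_data("genes absent from matrix: %s", paste(missing[1:3], collapse = ", "))
  fav <- labels %in% favorable_clusters
  V <- m$values[genes, , drop = FALSE]
  stat <- rowMeans(V[, fav, drop = FALSE]) - rowMeans(V[, !fav, drop = FALSE])
  if (any(stat == 0)) warning("zero association for some gene(s); assigned to gppg")
  structure(
    list(gppg = genes[stat >= 0], bppg = genes[stat < 0], association_stat = stat),
    class = "SignaturePair"
  )
}

#' Identify prognosis-favorable clusters from observed survival
#'
#' Ranks clusters by median observed survival time and returns every
#' cluster except the one with the shortest median (ties: the smallest
#' label is treated as worst). Used only to orient the GPPG/BPPG split.
#'
#' @param labels Cluster labels per sample (named by sample id).
#' @param clinical Clinical table with `sample_id` and `time` columns.
#' @return Vector of favorable cluster labels.
#' @export
favorable_clusters_by_survival <- function(labels, clinical) {
  lab <- labels[clinical$sample_id]
  if (anyNA(lab)) stop_data("cluster labels missing for some clinical samples")
  med <- tapply(clinical$time, lab, stats::median)
  worst <- names(med)[order(med, names(med))][1L]
  cl <- sort(unique(lab))
  cl[as.character(cl) != worst]
}
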