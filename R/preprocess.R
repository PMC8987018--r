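#' Convert FPKM to TPM
#'
#' Per sample j, `tpm_gj = fpkm_gj / sum_g(fpkm_gj) * 1e6`, so every column
#' sums to one million.
#'
#' @param m An [expression_matrix()] with scale `"fpkm"`.
#' @return An `ExpressionMatrix` with scale `"tpm"`.
#' @export
fpkm_to_tpm <- function(m) {
  m <- as_expr(m, "fpkm")
  assert_scale(m, "fpkm", "fpkm_to_tpm")
  cs <- colSums(m$values)
  bad <- which(cs <= 0)
  if (length(bad)) {
    stop_data("non-positive FPKM column sum for sample(s): %s",
      paste(sample_ids(m)[bad][seq_len(min(3, length(bad)))], collapse = ", "))
  }
  expression_matrix(sweep(m$values, 2L, cs, "/") * 1e6, "tpm")
}

#' Log2 transform with pseudocount 1
#'
#' @param m An `ExpressionMatrix` on the `"fpkm"` or `"tpm"` scale.
#' @return An `ExpressionMatrix` with scale `"log2"`, values `log2(x + 1)`.
#' @export
log2_transform <- function(m) {
  m <- as_expr(m, "tpm")
  assert_scale(m, c("fpkm", "tpm"), "log2_transform")
  if (any(m$values < 0)) stop_data("negative values cannot be log2-transformed")
  expression_matrix(log2(m$values + 1), "log2")
}

#' Gene-wise z-score standardization
#'
#' Centers and scales each gene to mean 0 and population SD 1 (divisor n,
#' not n - 1, so small fixtures have exact closed forms). Constant genes map
#' to all-zero rows with a warning rather than an error, so degenerate
#' synthetic inputs keep flowing through the pipeline.
#'
#' @param m An `ExpressionMatrix` on the `"log2"` scale.
#' @return An `ExpressionMatrix` with scale `"zscore"`.
#' @export
zscore_genes <- function(m) {
  m <- as_expr(m, "log2")
  assert_scale(m, c("log2", "tpm", "fpkm"), "zscore_genes")
  n <- ncol(m$values)
  if (n < 2L) stop_data("z-scoring needs at least 2 samples")
  mu <- rowMeans(m$values)
  centered <- m$values - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  const <- sd_pop == 0
  if (any(const)) {
    warning(sprintf("%d constant gene(s) set to all-zero z-scores", sum(const)))
    sd_pop[const] <- 1
  }
  expression_matrix(centered / sd_pop, "zscore")
}

#' Empirical-Bayes batch adjustment
#'
#' Removes additive (and optionally multiplicative) per-gene batch effects
#' from a log-scale matrix. After gene standardization, per-gene per-batch
#' location effects are estimated and shrunk toward a batch-level normal
#' prior, and scale effects toward an inverse-gamma prior, by the parametric
#' empirical-Bayes scheme; the adjusted data are mapped back so that grand
#' means are restored. With a single batch the input is returned unchanged.
#'
#' @param m An `ExpressionMatrix` on the `"log2"` scale.
#' @param batches Vector of batch labels, one per sample (or named by
#'   sample id).
#' @param mean_only If `TRUE` (default) only location effects are removed;
#'   set `FALSE` to also equalize per-batch scales.
#' @param n_iter Maximum EB fixed-point iterations per batch.
#' @return An `ExpressionMatrix` with scale `"log2"`.
#' @export
batch_adjust <- function(m, batches, mean_only = TRUE, n_iter = 50L) {
  m <- as_expr(m, "log2")
  X <- m$values
  n <- ncol(X)
  if (length(batches) != n) {
    if (!is.null(names(batches)) && all(sample_ids(m) %in% names(batches))) {
      batches <- batches[sample_ids(m)]
    } else {
      stop_data("batches must have one label per sample")
    }
  }
  batches <- as.factor(batches)
  tab <- table(batches)
  if (any(tab < 2L)) {
    stop_data("every batch needs >= 2 samples (offending: %s)",
      paste(names(tab)[tab < 2L], collapse = ", "))
  }
  if (nlevels(batches) == 1L) return(m)

  # Standardize genes: remove the grand mean; divide by the pooled SD of the
  # residuals about the per-batch means (so planted batch shifts do not
  # inflate the standardization).
  levs <- levels(batches)
  batch_means <- sapply(levs, function(b) rowMeans(X[, batches == b, drop = FALSE]))
  fitted <- batch_means[, as.integer(batches), drop = FALSE]
  grand <- as.vector(batch_means %*% (as.vector(table(batches)) / n))
  pooled_var <- rowSums((X - fitted)^2) / n
  pooled_var[pooled_var == 0] <- 1
  Z <- (X - grand) / sqrt(pooled_var)

  gamma_hat <- sapply(levs, function(b) rowMeans(Z[, batches == b, drop = FALSE]))
  gamma_hat <- matrix(gamma_hat, nrow = nrow(X), dimnames = list(rownames(X), levs))

  gamma_star <- gamma_hat
  delta_star <- matrix(1, nrow(X), length(levs), dimnames = dimnames(gamma_hat))
  for (j in seq_along(levs)) {
    nb <- sum(batches == levs[j])
    g <- gamma_hat[, j]
    # Hyperpriors by method of moments: gamma ~ N(gbar, t2), delta ~ InvGamma(a, b).
    gbar <- mean(g)
    t2 <- stats::var(g)
    if (t2 <= 0) next
    if (mean_only) {
      # location-only EB: unit residual variance in the shrinkage weight
      gamma_star[, j] <- (t2 * g + gbar) / (t2 + 1)
      next
    }
    zb <- Z[, batches == levs[j], drop = FALSE]
    d <- pmax(rowSums((zb - g)^2) / (nb - 1), 1e-12)
    vbar <- mean(d)
    s2 <- stats::var(d)
    a_prior <- (2 * s2 + vbar^2) / max(s2, 1e-12)
    b_prior <- (vbar * s2 + vbar^3) / max(s2, 1e-12)
    g_star <- g
    d_star <- d
    for (it in seq_len(n_iter)) {
      g_new <- (nb * t2 * g + d_star * gbar) / (nb * t2 + d_star)
      sse <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * sse + b_prior) / (nb / 2 + a_prior - 1)
      change <- max(abs(g_new - g_star) / abs(g_star), abs(d_new - d_star) / d_star)
      g_star <- g_new
      d_star <- d_new
      if (is.finite(change) && change < 1e-6) break
    }
    gamma_star[, j] <- g_star
    delta_star[, j] <- d_star
  }

  adj <- Z
  for (j in seq_along(levs)) {
    idx <- batches == levs[j]
    adj[, idx] <- adj[, idx] - gamma_star[, j]
    if (!mean_only) adj[, idx] <- adj[, idx] / sqrt(pmax(delta_star[, j], 1e-12))
  }
  out <- adj * sqrt(pooled_var) + grand
  expression_matrix(out, "log2")
}

#' Select the most variable genes
#'
#' Returns the `n` genes with the largest variance across samples; ties are
#' broken by lexicographic gene id.
#'
#' @param m An `ExpressionMatrix`.
#' @param n Number of genes to keep (<= number of genes).
#' @return Character vector of gene ids, ordered by decreasing variance.
#' @export
top_variable_genes <- function(m, n) {
  m <- as_expr(m)
  if (n > nrow(m$values)) stop_config("n exceeds the number of genes")
  v <- apply(m$values, 1L, stats::var)
  ids <- gene_ids(m)
  ord <- order(-v, ids)
  ids[ord][seq_len(n)]
}
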