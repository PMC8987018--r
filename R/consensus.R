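# Resampling-based consensus clustering of samples with PAC model selection.
#
# One engine serves build_consensus() and select_k(): the subsampled
# hierarchical trees (Euclidean distance, Ward linkage) do not depend on k,
# so each tree is built once and cut at every requested k — the behaviour of
# the standard consensus-clustering implementations. Distances are computed
# once on the full cohort and subset per iteration.

consensus_engine <- function(X, ks, n_iter, p_item, seed) {
  n <- ncol(X)
  if (any(ks < 2L)) stop_config("k must be >= 2")
  if (any(ks > n)) stop_config("k (%d) exceeds the number of samples (%d)", max(ks), n)
  if (n_iter < 1L) stop_config("n_iter must be >= 1")
  if (p_item <= 0 || p_item > 1) stop_config("p_item must be in (0, 1]")
  D <- as.matrix(stats::dist(t(X)))
  m <- ceiling(p_item * n)
  set.seed(seed)
  indic <- matrix(0, n, n)
  conn <- lapply(ks, function(k) matrix(0, n, n))
  names(conn) <- as.character(ks)
  for (it in seq_len(n_iter)) {
    idx <- sort(sample.int(n, m))
    hc <- stats::hclust(stats::as.dist(D[idx, idx]), method = "ward.D2")
    indic[idx, idx] <- indic[idx, idx] + 1
    for (j in seq_along(ks)) {
      lab <- stats::cutree(hc, k = ks[j])
      conn[[j]][idx, idx] <- conn[[j]][idx, idx] + outer(lab, lab, "==")
    }
  }
  sids <- colnames(X)
  lapply(seq_along(ks), function(j) {
    M <- conn[[j]]
    undef <- indic == 0
    if (any(undef[upper.tri(undef)])) {
      warning("some sample pairs were never co-sampled; their consensus set to 0")
    }
    M <- ifelse(undef, 0, M / pmax(indic, 1))
    M <- (M + t(M)) / 2
    diag(M) <- 1
    dimnames(M) <- list(sids, sids)
    structure(
      list(k = ks[j], M = M, n_iter = n_iter, indicator_counts = indic),
      class = "ConsensusMatrix"
    )
  })
}

#' Build a consensus matrix at a fixed k
#'
#' Each of `n_iter` iterations subsamples `ceiling(p_item * n)` samples
#' without replacement, clusters them by agglomerative clustering (Euclidean
#' distance, Ward linkage) cut at `k`, and accumulates co-cluster and
#' co-sample counts. The consensus entry M_ij is the ratio of the two counts
#' (0/0 pairs, never co-sampled, are set to 0 with a warning).
#'
#' @param X An [expression_matrix()] or a genes x samples matrix; samples
#'   are the objects being clustered.
#' @param k Number of clusters (>= 2).
#' @param n_iter Number of resampling iterations (study default 1000).
#' @param p_item Fraction of samples drawn per iteration.
#' @param seed RNG seed.
#' @return A `ConsensusMatrix`: list with `k`, symmetric `M` in [0, 1] with
#'   unit diagonal, `n_iter`, and the pairwise co-sampling counts.
#' @export
build_consensus <- function(X, k, n_iter = 1000L, p_item = 0.8, seed = 1L) {
  X <- as_expr(X)$values
  consensus_engine(X, as.integer(k), n_iter, p_item, seed)[[1L]]
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The empirical CDF of the strictly off-diagonal consensus entries
#' evaluated at `x2` minus its value at `x1`: the fraction of sample pairs
#' with ambiguous (intermediate) co-clustering frequency. Lower is cleaner.
#'
#' @param cm A `ConsensusMatrix` from [build_consensus()].
#' @param x1,x2 Window bounds, `0 <= x1 < x2 <= 1`.
#' @return PAC value in [0, 1].
#' @export
compute_pac <- function(cm, x1 = 0.1, x2 = 0.9) {
  if (!(x1 >= 0 && x1 < x2 && x2 <= 1)) stop_config("need 0 <= x1 < x2 <= 1")
  M <- if (inherits(cm, "ConsensusMatrix")) cm$M else cm
  if (nrow(M) < 2L) stop_data("PAC needs at least 2 samples")
  off <- M[upper.tri(M)]
  mean(off <= x2) - mean(off <= x1)
}

#' Select the number of clusters by minimum PAC
#'
#' Runs the consensus engine over `k_range` (sharing subsamples and trees
#' across k) and returns the k with the smallest PAC, ties broken toward
#' smaller k (parsimony).
#'
#' @inheritParams build_consensus
#' @param k_range Candidate cluster numbers, a subset of 2..(n-1).
#' @param x1,x2 PAC window.
#' @return List with `k_star`, `pac` (named per-k vector), `window`, and
#'   `consensus` (list of `ConsensusMatrix`, one per k).
#' @export
select_k <- function(X, k_range = 2:6, n_iter = 1000L, p_item = 0.8, seed = 1L,
                     x1 = 0.1, x2 = 0.9) {
  X <- as_expr(X)$values
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range >= ncol(X))) stop_config("k_range must lie within 2..(n_samples - 1)")
  cms <- consensus_engine(X, k_range, n_iter, p_item, seed)
  pac <- vapply(cms, compute_pac, numeric(1), x1 = x1, x2 = x2)
  names(pac) <- as.character(k_range)
  k_star <- k_range[which.min(pac)] # which.min takes the first (smallest k) on ties
  list(
    k_star = k_star, pac = pac, window = c(x1 = x1, x2 = x2),
    consensus = stats::setNames(cms, as.character(k_range))
  )
}

#' Final cluster labels from a consensus matrix
#'
#' Agglomerative clustering (average linkage) on the dissimilarity `1 - M`,
#' cut at `k`; labels are renumbered 1..k by decreasing cluster size (ties
#' by first occurrence), so the labeling is a function of M only.
#'
#' @param cm A `ConsensusMatrix`.
#' @param k Number of clusters; defaults to `cm$k`.
#' @return Named integer vector of cluster labels in 1..k.
#' @export
cluster_from_consensus <- function(cm, k = cm$k) {
  M <- cm$M
  hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
  raw <- stats::cutree(hc, k = k)
  sizes <- table(raw)
  new_order <- order(-as.vector(sizes), as.integer(names(sizes)))
  remap <- integer(length(sizes))
  remap[as.integer(names(sizes))[new_order]] <- seq_along(sizes)
  stats::setNames(remap[raw], rownames(M))
}
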