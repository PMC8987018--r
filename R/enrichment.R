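# Gene-set machinery: hypergeometric over-representation, preranked GSEA
# with a weighted running sum and gene-label permutation null, and
# single-sample (ssGSEA) rank-weighted ECDF scores.

#' Read / write gene sets in GMT format
#'
#' GMT is tab-delimited: set name, description, then member genes. Reading
#' goes through `fgsea::gmtPathways`; writing emits one line per set with
#' an empty description field.
#'
#' @param path File path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_data("GMT file not found: %s", path)
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop_data("duplicate set names in %s", path)
  lapply(sets, unique)
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Over-representation test for one gene set
#'
#' One-sided hypergeometric upper-tail probability of an overlap at least
#' as large as observed between the hit list and the gene set, within the
#' stated universe (identical to a one-sided Fisher exact test).
#'
#' @param hits Character vector of selected genes (subset of `universe`).
#' @param geneset Character vector, the gene set.
#' @param universe Character vector, the testable gene universe.
#' @return List with `p`, `overlap`, `expected`.
#' @export
ora_test <- function(hits, geneset, universe) {
  if (!length(universe)) stop_data("empty universe")
  universe <- unique(universe)
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop_data("hits must be a subset of the universe")
  gs <- intersect(unique(geneset), universe)
  if (!length(gs)) stop_data("gene set does not overlap the universe")
  k <- length(intersect(hits, gs))
  N <- length(universe)
  K <- length(gs)
  n <- length(hits)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(p = p, overlap = k, expected = n * K / N)
}

#' Over-representation analysis across a collection
#'
#' Runs [ora_test()] on every set and BH-adjusts across sets.
#'
#' @inheritParams ora_test
#' @param genesets Named list of gene sets.
#' @return Data frame: `set`, `size`, `overlap`, `expected`, `p`, `q`.
#' @export
ora_analysis <- function(hits, genesets, universe) {
  rows <- lapply(names(genesets), function(nm) {
    r <- ora_test(hits, genesets[[nm]], universe)
    data.frame(
      set = nm, size = length(intersect(genesets[[nm]], universe)),
      overlap = r$overlap, expected = r$expected, p = r$p,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out
}

# Weighted KS-style running-sum enrichment score: hit steps proportional to
# |stat|^weight (normalized), miss steps 1/(N - Nh); ES is the deviation of
# maximum absolute value.
running_es <- function(stat_sorted, in_set, weight = 1) {
  N <- length(stat_sorted)
  Nh <- sum(in_set)
  w <- abs(stat_sorted)^weight
  denom_hit <- sum(w[in_set])
  if (denom_hit == 0) denom_hit <- 1
  step <- ifelse(in_set, w / denom_hit, -1 / (N - Nh))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

#' Preranked gene-set enrichment analysis
#'
#' Genes are ranked by the supplied statistic (decreasing); the enrichment
#' score is the maximum deviation of a weighted running sum (hit increments
#' proportional to `|stat|^weight`, miss decrements `1/(N - Nh)`). The null
#' distribution is built by gene-label permutation; NES divides ES by the
#' mean |null ES| of the same sign, and the empirical p-value is two-sided
#' on |ES| with +1 continuity.
#'
#' @param stats Named numeric vector of per-gene ranking statistics.
#' @param geneset Character vector; must be a nonempty strict subset of the
#'   ranked genes.
#' @param n_perm Number of gene-label permutations.
#' @param weight Exponent on |stat| for hit increments (1 = classic).
#' @param seed RNG seed for the permutations.
#' @return List with `es`, `nes`, `p`, `size`.
#' @export
gsea_preranked <- function(stats, geneset, n_perm = 1000L, weight = 1, seed = 1L) {
  if (is.null(names(stats))) stop_data("stats must be named by gene")
  genes <- names(stats)
  gs <- intersect(unique(geneset), genes)
  if (!length(gs)) stop_data("gene set does not overlap the ranked list")
  if (length(gs) == length(genes)) stop_data("gene set covers all ranked genes; miss set empty")
  ord <- order(stats, decreasing = TRUE)
  s_sorted <- stats[ord]
  in_set <- names(s_sorted) %in% gs
  es <- running_es(s_sorted, in_set, weight)
  set.seed(derive_seed(seed, 7L))
  Nh <- sum(in_set)
  null_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(length(s_sorted), Nh)
    perm <- logical(length(s_sorted))
    perm[idx] <- TRUE
    running_es(s_sorted, perm, weight)
  }, numeric(1))
  same_sign <- null_es[sign(null_es) == sign(es)]
  nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
  p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
  list(es = es, nes = nes, p = p, size = Nh)
}

#' Single-sample GSEA scores
#'
#' For each sample, genes are ranked by expression (ties get average
#' ranks); a set's score is the sum over ranking positions of the
#' difference between the weighted in-set ECDF (weights `rank^alpha`) and
#' the unweighted out-of-set ECDF. With `normalize = TRUE` all scores are
#' divided by the range (max - min) of the whole score matrix.
#'
#' @param X An [expression_matrix()] (any scale; only within-sample ranks
#'   matter).
#' @param genesets Named list of gene sets; each must overlap the matrix.
#' @param alpha Rank weighting exponent (0.25 = published default).
#' @param normalize Divide by the global score range.
#' @return sets x samples numeric matrix of scores.
#' @export
ssgsea_scores <- function(X, genesets, alpha = 0.25, normalize = TRUE) {
  m <- as_expr(X)
  V <- m$values
  genes <- gene_ids(m)
  overlap <- lapply(genesets, intersect, genes)
  empty <- names(genesets)[lengths(overlap) == 0L]
  if (length(empty)) stop_data("gene set(s) with zero overlap: %s", paste(empty, collapse = ", "))
  N <- length(genes)
  out <- matrix(0, length(genesets), ncol(V),
    dimnames = list(names(genesets), colnames(V))
  )
  for (j in seq_len(ncol(V))) {
    r <- rank(V[, j], ties.method = "average") # high expression = high rank
    ord <- order(r, decreasing = TRUE)
    r_sorted <- r[ord]
    gene_sorted <- genes[ord]
    w <- r_sorted^alpha
    for (s in seq_along(genesets)) {
      inset <- gene_sorted %in% overlap[[s]]
      ecdf_in <- cumsum(w * inset) / sum(w[inset])
      ecdf_out <- cumsum(!inset) / (N - sum(inset))
      out[s, j] <- sum(ecdf_in - ecdf_out)
    }
  }
  if (normalize) {
    rng <- max(out) - min(out)
    if (rng > 0) out <- out / rng
  }
  out
}
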