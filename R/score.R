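#' First-principal-component sample scores for a gene signature
#'
#' PCA (centering only, no rescaling — the matrix is expected to be gene
#' z-scored already) of the samples x signature-genes submatrix; each
#' sample's coordinate on PC1 is returned. The sign indeterminacy of PC1 is
#' resolved by requiring a non-negative correlation between the scores and
#' the per-sample mean expression of the signature genes, so that "higher
#' score" means "signature up". A one-gene signature returns that gene's
#' centered values.
#'
#' @param X An [expression_matrix()], normally on the z-score scale.
#' @param genes Signature gene ids; all must be present in `X`.
#' @return Named numeric vector of per-sample PC1 scores.
#' @export
pc1_sample_scores <- function(X, genes) {
  m <- as_expr(X)
  missing <- setdiff(genes, gene_ids(m))
  if (length(missing)) {
    stop_data("signature genes absent from matrix: %s",
      paste(utils::head(missing, 5), collapse = ", "))
  }
  if (!length(genes)) stop_data("empty signature")
  S <- t(m$values[genes, , drop = FALSE]) # samples x genes
  if (nrow(S) < 3L) stop_data("PC1 scoring needs >= 3 samples")
  if (length(genes) == 1L) {
    return(stats::setNames(as.vector(base::scale(S[, 1L], scale = FALSE)), rownames(S)))
  }
  pc <- stats::prcomp(S, center = TRUE, scale. = FALSE)
  scores <- pc$x[, 1L]
  ref <- rowMeans(S)
  r <- suppressWarnings(stats::cor(scores, ref))
  if (is.finite(r) && r < 0) scores <- -scores
  stats::setNames(scores, rownames(S))
}

#' Per-sample pyroscore from a signature pair
#'
#' The pyroscore of sample i is the difference of its PC1 scores over the
#' good-prognosis genes (GPPGs) and the bad-prognosis genes (BPPGs):
#' `pyroscore = PC1_gppg - PC1_bppg`. An empty BPPG set contributes 0 with
#' a warning; an empty GPPG set is an error.
#'
#' @param X An [expression_matrix()] on the z-score scale.
#' @param sig A `SignaturePair` from [split_signatures()], or any list with
#'   `gppg` and `bppg` character vectors.
#' @return A `ScoreVector` data frame: `sample_id`, `pc1_gppg`, `pc1_bppg`,
#'   `pyroscore`.
#' @export
compute_pyroscore <- function(X, sig) {
  if (!length(sig$gppg)) stop_data("gppg signature is empty")
  pc_g <- pc1_sample_scores(X, sig$gppg)
  if (!length(sig$bppg)) {
    warning("bppg signature is empty; pyroscore equals the gppg PC1 score")
    pc_b <- stats::setNames(rep(0, length(pc_g)), names(pc_g))
  } else {
    pc_b <- pc1_sample_scores(X, sig$bppg)
  }
  out <- data.frame(
    sample_id = names(pc_g), pc1_gppg = as.vector(pc_g),
    pc1_bppg = as.vector(pc_b[names(pc_g)]),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$pyroscore <- out$pc1_gppg - out$pc1_bppg
  class(out) <- c("ScoreVector", "data.frame")
  out
}
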