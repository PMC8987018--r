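#' Expression matrix with a scale tag
#'
#' A thin S3 container for a genes x samples numeric matrix plus a tag
#' recording the measurement scale. Every transform in the package updates
#' the tag, so downstream stages can assert they receive the scale they
#' expect (e.g. z-scored input for PCA scoring).
#'
#' @param values Numeric matrix, genes as rows, samples as columns. Must have
#'   unique, non-empty rownames (gene ids) and colnames (sample ids).
#' @param scale One of `"fpkm"`, `"tpm"`, `"log2"`, `"zscore"`.
#' @return An object of class `ExpressionMatrix` with fields `values` and
#'   `scale`.
#' @examples
#' m <- matrix(rnorm(6), 2, 3, dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' expression_matrix(m, "log2")
#' @export
expression_matrix <- function(values, scale = c("log2", "fpkm", "tpm", "zscore")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop_data("expression values must be a numeric matrix")
  }
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || is.null(sid)) {
    stop_data("expression matrix must have gene rownames and sample colnames")
  }
  if (anyDuplicated(gid)) {
    stop_data("duplicate gene ids: %s", paste(unique(gid[duplicated(gid)])[1:3], collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stop_data("duplicate sample ids: %s", paste(unique(sid[duplicated(sid)])[1:3], collapse = ", "))
  }
  if (any(!is.finite(values))) stop_data("expression values must all be finite")
  structure(list(values = values, scale = scale), class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf(
    "ExpressionMatrix: %d genes x %d samples [scale: %s]\n",
    nrow(x$values), ncol(x$values), x$scale
  ))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `ExpressionMatrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

# Internal: accept either an ExpressionMatrix or a bare named matrix.
as_expr <- function(x, scale = "log2") {
  if (inherits(x, "ExpressionMatrix")) x else expression_matrix(x, scale)
}

assert_scale <- function(m, expected, what) {
  if (!m$scale %in% expected) {
    stop_data(
      "%s expects scale %s but got '%s'", what,
      paste(sprintf("'%s'", expected), collapse = " or "), m$scale
    )
  }
  invisible(m)
}

#' Read and write expression matrices as TSV
#'
#' The on-disk format is tab-delimited UTF-8 text: the first column holds
#' gene ids (header `gene_id`), remaining columns are samples, '.' decimal.
#' Lines starting with `#` are ignored (schema comment lines). Round-trips
#' are lossless to better than 1e-12 (values are written with full
#' precision). Windows line endings are accepted on read.
#'
#' @param path File path.
#' @param scale Scale tag to attach to the matrix read from `path`.
#' @return `read_expression` returns an [expression_matrix()];
#'   `write_expression` returns `path` invisibly.
#' @export
read_expression <- function(path, scale = c("log2", "fpkm", "tpm", "zscore")) {
  scale <- match.arg(scale)
  if (!file.exists(path)) stop_data("expression file not found: %s", path)
  first <- readLines(path, n = 50L)
  header <- first[!startsWith(first, "#")][1L]
  hdr_ids <- strsplit(sub("\r$", "", header), "\t", fixed = TRUE)[[1L]][-1L]
  if (anyDuplicated(hdr_ids)) stop_data("duplicated sample header in %s", path)
  df <- utils::read.table(
    path, header = TRUE, sep = "\t", quote = "", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  if (ncol(df) < 2L) stop_data("expression file needs a gene id column plus >=1 sample")
  gid <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  sid <- colnames(vals)
  if (anyDuplicated(sid)) stop_data("duplicated sample header in %s", path)
  if (anyDuplicated(gid)) stop_data("duplicated gene ids in %s", path)
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(gid, sid)
  expression_matrix(vals, scale)
}

#' @rdname read_expression
#' @param m An [expression_matrix()].
#' @export
write_expression <- function(m, path) {
  m <- as_expr(m)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# pyroscore expression matrix v1; scale=%s", m$scale), con)
  df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
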