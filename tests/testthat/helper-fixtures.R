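# Shared fixture builders; everything is generated in code at test time.

# Small named genes x samples matrix of iid normals.
rand_expr <- function(g = 20, n = 10, seed = 1, scale = "log2", sd = 1, mean = 0) {
  set.seed(seed)
  m <- matrix(rnorm(g * n, mean, sd), g, n,
    dimnames = list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:n))
  )
  expression_matrix(m, scale)
}

# Two well-separated sample clouds (for consensus clustering tests).
make_blobs <- function(n_per = 15, g = 10, sep = 10, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(g * n_per), g, n_per)
  b <- matrix(rnorm(g * n_per, mean = sep), g, n_per)
  m <- cbind(a, b)
  dimnames(m) <- list(sprintf("g%02d", 1:g), sprintf("s%02d", 1:(2 * n_per)))
  list(expr = expression_matrix(m, "log2"), truth = rep(1:2, each = n_per))
}

# Brute-force Mann-Whitney AUC of case scores vs control scores.
mw_auc <- function(case_scores, control_scores) {
  tot <- 0
  for (a in case_scores) {
    for (b in control_scores) {
      tot <- tot + (a > b) + 0.5 * (a == b)
    }
  }
  tot / (length(case_scores) * length(control_scores))
}

# Adjusted Rand index (contingency-table form), independent of any package.
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}
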