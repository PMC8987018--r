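test_that("identical groups give zero fold change and p = 1", {
  v <- rand_expr(10, 4, seed = 1)$values
  v[, 3:4] <- v[, 1:2]
  m <- expression_matrix(v, "log2")
  de <- moderated_t(m, 1:2, 3:4)
  expect_equal(de$log2FC, rep(0, 10))
  expect_equal(de$p, rep(1, 10))
})

test_that("zero prior df reduces the moderated t to the ordinary pooled t", {
  m <- rand_expr(200, 20, seed = 2)
  de <- moderated_t(m, 1:10, 11:20, prior_df = 0)
  ref_t <- apply(m$values, 1, function(x) {
    unname(t.test(x[1:10], x[11:20], var.equal = TRUE)$statistic)
  })
  expect_equal(de$t_mod, unname(ref_t), tolerance = 1e-8)
})

test_that("null p-values are uniform", {
  m <- rand_expr(2000, 40, seed = 3)
  de <- moderated_t(m, 1:20, 21:40)
  expect_gt(ks.test(de$p, "punif")$p.value, 0.01)
})

test_that("moderated t agrees with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(4)
  g <- 300
  # heteroscedastic genes so shrinkage actually matters
  v <- matrix(rnorm(g * 16), g, 16) * sqrt(rchisq(g, 4) / 4)
  dimnames(v) <- list(sprintf("g%03d", 1:g), sprintf("s%02d", 1:16))
  m <- expression_matrix(v, "log2")
  de <- moderated_t(m, 1:8, 9:16)
  design <- cbind(1, rep(c(1, 0), each = 8))
  fit <- limma::eBayes(limma::lmFit(v, design))
  expect_equal(de$t_mod, unname(fit$t[, 2]), tolerance = 1e-6)
  expect_equal(attr(de, "df_prior"), unname(fit$df.prior), tolerance = 1e-4)
  expect_equal(de$p, unname(fit$p.value[, 2]), tolerance = 1e-6)
})

test_that("BH adjustment matches a literal step-up oracle and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    q <- numeric(n)
    prev <- 1
    for (i in n:1) {
      prev <- min(prev, p[o[i]] * n / i)
      q[o[i]] <- prev
    }
    q
  }
  set.seed(5)
  p <- runif(500)
  expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-14)
  perm <- sample(500)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-14)
  expect_error(bh_adjust(c(0.5, 1.2)), class = "pyroscore_data_error")
})

test_that("pairwise DEGs require every pair to pass; labeling within a pair only flips sign", {
  set.seed(6)
  n_per <- 20
  v <- matrix(rnorm(50 * 3 * n_per), 50, 3 * n_per)
  dimnames(v) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:(3 * n_per)))
  lab <- rep(1:3, each = n_per)
  # g01 separates all three clusters; g02 differs in one pair only
  v["g01", lab == 1] <- v["g01", lab == 1] + 3
  v["g01", lab == 3] <- v["g01", lab == 3] - 3
  v["g02", lab == 1] <- v["g02", lab == 1] + 3
  m <- expression_matrix(v, "log2")
  degs <- pairwise_degs(m, lab)
  expect_true("g01" %in% degs)
  expect_false("g02" %in% degs)
  expect_true("g02" %in% pairwise_degs(m, lab, combine = "union"))
  # A/B swap within a pair flips log2FC sign only
  d12 <- moderated_t(m, which(lab == 1), which(lab == 2))
  d21 <- moderated_t(m, which(lab == 2), which(lab == 1))
  expect_equal(d12$log2FC, -d21$log2FC)
  expect_equal(d12$p, d21$p)
})

test_that("null data yield no pairwise DEGs in most runs", {
  zeros <- sapply(1:20, function(s) {
    m <- rand_expr(300, 30, seed = 100 + s)
    length(pairwise_degs(m, rep(1:3, each = 10)))
  })
  expect_gte(mean(zeros == 0), 0.95)
})

test_that("Boruta confirms a perfect predictor among noise and controls the null", {
  set.seed(7)
  n <- 60
  lab <- rep(1:2, each = n / 2)
  v <- matrix(rnorm(201 * n), 201, n)
  v[1, ] <- lab + rnorm(n, sd = 0.05)
  dimnames(v) <- list(c("signal", sprintf("noise%03d", 1:200)), sprintf("s%02d", 1:n))
  res <- boruta_select(expression_matrix(v, "log2"), lab,
    max_iter = 25, num_trees = 100, seed = 8)
  expect_true("signal" %in% res$confirmed)
  expect_lt(length(setdiff(res$confirmed, "signal")), 5)

  false_rates <- sapply(1:10, function(s) {
    set.seed(s)
    vn <- matrix(rnorm(50 * n), 50, n,
      dimnames = list(sprintf("f%02d", 1:50), sprintf("s%02d", 1:n)))
    rn <- boruta_select(expression_matrix(vn, "log2"), lab,
      max_iter = 20, num_trees = 100, seed = s)
    length(rn$confirmed) / 50
  })
  expect_lte(mean(false_rates), 0.05)
})

test_that("Boruta's confirmed set shrinks (weakly) as alpha tightens", {
  set.seed(9)
  n <- 80
  lab <- rep(1:2, each = n / 2)
  v <- matrix(rnorm(40 * n), 40, n)
  v[1:5, ] <- v[1:5, ] + matrix(rep(lab, each = 5), 5, n)
  dimnames(v) <- list(sprintf("f%02d", 1:40), sprintf("s%02d", 1:n))
  m <- expression_matrix(v, "log2")
  loose <- boruta_select(m, lab, max_iter = 20, alpha = 0.05, num_trees = 100, seed = 10)
  tight <- boruta_select(m, lab, max_iter = 20, alpha = 0.001, num_trees = 100, seed = 10)
  expect_true(all(tight$confirmed %in% loose$confirmed))
})

test_that("signature split is oriented by association sign and is antisymmetric", {
  set.seed(11)
  n_per <- 15
  lab <- rep(1:3, each = n_per)
  v <- matrix(rnorm(10 * 3 * n_per), 10, 3 * n_per)
  v[1, lab %in% c(1, 2)] <- v[1, lab %in% c(1, 2)] + 2
  v[2, ] <- -v[1, ]
  dimnames(v) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", seq_len(3 * n_per)))
  m <- expression_matrix(v, "log2")
  sig <- split_signatures(m, lab, c("g01", "g02"), favorable_clusters = c(1, 2))
  expect_identical(sig$gppg, "g01")
  expect_identical(sig$bppg, "g02")
  expect_error(
    split_signatures(m, lab, c("g01", "g02"), favorable_clusters = 1:3),
    class = "pyroscore_config_error"
  )
})

test_that("planted module membership is recovered exactly from cohort clusters", {
  cohort <- generate_cohort(cohort_config(n_genes = 500, effect_size = 1, seed = 12))
  tr <- cohort$truth
  z <- zscore_genes(cohort$expression)
  sig <- split_signatures(z, tr$cluster_labels,
    c(tr$favorable_genes, tr$unfavorable_genes),
    favorable_clusters = c(1, 2))
  expect_setequal(sig$gppg, tr$favorable_genes)
  expect_setequal(sig$bppg, tr$unfavorable_genes)
})

test_that("favorable clusters are those that outlive the worst cluster", {
  cohort <- generate_cohort(cohort_config(seed = 13))
  fav <- favorable_clusters_by_survival(cohort$truth$cluster_labels, cohort$clinical)
  expect_setequal(fav, c(1, 2)) # cluster 3 has the lowest latent score, hence worst survival
})
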