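# Supervised layer: screening, candidate subsets, M statistic, permutation
# null, empirical p-values, BH adjustment.

test_that("per-SNP screening matches an independent IRLS (glm) fit", {
  set.seed(12)
  n <- 80
  G <- rand_genotypes(n, 5, 12)
  y <- rbinom(n, 1, plogis(-0.3 + 0.5 * G[, 2]))
  p <- per_snp_pvalues(G, y)
  for (j in 1:5) {
    sm <- summary(glm(y ~ G[, j], family = binomial()))$coefficients
    expect_lt(abs(p[j] - sm[2, 4]), 1e-6)
    t_mine <- qnorm(p[j] / 2, lower.tail = FALSE)
    expect_lt(abs(t_mine - abs(sm[2, 3])), 1e-5)
  }
})

test_that("constant SNPs get p = 1 and separation yields a finite Firth p", {
  set.seed(3)
  G <- cbind(rep(1L, 30), rand_genotypes(30, 1, 3))
  y <- rbinom(30, 1, 0.5)
  p <- per_snp_pvalues(G, y)
  expect_equal(p[1], 1)
  # y a deterministic function of genotype: separation path
  G2 <- matrix(c(rep(0L, 10), rep(2L, 10)), ncol = 1)
  y2 <- c(rep(0L, 10), rep(1L, 10))
  expect_warning(p2 <- per_snp_pvalues(G2, y2), "Firth")
  expect_true(is.finite(p2) && p2 > 0 && p2 < 1)
})

test_that("candidate subsets follow nearest-rank percentiles and collapse ties", {
  set.seed(9)
  p20 <- runif(20)
  cs <- candidate_subsets(p20, v = 20)
  expect_equal(vapply(cs$subsets, length, integer(1)), 1:20)
  # nested
  for (i in seq_len(length(cs$subsets) - 1)) {
    expect_true(all(cs$subsets[[i]] %in% cs$subsets[[i + 1]]))
  }
  # all p equal: a single subset containing every SNP
  cs2 <- candidate_subsets(rep(0.5, 7))
  expect_length(cs2$subsets, 1)
  expect_equal(cs2$subsets[[1]], 1:7)
  # single SNP
  cs3 <- candidate_subsets(0.2)
  expect_length(cs3$subsets, 1)
  expect_equal(cs3$subsets[[1]], 1L)
  # nestedness holds for arbitrary vectors
  for (seed in 1:20) {
    set.seed(seed)
    pv <- sample(round(runif(sample(3:40, 1)), 2), replace = TRUE)
    cs <- candidate_subsets(pv)
    sizes <- vapply(cs$subsets, length, integer(1))
    expect_true(all(diff(sizes) > 0))
    for (i in seq_len(length(cs$subsets) - 1)) {
      expect_true(all(cs$subsets[[i]] %in% cs$subsets[[i + 1]]))
    }
    expect_equal(cs$subsets[[length(cs$subsets)]], seq_along(pv))
  }
})

test_that("the score t statistic is sign-symmetric and finite under separation", {
  set.seed(31)
  x <- rnorm(60)
  y <- rbinom(60, 1, plogis(x))
  f1 <- scpca:::.cpp_logistic_wald(x, y)
  f2 <- scpca:::.cpp_logistic_wald(-x, y)
  expect_equal(f1$t, -f2$t, tolerance = 1e-8)
  # score identical to the outcome: separation handled, finite t
  ysep <- c(rep(0, 20), rep(1, 20))
  fs <- scpca:::.cpp_logistic_wald(as.numeric(ysep), ysep)
  expect_true(fs$firth)
  expect_true(is.finite(fs$t))
})

test_that("subset t under the null is approximately standard normal", {
  set.seed(77)
  n <- 100
  ts <- replicate(200, {
    G <- matrix(sample(0:2, n * 4, replace = TRUE), n, 4)
    y <- rbinom(n, 1, 0.5)
    subset_t(1:4, G, y, method = "pca")
  })
  ks <- suppressWarnings(ks.test(ts, "pnorm"))
  expect_lt(unname(ks$statistic), 0.1)
  expect_lt(abs(mean(ts)), 0.2)
})

test_that("M selection takes the signed maximum absolute t, smaller subset on ties", {
  sel <- scpca:::.select_m(c(2.1, -3.4, 0.5))
  expect_equal(sel$M, -3.4)
  expect_equal(sel$index, 2L)
  tie <- scpca:::.select_m(c(2.0, -2.0, 1.0))
  expect_equal(tie$index, 1L)  # first (smallest subset) wins exact ties
})

test_that("m_statistic dominates the full-set t and reports the optimal subset", {
  set.seed(41)
  n <- 120
  G <- rand_genotypes(n, 8, 41)
  y <- rbinom(n, 1, plogis(0.6 * (G[, 3] - 1)))
  cfg <- fit_config(seed = 2, n_restarts = 1, max_iterations = 40,
                    tolerance = 1e-4)
  res <- m_statistic(snp_set("s", 1:8), G, y, method = "pca", config = cfg)
  t_full <- res$t_values[length(res$t_values)]
  expect_gte(abs(res$M), abs(t_full))
  expect_true(all(res$optimal_subset %in% 1:8))
  # single-SNP set: one unique subset, M equals its t
  res1 <- m_statistic(snp_set("s1", 3), G, y, method = "pca", config = cfg)
  expect_length(res1$t_values, 1)
  expect_equal(res1$M, res1$t_values[1])
})

test_that("the permutation null is reproducible and validated", {
  G <- rand_genotypes(50, 5, 61)
  cfg <- fit_config(seed = 3, n_restarts = 1, max_iterations = 30,
                    tolerance = 1e-3, batched = TRUE)
  S <- snp_set("s", 1:5)
  n1 <- permutation_null(S, G, 0.5, B = 15, method = "pca", config = cfg,
                         seed = 9)
  n2 <- permutation_null(S, G, 0.5, B = 15, method = "pca", config = cfg,
                         seed = 9)
  expect_identical(n1, n2)
  expect_length(n1, 15)
  expect_error(permutation_null(S, G, 0.5, B = 0, method = "pca"), "B")
  expect_error(permutation_null(S, G, 1.5, B = 5, method = "pca"),
               "prevalence")
})

test_that("empirical p-values use the add-one convention", {
  expect_equal(empirical_pvalue(5, rnorm(99)), 0.01)
  expect_equal(empirical_pvalue(1, rep(1, 7)), 1)
  # anti-monotone in |M|
  null <- rnorm(50)
  ms <- seq(0, 3, by = 0.5)
  ps <- vapply(ms, empirical_pvalue, numeric(1), null_M = null)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("BH adjustment matches the hand step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  for (seed in 1:100) {
    set.seed(seed)
    p <- runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    expect_true(all(adj <= 1))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("run_snpset_analysis returns per-set results with shared BH adjustment", {
  set.seed(71)
  G <- rand_genotypes(60, 10, 71)
  y <- rbinom(60, 1, 0.5)
  sets <- list(snp_set("gA", 1:5), snp_set("gB", 6:10), snp_set("gA2", 1:5))
  cfg <- fit_config(seed = 5, n_restarts = 1, max_iterations = 25,
                    tolerance = 1e-2, batched = TRUE)
  res <- run_snpset_analysis(G, y, sets, method = "pca", B = 19,
                             config = cfg, seed = 77)
  expect_s3_class(res, "scpca_assoc")
  expect_equal(nrow(res$results), 3)
  expect_true(all(res$results$p_value > 0 & res$results$p_value <= 1))
  expect_true(all(res$results$p_adjusted >= res$results$p_value - 1e-15))
  # identical SNP sets give identical M regardless of their id
  expect_equal(res$results$M[res$results$set_id == "gA"],
               res$results$M[res$results$set_id == "gA2"])
  # a failing set is skipped with a warning, others survive
  bad <- list(snp_set("gBad", 99), snp_set("gA", 1:5))
  expect_warning(res2 <- run_snpset_analysis(G, y, bad, method = "pca",
                                             B = 19, config = cfg, seed = 1),
                 "failed")
  expect_equal(res2$failed, "gBad")
  expect_equal(nrow(res2$results), 1)
})

test_that("pooled null mode shares null samples across sets", {
  set.seed(81)
  G <- rand_genotypes(50, 6, 81)
  y <- rbinom(50, 1, 0.5)
  sets <- list(snp_set("a", 1:3), snp_set("b", 4:6))
  cfg <- fit_config(seed = 5, n_restarts = 1, max_iterations = 25,
                    tolerance = 1e-2, batched = TRUE)
  res <- run_snpset_analysis(G, y, sets, method = "pca", B = 9,
                             config = cfg, seed = 3, pool_null = TRUE)
  pooled <- unlist(res$nulls, use.names = FALSE)
  expect_equal(res$results$p_value[1],
               empirical_pvalue(res$results$M[1], pooled))
})
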