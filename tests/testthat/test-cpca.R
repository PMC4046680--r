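# Categorical PCA core: encoding, likelihood, Newton steps, QR step, fit.

test_that("one-hot encoding partitions every cell across the three categories", {
  G <- matrix(c(0L, 1L, 2L, 1L), 2, 2)
  oh <- encode_one_hot(G)
  expect_equal(oh$indicators[["0"]], matrix(c(1L, 0L, 0L, 0L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(oh$indicators[["1"]], matrix(c(0L, 1L, 0L, 1L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(oh$indicators[["2"]], matrix(c(0L, 0L, 1L, 0L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(Reduce(`+`, oh$indicators), matrix(1L, 2, 2),
               ignore_attr = TRUE)
  oh1 <- encode_one_hot(matrix(2L, 1, 1))
  expect_equal(oh1$indicators[["2"]][1, 1], 1L)
  expect_equal(oh1$indicators[["0"]][1, 1] + oh1$indicators[["1"]][1, 1], 0L)
})

test_that("log-likelihood matches closed forms and an independent softmax", {
  # all parameters zero: every cell probability is 1/3
  m0 <- make_model(matrix(0, 2, 1), matrix(0, 4, 1), rep(0, 4))
  expect_equal(cpca_log_likelihood(matrix(0L, 2, 2), m0), -4 * log(3),
               tolerance = 1e-12)
  # single cell, observed category 1, theta = (1, -1)
  m1 <- make_model(matrix(1, 1, 1), matrix(c(1, -1), 2, 1), c(0, 0))
  expect_equal(cpca_log_likelihood(matrix(1L, 1, 1), m1),
               1 - log(1 + exp(1) + exp(-1)), tolerance = 1e-10)
  # random instances against the softmax oracle
  for (seed in 1:5) {
    G <- rand_genotypes(6, 4, seed)
    set.seed(seed + 100)
    U <- matrix(rnorm(6), 6, 1)
    V <- matrix(rnorm(8), 8, 1)
    mu <- rnorm(8)
    m <- make_model(U, V, mu)
    expect_equal(cpca_log_likelihood(G, m), ll_softmax_oracle(G, U, V, mu),
                 tolerance = 1e-8)
    expect_lt(cpca_log_likelihood(G, m), 0)
  }
})

test_that("non-finite natural parameters are rejected with the offending cell", {
  m <- make_model(matrix(c(1, NaN), 2, 1), matrix(1, 4, 1), rep(0, 4), K = 2)
  expect_error(cpca_log_likelihood(matrix(0L, 2, 2), m), "sample 2")
})

test_that("the hand-derived single-cell Newton step is exact", {
  # n = 1, d = 1, l = 1, V1 = 1, V2 = 0, mu = 0, observed category 1, u = 0:
  # gradient 2/3, Hessian -2/9, Newton update u = 3
  m <- make_model(matrix(0, 1, 1), matrix(c(1, 0), 2, 1), c(0, 0))
  G <- matrix(1L, 1, 1)
  gh <- scpca:::.score_grad_hess(G, m, 1)
  expect_equal(gh$gradient, 2 / 3, tolerance = 1e-12)
  expect_equal(gh$hessian[1, 1], -2 / 9, tolerance = 1e-12)
  expect_equal(drop(-solve(gh$hessian) %*% gh$gradient), 3, tolerance = 1e-10)
  stepped <- newton_step_scores(G, m)
  expect_equal(stepped$U[1, 1], 3, tolerance = 1e-10)
  # symmetric case with roles of u and V exchanged (U fixed at 1)
  m2 <- make_model(matrix(1, 1, 1), matrix(c(0, 0), 2, 1), c(0, 0))
  stepped2 <- newton_step_loadings(G, m2)
  expect_equal(stepped2$V[1, 1], 3, tolerance = 1e-10)
  expect_equal(stepped2$V[2, 1], 0, tolerance = 1e-10)
})

test_that("analytic gradients and Hessians match finite differences", {
  set.seed(7)
  G <- rand_genotypes(4, 3, 7)
  U <- matrix(rnorm(4, sd = 0.5), 4, 1)
  V <- matrix(rnorm(6, sd = 0.5), 6, 1)
  mu <- rnorm(6, sd = 0.5)
  m <- make_model(U, V, mu)

  # scores, row 2
  f_u <- function(u) ll_softmax_oracle(G, rbind(U[1, ], u, U[3, ], U[4, ]),
                                       V, mu)
  gh <- scpca:::.score_grad_hess(G, m, 2)
  expect_equal(gh$gradient, fd_gradient(f_u, U[2, ]), tolerance = 1e-6)
  expect_equal(gh$hessian, fd_hessian(f_u, U[2, ]), tolerance = 1e-4)

  # loadings, SNP 3 (rows 3 and 6 of the stacked matrix)
  f_v <- function(w) {
    V2 <- V; V2[3, ] <- w[1]; V2[6, ] <- w[2]
    ll_softmax_oracle(G, U, V2, mu)
  }
  gh <- scpca:::.loading_grad_hess(G, m, 3)
  expect_equal(gh$gradient, fd_gradient(f_v, c(V[3, ], V[6, ])),
               tolerance = 1e-6)
  expect_equal(gh$hessian, fd_hessian(f_v, c(V[3, ], V[6, ])),
               tolerance = 1e-4)

  # offsets, SNP 1
  f_m <- function(w) {
    mu2 <- mu; mu2[1] <- w[1]; mu2[4] <- w[2]
    ll_softmax_oracle(G, U, V, mu2)
  }
  gh <- scpca:::.offset_grad_hess(G, m, 1)
  expect_equal(gh$gradient, fd_gradient(f_m, mu[c(1, 4)]), tolerance = 1e-6)
  expect_equal(gh$hessian, fd_hessian(f_m, mu[c(1, 4)]), tolerance = 1e-4)
})

test_that("damped Newton sweeps never decrease the likelihood", {
  for (seed in 1:15) {
    G <- rand_genotypes(5, 3, seed + 300)
    set.seed(seed)
    m <- make_model(matrix(rnorm(5), 5, 1), matrix(rnorm(6), 6, 1), rnorm(6))
    ll0 <- cpca_log_likelihood(G, m)
    for (stepfun in list(newton_step_scores, newton_step_loadings,
                         newton_step_offsets)) {
      m2 <- stepfun(G, m)
      expect_gte(cpca_log_likelihood(G, m2), ll0 - 1e-9)
    }
  }
})

test_that("a stationary row is left unchanged by the scores step", {
  # balanced column: u = 0 with symmetric loadings has zero gradient
  G <- matrix(c(0L, 1L, 2L), 3, 1)
  m <- make_model(matrix(0, 3, 1), matrix(c(0, 0), 2, 1), c(0, 0))
  gh <- scpca:::.score_grad_hess(G, m, 1)
  expect_equal(gh$gradient, 0)
  m2 <- newton_step_scores(G, m)
  expect_equal(m2$U, m$U)
})

test_that("offset updates converge to the multinomial intercept MLE", {
  # U = 0: repeated offset Newton steps must reach log(n_k / n_0)
  G <- matrix(c(rep(0L, 6), rep(1L, 3), rep(2L, 2)), ncol = 1)
  m <- make_model(matrix(0, 11, 1), matrix(c(0.5, 0.5), 2, 1), c(0, 0))
  for (i in 1:30) m <- newton_step_offsets(G, m)
  expect_equal(m$mu[1], log(3 / 6), tolerance = 1e-8)
  expect_equal(m$mu[2], log(2 / 6), tolerance = 1e-8)
  # balanced counts: both offsets zero by symmetry
  G2 <- matrix(rep(0:2, each = 10), ncol = 1)
  m2 <- make_model(matrix(0, 30, 1), matrix(c(0.3, -0.2), 2, 1), c(0.5, -0.5))
  for (i in 1:30) m2 <- newton_step_offsets(G2, m2)
  expect_equal(m2$mu, c(0, 0), tolerance = 1e-8)
})

test_that("QR re-orthonormalization preserves natural parameters exactly", {
  set.seed(42)
  m <- make_model(matrix(rnorm(12), 6, 2), matrix(rnorm(16), 8, 2), rnorm(8))
  th_before <- scpca:::.cpca_theta(m)
  m2 <- orthonormalize(m)
  th_after <- scpca:::.cpca_theta(m2)
  expect_lt(max(abs(th_before[[1]] - th_after[[1]])), 1e-10)
  expect_lt(max(abs(th_before[[2]] - th_after[[2]])), 1e-10)
  expect_lt(max(abs(crossprod(m2$V) - diag(2))), 1e-12)
  # an already-orthonormal matrix is unchanged up to column signs
  m3 <- orthonormalize(m2)
  expect_equal(abs(m3$V), abs(m2$V), tolerance = 1e-12)
  # rank-deficient stacked loadings are refused
  bad <- make_model(matrix(rnorm(12), 6, 2),
                    cbind(rep(1, 8), rep(1, 8)), rnorm(8))
  expect_error(orthonormalize(bad), "rank deficient")
})

test_that("fit_cpca satisfies its contract on random data", {
  G <- rand_genotypes(25, 6, 99)
  m <- fit_cpca(G, fit_config(latent_dim = 2, n_restarts = 2, seed = 5,
                              max_iterations = 100))
  expect_true(all(diff(m$trace) >= -1e-6))
  expect_gte(m$log_likelihood, m$trace[1])
  expect_lt(max(abs(crossprod(m$V) - diag(2))), 1e-8)
  expect_true(is.finite(m$log_likelihood))
  # deterministic under the seed
  m2 <- fit_cpca(G, fit_config(latent_dim = 2, n_restarts = 2, seed = 5,
                               max_iterations = 100))
  expect_identical(m$log_likelihood, m2$log_likelihood)
  expect_identical(m$U, m2$U)
})

test_that("batched fitting mode is monotone and agrees closely with per-row mode", {
  G <- rand_genotypes(40, 8, 123)
  mb <- fit_cpca(G, fit_config(seed = 3, batched = TRUE))
  mp <- fit_cpca(G, fit_config(seed = 3))
  expect_true(all(diff(mb$trace) >= -1e-6))
  # same likelihood scale; modes may land in slightly different optima
  expect_lt(abs(mb$log_likelihood - mp$log_likelihood) /
              abs(mp$log_likelihood), 0.05)
})

test_that("identical samples yield fitted probabilities at the empirical frequencies", {
  row <- c(0L, 1L, 2L, 1L)
  G <- matrix(rep(row, each = 12), 12, 4)
  m <- fit_cpca(G, fit_config(n_restarts = 2, seed = 11,
                              max_iterations = 300, tolerance = 1e-8))
  p <- cpca_cell_probabilities(m)
  # empirical frequency per cell is 1 for the observed category
  for (j in seq_along(row)) {
    expect_equal(p[[as.character(row[j])]][1, j], 1, tolerance = 1e-3)
  }
})

test_that("with only categories 0/1 the fit reduces to Bernoulli (logistic) PCA", {
  # Reference-category reduction: embedding Bernoulli parameters into the
  # 3-category model with zero category-2 loadings and category-2 offsets
  # at the clip makes category 2 impossible, so (a) the likelihood equals
  # the Bernoulli likelihood, (b) one damped Newton sweep updates
  # (U, V1, mu1) identically, and (c) on a saturable instance both fits
  # converge to the same probabilities.
  embed <- function(U, V, mu, d) {
    list(U = U, V = rbind(V, 0 * V), mu = c(mu, rep(-30, d)))
  }
  for (seed in 1:5) {
    set.seed(seed + 450)
    n <- 12; d <- 4
    G <- matrix(rbinom(n * d, 1, 0.5), n, d)
    U <- matrix(rnorm(n, sd = 0.5), n, 1)
    V <- matrix(rnorm(d, sd = 0.5), d, 1)
    mu <- rnorm(d, sd = 0.5)
    e <- embed(U, V, mu, d)
    # (a) likelihood-level reduction
    ll1 <- scpca:::.cpp_cpca_loglik(G, 1L, U, V, mu)
    ll2 <- scpca:::.cpp_cpca_loglik(G, 2L, e$U, e$V, e$mu)
    expect_equal(ll1, ll2, tolerance = 1e-10)
    # (b) one damped Newton sweep is identical for the shared parameters
    for (what in c("scores", "loadings", "offsets")) {
      s1 <- scpca:::.cpp_cpca_step(G, 1L, U, V, mu, what, 20L)
      s2 <- scpca:::.cpp_cpca_step(G, 2L, e$U, e$V, e$mu, what, 20L)
      expect_equal(as.numeric(s1$U), as.numeric(s2$U), tolerance = 1e-6)
      expect_equal(as.numeric(s1$V), as.numeric(s2$V[1:d, ]),
                   tolerance = 1e-6)
      expect_equal(as.numeric(s1$mu), as.numeric(s2$mu[1:d]),
                   tolerance = 1e-6)
    }
  }
  # (c) a saturable instance: a perfectly rank-1-separable binary pattern
  G <- outer(rep(c(0L, 1L), each = 5), c(1L, 1L, 0L, 0L))
  G[, 3:4] <- 1L - G[, 3:4]
  cfg <- fit_config(n_restarts = 5, seed = 2, max_iterations = 300,
                    tolerance = 1e-10)
  m1 <- scpca:::.fit_efpca(G, 1L, cfg)
  m2 <- fit_cpca(G, cfg)
  p1 <- cpca_cell_probabilities(m1)[["1"]]
  p2 <- cpca_cell_probabilities(m2)[["1"]]
  expect_lt(max(abs(p1 - G)), 1e-3)
  expect_lt(max(abs(p2 - G)), 1e-3)
  expect_lt(max(abs(p1 - p2)), 1e-3)
})

test_that("first PC scores have the documented sign and length", {
  G <- rand_genotypes(15, 4, 17)
  m <- fit_cpca(G, fit_config(seed = 2))
  s <- first_pc_scores(m)
  expect_length(s, 15)
  expect_gte(cor(s, rowSums(G)), 0)
})

test_that("model serialization round-trips through JSON", {
  G <- rand_genotypes(10, 3, 31)
  m <- fit_cpca(G, fit_config(seed = 4, n_restarts = 2))
  path <- tempfile(fileext = ".json")
  write_cpca_model(m, path)
  m2 <- read_cpca_model(path)
  expect_equal(m2$U, m$U, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$V, m$V, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(m2$mu, m$mu, tolerance = 1e-12)
  expect_equal(m2$log_likelihood, m$log_likelihood, tolerance = 1e-12)
  expect_equal(cpca_log_likelihood(G, m2), cpca_log_likelihood(G, m),
               tolerance = 1e-10)
  expect_equal(first_pc_scores(m2), first_pc_scores(m), tolerance = 1e-12)
})

test_that("configuration validation catches invalid settings", {
  expect_error(fit_config(latent_dim = 0), "latent_dim")
  expect_error(fit_config(tolerance = 0), "tolerance")
  expect_error(fit_config(n_restarts = 0), "n_restarts")
  # latent_dim must be < min(n, K*d)
  expect_error(fit_cpca(matrix(0:2, 3, 1), fit_config(latent_dim = 3)),
               "latent_dim")
})
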