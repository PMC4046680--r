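# Independent oracles and small fixture builders used across the suite.

# Build a cpca_model directly from parameter values (U n x l, V stacked
# (K*d) x l, mu length K*d).
make_model <- function(U, V, mu, K = 2L, config = fit_config()) {
  d <- nrow(V) / K
  scpca:::.new_cpca_model(U = as.matrix(U), V = as.matrix(V), mu = mu,
                          K = K, d = d, loglik = NA_real_, trace = NULL,
                          converged = TRUE, n_iterations = 0L,
                          config = config,
                          g_rowsums = rep(1, nrow(as.matrix(U))))
}

# Multinomial log-likelihood computed independently via softmax over the
# clipped natural parameters (clip 30 is part of the model definition).
ll_softmax_oracle <- function(G, U, V, mu, K = 2L) {
  n <- nrow(G); d <- ncol(G)
  U <- as.matrix(U); V <- as.matrix(V)
  theta <- lapply(seq_len(K), function(k) {
    th <- U %*% t(V[((k - 1) * d + 1):(k * d), , drop = FALSE])
    th <- sweep(th, 2, mu[((k - 1) * d + 1):(k * d)], "+")
    pmin(pmax(th, -30), 30)
  })
  denom <- Reduce(`+`, lapply(theta, exp)) + 1
  obs <- matrix(0, n, d)
  for (k in seq_len(K)) obs <- obs + (G == k) * theta[[k]]
  sum(obs - log(denom))
}

# Generic numerical maximizer of the same likelihood (multi-start BFGS
# over the unconstrained parameterization; the orthonormality constraint
# is a pure gauge choice and does not change the attainable likelihood).
optim_oracle <- function(G, l = 1L, K = 2L, starts = 6L, seed = 99L,
                         maxit = 300L) {
  n <- nrow(G); d <- ncol(G)
  np <- n * l + K * d * l + K * d
  fn <- function(par) {
    U <- matrix(par[1:(n * l)], n, l)
    V <- matrix(par[n * l + 1:(K * d * l)], K * d, l)
    mu <- par[n * l + K * d * l + 1:(K * d)]
    ll_softmax_oracle(G, U, V, mu, K)
  }
  set.seed(seed)
  best <- -Inf
  for (s in seq_len(starts)) {
    o <- optim(rnorm(np, sd = 0.7), fn, method = "BFGS",
               control = list(fnscale = -1, maxit = maxit, reltol = 1e-10))
    best <- max(best, o$value)
  }
  best
}

# Hand-rolled Benjamini-Hochberg step-up, independent of p.adjust.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m * p[o[i]] / i)
    adj[o[i]] <- prev
  }
  adj
}

# Central finite differences of a scalar function.
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

fd_hessian <- function(f, x, eps = 1e-4) {
  p <- length(x)
  H <- matrix(0, p, p)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + eps
      xm[i] <- xm[i] - eps
      H[i, j] <- (f(xp) - 2 * f(x) + f(xm)) / eps^2
    } else {
      xpp <- x; xpm <- x; xmp <- x; xmm <- x
      xpp[i] <- xpp[i] + eps; xpp[j] <- xpp[j] + eps
      xpm[i] <- xpm[i] + eps; xpm[j] <- xpm[j] - eps
      xmp[i] <- xmp[i] - eps; xmp[j] <- xmp[j] + eps
      xmm[i] <- xmm[i] - eps; xmm[j] <- xmm[j] - eps
      H[i, j] <- (f(xpp) - f(xpm) - f(xmp) + f(xmm)) / (4 * eps^2)
    }
  }
  (H + t(H)) / 2
}

rand_genotypes <- function(n, d, seed) {
  set.seed(seed)
  matrix(sample(0:2, n * d, replace = TRUE), n, d)
}
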