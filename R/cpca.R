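# Categorical (multinomial exponential-family) PCA.
#
# Genotype cell (i, j) is a 3-category multinomial observation.  With
# category 0 as reference, the non-reference log-odds are modeled as
#   theta^k_ij = u_i . v^k_j + mu^k_j,   k in {1, 2},  theta^0 = 0,
# with shared scores U (n x l), per-category loadings V^k (d x l) and
# offsets mu^k.  The stacked loading matrix rbind(V^1, V^2) is kept
# column-orthonormal by QR with back-rotation of U.  Natural parameters
# are clipped at |theta| <= 30 before exponentiation so the likelihood
# stays finite under separation (zero-count categories); the clipped form
# is the objective optimized and reported throughout.

.THETA_CLIP <- 30

#' Fitting configuration for categorical / Bernoulli PCA
#'
#' @param latent_dim number of principal components l (>= 1).
#' @param max_iterations cap on alternating-update iterations.
#' @param tolerance relative log-likelihood change declaring convergence.
#' @param n_restarts random restarts; the fit with the best final
#'   log-likelihood is kept (the objective is non-concave).
#' @param seed RNG seed controlling initialization.
#' @param damping maximum step-halvings per Newton update; the first step
#'   not decreasing the likelihood is accepted.
#' @param refine run a coordinate-flip local search around the best
#'   restart (warm refits with single score/loading/offset rows flipped or
#'   zeroed, accepted only on improvement).  Useful on small,
#'   near-separable datasets where nearly tied local optima differ by
#'   which cells the low-rank fit sacrifices; costs O(n + d) extra refits
#'   per round, so it is off by default.
#' @param batched use batched sweeps with global (rather than per-row)
#'   step-halving: one likelihood evaluation per sweep instead of one per
#'   block, several-fold faster and still monotone in the total
#'   likelihood.  The screening-scale setting used by the permutation
#'   pipeline; per-row line search remains the default.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(latent_dim = 1L, max_iterations = 200L,
                       tolerance = 1e-6, n_restarts = 5L, seed = 1L,
                       damping = 20L, refine = FALSE, batched = FALSE) {
  .assert(.is_count(latent_dim) && latent_dim >= 1, "latent_dim must be >= 1")
  .assert(.is_count(max_iterations) && max_iterations >= 1,
          "max_iterations must be >= 1")
  .assert(is.numeric(tolerance) && tolerance > 0, "tolerance must be > 0")
  .assert(.is_count(n_restarts) && n_restarts >= 1, "n_restarts must be >= 1")
  .assert(.is_count(damping) && damping >= 0, "damping must be >= 0")
  structure(list(latent_dim = as.integer(latent_dim),
                 max_iterations = as.integer(max_iterations),
                 tolerance = tolerance, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), damping = as.integer(damping),
                 refine = isTRUE(refine), batched = isTRUE(batched)),
            class = "fit_config")
}

#' One-hot encode a genotype matrix
#'
#' Expands genotypes into three 0/1 indicator matrices, one per category:
#' `x^k[i, j] = 1` iff genotype (i, j) equals k.  For every cell the three
#' indicators sum to one.
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @return Object of class `one_hot_genotypes`: list with `indicators`
#'   (list of matrices named "0", "1", "2"), `n`, `d`, `c = 3`.
#' @export
encode_one_hot <- function(G) {
  Gm <- .gvalues(G)
  ind <- lapply(0:2, function(k) {
    m <- matrix(0L, nrow(Gm), ncol(Gm), dimnames = dimnames(Gm))
    m[Gm == k] <- 1L
    m
  })
  names(ind) <- as.character(0:2)
  structure(list(indicators = ind, n = nrow(Gm), d = ncol(Gm), c = 3L),
            class = "one_hot_genotypes")
}

# Recover the integer category matrix (entries 0..K) from either encoding.
.as_catmat <- function(x) {
  if (inherits(x, "one_hot_genotypes")) {
    Gm <- matrix(0L, x$n, x$d)
    for (k in seq_along(x$indicators) - 1L)
      Gm[x$indicators[[as.character(k)]] == 1L] <- k
    return(Gm)
  }
  if (inherits(x, "genotype_matrix")) return(x$values)
  Gm <- as.matrix(x)
  .assert(!anyNA(Gm) && all(Gm >= 0), "invalid category matrix")
  storage.mode(Gm) <- "integer"
  Gm
}

.new_cpca_model <- function(U, V, mu, K, d, loglik, trace, converged,
                            n_iterations, config, g_rowsums) {
  structure(list(U = as.matrix(U), V = as.matrix(V), mu = as.numeric(mu),
                 K = as.integer(K), d = as.integer(d),
                 latent_dim = ncol(U), log_likelihood = loglik, trace = trace,
                 converged = converged, n_iterations = n_iterations,
                 config = config, g_rowsums = g_rowsums),
            class = "cpca_model")
}

#' @export
print.cpca_model <- function(x, ...) {
  cat(sprintf(
    "cpca_model: %d samples, %d SNPs, %d non-reference categories, l = %d\n",
    nrow(x$U), x$d, x$K, x$latent_dim))
  cat(sprintf("  log-likelihood %.6f after %d iteration(s); converged: %s\n",
              x$log_likelihood, x$n_iterations, x$converged))
  invisible(x)
}

#' Per-category loading matrix of a fitted model
#'
#' @param model a `cpca_model`.
#' @param category non-reference category index (1..K).
#' @return d x l loading matrix for that category.
#' @export
cpca_loadings <- function(model, category) {
  .assert(inherits(model, "cpca_model"), "not a cpca_model")
  .assert(category >= 1 && category <= model$K, "category out of range")
  model$V[((category - 1L) * model$d + 1L):(category * model$d), ,
          drop = FALSE]
}

# Clipped natural parameters as a list of K n x d matrices.
.cpca_theta <- function(model) {
  lapply(seq_len(model$K), function(k) {
    th <- model$U %*% t(cpca_loadings(model, k))
    th <- sweep(th, 2L, model$mu[((k - 1L) * model$d + 1L):(k * model$d)], "+")
    pmin(pmax(th, -.THETA_CLIP), .THETA_CLIP)
  })
}

#' Fitted cell probabilities
#'
#' Multinomial probabilities implied by the model's natural parameters,
#' one n x d matrix per category (reference category first).
#'
#' @param model a `cpca_model`.
#' @return List of K + 1 matrices named "0", "1", ..., "K".
#' @export
cpca_cell_probabilities <- function(model) {
  theta <- .cpca_theta(model)
  denom <- Reduce(`+`, lapply(theta, exp)) + 1
  out <- c(list(1 / denom), lapply(theta, function(t) exp(t) / denom))
  names(out) <- as.character(0:model$K)
  out
}

#' Multinomial log-likelihood of genotypes under a model
#'
#' Computes `sum_ij [ theta^{g_ij}_ij - log(1 + sum_k exp theta^k_ij) ]`
#' with `theta^0 = 0`; always <= 0.
#'
#' @param x one-hot genotypes ([encode_one_hot()]), a [genotype_matrix],
#'   or a bare category matrix.
#' @param model a `cpca_model` (any parameter values; need not be fitted).
#' @return Scalar log-likelihood.
#' @export
cpca_log_likelihood <- function(x, model) {
  Gm <- .as_catmat(x)
  .assert(nrow(Gm) == nrow(model$U) && ncol(Gm) == model$d,
          "dimensions of data and model disagree")
  .assert(max(Gm) <= model$K, "category exceeds model's K")
  raw <- lapply(seq_len(model$K), function(k) {
    sweep(model$U %*% t(cpca_loadings(model, k)), 2L,
          model$mu[((k - 1L) * model$d + 1L):(k * model$d)], "+")
  })
  for (k in seq_along(raw)) {
    bad <- which(!is.finite(raw[[k]]))
    if (length(bad)) {
      ij <- arrayInd(bad[1L], dim(raw[[k]]))
      stop(sprintf(
        "non-finite natural parameter at sample %d, SNP %d, category %d",
        ij[1L], ij[2L], k), call. = FALSE)
    }
  }
  .cpp_cpca_loglik(Gm, model$K, model$U, model$V, model$mu)
}

# ---------------------------------------------------------------------------
# Analytic derivatives (R reference implementations used for validation of
# the compiled Newton steps against finite differences).

# Gradient and Hessian of the log-likelihood w.r.t. score row i.
.score_grad_hess <- function(Gm, model, i) {
  K <- model$K; d <- model$d; l <- model$latent_dim
  p <- cpca_cell_probabilities(model)
  g <- numeric(l); H <- matrix(0, l, l)
  for (j in seq_len(d)) {
    A <- t(vapply(seq_len(K), function(k) cpca_loadings(model, k)[j, ],
                  numeric(l)))
    A <- matrix(A, nrow = K)
    pk <- vapply(seq_len(K), function(k) p[[k + 1L]][i, j], numeric(1))
    xk <- as.numeric(Gm[i, j] == seq_len(K))
    g <- g + drop(t(A) %*% (xk - pk))
    S <- diag(pk, nrow = K) - tcrossprod(pk)
    H <- H - t(A) %*% S %*% A
  }
  list(gradient = g, hessian = H)
}

# Gradient and Hessian w.r.t. SNP j's stacked loading rows (length K*l).
.loading_grad_hess <- function(Gm, model, j) {
  K <- model$K; l <- model$latent_dim; U <- model$U
  p <- cpca_cell_probabilities(model)
  g <- numeric(K * l); H <- matrix(0, K * l, K * l)
  for (k in seq_len(K)) {
    xk <- as.numeric(Gm[, j] == k)
    pk <- p[[k + 1L]][, j]
    g[((k - 1L) * l + 1L):(k * l)] <- drop(t(U) %*% (xk - pk))
    for (k2 in seq_len(K)) {
      w <- if (k == k2) pk * (1 - pk) else -pk * p[[k2 + 1L]][, j]
      H[((k - 1L) * l + 1L):(k * l), ((k2 - 1L) * l + 1L):(k2 * l)] <-
        -t(U) %*% (U * w)
    }
  }
  list(gradient = g, hessian = H)
}

# Gradient and Hessian w.r.t. SNP j's K offsets.
.offset_grad_hess <- function(Gm, model, j) {
  K <- model$K
  p <- cpca_cell_probabilities(model)
  g <- numeric(K); H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    pk <- p[[k + 1L]][, j]
    g[k] <- sum(Gm[, j] == k) - sum(pk)
    for (k2 in seq_len(K)) {
      H[k, k2] <- if (k == k2) -sum(pk * (1 - pk))
      else sum(pk * p[[k2 + 1L]][, j])
    }
  }
  list(gradient = g, hessian = H)
}

# ---------------------------------------------------------------------------
# Single damped Newton sweeps (spec'd operations; thin wrappers over the
# compiled solver internals).

.cpca_step <- function(x, model, what, damping) {
  Gm <- .as_catmat(x)
  res <- .cpp_cpca_step(Gm, model$K, model$U, model$V, model$mu, what,
                        as.integer(damping))
  if (res$n_fallbacks > 0)
    warning(sprintf(
      "singular Hessian in %d %s update(s); gradient step used",
      res$n_fallbacks, what))
  model$U <- res$U; model$V <- res$V; model$mu <- as.numeric(res$mu)
  model$log_likelihood <- res$loglik
  model
}

#' Damped Newton update of the principal component scores
#'
#' Updates every score row u_i independently by a Newton step with
#' step-halving, holding loadings and offsets fixed.  The log-likelihood
#' never decreases.
#'
#' @param x genotype data (any form accepted by [cpca_log_likelihood()]).
#' @param model a `cpca_model`.
#' @param damping maximum step-halvings.
#' @return Updated model.
#' @export
newton_step_scores <- function(x, model, damping = 20L) {
  .cpca_step(x, model, "scores", damping)
}

#' Damped Newton update of the per-category loadings
#'
#' Updates SNP j's K loading rows jointly, holding scores and offsets
#' fixed; log-likelihood non-decreasing.
#'
#' @inheritParams newton_step_scores
#' @return Updated model.
#' @export
newton_step_loadings <- function(x, model, damping = 20L) {
  .cpca_step(x, model, "loadings", damping)
}

#' Damped Newton update of the per-SNP offsets
#'
#' Updates SNP j's K offsets jointly, holding scores and loadings fixed;
#' log-likelihood non-decreasing.  With scores at zero this converges to
#' the multinomial intercept MLE log(n_k / n_0).
#'
#' @inheritParams newton_step_scores
#' @return Updated model.
#' @export
newton_step_offsets <- function(x, model, damping = 20L) {
  .cpca_step(x, model, "offsets", damping)
}

#' Re-orthonormalize the stacked loading matrix
#'
#' Replaces the stacked loadings by the Q of their QR decomposition and
#' back-rotates the scores by R^T, so every natural parameter (and hence
#' the likelihood) is unchanged to machine precision.
#'
#' @param model a `cpca_model`.
#' @return Model with orthonormal stacked loadings.
#' @export
orthonormalize <- function(model) {
  .assert(inherits(model, "cpca_model"), "not a cpca_model")
  res <- .cpp_cpca_orthonormalize(model$U, model$V)
  if (res$min_rdiag < 1e-12)
    stop("stacked loading matrix is rank deficient; use a smaller latent_dim",
         call. = FALSE)
  model$U <- res$U; model$V <- res$V
  model
}

# ---------------------------------------------------------------------------

# Offset initialization: per-SNP empirical log-odds with add-1/2 smoothing.
.init_offsets <- function(Gm, K) {
  d <- ncol(Gm)
  mu <- numeric(K * d)
  for (j in seq_len(d)) {
    counts <- tabulate(Gm[, j] + 1L, nbins = K + 1L)
    for (k in seq_len(K))
      mu[(k - 1L) * d + j] <- log((counts[k + 1L] + 0.5) / (counts[1L] + 0.5))
  }
  mu
}

# Coordinate-flip local search around a fitted solution: warm refits with
# one score row flipped or zeroed, or one loading/offset row flipped.
# Nearly tied local optima of the non-concave objective differ in which
# cells the low-rank fit sacrifices; these sign perturbations move between
# them while plain restarts rarely do.  Only improvements are accepted.
.refine_fit <- function(Gm, K, best, config) {
  for (round in 1:5) {
    gained <- FALSE
    cands <- c(lapply(seq_len(nrow(best$U)), function(i) {
      U <- best$U; U[i, ] <- -U[i, ]; list(U = U, V = best$V, mu = best$mu)
    }), lapply(seq_len(nrow(best$U)), function(i) {
      U <- best$U; U[i, ] <- 0; list(U = U, V = best$V, mu = best$mu)
    }), lapply(seq_len(nrow(best$V)), function(j) {
      V <- best$V; V[j, ] <- -V[j, ]; list(U = best$U, V = V, mu = best$mu)
    }), lapply(seq_len(nrow(best$V)), function(j) {
      mu <- best$mu; mu[j] <- -mu[j]; list(U = best$U, V = best$V, mu = mu)
    }))
    for (cand in cands) {
      res <- .cpp_cpca_fit(Gm, K, cand$U, cand$V, cand$mu,
                           config$max_iterations, config$tolerance,
                           config$damping, config$batched)
      if (res$loglik > best$loglik + 1e-10) {
        best <- res
        gained <- TRUE
      }
    }
    if (!gained) break
  }
  best
}

# Shared exponential-family PCA driver: K = 2 is categorical (CPCA),
# K = 1 the Bernoulli (logistic PCA) reduction.
.fit_efpca <- function(Gm, K, config) {
  n <- nrow(Gm); d <- ncol(Gm); l <- config$latent_dim
  .assert(d >= 1L && n >= 1L, "empty genotype matrix")
  .assert(max(Gm) <= K, "genotype category exceeds K = %d", K)
  .assert(l < min(n, K * d),
          "latent_dim must be < min(n samples, %d * d SNPs)", K)
  set.seed(config$seed)
  mu_emp <- .init_offsets(Gm, K)
  best <- NULL
  improved <- FALSE
  fallbacks <- 0L
  # Restart 1 starts from the empirical log-odds offsets with small random
  # scores/loadings; later restarts cycle through larger initialization
  # scales with random offsets, which reaches basins the small-scale start
  # cannot (the objective is non-concave and tiny separable datasets have
  # many local optima).
  scales <- 0.1 * 2^((seq_len(config$n_restarts) - 1L) %% 5L)
  for (r in seq_len(config$n_restarts)) {
    U0 <- matrix(rnorm(n * l, sd = scales[r]), n, l)
    V0 <- matrix(rnorm(K * d * l, sd = scales[r]), K * d, l)
    mu0 <- if (r == 1L) mu_emp else rnorm(K * d, sd = scales[r])
    res <- .cpp_cpca_fit(Gm, K, U0, V0, mu0, config$max_iterations,
                         config$tolerance, config$damping, config$batched)
    fallbacks <- fallbacks + res$n_fallbacks
    if (res$loglik > res$trace[1L] + 1e-12) improved <- TRUE
    if (is.null(best) || res$loglik > best$loglik) best <- res
  }
  if (config$refine) best <- .refine_fit(Gm, K, best, config)
  converged <- best$converged
  if (!improved) {
    warning("no restart improved on its initialization; returning initial model")
    converged <- FALSE
  }
  model <- .new_cpca_model(best$U, best$V, best$mu, K, d, best$loglik,
                           best$trace, converged, best$n_iterations, config,
                           rowSums(Gm))
  model$n_fallbacks <- fallbacks  # gradient steps taken on singular Hessians
  model
}

#' Fit categorical PCA to a genotype matrix
#'
#' Maximizes the multinomial log-likelihood of the low-rank natural
#' parameter model by cycling damped Newton updates of scores, loadings
#' and offsets with QR re-orthonormalization, over several random
#' restarts; the fit with the best final likelihood is returned.  The
#' per-iteration likelihood trace (available as `model$trace`) is
#' non-decreasing within a restart.
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @param config a [fit_config()].
#' @return A fitted `cpca_model`.
#' @export
fit_cpca <- function(G, config = fit_config()) {
  .fit_efpca(.gvalues(G), K = 2L, config = config)
}

#' First principal component scores of a fitted model
#'
#' Returns the first column of the score matrix with its sign fixed so
#' that the correlation with per-sample minor-allele counts is
#' non-negative (PCA signs are arbitrary; this stabilizes output across
#' runs and does not affect two-sided downstream statistics).
#'
#' @param model a fitted `cpca_model`.
#' @return Length-n numeric vector.
#' @export
first_pc_scores <- function(model) {
  .assert(inherits(model, "cpca_model"), "not a cpca_model")
  .assert(!is.null(model$U) && is.finite(model$log_likelihood),
          "model is not fitted")
  s <- model$U[, 1L]
  if (sd(s) > 0 && sd(model$g_rowsums) > 0 &&
      cor(s, model$g_rowsums) < 0) s <- -s
  s
}

#' Serialize a fitted model to JSON
#'
#' Writes dimensions, scores, per-category loadings, offsets, the final
#' log-likelihood and a configuration echo to a single JSON document;
#' [read_cpca_model()] restores it.
#'
#' @param model a `cpca_model`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cpca_model <- function(model, path) {
  .assert(inherits(model, "cpca_model"), "not a cpca_model")
  doc <- list(
    n = nrow(model$U), d = model$d, K = model$K,
    latent_dim = model$latent_dim,
    U = model$U,
    V_stacked = model$V,
    mu_stacked = model$mu,
    V = lapply(seq_len(model$K), function(k) cpca_loadings(model, k)),
    mu = lapply(seq_len(model$K), function(k)
      model$mu[((k - 1L) * model$d + 1L):(k * model$d)]),
    log_likelihood = model$log_likelihood,
    converged = model$converged, n_iterations = model$n_iterations,
    g_rowsums = model$g_rowsums,
    config = unclass(model$config))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Restore a model written by [write_cpca_model()]
#'
#' @param path JSON file path.
#' @return A `cpca_model`.
#' @export
read_cpca_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(fit_config, doc$config)
  .new_cpca_model(matrix(doc$U, ncol = doc$latent_dim),
                  matrix(doc$V_stacked, ncol = doc$latent_dim),
                  as.numeric(doc$mu_stacked), doc$K, doc$d,
                  doc$log_likelihood, trace = NULL, doc$converged,
                  doc$n_iterations, cfg, doc$g_rowsums)
}
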