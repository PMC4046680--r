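# Supervised SNP-set association: univariate screening, nested candidate
# subsets at p-value percentiles, first-PC logistic t statistics, the
# max-|t| set statistic M, a Bernoulli-relabeling permutation null, and
# Benjamini-Hochberg adjustment across sets.

#' Per-SNP logistic screening p-values
#'
#' Fits, for each SNP, a maximum-likelihood logistic regression of the
#' phenotype on the numeric 0/1/2 genotype and returns the two-sided Wald
#' p-value of the slope.  Constant-genotype SNPs get p = 1; fits showing
#' separation are refit with Firth's penalized score (a warning reports
#' how many).
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @param y binary phenotype aligned to the rows of `G` (1 = case).
#' @param warn warn when a separation-triggered Firth refit occurred
#'   (suppressed inside the permutation pipeline, where the fallback is
#'   routine).
#' @return Numeric vector of d p-values.
#' @export
per_snp_pvalues <- function(G, y, warn = TRUE) {
  Gm <- .gvalues(G)
  validate_phenotype(y)
  .assert(length(y) == nrow(Gm), "phenotype length does not match samples")
  res <- .cpp_screen_logistic(Gm * 1.0, as.numeric(y))
  p <- 2 * pnorm(-abs(res$t))
  p[is.na(res$t)] <- 1  # constant columns carry no information
  if (warn && any(res$firth > 0))
    warning(sprintf("separation in %d SNP(s); Firth-penalized refit used",
                    sum(res$firth > 0)))
  p
}

#' Nested candidate SNP subsets from screening p-values
#'
#' Thresholds are the nearest-rank w * (100 / v) percentiles of the
#' p-values (w = 1..v); subset w holds the SNPs with p <= threshold w, so
#' subsets are nested and the last one is the full set.  Identical
#' subsets produced by tied thresholds are collapsed (each unique subset
#' is fitted once downstream).
#'
#' @param pvalues numeric vector of per-SNP p-values.
#' @param v number of percentile increments (default 20, i.e. every 5th
#'   percentile).
#' @return Object of class `candidate_subsets`: list with `subsets`
#'   (list of integer index vectors, increasing size), `thresholds`, `v`.
#' @export
candidate_subsets <- function(pvalues, v = 20L) {
  .assert(length(pvalues) >= 1L, "need at least one p-value")
  .assert(all(is.finite(pvalues)), "p-values must be finite")
  .assert(.is_count(v) && v >= 1L, "v must be a positive integer")
  d <- length(pvalues)
  ps <- sort(pvalues)
  ranks <- pmin(d, pmax(1L, ceiling(seq_len(v) / v * d)))  # nearest rank
  thresholds <- ps[ranks]
  subsets <- lapply(thresholds, function(t) which(pvalues <= t))
  keep <- !duplicated(vapply(subsets, length, integer(1)))
  structure(list(subsets = subsets[keep], thresholds = thresholds[keep],
                 v = as.integer(v)), class = "candidate_subsets")
}

# Internal: logistic Wald t of y on a single score vector.
.score_t <- function(scores, y) {
  if (sd(scores) == 0) return(0)
  fit <- .cpp_logistic_wald(as.numeric(scores), as.numeric(y))
  t <- fit$t
  if (!is.finite(t)) t <- 0
  t
}

# Internal: first-PC scores of a genotype submatrix by the named method.
.method_scores <- function(Gm, method, config) {
  switch(method,
         cpca = fit_cpca_scores(Gm, config)$scores,
         pca = fit_pca_scores(Gm)$scores,
         lpca = fit_lpca_scores(Gm, config)$scores,
         stop(sprintf("unknown method '%s'", method), call. = FALSE))
}

#' Wald t of the phenotype on a subset's first principal component
#'
#' Restricts the genotype matrix to the subset's columns, extracts the
#' first PC scores by the requested method, and fits a logistic
#' regression of the phenotype on the score (intercept + score),
#' returning the Wald t of the score coefficient.  Degenerate scores
#' (zero variance) give t = 0; separation is handled by a Firth refit.
#'
#' @param subset a [snp_set] or integer vector of column indices.
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @param y binary phenotype (1 = case).
#' @param method `"cpca"`, `"pca"` or `"lpca"`.
#' @param config a [fit_config()] for the CPCA/LPCA fits.
#' @return Scalar t statistic.
#' @export
subset_t <- function(subset, G, y, method = c("cpca", "pca", "lpca"),
                     config = fit_config()) {
  method <- match.arg(method)
  idx <- if (inherits(subset, "snp_set")) subset$snp_indices
  else as.integer(subset)
  .assert(length(idx) >= 1L, "subset is empty")
  Gm <- .gvalues(G)
  scores <- tryCatch(
    .method_scores(Gm[, idx, drop = FALSE], method, config),
    error = function(e) stop(sprintf(
      "PC fit failed for subset {%s}: %s",
      paste(head(idx, 5L), collapse = ","), conditionMessage(e)),
      call. = FALSE))
  .score_t(scores, y)
}

# Signed max-|t| selection with ties broken toward the smaller subset:
# subsets must arrive ordered by increasing size; strict > keeps the
# first (smallest) maximizer.
.select_m <- function(t_values) {
  best <- 1L
  for (i in seq_along(t_values))
    if (abs(t_values[i]) > abs(t_values[best])) best <- i
  list(index = best, M = t_values[best])
}

#' M statistic of a SNP set
#'
#' Screens the set's SNPs, forms nested candidate subsets, computes each
#' unique subset's first-PC logistic t, and returns the signed t with the
#' maximal absolute value (ties broken toward the smaller subset)
#' together with the optimal subset.
#'
#' @param S a [snp_set] or integer vector of column indices into `G`.
#' @inheritParams subset_t
#' @param v number of percentile thresholds for candidate subsets.
#' @return List: `M` (signed t), `optimal_subset` (original column
#'   indices), `t_values`, `subsets`.
#' @export
m_statistic <- function(S, G, y, method = c("cpca", "pca", "lpca"),
                        config = fit_config(), v = 20L) {
  method <- match.arg(method)
  .m_statistic(S, .gvalues(G), y, method, config, v, cache = NULL)
}

# First-PC scores by plain SVD (prcomp has too much per-call overhead for
# the permutation layer).
.pca_scores_fast <- function(Gm) {
  Xc <- sweep(Gm * 1.0, 2L, colMeans(Gm), "-")
  if (all(abs(Xc) < 1e-12)) return(numeric(nrow(Gm)))
  v1 <- svd(Xc, nu = 0L, nv = 1L)$v
  .fix_sign(drop(Xc %*% v1), rowSums(Gm))
}

# Workhorse behind m_statistic and the permutation layer.  Two
# performance devices, both phenotype-independent and hence shareable
# across permutation rounds through `cache`:
#  * the full set is fitted once (cold, with restarts) per genotype
#    matrix and method;
#  * each candidate subset is warm-started from the full-set solution
#    restricted to its SNPs, which converges in a handful of iterations.
.m_statistic <- function(S, Gm, y, method, config, v, cache = NULL) {
  idx <- if (inherits(S, "snp_set")) S$snp_indices else as.integer(S)
  .assert(length(idx) >= 1L, "SNP set is empty")
  sub <- Gm[, idx, drop = FALSE]
  d <- ncol(sub)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  p <- per_snp_pvalues(sub, y, warn = FALSE)
  cand <- candidate_subsets(p, v)

  get_scores <- function(s) {
    key <- paste(s, collapse = ",")
    scores <- cache[[key]]
    if (!is.null(scores)) return(scores)
    scores <- tryCatch(
      .subset_scores(sub, s, method, config, cache),
      error = function(e) stop(sprintf(
        "PC fit failed for subset {%s}: %s",
        paste(head(idx[s], 5L), collapse = ","), conditionMessage(e)),
        call. = FALSE))
    cache[[key]] <- scores
    scores
  }
  t_values <- vapply(cand$subsets, function(s) .score_t(get_scores(s), y),
                     numeric(1))
  sel <- .select_m(t_values)
  list(M = sel$M, optimal_subset = idx[cand$subsets[[sel$index]]],
       t_values = t_values, subsets = lapply(cand$subsets,
                                             function(s) idx[s]))
}

# Scores of one candidate subset, warm-started from the cached full-set
# exponential-family fit where applicable.
.subset_scores <- function(sub, s, method, config, cache) {
  d <- ncol(sub)
  if (method == "pca") return(.pca_scores_fast(sub[, s, drop = FALSE]))
  K <- if (method == "cpca") 2L else 1L
  Em <- if (method == "cpca") sub else {
    B <- cache[["__bin"]]
    if (is.null(B)) {
      B <- (sub > 0L) + 0L
      storage.mode(B) <- "integer"
      cache[["__bin"]] <- B
    }
    B
  }
  if (method == "lpca" && length(s) == 1L) {
    x <- Em[, s]
    return(.fix_sign(x - mean(x), rowSums(sub[, s, drop = FALSE])))
  }
  fkey <- paste0("__full_K", K)
  full <- cache[[fkey]]
  if (is.null(full)) {
    m <- .fit_efpca(Em, K, config)
    full <- list(U = m$U, V = m$V, mu = m$mu)
    cache[[fkey]] <- full
  }
  if (length(s) == d) {
    res <- full
  } else {
    rows <- as.integer(outer(s, (seq_len(K) - 1L) * d, "+"))
    res <- .cpp_cpca_fit(Em[, s, drop = FALSE], K, full$U,
                         full$V[rows, , drop = FALSE], full$mu[rows],
                         config$max_iterations, config$tolerance,
                         config$damping, config$batched)
  }
  .fix_sign(res$U[, 1L], rowSums(sub[, s, drop = FALSE]))
}

#' Permutation null sample of the M statistic
#'
#' For each round, a random phenotype is drawn i.i.d. Bernoulli at the
#' disease prevalence and the full screening/subset/M computation is
#' repeated on the unchanged genotypes.  Degenerate draws (all cases or
#' all controls) are redrawn up to 3 times.
#'
#' @inheritParams m_statistic
#' @param prevalence disease prevalence in (0, 1) used for the Bernoulli
#'   relabeling.
#' @param B number of permutation rounds (>= 1).
#' @param seed RNG seed; the null vector is reproducible bit-for-bit.
#' @param cache optional environment memoising per-subset PC scores
#'   (scores depend only on genotypes, so permutation rounds share fits);
#'   one is created internally when `NULL`.
#' @return Numeric vector of B null M values.
#' @export
permutation_null <- function(S, G, prevalence, B, method = c("cpca", "pca",
                                                             "lpca"),
                             config = fit_config(), seed = 1L, v = 20L,
                             cache = NULL) {
  method <- match.arg(method)
  .assert(.is_count(B) && B >= 1L, "B must be a positive integer")
  .assert(is.numeric(prevalence) && prevalence > 0 && prevalence < 1,
          "prevalence must be in (0, 1)")
  Gm <- .gvalues(G)
  n <- nrow(Gm)
  if (is.null(cache)) cache <- new.env(parent = emptyenv())
  set.seed(seed)
  vapply(seq_len(B), function(b) {
    for (attempt in 1:3) {
      ystar <- rbinom(n, 1L, prevalence)
      if (any(ystar == 1L) && any(ystar == 0L))
        return(.m_statistic(S, Gm, ystar, method, config, v, cache)$M)
    }
    stop("permutation round produced degenerate phenotypes 3 times",
         call. = FALSE)
  }, numeric(1))
}

#' Empirical p-value from a permutation null
#'
#' Add-one convention: `p = (1 + #{|M_b| >= |M_obs|}) / (B + 1)`, so
#' p is always in (0, 1].
#'
#' @param M_obs observed M statistic.
#' @param null_M numeric vector of null M values.
#' @return Scalar p-value.
#' @export
empirical_pvalue <- function(M_obs, null_M) {
  .assert(length(null_M) >= 1L, "null sample is empty")
  (1 + sum(abs(null_M) >= abs(M_obs))) / (length(null_M) + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR-adjusted p-values (monotone, capped at 1).
#'
#' @param pvalues numeric vector in [0, 1].
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  .assert(is.numeric(pvalues) && all(is.finite(pvalues)) &&
            all(pvalues >= 0 & pvalues <= 1),
          "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Aggregated association analysis over a collection of SNP sets
#'
#' Runs the full supervised pipeline per set — screening, candidate
#' subsets, M statistic, permutation null, empirical p-value — then
#' adjusts across sets by Benjamini-Hochberg.  Each set's permutation
#' stream is seeded deterministically from `seed` and the set id, so
#' results are reproducible and identical sets give identical output.
#' By default each set is tested against its own null sample;
#' `pool_null = TRUE` pools null M values across all sets instead.
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @param y binary phenotype (1 = case).
#' @param snpsets list of [snp_set] objects (gene- or pathway-level).
#' @param method `"cpca"`, `"pca"` or `"lpca"`.
#' @param B permutation rounds per set.
#' @param prevalence Bernoulli relabeling probability; defaults to the
#'   observed case fraction (true population prevalence is unknown in
#'   case-control data).
#' @param config a [fit_config()].
#' @param seed base RNG seed.
#' @param pool_null pool null samples across sets before computing
#'   empirical p-values.
#' @param v number of percentile thresholds for candidate subsets.
#' @return Object of class `scpca_assoc`: list with `results` (data.frame
#'   set_id, n_snps, n_snps_optimal, M, p_value, p_adjusted), `nulls`
#'   (per-set null vectors), `failed` (ids of sets that errored), and the
#'   call settings.
#' @export
run_snpset_analysis <- function(G, y, snpsets, method = c("cpca", "pca",
                                                          "lpca"),
                                B = 999L, prevalence = NULL,
                                config = fit_config(), seed = 1L,
                                pool_null = FALSE, v = 20L) {
  method <- match.arg(method)
  Gm <- .gvalues(G)
  validate_phenotype(y)
  .assert(length(y) == nrow(Gm), "phenotype length does not match samples")
  if (is.null(prevalence)) prevalence <- mean(y)
  rows <- list(); nulls <- list(); failed <- character()
  for (s in snpsets) {
    .assert(inherits(s, "snp_set"), "snpsets must be a list of snp_set")
    res <- tryCatch({
      cache <- new.env(parent = emptyenv())
      obs <- .m_statistic(s, Gm, y, method, config, v, cache)
      null_M <- permutation_null(s, Gm, prevalence, B, method = method,
                                 config = config,
                                 seed = .derive_seed(seed, s$set_id), v = v,
                                 cache = cache)
      list(obs = obs, null = null_M)
    }, error = function(e) {
      warning(sprintf("set '%s' failed: %s", s$set_id, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) { failed <- c(failed, s$set_id); next }
    nulls[[s$set_id]] <- res$null
    rows[[length(rows) + 1L]] <- data.frame(
      set_id = s$set_id, n_snps = length(s$snp_indices),
      n_snps_optimal = length(res$obs$optimal_subset), M = res$obs$M,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  if (!is.null(results)) {
    pool <- if (pool_null) unlist(nulls, use.names = FALSE) else NULL
    results$p_value <- vapply(seq_len(nrow(results)), function(i) {
      nm <- if (pool_null) pool else nulls[[results$set_id[i]]]
      empirical_pvalue(results$M[i], nm)
    }, numeric(1))
    results$p_adjusted <- bh_adjust(results$p_value)
  }
  structure(list(results = results, nulls = nulls, failed = failed,
                 method = method, B = as.integer(B), prevalence = prevalence,
                 pool_null = pool_null, seed = seed),
            class = "scpca_assoc")
}

#' @export
print.scpca_assoc <- function(x, ...) {
  cat(sprintf("scpca_assoc: %d set(s), method %s, B = %d permutations\n",
              if (is.null(x$results)) 0L else nrow(x$results), x$method, x$B))
  if (!is.null(x$results)) {
    ord <- order(x$results$p_value)
    print(head(x$results[ord, ], 10L), row.names = FALSE)
  }
  if (length(x$failed))
    cat("failed sets:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}
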