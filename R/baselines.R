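# Comparison-arm score extractors: standard PCA on the numeric 0/1/2
# coding, and logistic (Bernoulli) PCA on a binarized coding.  Both feed
# the same supervised association layer as categorical PCA.

.fix_sign <- function(scores, rowsums) {
  if (sd(scores) > 0 && sd(rowsums) > 0 && cor(scores, rowsums) < 0)
    scores <- -scores
  scores
}

#' First-PC scores by standard PCA
#'
#' Treats genotypes as numeric minor-allele counts, column-centers, and
#' projects onto the first right-singular direction.  Sign fixed as in
#' [first_pc_scores()].
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix (>= 2 samples).
#' @return List of class `pc_scores`: `scores` (length n), `method`.
#' @export
fit_pca_scores <- function(G) {
  Gm <- .gvalues(G)
  .assert(nrow(Gm) >= 2L, "PCA needs at least 2 samples")
  if (all(apply(Gm, 2L, sd) == 0)) {
    warning("zero-variance genotype matrix; returning zero scores")
    s <- numeric(nrow(Gm))
  } else {
    s <- prcomp(Gm, center = TRUE, scale. = FALSE)$x[, 1L]
    s <- .fix_sign(unname(s), rowSums(Gm))
  }
  structure(list(scores = s, method = "pca"), class = "pc_scores")
}

#' First-PC scores by logistic (Bernoulli) PCA
#'
#' Binarizes genotypes (dominant coding by default: any minor allele
#' maps to 1) and fits the Bernoulli reduction of the categorical PCA
#' solver (one non-reference category).  The original categorical coding
#' cannot distinguish heterozygotes from minor homozygotes after this
#' transform, which is exactly the information loss the categorical model
#' avoids.
#'
#' @param G a [genotype_matrix] or bare 0/1/2 matrix.
#' @param config a [fit_config()].
#' @param coding `"dominant"` (0 -> 0; 1, 2 -> 1) or `"recessive"`
#'   (0, 1 -> 0; 2 -> 1).
#' @return List of class `pc_scores` with the underlying `model` attached.
#' @export
fit_lpca_scores <- function(G, config = fit_config(),
                            coding = c("dominant", "recessive")) {
  coding <- match.arg(coding)
  Gm <- .gvalues(G)
  B <- if (coding == "dominant") (Gm > 0L) + 0L else (Gm == 2L) + 0L
  storage.mode(B) <- "integer"
  if (ncol(B) == 1L) {
    # a single binary SNP has one free direction: the centered column
    s <- .fix_sign(drop(B - mean(B)), rowSums(Gm))
    return(structure(list(scores = s, method = "lpca", model = NULL),
                     class = "pc_scores"))
  }
  model <- .fit_efpca(B, K = 1L, config = config)
  structure(list(scores = first_pc_scores(model), method = "lpca",
                 model = model), class = "pc_scores")
}

#' First-PC scores by categorical PCA
#'
#' Convenience wrapper: [fit_cpca()] followed by [first_pc_scores()].
#'
#' @inheritParams fit_lpca_scores
#' @return List of class `pc_scores` with the underlying `model` attached.
#' @export
fit_cpca_scores <- function(G, config = fit_config()) {
  model <- fit_cpca(G, config)
  structure(list(scores = first_pc_scores(model), method = "cpca",
                 model = model), class = "pc_scores")
}
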