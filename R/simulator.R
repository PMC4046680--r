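# Case-control genotype simulator.  Emulates haplotype-resampling designs:
# a pool of LD-structured 0/1 haplotypes (latent-Gaussian threshold model
# with block-wise correlation), genotypes as sums of two random
# haplotypes, and a per-SNP penetrance disease model with heterozygote /
# homozygote relative risks combined multiplicatively across causal SNPs.

#' Build a pool of LD-structured haplotypes
#'
#' Haplotypes are drawn from a block-wise latent-Gaussian threshold
#' model: within a block all latent variables share correlation `rho`
#' and each is thresholded at the quantile matching its SNP's target
#' minor-allele frequency; blocks are independent.  Columns are oriented
#' so the pool frequency of the 1 allele is <= 0.5.
#'
#' @param d number of SNPs.
#' @param block_size SNPs per LD block (last block may be shorter).
#' @param mafs target minor-allele frequencies in (0, 0.5]; a single
#'   value is recycled; `NULL` draws them from `maf_range`.
#' @param rho within-block latent correlation in [0, 1).
#' @param pool_size number of haplotypes.
#' @param seed RNG seed.
#' @param maf_range range for randomly drawn MAFs.
#' @return Object of class `haplotype_pool`: `haplotypes` (pool_size x d
#'   0/1 matrix), `blocks` (list of index vectors), `maf_target`,
#'   `maf_empirical`, `rho`.
#' @export
build_haplotype_pool <- function(d, block_size = 10L, mafs = NULL,
                                 rho = 0.7, pool_size = 10000L, seed = 1L,
                                 maf_range = c(0.05, 0.5)) {
  .assert(.is_count(d) && d >= 1, "d must be a positive integer")
  .assert(rho >= 0 && rho < 1, "rho must be in [0, 1)")
  set.seed(seed)
  if (is.null(mafs)) mafs <- runif(d, maf_range[1L], maf_range[2L])
  if (length(mafs) == 1L) mafs <- rep(mafs, d)
  .assert(length(mafs) == d && all(mafs > 0 & mafs <= 0.5),
          "mafs must be %d values in (0, 0.5]", d)
  starts <- seq(1L, d, by = block_size)
  blocks <- lapply(starts, function(s) s:min(s + block_size - 1L, d))
  H <- matrix(0L, pool_size, d)
  for (b in blocks) {
    z_common <- rnorm(pool_size)
    for (j in b) {
      z <- sqrt(rho) * z_common + sqrt(1 - rho) * rnorm(pool_size)
      H[, j] <- as.integer(z < qnorm(mafs[j]))
    }
  }
  freq <- colMeans(H)
  flip <- freq > 0.5
  if (any(flip)) {
    H[, flip] <- 1L - H[, flip]
    freq[flip] <- 1 - freq[flip]
  }
  .assert(all(freq > 0),
          "monomorphic SNP in haplotype pool; increase pool_size or MAF")
  structure(list(haplotypes = H, blocks = blocks, maf_target = mafs,
                 maf_empirical = freq, rho = rho),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype_pool: %d haplotypes x %d SNPs, %d block(s), rho = %g\n",
              nrow(x$haplotypes), ncol(x$haplotypes), length(x$blocks), x$rho))
  invisible(x)
}

#' Penetrance-based disease model
#'
#' Disease probability given genotypes: each causal SNP contributes a
#' factor 1, rr1 or rr2 for genotype 0, 1 or 2; factors multiply across
#' causal SNPs on a baseline penetrance f0, capped at 1.  `rr1 = rr2 = 1`
#' is the null model.
#'
#' @param causal_snps column indices of causal SNPs (may be empty for a
#'   pure null model).
#' @param f0 baseline penetrance (> 0).
#' @param rr1,rr2 heterozygote / homozygote relative risks (scalar or one
#'   per causal SNP).
#' @return Object of class `disease_model`.
#' @export
disease_model <- function(causal_snps, f0 = 0.05, rr1 = 1, rr2 = 1) {
  .assert(is.numeric(f0) && f0 > 0 && f0 <= 1, "f0 must be in (0, 1]")
  nc <- length(causal_snps)
  if (length(rr1) == 1L) rr1 <- rep(rr1, nc)
  if (length(rr2) == 1L) rr2 <- rep(rr2, nc)
  .assert(length(rr1) == nc && length(rr2) == nc,
          "rr1/rr2 must be scalar or one per causal SNP")
  .assert(all(rr1 >= 0) && all(rr2 >= 0), "relative risks must be >= 0")
  structure(list(causal_snps = as.integer(causal_snps), f0 = f0,
                 rr1 = rr1, rr2 = rr2), class = "disease_model")
}

#' Disease probability for given genotypes
#'
#' @param Gm genotype matrix (rows = samples) or a single genotype vector.
#' @param model a [disease_model()].
#' @return Vector of penetrances, capped at 1.
#' @export
penetrance <- function(Gm, model) {
  if (is.null(dim(Gm))) Gm <- matrix(Gm, nrow = 1L)
  pi <- rep(model$f0, nrow(Gm))
  for (c in seq_along(model$causal_snps)) {
    g <- Gm[, model$causal_snps[c]]
    pi <- pi * ifelse(g == 0L, 1, ifelse(g == 1L, model$rr1[c], model$rr2[c]))
  }
  pmin(1, pi)
}

#' Sample a balanced case-control genotype dataset
#'
#' Rejection sampling: genotypes are formed as the sum of two haplotypes
#' drawn at random from the pool; each individual is affected with
#' probability equal to their penetrance under the disease model, and
#' sampling continues until both quotas are met.
#'
#' @param pool a [build_haplotype_pool()] result.
#' @param model a [disease_model()].
#' @param n_cases,n_controls sample quotas.
#' @param seed RNG seed.
#' @return List: `G` (a [genotype_matrix], cases first), `y` (0/1
#'   vector).
#' @export
sample_case_control <- function(pool, model, n_cases, n_controls,
                                seed = 1L) {
  .assert(inherits(pool, "haplotype_pool"), "not a haplotype_pool")
  .assert(n_cases >= 0 && n_controls >= 0 && n_cases + n_controls > 0,
          "need a positive number of samples")
  H <- pool$haplotypes
  m <- nrow(H); d <- ncol(H)
  set.seed(seed)
  if (n_cases > 0) {
    pr_case <- mean(penetrance(H[sample.int(m, min(m, 2000L)), , drop = FALSE] +
                                 H[sample.int(m, min(m, 2000L)), , drop = FALSE],
                               model))
    .assert(pr_case > 0, "disease model gives zero case probability")
  }
  cases <- matrix(0L, 0L, d); controls <- matrix(0L, 0L, d)
  for (round in 1:1000) {
    need_case <- n_cases - nrow(cases)
    need_ctrl <- n_controls - nrow(controls)
    if (need_case <= 0 && need_ctrl <= 0) break
    batch <- max(200L, 2L * (need_case + need_ctrl))
    G <- H[sample.int(m, batch, replace = TRUE), , drop = FALSE] +
      H[sample.int(m, batch, replace = TRUE), , drop = FALSE]
    affected <- runif(batch) < penetrance(G, model)
    if (need_case > 0) {
      take <- which(affected)
      cases <- rbind(cases, G[head(take, need_case), , drop = FALSE])
    }
    if (need_ctrl > 0) {
      take <- which(!affected)
      controls <- rbind(controls, G[head(take, need_ctrl), , drop = FALSE])
    }
  }
  .assert(nrow(cases) == n_cases && nrow(controls) == n_controls,
          "case/control quotas not met; check the disease model")
  vals <- rbind(cases, controls)
  y <- c(rep(1L, n_cases), rep(0L, n_controls))
  ids <- c(sprintf("case%d", seq_len(n_cases)),
           sprintf("ctrl%d", seq_len(n_controls)))
  list(G = genotype_matrix(vals, sample_ids = ids), y = y)
}

#' Define a gene-based simulation scenario
#'
#' Describes a power-study design: a set of genes (independent LD-block
#' SNP groups), a subset of causal genes each carrying randomly chosen
#' disease SNPs at given relative risks, balanced case-control sampling,
#' and replicates.  Defaults mirror a chromosome-scale reference design:
#' 50 genes of 11-175 SNPs, 5 causal genes with 3 disease SNPs each,
#' 500 cases + 500 controls, 100 replicates.
#'
#' @param n_genes number of genes.
#' @param n_causal number of causal genes (the first `n_causal`).
#' @param rr1,rr2 heterozygote / homozygote relative risks of every
#'   disease SNP.
#' @param n_cases,n_controls per-dataset sample quotas.
#' @param n_replicates replicates per gene.
#' @param n_disease_snps disease SNPs per causal gene (randomly chosen).
#' @param snps_per_gene SNP count per gene: a single value, a vector of
#'   length `n_genes`, or `NULL` to draw uniformly from 11..175.
#' @param f0 baseline penetrance.
#' @param maf_range,rho,block_size,pool_size haplotype-pool parameters.
#' @param seed base seed; all per-dataset streams derive from it.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_genes = 50L, n_causal = 5L, rr1 = 1.2, rr2 = 1.3,
                         n_cases = 500L, n_controls = 500L,
                         n_replicates = 100L, n_disease_snps = 3L,
                         snps_per_gene = NULL, f0 = 0.05,
                         maf_range = c(0.05, 0.5), rho = 0.7,
                         block_size = 10L, pool_size = 10000L, seed = 1L) {
  .assert(n_causal <= n_genes, "n_causal cannot exceed n_genes")
  set.seed(.derive_seed(seed, "sizes"))
  if (is.null(snps_per_gene)) snps_per_gene <- sample(11:175, n_genes,
                                                      replace = TRUE)
  if (length(snps_per_gene) == 1L)
    snps_per_gene <- rep(snps_per_gene, n_genes)
  .assert(length(snps_per_gene) == n_genes,
          "snps_per_gene must have one entry per gene")
  .assert(all(snps_per_gene >= n_disease_snps),
          "genes must have at least n_disease_snps SNPs")
  structure(list(n_genes = as.integer(n_genes), n_causal = as.integer(n_causal),
                 rr1 = rr1, rr2 = rr2, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_replicates = as.integer(n_replicates),
                 n_disease_snps = as.integer(n_disease_snps),
                 snps_per_gene = as.integer(snps_per_gene), f0 = f0,
                 maf_range = maf_range, rho = rho,
                 block_size = as.integer(block_size),
                 pool_size = as.integer(pool_size), seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Dataset plan of a scenario
#'
#' One row per (replicate, gene) dataset to be simulated, with its
#' causal flag and derived seed; cheap (no data generated).
#'
#' @param scenario a [sim_scenario()].
#' @return data.frame(replicate, gene_index, gene_id, is_causal, seed).
#' @export
scenario_plan <- function(scenario) {
  grid <- expand.grid(gene_index = seq_len(scenario$n_genes),
                      replicate = seq_len(scenario$n_replicates))
  data.frame(replicate = grid$replicate, gene_index = grid$gene_index,
             gene_id = sprintf("gene%d", grid$gene_index),
             is_causal = grid$gene_index <= scenario$n_causal,
             seed = vapply(seq_len(nrow(grid)), function(i)
               .derive_seed(scenario$seed, "data", grid$replicate[i],
                            grid$gene_index[i]), integer(1)))
}

# Disease SNPs of a gene (fixed across replicates).
.gene_disease_snps <- function(scenario, gene_index) {
  set.seed(.derive_seed(scenario$seed, "snps", gene_index))
  sort(sample.int(scenario$snps_per_gene[gene_index],
                  scenario$n_disease_snps))
}

#' Simulate one (replicate, gene) dataset of a scenario
#'
#' The gene's haplotype pool and disease-SNP choice are fixed across
#' replicates; samples vary by replicate.  Null genes use
#' `rr1 = rr2 = 1`.
#'
#' @param scenario a [sim_scenario()].
#' @param replicate replicate number.
#' @param gene_index gene number.
#' @return List: `G`, `y`, `gene_id`, `replicate`, `is_causal`,
#'   `disease_snps`.
#' @export
simulate_dataset <- function(scenario, replicate, gene_index) {
  .assert(gene_index >= 1 && gene_index <= scenario$n_genes,
          "gene_index out of range")
  is_causal <- gene_index <= scenario$n_causal
  pool <- build_haplotype_pool(
    d = scenario$snps_per_gene[gene_index], block_size = scenario$block_size,
    rho = scenario$rho, pool_size = scenario$pool_size,
    seed = .derive_seed(scenario$seed, "pool", gene_index),
    maf_range = scenario$maf_range)
  dsnps <- .gene_disease_snps(scenario, gene_index)
  model <- if (is_causal)
    disease_model(dsnps, f0 = scenario$f0, rr1 = scenario$rr1,
                  rr2 = scenario$rr2)
  else disease_model(dsnps, f0 = scenario$f0, rr1 = 1, rr2 = 1)
  cc <- sample_case_control(pool, model, scenario$n_cases,
                            scenario$n_controls,
                            seed = .derive_seed(scenario$seed, "data",
                                                replicate, gene_index))
  list(G = cc$G, y = cc$y, gene_id = sprintf("gene%d", gene_index),
       replicate = replicate, is_causal = is_causal, disease_snps = dsnps)
}

#' Materialize every dataset of a scenario
#'
#' Convenience wrapper returning the full list of simulated datasets in
#' plan order; intended for desk-scale scenarios (use
#' [simulate_dataset()] with [scenario_plan()] to stream larger designs).
#'
#' @param scenario a [sim_scenario()].
#' @return List of [simulate_dataset()] results.
#' @export
generate_scenario <- function(scenario) {
  plan <- scenario_plan(scenario)
  lapply(seq_len(nrow(plan)), function(i)
    simulate_dataset(scenario, plan$replicate[i], plan$gene_index[i]))
}
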