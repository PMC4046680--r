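# scpca

Supervised categorical principal component analysis for gene- and
pathway-based association testing of case-control SNP data.

## The problem

Genome-wide association studies test one SNP at a time, which misses
genes and pathways whose variants each contribute only a weak signal.
Aggregated (SNP-set) testing compresses a set's genotypes into one
combined signal and tests that signal against the phenotype.  The usual
compressors bake in a genetic model: standard PCA on 0/1/2 allele
counts assumes risk proportional to allele count (additive), and
logistic PCA on binarized genotypes assumes a dominant or recessive
model.  `scpca` treats the three genotypes {0, 1, 2} as unordered
categories, so no relationship between heterozygote and homozygote
effects is imposed.

## The method

Genotype cell (i, j) is a 3-category multinomial observation with
category 0 as reference and natural parameters

    theta^k_ij = u_i' v^k_j + mu^k_j,   k = 1, 2;   theta^0 = 0,

where the scores `u_i` are shared across categories and the stacked
loading matrix `(V^1; V^2)` has orthonormal columns.  This multinomial
exponential-family PCA ("categorical PCA", CPCA) is fitted by
alternating damped Newton sweeps over scores, loadings and offsets with
QR re-orthonormalization, under random restarts (the likelihood is
non-concave).

For a SNP set S, the supervised layer screens each SNP by univariate
logistic regression, forms 20 nested candidate subsets at the
percentiles of the screening p-values, extracts each subset's first
principal component, and computes the Wald t of the phenotype on that
score.  The set statistic

    M = the signed t with maximal |t| across candidate subsets

is calibrated by a permutation null (phenotypes redrawn Bernoulli at
the disease prevalence, the whole screening/selection pipeline re-run),
giving an empirical p-value per set; Benjamini-Hochberg adjustment
controls the FDR across sets.  Standard-PCA (SPCA) and logistic-PCA
(SLPCA) comparison arms share the same supervised layer via
`method = "pca"` / `"lpca"`.

A block-correlated haplotype simulator with penetrance-based disease
models (per-SNP relative risks rr1/rr2 on a baseline penetrance f0,
multiplicative across causal SNPs) supports power and ROC studies; see
the methods vignette (`vignettes/scpca-methods.Rmd`) for the model,
numerical choices and limitations.

## Worked example

One causal gene (3 disease SNPs at relative risks 1.5/1.6, baseline
penetrance 0.05) and two null genes, 150 cases + 150 controls:

```r
library(scpca)

pool1 <- build_haplotype_pool(20, block_size = 10, rho = 0.7,
                              pool_size = 4000, seed = 11,
                              maf_range = c(0.1, 0.4))
model <- disease_model(causal_snps = c(3, 9, 15), f0 = 0.05,
                       rr1 = 1.5, rr2 = 1.6)
cc <- sample_case_control(pool1, model, n_cases = 150, n_controls = 150,
                          seed = 12)

null_geno <- function(seed) {
  p <- build_haplotype_pool(20, block_size = 10, rho = 0.7,
                            pool_size = 4000, seed = seed)
  H <- p$haplotypes
  set.seed(seed + 1)
  H[sample.int(nrow(H), 300, TRUE), ] + H[sample.int(nrow(H), 300, TRUE), ]
}
G <- cbind(cc$G$values, null_geno(21), null_geno(31))
colnames(G) <- paste0("snp", seq_len(60))

sets <- list(snp_set("gene1", 1:20), snp_set("gene2", 21:40),
             snp_set("gene3", 41:60))
cfg <- fit_config(n_restarts = 1, max_iterations = 25, tolerance = 1e-2,
                  batched = TRUE)
res <- run_snpset_analysis(G, cc$y, sets, method = "cpca", B = 199,
                           config = cfg, seed = 7)
print(res)
#> scpca_assoc: 3 set(s), method cpca, B = 199 permutations
#>  set_id n_snps n_snps_optimal        M p_value p_adjusted
#>   gene1     20             20 4.203380   0.005      0.015
#>   gene2     20              1 2.735962   0.180      0.270
#>   gene3     20              1 1.596086   0.825      0.825
```

The causal gene's best subset reaches |t| = 4.2, beating all 199
permutation statistics (empirical p = (1 + 0)/(199 + 1) = 0.005) and
staying significant after BH adjustment; the null genes do not.
`n_snps_optimal` is the size of the candidate subset whose first PC was
most trait-associated.

Input helpers read tab-separated genotype matrices or VCF
(`read_genotypes`), phenotype TSVs (`read_phenotype`), BED-like gene
intervals (`read_gene_intervals`, SNPs assigned within an inclusive
+/- 5 kb window by `map_snps_to_genes`) and MSigDB-style GMT pathway
files (`read_gmt_pathways`, sets larger than 250 genes dropped;
`pathway_snpsets` forms deduplicated pathway-level SNP sets).  A thin
command-line wrapper with `fit` / `test` / `simulate` / `evaluate`
subcommands is installed at `inst/cli/scpca.R`.

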