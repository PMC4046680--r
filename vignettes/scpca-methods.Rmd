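---
title: "Supervised categorical PCA for SNP-set association: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised categorical PCA for SNP-set association: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpca)
```

## The problem

Single-marker association tests in case-control studies miss genes and
pathways whose constituent SNPs each carry only a weak signal.
Aggregated association analysis tests a whole SNP set at once: the set's
genotypes are compressed into one combined signal, and that signal is
tested against the phenotype with a single degree of freedom.

Principal-component approaches build the combined signal as the first
principal component of the set's genotype matrix.  Standard PCA treats
the 0/1/2 minor-allele count as a Gaussian variable, which silently
assumes the risk of a genotype is proportional to its allele count (an
additive model).  Logistic PCA first collapses 0/1/2 to a binary
carrier indicator, which hard-codes a dominant (or recessive) model.
`scpca` instead treats the three genotypes as unordered categories:
each genotype cell is a 3-category multinomial observation, and the
low-rank structure lives on the natural-parameter (log-odds) scale.
No functional form ties the heterozygote effect to the homozygote
effect.

## The categorical PCA model

Write \(x_{ij} \in \{0, 1, 2\}\) for the genotype of sample \(i\) at SNP
\(j\).  With category 0 as the reference, the model places a shared
low-rank structure on the non-reference log-odds:

\[
\theta^k_{ij} = u_i^\top v^k_j + \mu^k_j, \qquad k \in \{1, 2\},
\qquad \theta^0_{ij} \equiv 0 ,
\]

\[
P(x_{ij} = k) = \frac{e^{\theta^k_{ij}}}{1 + e^{\theta^1_{ij}} + e^{\theta^2_{ij}}} .
\]

Here \(u_i \in \mathbb{R}^l\) are per-sample scores shared across
categories, \(v^k_j \in \mathbb{R}^l\) are per-SNP, per-category
loadings, and \(\mu^k_j\) are per-SNP offsets.  The stacked loading
matrix \((V^1; V^2)\) is constrained to have orthonormal columns, which
fixes the scale/rotation gauge without restricting the attainable
natural parameters.

Two modeling choices deserve comment:

* **Reference-category parameterization.**  A softmax over three free
  natural parameters per cell is not identifiable (adding a constant to
  all three changes nothing).  Fixing \(\theta^0 \equiv 0\) removes the
  gauge freedom, reduces exactly to Bernoulli (logistic) PCA when one
  category is absent, and leaves the attainable likelihood unchanged.
* **Clipped natural parameters.**  \(\theta\) is clipped at
  \(|\theta| \le 30\) before exponentiation.  Without the clip the
  likelihood of a separable cell diverges to a supremum at
  \(\theta = \pm\infty\); the clip keeps every quantity finite while
  changing probabilities by at most \(\approx 10^{-13}\).  The clipped
  form is the objective that is optimized and reported.

The Bernoulli reduction (`fit_lpca_scores`) is the same machinery with
one non-reference category after binarizing genotypes; the default
dominant coding maps any minor-allele carrier to 1, and
`coding = "recessive"` maps only minor homozygotes to 1.  Which coding
the classical logistic-PCA analyses used is not recoverable from the
literature we follow; dominant is the documented default assumption.

## Fitting: alternating damped Newton with QR re-orthonormalization

The log-likelihood is concave in each block (scores; one SNP's loading
rows; one SNP's offsets) with the others fixed, but not jointly.
`fit_cpca` cycles:

1. a damped Newton sweep over score rows (each row solved independently
   with its exact per-row gradient and Fisher information);
2. QR re-orthonormalization of the stacked loadings with the scores
   back-rotated by \(R^\top\), so every \(\theta\) — and hence the
   likelihood — is unchanged to machine precision (without the
   back-rotation the likelihood can decrease);
3. a damped Newton sweep over each SNP's loading-row pair;
4. a damped Newton sweep over each SNP's offset pair,

until the relative likelihood change drops below `tolerance` or
`max_iterations` is reached.  Several numerical devices matter in
practice:

* **Step-halving.**  Each Newton step is halved (up to `damping` = 20
  times) until the block's likelihood does not decrease; the
  per-iteration likelihood trace is therefore non-decreasing by
  construction, and the package asserts this on every fit.
* **Step expansion.**  On separable data the optimum sits on a ridge at
  the clip boundary and plain Newton creeps toward it logarithmically.
  Inside `fit_cpca` an accepted full step is greedily doubled while the
  likelihood keeps improving, which traverses such ridges in
  \(O(\log)\) sweeps.  The exported `newton_step_*` operations keep the
  plain step-halving contract.
* **Joint extrapolation.**  Alternating updates zigzag on bilinear
  ridges; after each cycle a heavy-ball-style candidate
  \(\beta_t + \alpha(\beta_t - \beta_{t-1})\), \(\alpha \in \{1, 2,
  \dots, 16\}\), over all parameters jointly is evaluated and accepted
  only if it improves.
* **Step caps and frozen directions.**  Newton steps are capped so no
  natural parameter moves by more than twice the clip in one step, and
  any category whose block gradient vanishes (typically a category
  absent from the data) is held fixed rather than dragged along its
  flat direction.
* **Singular curvature.**  If a block's information matrix is singular,
  a gradient step (still line-searched) is substituted; `newton_step_*`
  warn when this happens, and fitted models record the count.

**Initialization and restarts.**  The objective is non-concave, so the
fit is restarted `n_restarts` times and the best final likelihood wins.
The first restart starts from per-SNP empirical log-odds offsets with
small (\(\sigma = 0.1\)) random scores and loadings; subsequent
restarts cycle through larger initialization scales
(\(0.1 \times 2^{0..4}\)) with random offsets.  The small-scale start
alone proved unable to leave its basin on small separable datasets —
every restart found the same poor optimum — while the scale ladder
matches or beats a multi-start quasi-Newton maximizer of the same
objective.  `fit_config(refine = TRUE)` adds a coordinate-flip local
search around the best restart (warm refits with one score row flipped
or zeroed, or one loading/offset row flipped, accepted only on
improvement).  Nearly tied local optima of this likelihood differ in
which cells the rank-\(l\) fit sacrifices, and these sign moves travel
between them when random restarts rarely do; the search costs
\(O(n + d)\) refits per round and is off by default.

**Batched mode.**  `fit_config(batched = TRUE)` replaces per-block line
searches by batched sweeps: all block deltas are computed, applied
together, and the total likelihood is verified once, halving all steps
jointly on the rare decrease; gradient and likelihood passes are fused.
This is several-fold faster and still exactly monotone in the total
likelihood, at the cost of a slightly less greedy trajectory.  The
permutation pipeline uses it; interactive fits default to the per-row
mode.

**First-PC sign.**  PCA signs are arbitrary; the first component is
negated if its correlation with per-sample minor-allele counts is
negative.  Downstream statistics are two-sided, so this is purely a
stabilization of output across runs.

## The supervised association layer

The unsupervised first PC explains genotype variation, not the trait;
irrelevant SNPs dilute it.  For a SNP set \(S\), `run_snpset_analysis`
therefore:

1. screens each SNP by a logistic regression of the phenotype on its
   numeric 0/1/2 coding (Wald p-value; constant SNPs get \(p = 1\);
   separation triggers a Firth-penalized refit so every p-value is
   finite);
2. forms nested candidate subsets at the nearest-rank 5th, 10th, ...,
   100th percentiles of those p-values (`v = 20` thresholds; membership
   by \(p \le\) threshold, so the smallest subset is never empty and
   the largest is all of \(S\); tied thresholds produce duplicate
   subsets, which are collapsed and fitted once);
3. extracts each candidate subset's first PC (CPCA, PCA or LPCA) and
   computes the Wald \(t\) of the phenotype on that score;
4. takes as set statistic \(M\) the signed \(t\) of maximal absolute
   value across candidate subsets, breaking exact ties toward the
   smaller subset (parsimony; ties are measure-zero in practice);
5. calibrates \(M\) by a permutation null: phenotypes are redrawn
   i.i.d. Bernoulli at the disease prevalence and steps 1-4 are
   repeated on the unchanged genotypes \(B\) times.  The empirical
   p-value uses the add-one convention
   \(p = (1 + \#\{|M_b| \ge |M_{\mathrm{obs}}|\})/(B + 1)\), which is
   never zero;
6. adjusts across sets by Benjamini-Hochberg (`stats::p.adjust`).

Design points that were genuinely open:

* **Null pooling.**  The null sample is generated per SNP set by
  default; `pool_null = TRUE` pools null \(M\) values across all sets
  instead.  Both readings of "pooled together as a random sample from
  the null distribution" are defensible; per-set is the default because
  \(M\)'s null scale depends on the set's size and LD structure.
* **Prevalence.**  True population prevalence is unknowable from
  case-control data; the default is the observed case fraction,
  overridable via `prevalence`.
* **Sidedness.**  \(M\) keeps its sign for reporting, but significance
  is two-sided on \(|M|\).
* **Permutation count.**  \(B = 999\) is the default for real analyses;
  the studies below use smaller \(B\) (99 or 33), which only coarsens
  the p-value grid.
* **Screening coding.**  Step 1 uses the numeric 0/1/2 coding (the
  categorical alternative would spend an extra degree of freedom per
  SNP at the screening stage, where ranking is all that matters).

Because the PC extraction depends only on the genotypes — never on the
(permuted) phenotype — the pipeline memoises subset scores across
permutation rounds and warm-starts every candidate subset from the
restriction of the full-set fit.  Both devices change nothing
statistically; they only remove redundant refits.

## The genotype simulator

The simulator emulates a haplotype-resampling design without any
external reference data:

* **Haplotype pool.**  Haplotypes come from a block-wise
  latent-Gaussian threshold model: within a block of `block_size`
  (default 10) SNPs, latent normals share correlation `rho` (default
  0.7) and are thresholded at each SNP's target minor-allele frequency
  (drawn from `maf_range`, default \(U(0.05, 0.5)\)); blocks are
  independent, and columns are oriented so the 1 allele is the minor
  allele.
* **Genotypes** are sums of two haplotypes drawn at random from the
  pool, hence always in \{0, 1, 2\} with the pool's LD structure.
* **Disease model.**  Each causal SNP multiplies a baseline penetrance
  \(f_0\) (default 0.05; exposed as a parameter since no canonical
  value exists) by 1, \(rr_1\) or \(rr_2\) according to its genotype;
  factors combine multiplicatively across causal SNPs and the product
  is capped at 1.  \(rr_1 = rr_2 = 1\) is the null model.  Setting
  \(rr_2\) only slightly above \(rr_1\) — e.g. (1.2, 1.3), (1.3, 1.4),
  (1.5, 1.6) — deliberately breaks the additive relationship
  \(rr_2 = rr_1^2\), which is the regime where a categorical model has
  something to offer.
* **Sampling** is by rejection: an individual is affected with
  probability equal to their penetrance, and sampling continues until
  the case and control quotas are met, so controls are unaffected
  (not population) controls.
* **Scenarios** describe a gene-based power study: `n_genes` genes
  (default 50, with 11-175 SNPs each), the first `n_causal` (default 5)
  carrying 3 randomly chosen disease SNPs, balanced
  `n_cases`/`n_controls` (default 500/500) over `n_replicates` (default
  100).  Every dataset's random stream derives deterministically from
  the scenario seed, the replicate and the gene, so any single dataset
  can be regenerated in isolation.

What the simulator does **not** emulate: fine-scale recombination-rate
variation (blocks have a single exchangeable correlation), rare-variant
site-frequency spectra, population structure, genotyping error, or the
X chromosome.  Passing tests on simulated data therefore demonstrate
correct behavior under idealized LD and penetrance models, not
performance on any particular real cohort.

## Study sizes used by the test suite

The packaged checks run the full pipeline at desk scale, chosen so the
whole suite completes on one CPU in well under half an hour:

* *Solver-vs-oracle*: 20 random instances with \(n \le 8\), \(d \le 3\),
  compared against a multi-start BFGS maximizer of the same clipped
  likelihood.
* *Type-I calibration*: 200 null gene datasets, 100 cases + 100
  controls, 20 SNPs, \(B = 99\); the rejection rate at \(\alpha = 0.05\)
  is checked against the exact binomial band [0.024, 0.088] and the
  p-values against uniformity.
* *Power ordering*: 5 causal genes \(\times\) 50 replicates at
  \((rr_1, rr_2) = (1.2, 1.3)\) vs \((1.5, 1.6)\); genes of 20 SNPs
  (two LD blocks), 3 disease SNPs, 100 cases + 100 controls,
  \(B = 25\), all three methods.  Gene sizes of around a dozen SNPs or
  fewer put the categorical first PC in a separation-dominated regime
  (a single latent score can nearly saturate that few cells, producing
  heavy-tailed scores); 20 SNPs restores well-behaved scores while
  staying tractable.
* *Probability recovery*: data simulated from a known rank-1
  natural-parameter model at \(n \in \{100, 300, 1000\}\), \(d = 20\);
  the fitted cell-probability RMSE must decrease with \(n\).

The pipeline-scale solver configuration for these studies is
`fit_config(n_restarts = 1, max_iterations = 25, tolerance = 1e-2,
batched = TRUE)`: permutation validity needs only a deterministic map
from data to statistic, and score directions stabilize long before the
likelihood's last digits.

## Known limitations

* With a single latent dimension the method tests one combined signal
  per set; multiple-component extensions are not implemented.
* On very small SNP sets the categorical first PC is dominated by
  separation and its logistic \(t\) loses power relative to PCA/LPCA;
  this is intrinsic to unregularized exponential-family PCA at that
  scale, not specific to this implementation.
* The likelihood is non-concave; all guarantees are per-restart
  monotonicity and best-of-restarts selection, not global optimality
  (tiny separable instances can hold many near-tied optima whose
  fitted probabilities differ).
* Covariate adjustment, family designs and quantitative traits are out
  of scope.
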