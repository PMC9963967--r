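# isletmir

Genetic analysis of small-RNA expression in bulk tissue, built for studies
like miRNA profiling of human pancreatic islets in the context of type 2
diabetes. Donor-level data for such studies are access restricted, so the
package pairs every analysis stage with a ground-truth synthetic-data
generator: the whole pipeline runs end-to-end on simulated cohorts, and its
statistical properties (parameter recovery, calibration, error control) are
verified against that recorded truth.

## What it computes

* **Heritability and cis/trans architecture.** SNP-based heritability
  h<sup>2</sup><sub>g</sub> by REML on a standardized-dosage GRM
  (K = ZZ&prime;/M), then a two-GRM decomposition
  y = W&alpha; + u<sub>c</sub> + u<sub>t</sub> + &epsilon;,
  u<sub>c</sub> ~ N(0, &sigma;²<sub>cis</sub>K<sub>cis</sub>),
  u<sub>t</sub> ~ N(0, &sigma;²<sub>trans</sub>K<sub>trans</sub>), with the
  cis window (default ±250 kb, alternate ±20 Mb) anchored on the mature
  miRNA transcript or the mRNA TSS. Class comparisons: chi-squared on
  heritable fractions, Mann–Whitney U on h<sub>trans</sub>.
* **eQTL mapping.** OLS single-variant scans on rank-normalized expression
  with covariates, pooled Benjamini–Hochberg FDR, genotype×miRNA
  interaction models, Wald-ratio Mendelian randomization and Sobel
  mediation, cross-study effect concordance with allele harmonization.
* **Colocalization and credible sets.** Wakefield approximate Bayes
  factors, PP0–PP4 posteriors under a single-causal-variant model
  (priors p1 = p2 = 1e-4, p12 = 1e-5, all sums in log space), 99% credible
  sets, and credible-SNP overlap with mature-miRNA and predicted
  target-site intervals under an expression filter.
* **Differential expression.** Median-of-ratios size factors, per-feature
  NB Wald GLMs against sex/age/BMI/T2D/polygenic-score phenotypes,
  fixed-effect inverse-variance meta-analysis across strata, calls at
  FDR ≤ 5% and |log2FC| ≥ 1.
* **Cell-fraction sensitivity.** Two-cell-type (alpha/beta) deconvolution
  by non-negative least squares on sorted-cell signatures, and re-running
  any scan with the beta-cell fraction as a covariate to quantify
  cell-type-heterogeneity confounding.

See `vignettes/methods.Rmd` for the models, assumptions, numerical choices
and limitations, and `analysis/01...06` for the worked workflow (each
script narrates one stage and writes its tables under `results/`).

## Worked example

Simulate a cohort with known architecture, decompose one miRNA's expression
variance, and colocalize a simulated GWAS pair:

```r
library(isletmir)
cfg <- sim_config(n_samples = 200, n_variants = 500, h2_cis = 0.2,
                  h2_trans = 0.4, seed = 7)
geno  <- simulate_genotypes(cfg)
feats <- simulate_features(cfg, n_features = 1)
sim   <- simulate_expression(geno, feats, cfg)
y     <- transform_expression(sim$latent)[1, ]
part  <- partition_cis_trans(geno$variants, feats[1, ], 250000)
fit   <- fit_two_component(y, compute_grm(geno, part$cis),
                           compute_grm(geno, part$trans),
                           feature_id = feats$feature_id[1])
fit[, c("feature_id", "h_cis", "h_trans", "hg2", "converged")]
#>   feature_id     h_cis   h_trans       hg2 converged
#> 1     mir001 0.2068681 0.3267154 0.5335835      TRUE

gw <- simulate_gwas_pair(100, shared = TRUE, n1 = 5000, n2 = 5000, seed = 7)
cl <- coloc_abf(gw$trait1, gw$trait2)
cl
#> coloc_result over 100 SNPs
#> PP0 PP1 PP2 PP3 PP4
#>   0   0   0   0   1
cs <- credible_set_99(cl$labf1)
cs$size                          # 1 variant
gw$truth$causal1 %in% cs$variants  # TRUE
```

The decomposition estimates (0.21 cis, 0.33 trans) recover the generative
truth (0.20, 0.40) up to single-replicate sampling noise — averages over
replicates land within a few hundredths (see the acceptance suite). The
shared-causal GWAS pair is called as a colocalization (PP4 ≈ 1) and the 99%
credible set is the causal SNP alone.

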