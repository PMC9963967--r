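test_that("generators are pure functions of (config, seed)", {
  cfg <- sim_config(n_samples = 30, n_variants = 40, seed = 7)
  expect_identical(simulate_genotypes(cfg)$dosage, simulate_genotypes(cfg)$dosage)
  feats <- simulate_features(cfg, 3, genotypes = simulate_genotypes(cfg))
  e1 <- simulate_expression(simulate_genotypes(cfg), feats, cfg)
  e2 <- simulate_expression(simulate_genotypes(cfg), feats, cfg)
  expect_identical(e1$counts, e2$counts)
  g1 <- simulate_gwas_pair(20, shared = TRUE, seed = 5)
  g2 <- simulate_gwas_pair(20, shared = TRUE, seed = 5)
  expect_identical(g1$trait1$beta, g2$trait1$beta)
  sig <- simulate_signatures(seed = 2)
  fr <- cbind(a = c(0.2, 0.8), b = c(0.8, 0.2))
  expect_identical(simulate_mixture(sig, fr, seed = 3)$counts,
                   simulate_mixture(sig, fr, seed = 3)$counts)
})

test_that("dosages follow Binomial(2, f)", {
  cfg <- sim_config(n_samples = 10000, n_variants = 1, maf_range = c(0.5, 0.5),
                    seed = 11)
  d <- simulate_genotypes(cfg)$dosage
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(d) - 1.0), 3 * se)
})

test_that("LD blocks with zero flip probability give r^2 = 1", {
  cfg <- sim_config(n_samples = 50, n_variants = 6, ld_flip_prob = 0, seed = 3)
  gm <- simulate_genotypes(cfg)
  for (j in 2:6)
    expect_equal(ld_r2(gm, gm$variants$variant_id[j - 1],
                       gm$variants$variant_id[j]), 1.0)
})

test_that("realized variance fractions hit targets exactly", {
  cfg <- sim_config(n_samples = 80, n_variants = 200, h2_cis = 0.25,
                    h2_trans = 0.35, seed = 21)
  geno <- simulate_genotypes(cfg)
  feats <- simulate_features(cfg, 5)
  sim <- simulate_expression(geno, feats, cfg)
  for (tr in sim$truth$features) {
    expect_lt(abs(tr$h2_cis_realized - 0.25), 0.02)
    expect_lt(abs(tr$h2_trans_realized - 0.35), 0.02)
  }
  # and the latent trait has unit variance by construction
  expect_equal(unname(apply(sim$latent, 1, var)), rep(1, 5), tolerance = 1e-8)
})

test_that("expression without genetic effects is null against every variant", {
  cfg <- sim_config(n_samples = 200, n_variants = 500, h2_cis = 0,
                    h2_trans = 0, seed = 31)
  geno <- simulate_genotypes(cfg)
  feats <- simulate_features(cfg, 1)
  sim <- simulate_expression(geno, feats, cfg)
  y <- sim$latent[1, ]
  pv <- apply(geno$dosage, 2, function(g) {
    if (sd(g) == 0) return(NA_real_)
    summary(lm(y ~ g))$coefficients["g", 4]
  })
  ks <- suppressWarnings(ks.test(pv[!is.na(pv)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NB counts approach Poisson as dispersion vanishes", {
  cfg <- sim_config(n_samples = 2000, n_variants = 50, h2_cis = 0,
                    h2_trans = 0, nb_dispersion = 1e-6, mean_expression = 100,
                    libsize_sd = 0, seed = 41)
  geno <- simulate_genotypes(cfg)
  feats <- simulate_features(cfg, 1)
  sim <- simulate_expression(geno, feats, cfg)
  counts <- sim$counts[1, ]
  # condition on the latent mean: var(counts)/mean should be ~1 (Poisson);
  # remove the latent-driven variance analytically
  mu <- 100 * exp(sim$latent[1, ] - mean(sim$latent[1, ]))
  resid_var <- var(counts - mu) # leftover ~ Poisson noise around mu
  expect_lt(abs(resid_var / mean(mu) - 1), 0.1)
})

test_that("null GWAS z-scores are standard normal in magnitude", {
  g <- simulate_gwas_pair(1000, shared = TRUE, effect_size = 0, seed = 13)
  for (tr in list(g$trait1, g$trait2)) {
    mz <- mean(abs(tr$beta / tr$se))
    expect_lt(abs(mz - sqrt(2 / pi)), 0.05)
  }
})

test_that("gwas pair respects the shared flag and input guards", {
  gs <- simulate_gwas_pair(50, shared = TRUE, seed = 2)
  expect_identical(gs$truth$causal1, gs$truth$causal2)
  gd <- simulate_gwas_pair(50, shared = FALSE, seed = 2)
  expect_false(gd$truth$causal1 == gd$truth$causal2)
  expect_error(simulate_gwas_pair(1, shared = FALSE, seed = 1), "2 SNPs")
})

test_that("mixtures are linear in the fractions", {
  sig <- cbind(alpha = c(100, 0), beta = c(0, 100))
  rownames(sig) <- c("g1", "g2")
  # degenerate mixture reproduces the pure signature
  m1 <- simulate_mixture(sig, matrix(c(1, 0), 50, 2, byrow = TRUE),
                         phi = 0, seed = 5)
  expect_lt(abs(mean(m1$counts["g1", ]) - 100) / 100, 0.05)
  expect_true(all(m1$counts["g2", ] == 0))
  half <- simulate_mixture(sig, matrix(0.5, 200, 2), phi = 0, seed = 6)
  expect_lt(abs(mean(half$counts["g1", ]) - 50), 3 * sqrt(50 / 200))
  expect_lt(abs(mean(half$counts["g2", ]) - 50), 3 * sqrt(50 / 200))
  expect_error(simulate_mixture(sig, cbind(-0.1, 1.1), seed = 1), ">= 0")
  expect_error(simulate_mixture(sig, cbind(0.5, 0.4), seed = 1), "sum to 1")
})

test_that("config guards reject impossible settings", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(h2_cis = 0.6, h2_trans = 0.5), "sum")
  cfg <- sim_config(n_samples = 20, n_variants = 10, h2_cis = 0.3, seed = 1)
  geno <- simulate_genotypes(cfg)
  far <- data.frame(feature_id = "x", chrom = "chrZ", start = 100L, end = 200L,
                    strand = "+", biotype = "miRNA", confidence = "canonical")
  expect_error(simulate_expression(geno, far, cfg), "no cis variants")
})

test_that("DE count generator records its truth and honours the null", {
  d <- simulate_de_counts(30, n_features = 50, frac_alt = 0.2, lfc = 2, seed = 3)
  expect_equal(sum(d$truth$log2fc_true != 0), 10)
  expect_equal(sort(unique(abs(d$truth$log2fc_true))), c(0, 2))
  expect_equal(sum(d$phenotype), 15)
  d0 <- simulate_de_counts(30, n_features = 50, frac_alt = 0, seed = 3)
  expect_true(all(d0$truth$log2fc_true == 0))
})
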