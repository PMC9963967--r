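scan_one <- function(y, g, covariates = NULL) {
  gm <- structure(list(
    dosage = matrix(g, ncol = 1, dimnames = list(names(y), "v1")),
    variants = data.frame(variant_id = "v1", chrom = "chr1", pos = 1L,
                          ref = "A", alt = "G", maf = mean(g) / 2)),
    class = "genotype_matrix")
  expr <- matrix(y, nrow = 1, dimnames = list("f1", names(y)))
  assoc_scan(expr, gm, covariates = covariates,
             pairs = data.frame(feature_id = "f1", variant_id = "v1"))
}

test_that("a perfect linear relationship is recovered exactly", {
  set.seed(1)
  g <- rbinom(40, 2, 0.4)
  res <- scan_one(0.5 * g, g)
  expect_equal(res$beta, 0.5, tolerance = 1e-12)
  expect_lt(res$p, 1e-200)
})

test_that("scan effect sizes obey shift and allele-flip symmetries", {
  set.seed(2)
  g <- rbinom(50, 2, 0.3)
  y <- 0.3 * g + rnorm(50)
  b0 <- scan_one(y, g)$beta
  expect_equal(scan_one(y + 100, g)$beta, b0, tolerance = 1e-10)
  expect_equal(scan_one(y, 2 - g)$beta, -b0, tolerance = 1e-10)
})

test_that("permuted expression gives uniform p-values", {
  cfg <- sim_config(n_samples = 57, n_variants = 1000, seed = 77)
  geno <- simulate_genotypes(cfg)
  set.seed(77)
  y <- sample(rnorm(57))
  expr <- matrix(y, 1, dimnames = list("f1", rownames(geno$dosage)))
  pairs <- data.frame(feature_id = "f1",
                      variant_id = geno$variants$variant_id)
  res <- assoc_scan(expr, geno, pairs = pairs)
  ks <- suppressWarnings(ks.test(res$p[!is.na(res$p)], "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a cis effect explaining 25% of variance is detectable at n = 57", {
  hits <- sapply(1:400, function(r) {
    set.seed(r)
    g <- rbinom(57, 2, 0.3)
    while (sd(g) == 0) g <- rbinom(57, 2, 0.3)
    gs <- (g - mean(g)) / sd(g)
    y <- sqrt(0.25) * gs + sqrt(0.75) * rnorm(57)
    scan_one(y, g)$p < 1e-3
  })
  # analytic oracle: noncentral t with ncp = sqrt(n R^2 / (1 - R^2))
  crit <- qt(1 - 5e-4, 55)
  ncp <- sqrt(57 * 0.25 / 0.75)
  power <- 1 - pt(crit, 55, ncp) + pt(-crit, 55, ncp)
  se <- sqrt(power * (1 - power) / 400)
  expect_gt(mean(hits), power - 3 * se)
  expect_lt(mean(hits), power + 3 * se)
})

test_that("collinear covariates are rejected by name", {
  set.seed(3)
  g <- rbinom(30, 2, 0.4)
  cv <- cbind(a = rnorm(30))
  cv <- cbind(cv, b = 2 * cv[, "a"])
  expect_error(scan_one(rnorm(30), g, covariates = cv), "collinear")
})

test_that("BH q-values match the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- rep(0.03, 5)
  expect_equal(bh_fdr(p), p)
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH controls the FDR on a strong-signal mixture", {
  fdp <- sapply(1:200, function(r) {
    set.seed(r)
    alt <- rep(c(TRUE, FALSE), c(20, 180))
    z <- rnorm(200, mean = ifelse(alt, 4, 0))
    p <- 2 * pnorm(-abs(z))
    q <- bh_fdr(p)
    called <- q <= 0.05
    if (!any(called)) 0 else mean(!alt[called])
  })
  expect_lte(mean(fdp), 0.07)
})

test_that("interaction model recovers an exact product coefficient", {
  set.seed(4)
  g <- rbinom(60, 2, 0.4)
  m <- rnorm(60)
  y <- 1 + g + m + 2 * g * m
  res <- suppressWarnings(interaction_test(y, g, m))  # exact fit warns in lm
  expect_equal(res$beta, 2, tolerance = 1e-10)
  expect_error(interaction_test(rnorm(30), rep(1, 30), rnorm(30)), "constant")
  expect_warning(interaction_test(rnorm(15), rbinom(15, 2, 0.5), rnorm(15)),
                 "fragile")
})

test_that("interaction power is adequate at n = 100 for a 20% component", {
  hits <- sapply(1:100, function(r) {
    set.seed(10000 + r)
    g <- rbinom(100, 2, 0.3)
    m <- rnorm(100)
    gm <- g * m
    gm <- (gm - mean(gm)) / sd(gm)
    y <- sqrt(0.2) * gm + sqrt(0.8) * rnorm(100)
    interaction_test(y, g, m)$p < 0.05
  })
  expect_gte(mean(hits), 0.7)
})

test_that("Wald-ratio MR matches the delta-method formula", {
  r <- mr_wald(0.5, 0.05, 0.25, 0.05)
  expect_equal(r$beta_wald, 0.5)
  expect_equal(r$se_wald, sqrt(0.01 + 0.0025), tolerance = 1e-12)
  expect_equal(mr_wald(0.5, 0.05, 0, 0.05)$beta_wald, 0)
  expect_error(mr_wald(0, 0.1, 0.3, 0.1), "zero")
  expect_warning(mr_wald(0.1, 0.2, 0.3, 0.1), "weak instrument")
})

test_that("Sobel mediation matches the product-of-coefficients formula", {
  # construct data whose fitted a and b are immaterial; check against a
  # direct refit with lm
  set.seed(6)
  x <- rnorm(80); med <- 0.5 * x + rnorm(80); y <- 0.4 * med + rnorm(80)
  r <- mediation_sobel(x, med, y)
  a_ref <- summary(lm(med ~ x))$coefficients["x", 1:2]
  b_ref <- summary(lm(y ~ x + med))$coefficients["med", 1:2]
  expect_equal(r$ab, unname(a_ref[1] * b_ref[1]), tolerance = 1e-12)
  expect_equal(r$sobel_se,
               sqrt(b_ref[[1]]^2 * a_ref[[2]]^2 + a_ref[[1]]^2 * b_ref[[2]]^2),
               tolerance = 1e-12)
  # the worked numeric case: a = 0.5 (se 0.1), b = 0.4 (se 0.1)
  expect_equal(sqrt(0.4^2 * 0.1^2 + 0.5^2 * 0.1^2), sqrt(0.0041))
})

test_that("mediation effects center correctly under null and full mediation", {
  ab <- sapply(1:200, function(r) {
    set.seed(r)
    x <- rnorm(50); med <- rnorm(50); y <- 0.5 * med + rnorm(50)
    mediation_sobel(x, med, y)$ab
  })
  expect_lt(abs(mean(ab)), 0.02)
  direct <- sapply(1:200, function(r) {
    set.seed(r)
    x <- rnorm(50); med <- 0.8 * x + rnorm(50); y <- 0.8 * med + rnorm(50)
    mediation_sobel(x, med, y)$direct
  })
  expect_lt(abs(mean(direct)), 0.05)
})

test_that("effect concordance reproduces hand-computed Spearman values", {
  mk <- function(beta) data.frame(variant_id = c("v1", "v2", "v3"),
                                  feature_id = "f", beta = beta)
  expect_equal(effect_concordance(mk(c(1, 2, 3)), mk(c(10, 20, 30)))$rho, 1)
  expect_equal(effect_concordance(mk(c(1, 2, 3)), mk(c(-1, -2, -3)))$rho, -1)
  expect_equal(effect_concordance(mk(c(1, 2, 3)), mk(c(3, 1, 2)))$rho, -0.5)
  expect_error(effect_concordance(mk(c(1, 2, 3)),
                                  data.frame(variant_id = "x", feature_id = "y",
                                             beta = 1)), "overlap")
})

test_that("allele harmonization flips swapped alleles and drops ambiguous pairs", {
  a <- data.frame(variant_id = c("v1", "v2", "v3", "v4"), feature_id = "f",
                  beta = c(1, 2, 3, 4), ref = c("A", "A", "A", "A"),
                  alt = c("G", "G", "G", "T"))
  b <- a
  b$beta <- c(1, -2, 3, 4)
  b$ref[2] <- "G"; b$alt[2] <- "A"  # swapped alleles: flip back
  r <- effect_concordance(a, b)
  expect_equal(r$n_pairs, 3)  # v4 is A/T strand-ambiguous, dropped
  expect_equal(r$rho, 1)      # after harmonization the betas agree in rank
})
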