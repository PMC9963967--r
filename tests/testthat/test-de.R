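test_that("size factors match the median-of-ratios hand cases", {
  m <- matrix(c(4, 10, 8, 20), 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  # sample2 = 2 x sample1: geometric-mean reference gives (1/sqrt2, sqrt2)
  expect_equal(size_factors(m), c(S1 = 1 / sqrt(2), S2 = sqrt(2)),
               tolerance = 1e-12)
  ident <- matrix(c(5, 9, 5, 9), 2, dimnames = list(c("a", "b"), c("S1", "S2")))
  expect_equal(unname(size_factors(ident)), c(1, 1))
  # features with a zero are excluded from the reference
  z <- rbind(m, c(0, 100))
  rownames(z) <- c("a", "b", "c")
  expect_equal(size_factors(z), size_factors(m))
  expect_error(size_factors(rbind(c(0, 1), c(1, 0))), "cannot normalize")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(12)
  m <- matrix(rnbinom(5 * 6, mu = 100, size = 5) + 1, nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("S", 1:6)))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("scaling one sample scales its factor proportionally", {
  set.seed(13)
  m <- matrix(rpois(5 * 4, 50) + 1, nrow = 5,
              dimnames = list(paste0("f", 1:5), paste0("S", 1:4)))
  f0 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 3
  f1 <- size_factors(m2)
  expect_equal(f1[[2]] / f0[[2]], 3 * (f1[[1]] / f0[[1]]), tolerance = 1e-10)
})

test_that("abundance filter applies the count-and-fraction rule", {
  m <- rbind(low = c(0, 0, 10), ok = c(6, 6, 0), all = c(1, 1, 1))
  colnames(m) <- paste0("S", 1:3)
  expect_setequal(abundance_filter(m, 0, 0.5), rownames(m))
  kept <- abundance_filter(m, min_count = 5, min_fraction = 0.5)
  expect_true("ok" %in% kept)
  expect_false("low" %in% kept)
})

test_that("NB Wald DE recovers an exact two-group fold change", {
  counts <- rbind(f1 = c(10, 10, 10, 20, 20, 20))
  colnames(counts) <- paste0("S", 1:6)
  res <- nb_wald_de(counts, c(0, 0, 0, 1, 1, 1), sf = rep(1, 6),
                    dispersion = 0.1)
  expect_equal(res$log2fc, 1, tolerance = 1e-6)
  # offset invariance: doubling all size factors changes nothing
  res2 <- nb_wald_de(counts, c(0, 0, 0, 1, 1, 1), sf = rep(2, 6),
                     dispersion = 0.1)
  expect_equal(res2$log2fc, res$log2fc, tolerance = 1e-8)
  expect_error(nb_wald_de(counts, rep(1, 6)), "constant")
})

test_that("NB Wald DE holds its type-I error under a permuted phenotype", {
  rej <- unlist(lapply(1:6, function(r) {
    d <- simulate_de_counts(63, n_features = 100, frac_alt = 0, seed = 100 + r)
    res <- nb_wald_de(d$counts, d$phenotype)
    res$p[!is.na(res$p)] < 0.05
  }))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.08)
})

test_that("inverse-variance meta-analysis matches the hand formula", {
  s <- function(fid, b, se) data.frame(feature_id = fid, log2fc = b, se = se,
                                       p = 0.5)
  m <- ivw_meta(list(s("f", 1, 1), s("f", 3, 1)))
  expect_equal(m$log2fc, 2)
  expect_equal(m$se, 1 / sqrt(2), tolerance = 1e-6)
  # single stratum is the identity
  one <- ivw_meta(list(s("f", 1.5, 0.3)))
  expect_equal(one$log2fc, 1.5)
  expect_equal(one$se, 0.3)
  # equal effects: estimate unchanged, se shrinks by sqrt(2)
  two <- ivw_meta(list(s("f", 1.5, 0.3), s("f", 1.5, 0.3)))
  expect_equal(two$log2fc, 1.5)
  expect_equal(two$se, 0.3 / sqrt(2))
  # NA strata are dropped; all-NA propagates NA
  na_s <- s("f", NA_real_, NA_real_)
  expect_equal(ivw_meta(list(s("f", 2, 0.5), na_s))$log2fc, 2)
  expect_true(is.na(ivw_meta(list(na_s))$log2fc))
  # combined se never exceeds the smallest stratum se
  m3 <- ivw_meta(list(s("f", 1, 0.4), s("f", 0, 0.9)))
  expect_lte(m3$se, 0.4)
})

test_that("DE calling applies both thresholds", {
  meta <- data.frame(feature_id = c("a", "b", "c"),
                     log2fc = c(0.9, -1.2, 2), se = 0.1,
                     p = 0.001, q = c(0.04, 0.04, 0.2), n_strata = 1)
  expect_equal(apply_de_thresholds(meta), "b")
  expect_equal(apply_de_thresholds(meta[0, ]), character(0))
})

test_that("miRNA-mRNA association finds a planted negative regulator", {
  hits <- sapply(1:30, function(r) {
    set.seed(r)
    m <- rnorm(33)
    g <- -0.8 * m + rnorm(33, sd = sqrt(1 - 0.64))
    me <- matrix(m, 1, dimnames = list("mir1", paste0("S", 1:33)))
    ge <- matrix(g, 1, dimnames = list("gene1", paste0("S", 1:33)))
    res <- mirna_mrna_association(me, ge, scope = "all")
    res$beta < 0 && res$p < 0.05
  })
  expect_gte(mean(hits), 0.9)
  # independent pair: p uniform across reps
  pv <- sapply(1:100, function(r) {
    set.seed(1000 + r)
    me <- matrix(rnorm(33), 1, dimnames = list("mir1", paste0("S", 1:33)))
    ge <- matrix(rnorm(33), 1, dimnames = list("gene1", paste0("S", 1:33)))
    mirna_mrna_association(me, ge, scope = "all")$p
  })
  ks <- suppressWarnings(ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
  # empty target scope gives an empty result
  me <- matrix(rnorm(12), 1, dimnames = list("mir1", paste0("S", 1:12)))
  ge <- matrix(rnorm(12), 1, dimnames = list("gene1", paste0("S", 1:12)))
  empty <- mirna_mrna_association(me, ge, scope = "targets",
                                  target_pairs = data.frame(mirna_id = character(0),
                                                            gene_id = character(0)))
  expect_equal(nrow(empty), 0)
})
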