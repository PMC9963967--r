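# Independent oracle: enumerate the five causal configurations directly from
# per-SNP ABFs (linear space, fine for moderate values).
coloc_enum <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5) {
  S1 <- sum(abf1); S2 <- sum(abf2); S12 <- sum(abf1 * abf2)
  S3 <- S1 * S2 - S12
  un <- c(1, p1 * S1, p2 * S2, p1 * p2 * S3, p12 * S12)
  un / sum(un)
}

test_that("Wakefield log-ABF matches the closed form", {
  expect_equal(wakefield_labf(3, 1, prior_sd = 0), 0)        # point-null prior
  expect_equal(wakefield_labf(-2, 0.5, prior_sd = 0), 0)
  expect_equal(exp(wakefield_labf(0, 1, prior_sd = 0.2)), sqrt(1 / 1.04),
               tolerance = 1e-12)
  expect_equal(wakefield_labf(0.5, 0.1, prior_sd = 0.2),
               0.5 * (log(0.2) + 25 * 0.8), tolerance = 1e-12)
  expect_error(wakefield_labf(1, 0), "se")
})

test_that("single shared strong SNP drives PP4 with PP3 exactly zero", {
  # choose beta so that the ABF is huge, then compare with direct enumeration
  ss <- function(beta) data.frame(variant_id = "v1", beta = beta, se = 0.1,
                                  trait_type = "quantitative")
  res <- coloc_abf(ss(0.65), ss(0.65))
  abf <- exp(wakefield_labf(0.65, 0.1, prior_sd = 0.15))
  expect_equal(unname(res$pp), coloc_enum(abf, abf), tolerance = 1e-10)
  expect_equal(unname(res$pp["PP3"]), 0)
  expect_gt(res$pp["PP4"], 0.999)
})

test_that("flat evidence over many SNPs leaves PP0 dominant", {
  n <- 100
  ss <- data.frame(variant_id = sprintf("v%03d", 1:n), beta = 0, se = 1,
                   trait_type = "quantitative")
  res <- coloc_abf(ss, ss, prior_sd1 = 0, prior_sd2 = 0)  # every ABF = 1
  expected <- coloc_enum(rep(1, n), rep(1, n))
  expect_equal(unname(res$pp), expected, tolerance = 1e-10)
  expect_equal(which.max(res$pp), c(PP0 = 1))
  # closed-form configuration counts: (1, 100 p1, 100 p2, 9900 p1 p2, 100 p12)
  un <- c(1, 100e-4, 100e-4, 9900 * 1e-8, 100e-5)
  expect_equal(unname(res$pp), un / sum(un), tolerance = 1e-10)
})

test_that("posteriors sum to one and respect trait symmetry", {
  g <- simulate_gwas_pair(50, shared = TRUE, seed = 9)
  r12 <- coloc_abf(g$trait1, g$trait2)
  r21 <- coloc_abf(g$trait2, g$trait1)
  expect_lt(abs(sum(r12$pp) - 1), 1e-10)
  expect_equal(unname(r12$pp["PP1"]), unname(r21$pp["PP2"]), tolerance = 1e-10)
  expect_equal(unname(r12$pp["PP0"]), unname(r21$pp["PP0"]), tolerance = 1e-10)
  expect_equal(unname(r12$pp["PP3"]), unname(r21$pp["PP3"]), tolerance = 1e-10)
  expect_equal(unname(r12$pp["PP4"]), unname(r21$pp["PP4"]), tolerance = 1e-10)
  expect_error(coloc_abf(data.frame(variant_id = "a", beta = 1, se = 1),
                         data.frame(variant_id = "b", beta = 1, se = 1)),
               "shared")
})

test_that("log-space accumulation survives overflow-scale Bayes factors", {
  n <- 20
  ss <- data.frame(variant_id = sprintf("v%02d", 1:n),
                   beta = c(8, rep(0, n - 1)), se = 0.01,
                   trait_type = "quantitative")
  # lABF ~ 0.5 * z^2 = 320000: exp() would overflow; posterior must be finite
  res <- coloc_abf(ss, ss)
  expect_true(all(is.finite(res$pp)))
  expect_gt(res$pp["PP4"], 0.99)
})

test_that("credible sets are minimal prefixes of the sorted posterior", {
  # dominant SNP: singleton set
  labf <- log(c(a = 1e6, b = 1, c = 1))
  cs <- credible_set_99(labf)
  expect_equal(cs$variants, "a")
  expect_equal(cs$size, 1)
  # hand case: posteriors (0.6, 0.3, 0.08, 0.015, 0.005) -> first four
  post <- c(s1 = 0.6, s2 = 0.3, s3 = 0.08, s4 = 0.015, s5 = 0.005)
  cs2 <- credible_set_99(log(post))
  expect_equal(cs2$variants, c("s1", "s2", "s3", "s4"))
  expect_equal(cs2$mass, 0.995, tolerance = 1e-10)
  # uniform posteriors over 100 SNPs -> 99 of them
  cs3 <- credible_set_99(setNames(rep(0, 100), sprintf("v%03d", 1:100)))
  expect_equal(cs3$size, 99)
  # deterministic tie-break by variant id
  expect_equal(cs3$variants[1:3], c("v001", "v002", "v003"))
})

test_that("SNP-interval overlap respects half-open boundaries", {
  p <- 5000L
  snps <- data.frame(variant_id = c("in", "out"), chrom = "chr1",
                     pos = c(p + 1L, p + 1L),  # 1-based; internal coord = p
                     signal = "t2d")
  mir <- data.frame(feature_id = "mirA", chrom = "chr1", start = 1L,
                    end = 10L, strand = "+", biotype = "miRNA",
                    confidence = "canonical")
  sites_in <- data.frame(chrom = "chr1", start = p, end = p + 7L,
                         mirna_id = "mirA", gene_id = "g1")
  sites_out <- data.frame(chrom = "chr1", start = p + 1L, end = p + 8L,
                          mirna_id = "mirA", gene_id = "g1")
  me <- matrix(5, 1, 2, dimnames = list("mirA", c("S1", "S2")))
  ge <- matrix(5, 1, 2, dimnames = list("g1", c("S1", "S2")))
  ov_in <- overlap_credible_with_sites(snps[1, ], mir, sites_in, me, ge, 1)
  expect_equal(nrow(ov_in$site_overlaps), 1)
  ov_out <- overlap_credible_with_sites(snps[1, ], mir, sites_out, me, ge, 1)
  expect_equal(nrow(ov_out$site_overlaps), 0)
})

test_that("expression filters retain exactly the hand-counted records", {
  # 5 credible SNPs; SNPs 1 and 2 fall in target sites; only SNP 1's pair is
  # expressed on both sides
  snps <- data.frame(variant_id = paste0("s", 1:5), chrom = "chr1",
                     pos = c(101L, 201L, 301L, 401L, 501L), signal = "hba1c")
  mir <- data.frame(feature_id = c("mirA", "mirB"), chrom = "chr1",
                    start = c(9000L, 9100L), end = c(9022L, 9122L),
                    strand = "+", biotype = "miRNA", confidence = "canonical")
  sites <- data.frame(chrom = "chr1", start = c(100L, 200L),
                      end = c(107L, 207L), mirna_id = c("mirA", "mirB"),
                      gene_id = c("g1", "g2"))
  me <- matrix(c(10, 0.1), 2, 2, dimnames = list(c("mirA", "mirB"),
                                                 c("S1", "S2")))
  ge <- matrix(c(10, 10), 2, 2, dimnames = list(c("g1", "g2"), c("S1", "S2")))
  ov <- overlap_credible_with_sites(snps, mir, sites, me, ge, expr_threshold = 1)
  expect_equal(nrow(ov$site_overlaps), 2)  # audit keeps both
  expect_equal(nrow(ov$retained), 1)       # only the expressed pair survives
  expect_equal(ov$retained$variant_id, "s1")
  expect_equal(nrow(ov$mirna_overlaps), 0) # no SNP inside a mature miRNA
})
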