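# Synthetic cohort generator. Every downstream stage (GRM/REML, eQTL scan,
# colocalization, DE/meta, deconvolution) is exercised on data drawn from
# these generators with the ground truth recorded, since the real donor data
# are access-restricted. All generators are pure functions of (config, seed):
# a single global seed drives deterministic per-stage substreams.

.substream <- function(seed, stage) {
  offsets <- c(genotypes = 104729L, expression = 224737L, covariates = 350377L,
               gwas = 479909L, mixture = 611953L, features = 746773L)
  (as.integer(seed) + offsets[[stage]]) %% 2147483647L
}

#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic generators. Defaults emulate the
#' source cohort: 57 genotyped donors, common SNPs (MAF 0.05-0.5), moderate
#' over-dispersion typical of bulk small-RNA counts, and a donor panel with
#' sex, age, BMI, T2D status and a polygenic score.
#'
#' @param n_samples Number of donors (default 57).
#' @param n_variants Number of SNPs, spread uniformly over `chroms` (default 500).
#' @param maf_range Allele-frequency range for simulated SNPs, within (0, 0.5].
#' @param h2_cis,h2_trans Target cis/trans genetic variance fractions of the
#'   latent expression trait; must sum to < 1.
#' @param nb_dispersion Negative-binomial dispersion phi (Var = mu + phi mu^2).
#'   0 gives Poisson counts.
#' @param mean_expression Baseline count mean per feature.
#' @param n_cis_causal,n_trans_causal Causal variants per feature inside and
#'   outside the cis window.
#' @param window_size Cis window in bp on each side of a feature (default 250 kb).
#' @param chroms,chrom_length Chromosome names and common length (bp).
#' @param ld_flip_prob `NA` for linkage equilibrium; otherwise adjacent
#'   variants are allele-wise copies with this per-allele flip probability.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Donor covariate distributions.
#' @param t2d_prevalence Liability-threshold prevalence of T2D.
#' @param pgs_r2 Fraction of T2D liability variance carried by the polygenic
#'   score column, which controls the PGS-phenotype correlation.
#' @param libsize_sd SD of log-normal library size factors.
#' @param seed Global seed; fully determines all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 57, n_variants = 500,
                       maf_range = c(0.05, 0.5),
                       h2_cis = 0.2, h2_trans = 0.4,
                       nb_dispersion = 0.1, mean_expression = 1000,
                       n_cis_causal = 5, n_trans_causal = 20,
                       window_size = 250000,
                       chroms = c("chr1", "chr2"), chrom_length = 10e6,
                       ld_flip_prob = NA,
                       age_mean = 55, age_sd = 12,
                       bmi_mean = 28, bmi_sd = 5,
                       t2d_prevalence = 0.065, pgs_r2 = 0.1,
                       libsize_sd = 0.2, seed = 1) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (h2_cis < 0 || h2_trans < 0 || h2_cis + h2_trans >= 1)
    stop("variance fractions must be >= 0 and sum to < 1")
  if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a genotype dosage matrix
#'
#' Dosages are Binomial(2, f) with f ~ Uniform(`maf_range`); variants are in
#' linkage equilibrium unless `ld_flip_prob` is set, in which case each
#' variant after the first copies its left neighbour allele-wise with the
#' given per-allele flip probability (flip = redraw from Bernoulli(f)), so
#' flip probability 0 yields r^2 = 1 between neighbours.
#'
#' @param config A [sim_config()].
#' @return A `genotype_matrix` (see [read_genotypes()]).
#' @export
simulate_genotypes <- function(config) {
  set.seed(.substream(config$seed, "genotypes"))
  n <- config$n_samples; m <- config$n_variants
  f <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  if (is.na(config$ld_flip_prob)) {
    d <- matrix(stats::rbinom(n * m, 2, rep(f, each = n)), nrow = n)
  } else {
    # allele-level simulation so the copy-with-flip model is exact
    a1 <- matrix(0L, n, m); a2 <- matrix(0L, n, m)
    a1[, 1] <- stats::rbinom(n, 1, f[1]); a2[, 1] <- stats::rbinom(n, 1, f[1])
    for (j in seq_len(m)[-1]) {
      flip1 <- stats::rbinom(n, 1, config$ld_flip_prob) == 1
      flip2 <- stats::rbinom(n, 1, config$ld_flip_prob) == 1
      a1[, j] <- ifelse(flip1, stats::rbinom(n, 1, f[j]), a1[, j - 1])
      a2[, j] <- ifelse(flip2, stats::rbinom(n, 1, f[j]), a2[, j - 1])
    }
    d <- a1 + a2
  }
  chrom <- rep(config$chroms, each = ceiling(m / length(config$chroms)))[seq_len(m)]
  pos <- stats::ave(seq_len(m), chrom, FUN = function(i)
    sort(sample.int(config$chrom_length - 1, length(i))) + 1L)
  ids <- sprintf("rs%05d", seq_len(m))
  dimnames(d) <- list(sprintf("S%03d", seq_len(n)), ids)
  f_alt <- colMeans(d) / 2
  structure(list(
    dosage = d,
    variants = data.frame(variant_id = ids, chrom = chrom, pos = as.integer(pos),
                          ref = "A", alt = "G",
                          maf = pmin(f_alt, 1 - f_alt),
                          stringsAsFactors = FALSE)),
    class = "genotype_matrix")
}

#' Simulate feature intervals (miRNA- or mRNA-like)
#'
#' Places short features (22 bp, miRNA-like) or gene-length features at
#' uniform positions on the first configured chromosome, leaving the margins
#' so cis windows stay inside the chromosome.
#'
#' @param config A [sim_config()].
#' @param n_features Number of features.
#' @param biotype `"miRNA"` or `"mRNA"`.
#' @param genotypes Optional `genotype_matrix`; when given, each feature is
#'   anchored near a variant on the first chromosome so its cis window is
#'   guaranteed to contain at least one variant even in sparse panels.
#' @return Feature data.frame (see [read_intervals()]).
#' @export
simulate_features <- function(config, n_features = 20, biotype = "miRNA",
                              genotypes = NULL) {
  set.seed(.substream(config$seed, "features"))
  width <- if (biotype == "miRNA") 22L else 20000L
  lo <- config$window_size + 1
  hi <- config$chrom_length - config$window_size - width
  if (is.null(genotypes)) {
    start <- sort(sample(seq(lo, hi), n_features))
  } else {
    anchors <- genotypes$variants$pos[genotypes$variants$chrom ==
                                        config$chroms[1]]
    if (length(anchors) == 0) stop("no variants on the feature chromosome")
    a <- sample(anchors, n_features, replace = TRUE)
    jitter <- sample(seq(-config$window_size %/% 2, config$window_size %/% 2),
                     n_features, replace = TRUE)
    start <- sort(pmin(pmax(a + jitter, 1), config$chrom_length - width))
  }
  data.frame(
    feature_id = sprintf("%s%03d", if (biotype == "miRNA") "mir" else "gene",
                         seq_len(n_features)),
    chrom = config$chroms[1], start = start, end = start + width,
    strand = sample(c("+", "-"), n_features, replace = TRUE),
    biotype = biotype,
    confidence = sample(c("canonical", "isomiR_shift_le2", "other"),
                        n_features, replace = TRUE, prob = c(0.6, 0.2, 0.2)),
    stringsAsFactors = FALSE)
}

#' Simulate donor covariates
#'
#' Sex ~ Bernoulli(0.5); age and BMI normal; a polygenic score built as a
#' scaled genetic liability plus noise; T2D assigned by thresholding the
#' liability at the configured prevalence, so the PGS-T2D correlation is
#' controlled by `pgs_r2`.
#'
#' @param config A [sim_config()].
#' @param genotypes Optional `genotype_matrix` used to build the genetic part
#'   of the liability (random weights over up to 50 variants); a pure normal
#'   score is drawn when absent.
#' @return data.frame with `sample_id`, `sex`, `age`, `bmi`, `pgs`, `t2d`.
#' @export
simulate_covariates <- function(config, genotypes = NULL) {
  set.seed(.substream(config$seed, "covariates"))
  n <- config$n_samples
  if (!is.null(genotypes)) {
    m <- min(50L, ncol(genotypes$dosage))
    idx <- sample.int(ncol(genotypes$dosage), m)
    w <- stats::rnorm(m)
    score <- as.numeric(scale(genotypes$dosage[, idx, drop = FALSE] %*% w))
  } else {
    score <- stats::rnorm(n)
  }
  liability <- sqrt(config$pgs_r2) * score +
    sqrt(1 - config$pgs_r2) * stats::rnorm(n)
  data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    sex = stats::rbinom(n, 1, 0.5),
    age = stats::rnorm(n, config$age_mean, config$age_sd),
    bmi = stats::rnorm(n, config$bmi_mean, config$bmi_sd),
    pgs = score,
    t2d = as.integer(liability > stats::qnorm(1 - config$t2d_prevalence)),
    stringsAsFactors = FALSE)
}

#' Simulate expression counts with known cis/trans genetic architecture
#'
#' For each feature the latent trait is y = g_cis + g_trans + X beta + eps,
#' where g_cis sums effects of `n_cis_causal` standardized variants inside
#' the cis window, g_trans sums `n_trans_causal` variants outside it, and each
#' realized component is rescaled exactly so its sample variance equals the
#' target fraction (total latent variance 1 before covariate effects). Counts
#' are NB(mean = s_j * mean_expression * exp(y), dispersion phi) with
#' log-normal library size factors s_j.
#'
#' @param genotypes A `genotype_matrix`.
#' @param features Feature data.frame with coordinates.
#' @param config A [sim_config()]; `h2_cis`/`h2_trans` may be overridden per
#'   feature via `h2_cis`/`h2_trans` columns on `features`.
#' @param covariates Optional covariate data.frame; `covariate_effects` named
#'   vector maps its columns to latent effect sizes (default none).
#' @param covariate_effects Named numeric vector of per-SD latent effects.
#' @return list with `counts` (feature x sample matrix), `latent` (same shape,
#'   the Gaussian trait), and `truth` (per-feature causal variants, effects,
#'   realized variance fractions; plus `size_factors`).
#' @export
simulate_expression <- function(genotypes, features, config,
                                covariates = NULL, covariate_effects = NULL) {
  set.seed(.substream(config$seed, "expression"))
  n <- nrow(genotypes$dosage)
  Z <- scale(genotypes$dosage)  # standardized dosages
  Z[is.nan(Z)] <- 0             # monomorphic-in-sample variants carry no signal
  sf <- exp(stats::rnorm(n, 0, config$libsize_sd))
  sf <- sf / exp(mean(log(sf)))
  counts <- matrix(0, nrow(features), n,
                   dimnames = list(features$feature_id, rownames(genotypes$dosage)))
  latent <- counts
  truth <- vector("list", nrow(features))
  names(truth) <- features$feature_id
  cov_term <- 0
  if (!is.null(covariates) && length(covariate_effects) > 0) {
    X <- scale(as.matrix(covariates[, names(covariate_effects), drop = FALSE]))
    cov_term <- as.numeric(X %*% covariate_effects)
  }
  for (i in seq_len(nrow(features))) {
    h2c <- if (!is.null(features$h2_cis)) features$h2_cis[i] else config$h2_cis
    h2t <- if (!is.null(features$h2_trans)) features$h2_trans[i] else config$h2_trans
    part <- partition_cis_trans(genotypes$variants, features[i, ],
                                config$window_size)
    g_c <- .scaled_genetic_component(Z, part$cis, config$n_cis_causal, h2c,
                                     "cis", features$feature_id[i])
    g_t <- .scaled_genetic_component(Z, part$trans, config$n_trans_causal, h2t,
                                     "trans", features$feature_id[i])
    # orthogonalize trans against cis and noise against both before the exact
    # rescaling, so the realized variance fractions hit the targets exactly
    gc_v <- g_c$component
    gt_v <- .ortho_rescale(g_t$component, cbind(gc_v), h2t)
    eps <- .ortho_rescale(stats::rnorm(n), cbind(gc_v, gt_v), 1 - h2c - h2t)
    y <- gc_v + gt_v + eps + cov_term
    vy <- stats::var(y)
    latent[i, ] <- y
    mu <- sf * config$mean_expression * exp(y - mean(y))
    counts[i, ] <- if (config$nb_dispersion == 0) stats::rpois(n, mu)
                   else stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    truth[[i]] <- list(
      cis_causal = g_c$ids, cis_effects = g_c$effects,
      trans_causal = g_t$ids, trans_effects = g_t$effects,
      h2_cis_realized = stats::var(gc_v) / vy,
      h2_trans_realized = stats::var(gt_v) / vy)
  }
  list(counts = counts, latent = latent,
       truth = list(features = truth, size_factors = sf))
}

.ortho_rescale <- function(x, basis, target_var) {
  if (target_var <= 0) return(rep(0, length(x)))
  keep <- apply(basis, 2, function(b) stats::sd(b) > 0)
  if (any(keep)) {
    x <- stats::lm.fit(cbind(1, basis[, keep, drop = FALSE]), x)$residuals
  } else {
    x <- x - mean(x)
  }
  x / stats::sd(x) * sqrt(target_var)
}

.scaled_genetic_component <- function(Z, pool, n_causal, h2, label, fid) {
  n <- nrow(Z)
  if (h2 == 0) return(list(component = rep(0, n), ids = character(0),
                           effects = numeric(0)))
  if (length(pool) == 0)
    stop("no ", label, " variants available for feature ", fid,
         " with nonzero target variance")
  ids <- sample(pool, min(n_causal, length(pool)))
  b <- stats::rnorm(length(ids))
  g <- as.numeric(Z[, ids, drop = FALSE] %*% b)
  scl <- sqrt(h2) / stats::sd(g)
  list(component = g * scl, ids = ids, effects = b * scl)
}

#' Simulate a pair of GWAS summary-statistic sets
#'
#' Each trait follows a single-causal-variant model: an independent cohort of
#' binomial genotypes, a quantitative trait with the causal variant explaining
#' `effect_size` of its variance, and per-SNP marginal OLS summary statistics.
#' `shared = TRUE` gives both traits the same causal SNP (the positive
#' colocalization case); `FALSE` draws two distinct causal SNPs (which are
#' unlinked here, the PP3 case).
#'
#' @param n_snps Number of SNPs in the region.
#' @param shared Share one causal variant between the two traits?
#' @param n1,n2 Cohort sizes for the two traits.
#' @param effect_size Fraction of trait variance explained by the causal SNP
#'   (0 gives pure-null statistics for both traits).
#' @param seed Seed for this draw.
#' @param maf_range Allele-frequency range.
#' @return list with `trait1`, `trait2` (summary-stat data.frames compatible
#'   with [read_summary_stats()]) and `truth` (causal variant ids).
#' @export
simulate_gwas_pair <- function(n_snps, shared, n1 = 5000, n2 = 5000,
                               effect_size = 0.01, seed = 1,
                               maf_range = c(0.05, 0.5)) {
  if (!shared && n_snps < 2) stop("distinct causal variants need >= 2 SNPs")
  set.seed(.substream(seed, "gwas"))
  f <- stats::runif(n_snps, maf_range[1], maf_range[2])
  ids <- sprintf("rs%05d", seq_len(n_snps))
  pos <- sort(sample.int(5e5, n_snps)) + 1000000L
  c1 <- sample.int(n_snps, 1)
  c2 <- if (shared) c1 else sample(setdiff(seq_len(n_snps), c1), 1)
  one <- function(n, causal) {
    X <- matrix(stats::rbinom(n * n_snps, 2, rep(f, each = n)), nrow = n)
    y <- stats::rnorm(n)
    if (effect_size > 0) {
      x <- X[, causal]
      y <- sqrt(effect_size) * (x - mean(x)) / stats::sd(x) +
        sqrt(1 - effect_size) * y
    }
    xc <- sweep(X, 2, colMeans(X))
    vx <- colSums(xc^2)
    beta <- as.numeric(crossprod(xc, y - mean(y))) / vx
    rss <- sum((y - mean(y))^2) - beta^2 * vx
    se <- sqrt(rss / (n - 2) / vx)
    z <- beta / se
    data.frame(variant_id = ids, chrom = "chr1", pos = pos,
               beta = beta, se = se,
               p = 2 * stats::pt(-abs(z), df = n - 2),
               n = n, maf = pmin(f, 1 - f), trait_type = "quantitative",
               stringsAsFactors = FALSE)
  }
  list(trait1 = one(n1, c1), trait2 = one(n2, c2),
       truth = list(causal1 = ids[c1], causal2 = ids[c2], shared = shared))
}

#' Simulate counts with known differential expression against a phenotype
#'
#' One stratum of NB counts: log-normal baseline abundances, log-normal
#' library size factors, and a configurable fraction of features carrying a
#' true log2 fold change (random sign) against a balanced binary phenotype.
#' Compose several calls for multi-stratum meta-analysis studies.
#'
#' @param n_samples Samples in the stratum.
#' @param n_features Number of features.
#' @param frac_alt Fraction of features with a true effect (0 = pure null).
#' @param lfc True |log2 fold change| for affected features.
#' @param phi NB dispersion.
#' @param mean_expression Median baseline abundance.
#' @param libsize_sd SD of log library size factors.
#' @param seed Seed.
#' @return list with `counts`, `phenotype` (balanced 0/1), and `truth`
#'   (data.frame `feature_id`, `log2fc_true`).
#' @export
simulate_de_counts <- function(n_samples, n_features = 200, frac_alt = 0,
                               lfc = 1.5, phi = 0.1, mean_expression = 500,
                               libsize_sd = 0.2, seed = 1) {
  set.seed(.substream(seed, "expression") + 7L)
  pheno <- sample(rep(0:1, length.out = n_samples))
  alt <- seq_len(n_features) <= round(frac_alt * n_features)
  lfc_true <- ifelse(alt, sample(c(-1, 1), n_features, replace = TRUE) * lfc, 0)
  base <- stats::rlnorm(n_features, log(mean_expression), 1)
  sf <- exp(stats::rnorm(n_samples, 0, libsize_sd))
  mu <- outer(base, sf) * 2^(outer(lfc_true, pheno))
  counts <- matrix(
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
    nrow = n_features,
    dimnames = list(sprintf("f%04d", seq_len(n_features)),
                    sprintf("S%03d", seq_len(n_samples))))
  list(counts = counts, phenotype = pheno,
       truth = data.frame(feature_id = rownames(counts),
                          log2fc_true = lfc_true, stringsAsFactors = FALSE))
}

#' Simulate bulk counts as a two-cell-type mixture
#'
#' Bulk mean for each sample is the fraction-weighted sum of the signature
#' means; negative-binomial noise (Poisson when `phi = 0`) is applied on top.
#'
#' @param signatures Feature x cell-type matrix of mean abundances (2 columns).
#' @param fractions Sample x cell-type matrix; rows must be >= 0 and sum to 1.
#' @param phi NB dispersion (0 = Poisson).
#' @param seed Seed.
#' @return list with `counts` (feature x sample) and `truth` (the fractions).
#' @export
simulate_mixture <- function(signatures, fractions, phi = 0.1, seed = 1) {
  fractions <- as.matrix(fractions)
  if (any(fractions < 0)) stop("fractions must be >= 0")
  if (any(abs(rowSums(fractions) - 1) > 1e-8))
    stop("fractions must sum to 1 per sample")
  set.seed(.substream(seed, "mixture"))
  mu <- as.matrix(signatures) %*% t(fractions)  # features x samples
  counts <- matrix(
    if (phi == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
    nrow = nrow(mu), dimnames = list(rownames(signatures),
                                     sprintf("S%03d", seq_len(nrow(fractions)))))
  list(counts = counts, truth = list(fractions = fractions))
}

#' Simulate sorted-cell signature profiles for two cell types
#'
#' Log-normal baseline abundances with a subset of marker features up- or
#' down-weighted in one cell type, giving the contrast deconvolution needs.
#'
#' @param n_features Number of signature features.
#' @param n_markers Markers per cell type (strong fold difference).
#' @param mean_abundance Baseline abundance scale.
#' @param seed Seed.
#' @return Feature x 2 matrix with columns `alpha`, `beta`.
#' @export
simulate_signatures <- function(n_features = 50, n_markers = 15,
                                mean_abundance = 1000, seed = 1) {
  set.seed(.substream(seed, "mixture") + 1L)
  base <- stats::rlnorm(n_features, log(mean_abundance), 0.5)
  fold <- rep(1, n_features)
  up <- sample.int(n_features, 2 * n_markers)
  fold[up[seq_len(n_markers)]] <- stats::runif(n_markers, 4, 10)
  fold[up[n_markers + seq_len(n_markers)]] <- 1 / stats::runif(n_markers, 4, 10)
  sig <- cbind(alpha = base * sqrt(fold), beta = base / sqrt(fold))
  rownames(sig) <- sprintf("mir%03d", seq_len(n_features))
  sig
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits every on-disk artifact the pipeline consumes: genotypes (VCF),
#' feature intervals (BED), miRNA counts (TSV), donor metadata (TSV), a GWAS
#' summary-statistic pair (TSV), sorted-cell signatures (TSV), and the ground
#' truth (JSON).
#'
#' @param dir Output directory (created if needed).
#' @param config A [sim_config()].
#' @return Invisibly, a named list of the file paths written.
#' @export
write_sim_bundle <- function(dir, config = sim_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  geno <- simulate_genotypes(config)
  feats <- simulate_features(config, n_features = 20, genotypes = geno)
  covs <- simulate_covariates(config, geno)
  expr <- simulate_expression(geno, feats, config)
  gwas <- simulate_gwas_pair(100, shared = TRUE, seed = config$seed)
  sig <- simulate_signatures(seed = config$seed)
  paths <- list(
    vcf = file.path(dir, "genotypes.vcf"),
    bed = file.path(dir, "features.bed"),
    counts = file.path(dir, "mirna_counts.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    gwas1 = file.path(dir, "gwas_trait1.tsv"),
    gwas2 = file.path(dir, "gwas_trait2.tsv"),
    signatures = file.path(dir, "signatures.tsv"),
    truth = file.path(dir, "truth.json"))
  write_vcf(geno, paths$vcf)
  write_intervals(feats, paths$bed)
  write_counts(expr$counts, paths$counts)
  utils::write.table(covs, paths$metadata, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_summary_stats(gwas$trait1, paths$gwas1)
  write_summary_stats(gwas$trait2, paths$gwas2)
  utils::write.table(data.frame(feature_id = rownames(sig), sig),
                     paths$signatures, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(expression = expr$truth, gwas = gwas$truth),
                       paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
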