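# End-to-end driver: consume a simulated input bundle from disk, run every
# stage (GRM -> heritability -> eQTL -> coloc -> credible sets -> overlap ->
# DE -> meta -> deconvolution -> sensitivity), and write one TSV per stage.
# The analysis/ scripts are thin narrations over these calls.

#' Run the full pipeline on an input bundle
#'
#' @param input_dir Directory holding a bundle as written by
#'   [write_sim_bundle()] (genotypes.vcf, features.bed, mirna_counts.tsv,
#'   metadata.tsv, gwas_trait1.tsv, gwas_trait2.tsv, signatures.tsv).
#' @param out_dir Output directory for the stage TSVs.
#' @param window_size Cis window (bp).
#' @param heritable_threshold hg2 cutoff for the heritable flag.
#' @return Invisibly, a named list of output paths.
#' @export
run_pipeline <- function(input_dir, out_dir, window_size = 250000,
                         heritable_threshold = 0.9) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  geno <- read_genotypes(file.path(input_dir, "genotypes.vcf"), maf_min = 0.01)
  feats <- read_intervals(file.path(input_dir, "features.bed"))
  counts <- read_counts(file.path(input_dir, "mirna_counts.tsv"))
  meta <- utils::read.delim(file.path(input_dir, "metadata.tsv"))
  gwas1 <- read_summary_stats(file.path(input_dir, "gwas_trait1.tsv"))
  gwas2 <- read_summary_stats(file.path(input_dir, "gwas_trait2.tsv"))
  sig_tab <- utils::read.delim(file.path(input_dir, "signatures.tsv"))
  signatures <- as.matrix(sig_tab[, -1])
  rownames(signatures) <- sig_tab[[1]]

  keep <- abundance_filter(counts)
  counts <- counts[keep, , drop = FALSE]
  expr <- transform_expression(counts)
  covs <- as.matrix(meta[, c("sex", "age", "bmi")])

  paths <- list()
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }

  # heritability and cis/trans decomposition
  herit <- decompose_features(expr, geno, feats, covariates = covs,
                              window_size = window_size,
                              heritable_threshold = heritable_threshold)
  w(herit, "heritability")

  # cis-eQTL scan, pooled BH
  eqtl <- assoc_scan(expr, geno, covariates = covs, features = feats,
                     window_size = window_size)
  w(eqtl, "eqtl")

  # colocalization of the two GWAS traits over the shared region
  cl <- coloc_abf(gwas1, gwas2)
  w(data.frame(region = "region1", t(cl$pp), n_snps = cl$n_snps), "coloc")

  # 99% credible set for trait 1 and overlap with miRNA/target-site intervals
  cs <- credible_set_99(cl$labf1)
  cs_df <- data.frame(variant_id = cs$variants, posterior = cs$posterior,
                      signal = "trait1")
  w(cs_df, "credible_set")
  cred_snps <- merge(cs_df, gwas1[, c("variant_id", "chrom", "pos")],
                     by = "variant_id")
  target_sites <- data.frame(
    chrom = feats$chrom[1], start = feats$start[1] - 50L,
    end = feats$start[1] - 43L,
    mirna_id = feats$feature_id[1], gene_id = "gene001")
  mrna_expr <- matrix(10, 1, ncol(expr), dimnames = list("gene001", colnames(expr)))
  ov <- overlap_credible_with_sites(cred_snps, feats, target_sites,
                                    expr, mrna_expr, expr_threshold = -Inf)
  w(ov$site_overlaps, "overlap_audit")
  w(ov$retained, "overlap_retained")

  # differential expression per library-prep stratum + meta-analysis
  sf <- size_factors(counts)
  de_t2d <- nb_wald_de(counts, meta$t2d, covariates = covs, sf = sf,
                       stratum = "LP1")
  w(de_t2d, "de_t2d")
  meta_t2d <- ivw_meta(list(de_t2d))
  w(meta_t2d, "meta_t2d")
  w(data.frame(feature_id = apply_de_thresholds(meta_t2d)), "de_called")

  # deconvolution and sensitivity re-analysis
  fr <- estimate_fractions(counts, signatures)
  w(fr, "cell_fractions")
  sens <- sensitivity_reanalysis(
    function(cv) assoc_scan(expr, geno, covariates = cv, features = feats,
                            window_size = window_size),
    covs, fr[[3]])
  w(data.frame(pearson_r = sens$pearson_r,
               max_abs_delta = sens$max_abs_delta), "sensitivity")
  invisible(paths)
}

#' Validate the schema of every pipeline output
#'
#' Checks that each stage file exists, parses as TSV, and carries the
#' documented columns with values in their legal ranges.
#'
#' @param paths Named list from [run_pipeline()].
#' @return TRUE invisibly; stops with a message naming the first violation.
#' @export
validate_pipeline_outputs <- function(paths) {
  need <- function(name, cols, check = NULL) {
    p <- paths[[name]]
    if (is.null(p) || !file.exists(p)) stop("missing output: ", name)
    df <- utils::read.delim(p, check.names = FALSE)
    miss <- setdiff(cols, names(df))
    if (length(miss) > 0)
      stop(name, ": missing column(s) ", paste(miss, collapse = ", "))
    if (!is.null(check)) check(df)
    df
  }
  in01 <- function(x) all(is.na(x) | (x >= -1e-9 & x <= 1 + 1e-9))
  need("heritability", c("feature_id", "hg2_single", "heritable"),
       function(df) if (!in01(df$hg2_single)) stop("hg2 outside [0, 1]"))
  need("eqtl", c("variant_id", "feature_id", "beta", "se", "p", "q", "n"),
       function(df) {
         if (!in01(df$p) || !in01(df$q)) stop("eqtl p/q outside [0, 1]")
         if (any(!is.na(df$q) & !is.na(df$p) & df$q < df$p - 1e-12))
           stop("q below p in eqtl output")
       })
  need("coloc", c("PP0", "PP1", "PP2", "PP3", "PP4", "n_snps"),
       function(df) {
         pp <- as.numeric(df[1, c("PP0", "PP1", "PP2", "PP3", "PP4")])
         if (abs(sum(pp) - 1) > 1e-6) stop("coloc posteriors do not sum to 1")
       })
  need("credible_set", c("variant_id", "posterior"),
       function(df) if (sum(df$posterior) < 0.99 - 1e-9)
         stop("credible set mass below coverage"))
  need("overlap_audit", c("variant_id", "mirna_id", "gene_id",
                          "mirna_expressed", "mrna_expressed"))
  need("overlap_retained", c("variant_id", "mirna_id", "gene_id"))
  need("de_t2d", c("feature_id", "log2fc", "se", "p", "stratum"))
  need("meta_t2d", c("feature_id", "log2fc", "se", "p", "q", "n_strata"))
  need("cell_fractions", c("sample_id", "residual_norm"),
       function(df) {
         fr <- as.matrix(df[, setdiff(names(df), c("sample_id", "residual_norm"))])
         if (any(fr < -1e-9)) stop("negative cell fraction")
         if (any(abs(rowSums(fr) - 1) > 1e-6)) stop("fractions do not sum to 1")
       })
  need("sensitivity", c("pearson_r", "max_abs_delta"))
  invisible(TRUE)
}
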