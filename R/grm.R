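# Genetic relationship matrices, LD, and the cis/trans partitioning rule.

#' Compute a standardized-dosage genetic relationship matrix
#'
#' K = Z Z' / M over the requested variant subset, with z = (g - 2f) /
#' sqrt(2 f (1 - f)) and f the in-sample alt-allele frequency. For many
#' independent standardized variants E[diag(K)] = 1. Variants that are
#' monomorphic in-sample are dropped (they carry no relatedness information).
#'
#' @param genotypes A `genotype_matrix`.
#' @param variant_subset Character vector of variant ids (default: all).
#' @return A `kinship_matrix`: list with `K` (n x n symmetric), `n_variants`,
#'   `sample_ids`.
#' @export
compute_grm <- function(genotypes, variant_subset = NULL) {
  ids <- genotypes$variants$variant_id
  if (is.null(variant_subset)) variant_subset <- ids
  if (length(variant_subset) == 0) stop("empty variant subset")
  missing_ids <- setdiff(variant_subset, ids)
  if (length(missing_ids) > 0)
    stop("unknown variant id(s): ", paste(utils::head(missing_ids, 3), collapse = ", "))
  G <- genotypes$dosage[, variant_subset, drop = FALSE]
  f <- colMeans(G) / 2
  poly <- f > 0 & f < 1
  if (!any(poly)) stop("no polymorphic variants in subset")
  G <- G[, poly, drop = FALSE]
  f <- f[poly]
  Z <- sweep(sweep(G, 2, 2 * f), 2, sqrt(2 * f * (1 - f)), "/")
  M <- ncol(Z)
  K <- tcrossprod(Z) / M
  structure(list(K = K, n_variants = M, sample_ids = rownames(genotypes$dosage)),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("kinship_matrix: %d samples, %d variants, mean diag %.3f\n",
              nrow(x$K), x$n_variants, mean(diag(x$K))))
  invisible(x)
}

#' Repair a kinship matrix to positive semidefiniteness
#'
#' Adds eps * I with eps = max(0, -lambda_min) + 1e-8 so downstream solves are
#' well posed.
#'
#' @param K Symmetric matrix.
#' @return Repaired matrix.
#' @export
psd_repair <- function(K) {
  lam_min <- min(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  K + diag(max(0, -lam_min) + 1e-8, nrow(K))
}

#' Cis window for a feature
#'
#' miRNA features are anchored on the full mature-transcript interval; mRNA
#' features on the strand-aware TSS point (start for `+`, end for `-`). The
#' window is `[anchor_start - window_size, anchor_end + window_size)` on
#' internal 0-based half-open coordinates, clipped at 0.
#'
#' @param feature One-row feature data.frame.
#' @param window_size Window in bp on each side (default 250 kb).
#' @return list with `chrom`, `window_start`, `window_end`.
#' @export
cis_window <- function(feature, window_size = 250000) {
  if (identical(feature$biotype, "mRNA")) {
    tss <- if (feature$strand == "-") feature$end - 1L else feature$start
    a_start <- tss; a_end <- tss + 1L
  } else {
    a_start <- feature$start; a_end <- feature$end
  }
  list(chrom = feature$chrom,
       window_start = max(0L, a_start - window_size),
       window_end = a_end + window_size)
}

#' Partition variants into cis and trans sets around a feature
#'
#' Cis: same chromosome and position inside the (half-open) cis window; trans:
#' everything else. The partition is exhaustive and disjoint.
#'
#' @param variants Variant data.frame (`variant_id`, `chrom`, `pos` 1-based).
#' @param feature One-row feature data.frame.
#' @param window_size Window in bp (use `Inf` for whole-chromosome cis).
#' @return list with character vectors `cis` and `trans`.
#' @export
partition_cis_trans <- function(variants, feature, window_size = 250000) {
  w <- cis_window(feature, window_size)
  pos0 <- variants$pos - 1L  # internal 0-based
  in_cis <- variants$chrom == w$chrom &
    pos0 >= w$window_start & pos0 < w$window_end
  list(cis = variants$variant_id[in_cis],
       trans = variants$variant_id[!in_cis])
}

#' Squared linkage disequilibrium between two variants
#'
#' Squared Pearson correlation of the dosage vectors.
#'
#' @param genotypes A `genotype_matrix`.
#' @param variant_a,variant_b Variant ids.
#' @return r^2 in [0, 1].
#' @export
ld_r2 <- function(genotypes, variant_a, variant_b) {
  ga <- genotypes$dosage[, variant_a]
  gb <- genotypes$dosage[, variant_b]
  if (stats::sd(ga) == 0 || stats::sd(gb) == 0)
    stop("monomorphic variant: LD undefined")
  stats::cor(ga, gb)^2
}
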