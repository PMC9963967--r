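#' Read a genotype dosage matrix from VCF or a plain dosage table
#'
#' Parses either a VCF 4.x file (using the `GT` or `DS` FORMAT field) or a
#' plain tab-separated dosage table (first column `variant_id`, one column per
#' sample, with an optional `<path>.variants.tsv` sidecar carrying variant
#' metadata). Variants are filtered on minor allele frequency after folding
#' the alt-allele frequency to the minor allele, and missing dosages are
#' mean-imputed per variant so downstream kinship matrices and scans keep all
#' samples.
#'
#' @param path Path to a `.vcf` file or a dosage TSV.
#' @param maf_min Minimum folded minor allele frequency; variants below it are
#'   dropped. Default 0 keeps everything polymorphic handling to the caller.
#' @param max_missing Maximum fraction of missing dosages tolerated per
#'   variant; variants above it are dropped with a warning. Default 0.1.
#' @return A `genotype_matrix`: list with `dosage` (samples x variants numeric
#'   matrix, dimnames set), and `variants` (data.frame with `variant_id`,
#'   `chrom`, `pos` (1-based), `ref`, `alt`, `maf`).
#' @export
read_genotypes <- function(path, maf_min = 0, max_missing = 0.1) {
  stopifnot(file.exists(path))
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    gm <- .read_genotypes_vcf(path)
  } else {
    gm <- .read_genotypes_tsv(path)
  }
  if (anyDuplicated(gm$variants$variant_id))
    stop("duplicate variant_id in ", path)
  .finalize_genotypes(gm, maf_min = maf_min, max_missing = max_missing)
}

.read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fmt <- vcfR::vcf_field_names(v, tag = "FORMAT")$ID
  if ("DS" %in% fmt) {
    d <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else if ("GT" %in% fmt) {
    gt <- vcfR::extract.gt(v, element = "GT")
    # count alt alleles; treat any missing allele as missing dosage
    d <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      al <- strsplit(g, "[/|]")[[1]]
      if (any(al == ".")) return(NA_real_)
      sum(al != "0")
    })
  } else stop("VCF has neither GT nor DS FORMAT fields")
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  list(
    dosage = t(matrix(as.numeric(d), nrow = nrow(d),
                      dimnames = list(ids, colnames(d)))),
    variants = data.frame(
      variant_id = ids, chrom = fix[, "CHROM"],
      pos = as.integer(fix[, "POS"]),
      ref = fix[, "REF"], alt = fix[, "ALT"],
      stringsAsFactors = FALSE)
  )
}

.read_genotypes_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("dosage table needs variant_id plus sample columns")
  ids <- as.character(tab[[1]])
  d <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(d) <- ids
  meta_path <- paste0(path, ".variants.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(ids, meta$variant_id), , drop = FALSE]
  } else {
    meta <- data.frame(variant_id = ids, chrom = NA_character_,
                       pos = NA_integer_, ref = NA_character_,
                       alt = NA_character_, stringsAsFactors = FALSE)
  }
  list(dosage = d, variants = meta)
}

.finalize_genotypes <- function(gm, maf_min, max_missing) {
  d <- gm$dosage
  if (any(d < 0 | d > 2, na.rm = TRUE)) stop("dosages must lie in [0, 2]")
  miss_frac <- colMeans(is.na(d))
  all_missing <- miss_frac == 1
  if (any(all_missing))
    warning(sum(all_missing), " variant(s) with all dosages missing dropped")
  too_missing <- !all_missing & miss_frac > max_missing
  if (any(too_missing))
    warning(sum(too_missing), " variant(s) above missingness cap dropped")
  keep <- !(all_missing | too_missing)
  d <- d[, keep, drop = FALSE]
  vars <- gm$variants[keep, , drop = FALSE]
  # mean-impute remaining missing dosages per variant
  nas <- which(is.na(d), arr.ind = TRUE)
  if (nrow(nas) > 0) {
    mu <- colMeans(d, na.rm = TRUE)
    d[nas] <- mu[nas[, 2]]
  }
  f_alt <- colMeans(d) / 2
  maf <- pmin(f_alt, 1 - f_alt)
  keep2 <- maf >= maf_min
  d <- d[, keep2, drop = FALSE]
  vars <- vars[keep2, , drop = FALSE]
  vars$maf <- maf[keep2]
  rownames(vars) <- NULL
  structure(list(dosage = d, variants = vars), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Write a genotype matrix as a dosage TSV plus variant-metadata sidecar
#'
#' Inverse of [read_genotypes()] for the plain-dosage dialect: the main file
#' has `variant_id` then one column per sample; `<path>.variants.tsv` carries
#' chrom/pos/ref/alt/maf.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output TSV path.
#' @export
write_dosage <- function(gm, path) {
  tab <- data.frame(variant_id = gm$variants$variant_id,
                    t(gm$dosage), check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(gm$variants, paste0(path, ".variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF 4.2 with GT genotypes
#'
#' Dosages must be integral (0/1/2) to be representable as unphased GT calls.
#'
#' @param gm A `genotype_matrix`.
#' @param path Output `.vcf` path (uncompressed).
#' @export
write_vcf <- function(gm, path) {
  d <- round(gm$dosage)
  if (max(abs(d - gm$dosage)) > 1e-8)
    stop("write_vcf requires integral dosages; use write_dosage for DS-style data")
  gt_codes <- c("0/0", "0/1", "1/1")
  v <- gm$variants
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(gm$dosage)), collapse = "\t")),
             con)
  for (j in seq_len(ncol(d))) {
    writeLines(paste(c(v$chrom[j], v$pos[j], v$variant_id[j],
                       v$ref[j], v$alt[j], ".", "PASS", ".", "GT",
                       gt_codes[d[, j] + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}
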