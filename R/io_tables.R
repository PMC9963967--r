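#' Read feature intervals from BED6 or GFF3
#'
#' All internal coordinates are 0-based half-open (BED convention); GFF3's
#' 1-based closed coordinates are converted on read. Extra BED columns 7 and 8
#' (or GFF3 attributes `biotype` and `confidence`) populate the feature class
#' fields; absent, biotype defaults to `"miRNA"` and confidence to
#' `"canonical"`.
#'
#' @param path Path to a `.bed` or `.gff3`/`.gff` file.
#' @return data.frame with columns `feature_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `biotype`, `confidence`.
#' @export
read_intervals <- function(path) {
  gff <- grepl("\\.gff3?$", path)
  if (gff) {
    gr <- rtracklayer::import(path, format = "gff3")
  } else {
    nfield <- length(strsplit(readLines(path, n = 1), "\t")[[1]])
    extra <- if (nfield >= 8) c(biotype = "character", confidence = "character")
    gr <- rtracklayer::import(path, format = "bed", extraCols = extra)
  }
  start0 <- GenomicRanges::start(gr) - 1L  # GRanges is 1-based closed
  end0 <- GenomicRanges::end(gr)
  bad <- which(start0 >= end0)
  if (length(bad) > 0)
    stop("interval with start >= end after conversion at record ", bad[1])
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  id <- if (gff) {
    if (!is.null(mc$ID)) mc$ID else mc$Name
  } else mc$name
  if (is.null(id)) id <- paste0("feat", seq_along(gr))
  biotype <- if (!is.null(mc$biotype)) as.character(mc$biotype)
             else if (gff && !is.null(mc$type)) as.character(mc$type)
             else rep("miRNA", length(gr))
  confidence <- if (!is.null(mc$confidence)) as.character(mc$confidence)
                else rep("canonical", length(gr))
  data.frame(
    feature_id = as.character(id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = start0, end = end0,
    strand = as.character(GenomicRanges::strand(gr)),
    biotype = biotype, confidence = confidence,
    stringsAsFactors = FALSE)
}

#' Write feature intervals as BED6 (+ biotype, confidence columns)
#'
#' @param features data.frame as returned by [read_intervals()].
#' @param path Output path.
#' @export
write_intervals <- function(features, path) {
  tab <- data.frame(features$chrom, features$start, features$end,
                    features$feature_id, 0L, features$strand,
                    features$biotype, features$confidence)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a feature x sample count matrix from TSV
#'
#' First column holds feature ids, header row holds sample ids. Counts must be
#' non-negative integers.
#'
#' @param path Path to the TSV.
#' @return Integer-valued numeric matrix, features in rows.
#' @export
read_counts <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("no features in ", path)
  ids <- as.character(tab[[1]])
  if (anyDuplicated(ids)) stop("duplicated feature id: ",
                               ids[duplicated(ids)][1])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (ncol(m) == 0) stop("no samples in ", path)
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-count value at feature '%s', sample '%s'",
                 ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
  rownames(m) <- ids
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix as TSV (inverse of [read_counts()])
#' @param counts Feature x sample matrix with dimnames.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  tab <- data.frame(feature_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read GWAS summary statistics from TSV
#'
#' Expects columns `variant_id`, `chrom`, `pos`, `beta`, `se`, `p`, `n`,
#' `maf`, and optionally `trait_type` (`quantitative` or `case_control`) and
#' `case_fraction`. Validates `se > 0` and `p` in (0, 1]; a z-score that is
#' inconsistent with `p` under the normal approximation (beyond 10% relative
#' tolerance) triggers a warning, not an error, since printed summary tables
#' are routinely rounded.
#'
#' @param path Path to the TSV.
#' @return data.frame of summary statistics.
#' @export
read_summary_stats <- function(path) {
  ss <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("variant_id", "chrom", "pos", "beta", "se", "p", "n", "maf")
  miss <- setdiff(req, names(ss))
  if (length(miss) > 0) stop("missing summary-stat columns: ",
                             paste(miss, collapse = ", "))
  if (any(ss$se <= 0)) stop("se must be > 0")
  if (any(ss$p <= 0 | ss$p > 1)) stop("p must lie in (0, 1]")
  if (is.null(ss$trait_type)) ss$trait_type <- "quantitative"
  z_from_p <- stats::qnorm(ss$p / 2, lower.tail = FALSE)
  z <- abs(ss$beta / ss$se)
  ok <- z_from_p == 0 | abs(z - z_from_p) <= 0.1 * pmax(z_from_p, 1)
  if (any(!ok))
    warning(sum(!ok), " record(s) with |beta/se| inconsistent with p")
  ss
}

#' Write GWAS summary statistics as TSV (inverse of [read_summary_stats()])
#' @param ss Summary-statistic data.frame.
#' @param path Output path.
#' @export
write_summary_stats <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
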