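# Negative-binomial differential expression against donor phenotypes and
# fixed-effect inverse-variance meta-analysis across strata (library preps,
# external cohorts, ancestry groups), with the FDR <= 5% and |log2FC| >= 1
# calling rule applied after meta-analysis.

#' Median-of-ratios size factors
#'
#' DESeq-style normalization: the reference is the per-feature geometric mean
#' across samples computed over features with all-positive counts, and each
#' sample's factor is the median ratio of its counts to the reference.
#'
#' @param counts Feature x sample count matrix.
#' @return Positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos)) stop("cannot normalize: no feature with all-positive counts")
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)  # log geometric mean
  exp(apply(logc - ref, 2, stats::median))
}

#' Abundance filter for low-count features
#'
#' Keeps features with `count >= min_count` in at least `min_fraction` of
#' samples — the simple surrogate used here for noise filtering of
#' low-abundance transcripts.
#'
#' @param counts Feature x sample matrix.
#' @param min_count Per-sample count threshold.
#' @param min_fraction Minimum fraction of samples at or above it.
#' @return Character vector of retained feature ids.
#' @export
abundance_filter <- function(counts, min_count = 5, min_fraction = 0.5) {
  if (min_count < 0 || min_fraction < 0) stop("thresholds must be >= 0")
  keep <- rowMeans(counts >= min_count) >= min_fraction
  rownames(counts)[keep]
}

#' Negative-binomial Wald differential expression
#'
#' Per feature, an NB log-link GLM of counts on the phenotype plus covariates
#' with offset log(size factor). Continuous phenotypes are standardized to
#' unit SD first, so the reported log2 fold change is per phenotype SD; for a
#' binary phenotype it is the group contrast. Dispersion is per-feature
#' method-of-moments on normalized counts with floor 1e-4 (`"moments"`), or a
#' single supplied value (`"fixed"`). Features whose fit fails are reported
#' with `p = NA` and excluded from any downstream BH batch.
#'
#' @param counts Feature x sample matrix.
#' @param phenotype Numeric or 0/1 vector.
#' @param covariates Optional covariate matrix.
#' @param sf Size factors (default [size_factors()] of `counts`).
#' @param dispersion `"moments"` or a single numeric phi for `"fixed"` mode.
#' @param stratum Label recorded on the results.
#' @return data.frame: `feature_id`, `phenotype` label, `log2fc`, `se`
#'   (log2 scale), `p`, `stratum`.
#' @export
nb_wald_de <- function(counts, phenotype, covariates = NULL, sf = NULL,
                       dispersion = "moments", stratum = "stratum1") {
  if (stats::sd(phenotype) == 0) stop("phenotype is constant")
  n <- ncol(counts)
  p_cov <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n < p_cov + 2) stop("too few samples")
  if (is.null(sf)) sf <- size_factors(counts)
  binary <- all(phenotype %in% c(0, 1))
  x <- if (binary) phenotype else as.numeric(scale(phenotype))
  dat <- data.frame(x = x)
  fml_terms <- "x"
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    fml_terms <- c(fml_terms, colnames(covariates))
  }
  fml <- stats::reformulate(fml_terms, response = "y")
  out <- lapply(rownames(counts), function(fid) {
    yc <- counts[fid, ]
    norm <- yc / sf
    phi <- if (identical(dispersion, "moments")) {
      mu <- mean(norm)
      max((stats::var(norm) - mu) / mu^2, 1e-4)
    } else as.numeric(dispersion)
    dat$y <- yc
    fit <- tryCatch({
      g <- suppressWarnings(stats::glm(
        fml, data = dat, family = MASS::negative.binomial(theta = 1 / phi),
        offset = log(sf)))
      co <- summary(g)$coefficients["x", ]
      data.frame(feature_id = fid, log2fc = co[["Estimate"]] / log(2),
                 se = co[["Std. Error"]] / log(2), p = co[["Pr(>|t|)"]],
                 stringsAsFactors = FALSE)
    }, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$p))
      fit <- data.frame(feature_id = fid, log2fc = NA_real_, se = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE)
    fit
  })
  res <- do.call(rbind, out)
  res$stratum <- stratum
  rownames(res) <- NULL
  res
}

#' Fixed-effect inverse-variance meta-analysis of per-stratum DE results
#'
#' Weights w_k = 1 / se_k^2; combined effect = sum(w beta) / sum(w); combined
#' se = 1 / sqrt(sum(w)); two-sided normal p. Strata with missing estimates
#' are dropped per feature; features with no usable stratum get NA. q-values
#' are Benjamini-Hochberg across features (one phenotype per call).
#'
#' @param strata List of data.frames from [nb_wald_de()] (columns
#'   `feature_id`, `log2fc`, `se`, `p`).
#' @return data.frame: `feature_id`, `log2fc`, `se`, `p`, `q`, `n_strata`.
#' @export
ivw_meta <- function(strata) {
  if (length(strata) == 0) stop("no strata supplied")
  feats <- unique(unlist(lapply(strata, function(s) s$feature_id)))
  rows <- lapply(feats, function(fid) {
    b <- unlist(lapply(strata, function(s) s$log2fc[match(fid, s$feature_id)]))
    se <- unlist(lapply(strata, function(s) s$se[match(fid, s$feature_id)]))
    ok <- is.finite(b) & is.finite(se) & se > 0
    if (!any(ok))
      return(data.frame(feature_id = fid, log2fc = NA_real_, se = NA_real_,
                        p = NA_real_, n_strata = 0L, stringsAsFactors = FALSE))
    w <- 1 / se[ok]^2
    comb <- sum(w * b[ok]) / sum(w)
    comb_se <- 1 / sqrt(sum(w))
    data.frame(feature_id = fid, log2fc = comb, se = comb_se,
               # strong effects underflow to 0; floor inside (0, 1]
               p = max(2 * stats::pnorm(-abs(comb / comb_se)),
                       .Machine$double.xmin),
               n_strata = sum(ok), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- NA_real_
  ok <- !is.na(res$p)
  if (any(ok)) res$q[ok] <- bh_fdr(res$p[ok])
  res
}

#' Call differentially expressed features
#'
#' Applies the joint threshold: q <= `fdr` and |log2FC| >= `lfc`.
#'
#' @param meta data.frame from [ivw_meta()].
#' @param fdr FDR threshold (default 0.05).
#' @param lfc Absolute log2 fold-change threshold (default 1).
#' @return Character vector of called feature ids.
#' @export
apply_de_thresholds <- function(meta, fdr = 0.05, lfc = 1.0) {
  if (nrow(meta) == 0) return(character(0))
  called <- !is.na(meta$q) & meta$q <= fdr & abs(meta$log2fc) >= lfc
  meta$feature_id[called]
}

#' miRNA-mRNA expression association
#'
#' Per (miRNA, gene) pair, a linear model of transformed mRNA expression on
#' transformed miRNA expression plus covariates, with BH adjustment within
#' the chosen scope (all genes, or only predicted target pairs).
#'
#' @param mirna_expression,mrna_expression Transformed feature x sample
#'   matrices over the same samples.
#' @param covariates Optional covariate matrix.
#' @param scope `"all"` (every miRNA x gene pair) or `"targets"`.
#' @param target_pairs data.frame with `mirna_id`, `gene_id`, required when
#'   `scope = "targets"`.
#' @return data.frame: `variant_id` (NA; kept for schema compatibility with
#'   scan results), `feature_id` (the gene), `mirna_id`, `beta`, `se`, `p`,
#'   `q`, `n`, `scan_type`.
#' @export
mirna_mrna_association <- function(mirna_expression, mrna_expression,
                                   covariates = NULL,
                                   scope = c("all", "targets"),
                                   target_pairs = NULL) {
  scope <- match.arg(scope)
  n <- ncol(mirna_expression)
  if (ncol(mrna_expression) != n) stop("sample mismatch")
  if (n < 10) stop("need at least 10 paired samples")
  pairs <- if (scope == "all") {
    expand.grid(mirna_id = rownames(mirna_expression),
                gene_id = rownames(mrna_expression),
                stringsAsFactors = FALSE)
  } else {
    if (is.null(target_pairs)) stop("scope = 'targets' needs target_pairs")
    target_pairs[target_pairs$mirna_id %in% rownames(mirna_expression) &
                   target_pairs$gene_id %in% rownames(mrna_expression), ,
                 drop = FALSE]
  }
  if (nrow(pairs) == 0)
    return(data.frame(variant_id = character(0), feature_id = character(0),
                      mirna_id = character(0), beta = numeric(0),
                      se = numeric(0), p = numeric(0), q = numeric(0),
                      n = integer(0), scan_type = character(0)))
  W <- cbind(rep(1, n), covariates)
  out <- lapply(seq_len(nrow(pairs)), function(k) {
    m <- mirna_expression[pairs$mirna_id[k], ]
    y <- mrna_expression[pairs$gene_id[k], ]
    Xm <- cbind(m = m, W)
    XtXi <- solve(crossprod(Xm))
    beta_all <- XtXi %*% crossprod(Xm, y)
    rss <- sum((y - Xm %*% beta_all)^2)
    df <- n - ncol(Xm)
    se <- sqrt(rss / df * XtXi[1, 1])
    data.frame(variant_id = NA_character_, feature_id = pairs$gene_id[k],
               mirna_id = pairs$mirna_id[k], beta = beta_all[1], se = se,
               p = 2 * stats::pt(-abs(beta_all[1] / se), df),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$p <- pmax(res$p, .Machine$double.xmin)
  res$q <- bh_fdr(res$p)
  res$n <- n
  res$scan_type <- paste0("mirna_mrna_", scope)
  res
}
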