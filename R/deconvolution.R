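# Two-cell-type deconvolution of bulk small-RNA profiles from sorted-cell
# signatures, and the sensitivity re-analysis that adds the estimated beta
# fraction as a model covariate to probe cell-type-heterogeneity confounding.

#' Select signature features discriminating the two cell types
#'
#' Top-k features by |log2 ratio| between the two sorted profiles (a
#' pseudocount of 0.5 guards zeros).
#'
#' @param signatures Feature x 2 matrix of sorted-cell abundances.
#' @param k Number of features to keep (default 50).
#' @return Character vector of feature ids.
#' @export
select_signature_features <- function(signatures, k = 50) {
  lr <- abs(log2((signatures[, 1] + 0.5) / (signatures[, 2] + 0.5)))
  rownames(signatures)[order(-lr)][seq_len(min(k, nrow(signatures)))]
}

#' Estimate cell-type fractions by constrained least squares
#'
#' Bulk and signature profiles are put on a counts-per-million scale over the
#' signature features (mixing is linear in abundance, not log-abundance),
#' each sample's profile is regressed on the signature matrix by non-negative
#' least squares, and the fractions are renormalized to sum to 1.
#'
#' @param bulk Feature x sample matrix of bulk counts (or abundances).
#' @param signatures Feature x cell-type matrix (2 columns, e.g. alpha/beta).
#' @param features Optional subset of signature features to use; default
#'   [select_signature_features()] over all shared features.
#' @return data.frame: `sample_id`, one fraction column per cell type,
#'   `residual_norm`.
#' @export
estimate_fractions <- function(bulk, signatures, features = NULL) {
  if (ncol(signatures) < 2) stop("need two signature columns")
  shared <- intersect(rownames(bulk), rownames(signatures))
  if (length(shared) < 2) stop("need >= 2 shared signature features")
  if (is.null(features))
    features <- select_signature_features(signatures[shared, , drop = FALSE])
  features <- intersect(features, shared)
  S <- as.matrix(signatures[features, , drop = FALSE])
  if (max(abs(S[, 1] / sum(S[, 1]) - S[, 2] / sum(S[, 2]))) < 1e-12)
    stop("signatures collinear: cell-type profiles are indistinguishable")
  # depth-normalize the bulk only; the signatures keep their relative shape,
  # so the renormalized coefficients are the mixing weights of the supplied
  # profiles and the fit is invariant to bulk depth
  cpm <- function(m) sweep(m, 2, colSums(m), "/") * 1e6
  Sn <- S
  Bn <- cpm(as.matrix(bulk[features, , drop = FALSE]))
  out <- lapply(seq_len(ncol(Bn)), function(j) {
    fit <- pracma::lsqnonneg(Sn, Bn[, j])
    f <- fit$x
    if (sum(f) == 0) f <- rep(1 / length(f), length(f))
    data.frame(sample_id = colnames(Bn)[j], t(f / sum(f)),
               residual_norm = sqrt(fit$resid.norm))
  })
  res <- do.call(rbind, out)
  names(res)[1 + seq_len(ncol(S))] <- colnames(S)
  rownames(res) <- NULL
  res
}

#' Sensitivity re-analysis with a cell-fraction covariate
#'
#' Re-runs a supplied scan with the beta-cell fraction appended to the
#' covariates (only one fraction enters: under the sum-to-one constraint the
#' pair is collinear; a constant fraction vector is dropped with a warning)
#' and compares the paired effect estimates.
#'
#' @param scan_fn Function(covariates) -> results data.frame with a `beta`
#'   column and stable row identity (e.g. a closure over [assoc_scan()] or
#'   [nb_wald_de()]).
#' @param covariates Covariate matrix of the original fit (NULL allowed).
#' @param fractions Numeric vector: per-sample beta-cell fraction.
#' @return list with `comparison` (per-row `beta_without`, `beta_with`,
#'   `delta`), `pearson_r`, `max_abs_delta`.
#' @export
sensitivity_reanalysis <- function(scan_fn, covariates, fractions) {
  without <- scan_fn(covariates)
  if (stats::sd(fractions) == 0) {
    warning("cell-fraction covariate is constant; dropped (comparison degenerate)")
    with_cov <- covariates
  } else {
    with_cov <- cbind(covariates, cell_fraction = fractions)
  }
  with_ <- scan_fn(with_cov)
  eff_col <- if ("beta" %in% names(without)) "beta" else "log2fc"
  cmp <- data.frame(beta_without = without[[eff_col]],
                    beta_with = with_[[eff_col]])
  cmp$delta <- cmp$beta_with - cmp$beta_without
  ok <- stats::complete.cases(cmp)
  r <- if (sum(ok) >= 3 && stats::sd(cmp$beta_without[ok]) > 0 &&
           stats::sd(cmp$beta_with[ok]) > 0)
    stats::cor(cmp$beta_without[ok], cmp$beta_with[ok]) else NA_real_
  list(comparison = cmp, pearson_r = r,
       max_abs_delta = max(abs(cmp$delta[ok])))
}
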