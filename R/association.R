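# Single-variant association machinery: cis-eQTL and trans scans on
# transformed expression, Benjamini-Hochberg control pooled per scan,
# genotype x miRNA interaction models, the Wald-ratio Mendelian randomization
# estimate, and Sobel mediation.

#' Single-variant association scan
#'
#' For each requested (feature, variant) pair, ordinary least squares of the
#' transformed expression on the dosage plus covariates, with a two-sided
#' Wald p-value on the dosage coefficient. q-values are Benjamini-Hochberg,
#' pooled across all tests in the invocation (one scan = one FDR batch).
#'
#' @param expression Transformed feature x sample matrix.
#' @param genotypes A `genotype_matrix` (samples must match columns of
#'   `expression`).
#' @param covariates Optional numeric matrix of covariates.
#' @param pairs data.frame with columns `feature_id`, `variant_id`; by default
#'   every feature is paired with every variant in its cis window.
#' @param features Feature data.frame, needed when `pairs` is NULL to build
#'   cis windows.
#' @param window_size Cis window (bp) for the default pairing.
#' @param scan_type Label recorded on the results.
#' @return data.frame of class results: `variant_id`, `feature_id`, `beta`,
#'   `se`, `p`, `q`, `n`, `scan_type`.
#' @export
assoc_scan <- function(expression, genotypes, covariates = NULL, pairs = NULL,
                       features = NULL, window_size = 250000,
                       scan_type = "cis_eqtl") {
  n <- ncol(expression)
  if (n < 10) stop("need at least 10 samples")
  if (is.null(pairs)) {
    if (is.null(features)) stop("supply either pairs or features")
    pairs <- do.call(rbind, lapply(seq_len(nrow(features)), function(i) {
      cis <- partition_cis_trans(genotypes$variants, features[i, ],
                                 window_size)$cis
      if (length(cis) == 0) return(NULL)
      data.frame(feature_id = features$feature_id[i], variant_id = cis,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(pairs)) stop("no cis variants for any feature")
  }
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(W)$rank < ncol(W))
    stop("collinear covariates: ", paste(colnames(W), collapse = ", "))
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    g <- genotypes$dosage[, pairs$variant_id[k]]
    if (stats::sd(g) == 0) {
      out[[k]] <- data.frame(beta = NA_real_, se = NA_real_, p = NA_real_)
      next
    }
    y <- expression[pairs$feature_id[k], ]
    Xm <- cbind(g = g, W)
    XtXi <- solve(crossprod(Xm))
    beta_all <- XtXi %*% crossprod(Xm, y)
    rss <- sum((y - Xm %*% beta_all)^2)
    df <- n - ncol(Xm)
    se <- sqrt(rss / df * XtXi[1, 1])
    tstat <- beta_all[1] / se
    out[[k]] <- data.frame(beta = beta_all[1], se = se,
                           p = 2 * stats::pt(-abs(tstat), df))
  }
  res <- cbind(pairs[, c("variant_id", "feature_id")], do.call(rbind, out))
  res$q <- NA_real_
  ok <- !is.na(res$p)
  # perfect fits underflow to p = 0; floor at the smallest representable
  # double so the BH batch stays in (0, 1]
  res$p[ok] <- pmax(res$p[ok], .Machine$double.xmin)
  res$q[ok] <- bh_fdr(res$p[ok])
  res$n <- n
  res$scan_type <- scan_type
  rownames(res) <- NULL
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of p_(j) m / j, capped at
#' 1 (delegates to [stats::p.adjust()] after validating the inputs).
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values in the original order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Genotype x miRNA interaction test on a target transcript
#'
#' Fits target ~ genotype + miRNA + genotype:miRNA + covariates and reports
#' the Wald test on the product term, the model used to ask whether an eQTL
#' acts by perturbing miRNA binding.
#'
#' @param target_expression Numeric vector (transformed target expression).
#' @param dosage Genotype dosage vector.
#' @param mirna_expression Numeric vector (transformed miRNA expression).
#' @param covariates Optional covariate matrix.
#' @return One-row data.frame: `beta`, `se`, `p` for the interaction term,
#'   `n`, `scan_type = "interaction"`.
#' @export
interaction_test <- function(target_expression, dosage, mirna_expression,
                             covariates = NULL) {
  n <- length(target_expression)
  if (stats::sd(dosage) == 0) stop("genotype is constant")
  if (n < 20) warning("fewer than 20 samples: interaction test is fragile")
  X <- data.frame(y = target_expression, g = dosage, m = mirna_expression)
  fml <- y ~ g * m
  if (!is.null(covariates)) {
    X <- cbind(X, as.data.frame(covariates))
    fml <- stats::reformulate(c("g * m", colnames(covariates)), response = "y")
  }
  fit <- stats::lm(fml, data = X)
  co <- summary(fit)$coefficients["g:m", ]
  data.frame(beta = co[["Estimate"]], se = co[["Std. Error"]],
             p = co[["Pr(>|t|)"]], n = n, scan_type = "interaction")
}

#' Wald-ratio Mendelian randomization estimate
#'
#' beta_wald = beta_gy / beta_gx with the first-order delta-method standard
#' error sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 se_gx^2 / beta_gx^4).
#'
#' @param beta_gx,se_gx Instrument-exposure effect and SE.
#' @param beta_gy,se_gy Instrument-outcome effect and SE.
#' @return list with `beta_wald`, `se_wald`, `p`.
#' @export
mr_wald <- function(beta_gx, se_gx, beta_gy, se_gy) {
  if (beta_gx == 0) stop("instrument-exposure effect is zero")
  if (abs(beta_gx) / se_gx < 2)
    warning("weak instrument: |beta_gx| / se_gx < 2")
  beta_wald <- beta_gy / beta_gx
  se_wald <- sqrt(se_gy^2 / beta_gx^2 + beta_gy^2 * se_gx^2 / beta_gx^4)
  z <- beta_wald / se_wald
  list(beta_wald = beta_wald, se_wald = se_wald,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Sobel mediation analysis
#'
#' Product-of-coefficients mediation: `a` from mediator ~ exposure (+
#' covariates), `b` and the direct effect from outcome ~ exposure + mediator
#' (+ covariates); Sobel SE = sqrt(b^2 se_a^2 + a^2 se_b^2).
#'
#' @param exposure,mediator,outcome Numeric vectors.
#' @param covariates Optional covariate matrix.
#' @return list with `a`, `se_a`, `b`, `se_b`, `ab`, `sobel_se`, `sobel_p`,
#'   `direct`, `se_direct`.
#' @export
mediation_sobel <- function(exposure, mediator, outcome, covariates = NULL) {
  n <- length(exposure)
  p_cov <- if (is.null(covariates)) 0 else ncol(covariates)
  if (n <= p_cov + 3) stop("too few samples for mediation")
  dat <- data.frame(x = exposure, m = mediator, y = outcome)
  extra <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    dat <- cbind(dat, covariates)
    extra <- colnames(covariates)
  }
  fa <- summary(stats::lm(stats::reformulate(c("x", extra), "m"),
                          data = dat))$coefficients
  fb <- summary(stats::lm(stats::reformulate(c("x", "m", extra), "y"),
                          data = dat))$coefficients
  a <- fa["x", "Estimate"]; se_a <- fa["x", "Std. Error"]
  b <- fb["m", "Estimate"]; se_b <- fb["m", "Std. Error"]
  ab <- a * b
  sobel_se <- sqrt(b^2 * se_a^2 + a^2 * se_b^2)
  list(a = a, se_a = se_a, b = b, se_b = se_b, ab = ab,
       sobel_se = sobel_se,
       sobel_p = 2 * stats::pnorm(-abs(ab / sobel_se)),
       direct = fb["x", "Estimate"], se_direct = fb["x", "Std. Error"])
}

#' Effect-size concordance between two association result sets
#'
#' Joins on (variant_id, feature_id), harmonizes alleles when allele columns
#' are present (effect flipped when ref/alt are swapped; strand-ambiguous
#' A/T and C/G pairs dropped), and reports the Spearman correlation of the
#' harmonized effect sizes.
#'
#' @param results_a,results_b data.frames with `variant_id`, `feature_id`,
#'   `beta`, optionally `ref`/`alt`.
#' @return list with `rho`, `n_pairs`, `p`.
#' @export
effect_concordance <- function(results_a, results_b) {
  j <- merge(results_a, results_b, by = c("variant_id", "feature_id"),
             suffixes = c("_a", "_b"))
  if (nrow(j) == 0) stop("no overlapping (variant, feature) pairs")
  if (all(c("ref_a", "alt_a", "ref_b", "alt_b") %in% names(j))) {
    ambiguous <- function(r, a) paste0(r, a) %in% c("AT", "TA", "CG", "GC")
    j <- j[!ambiguous(j$ref_a, j$alt_a), , drop = FALSE]
    same <- j$ref_a == j$ref_b & j$alt_a == j$alt_b
    flipped <- j$ref_a == j$alt_b & j$alt_a == j$ref_b
    j <- j[same | flipped, , drop = FALSE]
    j$beta_b <- ifelse(j$ref_a == j$alt_b & j$alt_a == j$ref_b,
                       -j$beta_b, j$beta_b)
  }
  if (nrow(j) < 3) stop("fewer than 3 harmonized pairs")
  ct <- suppressWarnings(stats::cor.test(j$beta_a, j$beta_b,
                                         method = "spearman"))
  list(rho = unname(ct$estimate), n_pairs = nrow(j), p = ct$p.value)
}
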