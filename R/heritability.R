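# REML variance components: SNP-based heritability on a genome-wide GRM and
# the two-GRM cis/trans decomposition, plus the between-class comparative
# statistics (heritable-fraction chi-squared, h_trans Mann-Whitney U).
#
# Both fits profile out the overall scale, so the optimization runs over
# variance *fractions*: V = s^2 [ h_c K_cis + h_t K_trans + (1 - h_c - h_t) I ]
# with the REML profile likelihood evaluated by Cholesky factorization. The
# single-GRM fit diagonalizes K once so batches of features are cheap.

#' Transform a count matrix for variance-component and association models
#'
#' `"rint"` (default) applies a per-feature rank-based inverse-normal
#' transform (average ranks on ties, Blom-type offset 0.5), then centers and
#' scales exactly so each feature has mean 0 and unit variance.
#' `"sizefactor_log"` divides by median-of-ratios size factors and takes
#' log(x + 1).
#'
#' @param counts Feature x sample matrix.
#' @param method `"rint"` or `"sizefactor_log"`.
#' @return Numeric matrix, same shape; constant features are dropped with a
#'   warning under `"rint"` (their ranks are undefined).
#' @export
transform_expression <- function(counts, method = c("rint", "sizefactor_log")) {
  method <- match.arg(method)
  if (method == "sizefactor_log" && any(counts < 0))
    stop("counts must be non-negative")
  if (method == "rint") {
    const <- apply(counts, 1, function(x) stats::sd(x) == 0)
    if (any(const)) {
      warning(sum(const), " constant feature(s) skipped by the inverse-normal transform")
      counts <- counts[!const, , drop = FALSE]
    }
    if (nrow(counts) == 0) stop("no non-constant features to transform")
    t(apply(counts, 1, .rint))
  } else {
    sf <- size_factors(counts)
    log(sweep(counts, 2, sf, "/") + 1)
  }
}

.rint <- function(x) {
  r <- rank(x, ties.method = "average")
  q <- stats::qnorm((r - 0.5) / length(x))
  q <- q - mean(q)
  q / stats::sd(q)
}

#' Eigendecompose a kinship matrix for repeated single-GRM REML fits
#'
#' @param K A `kinship_matrix` or plain symmetric matrix.
#' @return Object of class `kinship_eigen` (`values`, `vectors`).
#' @export
kinship_eigen <- function(K) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  e <- eigen(K, symmetric = TRUE)
  e$values <- pmax(e$values, 0)
  structure(e, class = "kinship_eigen")
}

#' Single-GRM REML heritability
#'
#' Fits y = W a + u + e, u ~ N(0, sg^2 K), e ~ N(0, se^2 I) by REML on the
#' rotated (eigen) representation, profiling the total variance so the search
#' is one-dimensional over hg2 = sg^2 / (sg^2 + se^2).
#'
#' @param y Numeric response (a transformed feature vector).
#' @param K A `kinship_matrix`, matrix, or a pre-computed [kinship_eigen()]
#'   (pass the eigen form when fitting many features against one GRM).
#' @param covariates Optional numeric matrix of fixed effects (intercept is
#'   always included).
#' @return list with `hg2`, `sigma2_g`, `sigma2_e`, `loglik`, `converged`.
#' @export
fit_single_component <- function(y, K, covariates = NULL) {
  ek <- if (inherits(K, "kinship_eigen")) K else kinship_eigen(K)
  n <- length(y)
  if (nrow(ek$vectors) != n) stop("dimension mismatch between y and K")
  if (max(ek$values) - min(ek$values) < 1e-10)
    stop("unidentifiable: kinship matrix proportional to the identity")
  W <- cbind(`(Intercept)` = rep(1, n), covariates)
  p <- ncol(W)
  if (n <= p + 2) stop("too few samples for REML")
  yt <- crossprod(ek$vectors, y)
  Wt <- crossprod(ek$vectors, W)
  nll <- function(h) {
    d <- h * ek$values + (1 - h)
    Dw <- Wt / d
    XtX <- crossprod(Wt, Dw)
    b <- solve(XtX, crossprod(Dw, yt))
    r <- yt - Wt %*% b
    rss <- sum(r^2 / d)
    0.5 * (sum(log(d)) + determinant(XtX)$modulus[1] +
             (n - p) * log(rss / (n - p)))
  }
  opt <- stats::optimize(nll, interval = c(0, 1 - 1e-6), tol = 1e-8)
  # the boundary h = 0 is a frequent REML solution under the null; compare
  cand <- rbind(c(0, nll(0)), c(opt$minimum, opt$objective))
  best <- cand[which.min(cand[, 2]), ]
  h <- best[1]
  d <- h * ek$values + (1 - h)
  Dw <- Wt / d
  b <- solve(crossprod(Wt, Dw), crossprod(Dw, yt))
  s2 <- sum((yt - Wt %*% b)^2 / d) / (n - p)
  list(hg2 = h, sigma2_g = s2 * h, sigma2_e = s2 * (1 - h),
       loglik = -best[2], converged = TRUE)
}

# Profiled REML negative log-likelihood over (h_cis, h_trans) fractions.
.nll_two <- function(hc, ht, y, Kc, Kt, W) {
  n <- length(y); p <- ncol(W)
  V <- hc * Kc + ht * Kt + diag(1 - hc - ht, n)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) {
    R <- tryCatch(chol(V + diag(1e-8, n)), error = function(e) NULL)
    if (is.null(R)) return(1e10)
  }
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_W <- backsolve(R, forwardsolve(t(R), W))
  XtX <- crossprod(W, Vi_W)
  b <- solve(XtX, crossprod(Vi_W, y))
  rss <- sum(y * Vi_y) - 2 * sum(crossprod(W, Vi_y) * b) +
    sum(b * (XtX %*% b))
  if (rss <= 0) return(1e10)
  0.5 * (2 * sum(log(diag(R))) + determinant(XtX)$modulus[1] +
           (n - p) * log(rss / (n - p)))
}

#' Two-GRM REML decomposition of expression variance into cis and trans
#'
#' Fits y = W a + u_c + u_t + e with u_c ~ N(0, sc^2 K_cis), u_t ~ N(0,
#' st^2 K_trans), e ~ N(0, se^2 I). The profile REML likelihood is maximized
#' over the variance-fraction simplex via quasi-Newton (squared-parameter map
#' keeps fractions non-negative) from three fixed initializations, keeping the
#' best restricted log-likelihood; a coarse simplex grid is the fallback when
#' no start converges.
#'
#' @param y Transformed feature vector.
#' @param K_cis,K_trans `kinship_matrix` objects or plain matrices.
#' @param covariates Optional fixed-effect matrix (intercept always added).
#' @param feature_id Label carried into the output.
#' @param window_size Recorded in the output (bp).
#' @return One-row data.frame: `feature_id`, `sigma2_cis`, `sigma2_trans`,
#'   `sigma2_e`, `hg2`, `h_cis`, `h_trans`, `loglik`, `converged`,
#'   `window_size`.
#' @export
fit_two_component <- function(y, K_cis, K_trans, covariates = NULL,
                              feature_id = NA_character_,
                              window_size = NA_real_) {
  Kc <- if (inherits(K_cis, "kinship_matrix")) K_cis$K else K_cis
  Kt <- if (inherits(K_trans, "kinship_matrix")) K_trans$K else K_trans
  n <- length(y)
  if (nrow(Kc) != n || nrow(Kt) != n) stop("dimension mismatch")
  W <- cbind(rep(1, n), covariates)
  if (n <= ncol(W) + 2) stop("too few samples for REML")
  # map unconstrained (u, v) to the open simplex: h = u^2 etc., renormalized
  # only when the pair would leave it
  to_frac <- function(par) {
    h <- par^2
    s <- sum(h)
    if (s >= 0.999) h <- h / s * 0.999
    h
  }
  obj <- function(par) {
    h <- to_frac(par)
    .nll_two(h[1], h[2], y, Kc, Kt, W)
  }
  starts <- list(c(sqrt(0.1), sqrt(0.1)), c(sqrt(0.45), sqrt(0.1)),
                 c(sqrt(0.1), sqrt(0.45)))
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(stats::optim(s, obj, method = "L-BFGS-B",
                                 control = list(maxit = 200)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best) || !any_conv) {
    # bounded grid fallback over the fraction simplex
    grid <- expand.grid(hc = seq(0, 0.99, by = 0.03),
                        ht = seq(0, 0.99, by = 0.03))
    grid <- grid[grid$hc + grid$ht < 1, ]
    vals <- mapply(function(a, b) .nll_two(a, b, y, Kc, Kt, W),
                   grid$hc, grid$ht)
    i <- which.min(vals)
    best <- list(par = sqrt(as.numeric(grid[i, ])), value = vals[i])
    any_conv <- FALSE
  }
  # boundary candidates: REML often sits on an edge of the simplex
  h <- to_frac(best$par)
  cand <- rbind(h, c(0, 0), c(h[1] + h[2], 0), c(0, h[1] + h[2]))
  vals <- apply(cand, 1, function(x) .nll_two(x[1], x[2], y, Kc, Kt, W))
  h <- as.numeric(cand[which.min(vals), ])
  nll <- min(vals)
  hc <- h[1]; ht <- h[2]
  V <- hc * Kc + ht * Kt + diag(1 - hc - ht, n)
  R <- chol(V + diag(1e-10, n))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  Vi_W <- backsolve(R, forwardsolve(t(R), W))
  b <- solve(crossprod(W, Vi_W), crossprod(Vi_W, y))
  s2 <- (sum(y * Vi_y) - 2 * sum(crossprod(W, Vi_y) * b) +
           sum(b * (crossprod(W, Vi_W) %*% b))) / (n - ncol(W))
  data.frame(feature_id = feature_id,
             sigma2_cis = s2 * hc, sigma2_trans = s2 * ht,
             sigma2_e = s2 * (1 - hc - ht),
             hg2 = hc + ht, h_cis = hc, h_trans = ht,
             loglik = -nll, converged = any_conv,
             window_size = window_size,
             stringsAsFactors = FALSE)
}

#' Heritability and cis/trans decomposition for a batch of features
#'
#' Mirrors the study design: every feature is first classified by the
#' single-GRM fit on the genome-wide kinship matrix (heritable when hg2 >=
#' `heritable_threshold`), and the two-GRM cis/trans decomposition is then run
#' on the heritable features only. Trans kinship is derived from the exact
#' additivity K_all M_all = K_cis M_cis + K_trans M_trans.
#'
#' @param expression Transformed feature x sample matrix (see
#'   [transform_expression()]).
#' @param genotypes A `genotype_matrix`.
#' @param features Feature data.frame with coordinates (rows matching
#'   `rownames(expression)` by `feature_id`).
#' @param covariates Optional fixed-effect matrix.
#' @param window_size Cis window (bp).
#' @param heritable_threshold hg2 cutoff defining "heritable" (default 0.9).
#' @param decompose_all Decompose every feature rather than heritable only.
#' @return data.frame with one row per feature: single-GRM `hg2_single`,
#'   `heritable` flag, and (where decomposed) the [fit_two_component()] fields.
#' @export
decompose_features <- function(expression, genotypes, features,
                               covariates = NULL, window_size = 250000,
                               heritable_threshold = 0.9,
                               decompose_all = FALSE) {
  K_all <- compute_grm(genotypes)
  ek <- kinship_eigen(K_all)
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    fid <- features$feature_id[i]
    if (!fid %in% rownames(expression)) next
    y <- expression[fid, ]
    single <- fit_single_component(y, ek, covariates)
    heritable <- single$hg2 >= heritable_threshold
    row <- data.frame(feature_id = fid, hg2_single = single$hg2,
                      heritable = heritable, sigma2_cis = NA_real_,
                      sigma2_trans = NA_real_, sigma2_e = NA_real_,
                      hg2 = NA_real_, h_cis = NA_real_, h_trans = NA_real_,
                      loglik = NA_real_, converged = NA,
                      window_size = window_size, stringsAsFactors = FALSE)
    if (heritable || decompose_all) {
      part <- partition_cis_trans(genotypes$variants, features[i, ], window_size)
      if (length(part$cis) > 0 && length(part$trans) > 0) {
        K_cis <- compute_grm(genotypes, part$cis)
        M_all <- K_all$n_variants
        M_cis <- K_cis$n_variants
        M_trans <- M_all - M_cis
        K_trans <- (K_all$K * M_all - K_cis$K * M_cis) / M_trans
        dec <- fit_two_component(y, K_cis$K, K_trans, covariates,
                                 feature_id = fid, window_size = window_size)
        row[names(dec)[-1]] <- dec[-1]
        row$feature_id <- fid
      }
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Compare heritable fractions between two feature classes
#'
#' Pearson chi-squared test (no continuity correction, df = 1) on the 2x2
#' table of heritable vs not across the two classes.
#'
#' @param flags_a,flags_b Logical vectors of heritable flags for each class.
#' @return list with `table` (2x2), `chi2`, `p_chi2`.
#' @export
compare_heritable_fractions <- function(flags_a, flags_b) {
  if (length(flags_a) == 0 || length(flags_b) == 0)
    stop("each class needs at least one feature")
  tab <- rbind(A = c(heritable = sum(flags_a), not = sum(!flags_a)),
               B = c(heritable = sum(flags_b), not = sum(!flags_b)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate table: a zero marginal")
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(table = tab, chi2 = unname(ct$statistic), p_chi2 = ct$p.value)
}

#' Compare h_trans distributions between two feature classes
#'
#' Two-sided Mann-Whitney U test: exact enumeration when min(n, m) <= 8 with
#' no ties, otherwise the normal approximation with tie and continuity
#' corrections.
#'
#' @param htrans_a,htrans_b Numeric h_trans values per class.
#' @param alternative Passed to [stats::wilcox.test()] (default two-sided).
#' @return list with `U`, `p_mwu`, `median_a`, `median_b`.
#' @export
compare_htrans <- function(htrans_a, htrans_b, alternative = "two.sided") {
  if (length(htrans_a) == 0 || length(htrans_b) == 0)
    stop("each class needs at least one value")
  has_ties <- anyDuplicated(c(htrans_a, htrans_b)) > 0
  exact <- min(length(htrans_a), length(htrans_b)) <= 8 && !has_ties
  wt <- stats::wilcox.test(htrans_a, htrans_b, alternative = alternative,
                           exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p_mwu = wt$p.value,
       median_a = stats::median(htrans_a), median_b = stats::median(htrans_b))
}
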