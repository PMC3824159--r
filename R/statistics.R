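# The global gene-based statistics: Wald, MLC-B/Z, LC-B/Z, PC80, MinP-J/M,
# SSB, SSBw, SKAT and SKAT-C, each with its asymptotic null distribution.

test_result <- function(name, value, p_value, df = NA_integer_,
                        mixture_weights = NULL, analysis_set = NA_character_,
                        n_snps = NA_integer_, n_bins = NA_integer_) {
  structure(list(name = name, value = as.numeric(value),
                 df = df, mixture_weights = mixture_weights,
                 p_value = min(max(as.numeric(p_value), 0), 1),
                 analysis_set = analysis_set,
                 n_snps = n_snps, n_bins = n_bins),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$name, ": statistic = ", signif(x$value, 5),
      if (!is.na(x$df)) paste0(", df = ", x$df),
      if (!is.null(x$mixture_weights)) paste0(", mixture of ", length(x$mixture_weights), " chi2_1"),
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.test_result <- function(x, ...) {
  data.frame(statistic = x$name, value = x$value, df = x$df,
             p_value = x$p_value, analysis_set = x$analysis_set,
             n_snps = x$n_snps, n_bins = x$n_bins, row.names = NULL)
}

quad_form_inv <- function(b, S) {
  drop(crossprod(b, solve(S, b)))
}

#' Joint-regression Wald test
#'
#' Global test `b' S^{-1} b` of no association, with `b` the joint
#' coefficient vector and `S` its covariance; asymptotically chi-square
#' with K degrees of freedom.
#'
#' @param jf a [fit_joint()] result.
#' @return A `test_result`.
#' @export
wald_test <- function(jf) {
  q <- quad_form_inv(jf$beta, jf$cov)
  K <- jf$K
  test_result("Wald", q, stats::pchisq(q, K, lower.tail = FALSE),
              df = K, n_snps = K)
}

mlc_stat <- function(v, S, J) {
  A <- solve(S)
  AJ <- A %*% J
  M <- crossprod(J, AJ)                    # J' S^{-1} J
  u <- drop(crossprod(AJ, v))              # J' S^{-1} v  (= (Ws' v) up to M^{-1})
  drop(crossprod(u, solve(M, u)))          # v'A J (J'AJ)^{-1} J'A v
}

#' Multi-bin linear combination (MLC) tests
#'
#' Within each LD bin, coefficients are combined linearly with
#' covariance-derived weights `Ws = S^{-1} J (J' S^{-1} J)^{-1}`; the
#' within-bin combinations are then summed quadratically, giving
#' `(Ws'v)' (Ws' S Ws)^{-1} (Ws'v)`, chi-square with L (number of bins)
#' degrees of freedom under the null. Flavor `"B"` uses the joint betas
#' and their covariance; flavor `"Z"` the standardized Z statistics and
#' their correlation. With singleton bins (J = identity) MLC-B equals the
#' Wald test; with one all-SNP bin it equals the LC test.
#'
#' @param jf a [fit_joint()] result.
#' @param bins a `bin_assignment` computed on the same SNP set; SNPs
#'   dropped by the joint fit are removed from the indicator.
#' @param flavor `"B"` or `"Z"`.
#' @return A `test_result`.
#' @export
mlc_test <- function(jf, bins, flavor = c("B", "Z")) {
  flavor <- match.arg(flavor)
  J <- bin_indicator(bins, subset = jf$keep)
  v <- if (flavor == "B") jf$beta else jf$z
  S <- if (flavor == "B") jf$cov else jf$corr_z
  q <- mlc_stat(v, S, J)
  L <- ncol(J)
  test_result(paste0("MLC-", flavor), q,
              stats::pchisq(q, L, lower.tail = FALSE),
              df = L, n_snps = jf$K, n_bins = L)
}

#' Linear combination (LC) tests
#'
#' The one-bin special case of [mlc_test()]: all coefficients combined in
#' a single covariance-weighted linear combination, chi-square with 1 df.
#'
#' @inheritParams mlc_test
#' @return A `test_result`.
#' @export
lc_test <- function(jf, flavor = c("B", "Z")) {
  flavor <- match.arg(flavor)
  J <- matrix(1, nrow = jf$K, ncol = 1)
  v <- if (flavor == "B") jf$beta else jf$z
  S <- if (flavor == "B") jf$cov else jf$corr_z
  q <- mlc_stat(v, S, J)
  test_result(paste0("LC-", flavor), q,
              stats::pchisq(q, 1, lower.tail = FALSE),
              df = 1L, n_snps = jf$K, n_bins = 1L)
}

#' Principal-component regression test (PC80)
#'
#' Principal components of the centered genotype matrix (covariance PCA
#' by default, preserving MAF-driven variance structure) are computed;
#' the smallest leading set explaining more than `variance_fraction` of
#' the genotypic variance is kept, the trait is regressed on those S
#' components, and a Wald-type quadratic form on the S coefficients is
#' referred to chi-square with S df. With S = K the statistic equals the
#' joint-regression Wald test.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a [phenotype()] aligned with `gm`.
#' @param variance_fraction threshold of variance explained; default 0.80.
#' @param standardize use correlation (standardized) PCA instead.
#' @return A `test_result`.
#' @export
pc80_test <- function(gm, ph, variance_fraction = 0.80, standardize = FALSE) {
  Xc <- scale(gm$G, center = TRUE, scale = standardize)
  sv <- svd(Xc, nu = 0)
  vars <- sv$d^2
  cum <- cumsum(vars) / sum(vars)
  S <- if (any(cum > variance_fraction)) which(cum > variance_fraction)[1] else length(vars)
  P <- Xc %*% sv$v[, seq_len(S), drop = FALSE]
  prep <- .joint_prep_pc(P)
  n <- nrow(P)
  if (n <= S + 1L) stop("n <= S + 1; too many principal components")
  fit <- .joint_fit_y(prep, ph$y)
  q <- quad_form_inv(fit$beta, fit$cov)
  test_result("PC80", q, stats::pchisq(q, S, lower.tail = FALSE),
              df = S, n_snps = ncol(gm$G))
}

# PC scores are orthogonal by construction; skip the rank scan.
.joint_prep_pc <- function(P) {
  n <- nrow(P); S <- ncol(P)
  X <- cbind(`(Intercept)` = 1, P)
  XtX <- crossprod(X)
  XtX_inv <- chol2inv(chol(XtX))
  list(n = n, K = S, keep = seq_len(S), dropped = integer(0),
       X = X, XtX_inv = XtX_inv, H = XtX_inv %*% t(X),
       XtXc = crossprod(scale(P, center = TRUE, scale = FALSE)),
       df_resid = n - S - 1L)
}

# --- MinP -----------------------------------------------------------------

# Deterministic MVN rectangle probability: quasi-Monte-Carlo (Genz-Bretz)
# run under a locally fixed RNG state so results are reproducible and the
# caller's stream is untouched.
.pmvnorm_det <- function(lower, upper, R) {
  with_seed(680520L, {
    mvtnorm::pmvnorm(lower = lower, upper = upper, corr = R,
                     algorithm = mvtnorm::GenzBretz(abseps = 1e-6,
                                                    maxpts = 100000L))
  })
}

nearest_psd_corr <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol) return(R)
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  R2 <- stats::cov2cor(R2)
  warning("correlation matrix repaired to nearest PSD (perturbation norm ",
          signif(norm(R - R2, "F"), 3), ")")
  R2
}

#' Multivariate-normal adjustment of a minimum p-value
#'
#' Given the raw minimum of K two-sided normal p-values and the K x K
#' correlation matrix of the underlying Z statistics, computes the
#' multiplicity-adjusted p-value `1 - P(all |Zj| <= z*)` under
#' MVN(0, R), where `z*` is the normal quantile matching the raw minimum.
#' The rectangle probability uses quasi-Monte-Carlo integration with a
#' fixed internal seed. Equals the Sidak correction when R = I and the
#' raw minimum when all Z are perfectly correlated.
#'
#' @param p_min raw minimum two-sided p-value.
#' @param R correlation matrix of the Z statistics (repaired to the
#'   nearest PSD correlation if needed, with a warning).
#' @return Adjusted p-value in `[p_min, 1]`.
#' @export
mvn_minp_adjust <- function(p_min, R) {
  K <- nrow(R)
  if (K == 1L) return(p_min)
  if (all(abs(R[upper.tri(R)]) >= 1 - 1e-12)) return(p_min)  # degenerate MVN
  R <- nearest_psd_corr(R)
  zs <- stats::qnorm(1 - p_min / 2)
  prob <- .pmvnorm_det(rep(-zs, K), rep(zs, K), R)
  min(max(1 - as.numeric(prob), p_min), 1)
}

#' Minimum-p global test (MinP-J / MinP-M)
#'
#' The smallest per-SNP two-sided p-value among the joint (MinP-J) or
#' marginal (MinP-M) Z statistics, with a multiple-testing adjustment
#' under the multivariate normal null honoring the correlation between
#' estimates (a Bonferroni correction would be conservative under LD).
#'
#' @param fit a [fit_joint()] or [fit_marginals()] result.
#' @return A `test_result` whose `value` is the raw minimum p and whose
#'   `p_value` is the MVN-adjusted p.
#' @export
minp_test <- function(fit) {
  if (inherits(fit, "joint_fit")) {
    z <- fit$z; R <- fit$corr_z; name <- "MinP-J"
  } else if (inherits(fit, "marginal_fit")) {
    z <- fit$z_m; R <- fit$corr_zm; name <- "MinP-M"
  } else stop("fit must be a joint_fit or marginal_fit")
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_min <- min(p_raw)
  test_result(name, p_min, mvn_minp_adjust(p_min, R),
              n_snps = length(z))
}

# --- quadratic marginal statistics ----------------------------------------

clip_weights <- function(w) {
  tol <- 1e-10 * max(abs(w), 1e-300)
  neg <- w < 0
  if (any(w[neg] < -tol))
    warning("clipping ", sum(w[neg] < -tol), " negative mixture weight(s) to zero")
  w <- pmax(w, 0)
  w[w > 0]
}

#' Tail probability of a weighted mixture of chi-square(1) variables
#'
#' Null law `sum_i c_i chi2_1` arising for the quadratic statistics (SSB,
#' SSBw, SKAT, SKAT-C). The default is Liu-type moment matching (mean,
#' variance, skewness matched to a noncentral chi-square surrogate);
#' `method = "davies"` (alias `"imhof"`) computes the exact tail by
#' numerical inversion of the characteristic function (Imhof's integral).
#' Small negative weights from numerical noise are clipped to zero.
#'
#' @param q observed statistic.
#' @param weights non-negative mixture weights `c_i`.
#' @param method `"liu"`, `"davies"` or `"imhof"`.
#' @return p-value, clipped to `[1e-16, 1]`.
#' @export
mixture_chisq_pvalue <- function(q, weights, method = c("liu", "davies", "imhof")) {
  method <- match.arg(method)
  w <- clip_weights(as.numeric(weights))
  if (length(w) == 0L) stop("all mixture weights are zero")
  p <- if (method == "liu") liu_pvalue(q, w) else imhof_pvalue(q, w)
  min(max(p, 1e-16), 1)
}

# Liu, Tang & Zhang moment matching: central/noncentral chi-square surrogate
# matching mean, variance and skewness of the mixture.
liu_pvalue <- function(q, w) {
  c1 <- sum(w); c2 <- sum(w^2); c3 <- sum(w^3); c4 <- sum(w^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    delta <- 0
    l <- 1 / s2
  }
  mu_x <- l + delta
  sigma_x <- sqrt(2 * (l + 2 * delta))
  t <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(t * sigma_x + mu_x, df = l, ncp = delta, lower.tail = FALSE)
}

# Imhof's exact inversion of the characteristic function for a central
# weighted chi-square mixture: P(Q > q) = 1/2 + (1/pi) Int_0^U sin(theta)/(u rho) du,
# truncated at U where the integrand envelope bounds the tail below eps.
# One weight (or all equal) is a scaled chi-square, handled exactly.
imhof_pvalue <- function(q, w, eps = 1e-5) {
  m <- length(w)
  if (diff(range(w)) < 1e-14 * max(w))
    return(stats::pchisq(q / w[1], df = m, lower.tail = FALSE))
  U <- (1 / (pi * eps * (m / 2) * sqrt(prod(w))))^(2 / m)
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(w, u))) - 0.5 * q * u
    lrho <- 0.25 * colSums(log1p(outer(w^2, u^2)))
    sin(theta) / (u * exp(lrho))
  }
  int <- stats::integrate(f, 0, U, rel.tol = 1e-7, abs.tol = 1e-9,
                          subdivisions = 100000L, stop.on.error = FALSE)
  0.5 + int$value / pi
}

.ssb_eval <- function(beta_m, z_m, cov_m, corr, weighted, method) {
  if (weighted) {
    q <- sum(z_m^2)
    w <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
    name <- "SSBw"
  } else {
    q <- sum(beta_m^2)
    w <- eigen(cov_m, symmetric = TRUE, only.values = TRUE)$values
    name <- "SSB"
  }
  list(name = name, q = q, w = w,
       p = mixture_chisq_pvalue(q, w, method))
}

#' Sum of squared marginal betas (SSB / SSBw)
#'
#' `SSB = sum(beta_m^2)`; `SSBw` weights each squared coefficient by the
#' inverse of its variance (i.e. sums the squared marginal Z statistics).
#' Null distributions are mixtures of chi-square(1) with weights the
#' eigenvalues of the GEE-type covariance (SSB) or of its correlation
#' matrix (SSBw).
#'
#' @param mf a [fit_marginals()] result.
#' @param weighted `TRUE` for SSBw.
#' @param method p-value method, see [mixture_chisq_pvalue()].
#' @return A `test_result`.
#' @export
ssb_test <- function(mf, weighted = FALSE, method = "liu") {
  r <- .ssb_eval(mf$beta_m, mf$z_m, mf$cov_m, mf$corr_zm, weighted, method)
  test_result(r$name, r$q, r$p, mixture_weights = r$w, n_snps = mf$K)
}

# --- SKAT family ----------------------------------------------------------

skat_weights <- function(maf, scheme = c("lf", "common")) {
  scheme <- match.arg(scheme)
  if (scheme == "lf") stats::dbeta(maf, 1, 25)^2 else stats::dbeta(maf, 0.5, 0.5)^2
}

# B = Gc diag(sqrt(w)); Q = || B' yc ||^2; null weights = sigma0^2 * eigen(B'B)
.skat_prep <- function(G, w) {
  Gc <- scale(G, center = TRUE, scale = FALSE)
  B <- sweep(Gc, 2, sqrt(w), `*`)
  lam <- eigen(crossprod(B), symmetric = TRUE, only.values = TRUE)$values
  list(B = B, lam = lam)
}

#' Sequence kernel association test (SKAT)
#'
#' Variance-component score statistic `Q = yc' Gc W Gc' yc` with
#' MAF-based weights `w_i = dbeta(p_i; 1, 25)^2` (the low-frequency
#' scheme) or `dbeta(p_i; 0.5, 0.5)^2` (the common-variant scheme used
#' inside SKAT-C). The trait and genotypes are mean-centered, which is
#' what makes the mixture-of-chi-square null exact under the
#' intercept-only null model. Null weights are `s2 *` eigenvalues of
#' `W^{1/2} Gc'Gc W^{1/2}` with `s2` the null trait variance.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a [phenotype()] aligned with `gm`.
#' @param weight_scheme `"lf"` (Beta(1,25)) or `"common"` (Beta(0.5,0.5)).
#' @param method p-value method, see [mixture_chisq_pvalue()].
#' @return A `test_result`.
#' @export
skat_test <- function(gm, ph, weight_scheme = c("lf", "common"), method = "liu") {
  weight_scheme <- match.arg(weight_scheme)
  w <- skat_weights(gm$snps$maf, weight_scheme)
  prep <- .skat_prep(gm$G, w)
  yc <- ph$y - mean(ph$y)
  q <- sum(drop(crossprod(prep$B, yc))^2)
  sigma2 <- stats::var(ph$y)
  cw <- sigma2 * prep$lam
  test_result("SKAT", q, mixture_chisq_pvalue(q, cw, method),
              mixture_weights = cw, n_snps = ncol(gm$G))
}

#' Combined-set SKAT (SKAT-C)
#'
#' `SKAT-C = phi * SKAT_LF + (1 - phi) * SKAT_common`, the low-frequency
#' component weighted by Beta(1,25)^2 and the common component by
#' Beta(0.5,0.5)^2, with mixing proportion
#' `phi = SD(SKAT_LF) / (SD(SKAT_LF) + SD(SKAT_common))` where SD is each
#' component's null standard deviation `sqrt(2 sum c_i^2)`. The combined
#' null weights are the eigenvalues of the phi-scaled block-weighted
#' kernel built on the concatenated genotype blocks, so correlation
#' between the components is honored. If one subset is empty the
#' statistic falls back to the single-set SKAT (with a message).
#'
#' @param gm_lf [genotype_matrix()] of low frequency SNPs (or `NULL`).
#' @param gm_common [genotype_matrix()] of common SNPs (or `NULL`).
#' @param ph a [phenotype()].
#' @param method p-value method, see [mixture_chisq_pvalue()].
#' @return A `test_result`; the `phi` used is attached as attribute `"phi"`.
#' @export
skat_c_test <- function(gm_lf, gm_common, ph, method = "liu") {
  has_lf <- !is.null(gm_lf) && ncol(gm_lf$G) > 0
  has_c <- !is.null(gm_common) && ncol(gm_common$G) > 0
  if (!has_lf && !has_c) stop("both variant subsets are empty")
  if (!has_lf || !has_c) {
    message("SKAT-C: one variant subset empty; falling back to single-set SKAT")
    gm1 <- if (has_lf) gm_lf else gm_common
    res <- skat_test(gm1, ph, if (has_lf) "lf" else "common", method)
    res$name <- "SKAT-C"
    attr(res, "phi") <- if (has_lf) 1 else 0
    return(res)
  }
  yc <- ph$y - mean(ph$y)
  sigma2 <- stats::var(ph$y)
  p_lf <- .skat_prep(gm_lf$G, skat_weights(gm_lf$snps$maf, "lf"))
  p_c <- .skat_prep(gm_common$G, skat_weights(gm_common$snps$maf, "common"))
  sd_lf <- sqrt(2 * sum((sigma2 * p_lf$lam)^2))
  sd_c <- sqrt(2 * sum((sigma2 * p_c$lam)^2))
  phi <- sd_lf / (sd_lf + sd_c)
  q_lf <- sum(drop(crossprod(p_lf$B, yc))^2)
  q_c <- sum(drop(crossprod(p_c$B, yc))^2)
  q <- phi * q_lf + (1 - phi) * q_c
  Bcomb <- cbind(sqrt(phi) * p_lf$B, sqrt(1 - phi) * p_c$B)
  lam <- eigen(crossprod(Bcomb), symmetric = TRUE, only.values = TRUE)$values
  cw <- sigma2 * lam
  res <- test_result("SKAT-C", q, mixture_chisq_pvalue(q, cw, method),
                     mixture_weights = cw,
                     n_snps = ncol(gm_lf$G) + ncol(gm_common$G))
  attr(res, "phi") <- phi
  res
}
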