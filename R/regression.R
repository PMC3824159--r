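# Joint (multiple) and marginal (single-SNP) regression engines. Both are
# split into a genotype-only "prep" stage and a cheap per-trait stage so
# simulation studies with fixed genotypes can reuse the decompositions.

# --- joint model -----------------------------------------------------------

.joint_prep <- function(G) {
  n <- nrow(G); K <- ncol(G)
  Xc <- scale(G, center = TRUE, scale = FALSE)
  # deterministic collinearity drops: keep lowest indices giving full rank
  keep <- integer(0)
  for (j in seq_len(K)) {
    cand <- c(keep, j)
    if (qr(Xc[, cand, drop = FALSE])$rank == length(cand)) keep <- cand
  }
  dropped <- setdiff(seq_len(K), keep)
  k <- length(keep)
  if (n <= k + 1L)
    stop("n <= K + 1 after drops; use a smaller analysis set")
  X <- cbind(`(Intercept)` = 1, G[, keep, drop = FALSE])
  XtX <- crossprod(X)
  XtX_inv <- tryCatch(chol2inv(chol(XtX)),
                      error = function(e) stop("design matrix rank deficient after drops"))
  list(n = n, K = K, keep = keep, dropped = dropped,
       X = X, XtX_inv = XtX_inv, H = XtX_inv %*% t(X),
       XtXc = crossprod(Xc[, keep, drop = FALSE]),
       df_resid = n - k - 1L)
}

.joint_fit_y <- function(prep, y) {
  coefs <- drop(prep$H %*% y)
  resid <- y - drop(prep$X %*% coefs)
  sigma2 <- sum(resid^2) / prep$df_resid
  cov <- sigma2 * prep$XtX_inv[-1, -1, drop = FALSE]
  beta <- coefs[-1]
  z <- beta / sqrt(diag(cov))
  structure(list(beta = beta, cov = cov, z = z,
                 corr_z = stats::cov2cor(cov), sigma2 = sigma2,
                 dropped = prep$dropped, keep = prep$keep,
                 n = prep$n, K = length(prep$keep), K_input = prep$K,
                 XtXc = prep$XtXc),
            class = "joint_fit")
}

#' Fit the joint multi-SNP regression
#'
#' Ordinary least squares of the trait on all K SNPs plus an intercept:
#' `E[Y] = b0 + b1 X1 + ... + bK XK`. Returns the coefficient vector and
#' its covariance (the residual-variance-scaled block of `(X'X)^{-1}`),
#' the standardized Z statistics and their correlation. Columns that are
#' sample-collinear are dropped deterministically (lowest indices kept)
#' and recorded in `dropped`.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a [phenotype()] aligned with `gm` (see [join_phenotype()]).
#' @return Object of class `joint_fit`: `beta`, `cov`, `z`, `corr_z`,
#'   `sigma2`, `dropped`, `keep`, `n`, `K`.
#' @export
fit_joint <- function(gm, ph) {
  stopifnot(length(ph$y) == nrow(gm$G))
  .joint_fit_y(.joint_prep(gm$G), ph$y)
}

#' @export
print.joint_fit <- function(x, ...) {
  cat("joint_fit: K =", x$K, "SNPs, n =", x$n,
      if (length(x$dropped)) paste0("(", length(x$dropped), " dropped)"), "\n")
  invisible(x)
}

#' @export
as.data.frame.joint_fit <- function(x, ...) {
  data.frame(snp = names(x$beta), beta = x$beta, se = sqrt(diag(x$cov)),
             z = x$z, row.names = NULL)
}

# --- marginal models -------------------------------------------------------

.marg_prep <- function(G) {
  Gc <- scale(G, center = TRUE, scale = FALSE)
  sxx <- colSums(Gc^2)
  if (any(sxx == 0)) stop("zero-variance genotype column in marginal fit")
  M <- crossprod(Gc)                       # x_i' x_j (centered)
  list(n = nrow(G), K = ncol(G), Gc = Gc, sxx = sxx, M = M,
       Mnorm = M / tcrossprod(sxx))        # (x_i'x_j)/((x_i'x_i)(x_j'x_j))
}

.marg_fit_y <- function(prep, y) {
  beta_m <- drop(crossprod(prep$Gc, y)) / prep$sxx
  sigma2 <- stats::var(y)                  # intercept-only (null) trait variance
  cov_m <- sigma2 * prep$Mnorm
  z_m <- beta_m / sqrt(diag(cov_m))
  structure(list(beta_m = beta_m, cov_m = cov_m, z_m = z_m,
                 corr_zm = stats::cov2cor(cov_m), sigma2 = sigma2,
                 n = prep$n, K = prep$K),
            class = "marginal_fit")
}

#' Fit the K marginal single-SNP regressions
#'
#' One simple regression per SNP, `E[Y] = b0j + bj Xj`, with the
#' cross-covariance of the marginal estimates obtained by a GEE-type
#' construction: `Cov(bi, bj) = s2 (xi'xj) / ((xi'xi)(xj'xj))` with
#' centered genotype columns and `s2` the trait variance under the
#' intercept-only null model. Under this construction the correlation of
#' the marginal estimates equals the genotype correlation exactly.
#'
#' @inheritParams fit_joint
#' @return Object of class `marginal_fit`: `beta_m`, `cov_m`, `z_m`,
#'   `corr_zm`, `sigma2`, `n`, `K`.
#' @export
fit_marginals <- function(gm, ph) {
  stopifnot(length(ph$y) == nrow(gm$G))
  if (length(ph$y) < 3L) stop("marginal fits need n >= 3")
  .marg_fit_y(.marg_prep(gm$G), ph$y)
}

#' @export
print.marginal_fit <- function(x, ...) {
  cat("marginal_fit: K =", x$K, "SNPs, n =", x$n, "\n")
  invisible(x)
}

#' @export
as.data.frame.marginal_fit <- function(x, ...) {
  data.frame(snp = colnames(x$cov_m) %||% paste0("snp", seq_len(x$K)),
             beta_m = x$beta_m, se_m = sqrt(diag(x$cov_m)), z_m = x$z_m,
             row.names = NULL)
}
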