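# Omitted-causal-variant theory: expected joint and marginal regression
# coefficients of typed SNPs when the causal variant(s) are untyped.

#' Specify a causal trait model
#'
#' The additive model `Y = a1 C1 (+ a2 C2) + e`, `e ~ N(0, sigma^2)`,
#' with the causal genotype columns held outside the analysis set (the
#' omitted-variable setting).
#'
#' @param C n x 1 or n x 2 matrix of causal genotype codes (0/1/2).
#' @param effects numeric effects `a1` (and `a2`), one per causal column.
#' @param error_sd residual SD sigma; may be `NA` until calibrated.
#' @return Object of class `causal_model`.
#' @export
causal_model <- function(C, effects, error_sd = NA_real_) {
  C <- as.matrix(C)
  if (!ncol(C) %in% 1:2) stop("causal model supports one or two causal variants")
  if (length(effects) != ncol(C)) stop("one effect per causal column required")
  if (any(!is.finite(effects))) stop("effects must be finite")
  if (!is.na(error_sd) && (error_sd < 1e-4 - 1e-12 || error_sd > 100))
    warning("error_sd outside the calibration range [0.0001, 100]")
  structure(list(C = C, effects = as.numeric(effects),
                 error_sd = error_sd), class = "causal_model")
}

check_causal_omitted <- function(gm, cm, allow_causal_in_set = FALSE) {
  if (allow_causal_in_set) return(invisible())
  for (m in seq_len(ncol(cm$C))) {
    same <- apply(gm$G, 2, function(col) all(col == cm$C[, m]))
    if (any(same))
      stop("causal variant duplicated inside the analysis set (column ",
           which(same)[1], "); the omitted-variable premise is violated")
  }
  invisible()
}

#' Expected joint-regression coefficients under an omitted causal model
#'
#' When the causal variant C is untyped, the expected coefficient vector
#' of the typed SNPs in the joint regression is `a1 * d`, where `d` holds
#' the least-squares slopes of C regressed on the typed SNPs (plus
#' intercept); with two causal variants, `a1 * e + a2 * f` with `e`, `f`
#' the slope vectors of C1 and C2. Slopes are the sample least-squares
#' slopes for the supplied genotypes, making the simulation-consistency
#' property exact in expectation for that sample.
#'
#' @param gm analysis-set [genotype_matrix()] (causal columns excluded).
#' @param cm a [causal_model()].
#' @param allow_causal_in_set skip the omitted-causal check (testing aid).
#' @return Named length-K numeric vector of expected coefficients.
#' @export
expected_joint_betas <- function(gm, cm, allow_causal_in_set = FALSE) {
  check_causal_omitted(gm, cm, allow_causal_in_set)
  prep <- .joint_prep(gm$G)
  out <- numeric(ncol(gm$G))
  for (m in seq_len(ncol(cm$C))) {
    slopes <- drop(prep$H %*% cm$C[, m])[-1]
    d <- numeric(ncol(gm$G))
    d[prep$keep] <- slopes
    out <- out + cm$effects[m] * d
  }
  names(out) <- gm$snps$id
  out
}

#' Expected marginal-regression coefficients under an omitted causal model
#'
#' Per typed SNP i, `E[bi^M] = sum_m a_m rho(Cm, Xi) sd(Cm) / sd(Xi)`.
#' SDs are sample SDs when genotypes are available (`sd_method =
#' "sample"`), or the Hardy-Weinberg / haplotype-pairing form
#' `sqrt(2 p (1-p))` from the MAFs (`sd_method = "maf"`).
#'
#' @inheritParams expected_joint_betas
#' @param sd_method `"sample"` or `"maf"`.
#' @return Named length-K numeric vector.
#' @export
expected_marginal_betas <- function(gm, cm, sd_method = c("sample", "maf"),
                                    allow_causal_in_set = FALSE) {
  sd_method <- match.arg(sd_method)
  check_causal_omitted(gm, cm, allow_causal_in_set)
  out <- numeric(ncol(gm$G))
  sd_x <- if (sd_method == "sample") apply(gm$G, 2, stats::sd)
          else sqrt(2 * gm$snps$maf * (1 - gm$snps$maf))
  for (m in seq_len(ncol(cm$C))) {
    Cm <- cm$C[, m]
    rho <- drop(stats::cor(Cm, gm$G))
    p_c <- min(mean(Cm) / 2, 1 - mean(Cm) / 2)
    sd_c <- if (sd_method == "sample") stats::sd(Cm) else sqrt(2 * p_c * (1 - p_c))
    out <- out + cm$effects[m] * rho * sd_c / sd_x
  }
  names(out) <- gm$snps$id
  out
}

beta_summary <- function(v) {
  c(frac_gt_0.5 = mean(abs(v) > 0.5), sum = sum(v), sum_abs = sum(abs(v)),
    mean = mean(v), mean_abs = mean(abs(v)))
}

#' Expected coefficients (joint and marginal) with summaries
#'
#' Convenience wrapper computing [expected_joint_betas()] and
#' [expected_marginal_betas()] with the per-gene summaries used to
#' characterize trait models (fraction of |beta| > 0.5, sum, absolute
#' sum, mean, absolute mean).
#'
#' @inheritParams expected_marginal_betas
#' @return Object of class `expected_betas`: `joint`, `marginal`,
#'   `summaries` (data.frame, one row per method).
#' @export
expected_betas <- function(gm, cm, sd_method = "sample",
                           allow_causal_in_set = FALSE) {
  joint <- expected_joint_betas(gm, cm, allow_causal_in_set)
  marginal <- expected_marginal_betas(gm, cm, sd_method, allow_causal_in_set)
  structure(list(joint = joint, marginal = marginal,
                 summaries = summarize_expected_betas_raw(joint, marginal)),
            class = "expected_betas")
}

summarize_expected_betas_raw <- function(joint, marginal) {
  s <- rbind(joint = beta_summary(joint), marginal = beta_summary(marginal))
  data.frame(method = rownames(s), s, row.names = NULL)
}

#' Summaries of an expected-coefficient set
#' @param eb an `expected_betas` object.
#' @return data.frame with the per-method summaries.
#' @export
summarize_expected_betas <- function(eb) {
  summarize_expected_betas_raw(eb$joint, eb$marginal)
}

#' @export
print.expected_betas <- function(x, ...) {
  cat("expected_betas over", length(x$joint), "SNPs\n")
  print(x$summaries, digits = 4)
  invisible(x)
}

#' Pool-expected coefficients from haplotype frequencies
#'
#' Design-stage version of the omitted-causal expectations: the genotype
#' covariance under random haplotype pairing is twice the haplotype
#' allele covariance, so joint slopes are obtained from the pool allele
#' covariance directly and marginal slopes from pool allele correlations
#' and frequencies.
#'
#' @param pool a [generate_pool()] result.
#' @param analysis_sites integer indices of typed sites.
#' @param causal_sites integer indices of the causal site(s) (not in the
#'   analysis set).
#' @param effects effect sizes, one per causal site.
#' @return List with `joint` and `marginal` expected-coefficient vectors.
#' @export
pool_expected_betas <- function(pool, analysis_sites, causal_sites, effects) {
  if (any(causal_sites %in% analysis_sites))
    stop("causal sites must be omitted from the analysis set")
  A <- pool$alleles
  S <- stats::cov(A)            # genotype covariance = 2 * S; the 2 cancels
  Saa <- S[analysis_sites, analysis_sites, drop = FALSE]
  joint <- numeric(length(analysis_sites))
  marginal <- numeric(length(analysis_sites))
  sd_a <- sqrt(diag(Saa))
  for (m in seq_along(causal_sites)) {
    sac <- S[analysis_sites, causal_sites[m]]
    joint <- joint + effects[m] * drop(solve(Saa, sac))
    marginal <- marginal + effects[m] * sac / sd_a^2 * 1  # slope = cov/var
  }
  list(joint = joint, marginal = marginal)
}
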