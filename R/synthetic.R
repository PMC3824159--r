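# Seeded synthetic-data engine: haplotype pools with controlled MAF bands
# and LD profile, diploid genotypes by random haplotype pairing, additive
# causal trait models, and noncentrality-based variance calibration.

#' Specification of a synthetic gene panel
#'
#' Structural constraints for the generator: a gene of 8-15 biallelic
#' SNPs with MAF >= 1%, at least one r^2-bin containing
#' `lf_bin_min` or more low frequency SNPs (1% <= MAF < 5%), and a mean
#' pairwise |r| inside `mean_abs_r_band` (default the 0.17-0.59 range
#' observed across real gene panels, centered near 0.37). The haplotype
#' pool defaults to 340 haplotypes (170 diploid founders).
#'
#' @param n_snps target SNP count, or `NULL` to draw from 8:15.
#' @param lf_bin_min minimum number of correlated low frequency SNPs
#'   required in one bin (default 3).
#' @param mean_abs_r_band acceptance band for the mean pairwise |r|.
#' @param n_haplotypes pool size H (even).
#' @param bin_r2 r^2 binning threshold used for the structural check.
#' @param max_attempts rejection-sampling cap.
#' @param seed integer seed driving the generator.
#' @return Object of class `gene_panel_spec`.
#' @export
gene_panel_spec <- function(n_snps = NULL, lf_bin_min = 3,
                            mean_abs_r_band = c(0.17, 0.59),
                            n_haplotypes = 340, bin_r2 = 0.5,
                            max_attempts = 500, seed = NULL) {
  if (n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")
  if (!is.null(n_snps) && (n_snps < 8 || n_snps > 15))
    stop("n_snps must lie in [8, 15]")
  if (lf_bin_min < 2) stop("lf_bin_min must be at least 2")
  structure(list(n_snps = n_snps, lf_bin_min = lf_bin_min,
                 mean_abs_r_band = mean_abs_r_band,
                 n_haplotypes = n_haplotypes, bin_r2 = bin_r2,
                 max_attempts = max_attempts, seed = seed),
            class = "gene_panel_spec")
}

# one unconstrained pool draw; constraints are checked by the caller
.draw_pool <- function(spec) {
  H <- spec$n_haplotypes
  K <- spec$n_snps %||% sample(8:15, 1)
  cl <- min(spec$lf_bin_min + stats::rbinom(1, 1, 0.5), K - 2)
  cl_start <- sample(seq_len(K - cl + 1), 1)
  cl_idx <- seq(cl_start, length.out = cl)

  freqs <- numeric(K)
  freqs[cl_idx] <- stats::runif(cl, 0.015, 0.045)
  other <- setdiff(seq_len(K), cl_idx)
  is_common <- stats::runif(length(other)) < 0.75
  freqs[other[is_common]] <- stats::runif(sum(is_common), 0.08, 0.45)
  freqs[other[!is_common]] <- stats::runif(sum(!is_common), 0.013, 0.045)

  A <- matrix(0L, H, K)

  # low-frequency cluster: correlated carrier sets (carrier-copy scheme)
  carriers <- sample(H, max(round(freqs[cl_idx[1]] * H), 4))
  A[carriers, cl_idx[1]] <- 1L
  for (j in cl_idx[-1]) {
    target <- max(round(freqs[j] * H), 4)
    kept <- carriers[stats::runif(length(carriers)) < 0.92]
    if (length(kept) > target) kept <- sample(kept, target)
    if (length(kept) < target)
      kept <- c(kept, sample(setdiff(seq_len(H), kept), target - length(kept)))
    A[kept, j] <- 1L
    carriers <- which(A[, cl_idx[1]] == 1L)
  }

  # remaining sites: latent first-order Gaussian chain, thresholded
  if (length(other) > 0) {
    z <- matrix(0, H, length(other))
    z[, 1] <- stats::rnorm(H)
    if (length(other) > 1) {
      for (k in 2:length(other)) {
        rho <- stats::runif(1, 0.80, 0.97)
        z[, k] <- rho * z[, k - 1] + sqrt(1 - rho^2) * stats::rnorm(H)
      }
    }
    for (k in seq_along(other)) {
      j <- other[k]
      A[, j] <- as.integer(z[, k] < stats::qnorm(freqs[j]))
    }
  }

  # realized pool: recode to minor allele, drop unusable sites
  p <- colMeans(A)
  flip <- p > 0.5
  A[, flip] <- 1L - A[, flip]
  p[flip] <- 1 - p[flip]
  keep <- p >= 0.01 & p <= 0.5 & p > 0
  A <- A[, keep, drop = FALSE]
  p <- p[keep]
  list(A = A, p = p)
}

.check_pool <- function(A, p, spec) {
  K <- ncol(A)
  if (K < 8 || K > 15) return("snp_count")
  v <- apply(A, 2, stats::var)
  if (any(v == 0)) return("monomorphic")
  R <- stats::cor(A)
  bins <- ldselect_bins(R, spec$bin_r2)
  lf <- p >= 0.01 & p < 0.05
  lf_per_bin <- tapply(lf, bins$bin_of, sum)
  if (!any(lf_per_bin >= spec$lf_bin_min)) return("lf_bin")
  mar <- mean(abs(R[upper.tri(R)]))
  if (mar < spec$mean_abs_r_band[1] || mar > spec$mean_abs_r_band[2])
    return("mean_abs_r")
  NULL
}

#' Generate a haplotype pool meeting the panel constraints
#'
#' Draws a pool of `n_haplotypes` binary haplotypes over K sites: the
#' low-frequency cluster is generated by correlated carrier sets (so an
#' r^2 > 0.5 bin of low frequency SNPs exists by construction), and the
#' remaining sites by thresholding a latent first-order Gaussian
#' dependence chain at the target frequencies. Pools are
#' rejection-resampled (up to `max_attempts`) until the realized panel,
#' after the MAF >= 1% filter, has 8-15 SNPs, at least one bin with
#' `lf_bin_min`+ low frequency members, and mean pairwise |r| inside the
#' requested band. Fully deterministic given the spec seed.
#'
#' @param spec a [gene_panel_spec()].
#' @param seed overrides `spec$seed`.
#' @return Object of class `haplotype_pool`: `H`, `alleles` (H x K 0/1
#'   matrix), `sites` (data.frame: id, position, freq, freq_class).
#' @export
generate_pool <- function(spec = gene_panel_spec(), seed = NULL) {
  seed <- seed %||% spec$seed
  if (is.null(seed)) stop("a seed is required (spec$seed or seed argument)")
  with_seed(seed, {
    fails <- c(snp_count = 0L, monomorphic = 0L, lf_bin = 0L, mean_abs_r = 0L)
    for (attempt in seq_len(spec$max_attempts)) {
      d <- .draw_pool(spec)
      why <- .check_pool(d$A, d$p, spec)
      if (is.null(why)) {
        K <- ncol(d$A)
        colnames(d$A) <- paste0("snp", seq_len(K))
        return(structure(list(
          H = nrow(d$A), alleles = d$A,
          sites = data.frame(id = colnames(d$A), position = seq_len(K),
                             freq = d$p, freq_class = maf_class(d$p),
                             stringsAsFactors = FALSE)),
          class = "haplotype_pool"))
      }
      fails[why] <- fails[why] + 1L
    }
    stop("pool generation failed after ", spec$max_attempts,
         " attempts; most frequent unmet constraint: ",
         names(which.max(fails)), " (", max(fails), " failures)")
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool: H =", x$H, "haplotypes,", nrow(x$sites), "sites (",
      sum(x$sites$freq_class == "low_frequency"), "low frequency)\n")
  invisible(x)
}

#' LD bins of a haplotype pool panel
#'
#' Bins the panel sites on the haplotype allele correlation (which equals
#' the expected genotype correlation under random pairing).
#'
#' @param pool a [generate_pool()] result.
#' @param threshold r^2 cutoff, default 0.5.
#' @return A `bin_assignment`.
#' @export
pool_bins <- function(pool, threshold = 0.5) {
  ldselect_bins(stats::cor(pool$alleles), threshold)
}

#' Generate diploid genotypes by random haplotype pairing
#'
#' Each individual is the sum of two haplotypes drawn uniformly with
#' replacement from the pool. Sample-monomorphic columns are dropped with
#' a warning; columns whose sample MAF falls below 1% are kept (flagged
#' `excluded` class) so causal indexing is preserved.
#'
#' @param pool a [generate_pool()] result.
#' @param n sample size.
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
generate_genotypes <- function(pool, n, seed = NULL) {
  with_seed(seed, {
    i1 <- sample.int(pool$H, n, replace = TRUE)
    i2 <- sample.int(pool$H, n, replace = TRUE)
    G <- pool$alleles[i1, , drop = FALSE] + pool$alleles[i2, , drop = FALSE]
    if (n == 1L) {
      # too small to validate/filter; return the raw draw with pool metadata
      rownames(G) <- "ind1"
      return(structure(list(G = G, snps = data.frame(
        id = pool$sites$id, position = pool$sites$position,
        maf = pool$sites$freq, freq_class = pool$sites$freq_class,
        stringsAsFactors = FALSE), samples = "ind1"),
        class = "genotype_matrix"))
    }
    genotype_matrix(G, snp_ids = pool$sites$id,
                    positions = pool$sites$position,
                    samples = paste0("ind", seq_len(n)),
                    drop_rare = FALSE)
  })
}

#' Trait model specification
#'
#' The five additive causal models: (1) one low frequency causal SNP
#' (a1 = 1); (2) two deleterious low frequency causals in the same bin
#' (1, 1); (3) two low frequency causals in the same bin, one deleterious
#' and one protective (1, -1); (4) one common and one low frequency
#' causal, both deleterious (1, 1); (5) one deleterious common and one
#' protective low frequency causal (1, -1). `model_id = 0` is the null
#' model (no causal effect; pure noise trait).
#'
#' @param model_id integer 0-5.
#' @param causal_ids character ids of the causal sites (empty for null).
#' @param effects numeric effects, one per causal.
#' @param error_sd residual SD (NA until calibrated; 1 for the null model).
#' @return Object of class `trait_model_spec`.
#' @export
trait_model_spec <- function(model_id, causal_ids, effects,
                             error_sd = NA_real_) {
  structure(list(model_id = as.integer(model_id),
                 causal_ids = as.character(causal_ids),
                 effects = as.numeric(effects),
                 error_sd = error_sd),
            class = "trait_model_spec")
}

#' Null trait model (type-I-error design)
#' @param error_sd trait SD, default 1.
#' @return A [trait_model_spec()] with no causal variants.
#' @export
null_trait_model <- function(error_sd = 1) {
  trait_model_spec(0L, character(0), numeric(0), error_sd)
}

model_effects <- list(`1` = 1, `2` = c(1, 1), `3` = c(1, -1),
                      `4` = c(1, 1), `5` = c(1, -1))

#' Assign causal SNPs for a trait model
#'
#' Low frequency causals are drawn (seeded, uniformly) from a bin
#' containing `>= 3` correlated low frequency SNPs; common causals are
#' drawn from among all common SNPs. Effect signs follow the model
#' definitions (see [trait_model_spec()]).
#'
#' @param pool a [generate_pool()] result.
#' @param bins a `bin_assignment` on the pool panel (see [pool_bins()]).
#' @param model_id integer 1-5.
#' @param seed integer seed.
#' @param lf_bin_min minimum LF members defining a qualifying bin.
#' @return A [trait_model_spec()] (with `error_sd` still `NA`).
#' @export
assign_causals <- function(pool, bins, model_id, seed = NULL, lf_bin_min = 3) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("model_id must be 1..5")
  lf <- pool$sites$freq_class == "low_frequency"
  common <- pool$sites$freq_class == "common"
  lf_per_bin <- tapply(lf, bins$bin_of, sum)
  qual <- as.integer(names(lf_per_bin)[lf_per_bin >= lf_bin_min])
  if (length(qual) == 0L)
    stop("no bin with ", lf_bin_min, "+ low frequency SNPs; panel does not support this model")
  with_seed(seed, {
    b <- if (length(qual) == 1L) qual else sample(qual, 1)
    lf_in_bin <- which(lf & bins$bin_of == b)
    pick_lf <- function(k) if (length(lf_in_bin) == 1L) lf_in_bin else sample(lf_in_bin, k)
    causal <- switch(as.character(model_id),
      `1` = pick_lf(1),
      `2` = pick_lf(2),
      `3` = pick_lf(2),
      `4` = , `5` = {
        if (!any(common)) stop("no common SNPs available for this model")
        cidx <- which(common)
        c(if (length(cidx) == 1L) cidx else sample(cidx, 1), pick_lf(1))
      })
    trait_model_spec(model_id, pool$sites$id[causal],
                     model_effects[[as.character(model_id)]])
  })
}

#' Simulate a quantitative trait from a causal model
#'
#' `Y = a1 C1 (+ a2 C2) + e`, `e ~ N(0, error_sd^2)`, using the causal
#' genotype columns of the full genotype matrix. Downstream analysis
#' should exclude the causal columns (see [exclude_causals()]): the
#' omitted-variable setting in which typed SNPs capture the causal effect
#' only indirectly.
#'
#' @param gm_full [genotype_matrix()] including the causal columns.
#' @param tm a [trait_model_spec()] with `error_sd` set.
#' @param seed integer seed.
#' @return A [phenotype()].
#' @export
generate_trait <- function(gm_full, tm, seed = NULL) {
  if (is.na(tm$error_sd)) stop("error_sd is not set; calibrate first")
  n <- nrow(gm_full$G)
  with_seed(seed, {
    mu <- if (length(tm$causal_ids) == 0L) 0 else {
      idx <- match(tm$causal_ids, gm_full$snps$id)
      if (anyNA(idx)) stop("causal id(s) missing from genotype matrix")
      drop(gm_full$G[, idx, drop = FALSE] %*% tm$effects)
    }
    y <- mu + stats::rnorm(n, 0, tm$error_sd)
    phenotype(gm_full$samples, y)
  })
}

#' Drop a model's causal columns from a genotype matrix
#' @param gm a [genotype_matrix()].
#' @param tm a [trait_model_spec()].
#' @return The analysis [genotype_matrix()] without the causal columns.
#' @export
exclude_causals <- function(gm, tm) {
  if (length(tm$causal_ids) == 0L) return(gm)
  idx <- match(tm$causal_ids, gm$snps$id)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0L) return(gm)
  subset_gm(gm, setdiff(seq_len(ncol(gm$G)), idx))
}

#' Analytic power of the joint-regression Wald test
#'
#' Noncentral chi-square power at level `alpha` with K df and
#' noncentrality `delta / (sigma^2 + v_resid)`, where `delta` is the
#' quadratic form of the expected coefficients in the centered design and
#' `v_resid` the causal signal variance not captured by the typed SNPs.
#'
#' @param sigma trait error SD.
#' @param delta noncentrality numerator `E[b]' (Xc'Xc) E[b]`.
#' @param K degrees of freedom.
#' @param alpha significance level.
#' @param v_resid residual causal variance (default 0).
#' @return Power in (0, 1).
#' @export
wald_analytic_power <- function(sigma, delta, K, alpha = 0.05, v_resid = 0) {
  lam <- delta / (sigma^2 + v_resid)
  stats::pchisq(stats::qchisq(1 - alpha, K), K, ncp = lam, lower.tail = FALSE)
}

#' Calibrate the trait error SD to a target Wald power
#'
#' Solves for the error SD sigma at which the analytic (noncentral
#' chi-square) power of the joint Wald test on the analysis set (causal
#' columns excluded) equals `target_power` at level `alpha`. The
#' noncentrality uses the expected coefficients of the typed SNPs under
#' the omitted-causal model and the total residual variance
#' `sigma^2 + v_resid` (v_resid being the causal variance the typed SNPs
#' do not capture). The result is clamped to [0.0001, 100]; a clamp is
#' flagged in the `"clamped"` attribute and warned about (power targets
#' can be unattainable for weakly tagged causals). Power is strictly
#' decreasing in sigma, so the root is unique.
#'
#' @param gm_full [genotype_matrix()] including the causal columns.
#' @param tm a [trait_model_spec()].
#' @param target_power default 0.8.
#' @param alpha default 0.05.
#' @return sigma (numeric scalar) with attributes `clamped`, `delta`,
#'   `v_resid`, `K`.
#' @export
calibrate_sigma <- function(gm_full, tm, target_power = 0.8, alpha = 0.05) {
  if (length(tm$causal_ids) == 0L) stop("null model has no causal effect to calibrate")
  idx <- match(tm$causal_ids, gm_full$snps$id)
  if (anyNA(idx)) stop("causal id(s) missing from genotype matrix")
  Ca <- gm_full$G[, idx, drop = FALSE]
  gma <- subset_gm(gm_full, setdiff(seq_len(ncol(gm_full$G)), idx))
  prep <- .joint_prep(gma$G)
  # causal columns were excluded by construction; a coincidental perfect
  # sample-level tag is a legitimate typed SNP, so skip the duplicate check
  eb <- expected_joint_betas(gma, causal_model(Ca, tm$effects),
                             allow_causal_in_set = TRUE)
  ebk <- eb[prep$keep]
  delta <- drop(crossprod(ebk, prep$XtXc %*% ebk))
  ca <- drop(Ca %*% tm$effects)
  res <- ca - drop(prep$X %*% (prep$H %*% ca))
  v_resid <- sum(res^2) / prep$df_resid
  K <- length(prep$keep)

  clamped <- FALSE
  if (delta <= 0) {
    warning("expected coefficients are zero; target power unattainable, clamping sigma to 0.0001")
    sigma <- 1e-4
    clamped <- TRUE
  } else {
    qcrit <- stats::qchisq(1 - alpha, K)
    lam_star <- stats::uniroot(
      function(l) stats::pchisq(qcrit, K, ncp = l, lower.tail = FALSE) - target_power,
      c(1e-10, 1e8), tol = 1e-10)$root
    sigma2 <- delta / lam_star - v_resid
    if (sigma2 < 1e-8) {
      warning("target power unattainable; clamping sigma to 0.0001")
      sigma <- 1e-4; clamped <- TRUE
    } else {
      sigma <- sqrt(sigma2)
      if (sigma > 100) {
        warning("calibrated sigma above 100; clamping")
        sigma <- 100; clamped <- TRUE
      } else if (sigma < 1e-4) {
        warning("calibrated sigma below 0.0001; clamping")
        sigma <- 1e-4; clamped <- TRUE
      }
    }
  }
  structure(sigma, clamped = clamped, delta = delta, v_resid = v_resid, K = K)
}
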