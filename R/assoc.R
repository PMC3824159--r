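#' Gene-based association analysis of a quantitative trait
#'
#' The main fitting function: given one gene's genotypes and a
#' quantitative trait, runs the full pipeline — MAF partition into the
#' requested analysis set, LD binning at `r^2 > bin_r2`, within-bin
#' allele-coding correction, joint and marginal regression fits — and
#' evaluates the requested global statistics, each with its asymptotic
#' null distribution.
#'
#' @param gm a [genotype_matrix()] (or plain 0/1/2 matrix, coerced).
#' @param ph a [phenotype()] (or plain numeric vector, coerced); sample
#'   ids are aligned with [join_phenotype()] when both carry ids.
#' @param analysis_set `"all"`, `"common"` or `"low_frequency"`.
#' @param statistics statistic keys; default all twelve
#'   (`wald`, `mlc_b`, `mlc_z`, `lc_b`, `lc_z`, `pc80`, `minp_j`,
#'   `minp_m`, `ssb`, `ssbw`, `skat`, `skat_c`).
#' @param bin_r2 binning threshold (default 0.5).
#' @param pc_variance_fraction PC80 variance-explained threshold.
#' @param mixture_method p-value method for the quadratic statistics,
#'   see [mixture_chisq_pvalue()].
#' @return Object of class `gene_assoc` with components `results`
#'   (data.frame of statistic, value, df, p_value), `joint`, `marginal`,
#'   `bins`, `gm` (post-correction), `analysis_set`, `call`.
#' @examples
#' pool <- generate_pool(gene_panel_spec(n_snps = 10, seed = 7))
#' gm <- generate_genotypes(pool, 500, seed = 8)
#' y <- phenotype(gm$samples, rnorm(500))
#' fit <- gene_assoc(gm, y)
#' fit
#' coef(fit)[1:3]
#' @export
gene_assoc <- function(gm, ph, analysis_set = "all",
                       statistics = all_statistics, bin_r2 = 0.5,
                       pc_variance_fraction = 0.80,
                       mixture_method = "liu") {
  cl <- match.call()
  if (!inherits(gm, "genotype_matrix")) gm <- genotype_matrix(gm)
  if (!inherits(ph, "phenotype")) ph <- phenotype(gm$samples, ph)
  if (!identical(gm$samples, ph$samples)) {
    j <- join_phenotype(gm, ph); gm <- j$gm; ph <- j$ph
  }
  statistics <- match.arg(statistics, all_statistics, several.ok = TRUE)
  gm_set <- partition_by_maf(gm, analysis_set)
  bins <- ldselect_bins(correlation_matrix(gm_set), bin_r2)
  cc <- coding_correction(gm_set, bins)
  gm_set <- cc$gm; bins <- cc$bins

  jf <- fit_joint(gm_set, ph)
  mf <- fit_marginals(gm_set, ph)
  lf_set <- if (any(gm_set$snps$freq_class == "low_frequency"))
    subset_gm(gm_set, which(gm_set$snps$freq_class == "low_frequency"))
  co_set <- if (any(gm_set$snps$freq_class == "common"))
    subset_gm(gm_set, which(gm_set$snps$freq_class == "common"))

  res <- lapply(statistics, function(s) {
    switch(s,
      wald = wald_test(jf),
      mlc_b = mlc_test(jf, bins, "B"),
      mlc_z = mlc_test(jf, bins, "Z"),
      lc_b = lc_test(jf, "B"),
      lc_z = lc_test(jf, "Z"),
      pc80 = pc80_test(gm_set, ph, pc_variance_fraction),
      minp_j = minp_test(jf),
      minp_m = minp_test(mf),
      ssb = ssb_test(mf, weighted = FALSE, method = mixture_method),
      ssbw = ssb_test(mf, weighted = TRUE, method = mixture_method),
      skat = skat_test(gm_set, ph, "lf", method = mixture_method),
      skat_c = skat_c_test(lf_set, co_set, ph, method = mixture_method))
  })
  tab <- do.call(rbind, lapply(res, as.data.frame))
  tab$analysis_set <- analysis_set
  structure(list(results = tab, tests = res, joint = jf, marginal = mf,
                 bins = bins, gm = gm_set, analysis_set = analysis_set,
                 call = cl),
            class = "gene_assoc")
}

#' @export
print.gene_assoc <- function(x, digits = 4, ...) {
  cat("Gene-based association tests (analysis set: ", x$analysis_set,
      ", K = ", x$joint$K, " SNPs, L = ", x$bins$n_bins, " bins, n = ",
      x$joint$n, ")\n\n", sep = "")
  tab <- x$results[, c("statistic", "value", "df", "p_value")]
  tab$value <- signif(tab$value, digits)
  tab$p_value <- signif(tab$p_value, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.gene_assoc <- function(object, ...) {
  structure(list(fit = object,
                 joint = as.data.frame(object$joint),
                 marginal = as.data.frame(object$marginal),
                 bins = data.frame(snp = object$gm$snps$id,
                                   maf = object$gm$snps$maf,
                                   freq_class = object$gm$snps$freq_class,
                                   bin = object$bins$bin_of,
                                   flipped = object$bins$flipped)),
            class = "summary.gene_assoc")
}

#' @export
print.summary.gene_assoc <- function(x, ...) {
  print(x$fit)
  cat("\nPer-SNP fits:\n")
  per <- merge(x$bins, x$joint, by = "snp", sort = FALSE)
  per <- merge(per, x$marginal, by = "snp", sort = FALSE)
  print(per, digits = 3, row.names = FALSE)
  invisible(x)
}

#' @export
coef.gene_assoc <- function(object, type = c("joint", "marginal"), ...) {
  type <- match.arg(type)
  if (type == "joint") object$joint$beta else object$marginal$beta_m
}

#' @export
plot.gene_assoc <- function(x, ...) {
  p <- x$results$p_value
  graphics::barplot(-log10(p), names.arg = x$results$statistic, las = 2,
                    ylab = expression(-log[10](p)),
                    main = paste("Gene-based tests,", x$analysis_set, "set"), ...)
  graphics::abline(h = -log10(0.05), lty = 2)
  invisible(x)
}
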