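# Orchestration of the simulation experiment: for a gene panel, run the
# requested statistics on the requested analysis sets over N replicates
# and report empirical rejection rates at the nominal level.

all_statistics <- c("wald", "mlc_b", "mlc_z", "lc_b", "lc_z", "pc80",
                    "minp_j", "minp_m", "ssb", "ssbw", "skat", "skat_c")

stat_labels <- c(wald = "Wald", mlc_b = "MLC-B", mlc_z = "MLC-Z",
                 lc_b = "LC-B", lc_z = "LC-Z", pc80 = "PC80",
                 minp_j = "MinP-J", minp_m = "MinP-M", ssb = "SSB",
                 ssbw = "SSBw", skat = "SKAT", skat_c = "SKAT-C")

#' Study configuration
#'
#' @param n_individuals sample size per replicate (default 5000).
#' @param n_replicates number of replicates (default 1000).
#' @param alpha nominal level (default 0.05).
#' @param analysis_sets subset of `c("all", "common", "low_frequency")`.
#' @param statistics subset of the twelve statistic keys (see
#'   `genebin:::all_statistics`).
#' @param model_ids trait models to run; 0 is the null (type-I-error)
#'   design, 1-5 the causal models.
#' @param bin_r2 binning threshold.
#' @param pc_variance_fraction PC80 variance threshold.
#' @param seed master seed; every replicate derives its own stream from
#'   (seed, model, replicate index), so results are independent of
#'   evaluation order.
#' @return Object of class `study_config`.
#' @export
study_config <- function(n_individuals = 5000, n_replicates = 1000,
                         alpha = 0.05,
                         analysis_sets = c("all", "common", "low_frequency"),
                         statistics = all_statistics,
                         model_ids = 1:5, bin_r2 = 0.5,
                         pc_variance_fraction = 0.80, seed = 1) {
  stopifnot(n_replicates >= 1, alpha > 0, alpha < 1)
  analysis_sets <- match.arg(analysis_sets, several.ok = TRUE)
  statistics <- match.arg(statistics, all_statistics, several.ok = TRUE)
  structure(list(n_individuals = n_individuals, n_replicates = n_replicates,
                 alpha = alpha, analysis_sets = analysis_sets,
                 statistics = statistics, model_ids = model_ids,
                 bin_r2 = bin_r2,
                 pc_variance_fraction = pc_variance_fraction,
                 seed = seed),
            class = "study_config")
}

# Prepare one analysis set: partition, bin, coding-correct, precompute
# the genotype-side factorizations every statistic reuses across traits.
.prepare_set <- function(gm_analysis, set, cfg) {
  gm_set <- partition_by_maf(gm_analysis, set)
  bins <- ldselect_bins(correlation_matrix(gm_set), cfg$bin_r2)
  cc <- coding_correction(gm_set, bins)
  gm_set <- cc$gm; bins <- cc$bins
  stats_req <- cfg$statistics
  need_joint <- any(stats_req %in% c("wald", "mlc_b", "mlc_z", "lc_b",
                                     "lc_z", "minp_j"))
  need_marg <- any(stats_req %in% c("minp_m", "ssb", "ssbw"))
  prep <- list(gm = gm_set, bins = bins, set = set)
  if (need_joint) prep$joint <- .joint_prep(gm_set$G)
  if (need_marg) {
    prep$marg <- .marg_prep(gm_set$G)
    if (any(stats_req == "ssb"))
      prep$ssb_eig <- eigen(prep$marg$Mnorm, symmetric = TRUE,
                            only.values = TRUE)$values
    if (any(stats_req == "ssbw"))
      prep$ssbw_eig <- eigen(stats::cov2cor(prep$marg$Mnorm), symmetric = TRUE,
                             only.values = TRUE)$values
  }
  if (any(stats_req == "pc80")) {
    Xc <- scale(gm_set$G, center = TRUE, scale = FALSE)
    sv <- svd(Xc, nu = 0)
    cum <- cumsum(sv$d^2) / sum(sv$d^2)
    S <- if (any(cum > cfg$pc_variance_fraction))
      which(cum > cfg$pc_variance_fraction)[1] else length(sv$d)
    prep$pc <- .joint_prep_pc(Xc %*% sv$v[, seq_len(S), drop = FALSE])
    prep$pc_S <- S
  }
  if (any(stats_req == "skat"))
    prep$skat <- .skat_prep(gm_set$G, skat_weights(gm_set$snps$maf, "lf"))
  if (any(stats_req == "skat_c")) {
    lf <- gm_set$snps$freq_class == "low_frequency"
    co <- gm_set$snps$freq_class == "common"
    prep$skc <- list(
      lf = if (any(lf)) .skat_prep(gm_set$G[, lf, drop = FALSE],
                                   skat_weights(gm_set$snps$maf[lf], "lf")),
      common = if (any(co)) .skat_prep(gm_set$G[, co, drop = FALSE],
                                       skat_weights(gm_set$snps$maf[co], "common")))
  }
  prep
}

# p-values of the requested statistics for one trait vector
.eval_set <- function(prep, y, cfg) {
  out <- stats::setNames(rep(NA_real_, length(cfg$statistics)), cfg$statistics)
  jf <- if (!is.null(prep$joint)) .joint_fit_y(prep$joint, y)
  for (s in cfg$statistics) {
    out[s] <- switch(s,
      wald = wald_test(jf)$p_value,
      mlc_b = mlc_test(jf, prep$bins, "B")$p_value,
      mlc_z = mlc_test(jf, prep$bins, "Z")$p_value,
      lc_b = lc_test(jf, "B")$p_value,
      lc_z = lc_test(jf, "Z")$p_value,
      minp_j = minp_test(jf)$p_value,
      pc80 = {
        pf <- .joint_fit_y(prep$pc, y)
        q <- quad_form_inv(pf$beta, pf$cov)
        stats::pchisq(q, prep$pc_S, lower.tail = FALSE)
      },
      minp_m = , ssb = , ssbw = {
        mf <- .marg_fit_y(prep$marg, y)
        if (s == "minp_m") minp_test(mf)$p_value
        else if (s == "ssb")
          mixture_chisq_pvalue(sum(mf$beta_m^2), mf$sigma2 * prep$ssb_eig)
        else
          mixture_chisq_pvalue(sum(mf$z_m^2), prep$ssbw_eig)
      },
      skat = {
        yc <- y - mean(y)
        q <- sum(drop(crossprod(prep$skat$B, yc))^2)
        mixture_chisq_pvalue(q, stats::var(y) * prep$skat$lam)
      },
      skat_c = .eval_skat_c(prep$skc, y))
  }
  out
}

.eval_skat_c <- function(skc, y) {
  yc <- y - mean(y)
  s2 <- stats::var(y)
  if (is.null(skc$lf) || is.null(skc$common)) {
    one <- skc$lf %||% skc$common
    q <- sum(drop(crossprod(one$B, yc))^2)
    return(mixture_chisq_pvalue(q, s2 * one$lam))
  }
  sd_lf <- sqrt(2 * sum((s2 * skc$lf$lam)^2))
  sd_c <- sqrt(2 * sum((s2 * skc$common$lam)^2))
  phi <- sd_lf / (sd_lf + sd_c)
  q <- phi * sum(drop(crossprod(skc$lf$B, yc))^2) +
    (1 - phi) * sum(drop(crossprod(skc$common$B, yc))^2)
  lam <- eigen(crossprod(cbind(sqrt(phi) * skc$lf$B,
                               sqrt(1 - phi) * skc$common$B)),
               symmetric = TRUE, only.values = TRUE)$values
  mixture_chisq_pvalue(q, s2 * lam)
}

#' Run one simulation replicate
#'
#' Draws one trait vector under the model, then for each analysis set
#' partitions, bins, applies the coding correction, fits joint and
#' marginal regressions and evaluates the requested statistics. Causal
#' columns are excluded from every analysis set. Fully determined by
#' `replicate_seed`.
#'
#' @param gm_full [genotype_matrix()] including causal columns.
#' @param tm a [trait_model_spec()] with `error_sd` set.
#' @param cfg a [study_config()].
#' @param replicate_seed integer seed for the trait draw.
#' @return data.frame with columns analysis_set, statistic, p_value
#'   (skipped sets carry `NA`).
#' @export
run_replicate <- function(gm_full, tm, cfg, replicate_seed) {
  ph <- generate_trait(gm_full, tm, seed = replicate_seed)
  gm_analysis <- exclude_causals(gm_full, tm)
  out <- list()
  for (set in cfg$analysis_sets) {
    prep <- tryCatch(.prepare_set(gm_analysis, set, cfg),
                     error = function(e) NULL)
    p <- if (is.null(prep)) stats::setNames(rep(NA_real_, length(cfg$statistics)),
                                            cfg$statistics)
         else .eval_set(prep, ph$y, cfg)
    out[[set]] <- data.frame(analysis_set = set,
                             statistic = unname(stat_labels[names(p)]),
                             p_value = unname(p), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Run the full simulation study
#'
#' For each requested trait model: fresh genotypes are generated from the
#' pool (seeded per model), causal SNPs are assigned, the error SD is
#' calibrated to the target Wald power (skipped for the null model), and
#' `n_replicates` trait vectors are drawn (fresh noise on fixed
#' genotypes). Each replicate is evaluated on every analysis set and the
#' empirical rejection rate at `alpha` is reported with a Clopper-Pearson
#' 95% interval.
#'
#' @param cfg a [study_config()].
#' @param panel_spec a [gene_panel_spec()]; its seed defaults to a stream
#'   derived from `cfg$seed`.
#' @param pool optionally, a pre-generated [generate_pool()] result.
#' @param target_power Wald power target for calibration (default 0.8).
#' @return Object of class `study_result`: data.frame `rates` (model,
#'   analysis_set, statistic, rejections, n_replicates, rate, ci_lo,
#'   ci_hi, sigma, sigma_clamped) plus the pool and per-model trait
#'   models.
#' @export
run_study <- function(cfg = study_config(), panel_spec = gene_panel_spec(),
                      pool = NULL, target_power = 0.8) {
  if (is.null(pool)) {
    if (is.null(panel_spec$seed)) panel_spec$seed <- derive_seed(cfg$seed, 101)
    pool <- generate_pool(panel_spec)
  }
  pbins <- pool_bins(pool, cfg$bin_r2)
  rows <- list(); tms <- list()
  for (model in cfg$model_ids) {
    gm_full <- suppressWarnings(
      generate_genotypes(pool, cfg$n_individuals,
                         seed = derive_seed(cfg$seed, 2, model)))
    if (model == 0L) {
      tm <- null_trait_model()
      sigma <- 1; clamped <- FALSE
    } else {
      tm <- assign_causals(pool, pbins, model,
                           seed = derive_seed(cfg$seed, 3, model))
      sigma <- calibrate_sigma(gm_full, tm, target_power, cfg$alpha)
      clamped <- attr(sigma, "clamped")
      tm$error_sd <- as.numeric(sigma)
    }
    tms[[as.character(model)]] <- tm

    gm_analysis <- exclude_causals(gm_full, tm)
    preps <- list()
    for (set in cfg$analysis_sets)
      preps[[set]] <- tryCatch(.prepare_set(gm_analysis, set, cfg),
                               error = function(e) NULL)

    rej <- array(0L, dim = c(length(cfg$analysis_sets), length(cfg$statistics)),
                 dimnames = list(cfg$analysis_sets, cfg$statistics))
    nok <- rej
    for (r in seq_len(cfg$n_replicates)) {
      ph <- generate_trait(gm_full, tm, seed = derive_seed(cfg$seed, 4, model, r))
      for (set in cfg$analysis_sets) {
        if (is.null(preps[[set]])) next
        p <- .eval_set(preps[[set]], ph$y, cfg)
        ok <- !is.na(p)
        rej[set, ok] <- rej[set, ok] + (p[ok] < cfg$alpha)
        nok[set, ok] <- nok[set, ok] + 1L
      }
    }
    for (set in cfg$analysis_sets) {
      for (s in cfg$statistics) {
        n_ok <- nok[set, s]
        rate <- if (n_ok > 0) rej[set, s] / n_ok else NA_real_
        ci <- if (n_ok > 0)
          stats::binom.test(rej[set, s], n_ok)$conf.int else c(NA_real_, NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, analysis_set = set,
          statistic = unname(stat_labels[s]),
          rejections = rej[set, s], n_replicates = n_ok,
          rate = rate, ci_lo = ci[1], ci_hi = ci[2],
          sigma = if (model == 0L) NA_real_ else as.numeric(tms[[as.character(model)]]$error_sd),
          sigma_clamped = clamped,
          skipped = is.null(preps[[set]]), row.names = NULL)
      }
    }
  }
  structure(list(rates = do.call(rbind, rows), pool = pool,
                 trait_models = tms, config = cfg),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("study_result:", length(unique(x$rates$model)), "model(s),",
      x$config$n_replicates, "replicates, n =", x$config$n_individuals, "\n")
  print(utils::head(x$rates[, c("model", "analysis_set", "statistic",
                                "rate", "ci_lo", "ci_hi")], 24), digits = 3)
  if (nrow(x$rates) > 24) cat("...", nrow(x$rates) - 24, "more rows\n")
  invisible(x)
}
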