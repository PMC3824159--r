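test_that("omitted-causal joint expectations are the tagging regression slopes", {
  gm <- make_orthogonal_gm()
  n <- nrow(gm$G)
  # causal orthogonal to every analysis SNP -> exactly zero expectations
  C <- gm$G[, 3, drop = FALSE]
  gma <- genebin:::subset_gm(gm, 1:2)
  eb <- expected_joint_betas(gma, causal_model(C, 1))
  expect_equal(unname(eb), c(0, 0), tolerance = 1e-12)

  # causal included as X1 (check relaxed) -> slope 1 on itself, 0 elsewhere
  gm2 <- make_gm(100, 3, seed = 21)
  C2 <- gm2$G[, 1, drop = FALSE]
  eb2 <- expected_joint_betas(gm2, causal_model(C2, 2), allow_causal_in_set = TRUE)
  expect_equal(unname(eb2), c(2, 0, 0), tolerance = 1e-10)
  expect_error(expected_joint_betas(gm2, causal_model(C2, 1)), "omitted-variable")

  # exact cancellation of two identical causals with opposing effects
  eb3 <- expected_joint_betas(gma, causal_model(cbind(C, C), c(1, -1)))
  expect_equal(unname(eb3), c(0, 0), tolerance = 1e-14)
})

test_that("expected marginal betas match per-SNP regression slopes of the causal signal", {
  gm <- make_gm(250, 5, seed = 22)
  set.seed(23)
  C <- cbind(rbinom(250, 2, 0.04))
  a1 <- 1.5
  em <- expected_marginal_betas(gm, causal_model(C, a1))
  oracle <- apply(gm$G, 2, function(x) unname(coef(lm(a1 * C[, 1] ~ x))[2]))
  expect_equal(unname(em), unname(oracle), tolerance = 1e-10)
})

test_that("MAF-based SDs follow the haplotype-pairing variance form", {
  gm <- make_gm(400, 3, seed = 24)
  C <- cbind(rbinom(400, 2, 0.02))
  em <- expected_marginal_betas(gm, causal_model(C, 1), sd_method = "maf")
  p_c <- min(mean(C) / 2, 1 - mean(C) / 2)
  manual <- cor(C[, 1], gm$G) * sqrt(p_c * (1 - p_c)) /
    sqrt(gm$snps$maf * (1 - gm$snps$maf))
  expect_equal(unname(em), unname(drop(manual)), tolerance = 1e-10)
})

test_that("expected betas are linear in the effect sizes", {
  gm <- make_gm(200, 4, seed = 25)
  set.seed(26)
  C <- cbind(rbinom(200, 2, 0.03), rbinom(200, 2, 0.2))
  e10 <- expected_joint_betas(gm, causal_model(C, c(1, 0)))
  e01 <- expected_joint_betas(gm, causal_model(C, c(0, 1)))
  e_mix <- expected_joint_betas(gm, causal_model(C, c(2.5, -0.7)))
  expect_equal(unname(e_mix), unname(2.5 * e10 - 0.7 * e01), tolerance = 1e-12)
  m10 <- expected_marginal_betas(gm, causal_model(C, c(1, 0)))
  m01 <- expected_marginal_betas(gm, causal_model(C, c(0, 1)))
  m_mix <- expected_marginal_betas(gm, causal_model(C, c(2.5, -0.7)))
  expect_equal(unname(m_mix), unname(2.5 * m10 - 0.7 * m01), tolerance = 1e-12)
})

test_that("summaries recompute correctly from the coefficient vectors", {
  s0 <- genebin:::beta_summary(c(0, 0, 0))
  expect_equal(unname(s0), c(0, 0, 0, 0, 0))
  s1 <- genebin:::beta_summary(c(1, -1))
  expect_equal(s1[["sum"]], 0)
  expect_equal(s1[["sum_abs"]], 2)
  expect_equal(s1[["frac_gt_0.5"]], 1)
  s2 <- genebin:::beta_summary(c(0.6, 0.2))
  expect_equal(s2[["frac_gt_0.5"]], 0.5)

  gm <- make_gm(150, 3, seed = 27)
  C <- cbind(rbinom(150, 2, 0.1))
  eb <- expected_betas(gm, causal_model(C, 1))
  s <- summarize_expected_betas(eb)
  expect_equal(s$sum[s$method == "joint"], sum(eb$joint))
  expect_equal(s$mean_abs[s$method == "marginal"], mean(abs(eb$marginal)))
})

test_that("pool-based expectations agree with large-sample genotype expectations", {
  pool <- shared_pool()
  causal <- which(pool$sites$freq_class == "low_frequency")[1]
  analysis <- setdiff(seq_len(nrow(pool$sites)), causal)
  pe <- pool_expected_betas(pool, analysis, causal, 1)
  gm <- suppressWarnings(generate_genotypes(pool, 20000, seed = 28))
  idx_c <- match(pool$sites$id[causal], gm$snps$id)
  idx_a <- match(pool$sites$id[analysis], gm$snps$id)
  ok <- !is.na(idx_a)
  gma <- genebin:::subset_gm(gm, idx_a[ok])
  eb <- expected_joint_betas(gma, causal_model(gm$G[, idx_c, drop = FALSE], 1),
                             allow_causal_in_set = TRUE)
  expect_lt(max(abs(unname(eb) - pe$joint[ok])), 0.1)
})
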