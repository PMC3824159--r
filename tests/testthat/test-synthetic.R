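test_that("pool generation is deterministic and honors the structural constraints", {
  spec <- gene_panel_spec(n_snps = 12, seed = 404)
  p1 <- generate_pool(spec)
  p2 <- generate_pool(spec)
  expect_identical(p1$alleles, p2$alleles)

  for (seed in c(404, 808, 1212)) {
    pool <- generate_pool(gene_panel_spec(seed = seed))
    K <- nrow(pool$sites)
    expect_true(K >= 8 && K <= 15)
    expect_true(all(pool$sites$freq >= 0.01 & pool$sites$freq <= 0.5))
    lf <- pool$sites$freq_class == "low_frequency"
    expect_true(all(pool$sites$freq[lf] < 0.05))
    bins <- pool_bins(pool)
    lf_per_bin <- tapply(lf, bins$bin_of, sum)
    expect_true(any(lf_per_bin >= 3))
    R <- cor(pool$alleles)
    mar <- mean(abs(R[upper.tri(R)]))
    expect_true(mar >= 0.17 && mar <= 0.59)
  }
})

test_that("genotype sampling reproduces pool frequencies and Hardy-Weinberg variance", {
  pool <- shared_pool()
  n <- 4000
  gm <- suppressWarnings(generate_genotypes(pool, n, seed = 51))
  idx <- match(gm$snps$id, pool$sites$id)
  p_pool <- pool$sites$freq[idx]
  se <- sqrt(p_pool * (1 - p_pool) / (2 * n))
  expect_true(all(abs(gm$snps$maf - p_pool) <= 3 * se + 1e-9))
  v <- apply(gm$G, 2, var)
  expect_equal(unname(v), unname(2 * gm$snps$maf * (1 - gm$snps$maf)),
               tolerance = 0.12)
  # determinism
  gm2 <- suppressWarnings(generate_genotypes(pool, n, seed = 51))
  expect_identical(gm$G, gm2$G)
  expect_true(all(gm$G %in% 0:2))
  # single-individual draw still yields valid additive codes
  g1 <- generate_genotypes(pool, 1, seed = 52)
  expect_equal(nrow(g1$G), 1L)
  expect_true(all(g1$G %in% 0:2))
})

test_that("causal assignment follows the five trait-model structures", {
  pool <- shared_pool()
  bins <- pool_bins(pool)
  site_class <- setNames(pool$sites$freq_class, pool$sites$id)
  site_bin <- setNames(bins$bin_of, pool$sites$id)

  tm1 <- assign_causals(pool, bins, 1, seed = 61)
  expect_length(tm1$causal_ids, 1)
  expect_equal(unname(site_class[tm1$causal_ids]), "low_frequency")
  expect_equal(tm1$effects, 1)

  tm3 <- assign_causals(pool, bins, 3, seed = 62)
  expect_length(tm3$causal_ids, 2)
  expect_true(all(site_class[tm3$causal_ids] == "low_frequency"))
  expect_equal(length(unique(site_bin[tm3$causal_ids])), 1L)
  expect_equal(tm3$effects, c(1, -1))

  tm4 <- assign_causals(pool, bins, 4, seed = 63)
  expect_setequal(unname(site_class[tm4$causal_ids]),
                  c("common", "low_frequency"))
  expect_equal(tm4$effects, c(1, 1))
  tm5 <- assign_causals(pool, bins, 5, seed = 64)
  expect_equal(tm5$effects, c(1, -1))
})

test_that("trait generation follows the additive model with normal noise", {
  pool <- shared_pool()
  gm <- suppressWarnings(generate_genotypes(pool, 500, seed = 71))
  id <- gm$snps$id[1]
  tm <- trait_model_spec(1, id, 1, error_sd = 1e-12)
  ph <- generate_trait(gm, tm, seed = 72)
  expect_equal(ph$y, unname(gm$G[, id]), tolerance = 1e-9)

  tm0 <- null_trait_model(error_sd = 2)
  ph0 <- generate_trait(gm, tm0, seed = 73)
  expect_equal(var(ph0$y), 4, tolerance = 0.2)

  # opposing effects on the same column cancel exactly
  tmx <- trait_model_spec(3, c(id, id), c(1, -1), error_sd = 0.5)
  phx <- generate_trait(gm, tmx, seed = 74)
  expect_equal(var(phx$y), 0.25, tolerance = 0.15)

  expect_identical(generate_trait(gm, tm0, seed = 73)$y, ph0$y)
  expect_error(generate_trait(gm, trait_model_spec(1, id, 1)), "error_sd")
})

test_that("analytic Wald power decreases strictly in sigma and calibration clamps", {
  pow <- sapply(c(0.5, 1, 2, 4, 8), wald_analytic_power,
                delta = 50, K = 10, alpha = 0.05)
  expect_true(all(diff(pow) < 0))

  pool <- shared_pool()
  gm <- suppressWarnings(generate_genotypes(pool, 2000, seed = 81))
  bins <- pool_bins(pool)
  tm <- assign_causals(pool, bins, 1, seed = 82)
  sig <- calibrate_sigma(gm, tm)
  expect_false(attr(sig, "clamped"))
  # the calibrated sigma attains the target analytic power
  expect_equal(wald_analytic_power(as.numeric(sig), attr(sig, "delta"),
                                   attr(sig, "K"), 0.05, attr(sig, "v_resid")),
               0.8, tolerance = 1e-6)

  # huge effects push the solution above the cap
  tm_big <- tm; tm_big$effects <- 5000
  expect_warning(sig_big <- calibrate_sigma(gm, tm_big), "clamp")
  expect_equal(as.numeric(sig_big), 100)
  expect_true(attr(sig_big, "clamped"))
})

test_that("causal exclusion removes exactly the model's columns", {
  pool <- shared_pool()
  gm <- suppressWarnings(generate_genotypes(pool, 300, seed = 91))
  tm <- assign_causals(pool, pool_bins(pool), 2, seed = 92)
  gma <- exclude_causals(gm, tm)
  expect_equal(ncol(gma$G), ncol(gm$G) - 2)
  expect_false(any(tm$causal_ids %in% gma$snps$id))
})
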