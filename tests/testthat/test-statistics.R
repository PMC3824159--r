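fake_joint_fit <- function(beta, cov) {
  z <- beta / sqrt(diag(cov))
  structure(list(beta = beta, cov = cov, z = z,
                 corr_z = cov2cor(cov), sigma2 = 1,
                 dropped = integer(0), keep = seq_along(beta),
                 n = 1000L, K = length(beta), K_input = length(beta)),
            class = "joint_fit")
}

test_that("Wald quadratic form and chi-square reference behave as defined", {
  jf <- fake_joint_fit(c(1, 0), diag(2))
  w <- wald_test(jf)
  expect_equal(w$value, 1)
  expect_equal(w$p_value, pchisq(1, 2, lower.tail = FALSE))
  expect_equal(wald_test(fake_joint_fit(c(0, 0, 0), diag(3)))$p_value, 1)
  # K = 1 reduces to the squared Z / two-sided normal test
  jf1 <- fake_joint_fit(2, matrix(4))
  w1 <- wald_test(jf1)
  expect_equal(w1$value, 1)
  expect_equal(w1$p_value, 2 * pnorm(-1))
})

test_that("LC is antisymmetric-null for opposing effects under exchangeable covariance", {
  S <- matrix(c(1, 0.4, 0.4, 1), 2)
  jf <- fake_joint_fit(c(0.7, -0.7), S)
  expect_equal(lc_test(jf, "B")$value, 0, tolerance = 1e-14)
  expect_equal(lc_test(jf, "Z")$value, 0, tolerance = 1e-14)
})

test_that("statistics are equivariant under SNP relabeling", {
  pool <- shared_pool()
  gm <- suppressWarnings(generate_genotypes(pool, 500, seed = 31))
  set.seed(32)
  ph <- phenotype(gm$samples, rnorm(500) + 0.1 * gm$G[, 2])
  perm <- rev(seq_len(ncol(gm$G)))
  gm_p <- structure(list(G = gm$G[, perm], snps = gm$snps[perm, ],
                         samples = gm$samples), class = "genotype_matrix")
  for (stat in c("wald", "ssb", "skat")) {
    f1 <- gene_assoc(gm, ph, statistics = stat)
    f2 <- gene_assoc(gm_p, ph, statistics = stat)
    expect_equal(f1$results$value, f2$results$value, tolerance = 1e-9,
                 info = stat)
  }
})

test_that("Wald is invariant under coding flips even without correction", {
  gm <- make_gm(200, 5, seed = 33)
  set.seed(34)
  ph <- phenotype(gm$samples, rnorm(200) + 0.15 * gm$G[, 1])
  w0 <- wald_test(fit_joint(gm, ph))$value
  gm$G[, c(1, 4)] <- 2 - gm$G[, c(1, 4)]
  w1 <- wald_test(fit_joint(gm, ph))$value
  expect_equal(w0, w1, tolerance = 1e-10)
})

test_that("PC80 keeps the smallest component set exceeding the variance threshold", {
  gm <- make_orthogonal_gm()   # equal column variances -> equal eigenvalues
  set.seed(35)
  ph <- phenotype(gm$samples, rnorm(nrow(gm$G)))
  # 3 equal eigenvalues: need ceiling(0.8*3 + eps) = 3 components
  expect_equal(pc80_test(gm, ph, 0.80)$df, 3L)
  expect_equal(pc80_test(gm, ph, 0.60)$df, 2L)
  expect_equal(pc80_test(gm, ph, 0.30)$df, 1L)
})

test_that("mixture-of-chi-square p-values reduce exactly in degenerate cases", {
  expect_equal(mixture_chisq_pvalue(3, 2), pchisq(1.5, 1, lower.tail = FALSE))
  expect_equal(mixture_chisq_pvalue(10, rep(2, 4)),
               pchisq(5, 4, lower.tail = FALSE))
  expect_equal(mixture_chisq_pvalue(3, 2, "davies"),
               pchisq(1.5, 1, lower.tail = FALSE))
  expect_error(mixture_chisq_pvalue(1, c(0, 0)), "zero")
  # tiny negative eigenvalues are numerical noise, clipped silently
  expect_silent(p <- mixture_chisq_pvalue(3, c(2, 1, -1e-14)))
})

test_that("Liu and Imhof agree closely at moderate tail probabilities", {
  for (w in list(c(2, 1), c(5, 1, 0.5), c(3, 2, 1, 0.5, 0.25))) {
    q <- sum(w) * 2.2
    expect_equal(mixture_chisq_pvalue(q, w, "liu"),
                 mixture_chisq_pvalue(q, w, "davies"), tolerance = 0.03)
  }
})

test_that("MinP adjustment has the right degenerate limits", {
  expect_equal(mvn_minp_adjust(0.01, matrix(1)), 0.01)
  R1 <- matrix(1, 4, 4)   # perfectly correlated Z -> no multiplicity
  expect_equal(mvn_minp_adjust(0.02, R1), 0.02)
})

test_that("single-SNP SKAT agrees with the marginal score test", {
  gm <- make_gm(300, 1, seed = 36)
  set.seed(37)
  ph <- phenotype(gm$samples, rnorm(300))
  res <- skat_test(gm, ph)
  xc <- gm$G[, 1] - mean(gm$G[, 1])
  yc <- ph$y - mean(ph$y)
  score <- sum(xc * yc)^2 / (var(ph$y) * sum(xc^2))
  expect_equal(res$p_value, pchisq(score, 1, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("SKAT low-frequency weights upweight rare variants monotonically", {
  p <- seq(0.005, 0.5, by = 0.005)
  w <- genebin:::skat_weights(p, "lf")
  expect_true(all(diff(w) < 0))
  expect_equal(genebin:::skat_weights(1e-12, "lf"), 625, tolerance = 1e-6)
})

test_that("SKAT-C mixes components by null SDs and honors block structure", {
  gm <- make_orthogonal_gm()   # exactly orthogonal centered columns
  set.seed(38)
  ph <- phenotype(gm$samples, rnorm(nrow(gm$G)))
  g_lf <- structure(list(G = gm$G[, 1, drop = FALSE], snps = gm$snps[1, ],
                         samples = gm$samples), class = "genotype_matrix")
  g_lf$snps$maf <- 0.03; g_lf$snps$freq_class <- "low_frequency"
  g_c <- structure(list(G = gm$G[, 2:3], snps = gm$snps[2:3, ],
                        samples = gm$samples), class = "genotype_matrix")
  res <- skat_c_test(g_lf, g_c, ph)
  phi <- attr(res, "phi")
  expect_true(phi > 0 && phi < 1)
  # orthogonal blocks: combined null weights = union of scaled block weights
  p1 <- genebin:::.skat_prep(g_lf$G, genebin:::skat_weights(g_lf$snps$maf, "lf"))
  p2 <- genebin:::.skat_prep(g_c$G, genebin:::skat_weights(g_c$snps$maf, "common"))
  expected <- sort(c(phi * p1$lam, (1 - phi) * p2$lam), decreasing = TRUE)
  expect_equal(res$mixture_weights / var(ph$y), expected, tolerance = 1e-8)

  # one empty subset falls back to single-set SKAT
  expect_message(res2 <- skat_c_test(NULL, g_c, ph), "single-set")
  expect_equal(attr(res2, "phi"), 0)
  ref <- skat_test(g_c, ph, "common")
  expect_equal(res2$value, ref$value)
  expect_equal(res2$p_value, ref$p_value)
})
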