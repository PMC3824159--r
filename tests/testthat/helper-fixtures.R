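# Fixtures built in code. Shared panels are generated once per test run.

# random genotype matrix with mixed MAFs, guaranteed polymorphic columns
make_gm <- function(n, K, seed, mafs = NULL) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    mafs <- mafs %||% runif(K, 0.05, 0.45)
    repeat {
      G <- sapply(mafs, function(p) rbinom(n, 2, p))
      if (all(apply(G, 2, var) > 0)) break
    }
    genotype_matrix(G, drop_rare = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# orthogonal (balanced factorial) genotype design: centered columns are
# exactly uncorrelated, useful where sample-exact zeros are asserted
make_orthogonal_gm <- function() {
  d <- expand.grid(x1 = 0:2, x2 = 0:2, x3 = 0:2)
  G <- as.matrix(d[rep(seq_len(nrow(d)), 4), ])
  genotype_matrix(G, drop_rare = FALSE)
}

# one shared synthetic panel for the heavier tests
shared_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- generate_pool(gene_panel_spec(n_snps = 12, seed = 20260922))
    pool
  }
})

singleton_bins <- function(K) {
  structure(list(n_bins = K, bin_of = seq_len(K),
                 flipped = rep(FALSE, K), threshold = 0.5),
            class = "bin_assignment")
}

one_bin <- function(K) {
  structure(list(n_bins = 1L, bin_of = rep(1L, K),
                 flipped = rep(FALSE, K), threshold = 0.5),
            class = "bin_assignment")
}
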