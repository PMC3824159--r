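test_that("matrix input is read with sample-based MAF and frequency classes", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("sample\trs1", "a\t0", "b\t1", "c\t2", "d\t0"), f)
  gm <- read_genotypes(f)
  expect_equal(gm$snps$maf, 3 / 8)
  expect_equal(gm$snps$freq_class, "common")
  expect_equal(unname(gm$G[, 1]), c(0, 1, 2, 0))
  expect_equal(gm$samples, c("a", "b", "c", "d"))
})

test_that("major-allele coding is flipped to count the minor allele", {
  # column frequency 0.9 -> recoded 2-g, MAF 0.1
  G <- cbind(a = rep(2, 10), b = rbinom(10, 2, 0.5))
  G[1, 1] <- 0
  gm <- genotype_matrix(G, drop_rare = FALSE)
  expect_equal(gm$snps$maf[1], 0.1)
  expect_equal(unname(gm$G[1, 1]), 2)   # recoded from 0
  expect_true(all(abs(colMeans(gm$G) / 2 - gm$snps$maf) < 1e-12))
})

test_that("monomorphic and MAF<1% SNPs are filtered with warnings", {
  set.seed(1)
  G <- cbind(keep = rbinom(1000, 2, 0.3),
             rare = c(rep(1, 5), rep(0, 995)),     # maf 0.0025
             mono = rep(1, 1000))
  expect_warning(expect_warning(gm <- genotype_matrix(G), "monomorphic"),
                 "MAF < 0.01")
  expect_equal(gm$snps$id, "keep")
  expect_error(suppressWarnings(genotype_matrix(cbind(rep(0, 10)))),
               "no SNPs")
})

test_that("missing genotypes are rejected unless imputation is requested", {
  G <- cbind(a = c(0, 1, 2, NA, 1, 1), b = c(0, 1, 0, 1, 2, 0))
  expect_error(genotype_matrix(G), "missing")
  gm <- genotype_matrix(G, impute_missing = TRUE, drop_rare = FALSE)
  expect_true(all(gm$G %in% 0:2))
})

test_that("MAF partitioning is boundary-inclusive per the defining inequalities", {
  n <- 200
  G <- cbind(at05 = c(rep(1, 20), rep(0, 180)),    # maf exactly 0.05
             at01 = c(rep(1, 4), rep(0, 196)),     # maf exactly 0.01
             com = rep(c(0, 1, 2, 1), 50))
  gm <- genotype_matrix(G, drop_rare = FALSE)
  expect_equal(gm$snps$freq_class, c("common", "low_frequency", "common"))
  expect_equal(partition_by_maf(gm, "common")$snps$id, c("at05", "com"))
  expect_equal(partition_by_maf(gm, "low_frequency")$snps$id, "at01")
  expect_identical(partition_by_maf(gm, "all")$snps$id, gm$snps$id)
  gm_c <- partition_by_maf(gm, "common")
  expect_error(partition_by_maf(gm_c, "low_frequency"), "low_frequency")
})

test_that("phenotype join restricts to the sample intersection in genotype order", {
  gm <- make_gm(20, 3, seed = 5)
  ph <- phenotype(gm$samples, rnorm(20))
  suppressMessages({
    j1 <- join_phenotype(gm, ph)
    expect_identical(j1$gm$G, gm$G)
    expect_identical(j1$ph$y, ph$y)

    ph2 <- phenotype(c(gm$samples, "extra"), c(ph$y, 99))
    j2 <- join_phenotype(gm, ph2)
    expect_equal(length(j2$ph$y), 20)
  })
  ph3 <- phenotype(paste0("other", 1:20), rnorm(20))
  expect_error(join_phenotype(gm, ph3), "no samples shared")
})

test_that("coding flips preserve |r| between columns", {
  gm <- make_gm(100, 4, seed = 7)
  R0 <- abs(correlation_matrix(gm))
  gm$G[, 2] <- 2 - gm$G[, 2]
  R1 <- abs(cor(gm$G))
  expect_equal(R0, R1, tolerance = 1e-12)
})

test_that("VCF records are parsed, recoded to the minor allele, and validated", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3\ts4",
    "1\t100\trsA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "1\t200\trsB\tC\tT\t.\tPASS\t.\tGT\t1|1\t1|1\t0|1\t1|1"), f)
  gm <- read_genotypes(f)
  expect_equal(gm$snps$id, c("rsA", "rsB"))
  expect_equal(unname(gm$G[, "rsA"]), c(0, 1, 2, 0))
  # rsB ALT frequency 7/8 -> recoded, maf 1/8
  expect_equal(gm$snps$maf[2], 1 / 8)
  expect_equal(unname(gm$G[, "rsB"]), c(0, 0, 1, 0))
  expect_equal(gm$snps$position, c(100L, 200L))

  f2 <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "1\t300\trsM\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2"), f2)
  expect_error(read_genotypes(f2), "rsM")
})
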