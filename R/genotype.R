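#' Construct a validated genotype matrix
#'
#' Builds the central genotype container used by every analysis function:
#' an n x K matrix of additive genotype codes (minor-allele counts in
#' \{0, 1, 2\}) together with per-SNP metadata. The minor allele is always
#' the coded allele: any column whose allele frequency exceeds 0.5 is
#' recoded as `2 - g`. MAF is recomputed from the sample, never trusted
#' from input metadata, and each SNP is classified as `common`
#' (MAF >= 0.05), `low_frequency` (0.01 <= MAF < 0.05) or `excluded`
#' (MAF < 0.01).
#'
#' @param G numeric matrix (samples x SNPs) with entries in \{0, 1, 2\};
#'   `NA` entries are rejected unless `impute_missing = TRUE`.
#' @param snp_ids character vector of SNP identifiers (defaults to column
#'   names, or `snp1..snpK`).
#' @param positions integer 1-based positions (defaults to column index).
#' @param samples character sample identifiers (defaults to row names, or
#'   `s1..sn`).
#' @param drop_rare drop SNPs with sample MAF < 0.01 (with a warning)?
#'   Loaded data uses `TRUE`; the simulator keeps such columns so causal
#'   indexing stays intact.
#' @param impute_missing mean-impute missing genotypes (rounded to the
#'   nearest valid code)? Default rejects missing data.
#' @return An object of class `genotype_matrix`: list with elements `G`
#'   (matrix), `snps` (data.frame: id, position, maf, freq_class) and
#'   `samples`.
#' @export
genotype_matrix <- function(G, snp_ids = NULL, positions = NULL,
                            samples = NULL, drop_rare = TRUE,
                            impute_missing = FALSE) {
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  n <- nrow(G); K <- ncol(G)
  if (K < 1L) stop("genotype matrix needs at least one SNP column")
  if (n < 2L) stop("genotype matrix needs at least two samples")
  snp_ids <- snp_ids %||% colnames(G) %||% paste0("snp", seq_len(K))
  positions <- positions %||% seq_len(K)
  samples <- samples %||% rownames(G) %||% paste0("s", seq_len(n))
  if (anyNA(G)) {
    if (!impute_missing)
      stop("missing genotypes present; set impute_missing = TRUE or clean the input")
    for (j in seq_len(K)) {
      miss <- is.na(G[, j])
      if (any(miss)) {
        mj <- round(mean(G[!miss, j]))
        G[miss, j] <- min(max(mj, 0), 2)
      }
    }
  }
  if (!all(G %in% c(0, 1, 2)))
    stop("genotype codes must be 0, 1 or 2 (additive minor-allele counts)")

  # minor-allele convention: recode columns where the coded allele is major
  p <- colMeans(G) / 2
  flip <- p > 0.5
  if (any(flip)) {
    G[, flip] <- 2 - G[, flip]
    p[flip] <- 1 - p[flip]
  }
  v <- apply(G, 2, stats::var)
  mono <- v == 0
  rare <- !mono & p < 0.01
  keep <- !mono & (!drop_rare | !rare)
  if (any(mono))
    warning("dropping ", sum(mono), " monomorphic SNP(s): ",
            paste(snp_ids[mono], collapse = ", "))
  if (drop_rare && any(rare))
    warning("dropping ", sum(rare), " SNP(s) with MAF < 0.01: ",
            paste(snp_ids[rare], collapse = ", "))
  if (!any(keep)) stop("no SNPs survive validation/filtering")
  G <- G[, keep, drop = FALSE]
  snps <- data.frame(
    id = as.character(snp_ids[keep]),
    position = as.integer(positions[keep]),
    maf = p[keep],
    freq_class = maf_class(p[keep]),
    stringsAsFactors = FALSE
  )
  rownames(G) <- samples
  colnames(G) <- snps$id
  structure(list(G = G, snps = snps, samples = as.character(samples)),
            class = "genotype_matrix")
}

maf_class <- function(p) {
  ifelse(p >= 0.05, "common", ifelse(p >= 0.01, "low_frequency", "excluded"))
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(factor(x$snps$freq_class,
                      levels = c("common", "low_frequency", "excluded")))
  cat("genotype_matrix: ", length(x$samples), " samples x ",
      nrow(x$snps), " SNPs (", tab[["common"]], " common, ",
      tab[["low_frequency"]], " low frequency)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Read genotypes from VCF or a TSV genotype matrix
#'
#' VCF records must be biallelic SNPs; genotypes are taken from the GT
#' field and recoded so the column counts the sample minor allele. The
#' matrix format is a TSV with the sample id in the first column and one
#' header-named column per SNP holding 0/1/2 codes. In both cases SNPs
#' that are monomorphic or have sample MAF below 1% are dropped with a
#' warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"matrix"`.
#' @param impute_missing passed to [genotype_matrix()].
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix"),
                           impute_missing = FALSE) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "matrix"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix)))                    # single-record files
      fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
    bad <- grepl(",", fix[, "ALT"]) | nchar(fix[, "REF"]) != 1L |
      nchar(fix[, "ALT"]) != 1L
    if (any(bad)) {
      w <- which(bad)[1]
      stop("non-biallelic-SNP record at ", fix[w, "CHROM"], ":", fix[w, "POS"],
           " (", fix[w, "ID"], ")")
    }
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(s) {
      a <- strsplit(s, "[/|]")
      vapply(a, function(al) {
        if (any(is.na(al)) || any(al == ".")) return(NA_real_)
        sum(al == "1")
      }, numeric(1))
    }
    G <- t(matrix(count_alt(as.vector(gt)), nrow = nrow(gt),
                  dimnames = dimnames(gt)))   # samples x SNPs
    ids <- fix[, "ID"]
    ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
    genotype_matrix(G, snp_ids = ids, positions = as.integer(fix[, "POS"]),
                    samples = colnames(gt), drop_rare = TRUE,
                    impute_missing = impute_missing)
  } else {
    d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(d) < 2L) stop("matrix format needs a sample-id column plus SNP columns")
    G <- as.matrix(d[, -1, drop = FALSE])
    genotype_matrix(G, snp_ids = colnames(d)[-1],
                    samples = as.character(d[[1]]), drop_rare = TRUE,
                    impute_missing = impute_missing)
  }
}

#' Construct a phenotype vector
#'
#' @param samples character sample ids.
#' @param y numeric quantitative trait values, one per sample.
#' @return Object of class `phenotype` (list: samples, y).
#' @export
phenotype <- function(samples, y) {
  y <- as.numeric(y)
  samples <- as.character(samples)
  if (length(samples) != length(y)) stop("samples and y lengths differ")
  if (anyNA(y) || any(!is.finite(y))) stop("trait values must be finite")
  if (stats::var(y) <= 0) stop("trait has zero variance")
  structure(list(samples = samples, y = y), class = "phenotype")
}

#' Read a phenotype TSV (columns: sample, trait)
#' @param path file path.
#' @return A [phenotype()].
#' @export
read_phenotype <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("phenotype file needs columns: sample, trait")
  phenotype(d[[1]], d[[2]])
}

#' Subset a genotype matrix by MAF analysis set
#'
#' The three analysis sets of the combined common / low-frequency design:
#' all SNPs, common SNPs (MAF >= 0.05), or low frequency SNPs
#' (0.01 <= MAF < 0.05). Boundary values are included per the defining
#' inequalities.
#'
#' @param gm a [genotype_matrix()].
#' @param analysis_set `"all"`, `"common"` or `"low_frequency"`.
#' @return A [genotype_matrix()] restricted to the set.
#' @export
partition_by_maf <- function(gm, analysis_set = c("all", "common", "low_frequency")) {
  analysis_set <- match.arg(analysis_set)
  if (analysis_set == "all") return(gm)
  keep <- gm$snps$freq_class == analysis_set
  if (!any(keep))
    stop("analysis set '", analysis_set, "' is empty for this gene")
  subset_gm(gm, which(keep))
}

subset_gm <- function(gm, cols) {
  structure(list(G = gm$G[, cols, drop = FALSE],
                 snps = gm$snps[cols, , drop = FALSE],
                 samples = gm$samples),
            class = "genotype_matrix")
}

#' Align genotypes and phenotype on shared samples
#'
#' Restricts both objects to the intersection of sample ids, preserving
#' the genotype-matrix sample order.
#'
#' @param gm a [genotype_matrix()].
#' @param ph a [phenotype()].
#' @return List with elements `gm` and `ph`, aligned one-to-one.
#' @export
join_phenotype <- function(gm, ph) {
  common <- intersect(gm$samples, ph$samples)
  if (length(common) == 0L) stop("no samples shared between genotypes and phenotype")
  gi <- which(gm$samples %in% common)
  gm2 <- structure(list(G = gm$G[gi, , drop = FALSE],
                        snps = gm$snps,
                        samples = gm$samples[gi]),
                   class = "genotype_matrix")
  ph2 <- phenotype(gm2$samples, ph$y[match(gm2$samples, ph$samples)])
  message("joined ", length(common), " samples")
  list(gm = gm2, ph = ph2)
}
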