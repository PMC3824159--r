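#' Pairwise genotype correlation matrix
#'
#' Pearson correlation r of the additive 0/1/2 genotype columns; the LD
#' measure used for binning (as r^2) and for the coding correction (sign
#' of r).
#'
#' @param gm a [genotype_matrix()].
#' @return Symmetric K x K correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(gm) {
  v <- apply(gm$G, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance genotype column(s): ",
         paste(gm$snps$id[v == 0], collapse = ", "))
  stats::cor(gm$G)
}

#' Greedy LD binning (LDSelect-style)
#'
#' Partitions SNPs into bins of mutually associated markers. Repeatedly,
#' among unassigned SNPs, the SNP with the largest number of unassigned
#' partners at r^2 strictly above the threshold is chosen (ties broken by
#' lowest SNP index, for determinism); that SNP and all such partners form
#' the next bin, so larger bins are constructed first. SNPs with no
#' partner end as singleton bins.
#'
#' @param R correlation matrix from [correlation_matrix()].
#' @param threshold r^2 cutoff; a pair is binned together when
#'   `r^2 > threshold`. Default 0.5.
#' @return Object of class `bin_assignment`: `n_bins`, `bin_of` (length-K
#'   integer map), `flipped` (length-K logical, all `FALSE` until
#'   [coding_correction()]), `threshold`.
#' @export
ldselect_bins <- function(R, threshold = 0.5) {
  R <- as.matrix(R)
  K <- nrow(R)
  stopifnot(K == ncol(R))
  r2 <- R^2
  diag(r2) <- 0
  bin_of <- integer(K)
  b <- 0L
  unassigned <- rep(TRUE, K)
  while (any(unassigned)) {
    b <- b + 1L
    idx <- which(unassigned)
    cnt <- vapply(idx, function(i) sum(r2[i, idx] > threshold), numeric(1))
    pick <- idx[which.max(cnt)]          # ties -> lowest index (idx is sorted)
    members <- union(pick, idx[r2[pick, idx] > threshold])
    bin_of[members] <- b
    unassigned[members] <- FALSE
  }
  structure(list(n_bins = b, bin_of = bin_of,
                 flipped = rep(FALSE, K), threshold = threshold),
            class = "bin_assignment")
}

#' @export
print.bin_assignment <- function(x, ...) {
  cat("bin_assignment: ", length(x$bin_of), " SNPs in ", x$n_bins,
      " bins (r^2 > ", x$threshold, ")\n", sep = "")
  invisible(x)
}

#' Bin indicator matrix
#'
#' The K x L 0/1 matrix J with exactly one 1 per row marking each SNP's
#' bin; the weighting backbone of the MLC statistics.
#'
#' @param bins a `bin_assignment`.
#' @param subset optional integer vector restricting to a subset of SNP
#'   indices (e.g. after collinearity drops); empty bins are removed and
#'   bin columns re-indexed.
#' @return 0/1 indicator matrix.
#' @export
bin_indicator <- function(bins, subset = NULL) {
  bo <- bins$bin_of
  if (!is.null(subset)) bo <- bo[subset]
  lv <- sort(unique(bo))
  J <- outer(bo, lv, "==") * 1
  colnames(J) <- paste0("bin", lv)
  J
}

#' Within-bin allele-coding correction
#'
#' Within each bin of two or more SNPs, members are scanned in ascending
#' SNP index; a member whose number of strictly negative correlations
#' with the other bin members exceeds half of them is recoded `g -> 2-g`
#' and the within-bin correlations are recomputed immediately. One full
#' pass is made per bin, which reaches a fixed point on the structures
#' binning can produce (re-running yields no further flips). This aligns
#' codings so within-bin correlations are predominantly positive before
#' coefficients are combined linearly. MAF metadata refers to the minor
#' allele and is unchanged by a flip.
#'
#' @param gm a [genotype_matrix()] on which `bins` was computed.
#' @param bins a `bin_assignment` from [ldselect_bins()].
#' @return List with the recoded `gm` and `bins` carrying the `flipped`
#'   flags.
#' @export
coding_correction <- function(gm, bins) {
  G <- gm$G
  flipped <- bins$flipped
  for (b in seq_len(bins$n_bins)) {
    mem <- which(bins$bin_of == b)
    if (length(mem) < 2L) next
    Rb <- stats::cor(G[, mem, drop = FALSE])
    for (m in seq_along(mem)) {
      neg <- sum(Rb[m, -m] < 0)
      if (neg > (length(mem) - 1) / 2) {
        j <- mem[m]
        G[, j] <- 2 - G[, j]
        flipped[j] <- !flipped[j]
        Rb <- stats::cor(G[, mem, drop = FALSE])
      }
    }
  }
  gm$G <- G
  bins$flipped <- flipped
  list(gm = gm, bins = bins)
}

#' Write a bin report TSV (snp id, bin index, flipped flag)
#' @param gm a [genotype_matrix()].
#' @param bins a `bin_assignment`.
#' @param path output path.
#' @return Invisibly, the report data.frame.
#' @export
write_bin_report <- function(gm, bins, path) {
  d <- data.frame(snp = gm$snps$id, bin = bins$bin_of, flipped = bins$flipped)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(d)
}
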