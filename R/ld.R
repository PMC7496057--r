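#' Pairwise linkage disequilibrium as squared dosage correlation
#'
#' r2 between two SNPs is the squared Pearson correlation of their dosage
#' vectors over the jointly non-missing samples — the composite-genotype LD
#' measure used when phase is unknown.
#'
#' @param g a [geno_matrix()].
#' @param snp_a,snp_b SNP ids or column indices.
#' @return r2 in [0, 1]; NA (with a warning) if either SNP has zero dosage
#'   variance over the shared samples.
#' @export
ld_r2 <- function(g, snp_a, snp_b) {
  if (is.character(snp_a)) snp_a <- match(snp_a, g$map$snp)
  if (is.character(snp_b)) snp_b <- match(snp_b, g$map$snp)
  a <- g$dosage[, snp_a]; b <- g$dosage[, snp_b]
  ok <- !is.na(a) & !is.na(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 2 || stats::var(a) == 0 || stats::var(b) == 0) {
    warning("r2 undefined: zero-variance SNP over jointly typed samples")
    return(NA_real_)
  }
  stats::cor(a, b)^2
}

#' Prune SNPs in high linkage disequilibrium
#'
#' Scans SNPs in map order within each chromosome using a sliding window of
#' `window_snps` markers. Whenever a SNP's r2 with an already-retained SNP
#' in the window exceeds `r2_max`, the later SNP of the pair (the one being
#' scanned) is removed, so exactly one SNP from every offending pair
#' survives.
#'
#' @param g a [geno_matrix()].
#' @param r2_max retain threshold; pairs with r2 strictly above it lose
#'   their later member (default 0.9).
#' @param window_snps width of the within-chromosome scan window in
#'   markers (default 50).
#' @return list with `genotypes` (pruned [geno_matrix()]) and `removed`
#'   (character vector of removed SNP ids).
#' @export
ld_prune <- function(g, r2_max = 0.9, window_snps = 50L) {
  d <- g$dosage
  keep <- rep(TRUE, ncol(d))
  for (cc in unique(g$map$chr)) {
    idx <- which(g$map$chr == cc)
    idx <- idx[order(g$map$pos[idx])]
    for (k in seq_along(idx)) {
      j <- idx[k]
      if (k == 1L) next
      prev <- idx[max(1L, k - window_snps + 1L):(k - 1L)]
      prev <- prev[keep[prev]]
      for (i in prev) {
        r2 <- suppressWarnings(ld_r2(g, i, j))
        if (!is.na(r2) && r2 > r2_max) { keep[j] <- FALSE; break }
      }
    }
  }
  list(genotypes = subset_geno(g, snps = which(keep)),
       removed = g$map$snp[!keep])
}
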