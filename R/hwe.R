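#' Hardy-Weinberg exact test
#'
#' Exact conditional test of Hardy-Weinberg proportions given the allele
#' counts (the test PLINK's `--hwe` applies). With n1 + n2 rare alleles
#' fixed, the probability of each attainable heterozygote count is
#' hypergeometric-like; the two-sided P value is the sum of the
#' probabilities of all heterozygote counts no more probable than the
#' observed one.
#'
#' @param n_hom1 count of homozygotes for allele 1.
#' @param n_het count of heterozygotes.
#' @param n_hom2 count of homozygotes for allele 2.
#' @return Two-sided exact P value in (0, 1].
#' @examples
#' hwe_exact_test(5, 0, 5)   # strong heterozygote deficit, tiny P
#' hwe_exact_test(25, 50, 25) # textbook proportions, P = 1
#' @export
hwe_exact_test <- function(n_hom1, n_het, n_hom2) {
  if (any(c(n_hom1, n_het, n_hom2) < 0))
    stop("genotype counts must be non-negative")
  n <- n_hom1 + n_het + n_hom2
  if (n == 0) stop("at least one genotyped sample is required")
  n_rare <- 2L * min(n_hom1, n_hom2) + n_het
  pr <- hwe_het_distribution(n, n_rare)
  obs <- pr[as.character(n_het)]
  if (is.na(obs)) stop("heterozygote count incompatible with allele counts")
  # tolerance guards against probabilities equal up to rounding
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# probability mass over attainable heterozygote counts, conditional on the
# rare-allele count; computed by Levene/Haldane recurrence in log space
hwe_het_distribution <- function(n, n_rare) {
  hets <- seq.int(n_rare %% 2L, min(n_rare, 2L * n - n_rare), by = 2L)
  lp <- numeric(length(hets))
  # unnormalised log mass: n! 2^het / (hom1! het! hom2!)
  for (i in seq_along(hets)) {
    het <- hets[i]
    hom_r <- (n_rare - het) / 2
    hom_c <- n - het - hom_r
    lp[i] <- het * log(2) - lfactorial(hom_r) - lfactorial(het) -
      lfactorial(hom_c)
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  names(p) <- hets
  p
}

#' Per-SNP Hardy-Weinberg P values
#'
#' @param g a [geno_matrix()].
#' @return numeric vector of exact HWE P values, one per SNP (NA where no
#'   genotypes are observed).
#' @export
snp_hwe <- function(g) {
  apply(g$dosage, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NA_real_)
    hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
  })
}
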