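# Small fixtures built in code.

# hand-rolled genotype matrix from a dosage matrix and breed vector
toy_geno <- function(dosage, breeds, chr = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  ns <- ncol(dosage)
  if (is.null(chr)) chr <- rep("1", ns)
  if (is.null(pos)) pos <- seq(1000L, by = 1000L, length.out = ns)
  geno_matrix(dosage,
              data.frame(sample_id = sprintf("s%03d", seq_len(nrow(dosage))),
                         breed = breeds, stringsAsFactors = FALSE),
              data.frame(snp = sprintf("t%03d", seq_len(ns)),
                         chr = chr, pos = pos, a1 = "A", a2 = "G",
                         stringsAsFactors = FALSE))
}

# small clean cohort for integration-style tests
small_cohort <- function(seed = 1, n_breeds = 8, samples_per_breed = 15,
                         n_snps = 120, ...) {
  cfg <- sim_config(n_breeds = n_breeds,
                    samples_per_breed = samples_per_breed,
                    n_snps = n_snps, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  list(config = cfg, genotypes = g,
       phenotypes = simulate_phenotypes(cfg, g))
}

# independent closed-form oracle for the exact Hardy-Weinberg test:
# P(het = h | n, rare alleles) = n! 2^h / (homR! h! homC!) / C(2n, n_rare),
# normalised by the hypergeometric denominator rather than by summation
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  pr <- vapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    exp(lfactorial(n) - lfactorial(hom_r) - lfactorial(h) -
          lfactorial(hom_c) + h * log(2) -
          (lchoose(2 * n, n_rare)))
  }, 0)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# brute-force per-SNP association oracle via lm()
lm_assoc_oracle <- function(g, y) {
  do.call(rbind, lapply(seq_len(n_snps(g)), function(j) {
    x <- g$dosage[, j]
    ok <- !is.na(x)
    if (sum(ok) < 3 || length(unique(x[ok])) < 2 ||
        stats::var(y[ok]) == 0)
      return(data.frame(beta = NA_real_, raw_p = NA_real_))
    fit <- summary(stats::lm(y[ok] ~ x[ok]))
    data.frame(beta = fit$coefficients[2, 1],
               raw_p = fit$coefficients[2, 4])
  }))
}
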