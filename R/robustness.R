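#' Subject-resampling robustness of an association experiment
#'
#' Repeats the full association + permutation experiment `reps` times,
#' each time removing `floor(frac * n)` samples uniformly at random (with
#' 1274 samples and frac = 0.10 this leaves 1147), and summarises how
#' stably each SNP keeps its significance tier across replicates. A breed
#' emptied by the removal is simply absent from that replicate (warning).
#'
#' @param g a [geno_matrix()].
#' @param pheno breed phenotype data.frame.
#' @param column trait column name.
#' @param candidates character vector of SNP ids or NULL.
#' @param frac fraction of samples removed per replicate (default 0.10).
#' @param reps number of replicates (default 10).
#' @param n_perm permutations per replicate.
#' @param seed integer seed.
#' @param alpha,marginal tier thresholds.
#' @return list of class `resample_robustness`: `replicates` (list of
#'   association tables), `stability` (per SNP: times significant /
#'   marginal across replicates), `n_kept` (samples per replicate).
#' @export
resample_robustness <- function(g, pheno, column, candidates = NULL,
                                frac = 0.10, reps = 10L, n_perm = 1000L,
                                seed = 1L, alpha = 0.05, marginal = 0.1) {
  if (frac < 0 || frac >= 1) stop("frac must lie in [0, 1)")
  if (reps < 1) stop("reps must be at least 1")
  n <- n_samples(g)
  n_remove <- floor(frac * n)
  seeds <- derive_seed(seed, "resample") + seq_len(reps)
  replicates <- vector("list", reps)
  n_kept <- integer(reps)
  for (r in seq_len(reps)) {
    gg <- if (n_remove > 0) {
      drop <- with_seed(seeds[r], sample.int(n, n_remove))
      sub <- subset_geno(g, samples = setdiff(seq_len(n), drop))
      lost <- setdiff(unique(g$samples$breed), unique(sub$samples$breed))
      if (length(lost))
        warning("replicate ", r, " emptied breed(s): ",
                paste(lost, collapse = ", "))
      sub
    } else g
    n_kept[r] <- n_samples(gg)
    ex <- run_association_experiment(gg, pheno, column,
                                     candidates = candidates,
                                     n_perm = n_perm, seed = seed,
                                     alpha = alpha, marginal = marginal)
    replicates[[r]] <- ex$table
  }
  snps <- replicates[[1]]$snp
  tier_mat <- vapply(replicates,
                     function(t) t$tier[match(snps, t$snp)],
                     character(length(snps)))
  tier_mat <- matrix(tier_mat, nrow = length(snps))
  stability <- data.frame(
    snp = snps,
    times_significant = rowSums(tier_mat == "significant", na.rm = TRUE),
    times_marginal_or_better =
      rowSums(matrix(tier_mat %in% c("significant", "marginal"),
                     nrow = length(snps)), na.rm = TRUE),
    reps = reps, stringsAsFactors = FALSE)
  structure(list(replicates = replicates, stability = stability,
                 n_kept = n_kept, frac = frac, seed = as.integer(seed)),
            class = "resample_robustness")
}

#' Per-breed frequency of the global minor allele
#'
#' The minor-allele orientation is fixed once on the full cohort (the
#' dosage allele of the [geno_matrix()]), then its frequency is computed
#' within each breed over that breed's non-missing genotypes — so values
#' are comparable across breeds and may exceed 0.5 within a breed fixed
#' for the globally minor allele.
#'
#' @param g a [geno_matrix()].
#' @return breeds x SNPs numeric matrix of allele frequencies (NA where a
#'   breed has no genotype call at a SNP).
#' @export
per_breed_maf <- function(g) {
  breeds <- unique(g$samples$breed)
  out <- matrix(NA_real_, length(breeds), n_snps(g),
                dimnames = list(breeds, g$map$snp))
  for (i in seq_along(breeds)) {
    rows <- g$samples$breed == breeds[i]
    out[i, ] <- colMeans(g$dosage[rows, , drop = FALSE], na.rm = TRUE) / 2
  }
  out[!is.finite(out)] <- NA_real_
  out
}

#' Per-SNP correlation between breed allele frequency and a breed trait
#'
#' The independent validation scan: for each SNP, Pearson and Spearman
#' correlations across breeds between the per-breed minor-allele frequency
#' and the breed-level trait, over pairwise-complete breeds; Benjamini-
#' Hochberg q-values over all tested SNPs (`fdr_q` adjusts the Spearman P,
#' `pearson_q` the Pearson P). SNPs with fewer than 3 informative breeds
#' are skipped with a warning.
#'
#' @param freq breeds x SNPs matrix from [per_breed_maf()].
#' @param trait_values named numeric vector of breed trait values (names =
#'   breed labels matching `rownames(freq)`).
#' @return data.frame per tested SNP: `snp`, `n_breeds`, `pearson_r`,
#'   `pearson_p`, `spearman_rho`, `spearman_p`, `fdr_q`, `pearson_q`,
#'   sorted by `spearman_p`.
#' @export
maf_trait_correlation <- function(freq, trait_values) {
  tv <- trait_values[rownames(freq)]
  if (anyNA(tv))
    stop("trait values missing for breed(s): ",
         paste(rownames(freq)[is.na(tv)], collapse = ", "))
  res <- lapply(seq_len(ncol(freq)), function(j) {
    f <- freq[, j]
    ok <- !is.na(f)
    if (sum(ok) < 3) return(NULL)
    x <- f[ok]; y <- tv[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
    pe <- stats::cor.test(x, y, method = "pearson")
    sp <- spearman(x, y)
    data.frame(snp = colnames(freq)[j], n_breeds = sum(ok),
               pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
               spearman_rho = sp$rho, spearman_p = sp$p_value,
               stringsAsFactors = FALSE)
  })
  skipped <- sum(vapply(res, is.null, TRUE))
  if (skipped)
    warning(skipped, " SNP(s) skipped: fewer than 3 informative breeds ",
            "or zero variance")
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no SNP had enough informative breeds")
  out$fdr_q <- stats::p.adjust(out$spearman_p, method = "BH")
  out$pearson_q <- stats::p.adjust(out$pearson_p, method = "BH")
  out[order(out$spearman_p), , drop = FALSE]
}

#' Lowest-P SNPs from a frequency-trait correlation scan
#' @param scan result of [maf_trait_correlation()].
#' @param n how many SNPs to report (default 30).
#' @return the `n` rows with smallest Spearman P.
#' @export
top_maf_hits <- function(scan, n = 30L) {
  utils::head(scan[order(scan$spearman_p), , drop = FALSE], n)
}
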