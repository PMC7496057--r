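#' Expand breed-level trait values to a per-sample vector
#'
#' Each sample receives its breed's trait value, so the association model
#' sees a within-breed-constant quantitative phenotype.
#'
#' @param g a [geno_matrix()].
#' @param pheno breed phenotype data.frame.
#' @param column name of the trait column in `pheno`.
#' @return numeric vector, one value per sample of `g`.
#' @export
assign_breed_values <- function(g, pheno, column) {
  if (!column %in% names(pheno))
    stop("trait column not found in the phenotype table: ", column)
  idx <- match(g$samples$breed, pheno$breed)
  if (anyNA(idx))
    stop("breed(s) missing from the phenotype table: ",
         paste(unique(g$samples$breed[is.na(idx)]), collapse = ", "))
  as.numeric(pheno[[column]][idx])
}

# Sufficient statistics reused across permutations: the missingness mask M
# and the zero-filled dosage matrix G0, plus per-SNP dosage sums over the
# non-missing samples.
assoc_precompute <- function(g) {
  M <- !is.na(g$dosage)
  G0 <- g$dosage
  G0[!M] <- 0L
  storage.mode(M) <- "double"
  storage.mode(G0) <- "double"
  n <- colSums(M)
  Sg <- colSums(G0)
  Sgg <- colSums(G0 * G0)
  list(M = M, G0 = G0, n = n, Sg = Sg, Sgg = Sgg,
       Sxx = Sgg - Sg^2 / pmax(n, 1))
}

# Additive-model scan of every SNP against each column of Y (n x K).
# Per SNP: OLS of trait on dosage with intercept over non-missing samples;
# missing genotypes are case-deleted per SNP. Returns p x K matrices of
# two-sided Wald-t raw P values (and betas / SEs). Implemented through
# cross-products so a whole permutation batch costs three matrix products.
assoc_scan <- function(pre, Y) {
  Y <- as.matrix(Y)
  Sy <- crossprod(pre$M, Y)
  Syy <- crossprod(pre$M, Y * Y)
  Sgy <- crossprod(pre$G0, Y)
  n <- pre$n
  Sxy <- Sgy - (pre$Sg / pmax(n, 1)) * Sy
  Syy_c <- Syy - Sy^2 / pmax(n, 1)
  ok_snp <- n >= 3 & pre$Sxx > 1e-12
  beta <- Sxy / pre$Sxx
  r2 <- Sxy^2 / (pre$Sxx * Syy_c)
  df <- n - 2
  tt <- sqrt(pmax(r2, 0) * df / pmax(1 - r2, .Machine$double.eps))
  p <- 2 * stats::pt(-tt, df)
  p <- pmax(p, .Machine$double.xmin)
  bad <- !ok_snp | !(Syy_c > 1e-12) | !is.finite(p)
  p[bad] <- NA_real_
  beta[bad] <- NA_real_
  se <- abs(beta) / tt
  se[bad | tt == 0] <- NA_real_
  list(raw_p = p, beta = beta, se = se, n_used = n)
}

#' Per-SNP additive-model association
#'
#' For every SNP, ordinary least squares of the trait on minor-allele
#' dosage (0/1/2) with intercept, over the samples with a non-missing
#' genotype at that SNP; the raw P value is the two-sided Wald t-test on
#' the slope. SNPs monomorphic after case deletion, or with fewer than 3
#' typed samples, get `raw_p = NA` with a warning.
#'
#' @param g a [geno_matrix()].
#' @param trait_vector per-sample numeric trait (see
#'   [assign_breed_values()]).
#' @return data.frame with one row per SNP: `snp`, `chr`, `pos`, `n_used`,
#'   `beta`, `se`, `raw_p`.
#' @export
additive_association <- function(g, trait_vector) {
  if (length(trait_vector) != n_samples(g))
    stop("trait vector length must equal the number of samples")
  pre <- assoc_precompute(g)
  sc <- assoc_scan(pre, matrix(trait_vector, ncol = 1))
  if (anyNA(sc$raw_p))
    warning(sprintf("%d SNP(s) degenerate (monomorphic or < 3 samples after case deletion, or zero trait variance): raw_p set to NA",
                    sum(is.na(sc$raw_p))))
  data.frame(snp = g$map$snp, chr = g$map$chr, pos = g$map$pos,
             n_used = as.integer(sc$n_used),
             beta = sc$beta[, 1], se = sc$se[, 1], raw_p = sc$raw_p[, 1],
             stringsAsFactors = FALSE)
}

#' Breed-randomised permutation null of the minimum P value
#'
#' The family-wise null the corrected P values are measured against: in
#' each permutation the breed-to-value map is shuffled uniformly over
#' breed-label permutations (identical values still go to every sample of
#' a breed, preserving the within-breed-constant structure), the additive
#' scan is re-run on all SNPs with the original missing-data pattern, and
#' the minimum raw P across SNPs is recorded. Permutations are sampled
#' with replacement from the permutation group (the identity can occur).
#'
#' @param g a [geno_matrix()].
#' @param pheno breed phenotype data.frame.
#' @param column trait column name.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param scheme `"breed"` permutes whole breeds (the correct block
#'   scheme); `"individual"` permutes sample labels freely, deliberately
#'   ignoring breed structure — kept for calibration comparisons only.
#' @param chunk permutations evaluated per matrix product (memory knob).
#' @return list of class `perm_null`: `min_p` (length `n_perm`), `n_perm`,
#'   `seed`, `scheme`.
#' @export
breed_permutation_null <- function(g, pheno, column, n_perm = 1000L,
                                   seed = 1L,
                                   scheme = c("breed", "individual"),
                                   chunk = 200L) {
  scheme <- match.arg(scheme)
  if (n_perm < 1) stop("n_perm must be at least 1")
  breeds <- unique(g$samples$breed)
  if (length(breeds) < 2) stop("at least 2 breeds are required")
  y <- assign_breed_values(g, pheno, column)
  vals <- pheno[[column]][match(breeds, pheno$breed)]
  bidx <- match(g$samples$breed, breeds)
  pre <- assoc_precompute(g)
  nb <- length(breeds)
  n <- n_samples(g)
  with_seed(derive_seed(seed, paste0("perm_", column, "_", scheme)), {
    min_p <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      k <- min(chunk, n_perm - done)
      Y <- matrix(0, n, k)
      for (b in seq_len(k)) {
        Y[, b] <- if (scheme == "breed") vals[sample.int(nb)][bidx]
        else y[sample.int(n)]
      }
      p <- assoc_scan(pre, Y)$raw_p
      min_p[done + seq_len(k)] <- apply(p, 2, min, na.rm = TRUE)
      done <- done + k
    }
    structure(list(min_p = min_p, n_perm = as.integer(n_perm),
                   seed = as.integer(seed), scheme = scheme),
              class = "perm_null")
  })
}

#' Permutation-corrected (max-T / min-P) P value
#'
#' corrected P = (1 + #\{permutations whose minimum raw P <= raw P\}) /
#' (n_perm + 1). Ties count as exceedances (conservative). The estimator is
#' bounded below by 1/(n_perm+1) — with 1000 permutations, 1/1001 — and
#' above by 1.
#'
#' @param raw_p numeric vector of raw P values (NA passes through).
#' @param null a `perm_null` from [breed_permutation_null()].
#' @return numeric vector of corrected P values in [1/(n_perm+1), 1].
#' @export
corrected_p <- function(raw_p, null) {
  stopifnot(inherits(null, "perm_null"))
  sm <- sort(null$min_p)
  out <- (1 + findInterval(raw_p, sm)) / (null$n_perm + 1)
  out[is.na(raw_p)] <- NA_real_
  out
}

#' Significance tier from a corrected P value
#' @param p corrected P values.
#' @param alpha significant threshold (strict <, default 0.05).
#' @param marginal marginal threshold (strict <, default 0.1).
#' @return character vector: "significant", "marginal" or "ns".
#' @export
tier_of <- function(p, alpha = 0.05, marginal = 0.1) {
  out <- ifelse(is.na(p), NA_character_,
                ifelse(p < alpha, "significant",
                       ifelse(p < marginal, "marginal", "ns")))
  out
}

#' Run one association experiment with permutation correction
#'
#' The full inference for one trait: restrict to a candidate SNP set (or
#' use all SNPs), run the additive scan, build the breed-randomised minimum
#' P null, attach corrected P values and significance tiers.
#'
#' @param g a [geno_matrix()].
#' @param pheno breed phenotype data.frame.
#' @param column trait column name.
#' @param candidates character vector of SNP ids, or NULL for all SNPs.
#' @param n_perm permutations (default 1000).
#' @param seed integer seed.
#' @param alpha,marginal tier thresholds on corrected P (defaults 0.05 and
#'   0.1, both strict).
#' @return list of class `assoc_experiment`: `table` (association
#'   data.frame with `corrected_p` and `tier`), `null` (the `perm_null`),
#'   `column`, `genotypes` (the SNP-restricted [geno_matrix()]).
#' @export
run_association_experiment <- function(g, pheno, column, candidates = NULL,
                                       n_perm = 1000L, seed = 1L,
                                       alpha = 0.05, marginal = 0.1) {
  if (!is.null(candidates)) {
    missing_ids <- setdiff(candidates, g$map$snp)
    if (length(missing_ids))
      stop("candidate SNP id(s) absent from the genotype map: ",
           paste(utils::head(missing_ids, 10), collapse = ", "))
    g <- subset_geno(g, snps = candidates)
  }
  y <- assign_breed_values(g, pheno, column)
  tab <- suppressWarnings(additive_association(g, y))
  null <- breed_permutation_null(g, pheno, column, n_perm = n_perm,
                                 seed = seed)
  tab$corrected_p <- corrected_p(tab$raw_p, null)
  tab$tier <- tier_of(tab$corrected_p, alpha, marginal)
  structure(list(table = tab, null = null, column = column, genotypes = g),
            class = "assoc_experiment")
}

#' @export
print.assoc_experiment <- function(x, ...) {
  cat(sprintf("association experiment: trait '%s', %d SNPs, %d permutations\n",
              x$column, nrow(x$table), x$null$n_perm))
  cat(sprintf("  significant: %d, marginal: %d\n",
              sum(x$table$tier == "significant", na.rm = TRUE),
              sum(x$table$tier == "marginal", na.rm = TRUE)))
  invisible(x)
}
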