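#' Quality-control configuration
#'
#' Thresholds of the standard SNP-array QC cascade for across-breed
#' analysis: cap each breed at `per_breed_cap` samples, drop non-autosomal
#' SNPs, then SNPs with missingness above `max_missing`, minor allele
#' frequency below `min_maf`, Hardy-Weinberg exact P below `hwe_alpha`, and
#' finally LD-prune at `ld_r2_max`.
#'
#' @param per_breed_cap max samples retained per breed (default 30).
#' @param max_missing missingness threshold; SNPs strictly above are
#'   removed (default 0.10).
#' @param min_maf MAF threshold; SNPs strictly below are removed
#'   (default 0.01).
#' @param hwe_alpha HWE significance level; SNPs with exact P strictly
#'   below are removed (default 0.01).
#' @param hwe_mode `"pooled"` tests the breeds pooled into one sample
#'   (default); `"per_breed"` removes a SNP if any breed with at least 5
#'   typed samples fails at `hwe_alpha`.
#' @param ld_r2_max LD pruning threshold (default 0.9).
#' @param ld_window_snps LD scan window in markers (default 50).
#' @param seed seed for the per-breed subsampling draw.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(per_breed_cap = 30L, max_missing = 0.10,
                      min_maf = 0.01, hwe_alpha = 0.01,
                      hwe_mode = c("pooled", "per_breed"),
                      ld_r2_max = 0.9, ld_window_snps = 50L, seed = 1L) {
  hwe_mode <- match.arg(hwe_mode)
  stopifnot(per_breed_cap >= 1,
            max_missing > 0, max_missing < 1,
            min_maf > 0, min_maf < 1,
            hwe_alpha > 0, hwe_alpha < 1,
            ld_r2_max > 0, ld_r2_max < 1)
  structure(list(per_breed_cap = as.integer(per_breed_cap),
                 max_missing = max_missing, min_maf = min_maf,
                 hwe_alpha = hwe_alpha, hwe_mode = hwe_mode,
                 ld_r2_max = ld_r2_max,
                 ld_window_snps = as.integer(ld_window_snps),
                 seed = as.integer(seed)),
            class = "qc_config")
}

#' Cap the number of samples per breed
#'
#' Breeds at or below the cap are kept whole; larger breeds are reduced to
#' exactly `cap` samples chosen uniformly at random (deterministic per
#' seed). This equalises breed representation before association.
#'
#' @param g a [geno_matrix()].
#' @param cap maximum samples per breed.
#' @param seed integer seed.
#' @return a [geno_matrix()] with at most `cap` samples per breed.
#' @export
subsample_per_breed <- function(g, cap = 30L, seed = 1L) {
  stopifnot(cap >= 1)
  with_seed(derive_seed(seed, "subsample"), {
    keep <- unlist(lapply(split(seq_len(n_samples(g)), g$samples$breed),
                          function(ix) {
                            if (length(ix) <= cap) ix
                            else sort(sample(ix, cap))
                          }), use.names = FALSE)
    subset_geno(g, samples = sort(keep))
  })
}

#' Per-SNP missingness and minor allele frequency
#'
#' Missingness is the fraction of samples with no genotype call at the
#' SNP. MAF is min(f, 1-f) where f is the dosage-allele frequency over the
#' non-missing genotypes (NA if all are missing).
#'
#' @param g a [geno_matrix()].
#' @return numeric vector, one entry per SNP.
#' @export
snp_missingness <- function(g) colMeans(is.na(g$dosage))

#' @rdname snp_missingness
#' @export
snp_maf <- function(g) {
  f <- colMeans(g$dosage, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' Chromosome labels counted as non-autosomal (CanFam convention)
#' @return character vector of labels the autosome filter removes.
#' @export
non_autosomal_labels <- function() c("39", "X", "Y", "XY", "MT", "M")

#' Run the full QC cascade
#'
#' Stage order: per-breed cap, autosome restriction, missingness, MAF,
#' Hardy-Weinberg, LD pruning. The report telescopes: each stage's input
#' counts equal the previous stage's output counts.
#'
#' @param g a [geno_matrix()].
#' @param config a [qc_config()].
#' @return list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (class `qc_report`: per-stage sample/SNP counts and removed SNP ids).
#' @export
run_qc <- function(g, config = qc_config()) {
  stopifnot(inherits(config, "qc_config"))
  stages <- list()
  removed <- list()
  note <- function(stage, gg, rm_ids) {
    stages[[stage]] <<- c(samples = n_samples(gg), snps = n_snps(gg))
    removed[[stage]] <<- rm_ids
    if (n_samples(gg) == 0 || n_snps(gg) == 0)
      stop("QC produced an empty data set at stage: ", stage)
    gg
  }

  g <- note("input", g, character(0))
  g <- note("per_breed_cap",
            subsample_per_breed(g, config$per_breed_cap, config$seed),
            character(0))

  auto_drop <- g$map$snp[g$map$chr %in% non_autosomal_labels()]
  g <- note("autosomes", drop_snps(g, auto_drop), auto_drop)

  miss <- snp_missingness(g)
  maf_now <- snp_maf(g)
  miss_drop <- g$map$snp[miss > config$max_missing | is.na(maf_now)]
  g <- note("missingness", drop_snps(g, miss_drop), miss_drop)

  maf_drop <- g$map$snp[snp_maf(g) < config$min_maf]
  g <- note("maf", drop_snps(g, maf_drop), maf_drop)

  hwe_p <- if (config$hwe_mode == "pooled") snp_hwe(g) else
    per_breed_min_hwe(g)
  hwe_drop <- g$map$snp[!is.na(hwe_p) & hwe_p < config$hwe_alpha]
  g <- note("hwe", drop_snps(g, hwe_drop), hwe_drop)

  pr <- ld_prune(g, config$ld_r2_max, config$ld_window_snps)
  g <- note("ld_prune", pr$genotypes, pr$removed)

  report <- structure(list(stages = stages, removed = removed,
                           config = config, seed = config$seed),
                      class = "qc_report")
  list(genotypes = g, report = report)
}

drop_snps <- function(g, ids) {
  if (!length(ids)) return(g)
  subset_geno(g, snps = which(!(g$map$snp %in% ids)))
}

# per-breed HWE screen: min exact P over breeds with >= 5 typed samples
per_breed_min_hwe <- function(g, min_n = 5L) {
  breeds <- split(seq_len(n_samples(g)), g$samples$breed)
  p <- rep(NA_real_, n_snps(g))
  for (ix in breeds) {
    sub <- g$dosage[ix, , drop = FALSE]
    pb <- apply(sub, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < min_n) return(NA_real_)
      hwe_exact_test(sum(x == 2L), sum(x == 1L), sum(x == 0L))
    })
    p <- pmin(p, pb, na.rm = TRUE)
  }
  p[!is.finite(p)] <- NA_real_
  p
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC cascade (stage: samples x SNPs, removed SNPs)\n")
  for (s in names(x$stages)) {
    cat(sprintf("  %-14s %5d x %6d   -%d\n", s,
                x$stages[[s]]["samples"], x$stages[[s]]["snps"],
                length(x$removed[[s]])))
  }
  invisible(x)
}

#' Flatten a QC report into a tidy stage table
#' @param report a `qc_report`.
#' @return data.frame with columns stage, samples, snps, snps_removed.
#' @export
qc_report_table <- function(report) {
  data.frame(stage = names(report$stages),
             samples = vapply(report$stages, `[`, 0L, "samples"),
             snps = vapply(report$stages, `[`, 0L, "snps"),
             snps_removed = vapply(report$removed, length, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}
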