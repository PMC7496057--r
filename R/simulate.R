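#' Simulation configuration for breed-structured cohorts
#'
#' Describes a synthetic cohort with the statistical structure the
#' across-breed association analysis assumes: many closed breeds, a handful
#' of samples per breed, biallelic autosomal SNPs whose allele frequencies
#' diverge between breeds (Balding-Nichols model with divergence parameter
#' `differentiation`), and breed-level phenotypes in which heavier breeds
#' die of cancer more often and live shorter lives.
#'
#' @param n_breeds number of breeds.
#' @param samples_per_breed a single count applied to every breed, or an
#'   integer vector of length `n_breeds`.
#' @param n_snps number of biallelic SNPs.
#' @param n_chromosomes chromosomes to spread SNPs over; the last one is
#'   labelled as chromosome "39" and treated as the sex chromosome by the
#'   autosome filter (CanFam convention: 38 autosomes).
#' @param differentiation between-breed allele-frequency divergence F in
#'   [0, 1): per-breed frequencies are Beta-distributed with mean p and
#'   variance F p(1-p). F = 0 collapses every breed onto the ancestral
#'   frequency.
#' @param ancestral_maf_range pair in (0, 0.5]; ancestral frequencies are
#'   drawn uniformly from this interval.
#' @param missing_rate proportion of genotype cells set missing uniformly at
#'   random.
#' @param n_duplicate_snps number of extra SNPs appended as exact copies of
#'   randomly chosen originals (adjacent in the map), giving the LD-pruning
#'   stage known perfectly correlated pairs to remove.
#' @param weight_range kg pair for per-breed body weight (uniform).
#' @param slope_lifespan_per_kg years of life expectancy (at age 4) per kg;
#'   negative in dogs.
#' @param intercept_lifespan years at 0 kg (extrapolated intercept).
#' @param slope_cancer_per_kg percentage points of cancer mortality per kg;
#'   positive in dogs.
#' @param intercept_cancer percent cancer mortality at 0 kg.
#' @param noise_sd_lifespan,noise_sd_cancer SD of breed-level Gaussian noise
#'   added to each trait (years / percentage points).
#' @param cancer_lifespan_coupling percentage points of cancer mortality per
#'   year of weight-independent life-expectancy deviation. A positive value
#'   emulates age-related cancer mortality: breeds that outlive their
#'   weight-predicted lifespan accumulate more cancer deaths, which leaves
#'   raw cancer mortality nearly uncorrelated with lifespan while the
#'   weight-corrected cancer residuals correlate positively with it.
#' @param planted_effects data.frame with columns `snp` (1-based SNP index),
#'   `trait` ("cancer_mortality" or "life_expectancy") and `effect` (trait
#'   units per breed-mean dosage unit), or NULL.
#' @param seed integer seed; all randomness in the generator flows from it.
#' @return A validated list of class `sim_config`.
#' @details Defaults emulate the published study cohort: 63 breeds capped at
#'   30 samples each, moderate breed divergence (F = 0.2), a positive
#'   weight-cancer and negative weight-lifespan relationship with enough
#'   breed-level noise that the weight-cancer Spearman correlation sits near
#'   0.5 and the weight-lifespan correlation near -0.7.
#' @export
sim_config <- function(n_breeds = 63L,
                       samples_per_breed = 30L,
                       n_snps = 2000L,
                       n_chromosomes = 39L,
                       differentiation = 0.2,
                       ancestral_maf_range = c(0.05, 0.5),
                       missing_rate = 0.02,
                       n_duplicate_snps = 0L,
                       weight_range = c(3, 70),
                       slope_lifespan_per_kg = -0.08,
                       intercept_lifespan = 12,
                       slope_cancer_per_kg = 0.35,
                       intercept_cancer = 15,
                       noise_sd_lifespan = 1.6,
                       noise_sd_cancer = 12,
                       cancer_lifespan_coupling = 2.5,
                       planted_effects = NULL,
                       seed = 1L) {
  cfg <- list(n_breeds = as.integer(n_breeds),
              samples_per_breed = as.integer(samples_per_breed),
              n_snps = as.integer(n_snps),
              n_chromosomes = as.integer(n_chromosomes),
              differentiation = differentiation,
              ancestral_maf_range = as.numeric(ancestral_maf_range),
              missing_rate = missing_rate,
              n_duplicate_snps = as.integer(n_duplicate_snps),
              weight_range = as.numeric(weight_range),
              slope_lifespan_per_kg = slope_lifespan_per_kg,
              intercept_lifespan = intercept_lifespan,
              slope_cancer_per_kg = slope_cancer_per_kg,
              intercept_cancer = intercept_cancer,
              noise_sd_lifespan = noise_sd_lifespan,
              noise_sd_cancer = noise_sd_cancer,
              cancer_lifespan_coupling = cancer_lifespan_coupling,
              planted_effects = planted_effects,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop(sprintf("invalid simulation config: field '%s' %s",
                          field, why), call. = FALSE)
  chk(length(cfg$n_breeds) == 1 && cfg$n_breeds >= 1, "n_breeds",
      "must be a positive count")
  chk(all(cfg$samples_per_breed >= 1), "samples_per_breed",
      "must be positive")
  chk(length(cfg$samples_per_breed) %in% c(1L, cfg$n_breeds),
      "samples_per_breed", "must be scalar or one count per breed")
  chk(cfg$n_snps >= 1, "n_snps", "must be a positive count")
  chk(cfg$n_chromosomes >= 1, "n_chromosomes", "must be a positive count")
  chk(cfg$differentiation >= 0 && cfg$differentiation < 1,
      "differentiation", "must lie in [0, 1)")
  chk(length(cfg$ancestral_maf_range) == 2 &&
        cfg$ancestral_maf_range[1] > 0 &&
        cfg$ancestral_maf_range[2] <= 0.5 &&
        cfg$ancestral_maf_range[1] <= cfg$ancestral_maf_range[2],
      "ancestral_maf_range", "must be an increasing pair within (0, 0.5]")
  chk(cfg$missing_rate >= 0 && cfg$missing_rate < 1, "missing_rate",
      "must lie in [0, 1)")
  chk(cfg$n_duplicate_snps >= 0, "n_duplicate_snps", "must be >= 0")
  chk(cfg$weight_range[1] > 0 && diff(cfg$weight_range) >= 0,
      "weight_range", "must be a positive increasing kg pair")
  chk(cfg$noise_sd_lifespan >= 0 && cfg$noise_sd_cancer >= 0,
      "noise_sd_lifespan/noise_sd_cancer", "must be non-negative")
  if (!is.null(cfg$planted_effects)) {
    pe <- cfg$planted_effects
    chk(is.data.frame(pe) && all(c("snp", "trait", "effect") %in% names(pe)),
        "planted_effects", "must have columns snp, trait, effect")
    chk(all(pe$snp >= 1 & pe$snp <= cfg$n_snps + cfg$n_duplicate_snps),
        "planted_effects", "has SNP indices outside 1..n_snps")
    chk(all(pe$trait %in% c("cancer_mortality", "life_expectancy")),
        "planted_effects",
        "trait must be 'cancer_mortality' or 'life_expectancy'")
  }
  invisible(cfg)
}

# run expr under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(as.integer(seed))
  expr
}

# deterministic per-stage substream seeds below 2^31
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}

#' Simulate breed-structured genotypes
#'
#' Draws, for each SNP, an ancestral allele frequency p uniform over
#' `ancestral_maf_range`; per-breed frequencies from a Beta distribution
#' with mean p and variance F p(1-p) (F = `differentiation`, the standard
#' Balding-Nichols surrogate for between-population divergence); and
#' per-sample dosages Binomial(2, breed frequency). Genotype cells are then
#' set missing uniformly at random at `missing_rate`. SNPs are assigned
#' round-robin to chromosomes and given sorted distinct positions; any
#' duplicate SNPs requested are exact dosage copies placed adjacent to their
#' source SNP in the map.
#'
#' @param config a [sim_config()].
#' @return A [geno_matrix()]; attribute `"truth"` carries the simulated
#'   ancestral and per-breed frequencies plus the duplicate-pair table.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genotypes"), {
    nb <- config$n_breeds
    ns <- config$n_snps
    per <- if (length(config$samples_per_breed) == 1L)
      rep(config$samples_per_breed, nb) else config$samples_per_breed
    n <- sum(per)
    breeds <- sprintf("breed%02d", seq_len(nb))
    breed_of <- rep(breeds, per)

    p_anc <- stats::runif(ns, config$ancestral_maf_range[1],
                          config$ancestral_maf_range[2])
    FF <- config$differentiation
    if (FF > 0) {
      k <- (1 - FF) / FF
      pf <- matrix(stats::rbeta(nb * ns, rep(p_anc, each = nb) * k,
                                rep(1 - p_anc, each = nb) * k),
                   nrow = nb, ncol = ns)
    } else {
      pf <- matrix(rep(p_anc, each = nb), nrow = nb, ncol = ns)
    }
    d <- matrix(stats::rbinom(n * ns, 2L, pf[rep(seq_len(nb), per), ]),
                nrow = n, ncol = ns)

    # map: round-robin chromosome assignment, sorted distinct positions at
    # array-like density (~1 SNP per 50 kb)
    chr_idx <- rep_len(seq_len(config$n_chromosomes), ns)
    pos <- integer(ns)
    for (cc in unique(chr_idx)) {
      on_c <- which(chr_idx == cc)
      span <- max(1e6L, length(on_c) * 50000L)
      pos[on_c] <- sort(sample.int(span, length(on_c)))
    }
    ord <- order(chr_idx, pos)
    d <- d[, ord, drop = FALSE]
    chr_idx <- chr_idx[ord]; pos <- pos[ord]; p_anc <- p_anc[ord]
    pf <- pf[, ord, drop = FALSE]
    map <- data.frame(snp = sprintf("snp%05d", seq_len(ns)),
                      chr = as.character(chr_idx), pos = pos,
                      a1 = "A", a2 = "G", stringsAsFactors = FALSE)

    dup_pairs <- NULL
    if (config$n_duplicate_snps > 0) {
      src <- sample.int(ns, config$n_duplicate_snps)
      dup_ids <- sprintf("snp%05d_dup", src)
      dmap <- map[src, , drop = FALSE]
      dmap$snp <- dup_ids
      dmap$pos <- dmap$pos + 1L   # adjacent, stays within the scan window
      d <- cbind(d, d[, src, drop = FALSE])
      map <- rbind(map, dmap)
      ord2 <- order(as.integer(map$chr), map$pos)
      d <- d[, ord2, drop = FALSE]
      map <- map[ord2, , drop = FALSE]
      dup_pairs <- data.frame(source = sprintf("snp%05d", src),
                              duplicate = dup_ids, stringsAsFactors = FALSE)
    }

    if (config$missing_rate > 0) {
      miss <- stats::runif(length(d)) < config$missing_rate
      d[miss] <- NA_integer_
    }

    samples <- data.frame(sample_id = sprintf("dog%04d", seq_len(n)),
                          breed = breed_of, stringsAsFactors = FALSE)
    rownames(map) <- NULL
    g <- geno_matrix(d, samples, map)
    attr(g, "truth") <- list(p_ancestral = p_anc, breed_freq = pf,
                             breeds = breeds, duplicate_pairs = dup_pairs)
    g
  })
}

#' Simulate breed-level phenotypes
#'
#' Body weight is drawn per breed uniformly from `weight_range`; life
#' expectancy at age 4 and cancer mortality are affine in weight (negative
#' and positive slopes respectively) plus breed-level Gaussian noise.
#' Planted SNP effects add `effect * (breed-mean dosage)` to the named trait
#' before cancer mortality is clamped to [0, 100], so a planted association
#' survives clamping as long as the trait stays inside the range.
#'
#' @param config a [sim_config()].
#' @param genotypes the matching [geno_matrix()] from [simulate_genotypes()]
#'   (only needed when `planted_effects` is non-empty; otherwise optional).
#' @return A breed phenotype data.frame with columns `breed`,
#'   `body_weight_kg`, `life_expectancy_years`, `cancer_mortality_pct`.
#' @export
simulate_phenotypes <- function(config, genotypes = NULL) {
  validate_sim_config(config)
  breeds <- sprintf("breed%02d", seq_len(config$n_breeds))
  if (!is.null(genotypes)) {
    gb <- sort(unique(genotypes$samples$breed))
    if (!identical(sort(breeds), gb))
      stop("genotype matrix breed labels are inconsistent with the config")
  }
  with_seed(derive_seed(config$seed, "phenotypes"), {
    nb <- config$n_breeds
    w <- stats::runif(nb, config$weight_range[1], config$weight_range[2])
    e_lifespan <- stats::rnorm(nb, 0, config$noise_sd_lifespan)
    le <- config$intercept_lifespan + config$slope_lifespan_per_kg * w +
      e_lifespan
    cm <- config$intercept_cancer + config$slope_cancer_per_kg * w +
      config$cancer_lifespan_coupling * e_lifespan +
      stats::rnorm(nb, 0, config$noise_sd_cancer)

    pe <- config$planted_effects
    if (!is.null(pe) && nrow(pe)) {
      if (is.null(genotypes))
        stop("planted effects requested but no genotype matrix supplied")
      for (i in seq_len(nrow(pe))) {
        snp_col <- genotypes$dosage[, pe$snp[i]]
        mu <- tapply(snp_col, genotypes$samples$breed, mean, na.rm = TRUE)
        add <- pe$effect[i] * as.numeric(mu[breeds])
        add[is.na(add)] <- 0
        if (pe$trait[i] == "cancer_mortality") cm <- cm + add
        else le <- le + add
      }
    }
    cm <- pmin(pmax(cm, 0), 100)
    le <- pmax(le, 0.5)
    data.frame(breed = breeds,
               body_weight_kg = w,
               life_expectancy_years = le,
               cancer_mortality_pct = cm,
               stringsAsFactors = FALSE)
  })
}
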