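test_that("simulation is deterministic per seed and rejects bad configs", {
  cfg <- sim_config(n_breeds = 5, samples_per_breed = 10, n_snps = 50,
                    seed = 42)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  p1 <- simulate_phenotypes(cfg, g1)
  p2 <- simulate_phenotypes(cfg, g2)
  expect_identical(p1, p2)
  g3 <- simulate_genotypes(sim_config(n_breeds = 5, samples_per_breed = 10,
                                      n_snps = 50, seed = 43))
  expect_false(identical(g1$dosage, g3$dosage))

  expect_error(sim_config(differentiation = 1), "differentiation")
  expect_error(sim_config(ancestral_maf_range = c(0, 0.5)),
               "ancestral_maf_range")
  expect_error(sim_config(n_snps = 10,
                          planted_effects = data.frame(
                            snp = 11, trait = "cancer_mortality",
                            effect = 1)),
               "planted_effects")
})

test_that("zero divergence collapses breed frequencies onto the ancestral", {
  cfg <- sim_config(n_breeds = 6, samples_per_breed = 400, n_snps = 60,
                    differentiation = 0, missing_rate = 0, seed = 7)
  g <- simulate_genotypes(cfg)
  truth <- attr(g, "truth")
  freq <- per_breed_maf(g)
  # with 800 chromosomes per breed, binomial SE is sqrt(p q / 800) < 0.018
  for (j in seq_len(n_snps(g))) {
    p <- truth$p_ancestral[j]
    expect_true(all(abs(freq[, j] - p) < 5 * sqrt(p * (1 - p) / 800)))
  }
})

test_that("between-breed frequency variance tracks the divergence parameter", {
  # Balding-Nichols: Var(breed freq) = F p (1 - p)
  cfg <- sim_config(n_breeds = 20, samples_per_breed = 30, n_snps = 1000,
                    differentiation = 0.2, missing_rate = 0, seed = 1)
  g <- simulate_genotypes(cfg)
  truth <- attr(g, "truth")
  ratio <- vapply(seq_len(1000), function(j) {
    p <- truth$p_ancestral[j]
    stats::var(truth$breed_freq[, j]) / (p * (1 - p))
  }, 0)
  expect_equal(mean(ratio), 0.2, tolerance = 0.05)

  # and divergence of sampled genotypes grows monotonically with F
  spread <- vapply(c(0.02, 0.2, 0.5), function(f) {
    gg <- simulate_genotypes(sim_config(n_breeds = 20,
                                        samples_per_breed = 30,
                                        n_snps = 300, differentiation = f,
                                        missing_rate = 0, seed = 3))
    mean(apply(per_breed_maf(gg), 2, stats::var), na.rm = TRUE)
  }, 0)
  expect_true(spread[1] < spread[2] && spread[2] < spread[3])
})

test_that("genotype matrix invariants hold on simulated cohorts", {
  sc <- small_cohort(seed = 5, missing_rate = 0.05)
  g <- sc$genotypes
  d <- g$dosage[!is.na(g$dosage)]
  expect_true(all(d %in% 0:2))
  expect_false(anyDuplicated(g$map$snp) > 0)
  expect_false(anyDuplicated(g$samples$sample_id) > 0)
  expect_true(all(g$map$pos >= 1))
  expect_equal(mean(is.na(g$dosage)), 0.05, tolerance = 0.02)
  # positions sorted within chromosome
  for (cc in unique(g$map$chr))
    expect_false(is.unsorted(g$map$pos[g$map$chr == cc]))
})

test_that("noiseless phenotypes are exact affine functions of weight", {
  cfg <- sim_config(n_breeds = 12, samples_per_breed = 5, n_snps = 10,
                    noise_sd_lifespan = 0, noise_sd_cancer = 0, seed = 2)
  ph <- simulate_phenotypes(cfg)
  expect_equal(spearman(ph$body_weight_kg, ph$life_expectancy_years)$rho, -1)
  expect_equal(spearman(ph$body_weight_kg, ph$cancer_mortality_pct)$rho, 1)
  fit <- suppressWarnings(   # perfect fit trips summary.lm's warning
    linear_fit(ph$body_weight_kg, ph$life_expectancy_years))
  expect_equal(fit$slope, cfg$slope_lifespan_per_kg, tolerance = 1e-10)
})

test_that("default cohort reproduces the study's correlation sign pattern", {
  # weight-cancer positive, weight-lifespan negative, lifespan vs
  # weight-corrected cancer residuals positive
  cors <- t(vapply(1:5, function(s) {
    tr <- trait_report(simulate_phenotypes(sim_config(seed = s)))
    tr$correlations$rho
  }, numeric(4)))
  expect_true(all(cors[, 1] > 0))   # weight vs cancer
  expect_true(all(cors[, 2] < 0))   # weight vs lifespan
  expect_true(mean(cors[, 4] > 0) >= 0.8)  # lifespan vs cancer residuals
  expect_true(all(abs(cors[, 3]) < abs(cors[, 2])))  # raw cancer weaker
})

test_that("a strong planted effect makes its SNP the top association hit", {
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_breeds = 20, samples_per_breed = 20, n_snps = 80,
                      missing_rate = 0,
                      planted_effects = data.frame(
                        snp = 40, trait = "cancer_mortality",
                        effect = 30),
                      seed = s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(cfg, g)
    ph$cancer_residual <- residualize(
      ph$cancer_mortality_pct,
      cbind(ph$body_weight_kg, ph$life_expectancy_years))
    y <- assign_breed_values(g, ph, "cancer_residual")
    tab <- additive_association(g, y)
    which.min(tab$raw_p) == 40
  }, TRUE)
  expect_gte(mean(hits), 0.6)
})
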