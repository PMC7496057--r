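test_that("breed values broadcast to samples and missing breeds error", {
  g <- toy_geno(matrix(1L, 6, 2), rep(c("A", "B"), each = 3))
  ph <- data.frame(breed = c("A", "B"), val = c(1.0, 2.0))
  expect_equal(assign_breed_values(g, ph, "val"), c(1, 1, 1, 2, 2, 2))
  expect_error(assign_breed_values(g, ph[1, ], "val"), "B")
  expect_error(assign_breed_values(g, ph, "nope"), "column")
  # permuted breed map keeps within-breed constancy
  ph2 <- ph; ph2$val <- ph$val[c(2, 1)]
  y <- assign_breed_values(g, ph2, "val")
  expect_true(all(tapply(y, g$samples$breed, function(v)
    length(unique(v))) == 1))
})

test_that("the additive scan agrees with per-SNP lm() to high precision", {
  sc <- small_cohort(seed = 23, n_snps = 60, missing_rate = 0.08)
  g <- sc$genotypes
  tr <- trait_report(sc$phenotypes)
  y <- assign_breed_values(g, tr$phenotypes, "cancer_residual")
  tab <- suppressWarnings(additive_association(g, y))
  oracle <- lm_assoc_oracle(g, y)
  ok <- !is.na(oracle$raw_p)
  expect_gt(sum(ok), 30)
  expect_equal(tab$beta[ok], oracle$beta[ok], tolerance = 1e-10)
  expect_equal(tab$raw_p[ok], oracle$raw_p[ok], tolerance = 1e-10)
  expect_equal(is.na(tab$raw_p), !ok)
})

test_that("OLS equivariance: doubling the trait doubles beta, not P", {
  sc <- small_cohort(seed = 29, n_snps = 30, missing_rate = 0)
  g <- sc$genotypes
  y <- assign_breed_values(g, sc$phenotypes, "body_weight_kg")
  t1 <- additive_association(g, y)
  t2 <- additive_association(g, 2 * y)
  expect_equal(t2$beta, 2 * t1$beta, tolerance = 1e-12)
  expect_equal(t2$raw_p, t1$raw_p, tolerance = 1e-12)
  # constant trait: zero variance, every raw P absent
  expect_warning(t0 <- additive_association(g, rep(3, n_samples(g))),
                 "degenerate")
  expect_true(all(is.na(t0$raw_p)))
})

test_that("corrected P follows the (1 + exceedances)/(B + 1) estimator", {
  null <- structure(list(min_p = c(0.01, 0.02, 0.05, 0.2),
                         n_perm = 4L, seed = 1L, scheme = "breed"),
                    class = "perm_null")
  expect_equal(corrected_p(0.005, null), 1 / 5)   # beats all minima
  expect_equal(corrected_p(0.5, null), 1)          # beats none
  expect_equal(corrected_p(0.03, null), 3 / 5)
  expect_equal(corrected_p(0.02, null), 3 / 5)     # tie counts (<=)
  expect_true(is.na(corrected_p(NA_real_, null)))
  # monotone in raw P; bounded in [1/(B+1), 1]
  ps <- corrected_p(sort(runif(50)), null)
  expect_false(is.unsorted(ps))
  expect_true(all(ps >= 1 / 5 & ps <= 1))
})

test_that("tier thresholds are strict", {
  expect_equal(tier_of(c(0.049, 0.05, 0.099, 0.1, NA)),
               c("significant", "marginal", "marginal", "ns", NA))
})

test_that("the breed permutation null is deterministic and block-constant", {
  sc <- small_cohort(seed = 31, n_breeds = 6, samples_per_breed = 10,
                     n_snps = 40)
  tr <- trait_report(sc$phenotypes)
  n1 <- breed_permutation_null(sc$genotypes, tr$phenotypes,
                               "cancer_residual", n_perm = 50, seed = 5)
  n2 <- breed_permutation_null(sc$genotypes, tr$phenotypes,
                               "cancer_residual", n_perm = 50, seed = 5)
  expect_identical(n1$min_p, n2$min_p)
  expect_true(all(n1$min_p > 0 & n1$min_p <= 1))
  expect_length(n1$min_p, 50)
  # a trait constant across breeds is unchanged by any breed permutation,
  # so every permutation reproduces the observed (degenerate) scan
  ph_const <- tr$phenotypes
  ph_const$flat <- 1.7
  y0 <- assign_breed_values(sc$genotypes, ph_const, "flat")
  ph_perm <- ph_const
  ph_perm$flat <- ph_const$flat[sample(nrow(ph_const))]
  y1 <- assign_breed_values(sc$genotypes, ph_perm, "flat")
  expect_identical(y0, y1)
  expect_identical(suppressWarnings(additive_association(sc$genotypes, y0)),
                   suppressWarnings(additive_association(sc$genotypes, y1)))
  expect_error(breed_permutation_null(sc$genotypes, tr$phenotypes,
                                      "cancer_residual", n_perm = 0),
               "n_perm")
})

test_that("1 SNP and 2 breeds admit at most 2 distinct null minima", {
  g <- toy_geno(matrix(c(0L, 1L, 2L, 2L, 1L, 0L), 6, 1),
                rep(c("A", "B"), each = 3))
  ph <- data.frame(breed = c("A", "B"), val = c(-1, 4))
  null <- breed_permutation_null(g, ph, "val", n_perm = 40, seed = 2)
  expect_lte(length(unique(round(null$min_p, 12))), 2)
})

test_that("4-breed null matches exhaustive enumeration over 24 permutations", {
  set.seed(41)
  nb <- 4; per <- 12
  g <- toy_geno(matrix(rbinom(nb * per * 25, 2,
                              rep(runif(25, 0.15, 0.5),
                                  each = nb * per)),
                       nb * per, 25),
                rep(paste0("b", 1:nb), each = per))
  vals <- c(0.3, -1.2, 2.1, 0.9)
  ph <- data.frame(breed = paste0("b", 1:nb), val = vals)
  # exhaustive oracle: min raw P under every breed-value permutation
  perms <- expand.grid(rep(list(1:nb), nb))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == nb), ]
  exact <- apply(perms, 1, function(pm) {
    phx <- data.frame(breed = paste0("b", 1:nb), val = vals[unlist(pm)])
    y <- assign_breed_values(g, phx, "val")
    min(suppressWarnings(additive_association(g, y))$raw_p, na.rm = TRUE)
  })
  expect_equal(nrow(perms), 24)
  null <- breed_permutation_null(g, ph, "val", n_perm = 600, seed = 3)
  # every sampled minimum is one of the 24 attainable values
  expect_true(all(vapply(null$min_p, function(p)
    any(abs(p - exact) < 1e-12), TRUE)))
  # and the sampled mean matches the exhaustive mean within MC error
  se <- sd(exact) / sqrt(600) * 4 + 1e-3
  expect_lt(abs(mean(null$min_p) - mean(exact)), se)
})

test_that("a full experiment flags a strongly planted SNP as significant", {
  cfg <- sim_config(n_breeds = 20, samples_per_breed = 25, n_snps = 120,
                    missing_rate = 0.02,
                    planted_effects = data.frame(
                      snp = 60, trait = "life_expectancy", effect = 15),
                    seed = 47)
  g <- simulate_genotypes(cfg)
  ph <- trait_report(simulate_phenotypes(cfg, g))$phenotypes
  ex <- run_association_experiment(g, ph, "longevity_residual",
                                   n_perm = 200, seed = 47)
  planted_id <- g$map$snp[60]
  row <- ex$table[ex$table$snp == planted_id, ]
  expect_equal(which.min(ex$table$raw_p), 60)
  expect_equal(row$tier, "significant")
  expect_gte(row$corrected_p, 1 / 201)
  # unknown candidate ids are refused
  expect_error(run_association_experiment(g, ph, "longevity_residual",
                                          candidates = c("nope1")),
               "absent")
})
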