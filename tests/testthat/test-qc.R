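test_that("per-breed capping keeps small breeds whole and caps large ones", {
  breeds <- rep(c("small", "big"), c(25, 700))
  g <- toy_geno(matrix(rbinom(725 * 3, 2, 0.3), 725, 3), breeds)
  out <- subsample_per_breed(g, cap = 30, seed = 9)
  tab <- table(out$samples$breed)
  expect_equal(unname(tab[["small"]]), 25L)
  expect_equal(unname(tab[["big"]]), 30L)
  expect_equal(n_samples(out), sum(pmin(30, c(25, 700))))
  # deterministic per seed
  out2 <- subsample_per_breed(g, cap = 30, seed = 9)
  expect_identical(out$samples, out2$samples)
  out3 <- subsample_per_breed(g, cap = 30, seed = 10)
  expect_false(identical(out$samples, out3$samples))
})

test_that("missingness and MAF follow the counting definitions", {
  d <- matrix(0L, 20, 3)
  d[1:3, 1] <- NA               # 3/20 missing
  d[, 2] <- c(rep(0L, 17), 1L, 1L, 0L)  # freq 2/40
  d[1, 3] <- 1L                 # freq 1/40
  g <- toy_geno(d, rep("b", 20))
  expect_equal(unname(snp_missingness(g)), c(0.15, 0, 0))
  expect_equal(unname(snp_maf(g))[2:3], c(2 / 40, 1 / 40))

  g2 <- toy_geno(matrix(c(0L, 0L, 1L), 3, 1), rep("b", 3))
  expect_equal(unname(snp_maf(g2)), 1 / 6, tolerance = 1e-12)
  # monomorphic SNP has MAF 0
  g3 <- toy_geno(matrix(0L, 5, 1), rep("b", 5))
  expect_equal(unname(snp_maf(g3)), 0)
})

test_that("LD r2 equals squared Pearson correlation, sign-invariant", {
  a <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L)
  g <- toy_geno(cbind(a, a, 2L - a, rev(a)), rep("b", 8))
  expect_equal(ld_r2(g, 1, 2), 1)
  expect_equal(ld_r2(g, 1, 3), 1)   # perfect negative correlation
  expect_equal(ld_r2(g, "t001", "t004"), cor(a, rev(a))^2,
               tolerance = 1e-12)
  gz <- toy_geno(cbind(a, rep(1L, 8)), rep("b", 8))
  expect_warning(r2 <- ld_r2(gz, 1, 2), "zero-variance")
  expect_true(is.na(r2))
})

test_that("r2 matches a naive double-loop oracle on a 50-SNP instance", {
  sc <- small_cohort(seed = 11, n_snps = 50, missing_rate = 0.05)
  g <- sc$genotypes
  poly <- which(apply(g$dosage, 2, function(x) length(unique(na.omit(x)))) > 1)
  idx <- utils::head(poly, 20)
  for (i in idx[1:10]) for (j in idx[11:20]) {
    a <- g$dosage[, i]; b <- g$dosage[, j]
    ok <- !is.na(a) & !is.na(b)
    if (var(a[ok]) == 0 || var(b[ok]) == 0) next
    expect_equal(ld_r2(g, i, j), cor(a[ok], b[ok])^2, tolerance = 1e-12)
  }
})

test_that("mean null r2 between independent SNPs is about 1/n", {
  set.seed(4)
  n <- 1000
  d <- matrix(rbinom(n * 30, 2, 0.4), n, 30)
  g <- toy_geno(d, rep("b", n))
  r2s <- unlist(lapply(1:15, function(i)
    vapply(16:30, function(j) ld_r2(g, i, j), 0)))
  expect_lt(abs(mean(r2s) - 1 / n), 5e-4)
})

test_that("LD pruning removes the later SNP of each high-r2 pair", {
  a <- c(0L, 1L, 2L, 1L, 0L, 2L, 1L, 0L, 2L, 1L)
  b <- c(2L, 0L, 1L, 1L, 2L, 0L, 1L, 2L, 0L, 1L)
  g <- toy_geno(cbind(a, b, a, 2L - b), rep("x", 10))
  pr <- ld_prune(g, r2_max = 0.9, window_snps = 50)
  expect_setequal(pr$removed, c("t003", "t004"))
  expect_equal(pr$genotypes$map$snp, c("t001", "t002"))
  # no surviving pair within the window exceeds the threshold
  gg <- pr$genotypes
  for (i in seq_len(n_snps(gg) - 1)) for (j in (i + 1):n_snps(gg))
    expect_lte(suppressWarnings(ld_r2(gg, i, j)), 0.9)
})

test_that("the QC cascade telescopes and removes what it says it removes", {
  cfg <- sim_config(n_breeds = 8, samples_per_breed = 40, n_snps = 150,
                    n_duplicate_snps = 6, differentiation = 0.05,
                    missing_rate = 0.03, seed = 21)
  g <- simulate_genotypes(cfg)
  res <- run_qc(g, qc_config(per_breed_cap = 30, seed = 21))
  rep_tab <- qc_report_table(res$report)
  # telescoping: output of stage k = input of stage k+1
  for (k in 2:nrow(rep_tab)) {
    expect_equal(rep_tab$snps[k], rep_tab$snps[k - 1] -
                   rep_tab$snps_removed[k])
  }
  expect_equal(rep_tab$samples[2], 8 * 30)
  # non-autosomal chromosome "39" entirely gone
  expect_false(any(res$genotypes$map$chr %in% non_autosomal_labels()))
  expect_true(all(g$map$snp[g$map$chr == "39"] %in%
                    res$report$removed$autosomes))
  # every SNP removed by a threshold stage actually violates it (audited
  # on the stage's input data)
  g_at_miss <- subset_geno(
    subsample_per_breed(g, 30, 21),
    snps = which(!(g$map$chr %in% non_autosomal_labels())))
  miss <- snp_missingness(g_at_miss)
  for (s in res$report$removed$missingness)
    expect_true(miss[[which(g_at_miss$map$snp == s)]] > 0.10 ||
                  is.na(snp_maf(g_at_miss)[[which(g_at_miss$map$snp == s)]]))
  expect_error(run_qc(g, qc_config(min_maf = 0.999)), "stage")
})

test_that("with clean input only the planted duplicate SNPs are pruned", {
  cfg <- sim_config(n_breeds = 10, samples_per_breed = 30, n_snps = 100,
                    n_duplicate_snps = 8, differentiation = 0,
                    missing_rate = 0, ancestral_maf_range = c(0.2, 0.5),
                    seed = 31)
  g <- simulate_genotypes(cfg)
  truth <- attr(g, "truth")$duplicate_pairs
  res <- run_qc(g, qc_config(seed = 31))
  pruned <- res$report$removed$ld_prune
  # every duplicate pair lost exactly one member to the LD stage
  for (k in seq_len(nrow(truth))) {
    pair <- c(truth$source[k], truth$duplicate[k])
    survived <- setdiff(pair, c(pruned, unlist(res$report$removed)))
    expect_equal(length(survived), 1)
  }
})
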