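#' Random gene set over a simulated SNP map
#'
#' Draws gene intervals on the chromosomes of a genotype map, for exercising
#' the candidate-window stage when no curated gene table is supplied (the
#' intervals are synthetic and carry no biology).
#'
#' @param g a [geno_matrix()].
#' @param n_genes number of genes.
#' @param span_bp gene length range (uniform, default 2-100 kb).
#' @param seed integer seed.
#' @param prefix gene id prefix.
#' @return a [gene_set()].
#' @export
simulate_gene_set <- function(g, n_genes = 50L, span_bp = c(2000L, 100000L),
                              seed = 1L, prefix = "gene") {
  with_seed(derive_seed(seed, paste0("genes_", prefix)), {
    # anchor each gene near a randomly chosen SNP (with jitter beyond the
    # usual candidate window) so the windowing stage has non-trivial work
    anchor <- sample.int(nrow(g$map), n_genes, replace = TRUE)
    chr <- g$map$chr[anchor]
    jitter <- sample(-60000L:60000L, n_genes, replace = TRUE)
    start <- pmax(1L, g$map$pos[anchor] + jitter)
    len <- sample(span_bp[1]:span_bp[2], n_genes, replace = TRUE)
    gene_set(data.frame(gene = sprintf("%s%04d", prefix, seq_len(n_genes)),
                        chr = chr, start = start, end = start + len,
                        stringsAsFactors = FALSE))
  })
}

#' Default pipeline configuration
#'
#' A nested list accepted by [run_pipeline()]; any YAML config file is
#' merged over these defaults. `simulate = NULL` requires `inputs` paths
#' (ped, map, phenotypes, cancer_genes, longevity_genes) instead.
#'
#' @param seed root seed; every stage derives its own substream from it.
#' @return nested configuration list.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(seed = as.integer(seed),
       simulate = list(n_breeds = 20L, samples_per_breed = 30L,
                       n_snps = 2000L, n_duplicate_snps = 10L,
                       differentiation = 0.2, missing_rate = 0.02,
                       n_cancer_genes = 30L, n_longevity_genes = 50L),
       inputs = NULL,
       qc = list(per_breed_cap = 30L, max_missing = 0.10, min_maf = 0.01,
                 hwe_alpha = 0.01, hwe_mode = "pooled",
                 ld_r2_max = 0.9, ld_window_snps = 50L),
       window_bp = 20000L,
       association = list(n_perm = 200L, alpha = 0.05, marginal = 0.1),
       robustness = list(frac = 0.10, reps = 10L),
       run_robustness = TRUE,
       run_maf_scan = TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Run the full across-breed association pipeline
#'
#' Chains every stage: cohort simulation (or PLINK/TSV input), the QC
#' cascade, candidate-SNP windows around the cancer and longevity gene
#' sets, trait residualization and the correlation report, three
#' association + permutation experiments (body weight on all QC'd SNPs,
#' cancer residuals on cancer candidates, longevity residuals on longevity
#' candidates), the subject-resampling robustness check and the per-breed
#' allele-frequency correlation scans. All outputs are tab-separated text
#' in `out_dir`, plus `manifest.json` recording seeds, thresholds and
#' stage counts so a rerun reproduces every table byte-identically.
#'
#' @param config a nested list (see [default_pipeline_config()]) or the
#'   path to a YAML file with the same structure.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir = "breedgwas_run") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  config <- merge_config(default_pipeline_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out_dir, ...)
  seed <- as.integer(config$seed)
  counts <- list()

  # --- inputs: simulate or load -------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    planted <- if (!is.null(sc$planted_effects))
      as.data.frame(sc$planted_effects) else NULL
    cfg <- sim_config(
      n_breeds = sc$n_breeds, samples_per_breed = sc$samples_per_breed,
      n_snps = sc$n_snps,
      n_duplicate_snps = if (is.null(sc$n_duplicate_snps)) 0L else
        sc$n_duplicate_snps,
      differentiation = sc$differentiation,
      missing_rate = sc$missing_rate,
      planted_effects = planted, seed = seed)
    g <- simulate_genotypes(cfg)
    pheno <- simulate_phenotypes(cfg, g)
    write_plink_text(g, pth("cohort.ped"), pth("cohort.map"))
    data.table::fwrite(pheno, pth("phenotypes.tsv"), sep = "\t")
    if (!is.null(planted))
      data.table::fwrite(planted, pth("planted_truth.tsv"), sep = "\t")
    truth <- attr(g, "truth")
    if (!is.null(truth$duplicate_pairs))
      data.table::fwrite(truth$duplicate_pairs,
                         pth("duplicate_truth.tsv"), sep = "\t")
    cancer_genes <- simulate_gene_set(
      g, sc$n_cancer_genes, seed = seed, prefix = "cancer_gene")
    longevity_genes <- simulate_gene_set(
      g, sc$n_longevity_genes, seed = seed, prefix = "longevity_gene")
  } else {
    inp <- config$inputs
    if (is.null(inp))
      stop("pipeline config error: neither 'simulate' nor 'inputs' given")
    g <- read_plink_text(inp$ped, inp$map)
    pheno <- read_phenotypes(inp$phenotypes)
    cancer_genes <- read_gene_table(inp$cancer_genes)
    longevity_genes <- read_gene_table(inp$longevity_genes)
  }
  data.table::fwrite(as.data.frame(cancer_genes),
                     pth("cancer_genes.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(longevity_genes),
                     pth("longevity_genes.tsv"), sep = "\t")
  counts$input <- c(samples = n_samples(g), snps = n_snps(g))

  # --- qc ------------------------------------------------------------------
  qc_cfg <- qc_config(per_breed_cap = config$qc$per_breed_cap,
                      max_missing = config$qc$max_missing,
                      min_maf = config$qc$min_maf,
                      hwe_alpha = config$qc$hwe_alpha,
                      hwe_mode = config$qc$hwe_mode,
                      ld_r2_max = config$qc$ld_r2_max,
                      ld_window_snps = config$qc$ld_window_snps,
                      seed = seed)
  qc <- run_qc(g, qc_cfg)
  g <- qc$genotypes
  data.table::fwrite(qc_report_table(qc$report), pth("qc_report.tsv"),
                     sep = "\t")
  write_plink_text(g, pth("qc.ped"), pth("qc.map"))
  counts$qc <- c(samples = n_samples(g), snps = n_snps(g))

  # --- candidates -----------------------------------------------------------
  cancer_cand <- snps_near_genes(g, cancer_genes, config$window_bp)
  longevity_cand <- snps_near_genes(g, longevity_genes, config$window_bp)
  data.table::fwrite(cancer_cand, pth("cancer_candidates.tsv"), sep = "\t")
  data.table::fwrite(longevity_cand, pth("longevity_candidates.tsv"),
                     sep = "\t")
  counts$candidates <- c(cancer = nrow(cancer_cand),
                         longevity = nrow(longevity_cand))
  if (nrow(cancer_cand) == 0 || nrow(longevity_cand) == 0)
    stop("pipeline aborted at stage 'candidates': empty candidate set")

  # --- traits ---------------------------------------------------------------
  tr <- trait_report(pheno)
  pheno <- tr$phenotypes
  data.table::fwrite(pheno, pth("phenotypes_residualized.tsv"), sep = "\t")
  data.table::fwrite(tr$correlations, pth("trait_correlations.tsv"),
                     sep = "\t")

  # --- association x3 -------------------------------------------------------
  asc <- config$association
  experiments <- list(
    body_weight = list(column = "body_weight_kg", candidates = NULL),
    cancer = list(column = "cancer_residual",
                  candidates = cancer_cand$snp),
    longevity = list(column = "longevity_residual",
                     candidates = longevity_cand$snp))
  exp_res <- list()
  for (nm in names(experiments)) {
    e <- experiments[[nm]]
    ex <- run_association_experiment(
      g, pheno, e$column, candidates = e$candidates,
      n_perm = asc$n_perm, seed = seed,
      alpha = asc$alpha, marginal = asc$marginal)
    exp_res[[nm]] <- ex
    write_association_table(ex$table,
                            pth(sprintf("assoc_%s.tsv", nm)))
    write_manhattan_table(ex$table, g,
                          pth(sprintf("manhattan_%s.tsv", nm)))
    data.table::fwrite(data.frame(perm = seq_along(ex$null$min_p),
                                  min_p = ex$null$min_p),
                       pth(sprintf("perm_null_%s.tsv", nm)), sep = "\t")
    counts[[paste0("assoc_", nm)]] <-
      c(snps = nrow(ex$table),
        significant = sum(ex$table$tier == "significant", na.rm = TRUE),
        marginal = sum(ex$table$tier == "marginal", na.rm = TRUE))
  }

  # --- robustness -----------------------------------------------------------
  if (isTRUE(config$run_robustness)) {
    for (nm in c("cancer", "longevity")) {
      e <- experiments[[nm]]
      rb <- suppressWarnings(resample_robustness(
        g, pheno, e$column, candidates = e$candidates,
        frac = config$robustness$frac, reps = config$robustness$reps,
        n_perm = asc$n_perm, seed = seed,
        alpha = asc$alpha, marginal = asc$marginal))
      data.table::fwrite(rb$stability,
                         pth(sprintf("robustness_%s.tsv", nm)), sep = "\t")
      counts[[paste0("robustness_", nm)]] <- c(reps = length(rb$n_kept),
                                               kept = rb$n_kept[1])
    }
  }

  # --- maf scan -------------------------------------------------------------
  if (isTRUE(config$run_maf_scan)) {
    pb <- per_breed_maf(g)
    for (nm in names(experiments)) {
      e <- experiments[[nm]]
      tv <- stats::setNames(pheno[[e$column]], pheno$breed)
      snps_use <- if (is.null(e$candidates)) colnames(pb) else e$candidates
      scan <- suppressWarnings(
        maf_trait_correlation(pb[, snps_use, drop = FALSE], tv))
      data.table::fwrite(scan, pth(sprintf("maf_scan_%s.tsv", nm)),
                         sep = "\t")
      data.table::fwrite(top_maf_hits(scan, 30L),
                         pth(sprintf("maf_top30_%s.tsv", nm)), sep = "\t")
    }
  }

  manifest <- list(package_version =
                     as.character(utils::packageVersion("breedgwas")),
                   config = config, counts = lapply(counts, as.list))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(genotypes = g, phenotypes = pheno, qc_report = qc$report,
                 experiments = exp_res, manifest = manifest,
                 out_dir = out_dir))
}
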