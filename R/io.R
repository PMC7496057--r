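#' Read genotypes from PLINK text files (PED/MAP)
#'
#' Parses the classic PLINK whitespace-separated text pair. The MAP file
#' must have 4 columns (chromosome, SNP id, genetic distance, bp position);
#' the PED file 6 pedigree columns followed by two allele columns per SNP.
#' Allele pairs are recoded to dosages of the minor allele, where "minor" is
#' determined from allele frequencies over the loaded samples (ties at 0.5
#' broken toward the lexicographically smaller allele). The "0 0" allele
#' pair is the missing genotype. The breed label is taken from the PED
#' family-ID column unless `breed_map` overrides it.
#'
#' @param ped_path,map_path paths to the PED and MAP files.
#' @param breed_map optional data.frame (`sample_id`, `breed`) overriding
#'   the family-ID breed assignment.
#' @return A [geno_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, breed_map = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  mp <- data.table::fread(map_path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(mp) != 4)
    stop(sprintf("MAP parse error: expected 4 columns, found %d", ncol(mp)))
  names(mp) <- c("chr", "snp", "cm", "pos")
  ns <- nrow(mp)

  pd <- data.table::fread(ped_path, header = FALSE, colClasses = "character",
                          data.table = FALSE)
  if (ncol(pd) != 6 + 2 * ns) {
    bad <- which(vapply(strsplit(readLines(ped_path), "[ \t]+"),
                        length, 1L) != 6 + 2 * ns)[1]
    stop(sprintf(
      "PED parse error at line %d: expected %d columns for %d SNPs",
      if (is.na(bad)) 1L else bad, 6 + 2 * ns, ns))
  }

  n <- nrow(pd)
  fam <- pd[[1]]; iid <- pd[[2]]
  a1m <- as.matrix(pd[, seq(7, by = 2, length.out = ns), drop = FALSE])
  a2m <- as.matrix(pd[, seq(8, by = 2, length.out = ns), drop = FALSE])
  a1m[a1m == "0"] <- NA; a2m[a2m == "0"] <- NA
  half <- xor(is.na(a1m), is.na(a2m))
  if (any(half)) { a1m[half] <- NA; a2m[half] <- NA }

  dos <- matrix(NA_integer_, n, ns)
  allele1 <- allele2 <- character(ns)
  for (j in seq_len(ns)) {
    al <- c(a1m[, j], a2m[, j])
    tab <- sort(table(al[!is.na(al)]), decreasing = TRUE)
    if (length(tab) > 2)
      stop(sprintf("PED parse error: SNP %s has %d alleles (%s)",
                   mp$snp[j], length(tab), paste(names(tab), collapse = "/")))
    if (length(tab) == 0) { allele1[j] <- "0"; allele2[j] <- "0"; next }
    als <- names(tab)
    if (length(als) == 1) als <- c(als, "0")
    # minor = least frequent; tie at 0.5 -> lexicographically smaller
    minor <- if (tab[[length(tab)]] == tab[[1]]) min(als[als != "0"]) else
      als[length(als)]
    if (minor == "0") minor <- als[1]
    allele1[j] <- minor
    allele2[j] <- setdiff(als, minor)[1]
    dos[, j] <- (a1m[, j] == minor) + (a2m[, j] == minor)
  }

  breed <- fam
  if (!is.null(breed_map)) {
    if (!all(c("sample_id", "breed") %in% names(breed_map)))
      stop("breed_map needs columns 'sample_id' and 'breed'")
    idx <- match(iid, breed_map$sample_id)
    if (anyNA(idx))
      stop("breed_map is missing sample(s): ",
           paste(utils::head(iid[is.na(idx)], 5), collapse = ", "))
    breed <- breed_map$breed[idx]
  }

  geno_matrix(dos,
              data.frame(sample_id = iid, breed = breed,
                         stringsAsFactors = FALSE),
              data.frame(snp = mp$snp, chr = mp$chr,
                         pos = as.integer(mp$pos),
                         a1 = allele1, a2 = allele2,
                         stringsAsFactors = FALSE))
}

#' Write genotypes as PLINK text files (PED/MAP)
#'
#' Inverse of [read_plink_text()]: dosage k becomes k copies of allele `a1`
#' and 2-k copies of `a2`; missing becomes "0 0". The breed label is written
#' into the PED family-ID column.
#'
#' @param g a [geno_matrix()].
#' @param ped_path,map_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_plink_text <- function(g, ped_path, map_path) {
  mp <- g$map
  data.table::fwrite(data.frame(mp$chr, mp$snp, 0L, mp$pos),
                     map_path, sep = "\t", col.names = FALSE)
  d <- g$dosage
  n <- nrow(d); ns <- ncol(d)
  al <- matrix("0", n, 2 * ns)
  for (j in seq_len(ns)) {
    a1 <- mp$a1[j]; a2 <- mp$a2[j]
    gj <- d[, j]
    c1 <- ifelse(is.na(gj), "0", ifelse(gj >= 1, a1, a2))
    c2 <- ifelse(is.na(gj), "0", ifelse(gj == 2, a1, a2))
    al[, 2 * j - 1] <- c1; al[, 2 * j] <- c2
  }
  ped <- cbind(g$samples$breed, g$samples$sample_id, "0", "0", "0", "-9", al)
  data.table::fwrite(as.data.frame(ped), ped_path, sep = "\t",
                     col.names = FALSE, quote = FALSE)
  invisible(c(ped = ped_path, map = map_path))
}

#' Read a gene coordinate table
#'
#' Tab-separated, headered file with columns `gene`, `chr`, `start`, `end`
#' (1-based inclusive bp). Such tables stand in for externally curated gene
#' sets, e.g. longevity-associated genes or a cancer-pathway gene list.
#'
#' @param path file path.
#' @return data.frame of class `gene_set`.
#' @export
read_gene_table <- function(path) {
  gs <- read_tsv_checked(path, c("gene", "chr", "start", "end"))
  gene_set(gs)
}

#' Construct/validate a gene set
#' @param df data.frame with columns `gene`, `chr`, `start`, `end`.
#' @return the validated data.frame, classed `gene_set`.
#' @export
gene_set <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene))
    stop("gene table schema error: duplicated gene id(s): ",
         paste(unique(df$gene[duplicated(df$gene)]), collapse = ", "))
  df$chr <- as.character(df$chr)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start < 1)) stop("gene table schema error: start < 1")
  if (any(df$start > df$end))
    stop("gene table schema error: start > end for gene(s): ",
         paste(df$gene[df$start > df$end], collapse = ", "))
  class(df) <- c("gene_set", "data.frame")
  df
}

#' Read a per-breed phenotype table
#'
#' Tab-separated, headered; requires columns `breed`, `body_weight_kg`,
#' `life_expectancy_years`, `cancer_mortality_pct`. Extra columns (e.g.
#' residual traits) are kept.
#'
#' @param path file path.
#' @return data.frame, one row per breed.
#' @export
read_phenotypes <- function(path) {
  ph <- read_tsv_checked(path, c("breed", "body_weight_kg",
                                 "life_expectancy_years",
                                 "cancer_mortality_pct"))
  validate_phenotypes(ph)
}

validate_phenotypes <- function(ph) {
  if (anyDuplicated(ph$breed))
    stop("phenotype schema error: duplicated breed row(s): ",
         paste(unique(ph$breed[duplicated(ph$breed)]), collapse = ", "))
  if (any(ph$body_weight_kg <= 0))
    stop("phenotype schema error: body_weight_kg must be positive")
  if (any(ph$cancer_mortality_pct < 0 | ph$cancer_mortality_pct > 100))
    stop("phenotype schema error: cancer_mortality_pct outside [0, 100]")
  ph
}

#' Write / read an association result table
#'
#' Tab-separated with columns `snp`, `chr`, `pos`, `n_used`, `beta`, `se`,
#' `raw_p`, `corrected_p`, `tier`; full precision is preserved on a
#' write-read round trip.
#'
#' @param tab association data.frame (see [run_association_experiment()]).
#' @param path file path.
#' @return `write_association_table`: invisibly, the path.
#' @export
write_association_table <- function(tab, path) {
  need <- c("snp", "chr", "pos", "beta", "raw_p", "corrected_p", "tier")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("association table schema error: missing column(s): ",
         paste(miss, collapse = ", "))
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_association_table
#' @export
read_association_table <- function(path) {
  read_tsv_checked(path, c("snp", "chr", "pos", "beta", "raw_p",
                           "corrected_p", "tier"))
}

#' Write a Manhattan-plot-ready table
#'
#' The association table augmented with `cum_pos`, a cumulative genome
#' coordinate obtained by laying chromosomes end to end in natural label
#' order, and `neglog10_raw_p`.
#'
#' @inheritParams write_association_table
#' @param g the [geno_matrix()] whose map defines chromosome extents.
#' @return Invisibly, the path.
#' @export
write_manhattan_table <- function(tab, g, path) {
  chr_levels <- unique(g$map$chr[order(suppressWarnings(
    as.numeric(g$map$chr)), g$map$chr)])
  ext <- tapply(g$map$pos, factor(g$map$chr, levels = chr_levels), max)
  offset <- c(0, cumsum(as.numeric(ext)))[seq_along(chr_levels)]
  names(offset) <- chr_levels
  tab$cum_pos <- tab$pos + offset[as.character(tab$chr)]
  tab$neglog10_raw_p <- -log10(tab$raw_p)
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

# shared strict TSV reader: headered, named required columns
read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("schema error in %s: missing required column(s): %s",
                 path, paste(miss, collapse = ", ")))
  df
}
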