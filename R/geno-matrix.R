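#' Construct a genotype matrix object
#'
#' Bundles a samples-by-SNPs minor-allele dosage matrix with its SNP map and
#' per-sample breed labels. Dosages are integer 0/1/2 counts of one allele
#' (conventionally the minor allele as defined on the loaded sample set);
#' missing genotypes are `NA`.
#'
#' @param dosage integer matrix, samples in rows, SNPs in columns; entries
#'   0, 1, 2 or `NA`. Row names are sample ids, column names SNP ids.
#' @param map data.frame with columns `snp`, `chr` (character), `pos`
#'   (1-based bp), `a1`, `a2`; one row per dosage column, same order.
#' @param samples data.frame with columns `sample_id`, `breed`; one row per
#'   dosage row, same order.
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, samples, map) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  stopifnot(nrow(map) == ncol(dosage), nrow(samples) == nrow(dosage))
  need_map <- c("snp", "chr", "pos", "a1", "a2")
  if (!all(need_map %in% names(map)))
    stop("SNP map is missing column(s): ",
         paste(setdiff(need_map, names(map)), collapse = ", "))
  if (!all(c("sample_id", "breed") %in% names(samples)))
    stop("sample table needs columns 'sample_id' and 'breed'")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("non-missing dosages must be 0, 1 or 2")
  if (anyDuplicated(map$snp)) stop("SNP ids are not unique")
  if (anyDuplicated(samples$sample_id)) stop("sample ids are not unique")
  if (any(is.na(samples$breed) | samples$breed == ""))
    stop("every sample must carry a breed label")
  map$chr <- as.character(map$chr)
  map$pos <- as.integer(map$pos)
  if (any(is.na(map$pos)) || any(map$pos < 1L))
    stop("SNP positions must be positive 1-based integers")
  rownames(dosage) <- samples$sample_id
  colnames(dosage) <- map$snp
  structure(list(dosage = dosage, samples = samples, map = map),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d SNPs, %d breeds, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              length(unique(x$samples$breed)),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / SNPs in a genotype matrix
#' @param g a `geno_matrix`
#' @return integer count
#' @export
n_samples <- function(g) nrow(g$dosage)

#' @rdname n_samples
#' @export
n_snps <- function(g) ncol(g$dosage)

#' Subset a genotype matrix by samples and/or SNPs
#'
#' @param g a `geno_matrix`
#' @param samples integer/logical/character index over samples (optional)
#' @param snps integer/logical/character index over SNPs (optional)
#' @return a `geno_matrix` restricted to the selection, order preserved as
#'   given by the index.
#' @export
subset_geno <- function(g, samples = NULL, snps = NULL) {
  d <- g$dosage; sm <- g$samples; mp <- g$map
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, sm$sample_id)
    d <- d[samples, , drop = FALSE]
    sm <- sm[samples, , drop = FALSE]
  }
  if (!is.null(snps)) {
    if (is.character(snps)) {
      idx <- match(snps, mp$snp)
      if (anyNA(idx))
        stop("SNP id(s) not present in the map: ",
             paste(snps[is.na(idx)], collapse = ", "))
      snps <- idx
    }
    d <- d[, snps, drop = FALSE]
    mp <- mp[snps, , drop = FALSE]
  }
  rownames(sm) <- NULL; rownames(mp) <- NULL
  geno_matrix(d, sm, mp)
}
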