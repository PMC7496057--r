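#' Candidate SNPs within a window around a gene set
#'
#' Flags every SNP lying within `window_bp` of some gene in the set —
#' inside the closed interval [start - window, end + window] on the same
#' chromosome — the usual candidate-gene windowing used to restrict an
#' association scan to markers near genes of interest (e.g. a longevity
#' gene list or a cancer-pathway gene list, with the customary 20 kb
#' window reflecting LD decay in dog breeds). Strand is ignored. Interval
#' overlap is computed with GenomicRanges.
#'
#' @param g a [geno_matrix()] (only its map is used).
#' @param genes a [gene_set()].
#' @param window_bp window half-width in bp on each side (default 20000).
#' @return data.frame sorted by (chromosome, position) with one row per
#'   candidate SNP: `snp`, `chr`, `pos`, `genes` (comma-separated ids of
#'   all genes whose window contains it), `n_genes`.
#' @export
snps_near_genes <- function(g, genes, window_bp = 20000L) {
  if (window_bp < 0) stop("window_bp must be non-negative")
  stopifnot(inherits(genes, "gene_set"))
  snp_gr <- GenomicRanges::GRanges(
    g$map$chr, IRanges::IRanges(g$map$pos, width = 1L))
  gene_gr <- GenomicRanges::GRanges(
    genes$chr,
    IRanges::IRanges(pmax(1L, genes$start - as.integer(window_bp)),
                     genes$end + as.integer(window_bp)))
  # the two range sets legitimately cover different chromosome subsets
  hits <- suppressWarnings(GenomicRanges::findOverlaps(snp_gr, gene_gr))
  qh <- S4Vectors::queryHits(hits)
  if (!length(qh))
    return(data.frame(snp = character(0), chr = character(0),
                      pos = integer(0), genes = character(0),
                      n_genes = integer(0), stringsAsFactors = FALSE))
  attrib <- split(genes$gene[S4Vectors::subjectHits(hits)], qh)
  idx <- as.integer(names(attrib))
  out <- data.frame(snp = g$map$snp[idx],
                    chr = g$map$chr[idx],
                    pos = g$map$pos[idx],
                    genes = vapply(attrib, paste, "", collapse = ","),
                    n_genes = vapply(attrib, length, 0L),
                    stringsAsFactors = FALSE)
  out <- out[order(suppressWarnings(as.numeric(out$chr)), out$chr, out$pos), ]
  rownames(out) <- NULL
  out
}
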