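#' Read a TE presence/absence variant table
#'
#' Ingests the output format of split/discordant-read TE genotypers: a TSV
#' with one row per TE variant (`chrom`, `pos`, `kind` = insertion|deletion,
#' then one 0/1/NA presence column per individual).
#'
#' @param path TSV path with a header line.
#' @return data.frame of class `te_variants`.
#' @export
read_te_table <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "pos", "kind") %in% names(out)))
  class(out) <- c("te_variants", "data.frame")
  out
}

#' TE-associated candidate genes for one population pair
#'
#' Restricts the window universe to 1-kbp windows containing at least one TE
#' variant, computes SNP-based Hudson F\eqn{_{ST}} in those windows,
#' thresholds at the upper quantile *within that restricted distribution*
#' (assuming linkage between a TE variant and nearby SNPs), and returns genes
#' whose span overlaps the flank interval around each TE in an outlier
#' window — the flank is anchored on the TE position itself, not the window
#' edges.
#'
#' @param te a [read_te_table()] data.frame (columns `chrom`, `pos`).
#' @param af an [allele_frequencies()] table.
#' @param genes a [read_gene_models()] table.
#' @param pair two population labels.
#' @param window_size,min_snps as in [hudson_fst_windows()].
#' @param quantile outlier quantile within TE-containing windows.
#' @param flank_bp half-width of the gene-assignment interval around a
#'   candidate TE variant (default 2000).
#' @return a [candidate_set()] with `source = "TE"`.
#' @export
te_candidate_genes <- function(te, af, genes, pair, window_size = 1000L,
                               min_snps = 10L, quantile = 0.99,
                               flank_bp = 2000L) {
  stats <- hudson_fst_windows(af, pair, window_size, min_snps)
  te_key <- unique(paste(te$chrom, (te$pos - 1L) %/% window_size))
  win_key <- paste(stats$chrom, stats$start %/% window_size)
  stats_te <- stats[win_key %in% te_key, , drop = FALSE]
  attr(stats_te, "pair") <- pair
  empty <- structure(list(pair = pair, source = "TE", genes = character(0),
                          quantile = quantile,
                          windows = stats_te[0, , drop = FALSE]),
                     class = "candidate_set")
  if (!any(!is.na(stats_te$fst))) {
    warning("no TE-containing window with >= ", min_snps, " SNPs")
    return(empty)
  }
  ow <- outlier_windows(stats_te, quantile)
  ow_key <- paste(ow$chrom, ow$start %/% window_size)
  cand_te <- te[paste(te$chrom, (te$pos - 1L) %/% window_size) %in% ow_key,
                , drop = FALSE]
  if (nrow(cand_te) == 0) return(empty)
  fl <- GenomicRanges::GRanges(cand_te$chrom,
                               IRanges::IRanges(pmax(1L, cand_te$pos - flank_bp),
                                                cand_te$pos + flank_bp))
  hits <- GenomicRanges::findOverlaps(genes_as_granges(genes), fl)
  structure(list(pair = pair, source = "TE",
                 genes = sort(unique(genes$gene_id[S4Vectors::queryHits(hits)])),
                 quantile = quantile, windows = ow),
            class = "candidate_set")
}
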