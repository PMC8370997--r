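#' Read gene models from a GFF3 annotation
#'
#' Extracts `gene` features as full gene spans — the gene line of a GFF
#' covers 5' UTR through stop codon and 3' UTR, so windows falling in introns
#' or UTRs still hit the gene. Coordinates are converted to the package's
#' internal 0-based half-open convention.
#'
#' @param annotation path to a GFF3 file or a `GRanges`.
#' @return data.frame of class `gene_models`: `gene_id`, `chrom`, `start`
#'   (0-based), `end` (exclusive), `strand`.
#' @export
read_gene_models <- function(annotation) {
  gr <- if (inherits(annotation, "GRanges")) annotation
        else rtracklayer::import(annotation, format = "gff3")
  g <- gr[tolower(as.character(gr$type)) == "gene"]
  if (length(g) == 0) stop("annotation contains no gene features")
  id <- if (!is.null(g$ID)) as.character(g$ID) else as.character(g$Name)
  out <- data.frame(gene_id = id,
                    chrom = as.character(GenomicRanges::seqnames(g)),
                    start = GenomicRanges::start(g) - 1L,
                    end = GenomicRanges::end(g),
                    strand = as.character(BiocGenerics::strand(g)),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

genes_as_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1L, genes$end))
}

#' Empirical-quantile outlier windows
#'
#' Returns the windows whose F\eqn{_{ST}} reaches the upper empirical
#' quantile of all windows with a defined estimate; ties at the threshold are
#' all included. With fewer than `1/(1-quantile)` eligible windows the
#' quantile is not meaningful, so the top-1 window is returned with a
#' warning.
#'
#' @param stats a window data.frame from [hudson_fst_windows()].
#' @param quantile upper quantile defining outliers (default 0.99, i.e. the
#'   top 1 percent).
#' @return the outlier subset of `stats`, with attribute `threshold`.
#' @export
outlier_windows <- function(stats, quantile = 0.99) {
  stopifnot(quantile > 0.5, quantile < 1)
  eligible <- stats[!is.na(stats$fst), , drop = FALSE]
  if (nrow(eligible) == 0) stop("no windows with defined fst")
  if (nrow(eligible) < 1 / (1 - quantile)) {
    warning("fewer than ", ceiling(1 / (1 - quantile)),
            " eligible windows: returning the single top window")
    thr <- max(eligible$fst)
  } else {
    thr <- as.numeric(stats::quantile(eligible$fst, quantile))
  }
  out <- eligible[eligible$fst >= thr, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- thr
  attr(out, "quantile") <- quantile
  attr(out, "pair") <- attr(stats, "pair")
  out
}

#' Genes overlapping a set of windows
#'
#' A gene is included iff its span overlaps at least 1 bp of at least one
#' window (the spans include UTRs and introns, so an outlier window inside an
#' intron still flags the gene).
#'
#' @param windows data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [outlier_windows()].
#' @param genes a [read_gene_models()] table.
#' @return character vector of gene IDs.
#' @export
genes_for_windows <- function(windows, genes) {
  if (nrow(windows) == 0) return(character(0))
  w <- GenomicRanges::GRanges(windows$chrom,
                              IRanges::IRanges(windows$start + 1L,
                                               windows$end))
  hits <- GenomicRanges::findOverlaps(genes_as_granges(genes), w)
  sort(unique(genes$gene_id[S4Vectors::queryHits(hits)]))
}

#' One pair's candidate gene set from the windowed scan
#'
#' Convenience wrapper: outlier windows at `quantile`, then overlapping
#' genes.
#'
#' @inheritParams outlier_windows
#' @inheritParams genes_for_windows
#' @param source label recorded on the set: `"SNP"` or `"TE"`.
#' @return object of class `candidate_set`: list with `pair`, `source`,
#'   `genes`, `quantile`, `windows`.
#' @export
candidate_set <- function(stats, genes, quantile = 0.99, source = "SNP") {
  ow <- outlier_windows(stats, quantile)
  structure(list(pair = attr(stats, "pair"), source = source,
                 genes = genes_for_windows(ow, genes),
                 quantile = quantile, windows = ow),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set [%s, %s]: %d genes from %d outlier windows (q = %.2f)\n",
              paste(x$pair, collapse = "-"), x$source, length(x$genes),
              nrow(x$windows), x$quantile))
  invisible(x)
}

#' Parallel differentiation candidates
#'
#' Genes flagged as candidates in at least `min_pairs` population pairs, with
#' the supporting pairs attached. Requiring support from two or more
#' independent colonisation events is what turns per-pair outliers into
#' candidates for parallel selection.
#'
#' @param sets list of [candidate_set()] objects (or plain lists with `pair`
#'   and `genes`).
#' @param min_pairs minimum number of supporting pairs (default 2).
#' @return data.frame with `gene`, `n_pairs`, `pairs`
#'   (comma-separated pair labels).
#' @export
parallel_candidates <- function(sets, min_pairs = 2L) {
  stopifnot(length(sets) >= 2)
  pair_label <- vapply(sets, function(s)
    paste(s$pair, collapse = "-"), "")
  long <- data.frame(
    gene = unlist(lapply(sets, `[[`, "genes")),
    pair = rep(pair_label, vapply(sets, function(s) length(s$genes), 0L)),
    stringsAsFactors = FALSE)
  if (nrow(long) == 0)
    return(data.frame(gene = character(0), n_pairs = integer(0),
                      pairs = character(0)))
  supp <- tapply(long$pair, long$gene, function(p) sort(unique(p)))
  n <- lengths(supp)
  keep <- n >= min_pairs
  out <- data.frame(gene = names(supp)[keep],
                    n_pairs = as.integer(n[keep]),
                    pairs = vapply(supp[keep], paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pairs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Final serpentine adaptation candidates
#'
#' Intersects the parallel differentiation candidates with the
#' environment-associated genes, carrying per-gene provenance (supporting
#' pairs from the scan, supporting soil variables from the association).
#'
#' @param parallel data.frame from [parallel_candidates()].
#' @param gea_genes data.frame from [gea_candidate_genes()] (or a character
#'   vector of gene IDs).
#' @return data.frame: `gene`, `n_pairs`, `pairs`, `variables`.
#' @export
serpentine_adaptation_candidates <- function(parallel, gea_genes) {
  if (is.character(gea_genes))
    gea_genes <- data.frame(gene = gea_genes, variables = NA_character_,
                            stringsAsFactors = FALSE)
  out <- merge(parallel, gea_genes[, c("gene", "variables")], by = "gene")
  out <- out[order(-out$n_pairs, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}
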