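#' Fourfold-degenerate site extraction
#'
#' Identifies genomic positions at third codon positions where all four
#' nucleotides encode the same amino acid under the standard nuclear genetic
#' code — the usual proxy for putatively neutral sites. Works strand-aware
#' from CDS features (using their phase); transcripts whose phase-adjusted
#' CDS length is not divisible by 3 are skipped with a warning. Positions
#' covered by overlapping CDS in conflicting frames (fourfold in one reading,
#' not in another) are excluded.
#'
#' @param reference path to a FASTA file or a `Biostrings::DNAStringSet`.
#' @param annotation path to a GFF3 file or a `GenomicRanges::GRanges` with
#'   `type`, `phase` and a transcript grouping column (`Parent` or `ID`).
#' @return data.frame with columns `chrom`, `pos` (1-based) of
#'   fourfold-degenerate sites, sorted.
#' @export
fourfold_degenerate_sites <- function(reference, annotation) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- if (inherits(annotation, "GRanges")) annotation
        else rtracklayer::import(annotation, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0) stop("annotation contains no CDS features")
  parent <- if (!is.null(cds$Parent) && any(lengths(cds$Parent) > 0)) {
    vapply(as.list(cds$Parent),
           function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else as.character(cds$ID)
  if (anyNA(parent)) stop("CDS features lack Parent/ID grouping")

  code <- Biostrings::GENETIC_CODE
  pre <- substr(names(code), 1, 2)
  four_pre <- names(which(tapply(code, pre,
                                 function(a) length(unique(a)) == 1)))

  is4dg <- new.env(); non4dg <- new.env()
  mark <- function(envir, keys) for (k in keys) assign(k, TRUE, envir)
  base_of <- c("A", "C", "G", "T")

  for (tx in unique(parent)) {
    part <- cds[parent == tx]
    chr <- as.character(GenomicRanges::seqnames(part))[1]
    if (!chr %in% names(seqs)) { warning("no sequence for ", chr); next }
    strand <- as.character(BiocGenerics::strand(part))[1]
    ord <- order(GenomicRanges::start(part))
    if (strand == "-") ord <- rev(ord)
    part <- part[ord]
    pos <- unlist(lapply(seq_along(part), function(i) {
      s <- GenomicRanges::start(part)[i]; e <- GenomicRanges::end(part)[i]
      if (strand == "-") seq(e, s) else seq(s, e)
    }))
    ph <- part$phase[1]
    if (is.null(ph) || is.na(ph)) ph <- 0L
    if (ph > 0) pos <- pos[-seq_len(ph)]
    if (length(pos) %% 3 != 0) {
      warning("CDS length of ", tx, " not divisible by 3 after phase; skipped")
      next
    }
    chr_seq <- seqs[[chr]]
    bases <- strsplit(as.character(chr_seq), "")[[1]][pos]
    if (strand == "-")
      bases <- c(A = "T", C = "G", G = "C", T = "A", N = "N")[bases]
    n_codon <- length(pos) %/% 3
    idx3 <- 3 * seq_len(n_codon)
    prefix <- paste0(bases[idx3 - 2], bases[idx3 - 1])
    third_pos <- pos[idx3]
    deg <- prefix %in% four_pre
    key <- function(p) paste0(chr, ":", p)
    mark(is4dg, key(third_pos[deg]))
    mark(non4dg, key(third_pos[!deg]))
    mark(non4dg, key(pos[-idx3]))   # first/second codon positions
  }
  keys <- setdiff(ls(is4dg), ls(non4dg))
  if (length(keys) == 0)
    return(data.frame(chrom = character(0), pos = integer(0)))
  parts <- strsplit(keys, ":", fixed = TRUE)
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    pos = as.integer(vapply(parts, `[`, "", 2L)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}
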