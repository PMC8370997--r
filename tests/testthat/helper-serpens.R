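# shared constructors for small in-code fixtures

# genotype matrix from a dosage matrix (individuals x sites)
make_gm <- function(dosage, pop, ploidy = 4L, depth = NULL, chrom = "chr1",
                    pos = NULL) {
  n_sites <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("i", seq_len(nrow(dosage)))
  if (is.null(names(pop))) names(pop) <- rownames(dosage)
  if (is.null(pos)) pos <- seq_len(n_sites) * 100L
  genotype_matrix(dosage,
                  data.frame(chrom = chrom, pos = pos, ref = "A", alt = "T",
                             stringsAsFactors = FALSE),
                  pop, ploidy = ploidy, depth = depth)
}

# allele frequency table straight from population frequencies
make_af <- function(freq, a = 32L, chrom = "chr1", pos = NULL) {
  pops <- rownames(freq)
  if (is.null(pos)) pos <- seq_len(ncol(freq)) * 100L
  alt <- round(freq * a)
  sampled <- matrix(a, nrow(freq), ncol(freq), dimnames = dimnames(freq))
  structure(list(pops = pops, alt = alt, sampled = sampled,
                 freq = alt / sampled,
                 sites = data.frame(chrom = chrom, pos = as.integer(pos),
                                    ref = "A", alt = "T",
                                    stringsAsFactors = FALSE),
                 ploidy = 4L),
            class = "allele_freq_table")
}

# a mildly structured quartet coancestry (two pairs)
make_F0 <- function(diag_f = 0.041, pair_f = 0.0165, a = 32,
                    pops = c("S1", "N1", "S2", "N2")) {
  Fm <- matrix(0, 4, 4)
  Fm[1, 2] <- Fm[2, 1] <- Fm[3, 4] <- Fm[4, 3] <- pair_f
  diag(Fm) <- diag_f
  structure(list(F = Fm, a = rep(a, 4), pops = pops, n_snps = 5000L,
                 projected = FALSE),
            class = "coancestry")
}

# gene model table
make_genes <- function(start, end, chrom = "chr1",
                       id = sprintf("g%02d", seq_along(start))) {
  out <- data.frame(gene_id = id, chrom = chrom, start = as.integer(start),
                    end = as.integer(end), strand = "+",
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

# write a small VCF from explicit genotype strings (records x individuals)
write_test_vcf <- function(records, individuals, path,
                           format = "GT:DP") {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chr1,length=100000>",
           "##contig=<ID=chr2,length=100000>",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", individuals), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

vcf_rec <- function(chrom, pos, ref, alt, calls) {
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", "GT:DP", calls),
        collapse = "\t")
}
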