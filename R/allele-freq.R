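#' Per-population allele frequencies
#'
#' Aggregates allele dosages into per-population alternate-allele copy counts
#' and sampled copy totals. These sample frequencies feed both the windowed
#' F\eqn{_{ST}} scan and the composite-likelihood coancestry model.
#'
#' @param gm a [genotype_matrix()].
#' @param pops character vector of populations to tabulate; defaults to all
#'   populations present in `gm`.
#' @return An object of class `allele_freq_table`: matrices `alt`, `sampled`
#'   and `freq` (populations x sites; `freq` is NA where a population has no
#'   non-missing calls at a site, flagged and excluded downstream), plus the
#'   site table.
#' @export
allele_frequencies <- function(gm, pops = sort(unique(gm$pop))) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$dosage) > 0)
  alt <- matrix(0L, length(pops), ncol(gm$dosage),
                dimnames = list(pops, NULL))
  sampled <- alt
  for (p in pops) {
    rows <- which(gm$pop == p)
    d <- gm$dosage[rows, , drop = FALSE]
    alt[p, ] <- as.integer(colSums(d, na.rm = TRUE))
    sampled[p, ] <- as.integer(gm$ploidy * colSums(!is.na(d)))
  }
  freq <- alt / sampled
  freq[sampled == 0L] <- NA_real_
  structure(list(pops = pops, alt = alt, sampled = sampled, freq = freq,
                 sites = gm$sites, ploidy = gm$ploidy),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d sites\n",
              length(x$pops), ncol(x$freq)))
  cat("  populations:", paste(x$pops, collapse = " "), "\n")
  invisible(x)
}

#' Restrict an allele frequency table to a site subset
#' @param af an `allele_freq_table`.
#' @param idx integer or logical site index.
#' @return the restricted `allele_freq_table`.
#' @export
subset_af <- function(af, idx) {
  af$alt <- af$alt[, idx, drop = FALSE]
  af$sampled <- af$sampled[, idx, drop = FALSE]
  af$freq <- af$freq[, idx, drop = FALSE]
  af$sites <- af$sites[idx, , drop = FALSE]
  rownames(af$sites) <- NULL
  af
}
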