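#' Per-SNP Hudson F_ST components
#'
#' Unbiased per-SNP numerator and denominator of Hudson's estimator:
#' \deqn{N_k = (p_1-p_2)^2 - p_1(1-p_1)/(a_1-1) - p_2(1-p_2)/(a_2-1)}
#' \deqn{D_k = p_1(1-p_2) + p_2(1-p_1)}
#' with \eqn{a_i} the sampled allele-copy counts. Windowed F\eqn{_{ST}} is the
#' ratio of averages \eqn{\sum N_k / \sum D_k}, which is robust to
#' sample-size asymmetry and is the standard aggregation for window scans.
#'
#' @param p1,p2 sample allele frequencies in the two populations.
#' @param a1,a2 sampled allele-copy counts.
#' @return list with vectors `N` and `D`.
#' @keywords internal
hudson_components <- function(p1, p2, a1, a2) {
  list(N = (p1 - p2)^2 - p1 * (1 - p1) / (a1 - 1) - p2 * (1 - p2) / (a2 - 1),
       D = p1 * (1 - p2) + p2 * (1 - p1))
}

#' Windowed Hudson F_ST for one population pair
#'
#' Computes the ratio-of-averages Hudson F\eqn{_{ST}} in non-overlapping
#' fixed-length windows anchored at position 0 of each chromosome (fixed
#' windows keep positions homogeneous across population pairs, making
#' candidate windows directly comparable). Only sites variable in the pooled
#' pair sample count as SNPs; windows with fewer than `min_snps` SNPs carry
#' `fst = NA`. Negative estimates are retained, not clamped.
#'
#' @param af an [allele_frequencies()] table.
#' @param pair character vector of two population names, conventionally
#'   (serpentine, non-serpentine).
#' @param window_size window length in bp (default 1000).
#' @param min_snps minimum SNPs per window for a defined estimate (default
#'   10).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `n_snps`, `fst`; attribute `pair` records the pair.
#' @export
hudson_fst_windows <- function(af, pair, window_size = 1000L,
                               min_snps = 10L) {
  stopifnot(length(pair) == 2, all(pair %in% af$pops))
  p1 <- af$freq[pair[1], ]; p2 <- af$freq[pair[2], ]
  a1 <- af$sampled[pair[1], ]; a2 <- af$sampled[pair[2], ]
  ok <- !is.na(p1) & !is.na(p2)
  low <- ok & (a1 <= 1 | a2 <= 1)
  if (any(low)) {
    warning(sum(low), " SNP(s) skipped: <2 sampled allele copies")
    ok <- ok & !low
  }
  # variable in the pooled two-population sample
  snp <- ok & !(p1 == p2 & (p1 == 0 | p1 == 1))
  comp <- hudson_components(p1[snp], p2[snp], a1[snp], a2[snp])
  chrom <- af$sites$chrom[snp]
  win <- (af$sites$pos[snp] - 1L) %/% window_size
  key <- paste(chrom, win, sep = "\r")
  Nsum <- tapply(comp$N, key, sum)
  Dsum <- tapply(comp$D, key, sum)
  cnt <- tapply(comp$N, key, length)
  parts <- strsplit(names(Nsum), "\r", fixed = TRUE)
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 2L)) * window_size,
    stringsAsFactors = FALSE)
  out$end <- out$start + window_size
  out$n_snps <- as.integer(cnt)
  out$fst <- ifelse(out$n_snps >= min_snps,
                    as.numeric(Nsum) / as.numeric(Dsum), NA_real_)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pair") <- pair
  attr(out, "window_size") <- window_size
  attr(out, "min_snps") <- min_snps
  out
}
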