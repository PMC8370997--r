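#' Project a symmetric matrix to the nearest positive semidefinite matrix
#'
#' Eigendecomposition with negative eigenvalues clamped to zero. Used on
#' estimated and constructed coancestry matrices, whose estimators can stray
#' slightly outside the PSD cone.
#'
#' @param M symmetric matrix.
#' @param tol eigenvalues below `-tol` trigger the projection (default
#'   1e-10).
#' @return PSD matrix; attribute `projected` says whether clamping occurred.
#' @export
psd_project <- function(M, tol = 1e-10) {
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= -tol) {
    attr(M, "projected") <- FALSE
    return(M)
  }
  out <- e$vectors %*% diag(pmax(e$values, 0), nrow(M)) %*% t(e$vectors)
  out <- (out + t(out)) / 2
  dimnames(out) <- dimnames(M)
  attr(out, "projected") <- TRUE
  out
}

#' Neutral coancestry matrix of a population quartet
#'
#' Estimates the population-level allele-frequency coancestry matrix F from
#' putatively neutral genome-wide SNPs: per SNP, sample frequencies are
#' mean-centered across the populations and standardized by
#' \eqn{\epsilon(1-\epsilon)} with \eqn{\epsilon} the across-population mean;
#' F is the average outer product. The diagonal is corrected for binomial
#' sampling noise — the sample coancestry satisfies
#' \eqn{\hat F_{ii} = F_{ii} + (1 - F_{ii})/a_i}, so the \eqn{1/a_i} term is
#' removed to recover the population value. The result is projected to the
#' nearest PSD matrix if needed (recorded in attribute `projected`).
#'
#' @param af an [allele_frequencies()] table.
#' @param quartet character vector of four populations, conventionally
#'   ordered (S_i, N_i, S_j, N_j).
#' @param neutral_idx integer/logical index of putatively neutral sites in
#'   `af` (e.g. fourfold-degenerate SNPs); default all sites.
#' @param min_snps minimum usable SNPs (default 1000); fewer is an error.
#' @param eps_range usable range of the across-quartet mean frequency
#'   (default 0.05-0.95), matching the frequency class scored by
#'   [composite_loglik()]: the baseline must be estimated on the same
#'   class of sites it will be compared against, since standardized
#'   covariances of rare and common variants differ.
#' @return object of class `coancestry`: `F` (4x4), `a` (mean sampled copies
#'   per population), `pops`, `n_snps`.
#' @export
neutral_coancestry <- function(af, quartet, neutral_idx = NULL,
                               min_snps = 1000L,
                               eps_range = c(0.05, 0.95)) {
  stopifnot(length(quartet) == 4)
  if (!all(quartet %in% af$pops))
    stop("population(s) missing from frequency table: ",
         paste(setdiff(quartet, af$pops), collapse = ", "))
  if (!is.null(neutral_idx)) af <- subset_af(af, neutral_idx)
  x <- af$freq[quartet, , drop = FALSE]
  ok <- colSums(is.na(x)) == 0L
  x <- x[, ok, drop = FALSE]
  eps <- colMeans(x)
  poly <- eps >= eps_range[1] & eps <= eps_range[2]
  x <- x[, poly, drop = FALSE]
  eps <- eps[poly]
  S <- ncol(x)
  if (S < min_snps)
    stop("only ", S, " usable neutral SNPs (need >= ", min_snps, ")")
  dev <- sweep(x, 2, eps) / rep(sqrt(eps * (1 - eps)), each = 4)
  Fhat <- tcrossprod(dev) / S
  a <- rowMeans(af$sampled[quartet, ok, drop = FALSE][, poly, drop = FALSE])
  diag(Fhat) <- pmin(1, pmax(0, (diag(Fhat) - 1 / a) / (1 - 1 / a)))
  Fm <- psd_project(Fhat)
  structure(list(F = Fm, a = a, pops = quartet, n_snps = S,
                 projected = isTRUE(attr(Fm, "projected"))),
            class = "coancestry")
}

#' @export
print.coancestry <- function(x, ...) {
  cat(sprintf("coancestry matrix over (%s), %d neutral SNPs%s\n",
              paste(x$pops, collapse = ", "), x$n_snps,
              if (x$projected) " [PSD-projected]" else ""))
  Fm <- x$F
  dimnames(Fm) <- list(x$pops, x$pops)
  print(round(Fm, 4))
  invisible(x)
}
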