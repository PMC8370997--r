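#' Nucleotide diversity with per-site downsampling
#'
#' Per-population nucleotide diversity (\eqn{\pi}) averaged over all retained
#' sites, including invariant ones in the denominator. To keep the sample
#' equal across populations, each site enters only if at least
#' `downsample_individuals` individuals have non-missing calls there
#' (per-site downsampling). The per-site value is the unbiased pairwise
#' estimator \eqn{2\,x(a-x) / (a(a-1))} on the available copies, which equals
#' the expectation of the same estimator under any hypergeometric downsample
#' to fewer copies — so the reported \eqn{\pi} does not depend on which
#' individuals a random subsample would pick, only on the inclusion rule.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @param downsample_individuals minimum non-missing individuals per site
#'   (default 6, i.e. 24 allele copies in tetraploids).
#' @return object of class `diversity_stat`: list with `pi`, `n_sites`,
#'   `pop`, `downsample_individuals`.
#' @export
nucleotide_diversity <- function(gm, pop, downsample_individuals = 6L) {
  d <- gm$dosage[gm$pop == pop, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  use <- n_called >= downsample_individuals
  x <- colSums(d, na.rm = TRUE)[use]
  a <- gm$ploidy * n_called[use]
  pi_site <- 2 * x * (a - x) / (a * (a - 1))
  structure(list(pop = pop,
                 pi = if (any(use)) mean(pi_site) else NA_real_,
                 n_sites = sum(use),
                 downsample_individuals = downsample_individuals),
            class = "diversity_stat")
}

#' @export
print.diversity_stat <- function(x, ...) {
  cat(sprintf("diversity_stat [%s]: pi = %.5g over %d sites (>= %d inds/site)\n",
              x$pop, x$pi, x$n_sites, x$downsample_individuals))
  if (!is.null(x$tajimas_d))
    cat(sprintf("  Tajima's D = %.4g (S = %d, a = %d copies)\n",
                x$tajimas_d, x$S, x$a))
  invisible(x)
}

#' Tajima's D constants for sample size n (allele copies)
#' @keywords internal
tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D with per-site downsampling to a fixed copy number
#'
#' Standard Tajima's D on a fixed sample of `ploidy * downsample_individuals`
#' allele copies per site. Sites with at least `downsample_individuals`
#' non-missing individuals are downsampled to exactly that many copies by a
#' seeded hypergeometric draw of alternate-allele copies (the
#' segregating-site count, unlike \eqn{\pi}, cannot be collapsed to an
#' expectation). Watterson's \eqn{\theta} comes from the downsampled
#' segregating-site count and \eqn{\pi} from the downsampled copy counts over
#' the same sites.
#'
#' @inheritParams nucleotide_diversity
#' @param seed integer seed for the hypergeometric downsampling.
#' @return object of class `diversity_stat` including `tajimas_d` (NA
#'   sentinel when no site segregates), `S`, and `a` (copies used).
#' @export
tajimas_d <- function(gm, pop, downsample_individuals = 6L, seed = 1L) {
  d <- gm$dosage[gm$pop == pop, , drop = FALSE]
  n_called <- colSums(!is.na(d))
  use <- n_called >= downsample_individuals
  x_full <- colSums(d, na.rm = TRUE)[use]
  a_full <- gm$ploidy * n_called[use]
  a <- as.integer(gm$ploidy * downsample_individuals)
  needs <- a_full > a
  x <- x_full
  if (any(needs)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    x[needs] <- stats::rhyper(sum(needs), m = x_full[needs],
                              n = a_full[needs] - x_full[needs], k = a)
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  }
  seg <- x > 0 & x < a
  S <- sum(seg)
  res <- structure(list(pop = pop, n_sites = sum(use), S = S, a = a,
                        downsample_individuals = downsample_individuals,
                        pi = if (any(use)) mean(2 * x * (a - x) / (a * (a - 1)))
                             else NA_real_,
                        tajimas_d = NA_real_),
                   class = "diversity_stat")
  if (S < 1) return(res)   # undefined: explicit NA sentinel, not zero
  k <- tajima_constants(a)
  pi_sum <- sum(2 * x[seg] * (a - x[seg]) / (a * (a - 1)))
  res$tajimas_d <- (pi_sum - S / k$a1) /
    sqrt(k$e1 * S + k$e2 * S * (S - 1))
  res
}
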