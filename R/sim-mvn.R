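#' Model-faithful multivariate-normal frequency generator
#'
#' Draws quartet allele frequencies directly from the coancestry model the
#' composite-likelihood classifier assumes: per SNP an across-population
#' mean \eqn{\epsilon} from a neutral-SFS-like density \eqn{\propto 1/x}
#' truncated to `eps_range`, a population frequency vector from
#' \eqn{\mathcal N(\epsilon,\; \epsilon(1-\epsilon) F'(d))} under the
#' planted scenario's constructor (truncated to \[0, 1\]), then binomial
#' sampling down to the per-population allele-copy counts. Used for unit
#' tests and for calibrating the neutral decision threshold.
#'
#' @param F0 a [neutral_coancestry()] object (or 4x4 matrix plus `a`).
#' @param params a [scenario_params()] describing the planted scenario
#'   (`scenario = "NEUTRAL"` for calibration data).
#' @param sel_pos genomic position of the planted selected site.
#' @param n_snps number of SNPs (default 150).
#' @param positions SNP positions; default `n_snps` uniform draws over
#'   `sel_pos +/- window/2`.
#' @param window window width in bp when positions are drawn (default
#'   50000).
#' @param a per-population sampled allele copies (default `round(F0$a)`).
#' @param seed mandatory integer seed: the generator is a pure function of
#'   (arguments, seed).
#' @param eps_range truncation of the ancestral-frequency density.
#' @param chrom chromosome label for the emitted sites.
#' @return an `allele_freq_table` for the four populations.
#' @export
simulate_mvn_freqs <- function(F0, params, sel_pos, n_snps = 150,
                               positions = NULL, window = 50000,
                               a = NULL, seed, eps_range = c(0.02, 0.98),
                               chrom = "sim1") {
  stopifnot(!missing(seed))
  pops <- if (inherits(F0, "coancestry")) F0$pops else paste0("pop", 1:4)
  F0mat <- if (inherits(F0, "coancestry")) F0$F else as.matrix(F0)
  if (is.null(a)) a <- round(if (inherits(F0, "coancestry")) F0$a
                             else rep(32, 4))
  a <- as.integer(a)
  par <- params
  par$selected <- resolve_pop(par$selected, pops)
  if (!is.na(par$src[1])) par$src <- resolve_pop(par$src, pops)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  if (is.null(positions))
    positions <- sort(round(stats::runif(n_snps, sel_pos - window / 2,
                                         sel_pos + window / 2)))
  n_snps <- length(positions)
  lo <- eps_range[1]; hi <- eps_range[2]
  eps <- lo * (hi / lo)^stats::runif(n_snps)
  d <- abs(positions - sel_pos)
  Fp_all <- scenario_Fprime_entries(F0mat, d, par)
  x <- matrix(NA_real_, 4, n_snps)
  for (k in seq_len(n_snps)) {
    Sig <- eps[k] * (1 - eps[k]) * matrix(Fp_all[k, ], 4, 4)
    Sig <- (Sig + t(Sig)) / 2
    R <- NULL
    jit <- 0
    repeat {
      R <- tryCatch(chol(Sig + diag(jit, 4)), error = function(e) NULL)
      if (!is.null(R)) break
      jit <- max(jit * 10, 1e-10)
    }
    x[, k] <- pmin(1, pmax(0, eps[k] + drop(t(R) %*% stats::rnorm(4))))
  }
  alt <- matrix(stats::rbinom(4 * n_snps, size = a, prob = x), 4, n_snps)
  sampled <- matrix(a, 4, n_snps)
  dimnames(alt) <- dimnames(sampled) <- list(pops, NULL)
  freq <- alt / sampled
  structure(list(pops = pops, alt = alt, sampled = sampled, freq = freq,
                 sites = data.frame(chrom = chrom, pos = as.integer(positions),
                                    ref = "A", alt = "T",
                                    stringsAsFactors = FALSE),
                 ploidy = 4L),
            class = "allele_freq_table")
}
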