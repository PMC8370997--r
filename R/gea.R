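#' Association-stage site filter
#'
#' Keeps sites with zero missing genotypes and overall minor allele
#' frequency strictly above `maf_min`. Complete data is required because the
#' latent-factor decomposition and the per-SNP regressions assume a full
#' matrix; the MAF floor removes near-monomorphic sites with no power.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min minor allele frequency floor (default 0.05).
#' @return the filtered [genotype_matrix()].
#' @export
gea_site_filter <- function(gm, maf_min = 0.05) {
  complete <- colSums(is.na(gm$dosage)) == 0L
  p <- colSums(gm$dosage, na.rm = TRUE) / (gm$ploidy * nrow(gm$dosage))
  maf <- pmin(p, 1 - p)
  keep <- complete & maf > maf_min
  if (!any(keep))
    stop(sprintf(paste0("no sites pass the association filter ",
                        "(%d total; %d incomplete; %d at MAF <= %.3g)"),
                 length(keep), sum(!complete), sum(complete & maf <= maf_min),
                 maf_min))
  subset_sites(gm, keep)
}

#' Latent ancestry factors by truncated SVD
#'
#' Decomposes the column-centered dosage matrix by singular value
#' decomposition and returns the first K left singular vectors scaled by
#' their singular values — individual scores capturing genome-wide ancestry
#' structure. K defaults to the number of population pairs, the discrete
#' groups the confounder correction must absorb. Deterministic up to sign;
#' the sign is fixed by making each factor's largest-magnitude SNP loading
#' positive, so nested K give identical leading columns.
#'
#' @param gm a complete-data [genotype_matrix()] (post [gea_site_filter()]).
#' @param K number of factors; must be less than the number of individuals.
#' @return numeric matrix, individuals x K.
#' @export
latent_factors <- function(gm, K = 5L) {
  n <- nrow(gm$dosage)
  if (K >= n) stop("K must be smaller than the number of individuals")
  X <- scale(gm$dosage, center = TRUE, scale = FALSE)
  sv <- svd(X, nu = K, nv = K)
  flip <- vapply(seq_len(K), function(k) {
    v <- sv$v[, k]
    sign(v[which.max(abs(v))])
  }, 0)
  scores <- sv$u %*% diag(sv$d[seq_len(K)] * flip, K, K)
  rownames(scores) <- gm$individuals
  colnames(scores) <- paste0("LF", seq_len(K))
  scores
}

#' Latent-factor genotype-environment association
#'
#' Per-SNP least-squares regression of centered dosage on the centered
#' environmental variable plus K latent ancestry factors (the two-stage
#' equivalent of a ridge latent-factor mixed model: truncated-SVD factors,
#' per-SNP regression, genomic-control recalibration). The z-scores are
#' recalibrated by the genomic inflation factor
#' \eqn{\lambda_{GC} = \mathrm{median}(z^2)/0.4549} before p-values are taken
#' from \eqn{\chi^2_1}, and q-values control the FDR.
#'
#' @param gm a complete-data [genotype_matrix()] (post [gea_site_filter()]).
#' @param env data.frame with one row per individual; must contain
#'   `individual` plus the variable column.
#' @param variable name of the environmental variable column to test.
#' @param K number of latent factors (default 5); `K = 0` disables the
#'   correction (useful to demonstrate inflation).
#' @param factors optional precomputed [latent_factors()] matrix.
#' @return data.frame of class `assoc_result`: per SNP `chrom`, `pos`,
#'   `beta`, `z`, `p`, `q`; attributes `lambda_gc`, `K`, `variable`.
#' @export
lfmm_associations <- function(gm, env, variable, K = 5L, factors = NULL) {
  stopifnot(variable %in% names(env), "individual" %in% names(env))
  env <- env[match(gm$individuals, env$individual), , drop = FALSE]
  if (anyNA(env$individual))
    stop("env table does not cover all individuals")
  v <- env[[variable]]
  if (!all(is.finite(v))) stop("non-finite values in ", variable)
  if (stats::sd(v) == 0) stop("variable '", variable, "' is constant")
  if (is.null(factors) && K > 0) factors <- latent_factors(gm, K)
  X <- cbind(scale(v, scale = FALSE),
             if (K > 0) scale(factors, scale = FALSE))
  if (K > 0) {
    r2 <- summary(stats::lm(X[, 1] ~ X[, -1, drop = FALSE]))$r.squared
    if (r2 > 0.95)
      warning(sprintf(paste0("environmental variable nearly collinear with",
                             " latent factors (R^2 = %.3f); results flagged"),
                      r2))
  }
  Y <- scale(gm$dosage, center = TRUE, scale = FALSE)
  XtXi <- solve(crossprod(X))
  B <- XtXi %*% crossprod(X, Y)
  resid <- Y - X %*% B
  df <- nrow(Y) - ncol(X) - 1L   # -1 for the centering
  sigma2 <- colSums(resid^2) / df
  se <- sqrt(sigma2 * XtXi[1, 1])
  tstat <- as.numeric(B[1, ] / se)
  # map the t statistic to an exactly standard-normal z before genomic
  # control: at these sample sizes the t tail is noticeably heavier than
  # the normal one and would inflate the smallest p-values
  lp <- stats::pt(abs(tstat), df, lower.tail = FALSE, log.p = TRUE)
  z <- sign(tstat) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
  lambda <- stats::median(z^2) / stats::qchisq(0.5, 1)
  p <- stats::pchisq(z^2 / lambda, df = 1, lower.tail = FALSE)
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    beta = as.numeric(B[1, ]), z = z, p = p,
                    q = qvalues(p), stringsAsFactors = FALSE)
  attr(out, "lambda_gc") <- lambda
  attr(out, "K") <- K
  attr(out, "variable") <- variable
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' q-values from p-values
#'
#' Benjamini-Hochberg step-up adjusted values scaled by an estimate of the
#' null proportion \eqn{\pi_0}. The default \eqn{\pi_0 = 1} is conservative
#' and makes q-values equal BH-adjusted p-values; Storey's estimate
#' (`pi0 = "storey"`, \eqn{\hat\pi_0 = \#\{p > \lambda\}/((1-\lambda) m)} at
#' \eqn{\lambda = 0.5}) is opt-in. Output is monotone in p.
#'
#' @param p vector of p-values in (0, 1].
#' @param pi0 1 (default), a number in (0, 1\], or `"storey"`.
#' @return vector of q-values.
#' @export
qvalues <- function(p, pi0 = 1) {
  if (length(p) == 0) stop("empty p-value vector")
  stopifnot(all(p > 0 & p <= 1))
  if (identical(pi0, "storey")) {
    lambda <- 0.5
    pi0 <- min(1, max(mean(p > lambda) / (1 - lambda), 1 / length(p)))
  }
  stopifnot(is.numeric(pi0), pi0 > 0, pi0 <= 1)
  pmin(1, pi0 * stats::p.adjust(p, method = "BH"))
}

#' Environment-associated candidate genes
#'
#' A gene is included iff at least one SNP within its span is significant
#' (q below `fdr`) for at least one of the tested soil variables; per-gene
#' provenance records which variables support it.
#'
#' @param assoc_list named list of [lfmm_associations()] results (one per
#'   variable).
#' @param genes a [read_gene_models()] table.
#' @param fdr q-value threshold (default 0.05).
#' @return data.frame: `gene`, `n_snps` (significant SNPs in span),
#'   `variables` (comma-separated).
#' @export
gea_candidate_genes <- function(assoc_list, genes, fdr = 0.05) {
  if (is.null(names(assoc_list)))
    names(assoc_list) <- vapply(assoc_list, attr, "", "variable")
  hits <- do.call(rbind, lapply(names(assoc_list), function(nm) {
    a <- assoc_list[[nm]]
    sig <- a[a$q < fdr, c("chrom", "pos"), drop = FALSE]
    if (nrow(sig) == 0) return(NULL)
    sig$variable <- nm
    sig
  }))
  if (is.null(hits) || nrow(hits) == 0)
    return(data.frame(gene = character(0), n_snps = integer(0),
                      variables = character(0)))
  snp_gr <- GenomicRanges::GRanges(hits$chrom,
                                   IRanges::IRanges(hits$pos, hits$pos))
  ov <- GenomicRanges::findOverlaps(snp_gr, genes_as_granges(genes))
  if (length(ov) == 0)
    return(data.frame(gene = character(0), n_snps = integer(0),
                      variables = character(0)))
  df <- data.frame(gene = genes$gene_id[S4Vectors::subjectHits(ov)],
                   variable = hits$variable[S4Vectors::queryHits(ov)],
                   key = paste(hits$chrom, hits$pos)[S4Vectors::queryHits(ov)],
                   stringsAsFactors = FALSE)
  agg_n <- tapply(df$key, df$gene, function(k) length(unique(k)))
  agg_v <- tapply(df$variable, df$gene,
                  function(v) paste(sort(unique(v)), collapse = ","))
  out <- data.frame(gene = names(agg_n), n_snps = as.integer(agg_n),
                    variables = as.character(agg_v),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$gene), , drop = FALSE]
}
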