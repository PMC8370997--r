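#' Site filtering configuration
#'
#' Bundles the per-genotype and per-site filters applied when ingesting a
#' VCF: a per-individual depth minimum, a cap on the fraction of
#' filtered/missing genotypes per site (MFFG), an optional stage-local minor
#' allele frequency floor, and the parameters of the depth/heterozygosity
#' site masks used to flag likely mis-assembled (paralogous) regions.
#'
#' @param min_depth integer; genotypes with read depth below this are set to
#'   missing (default 8).
#' @param max_missing_fraction proportion in \[0, 1\]; sites whose fraction of
#'   missing genotypes (after depth filtering) exceeds this are dropped
#'   (default 0.2).
#' @param maf_min minor allele frequency floor in \[0, 0.5); 0 disables. MAF
#'   filters are stage-local (0 for diversity statistics, 0.05 for
#'   association), never global.
#' @param depth_mask_sd multiplier k: sites whose cross-individual mean depth
#'   exceeds global mean + k * SD are masked (default 2).
#' @param het_excess_threshold fraction of heterozygous calls above which a
#'   site is masked as showing excess heterozygosity (default 0.9).
#' @return An object of class `site_filter_config`.
#' @export
site_filter_config <- function(min_depth = 8, max_missing_fraction = 0.2,
                               maf_min = 0, depth_mask_sd = 2,
                               het_excess_threshold = 0.9) {
  stopifnot(min_depth >= 0,
            max_missing_fraction >= 0, max_missing_fraction <= 1,
            maf_min >= 0, maf_min < 0.5,
            depth_mask_sd > 0,
            het_excess_threshold > 0, het_excess_threshold <= 1)
  structure(list(min_depth = min_depth,
                 max_missing_fraction = max_missing_fraction,
                 maf_min = maf_min,
                 depth_mask_sd = depth_mask_sd,
                 het_excess_threshold = het_excess_threshold),
            class = "site_filter_config")
}

#' Construct a genotype matrix object
#'
#' The central genotype container: an individuals x sites integer matrix of
#' allele dosages (0..ploidy, NA for missing), per-individual population
#' labels, and site metadata. Sites must be biallelic SNPs sorted by
#' (chromosome, position).
#'
#' @param dosage integer matrix, individuals in rows, sites in columns; NA is
#'   missing.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`.
#' @param pop named character vector mapping individual -> population; names
#'   must equal `rownames(dosage)`.
#' @param ploidy integer; 4 for autotetraploids.
#' @param depth optional matrix of per-genotype read depths, same shape as
#'   `dosage`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, sites, pop, ploidy = 4L, depth = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  stopifnot(nrow(sites) == ncol(dosage),
            all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
            !is.null(rownames(dosage)),
            setequal(names(pop), rownames(dosage)))
  pop <- pop[rownames(dosage)]
  rng <- range(dosage, na.rm = TRUE)
  if (any(is.finite(rng)) && (rng[1] < 0 || rng[2] > ploidy))
    stop("dosage values must lie in 0..ploidy or be NA")
  ord <- order(sites$chrom, sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    dosage <- dosage[, ord, drop = FALSE]
    if (!is.null(depth)) depth <- depth[, ord, drop = FALSE]
  }
  if (anyDuplicated(sites[c("chrom", "pos")]))
    stop("duplicated site positions")
  rownames(sites) <- NULL
  structure(list(dosage = dosage, depth = depth, sites = sites,
                 individuals = rownames(dosage), pop = pop,
                 ploidy = as.integer(ploidy)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d sites (ploidy %d)\n",
              nrow(x$dosage), ncol(x$dosage), x$ploidy))
  cat(sprintf("  populations: %s\n",
              paste(sprintf("%s(%d)", names(table(x$pop)), table(x$pop)),
                    collapse = " ")))
  cat(sprintf("  missing genotypes: %.2f%%\n",
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix by site index
#' @param gm a `genotype_matrix`.
#' @param idx integer or logical index over sites.
#' @return a `genotype_matrix` restricted to the selected sites.
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$dosage[, idx, drop = FALSE],
                  gm$sites[idx, , drop = FALSE],
                  gm$pop, gm$ploidy,
                  depth = if (!is.null(gm$depth)) gm$depth[, idx, drop = FALSE])
}

#' Read tetraploid genotypes from a VCF
#'
#' Parses a multi-sample VCF with fixed-ploidy GT fields (four allele slots
#' per call for autotetraploids), keeps biallelic SNP records only, converts
#' calls to alternate-allele dosages, masks genotypes below the per-individual
#' depth minimum, and drops sites whose missing fraction exceeds the MFFG
#' cap. Invariant (all-reference) sites are retained so diversity statistics
#' can use them in the denominator.
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param pop named character vector (individual -> population) or path to a
#'   two-column TSV (individual, population) with no header.
#' @param filter a [site_filter_config()].
#' @param ploidy expected ploidy of every GT call; a record with a different
#'   number of allele slots is an error naming the record.
#' @return A [genotype_matrix()].
#' @export
read_tetraploid_vcf <- function(path, pop, filter = site_filter_config(),
                                ploidy = 4L) {
  if (is.character(pop) && length(pop) == 1 && file.exists(pop)) {
    pm <- utils::read.table(pop, header = FALSE, sep = "\t",
                            col.names = c("individual", "population"),
                            colClasses = "character")
    pop <- stats::setNames(pm$population, pm$individual)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)))   # single-record VCFs drop to a vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  chrom <- fix[, "CHROM"]; posn <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  for (ch in unique(chrom)) {
    p <- posn[chrom == ch]
    if (is.unsorted(p, strictly = TRUE))
      stop("VCF not sorted by position on ", ch)
  }
  bial <- !is.na(ref) & nchar(ref) == 1 & ref %in% c("A", "C", "G", "T") &
    !is.na(alt) & !grepl(",", alt) & nchar(alt) == 1 &
    alt %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, "GT")
  dp <- tryCatch(vcfR::extract.gt(v, "DP", as.numeric = TRUE),
                 error = function(e) NULL)
  keep <- which(bial)
  gt <- gt[keep, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep, , drop = FALSE]
  chrom <- chrom[keep]; posn <- posn[keep]; ref <- ref[keep]; alt <- alt[keep]

  # vectorized string ops (no per-call splitting): slot count from the
  # separator count, dosage from the count of '1' alleles
  gtv <- as.vector(gt)
  called <- !is.na(gtv) & !grepl(".", gtv, fixed = TRUE)
  nch <- nchar(gtv)
  nsep <- nch - nchar(gsub("/", "", gsub("|", "/", gtv, fixed = TRUE),
                           fixed = TRUE))
  badp <- called & (nsep + 1L != ploidy)
  if (any(badp)) {
    bad <- arrayInd(which(badp)[1], dim(gt))
    stop(sprintf("mixed-ploidy GT at %s:%d (sample %s): expected %d alleles",
                 chrom[bad[1]], posn[bad[1]], colnames(gt)[bad[2]], ploidy))
  }
  dosv <- rep(NA_integer_, length(gtv))
  dosv[called] <- nch[called] -
    nchar(gsub("1", "", gtv[called], fixed = TRUE))
  dos <- matrix(dosv, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  if (!is.null(dp)) dos[!is.na(dp) & dp < filter$min_depth] <- NA_integer_
  miss_frac <- rowMeans(is.na(dos))
  keep2 <- miss_frac <= filter$max_missing_fraction
  dos <- dos[keep2, , drop = FALSE]
  if (!is.null(dp)) dp <- dp[keep2, , drop = FALSE]
  sites <- data.frame(chrom = chrom[keep2], pos = posn[keep2],
                      ref = ref[keep2], alt = alt[keep2],
                      stringsAsFactors = FALSE)
  inds <- colnames(dos)
  if (!all(inds %in% names(pop)))
    stop("population map missing individuals: ",
         paste(setdiff(inds, names(pop)), collapse = ", "))
  genotype_matrix(t(dos), sites, pop[inds], ploidy = ploidy,
                  depth = if (!is.null(dp)) t(dp))
}

#' Depth and heterozygosity site masks
#'
#' Flags sites whose cross-individual mean read depth exceeds the global mean
#' by more than `depth_mask_sd` standard deviations, or whose fraction of
#' heterozygous calls (dosage not in \{0, ploidy\}; all heterozygote dosage
#' classes treated identically) exceeds `het_excess_threshold`. Both signals
#' mark likely collapsed paralogous regions.
#'
#' @param gm a [genotype_matrix()].
#' @param filter a [site_filter_config()].
#' @return integer vector of masked site indices (columns of `gm$dosage`).
#' @export
depth_het_mask <- function(gm, filter = site_filter_config()) {
  masked <- integer(0)
  if (!is.null(gm$depth)) {
    site_mean <- colMeans(gm$depth, na.rm = TRUE)
    mu <- mean(site_mean, na.rm = TRUE)
    s <- stats::sd(site_mean, na.rm = TRUE)
    if (is.finite(s) && s > 0)
      masked <- which(site_mean > mu + filter$depth_mask_sd * s)
  } else {
    warning("no depth data: applying heterozygosity mask only")
  }
  het <- gm$dosage > 0L & gm$dosage < gm$ploidy
  het_frac <- colMeans(het, na.rm = TRUE)
  het_frac[is.nan(het_frac)] <- 0
  sort(unique(c(masked, which(het_frac > filter$het_excess_threshold))))
}
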