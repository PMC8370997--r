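#' Pipeline run configuration
#'
#' Collects the file paths and every stage parameter of the end-to-end
#' analysis in one validated object. Defaults are the analysis constants
#' used throughout: 1-kb windows with at least 10 SNPs, top-1-percent
#' outliers, candidates in at least 2 pairs, 5 latent factors, FDR 0.05,
#' 25-kb coancestry flanks with 8 proposed sites, neutral MCL threshold 21
#' and a 10-percent serpentine margin, and +/-2-kb TE flanks.
#'
#' @param vcf,gff,popmap,env required input paths (VCF with ploidy-4 GT,
#'   GFF3 gene annotation, individual-to-population TSV, soil covariate
#'   TSV).
#' @param te optional TE variant TSV.
#' @param pairs data.frame with columns `S`, `N` naming the serpentine and
#'   non-serpentine population of each pair; NULL autodetects populations
#'   named `S<k>`/`N<k>`.
#' @param window_size,min_snps,quantile,min_pairs,K,fdr,flank,n_sites,neutral_threshold,serpentine_margin,te_flank
#'   stage parameters (see the stage functions).
#' @param env_variables soil variables tested for association.
#' @param r_bp,Ne sweep-model constants passed to the classifier.
#' @param maf_min association-stage MAF floor.
#' @param filter a [site_filter_config()] for ingestion.
#' @param neutral_buffer_bp SNPs farther than this from any gene span form
#'   the putatively neutral set for the coancestry estimate (used when no
#'   fourfold-degenerate mask is supplied).
#' @param seed root seed; every stage derives its randomness from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(vcf, gff, popmap, env, te = NULL, pairs = NULL,
                       window_size = 1000L, min_snps = 10L, quantile = 0.99,
                       min_pairs = 2L, K = 5L, fdr = 0.05, flank = 25000,
                       n_sites = 8L, neutral_threshold = 21,
                       serpentine_margin = 0.10, te_flank = 2000L,
                       env_variables = c("CaMg", "Mg", "Ni", "Co"),
                       r_bp = 2e-8, Ne = 30000, maf_min = 0.05,
                       filter = site_filter_config(),
                       neutral_buffer_bp = 5000L, seed = 1L) {
  for (f in c(vcf, gff, popmap, env, te))
    if (!is.null(f) && !file.exists(f)) stop("missing input file: ", f)
  structure(list(vcf = vcf, gff = gff, popmap = popmap, env = env, te = te,
                 pairs = pairs, window_size = window_size,
                 min_snps = min_snps, quantile = quantile,
                 min_pairs = min_pairs, K = K, fdr = fdr, flank = flank,
                 n_sites = n_sites, neutral_threshold = neutral_threshold,
                 serpentine_margin = serpentine_margin, te_flank = te_flank,
                 env_variables = env_variables, r_bp = r_bp, Ne = Ne,
                 maf_min = maf_min, filter = filter,
                 neutral_buffer_bp = neutral_buffer_bp,
                 seed = as.integer(seed)),
            class = "run_config")
}

detect_pairs <- function(pops) {
  ks <- sort(unique(as.integer(sub("^[SN]", "", pops))))
  pairs <- data.frame(S = paste0("S", ks), N = paste0("N", ks),
                      stringsAsFactors = FALSE)
  if (!all(unlist(pairs) %in% pops))
    stop("cannot autodetect pairs; supply `pairs` explicitly")
  pairs
}

#' Run the full analysis pipeline
#'
#' Executes the stages end to end: VCF ingestion and filtering, per-pair
#' windowed F\eqn{_{ST}} scans and outlier candidate sets, parallel
#' candidates with the multi-set intersection test, latent-factor
#' genotype-environment association over the soil variables, the final
#' serpentine-adaptation candidate list, the optional TE-based scan, and
#' composite-likelihood source classification of each candidate gene on
#' each supporting quartet of populations. Intermediates are written as
#' TSV/JSON under `out_dir` when given; the run is deterministic given the
#' config (including its seed).
#'
#' @param cfg a [run_config()].
#' @param out_dir optional directory for intermediate and report files.
#' @return object of class `serpens_report`.
#' @export
run_all <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(obj, name) {
    if (!is.null(out_dir))
      utils::write.table(obj, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage:%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  gm <- stage("ingest", read_tetraploid_vcf(cfg$vcf, cfg$popmap, cfg$filter))
  genes <- stage("ingest", read_gene_models(cfg$gff))
  pairs <- if (is.null(cfg$pairs)) detect_pairs(unique(gm$pop)) else cfg$pairs
  af <- stage("frequencies", allele_frequencies(gm))

  # per-pair scans and candidate sets
  scan <- stage("scan", {
    lapply(seq_len(nrow(pairs)), function(k) {
      st <- hudson_fst_windows(af, c(pairs$S[k], pairs$N[k]),
                               cfg$window_size, cfg$min_snps)
      list(stats = st, set = candidate_set(st, genes, cfg$quantile))
    })
  })
  sets <- lapply(scan, `[[`, "set")
  for (k in seq_along(sets))
    emit(scan[[k]]$stats, sprintf("fst_windows_pair%d.tsv", k))
  cand_tab <- do.call(rbind, lapply(sets, function(s)
    if (length(s$genes))
      data.frame(gene = s$genes, pair = paste(s$pair, collapse = "-"),
                 source = s$source, stringsAsFactors = FALSE)))
  emit(cand_tab, "candidates_per_pair.tsv")

  par_cand <- stage("parallel", parallel_candidates(sets, cfg$min_pairs))
  emit(par_cand, "parallel_candidates.tsv")
  isect <- stage("parallel", multiset_intersection_test(
    lapply(sets, `[[`, "genes"), universe_n = nrow(genes),
    seed = cfg$seed + 101L))

  # genotype-environment association; ancestry factors are estimated on
  # SNPs outside strongly differentiated windows so that selection-driven
  # axes cannot absorb the environmental signal (analogous to running the
  # structure analyses on putatively neutral SNPs)
  env <- utils::read.table(cfg$env, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  gea <- stage("gea", {
    gmc <- gea_site_filter(gm, cfg$maf_min)
    hot <- do.call(rbind, lapply(scan, function(sc)
      outlier_windows(sc$stats, 0.95)[, c("chrom", "start", "end")]))
    key <- paste(hot$chrom, hot$start %/% cfg$window_size)
    in_hot <- paste(gmc$sites$chrom,
                    (gmc$sites$pos - 1L) %/% cfg$window_size) %in% key
    fac <- latent_factors(if (mean(in_hot) < 0.9)
      subset_sites(gmc, !in_hot) else gmc, cfg$K)
    assoc <- lapply(cfg$env_variables, function(v)
      lfmm_associations(gmc, env, v, cfg$K, factors = fac))
    names(assoc) <- cfg$env_variables
    list(assoc = assoc, genes = gea_candidate_genes(assoc, genes, cfg$fdr))
  })
  emit(gea$genes, "gea_candidate_genes.tsv")

  serp <- stage("overlap",
                serpentine_adaptation_candidates(par_cand, gea$genes))
  emit(serp, "serpentine_adaptation_candidates.tsv")

  # optional TE-based candidates
  te_sets <- NULL; te_parallel <- NULL
  if (!is.null(cfg$te)) {
    te <- read_te_table(cfg$te)
    te_sets <- stage("te", lapply(seq_len(nrow(pairs)), function(k)
      te_candidate_genes(te, af, genes, c(pairs$S[k], pairs$N[k]),
                         cfg$window_size, cfg$min_snps, cfg$quantile,
                         cfg$te_flank)))
    te_parallel <- stage("te", parallel_candidates(te_sets, cfg$min_pairs))
    emit(te_parallel, "te_parallel_candidates.tsv")
  }

  # composite-likelihood source classification per gene x quartet
  dmc <- stage("dmc", {
    neutral_idx <- neutral_site_index(af, genes, cfg$neutral_buffer_bp)
    pair_label <- paste(pairs$S, pairs$N, sep = "-")
    F0_cache <- new.env()
    cases <- list()
    for (g in serp$gene) {
      grow <- genes[genes$gene_id == g, ]
      supp <- match(strsplit(serp$pairs[serp$gene == g], ",")[[1]],
                    pair_label)
      for (qt in utils::combn(sort(supp), 2, simplify = FALSE)) {
        quartet <- c(pairs$S[qt[1]], pairs$N[qt[1]],
                     pairs$S[qt[2]], pairs$N[qt[2]])
        key <- paste(quartet, collapse = "|")
        if (!exists(key, envir = F0_cache, inherits = FALSE))
          F0_cache[[key]] <- neutral_coancestry(af, quartet, neutral_idx,
                                                min_snps = 200L)
        cases[[length(cases) + 1L]] <-
          dmc_case(af, grow, quartet, F0_cache[[key]],
                   r_bp = cfg$r_bp, Ne = cfg$Ne, flank = cfg$flank,
                   n_sites = cfg$n_sites,
                   neutral_threshold = cfg$neutral_threshold,
                   serpentine_margin = cfg$serpentine_margin)
      }
    }
    cases
  })
  sources <- if (length(dmc)) summarize_sources(dmc) else NULL
  if (!is.null(sources)) emit(sources$table, "dmc_cases.tsv")

  report <- structure(list(
    n_individuals = nrow(gm$dosage), n_sites = ncol(gm$dosage),
    pairs = pairs,
    candidate_counts = vapply(sets, function(s) length(s$genes), 0L),
    intersection = isect,
    n_parallel = nrow(par_cand), parallel = par_cand,
    n_gea = nrow(gea$genes),
    lambda_gc = vapply(gea$assoc, attr, 0, "lambda_gc"),
    n_serpentine = nrow(serp), serpentine = serp,
    te_parallel = te_parallel,
    sources = sources,
    config = cfg, seed = cfg$seed),
    class = "serpens_report")
  if (!is.null(out_dir)) {
    jsonlite::write_json(
      list(seed = cfg$seed,
           candidate_counts = report$candidate_counts,
           n_parallel = report$n_parallel,
           intersection_p = isect$p_value,
           n_gea = report$n_gea, n_serpentine = report$n_serpentine,
           source_counts = if (!is.null(sources))
             as.list(sources$counts) else NULL),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  report
}

# SNPs far from every gene span: the putatively neutral background used for
# the coancestry estimate when no codon-based mask is available
neutral_site_index <- function(af, genes, buffer = 5000L) {
  snp_gr <- GenomicRanges::GRanges(af$sites$chrom,
                                   IRanges::IRanges(af$sites$pos,
                                                    af$sites$pos))
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(pmax(1L, genes$start + 1L - buffer),
                                  genes$end + buffer))
  ov <- GenomicRanges::findOverlaps(snp_gr, gene_gr)
  setdiff(seq_len(nrow(af$sites)), unique(S4Vectors::queryHits(ov)))
}

#' @export
print.serpens_report <- function(x, ...) {
  cat("serpens pipeline report\n")
  cat(sprintf("  %d individuals, %d sites, %d population pairs\n",
              x$n_individuals, x$n_sites, nrow(x$pairs)))
  cat(sprintf("  per-pair candidate genes: %s\n",
              paste(x$candidate_counts, collapse = ", ")))
  cat(sprintf("  parallel candidates (>= %d pairs): %d (intersection p = %.3g)\n",
              x$config$min_pairs, x$n_parallel, x$intersection$p_value))
  cat(sprintf("  environment-associated genes: %d (lambda_gc: %s)\n",
              x$n_gea, paste(sprintf("%.2f", x$lambda_gc), collapse = ", ")))
  cat(sprintf("  serpentine adaptation candidates: %d\n", x$n_serpentine))
  if (!is.null(x$te_parallel))
    cat(sprintf("  TE-based parallel candidates: %d\n", nrow(x$te_parallel)))
  if (!is.null(x$sources)) {
    cat("  source classification:\n")
    n <- nrow(x$sources$table)
    for (nm in names(x$sources$counts))
      cat(sprintf("    %-10s %3d\n", nm, x$sources$counts[[nm]]))
  }
  invisible(x)
}
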