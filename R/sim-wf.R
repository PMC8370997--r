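#' Configuration of the forward Wright-Fisher pair simulator
#'
#' Defines the study design the generator emulates: replicated
#' serpentine/non-serpentine population pairs that split from regional
#' ancestors (themselves splitting earlier from a common root), tetraploid
#' individuals sampled at the tips, soil covariates shifted by substrate,
#' and planted selected genes under one of the three parallel-selection
#' modes. Defaults follow the study conditions: 5 pairs of 8 tetraploid
#' individuals, Ne = 30,000, pair split ~3,000 generations ago (the
#' reported range is ~2,700-4,300), mutation rate 4.3e-8, and site densities
#' tuned so genome-wide diversity lands at \eqn{\pi \approx 0.03}
#' (see [analytic_pi()]).
#'
#' @param n_pairs number of S-N population pairs (default 5).
#' @param n_per_pop tetraploid individuals sampled per population (default
#'   8).
#' @param ploidy default 4.
#' @param Ne effective individuals per population (default 30000).
#' @param T_regional generations since the regional ancestors split from the
#'   common root (default 5000, i.e. recent postglacial regional structure).
#' @param T_pair generations since each S-N pair split (default 3000).
#' @param mu per-bp per-generation mutation rate (default 4.3e-8; recorded
#'   in the manifest).
#' @param r_bp recombination rate per bp per generation used for the
#'   hitchhiking footprint around planted loci (default 2e-6, giving a decay
#'   scale of a few kb, consistent with rapid genotypic LD decay).
#' @param L chromosome length in bp (default 1e6, single chromosome).
#' @param n_genes gene models to place (default 50).
#' @param gene_length_range min/max gene length in bp.
#' @param sites_poly_per_kb ancestral-polymorphic sites emitted per 1-kb
#'   window (default 36).
#' @param sites_inv_per_kb invariant sites emitted per window (default 62;
#'   the polymorphic:total ratio sets the analytic \eqn{\pi} target).
#' @param rho_regional Gaussian-copula correlation between each regional
#'   ancestor's frequency quantile and the shared root quantile (default
#'   0.985, which makes regions 2-3x more differentiated than the pairs
#'   within them — populations group by region, while S-N pairs remain the
#'   tightest units). Lower values separate the regional clusters more
#'   strongly; the copula preserves the stationary site-frequency spectrum
#'   exactly, unlike an equivalently deep mutation-free drift branch.
#' @param planted data.frame with one row per planted selected gene:
#'   columns `mode` ("STANDING", "IND", "MIG"), `s`, `g`, `t`, `m`,
#'   `pair1`, `pair2` (the quartet). NULL plants nothing.
#' @param dominance exponent of the dosage-response fitness map
#'   (1 = additive per dosage).
#' @param env_effect scales the substrate contrast of the soil variables
#'   (1 = default contrast: higher Mg, Ni, Co and lower Ca/Mg on
#'   serpentine; 0 = no contrast).
#' @param te_per_kb density of TE presence/absence variants (default 0.3).
#' @param mean_depth mean per-genotype read depth (Poisson; default 21).
#' @param seed mandatory integer seed; every draw flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 5L, n_per_pop = 8L, ploidy = 4L,
                       Ne = 30000, T_regional = 5000, T_pair = 3000,
                       mu = 4.3e-8, r_bp = 2e-6, L = 1e6, n_genes = 50L,
                       gene_length_range = c(2000L, 6000L),
                       sites_poly_per_kb = 36L, sites_inv_per_kb = 62L,
                       rho_regional = 0.985,
                       planted = NULL, dominance = 1, env_effect = 1,
                       te_per_kb = 0.3, mean_depth = 21, seed) {
  stopifnot(!missing(seed), T_pair < T_regional, n_pairs >= 1,
            mu > 0, mu < 1, r_bp > 0, r_bp < 1)
  if (!is.null(planted)) {
    stopifnot(all(c("mode", "s", "pair1", "pair2") %in% names(planted)),
              all(planted$mode %in% c("STANDING", "IND", "MIG")),
              all(planted$pair1 <= n_pairs), all(planted$pair2 <= n_pairs),
              all(planted$pair1 != planted$pair2))
  }
  structure(list(n_pairs = n_pairs, n_per_pop = n_per_pop, ploidy = ploidy,
                 Ne = Ne, T_regional = T_regional, T_pair = T_pair, mu = mu,
                 r_bp = r_bp, L = L, n_genes = n_genes,
                 gene_length_range = gene_length_range,
                 sites_poly_per_kb = sites_poly_per_kb,
                 sites_inv_per_kb = sites_inv_per_kb,
                 rho_regional = rho_regional,
                 planted = planted, dominance = dominance,
                 env_effect = env_effect, te_per_kb = te_per_kb,
                 mean_depth = mean_depth, seed = as.integer(seed)),
            class = "sim_config")
}

#' Analytic diversity target of the generator
#'
#' Expected per-site nucleotide diversity of the emitted data under the
#' generator's own initialization: ancestral frequencies \eqn{\propto 1/x}
#' on \eqn{[1/A, 1-1/A]} give mean heterozygosity
#' \eqn{(1-2/A)/\log((A-1)^2/1)} per polymorphic site, decayed by
#' the pair-branch drift decay \eqn{e^{-T_{pair}/A}} (the copula-based
#' regional level preserves the marginal exactly) and diluted by the
#' invariant-site fraction. The simulator's diversity check compares against this value,
#' so the check is self-consistent by construction.
#'
#' @param cfg a [sim_config()].
#' @return expected mean per-site \eqn{\pi}.
#' @export
analytic_pi <- function(cfg) {
  A <- cfg$ploidy * cfg$Ne
  x0 <- 1 / A
  h <- (1 - 2 * x0) / log((1 - x0) / x0)
  f_poly <- cfg$sites_poly_per_kb /
    (cfg$sites_poly_per_kb + cfg$sites_inv_per_kb)
  f_poly * h * exp(-cfg$T_pair / A)
}

# Balding-Nichols conditioned drift: one Beta draw with mean p and variance
# F p (1 - p), F = 1 - exp(-t / A). Exact for the coancestry accumulated on
# a branch; absorbing states preserved.
bn_drift <- function(p, t, A) {
  Fb <- 1 - exp(-t / A)
  if (Fb <= 0) return(p)
  k <- (1 - Fb) / Fb
  out <- p
  inner <- p > 0 & p < 1
  out[inner] <- stats::rbeta(sum(inner), p[inner] * k, (1 - p[inner]) * k)
  out
}

# deterministic one-generation selection update on allele frequency with
# dosage-response exponent `dom` (1 = additive genic selection)
sel_step <- function(p, s, ploidy, dom = 1) {
  if (dom == 1) return(p * (1 + s) / (1 + s * p))
  k <- 0:ploidy
  w <- 1 + s * (k / ploidy)^dom
  gk <- stats::dbinom(k, ploidy, p)
  sum(gk * w * k / ploidy) / sum(gk * w)
}

# per-generation selection + binomial drift trajectory over T generations;
# de-novo origin is resupplied at 1/A until established (recurrent
# mutation), and the trajectory is conditioned on ending above `est` when
# `condition` is TRUE (a planted sweep that drift happens to lose is a
# failed plant, not a study condition).
sweep_trajectory <- function(p0, s, T, A, ploidy, dom = 1, origin = FALSE,
                             condition = TRUE, est = 0.5, max_try = 25L) {
  for (i in seq_len(max_try)) {
    p <- p0
    for (gen in seq_len(T)) {
      if (origin && p == 0) p <- 1 / A
      p <- sel_step(p, s, ploidy, dom)
      p <- stats::rbinom(1, A, p) / A
    }
    if (!condition || p >= est) return(p)
  }
  warning("planted sweep failed to establish after ", max_try, " tries")
  p
}

# migration-coupled sweep: source sweeps from de novo origin; recipient
# receives migrants at rate m each generation, then selection + drift.
mig_trajectory <- function(s, m, T, A, ploidy, dom = 1, condition = TRUE,
                           est = 0.5, max_try = 25L) {
  for (i in seq_len(max_try)) {
    ps <- 0; pr <- 0
    for (gen in seq_len(T)) {
      if (ps == 0) ps <- 1 / A
      ps <- sel_step(ps, s, ploidy, dom)
      ps <- stats::rbinom(1, A, ps) / A
      pr <- (1 - m) * pr + m * ps
      if (pr > 0) pr <- sel_step(pr, s, ploidy, dom)
      pr <- stats::rbinom(1, A, pr) / A
    }
    if (!condition || (ps >= est && pr >= est)) return(c(src = ps, rec = pr))
  }
  warning("planted migration sweep failed to establish")
  c(src = ps, rec = pr)
}

#' Forward Wright-Fisher simulation of replicated population pairs
#'
#' Simulates allele frequencies down the population tree (common root ->
#' regional ancestors at `T_regional` -> S/N pair tips at `T_pair`),
#' samples tetraploid individuals, and emulates the study design:
#' planted selected genes per mode, substrate-shifted soil covariates with
#' pair-level random effects, and TE presence/absence variants (a TE is
#' placed inside each planted gene so the TE scan has true positives).
#' Neutral drift on each branch uses conditioned Beta (Balding-Nichols)
#' transitions — exactly the frequency covariance the downstream coancestry
#' model assumes — while planted loci evolve generation by generation with
#' a deterministic selection step before binomial drift. Around each
#' planted locus a deterministic hitchhiking adjustment moves linked-site
#' frequencies in the selected populations toward the swept haplotype
#' (shared between populations under STANDING/MIG, independent under IND)
#' with retention \eqn{y = e^{-r d \log(As)/s}}: this is what lets the
#' classifier see the mode of convergence. Distinct sites are otherwise
#' unlinked.
#'
#' @param cfg a [sim_config()].
#' @return list of class `wf_bundle`: `gm` (a [genotype_matrix()]), `genes`
#'   (gene models), `env` (soil covariate table), `te` (TE variants),
#'   `truth` (planted-gene truth table), `freqs` (population frequencies),
#'   `cfg`.
#' @export
simulate_wf_pairs <- function(cfg) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)
  A <- cfg$ploidy * cfg$Ne
  n_win <- as.integer(cfg$L %/% 1000)
  per_win <- cfg$sites_poly_per_kb + cfg$sites_inv_per_kb

  # site positions: fixed number per 1-kb window, polymorphic flag
  off <- unlist(lapply(seq_len(n_win), function(w)
    sort(sample.int(1000L, per_win)) + (w - 1L) * 1000L))
  is_poly <- unlist(lapply(seq_len(n_win), function(w) {
    f <- rep(FALSE, per_win)
    f[sample.int(per_win, cfg$sites_poly_per_kb)] <- TRUE
    f
  }))
  pos <- as.integer(off)

  # gene models: non-overlapping spans
  glen <- sample(seq(cfg$gene_length_range[1], cfg$gene_length_range[2]),
                 cfg$n_genes, replace = TRUE)
  slot <- floor(cfg$L / cfg$n_genes)
  gstart <- (seq_len(cfg$n_genes) - 1L) * slot +
    vapply(glen, function(l) sample.int(max(1L, slot - l - 200L), 1L), 0L)
  genes <- data.frame(gene_id = sprintf("gene_%03d", seq_len(cfg$n_genes)),
                      chrom = "chr1", start = as.integer(gstart),
                      end = as.integer(gstart + glen),
                      strand = sample(c("+", "-"), cfg$n_genes, TRUE),
                      stringsAsFactors = FALSE)
  class(genes) <- c("gene_models", "data.frame")

  # planted loci: assign genes spread along the chromosome, selected site at
  # the gene midpoint, emitted as an extra polymorphic site
  planted <- cfg$planted
  truth <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    gi <- round(seq(2, cfg$n_genes - 1, length.out = nrow(planted)))
    sel_pos <- as.integer(round((genes$start[gi] + genes$end[gi]) / 2))
    while (any(sel_pos %in% pos) || anyDuplicated(sel_pos))
      sel_pos[sel_pos %in% pos | duplicated(sel_pos)] <-
        sel_pos[sel_pos %in% pos | duplicated(sel_pos)] + 1L
    truth <- data.frame(gene = genes$gene_id[gi], mode = planted$mode,
                        s = planted$s,
                        g = if ("g" %in% names(planted)) planted$g else NA,
                        t = if ("t" %in% names(planted)) planted$t else NA,
                        m = if ("m" %in% names(planted)) planted$m else NA,
                        pair1 = planted$pair1, pair2 = planted$pair2,
                        sel_pos = sel_pos, stringsAsFactors = FALSE)
    ordp <- order(c(pos, sel_pos))
    is_poly <- c(is_poly, rep(TRUE, length(sel_pos)))[ordp]
    pos <- c(pos, sel_pos)[ordp]
  }
  n_sites <- length(pos)
  sel_idx <- if (!is.null(truth)) match(truth$sel_pos, pos) else integer(0)

  # ancestral frequencies: 1/x SFS for polymorphic sites (inverse-CDF of
  # the truncated 1/x density), 0 for invariant sites
  x0 <- 1 / A
  qstat <- function(u) x0 * ((1 - x0) / x0)^u
  u0 <- stats::runif(n_sites)
  p0 <- numeric(n_sites)
  p0[is_poly] <- qstat(u0[is_poly])
  p0[sel_idx] <- 0   # planted alleles handled per mode below

  pops <- as.vector(t(outer(c("S", "N"), seq_len(cfg$n_pairs), paste0)))
  # regional ancestors: a Gaussian copula on the stationary 1/x marginal —
  # each region's quantile is correlated (rho_regional) with the shared
  # root quantile. This makes the regional clusters the dominant genetic
  # structure (the study's populations group by region, not substrate)
  # while preserving the stationary site-frequency spectrum exactly and
  # keeping cross-region contrasts continuous and unimodal; an equivalently
  # deep mutation-free drift branch would deplete rare variants and push
  # Tajima's D out of its realistic range.
  z0 <- stats::qnorm(u0)
  rho <- cfg$rho_regional
  can_vary <- is_poly
  can_vary[sel_idx] <- FALSE
  p_reg <- lapply(seq_len(cfg$n_pairs), function(k) {
    zk <- rho * z0 + sqrt(1 - rho^2) * stats::rnorm(n_sites)
    pk <- p0
    pk[can_vary] <- qstat(stats::pnorm(zk[can_vary]))
    pk
  })
  p_tip <- list()
  for (k in seq_len(cfg$n_pairs)) {
    p_tip[[paste0("S", k)]] <- bn_drift(p_reg[[k]], cfg$T_pair, A)
    p_tip[[paste0("N", k)]] <- bn_drift(p_reg[[k]], cfg$T_pair, A)
  }

  # planted selection trajectories + hitchhiking adjustment
  if (!is.null(truth)) {
    tau_of <- function(s) log(A * s) / s
    for (r in seq_len(nrow(truth))) {
      md <- truth$mode[r]; s <- truth$s[r]; j <- sel_idx[r]
      sp <- c(truth$pair1[r], truth$pair2[r])
      spops <- paste0("S", sp)
      qb <- numeric(2); names(qb) <- spops
      if (md == "STANDING") {
        for (i in 1:2) {
          # the pair's regional ancestor holds the standing allele; its S
          # member sweeps from it, its N member drifts neutrally from it.
          # The standing phase and the sweep are conditioned jointly on
          # establishment: a standing allele that drift loses before
          # selection begins is not the planted condition.
          for (try in 1:200) {
            stand <- bn_drift(truth$g[r], truth$t[r], A)
            qb[i] <- sweep_trajectory(stand, s, cfg$T_pair, A, cfg$ploidy,
                                      cfg$dominance, condition = FALSE)
            if (qb[i] >= 0.5) break
          }
          if (qb[i] < 0.5)
            warning("planted standing sweep failed to establish")
          p_tip[[paste0("N", sp[i])]][j] <- bn_drift(stand, cfg$T_pair, A)
        }
      } else if (md == "IND") {
        for (i in 1:2)
          qb[i] <- sweep_trajectory(0, s, cfg$T_pair, A, cfg$ploidy,
                                    cfg$dominance, origin = TRUE)
      } else { # MIG
        pv <- mig_trajectory(s, truth$m[r], cfg$T_pair, A, cfg$ploidy,
                             cfg$dominance)
        qb[1] <- pv["src"]; qb[2] <- pv["rec"]
      }
      for (i in 1:2) p_tip[[spops[i]]][j] <- qb[i]

      # hitchhiking: deterministic pull toward the swept haplotype, with
      # haplotype sharing between the two selected populations governed by
      # the same standing-phase / migration competing-exponential
      # probabilities the coancestry model assumes: at a site d bp away the
      # haplotypes are identical by descent with probability P_share(d)
      # (certain for neither IND nor at large d, where recombination during
      # the standing phase decouples them)
      d <- abs(pos - truth$sel_pos[r])
      y <- exp(-cfg$r_bp * d * tau_of(s))
      near <- which(y > 1e-3 & seq_len(n_sites) != j & is_poly)
      if (length(near)) {
        share_p <- if (md == "STANDING") {
          delta <- 1 / (A * truth$g[r])
          rho <- cfg$r_bp * d[near]
          lam <- delta + 2 * rho
          (delta / lam) * (1 - exp(-lam * truth$t[r]))
        } else if (md == "MIG") {
          1 / (1 + 2 * A * truth$m[r] * cfg$r_bp * d[near])
        } else rep(0, length(near))
        shared <- stats::runif(length(near)) < share_p
        b_shared <- stats::rbinom(length(near), 1, p0[near])
        for (i in 1:2) {
          pn <- p_tip[[spops[i]]][near]
          b_own <- stats::rbinom(length(near), 1, pn)
          b <- ifelse(shared, b_shared, b_own)
          w <- y[near] * qb[i]
          p_tip[[spops[i]]][near] <- (1 - w) * pn + w * b
        }
      }
    }
  }

  # sample tetraploid individuals and depths
  inds <- unlist(lapply(pops, function(p)
    sprintf("%s_i%02d", p, seq_len(cfg$n_per_pop))))
  pop_of <- stats::setNames(rep(pops, each = cfg$n_per_pop), inds)
  dosage <- matrix(NA_integer_, length(inds), n_sites,
                   dimnames = list(inds, NULL))
  for (p in pops) {
    rows <- which(pop_of == p)
    dosage[rows, ] <- matrix(
      stats::rbinom(length(rows) * n_sites, cfg$ploidy,
                    rep(p_tip[[p]], each = length(rows))),
      length(rows), n_sites)
  }
  depth <- matrix(stats::rpois(length(dosage), cfg$mean_depth),
                  nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_sites, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  sites <- data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
  gm <- genotype_matrix(dosage, sites, pop_of, cfg$ploidy, depth = depth)

  # soil covariates: substrate contrast, pair random effect, individual noise
  env_mean <- list(CaMg = c(S = 0.4, N = 3.0), Mg = c(S = 3000, N = 800),
                   Ni = c(S = 90, N = 12), Co = c(S = 25, N = 6))
  env_cv <- c(CaMg = 0.20, Mg = 0.15, Ni = 0.25, Co = 0.25)
  env <- data.frame(individual = inds,
                    pair = as.integer(sub("^[SN]", "", pop_of)),
                    substrate = substr(pop_of, 1, 1),
                    stringsAsFactors = FALSE)
  for (v in names(env_mean)) {
    mid <- mean(env_mean[[v]])
    mS <- mid + cfg$env_effect * (env_mean[[v]]["S"] - mid)
    mN <- mid + cfg$env_effect * (env_mean[[v]]["N"] - mid)
    base <- ifelse(env$substrate == "S", mS, mN)
    # one random effect per locality pair, shared by its S and N members
    # (so the substrate contrast is not confounded with locality noise)
    pair_re <- stats::rnorm(cfg$n_pairs, 0, env_cv[v] * mid / 2)
    val <- base + pair_re[env$pair] +
      stats::rnorm(length(inds), 0, env_cv[v] * mid)
    env[[v]] <- pmax(val, 0.01 * mid)
  }

  # TE presence/absence variants; one TE inside each planted gene
  n_te <- max(1L, round(cfg$te_per_kb * cfg$L / 1000))
  te_pos <- sort(sample.int(cfg$L, n_te))
  if (!is.null(truth))
    te_pos <- sort(c(te_pos, truth$sel_pos + 150L))
  te <- data.frame(chrom = "chr1", pos = as.integer(te_pos),
                   kind = sample(c("insertion", "deletion"),
                                 length(te_pos), TRUE),
                   stringsAsFactors = FALSE)
  te_freq <- stats::rbeta(nrow(te), 0.8, 0.8)
  pres <- matrix(stats::rbinom(nrow(te) * length(inds), 1,
                               rep(te_freq, length(inds))),
                 nrow(te), length(inds), dimnames = list(NULL, inds))
  te <- cbind(te, as.data.frame(pres))
  class(te) <- c("te_variants", "data.frame")

  structure(list(gm = gm, genes = genes, env = env, te = te, truth = truth,
                 freqs = p_tip, pops = pops, cfg = cfg),
            class = "wf_bundle")
}

#' @export
print.wf_bundle <- function(x, ...) {
  cat(sprintf("wf_bundle: %d pairs, %d individuals, %d sites, %d genes\n",
              x$cfg$n_pairs, nrow(x$gm$dosage), ncol(x$gm$dosage),
              nrow(x$genes)))
  if (!is.null(x$truth))
    cat(sprintf("  planted: %s\n",
                paste(sprintf("%s(%s)", x$truth$gene, x$truth$mode),
                      collapse = " ")))
  invisible(x)
}

gt_string <- function(dosage, ploidy) {
  lut <- vapply(0:ploidy, function(k)
    paste(c(rep("0", ploidy - k), rep("1", k)), collapse = "/"), "")
  out <- lut[dosage + 1L]
  out[is.na(dosage)] <- paste(rep(".", ploidy), collapse = "/")
  out
}

#' Write a simulated bundle to standard file formats
#'
#' Emits the bundle as a ploidy-4 VCF (GT:DP), a GFF3 of gene models, soil
#' covariate / TE / truth TSVs, a population map, and a run-manifest JSON
#' recording the seed and configuration. Everything round-trips through
#' [read_tetraploid_vcf()] and [read_gene_models()].
#'
#' @param bundle a [simulate_wf_pairs()] result.
#' @param dir output directory (created if needed).
#' @return named list of file paths (class `fixture_paths`).
#' @export
write_fixture <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gm <- bundle$gm
  paths <- list(vcf = file.path(dir, "sim.vcf"),
                gff = file.path(dir, "genes.gff3"),
                env = file.path(dir, "env.tsv"),
                te = file.path(dir, "te.tsv"),
                truth = file.path(dir, "truth.tsv"),
                popmap = file.path(dir, "popmap.tsv"),
                manifest = file.path(dir, "manifest.json"))
  # VCF
  n_ind <- nrow(gm$dosage)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=chr1,length=%d>", as.integer(bundle$cfg$L)),
           "##source=serpens-wf-simulator",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$individuals), collapse = "\t"))
  cols <- lapply(seq_len(n_ind), function(i)
    paste0(gt_string(gm$dosage[i, ], gm$ploidy), ":", gm$depth[i, ]))
  body <- do.call(paste, c(list(gm$sites$chrom, gm$sites$pos, ".",
                                gm$sites$ref, gm$sites$alt, ".", ".", ".",
                                "GT:DP"), cols, sep = "\t"))
  writeLines(c(hdr, body), paths$vcf)
  # GFF3
  g <- bundle$genes
  writeLines(c("##gff-version 3",
               sprintf("%s\tserpens_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)),
             paths$gff)
  utils::write.table(bundle$env, paths$env, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$te, paths$te, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bundle$truth))
    utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  utils::write.table(data.frame(ind = gm$individuals, pop = gm$pop),
                     paths$popmap, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  cfgj <- bundle$cfg
  class(cfgj) <- NULL
  jsonlite::write_json(list(seed = bundle$cfg$seed, config = cfgj,
                            files = lapply(paths, basename)),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  structure(paths, class = "fixture_paths")
}

#' Emit a ready-made synthetic fixture
#'
#' Two canned study designs: `"tiny"` (one 200-kb chromosome, 10 genes, 2
#' population pairs, one STANDING and one IND planted gene) for fast
#' checks, and `"default"` (1 Mb, 50 genes, 5 pairs, 4 STANDING + 1 IND
#' planted genes — shared ancestral variation dominant with a single de
#' novo exception, echoing the study design).
#'
#' @param size `"tiny"` or `"default"`.
#' @param dir output directory; NULL returns the in-memory bundle only.
#' @param seed integer seed.
#' @param ... overrides passed to [sim_config()].
#' @return if `dir` is NULL the `wf_bundle`, else the file-path list with
#'   the bundle in attribute `bundle`.
#' @export
emit_fixture <- function(size = c("tiny", "default"), dir = NULL, seed = 1L,
                         ...) {
  size <- match.arg(size)
  base <- if (size == "tiny") {
    list(L = 2e5, n_genes = 10L, n_pairs = 2L,
         planted = data.frame(mode = c("STANDING", "IND"),
                              s = 0.1, g = c(0.001, NA), t = c(500, NA),
                              m = NA, pair1 = 1L, pair2 = 2L))
  } else {
    list(L = 1e6, n_genes = 50L, n_pairs = 5L,
         planted = data.frame(
           mode = c("STANDING", "STANDING", "STANDING", "STANDING", "IND"),
           s = 0.1, g = c(0.001, 0.001, 0.001, 0.001, NA),
           t = c(500, 500, 500, 500, NA), m = NA,
           pair1 = c(1L, 2L, 3L, 4L, 1L), pair2 = c(2L, 3L, 4L, 5L, 3L)))
  }
  args <- utils::modifyList(c(base, list(seed = seed)), list(...))
  cfg <- do.call(sim_config, args)
  bundle <- simulate_wf_pairs(cfg)
  if (is.null(dir)) return(bundle)
  paths <- write_fixture(bundle, dir)
  attr(paths, "bundle") <- bundle
  paths
}
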