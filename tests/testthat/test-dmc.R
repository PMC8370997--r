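test_that("sweep retention follows the closed form", {
  expect_equal(sweep_retention(0, 0.05), 1)
  expect_lt(sweep_retention(1e9, 0.05), 1e-12)
  # r=1e-8, d=1e4, s=0.05, Ne=30000, ploidy 4 -> tau ~ 173.99, y ~ 0.98275
  expect_equal(sweep_retention(1e4, 0.05, r_bp = 1e-8),
               exp(-1e-8 * 1e4 * log(120000 * 0.05) / 0.05))
  expect_equal(sweep_retention(1e4, 0.05, r_bp = 1e-8), 0.98275,
               tolerance = 1e-4)
  expect_error(sweep_retention(100, 1e-6), "invalid")
  expect_error(scenario_params("IND", s = 1e-6), "invalid")
})

test_that("scenario constructors: neutral limit, IND off-diagonals, standing limit", {
  F0 <- make_F0()
  # far from the site every scenario collapses to F0
  for (sc in c("IND", "STANDING", "MIG")) {
    par <- scenario_params(sc, s = 0.05, g = 0.01, t = 500, m = 1e-3,
                           src = 1, selected = c(1, 3))
    Fp <- scenario_coancestry(F0, 5e9, par)
    expect_lt(max(abs(Fp - F0$F)), 1e-8)
  }
  # IND leaves every off-diagonal untouched
  par_ind <- scenario_params("IND", s = 0.05, selected = c(1, 3))
  Fi <- scenario_coancestry(F0, 1000, par_ind)
  off <- row(Fi) != col(Fi)
  expect_equal(Fi[off], F0$F[off])
  expect_gt(Fi[1, 1], F0$F[1, 1])
  expect_equal(Fi[2, 2], F0$F[2, 2])

  # single shared origin: coalescence certain (tiny g, finite t) drives the
  # cross-population selected entry to y^2 + (1 - y^2) F0_ij
  par_st <- scenario_params("STANDING", s = 0.05, g = 1e-6, t = 50,
                            selected = c(1, 3))
  d <- 100
  y2 <- sweep_retention(d, 0.05)^2
  Fs <- scenario_coancestry(F0, d, par_st)
  expect_equal(Fs[1, 3], y2 * 1 + (1 - y2) * F0$F[1, 3], tolerance = 5e-3)
})

test_that("IND never raises cross-population entries; STANDING and MIG do", {
  F0 <- make_F0()
  d <- 500
  par_ind <- scenario_params("IND", s = 0.05, selected = c(1, 3))
  par_st <- scenario_params("STANDING", s = 0.05, g = 0.001, t = 500,
                            selected = c(1, 3))
  par_mig <- scenario_params("MIG", s = 0.05, m = 1e-3, src = 1,
                             selected = c(1, 3))
  expect_equal(scenario_coancestry(F0, d, par_ind)[1, 3], F0$F[1, 3])
  expect_gt(scenario_coancestry(F0, d, par_st)[1, 3], F0$F[1, 3])
  expect_gt(scenario_coancestry(F0, d, par_mig)[1, 3], F0$F[1, 3])
})

test_that("sampling-corrected scenario covariances are PSD across the grid", {
  F0 <- make_F0()
  grid <- dmc_grid()
  worst <- Inf
  for (sc in c("IND", "STANDING", "MIG"))
    for (par in serpens:::expand_scenario_grid(sc, grid, c(1L, 3L),
                                               2e-8, 30000, 4))
      for (d in c(0, 100, 1000, 10000, 25000)) {
        Fp <- serpens:::scenario_Fprime_entries(F0$F, d, par)[1, ]
        C <- matrix(Fp, 4, 4)
        diag(C) <- diag(C) + pmax(1 - diag(C), 0.5) / 32
        worst <- min(worst, eigen((C + t(C)) / 2, symmetric = TRUE,
                                  only.values = TRUE)$values)
      }
  expect_gt(worst, -1e-8)
})

test_that("composite likelihood equals an independently coded MVN oracle", {
  F0 <- make_F0()
  par <- scenario_params("STANDING", s = 0.05, g = 0.01, t = 500,
                         selected = c(1, 3))
  af <- simulate_mvn_freqs(F0, par, sel_pos = 50000, n_snps = 80,
                           window = 30000, seed = 77)
  gene <- list(gene_id = "g", chrom = "sim1", start = 48000, end = 52000)
  one_grid <- dmc_grid(s = 0.05, g = 0.01, t = 500, m = 1e-3)
  fit <- composite_loglik(af, gene, F0, "STANDING", c(1, 3), grid = one_grid,
                          n_sites = 4)

  # oracle: direct dense linear algebra with a different mean-free basis
  oracle <- function(sel_pos) {
    x <- af$freq; a <- af$sampled; posn <- af$sites$pos
    eps <- colMeans(x)
    ok <- eps >= 0.05 & eps <= 0.95
    x <- x[, ok]; a <- a[, ok]; posn <- posn[ok]; eps <- eps[ok]
    H <- contr.helmert(4)
    B <- t(H) / sqrt(colSums(H^2))          # 3 x 4 orthonormal, mean-free
    ll <- 0
    for (k in seq_along(posn)) {
      Fp <- matrix(serpens:::scenario_Fprime_entries(
        F0$F, abs(posn[k] - sel_pos), par)[1, ], 4, 4)
      C <- Fp
      diag(C) <- diag(C) + pmax(1 - diag(C), 0.5) / a[, k]
      Sig <- eps[k] * (1 - eps[k]) * (B %*% C %*% t(B))
      z <- B %*% (x[, k] - eps[k])
      ll <- ll - 0.5 * (3 * log(2 * pi) + determinant(Sig)$modulus +
                          drop(t(z) %*% solve(Sig, z)))
    }
    as.numeric(ll)
  }
  prop <- seq(gene$start + 1, gene$end, length.out = 4)
  expect_equal(fit$mcl, max(vapply(prop, oracle, 0)), tolerance = 1e-6)
  expect_equal(fit$profile$cll, vapply(prop, oracle, 0), tolerance = 1e-6)
})

test_that("composite likelihood is invariant to SNP order and grows with grid refinement", {
  F0 <- make_F0()
  par <- scenario_params("NEUTRAL")
  af <- simulate_mvn_freqs(F0, par, sel_pos = 50000, n_snps = 60, seed = 9)
  gene <- list(gene_id = "g", chrom = "sim1", start = 48000, end = 52000)
  fit1 <- composite_loglik(af, gene, F0, "IND", c(1, 3))
  perm <- sample(ncol(af$freq))
  af2 <- subset_af(af, perm)
  # restore sorted site order, as the container requires
  af2 <- subset_af(af2, order(af2$sites$pos))
  fit2 <- composite_loglik(af2, gene, F0, "IND", c(1, 3))
  expect_equal(fit1$mcl, fit2$mcl, tolerance = 1e-9)

  coarse <- dmc_grid(s = c(0.01, 0.1), g = 0.01, t = 500, m = 1e-3)
  fine <- dmc_grid(s = c(0.001, 0.01, 0.05, 0.1, 0.5), g = 0.01, t = 500,
                   m = 1e-3)
  f_c <- composite_loglik(af, gene, F0, "IND", c(1, 3), grid = coarse)
  f_f <- composite_loglik(af, gene, F0, "IND", c(1, 3), grid = fine)
  expect_gte(f_f$mcl, f_c$mcl)

  # underpowered flag on tiny windows
  af_small <- subset_af(af, 1:5)
  expect_warning(
    fit_s <- composite_loglik(af_small, gene, F0, "NEUTRAL", integer(0)),
    "underpowered")
  expect_true(fit_s$underpowered)
})

test_that("decision rules: thresholds, margins, and error paths", {
  # delta_S below the neutral threshold
  expect_equal(classify_case(15, 0, "STANDING")$classification, "neutral")
  # delta_S = 30, delta_N = 29 -> 30 <= 1.1 * 29 -> excluded as ambiguous
  cl <- classify_case(30, 29, "STANDING")
  expect_equal(cl$classification, "ambiguous")
  expect_equal(cl$source, "excluded")
  # clear serpentine advantage -> the argmax scenario, with collapsing
  expect_equal(classify_case(100, 20, "STANDING")$source, "shared_origin")
  expect_equal(classify_case(100, 20, "MIG")$source, "shared_origin")
  expect_equal(classify_case(100, 20, "IND")$source, "de_novo")
  # negative delta_N counts as zero in the margin rule
  expect_equal(classify_case(25, -50, "IND")$classification, "de_novo")
  expect_error(classify_case(30, NULL, "IND"), "delta_n")
})

test_that("classification is invariant to relabeling the two pairs of a quartet", {
  F0 <- make_F0()
  par <- scenario_params("STANDING", s = 0.05, g = 0.005, t = 500,
                         selected = c(1, 3))
  af <- simulate_mvn_freqs(F0, par, sel_pos = 50000, n_snps = 120, seed = 13)
  gene <- list(gene_id = "g", chrom = "sim1", start = 48000, end = 52000)
  cs1 <- dmc_case(af, gene, F0$pops, F0)

  swap <- c(3, 4, 1, 2)   # (S2, N2, S1, N1)
  F0s <- F0
  F0s$F <- F0$F[swap, swap]
  F0s$a <- F0$a[swap]
  F0s$pops <- F0$pops[swap]
  af_s <- af
  af_s$freq <- af$freq[swap, ]; af_s$alt <- af$alt[swap, ]
  af_s$sampled <- af$sampled[swap, ]
  af_s$pops <- af$pops[swap]
  rownames(af_s$freq) <- rownames(af_s$alt) <- rownames(af_s$sampled) <-
    af_s$pops
  cs2 <- dmc_case(af_s, gene, F0s$pops, F0s)
  expect_equal(cs1$classification, cs2$classification)
  expect_equal(cs1$delta_s, cs2$delta_s, tolerance = 1e-8)
  expect_equal(cs1$delta_n, cs2$delta_n, tolerance = 1e-8)
})

test_that("MVN scenario recovery works case by case", {
  F0 <- make_F0()
  gene <- list(gene_id = "g", chrom = "sim1", start = 48000, end = 52000)
  mk <- function(kind, rngseed, ...) {
    par <- scenario_params(kind, ..., selected = c(1, 3))
    simulate_mvn_freqs(F0, par, sel_pos = 50000, n_snps = 150,
                       window = 50000, seed = rngseed)
  }
  n_ok <- 0L
  for (r in 1:6) {
    cs <- dmc_case(mk("STANDING", 800 + r, s = 0.05, g = 0.005, t = 500),
                   gene, F0$pops, F0)
    if (cs$source == "shared_origin") n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 5L)
  n_ok <- 0L
  for (r in 1:6) {
    cs <- dmc_case(mk("IND", 900 + r, s = 0.05), gene, F0$pops, F0)
    if (cs$source == "de_novo") n_ok <- n_ok + 1L
  }
  expect_gte(n_ok, 5L)
  cs_n <- dmc_case(mk("NEUTRAL", 950), gene, F0$pops, F0)
  expect_equal(cs_n$classification, "neutral")
})

test_that("source summaries count and collapse correctly", {
  mk_case <- function(gene, cls, src, ds = 50) {
    structure(list(gene = gene, quartet = c("S1", "N1", "S2", "N2"),
                   mcl_neutral = 0,
                   mcl_s = c(IND = 1, STANDING = 2, MIG = 3),
                   mcl_n = c(IND = 0, STANDING = 0, MIG = 0),
                   delta_s = ds, delta_n = 0, best_scenario_s = "STANDING",
                   classification = cls, source = src),
              class = "dmc_case")
  }
  cases <- c(lapply(1:28, function(i)
    mk_case(paste0("g", i), "standing", "shared_origin")),
    list(mk_case("g29", "de_novo", "de_novo")))
  s <- summarize_sources(cases)
  expect_equal(s$shared_origin_prop, 28 / 29)
  expect_equal(unname(s$counts[["standing"]]), 28L)
  all_neutral <- lapply(1:5, function(i)
    mk_case(paste0("g", i), "neutral", "none"))
  s2 <- summarize_sources(all_neutral)
  expect_true(is.na(s2$shared_origin_prop))
  expect_equal(unname(s2$counts[["neutral"]]), 5L)
})
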