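mk_windows <- function(fst, start = (seq_along(fst) - 1L) * 1000L,
                       n_snps = 15L, pair = c("S1", "N1")) {
  out <- data.frame(chrom = "chr1", start = start, end = start + 1000L,
                    n_snps = n_snps, fst = fst)
  attr(out, "pair") <- pair
  out
}

test_that("outlier windows honor the empirical quantile with ties", {
  set.seed(1)
  # 100 distinct values at q = 0.99 -> the single maximum
  w <- mk_windows(sample(seq(0, 0.99, 0.01)))
  ow <- outlier_windows(w, 0.99)
  expect_equal(nrow(ow), 1L)
  expect_equal(ow$fst, max(w$fst))

  # 200 windows with the top 3 tied -> all 3 returned
  fst <- c(runif(197, 0, 0.5), rep(0.9, 3))
  w2 <- mk_windows(fst)
  ow2 <- outlier_windows(w2, 0.99)
  expect_equal(nrow(ow2), 3L)
  expect_true(all(ow2$fst == 0.9))

  # lowering the quantile never shrinks the set
  ow97 <- outlier_windows(w2, 0.97)
  expect_true(all(paste(ow2$chrom, ow2$start) %in%
                    paste(ow97$chrom, ow97$start)))
  expect_gte(nrow(ow97), nrow(ow2))

  # fewer than 100 eligible windows -> warning, top-1
  w3 <- mk_windows(runif(50))
  expect_warning(ow3 <- outlier_windows(w3, 0.99), "top window")
  expect_equal(nrow(ow3), 1L)
})

test_that("gene-window overlap uses full gene spans (1 bp suffices)", {
  genes <- make_genes(start = c(500, 2500, 10000), end = c(1500, 3500, 12000))
  w <- data.frame(chrom = "chr1", start = c(1000L, 5000L), end = c(2000L, 6000L))
  # window 1000-2000 overlaps g01 (span 500-1500) by 500 bp; window
  # 5000-6000 is intergenic
  expect_equal(genes_for_windows(w, genes), "g01")
  # a window straddling two adjacent genes returns both
  w2 <- data.frame(chrom = "chr1", start = 1400L, end = 2600L)
  expect_equal(genes_for_windows(w2, genes), c("g01", "g02"))
  # empty window set
  expect_equal(genes_for_windows(w[0, ], genes), character(0))
})

test_that("parallel candidates require support from enough pairs", {
  sets <- list(
    list(pair = c("S1", "N1"), genes = c("g1", "g2", "g3")),
    list(pair = c("S2", "N2"), genes = c("g2", "g4")),
    list(pair = c("S3", "N3"), genes = c("g2", "g3")),
    list(pair = c("S4", "N4"), genes = c("g2")),
    list(pair = c("S5", "N5"), genes = c("g5")))
  pc <- parallel_candidates(sets, 2)
  expect_equal(pc$gene, c("g2", "g3"))
  expect_equal(pc$n_pairs, c(4L, 2L))
  # no gene in all five lists
  expect_equal(nrow(parallel_candidates(sets, 5)), 0L)
  # disjoint lists
  disj <- list(list(pair = "a", genes = "g1"), list(pair = "b", genes = "g2"))
  expect_equal(nrow(parallel_candidates(disj, 2)), 0L)
})

test_that("parallel_candidates(min_pairs = 2) equals the union of pairwise intersections", {
  set.seed(9)
  for (rep in 1:5) {
    sets <- lapply(1:4, function(k)
      list(pair = paste0("P", k),
           genes = sample(sprintf("g%02d", 1:40), sample(5:20, 1))))
    pc <- parallel_candidates(sets, 2)
    pw <- unique(unlist(lapply(utils::combn(4, 2, simplify = FALSE),
                               function(ij) intersect(sets[[ij[1]]]$genes,
                                                      sets[[ij[2]]]$genes))))
    expect_setequal(pc$gene, pw)
  }
})

test_that("two-list intersection p is the exact hypergeometric tail", {
  # N=20, |A|=|B|=5, k=4 -> (C(5,4)C(15,1)+C(5,5)C(15,0))/C(20,5)
  A <- paste0("g", 1:5); B <- paste0("g", c(1:4, 10))
  res <- multiset_intersection_test(list(A, B), 20)
  expect_equal(res$k, 4L)
  expect_equal(res$p_value, 76 / 15504, tolerance = 1e-12)
  expect_equal(res$expected, 20 * (5 / 20) * (5 / 20))
  # k = 0 -> p = 1 exactly
  res0 <- multiset_intersection_test(list(paste0("g", 1:5),
                                          paste0("h", 1:5)), 50)
  expect_identical(res0$p_value, 1)
  # universe smaller than a list is an error
  expect_error(multiset_intersection_test(list(A, B), 3), "universe")
})

test_that("two-list p equals exhaustive subset enumeration for small universes", {
  # fix A, enumerate every possible B of its size, count overlap >= k
  N <- 12; sa <- 4; sb <- 5
  A <- seq_len(sa)
  combs <- utils::combn(N, sb)
  for (k in 1:3) {
    exhaustive <- mean(apply(combs, 2, function(B) length(intersect(A, B)) >= k))
    obsA <- paste0("g", A)
    obsB <- paste0("g", c(seq_len(k), seq(sa + 1, sa + sb - k)))
    res <- multiset_intersection_test(list(obsA, paste0("g", c(seq_len(k),
                                      seq(sa + 1, sa + sb - k)))), N)
    expect_equal(res$k, k)
    expect_equal(res$p_value, exhaustive, tolerance = 1e-12)
  }
})

test_that("r-way intersection reports both the exact form and its Monte Carlo oracle", {
  set.seed(4)
  lists <- lapply(1:3, function(i) sample(sprintf("g%03d", 1:200), 60))
  res <- suppressWarnings(
    multiset_intersection_test(lists, 200, mc_reps = 20000, seed = 11))
  expect_false(is.na(res$p_mc))
  expect_equal(res$method, "product-form binomial + Monte Carlo")
  # the fixed-size permutation null and the independence-based exact tail
  # stay close in absolute terms; when they differ beyond 3 Monte Carlo
  # standard errors the function says so instead of silently preferring one
  expect_lt(abs(res$p_value - res$p_mc), 0.05)
  se <- sqrt(res$p_mc * (1 - res$p_mc) / 20000)
  if (abs(res$p_value - res$p_mc) > 3 * se)
    expect_warning(multiset_intersection_test(lists, 200, mc_reps = 20000,
                                              seed = 11),
                   "3 SE")
})

test_that("TE candidates use the restricted window universe and point flanks", {
  set.seed(6)
  # 30 windows of SNPs; windows 0,1,2 contain TEs; window 2 has high FST
  n_win <- 30; per <- 12
  pos <- unlist(lapply(0:(n_win - 1), function(w) w * 1000 + seq(50, 950, length.out = per)))
  p1 <- rep(0.4, length(pos)); p2 <- rep(0.42, length(pos))
  hot <- pos >= 2000 & pos < 3000
  p2[hot] <- 0.95
  af <- make_af(rbind(S1 = p1, N1 = p2), a = 32, pos = round(pos))
  te <- data.frame(chrom = "chr1", pos = c(500L, 1500L, 2400L),
                   kind = "insertion", stringsAsFactors = FALSE)
  genes <- make_genes(start = c(3500, 8000), end = c(4800, 9000))
  # gene g01 starts 1100 bp from the TE at 2400 -> within the 2 kb flank
  cs <- suppressWarnings(
    te_candidate_genes(te, af, genes, c("S1", "N1"), quantile = 0.6))
  expect_equal(cs$genes, "g01")
  expect_equal(cs$source, "TE")
  # with the flank shrunk below the gap, the gene is excluded
  cs2 <- suppressWarnings(
    te_candidate_genes(te, af, genes, c("S1", "N1"), quantile = 0.6,
                       flank_bp = 1000L))
  expect_equal(cs2$genes, character(0))
  # restricted-universe threshold differs from the genome-wide one
  st_all <- hudson_fst_windows(af, c("S1", "N1"))
  thr_all <- attr(outlier_windows(st_all, 0.6), "threshold")
  te_key <- unique((te$pos - 1) %/% 1000)
  st_te <- st_all[(st_all$start / 1000) %in% te_key, ]
  attr(st_te, "pair") <- c("S1", "N1")
  thr_te <- attr(suppressWarnings(outlier_windows(st_te, 0.6)), "threshold")
  expect_false(isTRUE(all.equal(thr_all, thr_te)))
})

test_that("serpentine candidates are the provenance-carrying intersection", {
  par <- data.frame(gene = c("g1", "g2", "g3"), n_pairs = c(3L, 2L, 2L),
                    pairs = c("a,b,c", "a,b", "b,c"),
                    stringsAsFactors = FALSE)
  gea <- data.frame(gene = c("g2", "g4"), n_snps = c(2L, 1L),
                    variables = c("Ni,Co", "Mg"), stringsAsFactors = FALSE)
  out <- serpentine_adaptation_candidates(par, gea)
  expect_equal(out$gene, "g2")
  expect_equal(out$variables, "Ni,Co")
  # disjoint inputs -> empty; identical inputs -> identity
  expect_equal(nrow(serpentine_adaptation_candidates(par, gea[2, ])), 0L)
  all_g <- serpentine_adaptation_candidates(
    par, data.frame(gene = par$gene, variables = "Ni"))
  expect_setequal(all_g$gene, par$gene)
})
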