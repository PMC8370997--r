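mk_struct_gm <- function(seed, n_g = 5, n_per = 12, S = 3000, drift_sd = 0.08,
                         true_idx = integer(0), env = NULL, beta = 0) {
  set.seed(seed)
  n <- n_g * n_per
  grp <- rep(seq_len(n_g), each = n_per)
  p0 <- runif(S, 0.1, 0.9)
  pg <- sapply(seq_len(n_g), function(g)
    pmin(0.99, pmax(0.01, p0 + rnorm(S, 0, drift_sd))))
  dos <- matrix(0L, n, S)
  for (i in seq_len(n)) dos[i, ] <- rbinom(S, 4, pg[, grp[i]])
  if (length(true_idx) && !is.null(env))
    for (j in true_idx) {
      shift <- plogis(qlogis(pg[j, grp]) + beta * env)
      dos[, j] <- rbinom(n, 4, shift)
    }
  rownames(dos) <- paste0("i", seq_len(n))
  make_gm(dos, setNames(paste0("P", grp), rownames(dos)))
}

test_that("association site filter keeps complete common sites only", {
  dos <- matrix(rep(c(0L, 4L), 5), 10, 4)   # freq 0.5, complete
  dos[1, 2] <- NA                            # one missing -> dropped
  dos[, 3] <- c(rep(0L, 9), 1L)              # MAF 0.025 -> dropped
  dos[, 4] <- rep(4L, 10)                    # fixed alternate -> MAF 0
  rownames(dos) <- paste0("i", 1:10)
  gm <- make_gm(dos, setNames(rep("P", 10), rownames(dos)))
  kept <- gea_site_filter(gm, 0.05)
  expect_equal(ncol(kept$dosage), 1L)
  expect_equal(kept$sites$pos, 100L)
  # nothing passes -> informative error with the filter census
  expect_error(gea_site_filter(subset_sites(gm, 2:4), 0.05), "filter")
})

test_that("latent factors: duplicate symmetry, nesting, group separation", {
  set.seed(21)
  half <- matrix(rbinom(10 * 400, 4, 0.4), 10, 400)
  dos <- rbind(half, half)   # two identical blocks
  rownames(dos) <- paste0("i", 1:20)
  gm <- gea_site_filter(make_gm(dos,
    setNames(rep("P", 20), rownames(dos))), 0.01)
  fac <- latent_factors(gm, 3)
  expect_equal(fac[1:10, ], fac[11:20, ], ignore_attr = TRUE,
               tolerance = 1e-8)

  gm5 <- gea_site_filter(mk_struct_gm(22), 0.02)
  f3 <- latent_factors(gm5, 3); f5 <- latent_factors(gm5, 5)
  expect_equal(f3, f5[, 1:3], tolerance = 1e-8)
  expect_error(latent_factors(gm5, nrow(gm5$dosage)), "smaller")

  # K = 5 scores separate the five groups: mean within-group distance is
  # well below mean between-group distance (positive silhouette-like gap)
  grp <- rep(1:5, each = 12)
  dd <- as.matrix(dist(f5))
  same <- outer(grp, grp, "==") & upper.tri(dd)
  diff <- outer(grp, grp, "!=") & upper.tri(dd)
  expect_lt(mean(dd[same]), mean(dd[diff]))
})

test_that("null associations are calibrated and affine-invariant", {
  gm <- mk_struct_gm(31, n_g = 1, n_per = 50, S = 6000, drift_sd = 0)
  gm <- gea_site_filter(gm, 0.05)
  env <- data.frame(individual = gm$individuals,
                    var = rnorm(nrow(gm$dosage)))
  a <- lfmm_associations(gm, env, "var", K = 0)
  expect_gt(mean(a$p < 0.05), 0.03)
  expect_lt(mean(a$p < 0.05), 0.07)
  expect_lt(abs(attr(a, "lambda_gc") - 1), 0.1)
  # affine rescaling of the variable leaves p untouched
  env$var2 <- 3 * env$var + 7
  a2 <- lfmm_associations(gm, env, "var2", K = 0)
  expect_equal(a$p, a2$p, tolerance = 1e-10)
  # constant variable is an error
  env$flat <- 1
  expect_error(lfmm_associations(gm, env, "flat", K = 0), "constant")
})

test_that("latent factors deflate structure-driven inflation by > 1.5x", {
  lam0 <- lam5 <- numeric(4)
  for (r in 1:4) {
    gm <- gea_site_filter(mk_struct_gm(40 + r), 0.05)
    grp <- as.integer(sub("P", "", gm$pop))
    env <- data.frame(individual = gm$individuals,
                      var = as.numeric(scale(grp)) + rnorm(length(grp), 0, 0.5))
    lam0[r] <- attr(lfmm_associations(gm, env, "var", K = 0), "lambda_gc")
    lam5[r] <- attr(lfmm_associations(gm, env, "var", K = 5), "lambda_gc")
  }
  expect_gt(mean(lam0) / mean(lam5), 1.5)
})

test_that("a strongly associated planted SNP is recovered at q < 0.05", {
  hits <- 0L
  for (r in 1:20) {
    set.seed(9600 + r)   # env stream decoupled from the genotype stream
    n <- 60
    env_v <- rnorm(n)
    gm <- mk_struct_gm(600 + r, n_g = 5, n_per = 12, S = 1500,
                       true_idx = 25L, env = env_v, beta = 3)
    gm <- gea_site_filter(gm, 0.05)
    env <- data.frame(individual = gm$individuals, var = env_v)
    a <- lfmm_associations(gm, env, "var", K = 5)
    j <- which(a$pos == 2500L)   # site index 25 at 100 bp spacing
    if (length(j) == 1 && a$q[j] < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("FDR among declared SNPs stays near nominal under confounding", {
  n_fp <- 0L; n_dec <- 0L
  for (r in 1:20) {
    set.seed(9700 + r)   # env stream decoupled from the genotype stream
    n_g <- 5; n_per <- 12
    grp <- rep(1:n_g, each = n_per)
    env_v <- as.numeric(scale(grp)) + rnorm(n_g * n_per, 0, 1)
    true_idx <- sample.int(4000, 10)
    gm <- mk_struct_gm(700 + r, S = 4000, true_idx = true_idx, env = env_v,
                       beta = 2.2)
    gm <- gea_site_filter(gm, 0.05)
    env <- data.frame(individual = gm$individuals, var = env_v)
    a <- lfmm_associations(gm, env, "var", K = 5)
    dec <- which(a$q < 0.05)
    n_dec <- n_dec + length(dec)
    n_fp <- n_fp + sum(!(a$pos[dec] %in% (true_idx * 100L)))
  }
  # pooled false-discovery proportion over the replicates
  expect_gt(n_dec, 0L)
  expect_lte(n_fp / n_dec, 2 * 0.05)
})

test_that("q-values are BH with conservative pi0 and monotone in p", {
  expect_equal(qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(qvalues(0.5), 0.5)
  set.seed(50)
  p <- runif(200)
  q <- qvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  expect_true(all(q <= 1))
  # Storey option never exceeds the conservative default
  expect_true(all(qvalues(p, pi0 = "storey") <= q + 1e-12))
  expect_error(qvalues(numeric(0)), "empty")
})

test_that("candidate genes require an in-span significant SNP for any variable", {
  genes <- make_genes(start = c(1000, 5000), end = c(2000, 6000))
  mk_assoc <- function(pos, q, variable) {
    out <- data.frame(chrom = "chr1", pos = pos, beta = 1, z = 1,
                      p = q, q = q, stringsAsFactors = FALSE)
    attr(out, "variable") <- variable
    out
  }
  # one SNP significant for Ni only, inside g01; one significant SNP 10 bp
  # outside g02's span; Mg has nothing
  assoc <- list(Ni = mk_assoc(c(1500L, 6010L), c(0.001, 0.004), "Ni"),
                Mg = mk_assoc(1500L, 0.9, "Mg"))
  out <- gea_candidate_genes(assoc, genes, 0.05)
  expect_equal(out$gene, "g01")
  expect_equal(out$variables, "Ni")
  # all q above the threshold -> empty
  none <- gea_candidate_genes(list(Ni = mk_assoc(1500L, 0.9, "Ni")), genes)
  expect_equal(nrow(none), 0L)
})
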