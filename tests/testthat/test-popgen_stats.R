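test_that("observed heterozygosity handles saturated and hand cases", {
  expect_equal(observed_heterozygosity(toy_gm(matrix(1L, 4, 3)))$ho, 1)
  expect_equal(observed_heterozygosity(toy_gm(cbind(c(0L, 2L, 0L))))$ho, 0)
  expect_equal(observed_heterozygosity(toy_gm(cbind(c(0L, 1L, NA))))$ho, 0.5)
  # a locus with zero calls in a population is excluded from the mean
  gm <- toy_gm(cbind(c(1L, 1L), c(NA, NA)))
  expect_equal(observed_heterozygosity(gm)$ho, 1)
})

test_that("gene diversity follows the Nei-Chesser unbiased estimator", {
  # monomorphic locus
  expect_equal(gene_diversity_hs(toy_gm(matrix(0L, 5, 1)))$hs[1], 0)
  # n = 2, genotypes {0, 1}: p = 0.25, Ho = 0.5
  # Hs = 2 * (1 - 0.0625 - 0.5625 - 0.125) = 0.5
  expect_equal(gene_diversity_hs(toy_gm(cbind(c(0L, 1L))))$hs[1], 0.5)
  # loci with n < 2 are skipped
  gm <- toy_gm(cbind(c(0L, 1L), c(1L, NA)))
  expect_equal(gene_diversity_hs(gm)$hs[1], 0.5)
})

test_that("gene diversity converges to 2p(1-p) in large panmictic samples", {
  set.seed(41)
  p <- 0.3
  g <- matrix(rbinom(4000 * 5, 2, p), 4000, 5)
  hs <- gene_diversity_hs(toy_gm(g))$hs[1]
  expect_lt(abs(hs - 2 * p * (1 - p)), 0.01)
})

test_that("Hs exceeds Ho on average under population structure (Wahlund)", {
  sim <- simulate_structured_population(K = 3, F = 0.3, n_per_pop = 30,
                                        n_loci = 500, admixture_alpha = 0,
                                        missing_rate = 0, seed = 42)
  div <- diversity_table(sim$genotypes, sim$popmap)
  tot <- div[div$pop == "Total", ]
  expect_gt(tot$hs, tot$ho)
})

test_that("Fst shows no differentiation for identical populations, 1 when fixed", {
  # duplicating one sample into two "populations" leaves no between-
  # population signal: theta is non-positive (the unbiased estimator's
  # finite-sample correction makes it slightly negative, never positive)
  # and matches the direct formula exactly
  tab <- matrix(rep(c(0L, 1L, 2L, 1L), 5), nrow = 4)
  gm <- toy_gm(rbind(tab, tab))
  pm <- toy_popmap(gm, rep(c("P1", "P2"), each = 4))
  th <- pairwise_fst(gm, pm, n_boot = 0)$pairs$theta
  expect_lte(th, 0)
  expect_equal(th, wc_theta_direct(list(tab, tab)), tolerance = 1e-12)
  # and the estimator is centred on zero under true panmixia
  set.seed(40)
  null_th <- replicate(40, {
    g <- matrix(rbinom(20 * 80, 2, rep(runif(80, 0.1, 0.9), each = 20)),
                20, 80)
    gmn <- toy_gm(g)
    pairwise_fst(gmn, toy_popmap(gmn, rep(c("A", "B"), each = 10)),
                 n_boot = 0)$pairs$theta
  })
  expect_lt(abs(mean(null_th)), 0.01)
  gm2 <- toy_gm(rbind(matrix(0L, 5, 20), matrix(2L, 5, 20)))
  pm2 <- toy_popmap(gm2, rep(c("P1", "P2"), each = 5))
  expect_equal(pairwise_fst(gm2, pm2, n_boot = 0)$pairs$theta, 1)
})

test_that("theta equals direct Weir-Cockerham formula evaluation", {
  set.seed(43)
  pops <- list(matrix(sample(0:2, 6 * 12, TRUE), 6),
               matrix(sample(0:2, 5 * 12, TRUE), 5),
               matrix(sample(0:2, 7 * 12, TRUE), 7))
  pops[[2]][sample(60, 6)] <- NA
  # pairwise: compare each pair against the 2-population direct formula
  gm <- toy_gm(do.call(rbind, pops))
  pm <- toy_popmap(gm, rep(c("A", "B", "C"), times = c(6, 5, 7)))
  fst <- pairwise_fst(gm, pm, n_boot = 0)
  combos <- list(c("A", "B"), c("A", "C"), c("B", "C"))
  idx <- list(1:2, c(1, 3), 2:3)
  for (k in 1:3) {
    direct <- wc_theta_direct(pops[idx[[k]]])
    expect_equal(fst$theta[combos[[k]][1], combos[[k]][2]], direct,
                 tolerance = 1e-12)
  }
})

test_that("theta is invariant to population label swapping", {
  set.seed(44)
  gm <- random_gm(24, 60, missing = 0.1)
  pm <- toy_popmap(gm, rep(c("X", "Y"), each = 12))
  pm_swapped <- pm
  pm_swapped$pop <- ifelse(pm$pop == "X", "Y", "X")
  t1 <- pairwise_fst(gm, pm, n_boot = 0)$pairs$theta
  t2 <- pairwise_fst(gm, pm_swapped, n_boot = 0)$pairs$theta
  expect_equal(t1, t2)
})

test_that("theta increases with simulated divergence", {
  means <- vapply(c(0.02, 0.1, 0.25), function(f) {
    sim <- simulate_structured_population(K = 2, F = f, n_per_pop = 40,
                                          n_loci = 600,
                                          admixture_alpha = 0,
                                          missing_rate = 0, seed = 45)
    pairwise_fst(sim$genotypes, sim$popmap, n_boot = 0)$pairs$theta
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("AMOVA SSDs match hand-computed values on a tiny example", {
  # 6 individuals, 2 loci, no missing data: delta2 = squared Euclidean
  d <- rbind(c(0, 0), c(0, 1), c(1, 0),
             c(2, 2), c(2, 1), c(1, 2))
  gm <- toy_gm(matrix(as.integer(d), 6, 2))
  pm <- toy_popmap(gm, rep(c("G1", "G2"), each = 3))
  D2 <- as.matrix(dist(d))^2
  ssd_total <- sum(D2[lower.tri(D2)]) / 6
  ssd_within <- sum(D2[1:3, 1:3][lower.tri(D2[1:3, 1:3])]) / 3 +
    sum(D2[4:6, 4:6][lower.tri(D2[4:6, 4:6])]) / 3
  am <- amova(gm, pm, n_permutations = 99, seed = 1)
  expect_equal(am$SSD_total, ssd_total, tolerance = 1e-12)
  expect_equal(am$SSD_within, ssd_within, tolerance = 1e-12)
  expect_equal(am$SSD_among, ssd_total - ssd_within, tolerance = 1e-12)
  expect_equal(am$df_among, 1L)
  expect_equal(am$df_within, 4L)
})

test_that("AMOVA SSD additivity and permutation p-value bounds hold", {
  set.seed(46)
  gm <- random_gm(18, 50, missing = 0.15)
  pm <- toy_popmap(gm, rep(c("A", "B", "C"), each = 6))
  am <- amova(gm, pm, n_permutations = 199, seed = 9)
  expect_lt(abs(am$SSD_total - (am$SSD_among + am$SSD_within)) /
              am$SSD_total, 1e-8)
  expect_true(am$p_value > 0 && am$p_value <= 1)
  expect_lte(am$percent_among, 100)
  # label-permutation invariance of Phi_ST
  relab <- pm
  relab$pop <- c(A = "C", B = "A", C = "B")[pm$pop]
  am2 <- amova(gm, relab, n_permutations = 0, seed = 9)
  expect_equal(am2$phi_st, am$phi_st, tolerance = 1e-12)
})

test_that("duplicated individuals in maximally distinct groups give ~100%", {
  base <- rbind(matrix(0L, 4, 30), matrix(2L, 4, 30))
  gm <- toy_gm(base)
  pm <- toy_popmap(gm, rep(c("G1", "G2"), each = 4))
  am <- amova(gm, pm, n_permutations = 0)
  expect_equal(am$percent_among, 100)
})

test_that("AMOVA under panmixia gives near-zero variance and calibrated p", {
  set.seed(47)
  pvals <- replicate(20, {
    gm <- random_gm(20, 40, missing = 0)
    pm <- toy_popmap(gm, rep(c("A", "B"), each = 10))
    amova(gm, pm, n_permutations = 99, seed = sample.int(1e6, 1))$p_value
  })
  # p-values roughly uniform: mean near 0.5, spread across the range
  expect_gt(mean(pvals), 0.25)
  expect_lt(mean(pvals), 0.75)
  expect_gt(max(pvals) - min(pvals), 0.3)
})

test_that("PCA separates structured groups and conserves variance", {
  sim <- simulate_structured_population(K = 2, F = 0.3, n_per_pop = 25,
                                        n_loci = 300, admixture_alpha = 0,
                                        missing_rate = 0.05, seed = 48)
  pc <- pca_genotypes(sim$genotypes, n_components = 5)
  expect_equal(sum(pc$percent_variance), 100, tolerance = 1e-8)
  expect_true(all(diff(pc$percent_variance) <= 1e-8))
  grp <- sim$popmap$pop[match(rownames(pc$scores), sim$popmap$accession)]
  centers <- tapply(pc$scores[, 1], grp, mean)
  spread <- tapply(pc$scores[, 1], grp, sd)
  expect_gt(abs(diff(centers)), 2 * max(spread))
  expect_gt(pc$percent_variance[1], pc$percent_variance[2])
})

test_that("PCA scores match the covariance eigendecomposition", {
  set.seed(49)
  gm <- random_gm(10, 15, missing = 0.1)
  pc <- pca_genotypes(gm, n_components = 3)
  X <- gm$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- mu[j]
  X <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(crossprod(X))
  pct <- 100 * ev$values / sum(ev$values)
  expect_equal(pc$percent_variance[1:3], pct[1:3], tolerance = 1e-8)
  for (k in 1:3) {
    expect_equal(as.numeric(abs(cor(pc$scores[, k], X %*% ev$vectors[, k]))),
                 1, tolerance = 1e-8)
  }
  expect_error(pca_genotypes(toy_gm(matrix(1L, 4, 3))), "zero-variance")
})

test_that("haversine geography behaves analytically", {
  co <- data.frame(lat = c(0, 0), lon = c(0, 180))
  expect_equal(geo_distance_km(co)[1, 2], pi * 6371, tolerance = 1e-6)
})

test_that("Mantel recovers perfect and absent association", {
  set.seed(50)
  co <- data.frame(lat = runif(12, -10, 0), lon = runif(12, -80, -70))
  geo <- geo_distance_km(co)
  res <- mantel_ibd(geo, co, n_permutations = 199, seed = 2)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_lt(res$p_value, 0.05)
  # independent random matrix: r near 0, p not extreme
  rnd <- matrix(runif(144), 12)
  rnd <- (rnd + t(rnd)) / 2
  diag(rnd) <- 0
  res2 <- mantel_ibd(rnd, co, n_permutations = 199, seed = 3)
  expect_lt(abs(res2$r), 0.5)
  expect_error(mantel_ibd(geo[1:2, 1:2], co[1:2, ]), "at least 3")
})

test_that("Mantel statistic agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(51)
  gm <- random_gm(10, 40, missing = 0.05)
  co <- data.frame(lat = runif(10, -10, 0), lon = runif(10, -80, -70))
  gd <- allele_sharing_distance(gm)
  ours <- mantel_ibd(gd, co, n_permutations = 99, seed = 1)
  ref <- vegan::mantel(as.dist(gd), as.dist(geo_distance_km(co)),
                       permutations = 99)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-10)
})
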