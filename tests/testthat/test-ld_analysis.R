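test_that("EM haplotype frequencies solve phase-unambiguous cases exactly", {
  h <- em_haplotype_freqs(c(0, 2, 0, 2), c(0, 2, 0, 2))
  expect_equal(as.numeric(h), c(0.5, 0, 0, 0.5), tolerance = 1e-9)
  # perfect repulsion without heterozygotes
  h2 <- em_haplotype_freqs(c(0, 0, 2, 2), c(2, 2, 0, 0))
  expect_equal(as.numeric(h2), c(0, 0.5, 0.5, 0), tolerance = 1e-9)
  expect_equal(sum(h2), 1, tolerance = 1e-9)
  # monomorphic locus in the pairwise-complete subset is undefined
  h3 <- em_haplotype_freqs(c(0, 0, 0, NA), c(0, 1, 2, 1))
  expect_true(all(is.na(h3)))
  expect_true(is.na(r2_pair(c(0, 0, 0), c(0, 1, 2))))
})

test_that("EM matches the 1-D likelihood-grid oracle on random pairs", {
  set.seed(61)
  for (rep in 1:25) {
    g1 <- sample(0:2, 20, replace = TRUE)
    g2 <- sample(0:2, 20, replace = TRUE)
    if (rep %% 3 == 0) g2[sample(20, 8)] <- g1[sample(20, 8)]
    if (rep %% 4 == 0) g1[sample(20, 3)] <- NA
    oracle <- grid_r2_oracle(g1, g2)
    ours <- r2_pair(g1, g2)
    if (is.na(oracle)) {
      expect_true(is.na(ours))
    } else {
      expect_lt(abs(ours - oracle), 1e-6)
    }
  }
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(62)
  for (rep in 1:10) {
    g1 <- sample(0:2, 30, replace = TRUE)
    g2 <- ifelse(runif(30) < 0.5, g1, sample(0:2, 30, replace = TRUE))
    h <- em_haplotype_freqs(g1, g2)
    tr <- attr(h, "loglik_trace")
    if (!is.null(tr) && length(tr) > 1) {
      expect_true(all(diff(tr) >= -1e-9))
    }
  }
})

test_that("r2 is symmetric and invariant to allele relabeling", {
  set.seed(63)
  for (rep in 1:10) {
    g1 <- sample(0:2, 25, replace = TRUE)
    g2 <- ifelse(runif(25) < 0.4, g1, sample(0:2, 25, replace = TRUE))
    g1[sample(25, 2)] <- NA
    r <- r2_pair(g1, g2)
    expect_equal(r2_pair(g2, g1), r, tolerance = 1e-9)
    expect_equal(r2_pair(2L - g1, g2), r, tolerance = 1e-7)
    expect_equal(r2_pair(g1, 2L - g2), r, tolerance = 1e-7)
  }
})

test_that("orthogonal loci give r2 = 0 and identical columns give 1", {
  expect_equal(r2_pair(c(0, 0, 2, 2), c(0, 2, 0, 2)), 0, tolerance = 1e-12)
  g <- c(0, 2, 2, 0, 2, 0)
  expect_equal(r2_pair(g, g), 1, tolerance = 1e-9)
})

test_that("windowed LD respects the distance predicate", {
  d <- matrix(sample(0:2, 8 * 3, TRUE), 8)
  gm <- toy_gm(d, pos = c(1L, 500000L, 1200000L))
  tab <- windowed_ld(gm, window_bp = 1e6)
  got <- paste(tab$pos_i, tab$pos_j)
  expect_true(all(got %in% c("1 500000", "500000 1200000")))
  # single-marker chromosome contributes no pairs
  gm2 <- toy_gm(matrix(sample(0:2, 8, TRUE), 8, 1))
  expect_equal(nrow(windowed_ld(gm2)), 0L)
})

test_that("windowed pair set equals a brute-force double loop", {
  set.seed(64)
  gm <- random_gm(15, 40, missing = 0.1, n_chrom = 2)
  win <- 3e5
  tab <- windowed_ld(gm, win)
  mk <- gm$markers
  expected <- list()
  for (i in seq_len(39)) {
    for (j in (i + 1):40) {
      if (mk$chrom[i] != mk$chrom[j]) next
      dist <- mk$pos[j] - mk$pos[i]
      if (dist <= 0 || dist > win) next
      r2 <- r2_pair(gm$dosage[, i], gm$dosage[, j])
      if (is.na(r2)) next
      expected[[length(expected) + 1]] <-
        c(mk$pos[i], mk$pos[j], r2)
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(tab), nrow(expected))
  ord_g <- order(tab$pos_i, tab$pos_j)
  ord_e <- order(expected[, 1], expected[, 2])
  expect_equal(tab$pos_i[ord_g], as.integer(expected[ord_e, 1]))
  expect_equal(tab$r2[ord_g], expected[ord_e, 3], tolerance = 1e-9)
})

test_that("Hill-Weir expectation has the analytic limits", {
  n <- 50
  expect_equal(hill_weir_er2(0, 1e-4, n),
               (10 / 22) * (1 + 36 / (22 * n)), tolerance = 1e-12)
  # n -> Inf at C = 0 tends to 5/11
  expect_equal(hill_weir_er2(0, 1e-4, 1e12), 5 / 11, tolerance = 1e-9)
  # d -> Inf tends to 1/n
  expect_equal(hill_weir_er2(1e12, 1e-4, n), 1 / n, tolerance = 1e-6)
  # strictly decreasing in distance for rho > 0
  d <- seq(1, 1e6, length.out = 500)
  expect_true(all(diff(hill_weir_er2(d, 1e-4, n)) < 0))
})

test_that("decay fitting recovers the generating parameter from noisy pairs", {
  rho_true <- 2e-4
  errs <- vapply(1:10, function(rep) {
    set.seed(100 + rep)
    d <- runif(2000, 1, 5e4)
    r2 <- hill_weir_er2(d, rho_true, 100) + rnorm(2000, 0, 0.02)
    fit <- fit_decay(data.frame(distance_bp = d, r2 = r2), n = 100)
    abs(fit$rho - rho_true) / rho_true
  }, numeric(1))
  expect_true(all(errs < 0.1))
})

test_that("decay distance solves the baseline crossing and shrinks with rho", {
  fit <- fit_decay(data.frame(distance_bp = runif(100, 1, 5e4),
                              r2 = hill_weir_er2(runif(100, 1, 5e4), 1e-4, 80)),
                   n = 80)
  # curve value at the reported distance equals the baseline to ~1 bp
  expect_lt(abs(hill_weir_er2(fit$decay_distance_bp, fit$rho, 80) - 0.1),
            1e-4)
  d_at <- function(rho) {
    set.seed(1)
    d <- runif(500, 1, 1e5)
    fit_decay(data.frame(distance_bp = d,
                         r2 = hill_weir_er2(d, rho, 80)),
              n = 80)$decay_distance_bp
  }
  dd <- vapply(c(5e-5, 2e-4, 1e-3), d_at, numeric(1))
  expect_true(all(diff(dd) < 0))
  # when the baseline exceeds E(r2)(0) = 0.6405 at n = 4, decay = 0
  flat <- fit_decay(data.frame(distance_bp = runif(50, 1, 1e4),
                               r2 = hill_weir_er2(runif(50, 1, 1e4), 1e-3, 4)),
                    n = 4, baseline = 0.7)
  expect_equal(flat$decay_distance_bp, 0)
})

test_that("mean r2 decays monotonically with distance on simulated LD data", {
  gm <- simulate_ld_genotypes(n_ind = 80, n_loci = 250, seed = 65)
  pairs <- windowed_ld(gm, 2e5)
  bins <- cut(pairs$distance_bp,
              quantile(pairs$distance_bp, seq(0, 1, length.out = 7)),
              include.lowest = TRUE)
  mu <- tapply(pairs$r2, bins, mean)
  expect_lt(cor(seq_along(mu), as.numeric(mu), method = "spearman"), 0)
  expect_true(all(diff(as.numeric(mu)) < 0.02))  # allow tiny local noise
})

test_that("local LD profile tallies consecutive unit pairs", {
  g <- c(0L, 2L, 0L, 2L, 1L, 0L, 2L, 1L)
  h <- sample(0:2, 8, replace = TRUE)
  gm <- toy_gm(cbind(g, g, h), pos = c(100L, 300L, 5000L))
  units <- data.frame(unit_id = 1:3, chrom = "chr01",
                      cut_pos = c(100L, 300L, 5000L),
                      start = c(7L, 207L, 4907L),
                      end = c(193L, 393L, 5093L), n_snps = 1L)
  gm$markers$unit_id <- 1:3
  prof <- local_ld_profile(gm, units, baseline = 0.1)
  expect_equal(nrow(prof$profile), 2L)
  # identical single SNPs in consecutive units: mean r2 = 1, >= baseline
  first <- prof$profile[prof$profile$left_cut_pos == 100L, ]
  expect_equal(first$mean_r2, 1, tolerance = 1e-9)
  tot <- prof$summary[prof$summary$chrom == "Total", ]
  expect_equal(tot$n_ge_baseline + tot$n_lt_baseline, 2L)
  # single unit on a chromosome yields no pairs
  one <- local_ld_profile(gm, units[3, , drop = FALSE])
  expect_equal(nrow(one$profile), 0L)
})

test_that("local LD summary reproduces mean-over-pairs and the tallies add up", {
  set.seed(66)
  gm <- simulate_ld_genotypes(n_ind = 40, n_loci = 60,
                              mean_spacing_bp = 500, seed = 67)
  mk <- gm$markers
  mk$unit_id <- sort(rep_len(1:12, 60))
  gm$markers <- mk
  units <- data.frame(unit_id = 1:12, chrom = "chr01",
                      cut_pos = tapply(mk$pos, mk$unit_id, min),
                      start = tapply(mk$pos, mk$unit_id, min),
                      end = tapply(mk$pos, mk$unit_id, max), n_snps = 5L)
  prof <- local_ld_profile(gm, units)
  # brute-force the first adjacent pair
  left <- which(mk$unit_id == 1); right <- which(mk$unit_id == 2)
  r2s <- c()
  for (i in left) for (j in right) {
    r2 <- r2_pair(gm$dosage[, i], gm$dosage[, j])
    if (!is.na(r2)) r2s <- c(r2s, r2)
  }
  expect_equal(prof$profile$mean_r2[1], mean(r2s), tolerance = 1e-9)
  summ <- prof$summary
  tot <- summ[summ$chrom == "Total", ]
  expect_equal(tot$n_ge_baseline + tot$n_lt_baseline, nrow(prof$profile))
  expect_equal(tot$proportion_pct,
               proportion_report(tot$n_ge_baseline,
                                 tot$n_ge_baseline + tot$n_lt_baseline))
})

test_that("decay distance shrinks as the simulated switch rate grows", {
  dd <- vapply(c(1e-6, 1e-5, 1e-4), function(cc) {
    gm <- simulate_ld_genotypes(n_ind = 60, n_loci = 200,
                                switch_rate = cc, seed = 68)
    pairs <- windowed_ld(gm, 3e5)
    fit <- fit_decay(pairs, ld_sample_size(pairs))
    if (fit$decay_reached) fit$decay_distance_bp else Inf
  }, numeric(1))
  expect_true(all(diff(dd) < 0))
})
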