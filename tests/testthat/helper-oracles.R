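# Independent oracles used across the suite. Each is a deliberately
# naive implementation kept separate from the package's computation
# paths: grid search instead of EM, per-locus loops instead of
# vectorised algebra, substring/interval scans instead of Biostrings /
# IRanges.

# observed-data log-likelihood of a two-locus genotype table under
# haplotype frequencies, summed over the nine dosage cells under
# random union of gametes (HWE at the haplotype level)
loglik_2locus <- function(g1, g2, pAB, pAb, paB, pab) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  cell_p <- matrix(c(
    pab^2,          2 * paB * pab,            paB^2,
    2 * pAb * pab,  2 * (pAB * pab + pAb * paB), 2 * pAB * paB,
    pAb^2,          2 * pAB * pAb,            pAB^2), nrow = 3,
    byrow = TRUE)   # rows = dosage at locus 1, cols = dosage at locus 2
  ll <- 0
  for (i in seq_along(g1)) {
    p <- cell_p[g1[i] + 1, g2[i] + 1]
    ll <- ll + log(max(p, .Machine$double.xmin))
  }
  ll
}

# 1-D likelihood maximisation over pAB (allele frequencies fixed by the
# counts): coarse grid, then golden-section refinement of the bracket
grid_r2_oracle <- function(g1, g2, n_grid = 2001) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  n <- length(g1)
  pA <- sum(g1) / (2 * n)
  pB <- sum(g2) / (2 * n)
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NA_real_)
  lo <- max(0, pA + pB - 1)
  hi <- min(pA, pB)
  ll_at <- function(pAB)
    loglik_2locus(g1, g2, pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB)
  grid <- seq(lo, hi, length.out = n_grid)
  ll <- vapply(grid, ll_at, numeric(1))
  k <- which.max(ll)
  bl <- grid[max(1, k - 1)]; bh <- grid[min(n_grid, k + 1)]
  pAB <- if (bh > bl) {
    stats::optimize(ll_at, c(bl, bh), maximum = TRUE, tol = 1e-12)$maximum
  } else grid[k]
  if (ll_at(grid[k]) > ll_at(pAB)) pAB <- grid[k]
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  min(max(r2, 0), 1)
}

# Weir-Cockerham theta by direct per-locus formula evaluation on raw
# dosage tables (one matrix per population, no missing handling beyond
# dropping NA calls)
wc_theta_direct <- function(pop_list) {
  r <- length(pop_list)
  L <- ncol(pop_list[[1]])
  A <- B <- C <- numeric(0)
  for (l in seq_len(L)) {
    n <- p <- h <- numeric(r)
    for (k in seq_len(r)) {
      g <- pop_list[[k]][, l]
      g <- g[!is.na(g)]
      n[k] <- length(g)
      p[k] <- sum(g) / (2 * length(g))
      h[k] <- mean(g == 1)
    }
    if (any(n < 2)) next
    nbar <- mean(n)
    nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    if (is.finite(a) && is.finite(b) && is.finite(cc)) {
      A <- c(A, a); B <- c(B, b); C <- c(C, cc)
    }
  }
  sum(A) / sum(A + B + C)
}

# naive forward-strand substring scan
naive_motif_scan <- function(seq_string, motif) {
  s <- toupper(seq_string)
  m <- nchar(motif)
  hits <- integer(0)
  for (p in seq_len(max(0L, nchar(s) - m + 1L))) {
    if (substr(s, p, p + m - 1L) == motif) hits <- c(hits, p)
  }
  hits
}

# naive point-in-interval classification
naive_classify <- function(positions, intervals) {
  vapply(positions, function(p) {
    for (r in seq_len(nrow(intervals))) {
      if (p >= intervals$start[r] && p <= intervals$end[r]) return("heterochromatin")
    }
    "euchromatin"
  }, character(1))
}

# naive all-pairs interval intersection counts for the overlap report
naive_overlap_counts <- function(units, markers, genes, chr) {
  u <- units[units$chrom == chr, , drop = FALSE]
  m <- markers[markers$chrom == chr, , drop = FALSE]
  g <- genes[genes$chrom == chr, , drop = FALSE]
  g_seq <- 0L; g_snp <- 0L
  for (r in seq_len(nrow(g))) {
    hit_u <- FALSE; hit_s <- FALSE
    for (q in seq_len(nrow(u))) {
      if (g$start[r] <= u$end[q] && u$start[q] <= g$end[r]) hit_u <- TRUE
    }
    for (q in seq_len(nrow(m))) {
      if (m$pos[q] >= g$start[r] && m$pos[q] <= g$end[r]) hit_s <- TRUE
    }
    g_seq <- g_seq + hit_u; g_snp <- g_snp + hit_s
  }
  s_gene <- 0L
  for (q in seq_len(nrow(m))) {
    inside <- FALSE
    for (r in seq_len(nrow(g))) {
      if (m$pos[q] >= g$start[r] && m$pos[q] <= g$end[r]) inside <- TRUE
    }
    s_gene <- s_gene + inside
  }
  c(snps = nrow(m), genes_in_sequenced_regions = g_seq,
    genes_with_snps = g_snp, snps_in_gene_regions = s_gene)
}

# small deterministic genotype matrix builder
toy_gm <- function(dosage, chrom = NULL, pos = NULL) {
  dosage <- as.matrix(dosage)
  L <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr01", L)
  if (is.null(pos)) pos <- seq_len(L) * 100L
  genotype_matrix(dosage, data.frame(chrom = chrom, pos = pos,
                                     ref = "A", alt = "G"))
}

toy_popmap <- function(gm, pops) {
  pop_map(data.frame(accession = rownames(gm$dosage), pop = pops),
          gm = gm)
}

# random dosage matrix with missing values (for property tests)
random_gm <- function(n, L, missing = 0.1, n_chrom = 2) {
  d <- matrix(sample(0:2, n * L, replace = TRUE), n, L)
  d[runif(n * L) < missing] <- NA_integer_
  chrom <- sprintf("chr%02d", sort(rep_len(seq_len(n_chrom), L)))
  pos <- integer(L)
  for (cc in unique(chrom)) {
    k <- sum(chrom == cc)
    pos[chrom == cc] <- sort(sample.int(1e6, k))
  }
  genotype_matrix(d, data.frame(chrom = chrom, pos = pos, ref = "A",
                                alt = "G"))
}
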