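# Two-locus LD from unphased dosages. r2 is computed from maximum-
# likelihood haplotype frequencies obtained by EM over the double-
# heterozygote phase ambiguity, on pairwise-complete observations --
# the convention of the standard unphased-genotype LD tool chain.

# Tally the 3x3 genotype table of a dosage pair over pairwise-complete
# individuals. Returns counts in order c00,c01,c02,c10,c11,c12,c20,c21,c22
# (first index = dosage at locus 1).
.pair_counts <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L)
}

# 3x3 genotype tallies for an arbitrary list of column pairs, via
# indicator cross-products computed in column blocks (keeps memory
# bounded on dense pair sets). Returns a length(ii) x 9 matrix in the
# .pair_counts column order.
.pair_counts_many <- function(dosage, ii, jj, block = 512L) {
  P <- length(ii)
  ind <- lapply(0:2, function(v) {
    m <- dosage == v
    m[is.na(m)] <- FALSE
    storage.mode(m) <- "double"
    m
  })
  counts <- matrix(0, nrow = P, ncol = 9L)
  ord <- order(ii, jj)
  ii_o <- ii[ord]; jj_o <- jj[ord]
  starts <- seq(1L, P, by = block)
  for (s in starts) {
    e <- min(s + block - 1L, P)
    rows <- s:e
    lcols <- sort(unique(ii_o[rows]))
    rcols <- sort(unique(jj_o[rows]))
    li <- match(ii_o[rows], lcols)
    ri <- match(jj_o[rows], rcols)
    lin <- cbind(li, ri)
    cat_k <- 0L
    for (a in 1:3) {
      for (b in 1:3) {
        cat_k <- cat_k + 1L
        cp <- crossprod(ind[[a]][, lcols, drop = FALSE],
                        ind[[b]][, rcols, drop = FALSE])
        counts[ord[rows], cat_k] <- cp[lin]
      }
    }
  }
  counts
}

# Vectorised EM over many pairs at once. `counts` is a P x 9 matrix of
# 3x3 genotype tallies. Returns a list of haplotype-frequency vectors
# (pAB, pAb, paB, pab), allele frequencies, r2 and the pairwise-complete
# sample size; entries are NA where a locus is monomorphic in the
# complete subset.
.em_r2_counts <- function(counts, tol = 1e-10, max_iter = 1000L) {
  counts <- matrix(as.numeric(counts), ncol = 9L)
  n_ind <- rowSums(counts)
  c00 <- counts[, 1]; c01 <- counts[, 2]; c02 <- counts[, 3]
  c10 <- counts[, 4]; c11 <- counts[, 5]; c12 <- counts[, 6]
  c20 <- counts[, 7]; c21 <- counts[, 8]; c22 <- counts[, 9]
  # phase-unambiguous haplotype tallies
  nAB0 <- 2 * c22 + c21 + c12
  nAb0 <- 2 * c20 + c21 + c10
  naB0 <- 2 * c02 + c12 + c01
  nab0 <- 2 * c00 + c01 + c10
  dh <- c11
  tot <- 2 * n_ind
  pA <- (nAB0 + nAb0 + dh) / tot
  pB <- (nAB0 + naB0 + dh) / tot
  defined <- n_ind > 0 & pA > 0 & pA < 1 & pB > 0 & pB < 1
  # init at linkage equilibrium
  pAB <- pA * pB; pAb <- pA * (1 - pB); paB <- (1 - pA) * pB
  pab <- (1 - pA) * (1 - pB)
  act <- which(defined)
  for (it in seq_len(max_iter)) {
    if (!length(act)) break
    cis <- pAB[act] * pab[act]
    trans <- pAb[act] * paB[act]
    s <- cis + trans
    w <- ifelse(s > 0, cis / s, 0.5)
    new_pAB <- (nAB0[act] + w * dh[act]) / tot[act]
    new_pab <- (nab0[act] + w * dh[act]) / tot[act]
    new_pAb <- (nAb0[act] + (1 - w) * dh[act]) / tot[act]
    new_paB <- (naB0[act] + (1 - w) * dh[act]) / tot[act]
    delta <- pmax(abs(new_pAB - pAB[act]), abs(new_pAb - pAb[act]),
                  abs(new_paB - paB[act]), abs(new_pab - pab[act]))
    pAB[act] <- new_pAB; pAb[act] <- new_pAb
    paB[act] <- new_paB; pab[act] <- new_pab
    act <- act[delta >= tol]
  }
  D <- pAB - pA * pB
  r2 <- D * D / (pA * (1 - pA) * pB * (1 - pB))
  r2 <- pmin(pmax(r2, 0), 1)
  r2[!defined] <- NA_real_
  pAB[!defined] <- NA_real_; pAb[!defined] <- NA_real_
  paB[!defined] <- NA_real_; pab[!defined] <- NA_real_
  list(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
       pA = pA, pB = pB, r2 = r2, n = n_ind)
}

# Observed-data log-likelihood of a genotype tally under given haplotype
# frequencies (HWE at the haplotype level); additive constants dropped.
.pair_loglik <- function(counts, pAB, pAb, paB, pab) {
  xlog <- function(x, p) ifelse(x > 0, x * log(pmax(p, .Machine$double.xmin)), 0)
  # counts order: c00,c01,c02,c10,c11,c12,c20,c21,c22
  nAB0 <- 2 * counts[9] + counts[8] + counts[6]
  nAb0 <- 2 * counts[7] + counts[8] + counts[4]
  naB0 <- 2 * counts[3] + counts[6] + counts[2]
  nab0 <- 2 * counts[1] + counts[2] + counts[4]
  dh <- counts[5]
  xlog(nAB0, pAB) + xlog(nAb0, pAb) + xlog(naB0, paB) + xlog(nab0, pab) +
    xlog(dh, 2 * (pAB * pab + pAb * paB))
}

#' Maximum-likelihood haplotype frequencies for two unphased loci
#'
#' EM estimation of the four two-locus haplotype frequencies from
#' unphased dosage vectors, resolving the double-heterozygote phase
#' ambiguity. The allele frequencies are fixed by the genotype counts;
#' EM moves only the coupling between loci. Initialisation is at linkage
#' equilibrium; iteration stops when every frequency moves by less than
#' `tol` (default 1e-10) or after `max_iter` iterations. When the
#' double-heterozygote split is degenerate (both phase products zero)
#' the count is split equally.
#'
#' @param g1,g2 dosage vectors (0/1/2/NA) of equal length; only
#'   pairwise-complete individuals are used.
#' @param tol convergence tolerance on haplotype frequencies.
#' @param max_iter iteration cap.
#' @return named vector `c(pAB, pAb, paB, pab)` (A/B = alt alleles at
#'   locus 1/2), with attributes `pA`, `pB`, `n` (pairwise-complete
#'   sample size) and `loglik_trace` (observed-data log-likelihood after
#'   each EM iteration). `NA`s if either locus is monomorphic in the
#'   pairwise-complete subset.
#' @export
em_haplotype_freqs <- function(g1, g2, tol = 1e-10, max_iter = 1000L) {
  stopifnot(length(g1) == length(g2))
  counts <- .pair_counts(g1, g2)
  # scalar EM with a log-likelihood trace (the batch path skips the trace)
  res <- .em_r2_counts(matrix(counts, nrow = 1), tol = tol,
                       max_iter = max_iter)
  if (is.na(res$pAB)) {
    out <- c(pAB = NA_real_, pAb = NA_real_, paB = NA_real_, pab = NA_real_)
    attr(out, "n") <- res$n
    return(out)
  }
  # re-run scalar iterations to record the trace
  pA <- res$pA; pB <- res$pB
  pAB <- pA * pB; pAb <- pA * (1 - pB); paB <- (1 - pA) * pB
  pab <- (1 - pA) * (1 - pB)
  nAB0 <- 2 * counts[9] + counts[8] + counts[6]
  nAb0 <- 2 * counts[7] + counts[8] + counts[4]
  naB0 <- 2 * counts[3] + counts[6] + counts[2]
  nab0 <- 2 * counts[1] + counts[2] + counts[4]
  dh <- counts[5]; tot <- 2 * sum(counts)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    cis <- pAB * pab; trans <- pAb * paB
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- c((nAB0 + w * dh), (nAb0 + (1 - w) * dh),
             (naB0 + (1 - w) * dh), (nab0 + w * dh)) / tot
    delta <- max(abs(new - c(pAB, pAb, paB, pab)))
    pAB <- new[1]; pAb <- new[2]; paB <- new[3]; pab <- new[4]
    trace <- c(trace, .pair_loglik(counts, pAB, pAb, paB, pab))
    if (delta < tol) break
  }
  out <- c(pAB = pAB, pAb = pAb, paB = paB, pab = pab)
  attr(out, "pA") <- pA
  attr(out, "pB") <- pB
  attr(out, "n") <- sum(counts)
  attr(out, "loglik_trace") <- trace
  out
}

#' Squared allelic correlation (r2) between two unphased loci
#'
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))` with `D = pAB - pA*pB` from the EM
#' haplotype frequencies; clipped to \[0, 1\].
#'
#' @inheritParams em_haplotype_freqs
#' @return r2 in \[0, 1\], or `NA` when either locus is monomorphic in
#'   the pairwise-complete subset.
#' @export
r2_pair <- function(g1, g2) {
  res <- .em_r2_counts(matrix(.pair_counts(g1, g2), nrow = 1))
  res$r2
}

#' All intra-chromosome marker pairs within a window
#'
#' Computes EM r2 for every pair of markers on the same chromosome whose
#' distance is positive and at most `window_bp` (1 Mb by default).
#'
#' @param gm a [genotype_matrix()] with markers sorted by position.
#' @param window_bp maximum pair distance in bases.
#' @return data.frame of class `ld_pair_table` with columns `chrom`,
#'   `pos_i`, `pos_j`, `distance_bp`, `r2`, `n`; pairs whose r2 is
#'   undefined (monomorphic in the pairwise-complete subset) are dropped
#'   and counted in the `n_undefined` attribute.
#' @export
windowed_ld <- function(gm, window_bp = 1e6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  ii_l <- list(); jj_l <- list()
  for (chr in unique(mk$chrom)) {
    idx <- which(mk$chrom == chr)
    pos <- mk$pos[idx]
    if (length(idx) < 2L) next
    hi <- findInterval(pos + window_bp, pos)
    span <- hi - seq_along(idx)
    keep <- span > 0L
    if (!any(keep)) next
    ii_l[[chr]] <- rep(idx[keep], span[keep])
    jj_l[[chr]] <- idx[unlist(lapply(which(keep), function(k)
      (k + 1L):hi[k]), use.names = FALSE)]
  }
  ii <- unlist(ii_l, use.names = FALSE)
  jj <- unlist(jj_l, use.names = FALSE)
  keep <- mk$pos[jj] > mk$pos[ii]   # drop zero-distance duplicates
  ii <- ii[keep]; jj <- jj[keep]
  if (!length(ii)) {
    out <- data.frame(chrom = character(), pos_i = integer(),
                      pos_j = integer(), distance_bp = integer(),
                      r2 = numeric(), n = integer())
    attr(out, "n_undefined") <- 0L
    class(out) <- c("ld_pair_table", "data.frame")
    return(out)
  }
  res <- .em_r2_counts(.pair_counts_many(gm$dosage, ii, jj))
  out <- data.frame(chrom = mk$chrom[ii], pos_i = mk$pos[ii],
                    pos_j = mk$pos[jj],
                    distance_bp = mk$pos[jj] - mk$pos[ii],
                    r2 = res$r2, n = res$n, stringsAsFactors = FALSE)
  n_undef <- sum(is.na(out$r2))
  out <- out[!is.na(out$r2), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_undefined") <- n_undef
  class(out) <- c("ld_pair_table", "data.frame")
  out
}

#' Expected r2 under drift-recombination equilibrium
#'
#' The Hill-Weir expectation of r2 at recombination scale `C = rho * d`
#' in a sample of `n` individuals, including the finite-sample term:
#' `E(r2) = ((10+C)/((2+C)(11+C))) * (1 + ((3+C)(12+12C+C^2)) /
#' (n(2+C)(11+C)))`. At C = 0 this is (5/11)(1 + 36/(22n)); for large C
#' it approaches 1/n.
#'
#' @param d distance in bases (vectorised).
#' @param rho recombination-scale parameter per base.
#' @param n sample size used in the expectation.
#' @return expected r2.
#' @export
hill_weir_er2 <- function(d, rho, n) {
  C <- rho * d
  ((10 + C) / ((2 + C) * (11 + C))) *
    (1 + ((3 + C) * (12 + 12 * C + C^2)) / (n * (2 + C) * (11 + C)))
}

#' Fit the Hill-Weir LD-decay curve
#'
#' One-parameter nonlinear least squares of the Hill-Weir expectation to
#' an (distance, r2) cloud: minimises the residual sum of squares over
#' `rho` (grid-seeded golden-section refinement on log10(rho), bounds
#' 1e-12..1 per bp), with `n` fixed. The decay distance is the smallest
#' distance at which the fitted curve equals `baseline`, found by
#' bisection over \[1, 10 * max distance\] to 1 bp.
#'
#' @param pairs `ld_pair_table` (or any data.frame with `distance_bp`
#'   and `r2`), at least 10 pairs.
#' @param n sample size used in the expectation; see
#'   [ld_sample_size()] for the package's convention.
#' @param baseline r2 level defining the decay distance (default 0.1).
#' @param binned if `TRUE`, fit to mean r2 in `bin_width` distance bins
#'   instead of raw pairs (plotting parity mode).
#' @param bin_width bin width in bases for `binned = TRUE`.
#' @return object of class `ld_decay_fit`: list with `rho`, `n`,
#'   `baseline`, `decay_distance_bp` (`NA` if the curve never reaches
#'   the baseline in range, with `decay_reached = FALSE`), `rss`,
#'   `n_pairs`, `mode`.
#' @export
fit_decay <- function(pairs, n, baseline = 0.1, binned = FALSE,
                      bin_width = 1000) {
  pairs <- as.data.frame(pairs)
  pairs <- pairs[is.finite(pairs$r2) & is.finite(pairs$distance_bp), ,
                 drop = FALSE]
  if (nrow(pairs) < 10L) stop("need at least 10 (distance, r2) pairs")
  if (n < 2) stop("n must be >= 2")
  if (binned) {
    bin <- floor(pairs$distance_bp / bin_width)
    d <- tapply(pairs$distance_bp, bin, mean)
    r2 <- tapply(pairs$r2, bin, mean)
    d <- as.numeric(d); r2 <- as.numeric(r2)
  } else {
    d <- pairs$distance_bp; r2 <- pairs$r2
  }
  rss_fun <- function(log10_rho) {
    sum((r2 - hill_weir_er2(d, 10^log10_rho, n))^2)
  }
  grid <- seq(-12, 0, length.out = 61)
  vals <- vapply(grid, rss_fun, numeric(1))
  if (!any(is.finite(vals))) stop("decay fit failed: non-finite RSS on grid")
  k <- which.min(vals)
  lo <- grid[max(1L, k - 1L)]; hi <- grid[min(length(grid), k + 1L)]
  opt <- stats::optimize(rss_fun, c(lo, hi), tol = 1e-8)
  rho <- 10^opt$minimum
  max_d <- max(d)
  f <- function(x) hill_weir_er2(x, rho, n) - baseline
  if (hill_weir_er2(0, rho, n) <= baseline) {
    decay <- 0
    reached <- TRUE
  } else if (f(10 * max_d) > 0) {
    decay <- NA_real_
    reached <- FALSE
  } else if (f(1) <= 0) {
    decay <- 1
    reached <- TRUE
  } else {
    lo_d <- 1; hi_d <- 10 * max_d
    while (hi_d - lo_d > 1) {        # bisection to 1 bp
      mid <- (lo_d + hi_d) / 2
      if (f(mid) > 0) lo_d <- mid else hi_d <- mid
    }
    decay <- hi_d
    reached <- TRUE
  }
  structure(list(rho = rho, n = n, baseline = baseline,
                 decay_distance_bp = decay, decay_reached = reached,
                 rss = opt$objective, n_pairs = length(d),
                 mode = if (binned) "binned" else "raw"),
            class = "ld_decay_fit")
}

#' @export
print.ld_decay_fit <- function(x, ...) {
  cat("Hill-Weir LD decay fit\n")
  cat(sprintf("  rho: %.4g per bp   (n = %d, %d pairs, %s mode)\n",
              x$rho, x$n, x$n_pairs, x$mode))
  if (x$decay_reached) {
    cat(sprintf("  decay distance at r2 = %.2g: %.1f kb\n",
                x$baseline, x$decay_distance_bp / 1000))
  } else {
    cat(sprintf("  curve does not reach r2 = %.2g within range\n",
                x$baseline))
  }
  invisible(x)
}

#' @export
coef.ld_decay_fit <- function(object, ...) c(rho = object$rho)

#' @export
predict.ld_decay_fit <- function(object, distance_bp, ...) {
  hill_weir_er2(distance_bp, object$rho, object$n)
}

#' @export
plot.ld_decay_fit <- function(x, pairs = NULL, max_bp = NULL, ...) {
  if (is.null(max_bp)) {
    max_bp <- if (!is.null(pairs)) max(pairs$distance_bp) else
      5 * max(x$decay_distance_bp, 1e4, na.rm = TRUE)
  }
  d <- seq(1, max_bp, length.out = 400)
  if (!is.null(pairs)) {
    plot(pairs$distance_bp / 1000, pairs$r2, pch = 16, cex = 0.3,
         col = grDevices::grey(0.6), xlab = "distance (kb)",
         ylab = expression(r^2), ...)
    graphics::lines(d / 1000, predict(x, d), col = "red", lwd = 2)
  } else {
    plot(d / 1000, predict(x, d), type = "l", col = "red", lwd = 2,
         xlab = "distance (kb)", ylab = expression(E(r^2)), ...)
  }
  graphics::abline(h = x$baseline, lty = 3)
  invisible(x)
}

#' Sample size for the LD-decay expectation
#'
#' The package's convention: twice the median pairwise-complete
#' individual count over a sample of marker pairs, fixed before fitting.
#'
#' @param pairs an `ld_pair_table` with an `n` column.
#' @return integer sample size (chromosome count).
#' @export
ld_sample_size <- function(pairs) {
  as.integer(round(2 * stats::median(pairs$n)))
}

#' Local LD profile over consecutive sequencing units
#'
#' For each pair of consecutive sequencing units on a chromosome, the
#' mean r2 over all SNP pairs with one SNP in each unit, recorded at the
#' left unit's cut position. Tallies of mean r2 at or above vs below the
#' baseline are reported per chromosome and overall, with the proportion
#' of linked flanking pairs as a percentage.
#'
#' @param gm a [genotype_matrix()] whose markers carry `unit_id`.
#' @param units unit table from [build_units()].
#' @param baseline r2 threshold (default 0.1).
#' @return list with `profile` (data.frame `chrom`, `left_cut_pos`,
#'   `mean_r2`, `n_snp_pairs`) and `summary` (per-chromosome + Total
#'   rows: `n_ge_baseline`, `n_lt_baseline`, `proportion_pct`). Unit
#'   pairs with no defined r2 are excluded from the tallies and counted
#'   in the `n_no_defined_r2` attribute of `profile`.
#' @export
local_ld_profile <- function(gm, units, baseline = 0.1) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  if (all(is.na(mk$unit_id))) stop("markers carry no unit assignment")
  prof <- list()
  dropped <- 0L
  for (chr in unique(units$chrom)) {
    u <- units[units$chrom == chr, , drop = FALSE]
    u <- u[order(u$cut_pos), , drop = FALSE]
    if (nrow(u) < 2L) next
    for (k in seq_len(nrow(u) - 1L)) {
      left <- which(mk$unit_id == u$unit_id[k])
      right <- which(mk$unit_id == u$unit_id[k + 1L])
      if (!length(left) || !length(right)) next
      pairs_idx <- expand.grid(i = left, j = right)
      counts <- .pair_counts_many(gm$dosage, pairs_idx$i, pairs_idx$j)
      r2 <- .em_r2_counts(counts)$r2
      r2 <- r2[!is.na(r2)]
      if (!length(r2)) {
        dropped <- dropped + 1L
        next
      }
      prof[[length(prof) + 1L]] <-
        data.frame(chrom = chr, left_cut_pos = u$cut_pos[k],
                   mean_r2 = mean(r2), n_snp_pairs = length(r2),
                   stringsAsFactors = FALSE)
    }
  }
  profile <- if (length(prof)) do.call(rbind, prof) else
    data.frame(chrom = character(), left_cut_pos = integer(),
               mean_r2 = numeric(), n_snp_pairs = integer())
  attr(profile, "n_no_defined_r2") <- dropped
  chroms <- unique(profile$chrom)
  summ <- data.frame(chrom = c(chroms, "Total"), n_ge_baseline = 0L,
                     n_lt_baseline = 0L, proportion_pct = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_along(chroms)) {
    sel <- profile$chrom == chroms[k]
    summ$n_ge_baseline[k] <- sum(profile$mean_r2[sel] >= baseline)
    summ$n_lt_baseline[k] <- sum(profile$mean_r2[sel] < baseline)
  }
  kt <- nrow(summ)
  summ$n_ge_baseline[kt] <- sum(summ$n_ge_baseline[-kt])
  summ$n_lt_baseline[kt] <- sum(summ$n_lt_baseline[-kt])
  tot <- summ$n_ge_baseline + summ$n_lt_baseline
  summ$proportion_pct <- ifelse(tot > 0,
                                .round_half_up(100 * summ$n_ge_baseline / tot, 2),
                                NA_real_)
  list(profile = profile, summary = summ)
}
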