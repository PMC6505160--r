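# Diversity and differentiation statistics on dosage matrices.
# Conventions: loci are treated independently; per-population statistics
# use only individuals with a called genotype at the locus in hand.

# split accession row indices by population label
.pop_indices <- function(gm, popmap) {
  popmap <- popmap[popmap$accession %in% rownames(gm$dosage), , drop = FALSE]
  split(match(popmap$accession, rownames(gm$dosage)), popmap$pop)
}

# per-locus called count, alt frequency and heterozygote proportion for
# a set of accession rows
.locus_stats <- function(dosage, rows) {
  d <- dosage[rows, , drop = FALSE]
  n <- colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
  h <- ifelse(n > 0, colSums(d == 1L, na.rm = TRUE) / n, NA_real_)
  list(n = n, p = p, h = h)
}

#' Observed heterozygosity
#'
#' Per locus, the proportion of heterozygous calls among non-missing
#' individuals; per population, the mean over loci with at least one
#' call. With a population map, one row per population plus a `Total`
#' row treating the whole collection as one group.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap optional [pop_map()]; omitted = single group.
#' @return data.frame `pop`, `n`, `missing_pct`, `ho`.
#' @export
observed_heterozygosity <- function(gm, popmap = NULL) {
  groups <- if (is.null(popmap)) list(Total = seq_len(nrow(gm$dosage))) else
    c(.pop_indices(gm, popmap), list(Total = seq_len(nrow(gm$dosage))))
  out <- lapply(names(groups), function(g) {
    rows <- groups[[g]]
    st <- .locus_stats(gm$dosage, rows)
    data.frame(pop = g, n = length(rows),
               missing_pct = 100 * mean(is.na(gm$dosage[rows, , drop = FALSE])),
               ho = mean(st$h[st$n > 0]), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Within-population gene diversity (expected heterozygosity)
#'
#' The Nei-Chesser unbiased estimator. Per locus with `n` called
#' individuals, alt frequency `p` and observed heterozygote proportion
#' `Ho`: `Hs = n/(n-1) * (1 - p^2 - (1-p)^2 - Ho/(2n))`; loci with fewer
#' than two called individuals are skipped. The population value is the
#' mean over valid loci. Two `Total` conventions are reported: the whole
#' collection pooled as one population (`Total_pooled`) and the
#' unweighted mean of the per-population values (`Total_mean`, `NA`
#' without a population map).
#'
#' @inheritParams observed_heterozygosity
#' @return data.frame `pop`, `n`, `hs`.
#' @export
gene_diversity_hs <- function(gm, popmap = NULL) {
  hs_group <- function(rows) {
    st <- .locus_stats(gm$dosage, rows)
    ok <- st$n >= 2L
    n <- st$n[ok]; p <- st$p[ok]; h <- st$h[ok]
    hs_l <- n / (n - 1) * (1 - p^2 - (1 - p)^2 - h / (2 * n))
    mean(hs_l)
  }
  groups <- if (is.null(popmap)) list() else .pop_indices(gm, popmap)
  rows_all <- seq_len(nrow(gm$dosage))
  out <- lapply(names(groups), function(g)
    data.frame(pop = g, n = length(groups[[g]]), hs = hs_group(groups[[g]]),
               stringsAsFactors = FALSE))
  out <- do.call(rbind, c(out, list(
    data.frame(pop = "Total_pooled", n = length(rows_all),
               hs = hs_group(rows_all), stringsAsFactors = FALSE),
    data.frame(pop = "Total_mean", n = length(rows_all),
               hs = if (length(groups))
                 mean(vapply(groups, hs_group, numeric(1))) else NA_real_,
               stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

#' Diversity summary table
#'
#' Sample size, missing percentage, observed heterozygosity and gene
#' diversity per subpopulation, in the layout of a collection summary
#' table (Total row first).
#'
#' @inheritParams observed_heterozygosity
#' @return data.frame `pop`, `n`, `missing_pct`, `ho`, `hs`.
#' @export
diversity_table <- function(gm, popmap) {
  ho <- observed_heterozygosity(gm, popmap)
  hs <- gene_diversity_hs(gm, popmap)
  hs_val <- c(stats::setNames(hs$hs, hs$pop))
  out <- ho
  out$hs <- ifelse(out$pop == "Total", hs_val["Total_pooled"],
                   hs_val[out$pop])
  out <- out[c(which(out$pop == "Total"), which(out$pop != "Total")), ]
  rownames(out) <- NULL
  out
}

# Weir-Cockerham variance components for one population pair,
# vectorised over loci. Inputs are per-locus n, p, h for each pop.
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  ok <- n1 >= 2L & n2 >= 2L
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  ok <- ok & is.finite(a) & is.finite(b) & is.finite(cc)
  list(a = a, b = b, c = cc, ok = ok)
}

#' Pairwise Weir-Cockerham Fst
#'
#' Theta for every pair of populations, as the ratio of summed variance
#' components over loci (`sum(a) / sum(a+b+c)`), the cited estimator's
#' standard form. Loci where either population has fewer than two called
#' individuals, or where components are undefined, are excluded from
#' both sums. Optional bootstrap over loci gives a percentile CI.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [pop_map()] with at least two populations.
#' @param n_boot bootstrap replicates over loci (0 = no CI).
#' @param seed RNG seed for the bootstrap.
#' @return object of class `fst_result`: list with `theta` (symmetric
#'   matrix, `NA` diagonal), `pairs` (data.frame `pop1`, `pop2`,
#'   `theta`, `n_loci`, `ci_lo`, `ci_hi`).
#' @export
pairwise_fst <- function(gm, popmap, n_boot = 1000L, seed = 1L) {
  groups <- .pop_indices(gm, popmap)
  if (length(groups) < 2L) stop("need at least two populations")
  pops <- names(groups)
  st <- lapply(groups, function(rows) .locus_stats(gm$dosage, rows))
  theta <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
  pairs <- list()
  set.seed(seed)
  for (i in seq_along(pops)[-length(pops)]) {
    for (j in (i + 1L):length(pops)) {
      s1 <- st[[i]]; s2 <- st[[j]]
      w <- .wc_components(s1$n, s1$p, s1$h, s2$n, s2$p, s2$h)
      a <- w$a[w$ok]; b <- w$b[w$ok]; cc <- w$c[w$ok]
      denom <- sum(a + b + cc)
      th <- if (length(a) == 0L || denom == 0) NA_real_ else sum(a) / denom
      ci <- c(NA_real_, NA_real_)
      if (n_boot > 0L && length(a) >= 2L && !is.na(th)) {
        bt <- vapply(seq_len(n_boot), function(rep) {
          idx <- sample.int(length(a), replace = TRUE)
          den <- sum(a[idx] + b[idx] + cc[idx])
          if (den == 0) NA_real_ else sum(a[idx]) / den
        }, numeric(1))
        ci <- stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
      }
      theta[i, j] <- theta[j, i] <- th
      pairs[[length(pairs) + 1L]] <-
        data.frame(pop1 = pops[i], pop2 = pops[j], theta = th,
                   n_loci = length(a), ci_lo = ci[1], ci_hi = ci[2],
                   stringsAsFactors = FALSE)
    }
  }
  structure(list(theta = theta, pairs = do.call(rbind, pairs)),
            class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Pairwise Weir-Cockerham Fst (theta, ratio of sums over loci)\n")
  print(round(x$theta, 4))
  invisible(x)
}

# Missing-scaled squared-Euclidean distance matrix on dosages:
# delta2_ij = sum over shared called loci of (d_i - d_j)^2 * (L / L_ij).
.amova_dist2 <- function(dosage) {
  L <- ncol(dosage)
  M <- !is.na(dosage)
  X <- dosage
  X[!M] <- 0
  storage.mode(X) <- "double"
  Mn <- matrix(as.numeric(M), nrow(M))
  X2 <- X^2
  S <- X2 %*% t(Mn) + Mn %*% t(X2) - 2 * X %*% t(X)
  Lij <- Mn %*% t(Mn)
  D2 <- ifelse(Lij > 0, S * (L / Lij), NA_real_)
  diag(D2) <- 0
  D2
}

# SSD decomposition and Phi_ST from a squared-distance matrix and a
# grouping factor
.amova_from_dist <- function(D2, groups) {
  N <- nrow(D2)
  K <- nlevels(groups)
  tot <- sum(D2[lower.tri(D2)]) / N
  within <- 0
  nk <- tabulate(groups)
  for (k in seq_len(K)) {
    idx <- which(as.integer(groups) == k)
    if (length(idx) > 1L) {
      sub <- D2[idx, idx, drop = FALSE]
      within <- within + sum(sub[lower.tri(sub)]) / length(idx)
    }
  }
  among <- tot - within
  n0 <- (N - sum(nk^2) / N) / (K - 1)
  sigma_w <- within / (N - K)
  sigma_a <- (among / (K - 1) - sigma_w) / n0
  phi <- if (sigma_a + sigma_w == 0) NA_real_ else
    sigma_a / (sigma_a + sigma_w)
  list(SSD_total = tot, SSD_among = among, SSD_within = within,
       df_among = K - 1, df_within = N - K,
       sigma_a = sigma_a, sigma_w = sigma_w, phi = phi)
}

#' Distance-based AMOVA
#'
#' One-level analysis of molecular variance on the missing-scaled
#' squared-Euclidean dosage distance: the squared distance between two
#' accessions is the sum of squared dosage differences over their shared
#' called loci, rescaled by total loci over shared loci. Sums of squared
#' deviations are partitioned among and within populations, variance
#' components follow the standard unbalanced-design coefficients, and
#' significance comes from permuting individuals among groups (group
#' sizes fixed) with the add-one rule.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap a [pop_map()] with K >= 2 groups.
#' @param n_permutations permutations for the p-value (default 999).
#' @param seed RNG seed.
#' @return object of class `amova_result`: list with `SSD_total`,
#'   `SSD_among`, `SSD_within`, `df_among`, `df_within`, `sigma_a`,
#'   `sigma_w`, `phi_st`, `percent_among`, `p_value`, `n_permutations`.
#' @export
amova <- function(gm, popmap, n_permutations = 999L, seed = 1L) {
  groups_idx <- .pop_indices(gm, popmap)
  if (length(groups_idx) < 2L) stop("need at least two groups")
  rows <- unlist(groups_idx, use.names = FALSE)
  N <- length(rows)
  if (N < length(groups_idx) + 1L) stop("need at least K+1 individuals")
  fac <- factor(rep(names(groups_idx), lengths(groups_idx)))
  if (any(lengths(groups_idx) == 1L)) {
    warning("group(s) of size 1 contribute no within-group distances")
  }
  D2 <- .amova_dist2(gm$dosage[rows, , drop = FALSE])
  obs <- .amova_from_dist(D2, fac)
  p_val <- NA_real_
  if (!is.na(obs$phi) && n_permutations > 0L) {
    set.seed(seed)
    ge <- 0L
    for (b in seq_len(n_permutations)) {
      perm <- .amova_from_dist(D2, sample(fac))
      if (!is.na(perm$phi) && perm$phi >= obs$phi) ge <- ge + 1L
    }
    p_val <- (1 + ge) / (1 + n_permutations)
  }
  pct <- if (is.na(obs$phi)) NA_real_ else 100 * obs$phi
  structure(c(obs, list(phi_st = obs$phi, percent_among = pct,
                        p_value = p_val,
                        n_permutations = as.integer(n_permutations))),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (missing-scaled squared-Euclidean dosage distance)\n")
  cat(sprintf("  SSD among: %.4f (df %d)   SSD within: %.4f (df %d)\n",
              x$SSD_among, x$df_among, x$SSD_within, x$df_within))
  cat(sprintf("  sigma2 among: %.4f   sigma2 within: %.4f\n",
              x$sigma_a, x$sigma_w))
  if (is.na(x$phi_st)) {
    cat("  Phi_ST undefined (no variance)\n")
  } else {
    cat(sprintf("  Phi_ST: %.4f   variance among groups: %.2f%%   p = %.4g\n",
                x$phi_st, x$percent_among, x$p_value))
  }
  invisible(x)
}

#' Principal component analysis of a genotype matrix
#'
#' Missing dosages are imputed with the per-marker mean, columns are
#' centred (no variance scaling), and scores come from the singular
#' value decomposition. Percent variance per component is the squared
#' singular value over the total.
#'
#' @param gm a [genotype_matrix()].
#' @param n_components number of components to return.
#' @return list of class `pca_result`: `scores` (accessions x
#'   components), `percent_variance` (all components), `n_components`.
#' @export
pca_genotypes <- function(gm, n_components = 10L) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$dosage) < 2L) stop("need at least two individuals")
  X <- gm$dosage
  storage.mode(X) <- "double"
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(is.na(X)) > 0L)) X[is.na(X[, j]), j] <- mu[j]
  X <- sweep(X, 2L, colMeans(X))
  sv <- svd(X)
  total <- sum(sv$d^2)
  if (total == 0) stop("zero-variance genotype matrix")
  pct <- 100 * sv$d^2 / total
  k <- min(n_components, length(sv$d))
  scores <- X %*% sv$v[, seq_len(k), drop = FALSE]
  rownames(scores) <- rownames(gm$dosage)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, percent_variance = pct,
                 n_components = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA of genotype matrix: %d components returned\n",
              x$n_components))
  cat("  percent variance:",
      paste(sprintf("%.2f", utils::head(x$percent_variance,
                                        x$n_components)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Great-circle distance matrix from coordinates
#'
#' Haversine distances in kilometres (Earth radius 6371 km).
#'
#' @param coords data.frame with `lat`, `lon` in decimal degrees (and
#'   optionally `accession` used for dimnames).
#' @return symmetric matrix of distances in km.
#' @export
geo_distance_km <- function(coords) {
  n <- nrow(coords)
  m <- matrix(0, n, n)
  pts <- cbind(coords$lon, coords$lat)
  for (i in seq_len(n)) {
    m[i, ] <- geosphere::distHaversine(pts[i, ], pts, r = 6371000) / 1000
  }
  if (!is.null(coords$accession)) {
    dimnames(m) <- list(coords$accession, coords$accession)
  }
  m
}

#' Mantel test of isolation by distance
#'
#' Pearson correlation between the strictly-lower-triangle entries of a
#' genetic and a geographic distance matrix; geographic distances are
#' haversine kilometres computed from the coordinates. Significance by
#' permuting the accession order of the genetic matrix (one-sided,
#' correlation at least the observed, add-one rule).
#'
#' @param genetic_distance square symmetric matrix, same accession order
#'   as `coords`.
#' @param coords data.frame with `lat` and `lon` per accession.
#' @param n_permutations permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r`, `p_value`, `n`, `n_permutations`.
#' @export
mantel_ibd <- function(genetic_distance, coords, n_permutations = 999L,
                       seed = 1L) {
  gd <- as.matrix(genetic_distance)
  n <- nrow(gd)
  if (n < 3L) stop("need at least 3 accessions")
  if (nrow(coords) != n) stop("coordinate rows must match matrix order")
  if (max(abs(gd - t(gd))) > 1e-8) stop("genetic distance must be symmetric")
  geo <- geo_distance_km(coords)
  lt <- lower.tri(gd)
  r_obs <- stats::cor(gd[lt], geo[lt])
  set.seed(seed)
  ge <- 0L
  for (b in seq_len(n_permutations)) {
    perm <- sample.int(n)
    r_perm <- stats::cor(gd[perm, perm][lt], geo[lt])
    if (r_perm >= r_obs) ge <- ge + 1L
  }
  list(r = r_obs, p_value = (1 + ge) / (1 + n_permutations), n = n,
       n_permutations = as.integer(n_permutations))
}

#' Allele-sharing genetic distance
#'
#' One minus the mean proportion of shared alleles over pairwise-complete
#' loci: per locus the shared fraction is `1 - |d_i - d_j| / 2`. The
#' package's default genetic-distance input for [mantel_ibd()].
#'
#' @param gm a [genotype_matrix()].
#' @return symmetric distance matrix with accession dimnames.
#' @export
allele_sharing_distance <- function(gm) {
  d <- gm$dosage
  n <- nrow(d)
  out <- matrix(0, n, n, dimnames = list(rownames(d), rownames(d)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      diff <- abs(d[i, ] - d[j, ])
      out[i, j] <- out[j, i] <- mean(diff, na.rm = TRUE) / 2
    }
  }
  out
}
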