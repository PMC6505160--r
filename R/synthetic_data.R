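# Seeded generators producing inputs with the statistical structure the
# analyses assume: Balding-Nichols structured genotypes with Dirichlet
# admixture, a founder-mosaic model for distance-decaying LD, a toy
# genome with planted restriction sites, and transect coordinates.
# Every generator takes an explicit seed; none falls back to the clock.

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}

# exponentially spaced marker positions over `n_chrom` chromosomes
.sim_positions <- function(n_loci, n_chrom, mean_spacing_bp) {
  chrom <- sort(rep_len(seq_len(n_chrom), n_loci))
  pos <- integer(n_loci)
  for (c in unique(chrom)) {
    sel <- chrom == c
    pos[sel] <- cumsum(1L + stats::rexp(sum(sel), 1 / mean_spacing_bp))
  }
  data.frame(chrom = sprintf("chr%02d", chrom), pos = as.integer(pos),
             ref = "A", alt = "G", stringsAsFactors = FALSE)
}

#' Simulate a structured, optionally admixed population
#'
#' Balding-Nichols model: ancestral allele frequencies are uniform on
#' (0.05, 0.95); each of K populations draws its frequency from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` so that F is the expected
#' differentiation; `F = 0` copies the ancestral frequencies exactly.
#' Individual ancestry is Dirichlet(`admixture_alpha`) when
#' `admixture_alpha > 0`, or single-population (unadmixed) when 0.
#' Genotypes are Binomial(2, sum_k q_k p_k) dosages; missingness is an
#' independent Bernoulli mask. Defaults emulate a wild-tomato diversity
#' panel: 3 ancestral populations, 33 accessions per population,
#' moderate admixture, strong differentiation (F = 0.4) and a 5.7%
#' missing-call rate.
#'
#' @param K number of ancestral populations.
#' @param F differentiation parameter in \[0, 1).
#' @param n_per_pop individuals per population.
#' @param n_loci number of biallelic markers.
#' @param admixture_alpha Dirichlet concentration (scalar or length K);
#'   0 = unadmixed.
#' @param missing_rate per-call missing probability.
#' @param n_chrom chromosomes markers are spread over.
#' @param mean_spacing_bp mean exponential marker spacing.
#' @param seed RNG seed (required).
#' @return list with `genotypes` ([genotype_matrix()]), `popmap`
#'   ([pop_map()] with ancestry fractions `q_POP*`), `pop_freqs`
#'   (K x L matrix) and `ancestral_freqs` (length L).
#' @export
simulate_structured_population <- function(K = 3L, F = 0.4,
                                           n_per_pop = 33L, n_loci = 1000L,
                                           admixture_alpha = 0.3,
                                           missing_rate = 0.057,
                                           n_chrom = 12L,
                                           mean_spacing_bp = 35000,
                                           seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(K >= 1L, F >= 0, F < 1, n_per_pop >= 1L, n_loci >= 1L,
            missing_rate >= 0, missing_rate < 1)
  set.seed(seed)
  L <- n_loci
  N <- K * n_per_pop
  p_anc <- stats::runif(L, 0.05, 0.95)
  if (F == 0) {
    pop_freqs <- matrix(rep(p_anc, each = K), nrow = K)
  } else {
    pop_freqs <- matrix(stats::rbeta(K * L,
                                     rep(p_anc, each = K) * (1 - F) / F,
                                     rep(1 - p_anc, each = K) * (1 - F) / F),
                        nrow = K)
  }
  pops <- paste0("POP", seq_len(K))
  if (length(admixture_alpha) == 1L && admixture_alpha == 0) {
    q <- matrix(0, N, K)
    q[cbind(seq_len(N), rep(seq_len(K), each = n_per_pop))] <- 1
  } else {
    alpha <- rep_len(admixture_alpha, K)
    # bias each individual toward its home population so single- and
    # mixed-ancestry groups both occur
    q <- matrix(0, N, K)
    for (k in seq_len(K)) {
      rows <- (k - 1L) * n_per_pop + seq_len(n_per_pop)
      a <- alpha; a[k] <- a[k] + 1
      q[rows, ] <- .rdirichlet(n_per_pop, a)
    }
  }
  mix <- q %*% pop_freqs                      # N x L expected frequency
  dose <- matrix(stats::rbinom(N * L, 2L, as.vector(mix)), N, L)
  if (missing_rate > 0) {
    dose[stats::runif(N * L) < missing_rate] <- NA_integer_
  }
  label <- pops[max.col(q, ties.method = "first")]
  acc <- sprintf("ACC%03d", seq_len(N))
  rownames(dose) <- acc
  markers <- .sim_positions(L, n_chrom, mean_spacing_bp)
  # generated columns follow marker order after the constructor sort
  ord <- order(markers$chrom, markers$pos)
  gm <- genotype_matrix(dose[, ord, drop = FALSE], markers[ord, ])
  pm <- data.frame(accession = acc, pop = label, stringsAsFactors = FALSE)
  qdf <- as.data.frame(q)
  names(qdf) <- paste0("q_", pops)
  pm <- pop_map(cbind(pm, qdf), gm = gm)
  list(genotypes = gm, popmap = pm,
       pop_freqs = pop_freqs[, ord, drop = FALSE],
       ancestral_freqs = p_anc[ord])
}

#' Simulate genotypes with distance-decaying LD
#'
#' Founder-mosaic (haplotype-pool) model: M founder haplotypes are drawn
#' site-wise from the population allele frequencies; each gamete copies
#' from one founder and switches to a random founder between adjacent
#' markers with probability `1 - exp(-switch_rate * spacing)`. Two
#' gametes per individual give the dosage. LD arises from the finite
#' founder pool and decays with distance as founder identity is lost;
#' the default 3e-6 switches per bp puts the fitted decay distance at
#' baseline r2 = 0.1 in the 15-25 kb range, the rapid-decay regime of a
#' partially-outcrossing wild population. The model is
#' phenomenological: the fitted decay parameter is not analytically
#' tied to `switch_rate`.
#'
#' @param n_ind individuals.
#' @param n_loci markers on one chromosome.
#' @param M founder haplotypes (>= 2).
#' @param switch_rate founder-switch rate per bp (> 0).
#' @param mean_spacing_bp mean exponential marker spacing.
#' @param missing_rate per-call missing probability.
#' @param seed RNG seed (required).
#' @return a [genotype_matrix()] (single chromosome `chr01`).
#' @export
simulate_ld_genotypes <- function(n_ind = 98L, n_loci = 300L, M = 10L,
                                  switch_rate = 3e-6,
                                  mean_spacing_bp = 2000,
                                  missing_rate = 0, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(M >= 2L, switch_rate > 0, n_loci >= 2L)
  set.seed(seed)
  L <- n_loci
  pos <- as.integer(cumsum(1L + stats::rexp(L, 1 / mean_spacing_bp)))
  p <- stats::runif(L, 0.1, 0.9)
  founders <- matrix(stats::rbinom(M * L, 1L, rep(p, each = M)), M, L)
  spacing <- diff(pos)
  switch_prob <- 1 - exp(-switch_rate * spacing)
  gamete <- function() {
    sw <- c(TRUE, stats::runif(L - 1L) < switch_prob)
    seg <- cumsum(sw)
    pick <- sample.int(M, max(seg), replace = TRUE)
    founders[cbind(pick[seg], seq_len(L))]
  }
  dose <- matrix(0L, n_ind, L)
  for (i in seq_len(n_ind)) dose[i, ] <- gamete() + gamete()
  if (missing_rate > 0) {
    dose[stats::runif(n_ind * L) < missing_rate] <- NA_integer_
  }
  rownames(dose) <- sprintf("ACC%03d", seq_len(n_ind))
  markers <- data.frame(chrom = "chr01", pos = pos, ref = "A", alt = "G",
                        stringsAsFactors = FALSE)
  genotype_matrix(dose, markers)
}

#' Simulate a toy genome fixture for RAD design
#'
#' Random background sequence per chromosome with restriction-motif
#' occurrences planted at recorded positions; a central heterochromatin
#' block on each chromosome; gene intervals placed preferentially in the
#' euchromatic arms at a stated enrichment. Ground truth comes from a
#' construction-time plain-text scan of the final sequence (independent
#' of the digestion code), so digestion, classification and overlap
#' counts can be checked exactly.
#'
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param motif restriction motif to plant (default CTGCAG).
#' @param sites_per_chrom motif occurrences planted per chromosome.
#' @param het_fraction fraction of each chromosome covered by the
#'   central heterochromatin block.
#' @param genes_per_chrom gene intervals per chromosome.
#' @param gene_length gene interval length in bp.
#' @param eu_gene_enrichment relative density of genes in euchromatin vs
#'   heterochromatin (default 4).
#' @param seed RNG seed (required).
#' @param dir if non-NULL, write `genome.fa`, `genes.gff3`, `het.bed`
#'   there and include the paths in the result.
#' @return list with `sequences` ([Biostrings::DNAStringSet]), `sites`
#'   (ground-truth cut-site data.frame with true `region_class`),
#'   `annotation` ([genome_annotation()]) and (if written) `paths`.
#' @export
simulate_genome_fixture <- function(chrom_lengths = c(chr01 = 120000L,
                                                      chr02 = 90000L),
                                    motif = "CTGCAG",
                                    sites_per_chrom = 40L,
                                    het_fraction = 0.3,
                                    genes_per_chrom = 30L,
                                    gene_length = 1500L,
                                    eu_gene_enrichment = 4,
                                    seed, dir = NULL) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  m <- nchar(motif)
  seqs <- character(length(chrom_lengths))
  het <- NULL; genes <- NULL; truth <- NULL
  for (k in seq_along(chrom_lengths)) {
    chr <- names(chrom_lengths)[k]
    len <- chrom_lengths[k]
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
               collapse = "")
    plant <- sort(sample.int(len - m, sites_per_chrom))
    # keep planted motifs non-overlapping
    plant <- plant[c(TRUE, diff(plant) >= m)]
    for (p in plant) substr(s, p, p + m - 1L) <- motif
    seqs[k] <- s
    # ground truth by construction scan of the final sequence
    hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
    hits <- if (hits[1] == -1L) integer(0) else as.integer(hits)
    het_start <- as.integer(len * (0.5 - het_fraction / 2)) + 1L
    het_end <- as.integer(len * (0.5 + het_fraction / 2))
    het <- rbind(het, data.frame(chrom = chr, start = het_start,
                                 end = het_end, stringsAsFactors = FALSE))
    truth <- rbind(truth, data.frame(
      chrom = chr, motif_start = hits,
      region_class = ifelse(hits >= het_start & hits <= het_end,
                            "heterochromatin", "euchromatin"),
      stringsAsFactors = FALSE))
    # genes: euchromatic arms sampled eu_gene_enrichment times as often
    g_start <- integer(genes_per_chrom)
    for (g in seq_len(genes_per_chrom)) {
      in_het <- stats::runif(1) < het_fraction /
        (het_fraction + eu_gene_enrichment * (1 - het_fraction))
      rng <- if (in_het) c(het_start, het_end - gene_length) else
        if (stats::runif(1) < 0.5) c(1L, het_start - gene_length) else
          c(het_end + 1L, len - gene_length)
      g_start[g] <- sample(seq(rng[1], max(rng[1], rng[2])), 1L)
    }
    g_start <- sort(g_start)
    genes <- rbind(genes, data.frame(
      chrom = chr, start = g_start, end = g_start + gene_length - 1L,
      gene_id = sprintf("%s_g%03d", chr, seq_len(genes_per_chrom)),
      stringsAsFactors = FALSE))
  }
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(chrom_lengths)
  ann <- genome_annotation(genes, het)
  out <- list(sequences = dna, sites = truth, annotation = ann)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fa <- file.path(dir, "genome.fa")
    gff <- file.path(dir, "genes.gff3")
    bed <- file.path(dir, "het.bed")
    Biostrings::writeXStringSet(dna, fa)
    writeLines(c("##gff-version 3",
                 sprintf("%s\tradpop\tgene\t%d\t%d\t.\t+\t.\tID=%s",
                         genes$chrom, genes$start, genes$end,
                         genes$gene_id)), gff)
    utils::write.table(data.frame(het$chrom, het$start - 1L, het$end),
                       bed, sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    out$paths <- c(fasta = fa, gff = gff, het_bed = bed)
  }
  out
}

#' Simulate geographic coordinates with isolation by distance
#'
#' Population centroids are placed along a north-south transect (the
#' Andean-coast layout of the emulated collection), with inter-centroid
#' spacing proportional to `divergence`; individuals are jittered around
#' their centroid with Gaussian noise, so genetic and geographic
#' distance correlate positively by construction.
#'
#' @param popmap a [pop_map()].
#' @param divergence optional per-population numeric controlling
#'   centroid spacing (defaults to equal spacing).
#' @param lat_range latitude range of the transect (decimal degrees).
#' @param lon_range longitude range of the transect.
#' @param jitter_sd_deg per-individual Gaussian jitter (degrees).
#' @param seed RNG seed (required).
#' @return `popmap` with `lat` and `lon` columns filled.
#' @export
simulate_coordinates <- function(popmap, divergence = NULL,
                                 lat_range = c(0, -17),
                                 lon_range = c(-80, -70),
                                 jitter_sd_deg = 0.3, seed) {
  if (missing(seed)) stop("seed is required")
  set.seed(seed)
  pops <- sort(unique(popmap$pop))
  K <- length(pops)
  w <- if (is.null(divergence)) rep(1, K) else rep_len(divergence, K)
  at <- c(0, cumsum(w[-1]))
  at <- if (max(at) == 0) rep(0.5, K) else at / max(at)
  cen_lat <- lat_range[1] + at * diff(lat_range)
  cen_lon <- lon_range[1] + at * diff(lon_range)
  idx <- match(popmap$pop, pops)
  popmap$lat <- cen_lat[idx] +
    stats::rnorm(nrow(popmap), 0, jitter_sd_deg)
  popmap$lon <- cen_lon[idx] +
    stats::rnorm(nrow(popmap), 0, jitter_sd_deg)
  popmap
}

#' Write a population map
#'
#' @param popmap a [pop_map()].
#' @param path output file (tab-separated, header included).
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(popmap, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
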