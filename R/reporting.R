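# Headline-ratio formatting and the end-to-end pipeline driver.

# half-up rounding (R's round() is round-half-even); non-negative inputs
.round_half_up <- function(x, digits = 2L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Headline percentage
#'
#' `100 * numerator / denominator`, rounded half-up to two decimals --
#' the convention used for every reported ratio (e.g. SNPs in gene
#' regions over all SNPs).
#'
#' @param numerator,denominator non-negative integers with
#'   `numerator <= denominator`, `denominator > 0`.
#' @param label optional label attached as an attribute.
#' @return percentage as a bare numeric.
#' @export
proportion_report <- function(numerator, denominator, label = NULL) {
  if (denominator <= 0) stop("denominator must be positive")
  if (numerator > denominator) stop("numerator must be <= denominator")
  if (numerator < 0) stop("numerator must be non-negative")
  out <- .round_half_up(100 * numerator / denominator, 2L)
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Run the full analysis pipeline
#'
#' Orchestrates the package in the order of the emulated study: read
#' genotypes and population map; digest the reference (when a FASTA is
#' given), classify sites against the annotation and build sequencing
#' units; apply presence and MAF filters; prune within-unit redundant
#' SNPs; compute the diversity table, pairwise Fst, AMOVA and PCA;
#' compute windowed LD, the decay fit and the local LD profile; run the
#' Mantel isolation-by-distance test when coordinates are present. All
#' randomness flows from `seed`; inputs are never mutated; every table
#' is written tab-separated with headers, alongside a key=value config
#' echo and a run log recording marker counts surviving each stage.
#'
#' @param config named list: `genotypes` (path), `popmap` (path),
#'   optional `fasta`, `gff`, `het_bed`, and parameters `out_dir`,
#'   `seed` (default 1), `motif` ("CTGCAG"), `read_span` (93),
#'   `min_presence` (75/99), `min_maf` (0.05), `window_bp` (1e6),
#'   `baseline` (0.1), `n_permutations` (999), `n_boot` (1000).
#' @return invisibly, a list with the in-memory results; files are
#'   written under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(seed = 1L, motif = "CTGCAG", read_span = 93L,
                   min_presence = 75 / 99, min_maf = 0.05,
                   window_bp = 1e6, baseline = 0.1,
                   n_permutations = 999L, n_boot = 1000L)
  config <- utils::modifyList(defaults, config)
  for (key in c("genotypes", "popmap", "out_dir")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  }
  for (key in c("genotypes", "popmap", "fasta", "gff", "het_bed")) {
    p <- config[[key]]
    if (!is.null(p) && !file.exists(p)) {
      stop("input file for '", key, "' does not exist: ", p)
    }
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out_path <- function(f) file.path(config$out_dir, f)
  log_lines <- c(sprintf("radpop %s", as.character(utils::packageVersion("radpop"))),
                 sprintf("seed: %d", config$seed))
  tsv <- function(x, f) utils::write.table(x, out_path(f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)

  gm <- read_genotypes(config$genotypes)
  pm <- read_popmap(config$popmap, gm = gm)
  log_lines <- c(log_lines, sprintf("input markers: %d", ncol(gm$dosage)))

  ann <- NULL
  if (!is.null(config$gff) || !is.null(config$het_bed)) {
    ann <- read_annotation(config$gff, config$het_bed)
  }

  # stage 1: presence + MAF filters
  filt <- filter_markers(gm, filter_config(config$min_presence,
                                           config$min_maf))
  gm_f <- filt$genotypes
  counts <- attr(filt$log, "stage_counts")
  log_lines <- c(log_lines,
                 sprintf("after presence filter: %d", counts["after_presence"]),
                 sprintf("after MAF filter: %d", counts["after_maf"]))
  tsv(filt$log, "filter_log.tsv")

  # stage 2: digestion, units, redundancy pruning, overlap report
  units <- NULL
  gm_p <- gm_f
  results <- list(genotypes = gm_f)
  if (!is.null(config$fasta)) {
    sites <- digest_genome(config$fasta, config$motif)
    if (!is.null(ann)) {
      cl <- classify_sites(sites, ann)
      sites <- cl$sites
      tsv(data.frame(class = names(cl$counts), n = as.integer(cl$counts),
                     pct = vapply(unname(cl$counts), proportion_report,
                                  numeric(1), denominator = sum(cl$counts))),
          "site_classes.tsv")
    }
    bu <- build_units(sites, gm_f$markers, config$read_span)
    units <- bu$units
    gm_f$markers$unit_id <- bu$markers$unit_id
    pruned <- prune_redundant(gm_f)
    gm_p <- pruned$genotypes
    log_lines <- c(log_lines,
                   sprintf("sequencing units: %d", nrow(units)),
                   sprintf("after redundancy pruning: %d", ncol(gm_p$dosage)))
    tsv(units, "units.tsv")
    if (!is.null(ann)) {
      tsv(overlap_report(units, gm_f$markers, ann), "overlap_report.tsv")
    }
    results$units <- units
    results$genotypes_pruned <- gm_p
  }

  # stage 3: diversity and differentiation
  div <- diversity_table(gm_f, pm)
  tsv(div, "diversity.tsv")
  fst <- pairwise_fst(gm_f, pm, n_boot = config$n_boot, seed = config$seed)
  utils::write.table(cbind(pop = rownames(fst$theta), round(fst$theta, 6)),
                     out_path("fst_matrix.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  am <- amova(gm_f, pm, n_permutations = config$n_permutations,
              seed = config$seed)
  tsv(data.frame(statistic = c("SSD_among", "SSD_within", "SSD_total",
                               "df_among", "df_within", "sigma2_among",
                               "sigma2_within", "phi_st", "percent_among",
                               "p_value"),
                 value = c(am$SSD_among, am$SSD_within, am$SSD_total,
                           am$df_among, am$df_within, am$sigma_a,
                           am$sigma_w, am$phi_st, am$percent_among,
                           am$p_value)),
      "amova.tsv")
  pca <- pca_genotypes(gm_p, n_components = 10L)
  tsv(data.frame(component = seq_along(pca$percent_variance),
                 percent_variance = pca$percent_variance), "pca_variance.tsv")
  results <- c(results, list(diversity = div, fst = fst, amova = am,
                             pca = pca))

  # stage 4: LD
  pairs <- windowed_ld(gm_f, config$window_bp)
  tsv(data.frame(CHR_A = pairs$chrom, BP_A = pairs$pos_i,
                 CHR_B = pairs$chrom, BP_B = pairs$pos_j, R2 = pairs$r2),
      "ld_pairs.tsv")
  decay <- NULL
  if (nrow(pairs) >= 10L) {
    decay <- fit_decay(pairs, n = ld_sample_size(pairs),
                       baseline = config$baseline)
    tsv(data.frame(rho = decay$rho, n = decay$n,
                   baseline = decay$baseline,
                   decay_distance_bp = decay$decay_distance_bp,
                   mode = decay$mode), "ld_decay.tsv")
  }
  local <- NULL
  if (!is.null(units) && nrow(units) > 1L) {
    local <- local_ld_profile(gm_f, units, baseline = config$baseline)
    tsv(local$profile, "local_ld_profile.tsv")
    tsv(local$summary, "local_ld_summary.tsv")
  }
  results <- c(results, list(ld_pairs = pairs, decay = decay,
                             local_ld = local))

  # stage 5: isolation by distance (needs coordinates)
  if (all(c("lat", "lon") %in% names(pm)) && !anyNA(pm$lat) &&
      nrow(pm) >= 3L) {
    ord <- match(rownames(gm_f$dosage), pm$accession)
    coords <- pm[ord, , drop = FALSE]
    ibd <- mantel_ibd(allele_sharing_distance(gm_f), coords,
                      n_permutations = config$n_permutations,
                      seed = config$seed)
    tsv(data.frame(r = ibd$r, p_value = ibd$p_value, n = ibd$n), "ibd.tsv")
    results$ibd <- ibd
  }

  writeLines(sprintf("%s=%s", names(config),
                     vapply(config, function(v) paste(format(v), collapse = ","),
                            character(1))),
             out_path("config_echo.txt"))
  writeLines(log_lines, out_path("run_log.txt"))
  invisible(results)
}
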