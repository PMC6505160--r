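#' Filter configuration
#'
#' Defaults mirror the study design this package reproduces: a marker
#' must be called in at least 75 of 99 accessions (presence fraction
#' 75/99), have minor allele frequency at least 0.05, and within-unit
#' redundancy is pruned at complete LD (r2 = 1).
#'
#' @param min_presence_fraction minimum fraction of accessions with a
#'   called genotype, in (0, 1].
#' @param min_maf minimum minor allele frequency, in \[0, 0.5).
#' @param redundancy_r2 r2 at or above which two SNPs in one sequencing
#'   unit are redundant (default 1, i.e. complete LD).
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_presence_fraction = 75 / 99,
                          min_maf = 0.05,
                          redundancy_r2 = 1.0) {
  stopifnot(min_presence_fraction > 0, min_presence_fraction <= 1,
            min_maf >= 0, min_maf < 0.5, redundancy_r2 > 0)
  structure(list(min_presence_fraction = min_presence_fraction,
                 min_maf = min_maf, redundancy_r2 = redundancy_r2),
            class = "filter_config")
}

#' Alternate-allele frequency at a marker
#'
#' @param gm a [genotype_matrix()].
#' @param marker_index marker column index (vectorised).
#' @return data.frame with `alt_freq` (sum of dosages over twice the
#'   called count; `NA` when no genotype is called), `n_called`, `maf`.
#' @export
allele_frequency <- function(gm, marker_index = seq_len(ncol(gm$dosage))) {
  d <- gm$dosage[, marker_index, drop = FALSE]
  n_called <- colSums(!is.na(d))
  alt <- colSums(d, na.rm = TRUE)
  alt_freq <- ifelse(n_called > 0, alt / (2 * n_called), NA_real_)
  data.frame(alt_freq = alt_freq, n_called = n_called,
             maf = pmin(alt_freq, 1 - alt_freq))
}

#' Presence and MAF filters
#'
#' Keeps a marker iff its call fraction is at least
#' `min_presence_fraction` and its minor allele frequency at least
#' `min_maf` (both boundaries inclusive). Marker order is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param config a [filter_config()].
#' @return list with `genotypes` (the filtered matrix) and `log`
#'   (data.frame `chrom`, `pos`, `stage`, `reason` for every dropped
#'   marker, plus a `stage_counts` attribute with marker counts before
#'   filtering, after the presence filter and after the MAF filter).
#' @export
filter_markers <- function(gm, config = filter_config()) {
  stopifnot(inherits(gm, "genotype_matrix"))
  N <- nrow(gm$dosage)
  af <- allele_frequency(gm)
  presence_ok <- af$n_called / N >= config$min_presence_fraction
  maf_ok <- !is.na(af$maf) & af$maf >= config$min_maf
  keep <- presence_ok & maf_ok
  stage <- ifelse(!presence_ok, "presence",
                  ifelse(!maf_ok, "maf", NA_character_))
  reason <- ifelse(!presence_ok,
                   sprintf("called %d/%d < %.4f", af$n_called, N,
                           config$min_presence_fraction),
                   ifelse(!maf_ok,
                          sprintf("MAF %.4f < %.4f", af$maf, config$min_maf),
                          NA_character_))
  log <- data.frame(chrom = gm$markers$chrom[!keep],
                    pos = gm$markers$pos[!keep],
                    stage = stage[!keep], reason = reason[!keep],
                    stringsAsFactors = FALSE)
  attr(log, "stage_counts") <- c(input = ncol(gm$dosage),
                                 after_presence = sum(presence_ok),
                                 after_maf = sum(keep))
  if (!any(keep)) warning("no markers survive filtering")
  list(genotypes = gm[, keep], log = log)
}

#' Prune redundant SNPs within sequencing units
#'
#' Within each sequencing unit, SNPs are scanned in ascending position;
#' a SNP is dropped iff it is in complete LD (r2 = 1, within 1e-9)
#' with any already-retained SNP of the same unit, so the first SNP of a
#' unit is always kept. r2 comes from [r2_pair()] on pairwise-complete
#' observations. SNPs without a unit assignment are retained; SNPs in
#' different units are never compared.
#'
#' @param gm a [genotype_matrix()] whose markers carry `unit_id` (from
#'   [build_units()]).
#' @param redundancy_r2 threshold treated as complete LD (default 1).
#' @param tol numeric tolerance around the threshold.
#' @return list with `genotypes` (pruned matrix) and `kept` (data.frame
#'   `unit_id`, `n_in`, `n_kept`).
#' @export
prune_redundant <- function(gm, redundancy_r2 = 1.0, tol = 1e-9) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  keep <- rep(TRUE, nrow(mk))
  unit_ids <- sort(unique(mk$unit_id[!is.na(mk$unit_id)]))
  kept_log <- data.frame(unit_id = unit_ids, n_in = 0L, n_kept = 0L)
  for (u in seq_along(unit_ids)) {
    idx <- which(mk$unit_id == unit_ids[u])
    idx <- idx[order(mk$pos[idx])]
    kept_log$n_in[u] <- length(idx)
    if (length(idx) < 2L) {
      kept_log$n_kept[u] <- length(idx)
      next
    }
    retained <- idx[1L]
    for (i in idx[-1L]) {
      r2 <- vapply(retained, function(j)
        r2_pair(gm$dosage[, i], gm$dosage[, j]), numeric(1))
      r2 <- r2[!is.na(r2)]
      if (length(r2) && any(r2 >= redundancy_r2 - tol)) {
        keep[i] <- FALSE
      } else {
        retained <- c(retained, i)
      }
    }
    kept_log$n_kept[u] <- sum(keep[idx])
  }
  list(genotypes = gm[, keep], kept = kept_log)
}

#' Per-accession missingness
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame `accession`, `missing_fraction`, with the overall
#'   mean as attribute `mean_missing`.
#' @export
missingness_report <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  frac <- rowMeans(is.na(gm$dosage))
  out <- data.frame(accession = rownames(gm$dosage),
                    missing_fraction = as.numeric(frac),
                    stringsAsFactors = FALSE)
  attr(out, "mean_missing") <- mean(frac)
  out
}
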