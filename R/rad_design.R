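#' In-silico restriction digestion of a genome
#'
#' Scans the forward strand of each sequence for exact occurrences of a
#' restriction motif. For palindromic motifs (e.g. PstI's CTGCAG, its own
#' reverse complement) the forward scan is complete. Overlapping
#' occurrences are all reported. Sequences are upper-cased before the
#' scan and IUPAC ambiguity codes never match.
#'
#' @param fasta path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param motif recognition sequence over A/C/G/T (default PstI, CTGCAG).
#' @return data.frame of cut sites: `chrom`, `motif_start` (1-based
#'   position of the first motif base) and `region_class`
#'   (`NA` until [classify_sites()] is applied).
#' @examples
#' seqs <- Biostrings::DNAStringSet(c(chrA = "AAACTGCAGAAA"))
#' digest_genome(seqs)
#' @export
digest_genome <- function(fasta, motif = "CTGCAG") {
  if (!is.character(motif) || length(motif) != 1L || nchar(motif) == 0L) {
    stop("motif must be a single non-empty string")
  }
  if (grepl("[^ACGTacgt]", motif)) {
    stop("motif must contain only A, C, G, T")
  }
  seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
    Biostrings::readDNAStringSet(fasta)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  # fixed = TRUE: ambiguity codes in the subject never match the motif
  hits <- Biostrings::vmatchPattern(toupper(motif),
                                    Biostrings::DNAStringSet(toupper(seqs)),
                                    fixed = TRUE)
  starts <- lapply(hits, Biostrings::start)
  n <- lengths(starts)
  data.frame(chrom = rep(names(seqs), n),
             motif_start = unlist(starts, use.names = FALSE),
             region_class = rep(NA_character_, sum(n)),
             stringsAsFactors = FALSE)
}

#' Classify cut sites as euchromatic or heterochromatic
#'
#' A site is heterochromatic iff its `motif_start` falls inside any
#' heterochromatin interval (1-based inclusive); every other site is
#' euchromatic. Sites on chromosomes absent from the annotation are
#' classified euchromatic with a warning.
#'
#' @param sites data.frame from [digest_genome()].
#' @param annotation a [genome_annotation()].
#' @return list with `sites` (the input with `region_class` filled) and
#'   `counts` (named vector: euchromatin, heterochromatin).
#' @export
classify_sites <- function(sites, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  het <- annotation$heterochromatin
  known <- unique(c(annotation$genes$chrom, het$chrom))
  orphan <- setdiff(unique(sites$chrom), known)
  if (length(orphan) && length(known)) {
    warning("chromosome(s) absent from annotation, classified euchromatic: ",
            paste(orphan, collapse = ", "))
  }
  cls <- rep("euchromatin", nrow(sites))
  for (chr in intersect(unique(sites$chrom), unique(het$chrom))) {
    sel <- sites$chrom == chr
    h <- het[het$chrom == chr, , drop = FALSE]
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(sites$motif_start[sel], width = 1L),
      IRanges::IRanges(h$start, h$end))
    inside <- unique(S4Vectors::queryHits(ov))
    cls[which(sel)[inside]] <- "heterochromatin"
  }
  sites$region_class <- cls
  counts <- c(euchromatin = sum(cls == "euchromatin"),
              heterochromatin = sum(cls == "heterochromatin"))
  list(sites = sites, counts = counts)
}

#' Build sequencing units around cut sites
#'
#' A sequencing unit is the genomic interval captured by single-end reads
#' on both sides of a restriction site: `[motif_start - read_span,
#' motif_start + read_span]` (186 bp for the default 93 bp span), kept
#' only when it contains at least one SNP. Each SNP is assigned to the
#' nearest cut site whose interval contains it; ties go to the left
#' (lower-coordinate) site. SNPs covered by no interval stay unit-less.
#'
#' @param sites cut-site data.frame from [digest_genome()].
#' @param markers marker data.frame (`chrom`, `pos`, ...), sorted by
#'   (chrom, pos) as in a [genotype_matrix()].
#' @param read_span bases captured on each side of the motif start
#'   (default 93).
#' @return list with `units` (data.frame `unit_id`, `chrom`, `cut_pos`,
#'   `start`, `end`, `n_snps`), `markers` (input with `unit_id` filled)
#'   and `unassigned` (row indices of markers in no unit).
#' @export
build_units <- function(sites, markers, read_span = 93L) {
  stopifnot(read_span > 0)
  markers <- as.data.frame(markers)
  markers$unit_id <- NA_integer_
  site_key <- rep(NA_integer_, nrow(markers))  # row index into 'sites'
  for (chr in unique(markers$chrom)) {
    msel <- which(markers$chrom == chr)
    srows <- which(sites$chrom == chr)
    if (!length(srows)) next
    cuts <- sites$motif_start[srows]
    o <- order(cuts)
    srows <- srows[o]; cuts <- cuts[o]
    pos <- markers$pos[msel]
    left <- findInterval(pos, cuts)          # nearest cut at or below pos
    right <- left + 1L
    dl <- ifelse(left >= 1L, pos - cuts[pmax(left, 1L)], Inf)
    dr <- ifelse(right <= length(cuts), cuts[pmin(right, length(cuts))] - pos, Inf)
    dl[dl > read_span] <- Inf
    dr[dr > read_span] <- Inf
    pick <- ifelse(is.infinite(dl) & is.infinite(dr), NA_integer_,
                   ifelse(dl <= dr, left, right))  # tie -> left site
    ok <- !is.na(pick)
    site_key[msel[ok]] <- srows[pick[ok]]
  }
  used <- sort(unique(site_key[!is.na(site_key)]))
  if (length(used)) {
    units <- data.frame(chrom = sites$chrom[used],
                        cut_pos = sites$motif_start[used],
                        stringsAsFactors = FALSE)
    ord <- order(units$chrom, units$cut_pos)
    units <- units[ord, , drop = FALSE]
    used <- used[ord]
    units$unit_id <- seq_len(nrow(units))
    units$start <- pmax(1L, units$cut_pos - as.integer(read_span))
    units$end <- units$cut_pos + as.integer(read_span)
    units$n_snps <- as.integer(table(factor(site_key, levels = used)))
    markers$unit_id <- units$unit_id[match(site_key, used)]
    units <- units[c("unit_id", "chrom", "cut_pos", "start", "end", "n_snps")]
    rownames(units) <- NULL
  } else {
    units <- data.frame(unit_id = integer(), chrom = character(),
                        cut_pos = integer(), start = integer(),
                        end = integer(), n_snps = integer(),
                        stringsAsFactors = FALSE)
  }
  list(units = units, markers = markers,
       unassigned = which(is.na(markers$unit_id)))
}

#' Marker / gene overlap summary per chromosome
#'
#' Counts, per chromosome and in total: SNPs; genes whose interval
#' intersects at least one sequencing unit ("genes in sequenced
#' regions"); genes containing at least one SNP; and SNPs falling inside
#' at least one gene interval. A gene counts as sequenced at >= 1 bp of
#' overlap with a unit.
#'
#' @param units unit data.frame from [build_units()].
#' @param markers marker data.frame (`chrom`, `pos`).
#' @param annotation a [genome_annotation()] with a gene track.
#' @return data.frame with one row per chromosome plus a `Total` row;
#'   columns `chrom`, `snps`, `genes_in_sequenced_regions`,
#'   `genes_with_snps`, `snps_in_gene_regions`.
#' @export
overlap_report <- function(units, markers, annotation) {
  stopifnot(inherits(annotation, "genome_annotation"))
  genes <- annotation$genes
  chroms <- sort(unique(c(markers$chrom, units$chrom)))
  out <- data.frame(chrom = chroms, snps = 0L,
                    genes_in_sequenced_regions = 0L, genes_with_snps = 0L,
                    snps_in_gene_regions = 0L, stringsAsFactors = FALSE)
  for (k in seq_along(chroms)) {
    chr <- chroms[k]
    m <- markers[markers$chrom == chr, , drop = FALSE]
    u <- units[units$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    out$snps[k] <- nrow(m)
    if (nrow(g)) {
      gr <- IRanges::IRanges(g$start, g$end)
      if (nrow(u)) {
        ov <- IRanges::findOverlaps(gr, IRanges::IRanges(u$start, u$end))
        out$genes_in_sequenced_regions[k] <-
          length(unique(S4Vectors::queryHits(ov)))
      }
      if (nrow(m)) {
        ov <- IRanges::findOverlaps(gr, IRanges::IRanges(m$pos, width = 1L))
        out$genes_with_snps[k] <- length(unique(S4Vectors::queryHits(ov)))
        out$snps_in_gene_regions[k] <-
          length(unique(S4Vectors::subjectHits(ov)))
      }
    }
  }
  total <- data.frame(chrom = "Total", snps = sum(out$snps),
                      genes_in_sequenced_regions =
                        sum(out$genes_in_sequenced_regions),
                      genes_with_snps = sum(out$genes_with_snps),
                      snps_in_gene_regions = sum(out$snps_in_gene_regions),
                      stringsAsFactors = FALSE)
  rbind(out, total)
}

#' Write cut sites or units as BED
#'
#' Intervals are emitted 0-based half-open per the BED convention.
#'
#' @param x cut-site data.frame (`chrom`, `motif_start`) or unit
#'   data.frame (`chrom`, `start`, `end`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_intervals_bed <- function(x, path) {
  if ("motif_start" %in% names(x)) {
    bed <- data.frame(x$chrom, x$motif_start - 1L, x$motif_start)
  } else {
    bed <- data.frame(x$chrom, x$start - 1L, x$end)
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
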