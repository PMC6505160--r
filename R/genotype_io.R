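#' Construct a genotype matrix
#'
#' The central data object of the package: a biallelic SNP genotype table
#' stored as alt-allele dosages (0, 1, 2) with `NA` for missing calls,
#' together with marker metadata. Markers are kept sorted by
#' (chromosome, position); all coordinates are 1-based reference
#' coordinates.
#'
#' @param dosage numeric or integer matrix, accessions in rows and markers
#'   in columns. Every non-missing value must be exactly 0, 1 or 2;
#'   missing genotypes are `NA`.
#' @param markers data.frame with one row per marker and columns `chrom`
#'   (character), `pos` (integer, 1-based), `ref`, `alt` (single
#'   characters, distinct). An optional `unit_id` column records the
#'   sequencing unit assigned by [build_units()].
#' @param accession_ids character vector of unique accession identifiers;
#'   defaults to `rownames(dosage)`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` (integer matrix with accession rownames) and `markers`.
#' @seealso [read_genotypes()], [write_genotypes()]
#' @export
genotype_matrix <- function(dosage, markers, accession_ids = rownames(dosage)) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = length(accession_ids))
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(accession_ids)) {
    accession_ids <- sprintf("ACC%d", seq_len(nrow(dosage)))
  }
  accession_ids <- as.character(accession_ids)
  if (anyDuplicated(accession_ids)) stop("accession ids must be unique")
  if (nrow(dosage) != length(accession_ids)) {
    stop("nrow(dosage) must equal the number of accessions")
  }
  markers <- as.data.frame(markers)
  required <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(markers))
  if (length(missing_cols)) {
    stop("markers is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (ncol(dosage) != nrow(markers)) {
    stop("ncol(dosage) must equal nrow(markers)")
  }
  markers$chrom <- as.character(markers$chrom)
  markers$pos <- as.integer(markers$pos)
  markers$ref <- as.character(markers$ref)
  markers$alt <- as.character(markers$alt)
  if (is.null(markers$unit_id)) {
    markers$unit_id <- rep(NA_integer_, nrow(markers))
  }
  if (nrow(markers)) {
    if (any(markers$pos < 1L)) stop("marker positions must be >= 1")
    if (any(markers$ref == markers$alt)) stop("ref and alt alleles must differ")
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0L, 1L, 2L))) {
    stop("dosage values must be 0, 1, 2 or NA")
  }
  ord <- order(markers$chrom, markers$pos)
  markers <- markers[ord, , drop = FALSE]
  rownames(markers) <- NULL
  dosage <- dosage[, ord, drop = FALSE]
  rownames(dosage) <- accession_ids
  colnames(dosage) <- NULL
  structure(list(dosage = dosage, markers = markers),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d markers\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (ncol(x$dosage)) {
    cat(sprintf("  chromosomes: %s\n",
                paste(unique(x$markers$chrom), collapse = ", ")))
    cat(sprintf("  missing calls: %.2f%%\n",
                100 * mean(is.na(x$dosage))))
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix
#'
#' `x[i, j]` keeps accessions `i` and markers `j` (indices, names for
#' accessions, or logical vectors) and returns a valid `genotype_matrix`.
#'
#' @param x a `genotype_matrix`.
#' @param i,j accession / marker selectors.
#' @param ... ignored.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(nrow(x$markers))
  sub <- x$dosage[i, j, drop = FALSE]
  genotype_matrix(sub, x$markers[j, , drop = FALSE],
                  accession_ids = rownames(sub))
}

#' Read a genotype matrix from VCF or a dosage table
#'
#' Supports two formats: VCF 4.x (GT field; biallelic SNP records only;
#' phase separators are read but phase is ignored) and the package's
#' tab-separated dosage dialect: header `chrom pos ref alt <accession...>`,
#' one row per marker, cell values 0/1/2/NA.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage_tsv"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage_tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
      "vcf"
    } else {
      "dosage_tsv"
    }
  }
  if (!file.exists(path)) stop("no such file: ", path)
  switch(format,
         vcf = .read_vcf(path),
         dosage_tsv = .read_dosage_tsv(path))
}

.read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF: ", conditionMessage(e)))
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    samples <- colnames(v@gt)
    samples <- samples[samples != "FORMAT"]
    return(genotype_matrix(matrix(integer(), nrow = length(samples), ncol = 0),
                           data.frame(chrom = character(), pos = integer(),
                                      ref = character(), alt = character()),
                           accession_ids = samples))
  }
  bad <- which(is.na(fix$ALT) | grepl(",", fix$ALT) |
                 nchar(fix$REF) != 1L | nchar(fix$ALT) != 1L)
  if (length(bad)) {
    stop("non-biallelic-SNP record(s) at VCF data line(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt[gt == "."] <- NA_character_
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L, "./." = NA_integer_)
  idx <- match(gt, names(known))
  if (any(!is.na(gt) & is.na(idx))) {
    bad_gt <- unique(gt[!is.na(gt) & is.na(idx)])
    stop("unsupported GT value(s): ", paste(bad_gt, collapse = ", "))
  }
  dose[] <- known[idx]
  markers <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
  genotype_matrix(t(dose), markers, accession_ids = colnames(gt))
}

.read_dosage_tsv <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", "."))
  required <- c("chrom", "pos", "ref", "alt")
  if (!all(required %in% names(tab))) {
    stop("dosage table must start with columns: ",
         paste(required, collapse = ", "))
  }
  acc <- setdiff(names(tab), required)
  dose <- t(as.matrix(tab[, acc, drop = FALSE]))
  genotype_matrix(dose, tab[required], accession_ids = acc)
}

#' Write a genotype matrix
#'
#' Round-trips exactly through [read_genotypes()]: dosages, accession ids
#' and marker coordinates are preserved. Missing genotypes become `./.`
#' in VCF and `NA` in the dosage table.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"dosage_tsv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path, format = c("vcf", "dosage_tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(gm, "genotype_matrix"))
  if (format == "dosage_tsv") {
    tab <- cbind(gm$markers[c("chrom", "pos", "ref", "alt")],
                 as.data.frame(t(gm$dosage)))
    names(tab) <- c("chrom", "pos", "ref", "alt", rownames(gm$dosage))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    gt_codes <- c("0/0", "0/1", "1/1")
    samples <- rownames(gm$dosage)
    header <- c("##fileformat=VCFv4.2",
                "##source=radpop",
                '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
                paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", samples),
                      collapse = "\t"))
    lines <- header
    if (nrow(gm$markers)) {
      gt <- matrix("./.", nrow = nrow(gm$markers), ncol = length(samples))
      d <- t(gm$dosage)
      ok <- !is.na(d)
      gt[ok] <- gt_codes[d[ok] + 1L]
      body <- paste(gm$markers$chrom, gm$markers$pos, ".",
                    gm$markers$ref, gm$markers$alt, ".", "PASS", ".", "GT",
                    apply(gt, 1L, paste, collapse = "\t"),
                    sep = "\t")
      lines <- c(lines, body)
    }
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a population map
#'
#' Tab-separated, with a header containing at least `accession` and `pop`
#' columns, optionally `lat` and `lon` (decimal degrees) and ancestry
#' fraction columns named `q_<label>` which must sum to 1 per accession.
#'
#' @param path input file.
#' @param gm optional [genotype_matrix()] to validate against: every
#'   mapped accession must exist in `gm`.
#' @return data.frame of class `pop_map`.
#' @export
read_popmap <- function(path, gm = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if ("label" %in% names(tab) && !"pop" %in% names(tab)) {
    names(tab)[names(tab) == "label"] <- "pop"
  }
  pop_map(tab, gm = gm)
}

#' Validate a population map
#'
#' @param df data.frame with columns `accession`, `pop` and optionally
#'   `lat`, `lon` and ancestry fractions `q_*`.
#' @param gm optional companion [genotype_matrix()].
#' @return `df`, classed `pop_map`.
#' @export
pop_map <- function(df, gm = NULL) {
  df <- as.data.frame(df)
  if (!all(c("accession", "pop") %in% names(df))) {
    stop("population map needs 'accession' and 'pop' columns")
  }
  df$accession <- as.character(df$accession)
  df$pop <- as.character(df$pop)
  if (anyDuplicated(df$accession)) stop("duplicated accession in population map")
  qcols <- grep("^q_", names(df), value = TRUE)
  if (length(qcols)) {
    q <- as.matrix(df[qcols])
    if (any(q < 0)) stop("ancestry fractions must be non-negative")
    if (any(abs(rowSums(q) - 1) > 1e-6)) {
      stop("ancestry fractions must sum to 1 (+- 1e-6) per accession")
    }
  }
  if (!is.null(gm)) {
    unknown <- setdiff(df$accession, rownames(gm$dosage))
    if (length(unknown)) {
      stop("accession(s) absent from genotype matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    }
  }
  class(df) <- c("pop_map", "data.frame")
  df
}

#' Read genome annotation (genes and heterochromatin)
#'
#' Gene intervals come from the `gene` features of a GFF3 file (1-based
#' inclusive, kept as-is); heterochromatin intervals from a 3-column BED
#' file (0-based half-open, converted to 1-based inclusive on read).
#' Chromosome names are kept verbatim.
#'
#' @param gff_path GFF3 gene-model file, or `NULL` for no gene track.
#' @param het_bed_path BED3 heterochromatin file, or `NULL` for an empty
#'   heterochromatin track (all positions euchromatic downstream).
#' @return object of class `genome_annotation`: list with data.frames
#'   `genes` (`chrom`, `start`, `end`, `gene_id`) and `heterochromatin`
#'   (`chrom`, `start`, `end`).
#' @export
read_annotation <- function(gff_path = NULL, het_bed_path = NULL) {
  genes <- data.frame(chrom = character(), start = integer(),
                      end = integer(), gene_id = character(),
                      stringsAsFactors = FALSE)
  het <- data.frame(chrom = character(), start = integer(), end = integer(),
                    stringsAsFactors = FALSE)
  if (!is.null(gff_path)) {
    gr <- rtracklayer::import(gff_path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) == "gene"]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else
      paste0("gene", seq_along(gr))
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr),
                        end = GenomicRanges::end(gr),
                        gene_id = ids, stringsAsFactors = FALSE)
  }
  if (!is.null(het_bed_path)) {
    bed <- utils::read.table(het_bed_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end"),
                             colClasses = c("character", "integer", "integer"))
    if (nrow(bed)) {
      if (any(bed$start < 0L | bed$end < 0L)) {
        stop("negative coordinates in BED file")
      }
      het <- data.frame(chrom = bed$chrom,
                        start = bed$start + 1L,  # 0-based half-open -> 1-based
                        end = bed$end, stringsAsFactors = FALSE)
    }
  }
  genome_annotation(genes, het)
}

#' Assemble a genome annotation from interval tables
#'
#' @param genes data.frame `chrom`, `start`, `end`, `gene_id`
#'   (1-based inclusive).
#' @param heterochromatin data.frame `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @return object of class `genome_annotation`.
#' @export
genome_annotation <- function(genes = NULL, heterochromatin = NULL) {
  empty_genes <- data.frame(chrom = character(), start = integer(),
                            end = integer(), gene_id = character(),
                            stringsAsFactors = FALSE)
  empty_het <- data.frame(chrom = character(), start = integer(),
                          end = integer(), stringsAsFactors = FALSE)
  genes <- if (is.null(genes)) empty_genes else as.data.frame(genes)
  het <- if (is.null(heterochromatin)) empty_het else
    as.data.frame(heterochromatin)
  for (tab in list(genes, het)) {
    if (nrow(tab) && any(tab$start > tab$end)) {
      stop("interval start must be <= end")
    }
    if (nrow(tab) && any(tab$start < 1L)) stop("intervals must start at >= 1")
  }
  if (nrow(genes) && is.null(genes$gene_id)) {
    genes$gene_id <- paste0("gene", seq_len(nrow(genes)))
  }
  structure(list(genes = genes, heterochromatin = het),
            class = "genome_annotation")
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("genome_annotation: %d genes, %d heterochromatin intervals\n",
              nrow(x$genes), nrow(x$heterochromatin)))
  invisible(x)
}

#' Import a supplementary-style genotype spreadsheet export
#'
#' Convenience importer for externally supplied genotype tables that are
#' already in (or have been converted to) the package's dosage dialect.
#' Thin wrapper over [read_genotypes()] kept as the documented landing
#' point for published genotype matrices distributed as spreadsheets.
#'
#' @param path tab-separated dosage file (see [read_genotypes()]).
#' @return a [genotype_matrix()].
#' @export
import_supplementary_genotypes <- function(path) {
  read_genotypes(path, format = "dosage_tsv")
}
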