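#' @import methods
#' @importFrom stats cmdscale cor sd setNames rbinom runif rbeta
#' @importFrom utils read.table write.table
NULL

#' TaxaGenotypes: diploid biallelic genotypes with marker and taxon metadata
#'
#' Container for an accessions-by-markers diploid biallelic genotype matrix
#' together with per-marker metadata (chromosome, position, alleles,
#' gene-fragment assignment), the gene-fragment intervals, and the taxon map
#' assigning reference accessions to ancestral taxa. Genotypes are stored as
#' alternate-allele dosage (0, 1, 2 or `NA` for missing) with markers in rows
#' and accessions in columns, following the Bioconductor convention of
#' features-by-samples. Calls are unphased: a dosage of 1 represents the
#' unordered heterozygous pair.
#'
#' @slot geno integer matrix, markers x accessions, values in \{0, 1, 2, NA\}.
#' @slot markers data.frame with columns `marker_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `fragment_id` (`NA` when the marker falls in no
#'   fragment).
#' @slot fragments data.frame with columns `fragment_id`, `chrom`, `start`,
#'   `end` (1-based inclusive after conversion from BED) and `length_bp`.
#' @slot taxa data.frame with columns `accession_id`, `taxon` (`NA` for test
#'   accessions) and `role` (`"REFERENCE"` or `"TEST"`); may have zero rows
#'   when no taxon map has been attached.
#'
#' @seealso [TaxaGenotypes()] for the constructor, [readGenotypes()] to load
#'   from VCF or wide TSV.
#' @export
setClass("TaxaGenotypes",
  slots = c(
    geno = "matrix",
    markers = "data.frame",
    fragments = "data.frame",
    taxa = "data.frame"
  )
)

emptyFragments <- function() {
  data.frame(fragment_id = character(), chrom = character(),
             start = integer(), end = integer(), length_bp = integer(),
             stringsAsFactors = FALSE)
}

emptyTaxa <- function() {
  data.frame(accession_id = character(), taxon = character(),
             role = character(), stringsAsFactors = FALSE)
}

setValidity("TaxaGenotypes", function(object) {
  msg <- character()
  g <- object@geno
  mk <- object@markers
  fr <- object@fragments
  tx <- object@taxa
  if (!is.numeric(g) && !all(is.na(g)))
    msg <- c(msg, "genotype matrix must be numeric dosage (0/1/2/NA)")
  bad <- g[!is.na(g)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  need <- c("marker_id", "chrom", "pos", "ref", "alt", "fragment_id")
  if (!all(need %in% names(mk)))
    msg <- c(msg, paste("markers must have columns:", paste(need, collapse = ", ")))
  else {
    if (nrow(mk) != nrow(g))
      msg <- c(msg, "markers table and genotype rows disagree")
    if (anyDuplicated(mk$marker_id))
      msg <- c(msg, "marker_id values must be unique")
    if (any(!is.na(mk$pos) & mk$pos < 1))
      msg <- c(msg, "marker positions must be strictly positive (1-based)")
    if (anyDuplicated(paste(mk$chrom, mk$pos)))
      msg <- c(msg, "(chromosome, position) pairs must be unique")
  }
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msg <- c(msg, "accession ids (column names) must be present and unique")
  if (!is.null(rownames(g)) && !identical(rownames(g), as.character(mk$marker_id)))
    msg <- c(msg, "genotype rownames must match markers$marker_id")
  if (nrow(fr)) {
    if (anyDuplicated(fr$fragment_id))
      msg <- c(msg, "fragment_id values must be unique")
    if (any(fr$end < fr$start))
      msg <- c(msg, "fragment end must be >= start")
    # markers with a fragment assignment must fall inside the interval
    idx <- which(!is.na(mk$fragment_id))
    if (length(idx)) {
      fi <- match(mk$fragment_id[idx], fr$fragment_id)
      if (anyNA(fi))
        msg <- c(msg, "marker assigned to unknown fragment")
      else {
        ok <- mk$chrom[idx] == fr$chrom[fi] &
          mk$pos[idx] >= fr$start[fi] & mk$pos[idx] <= fr$end[fi]
        if (!all(ok))
          msg <- c(msg, paste("markers outside their fragment interval:",
                              paste(mk$marker_id[idx][!ok], collapse = ", ")))
      }
    }
  }
  if (nrow(tx)) {
    if (!all(c("accession_id", "taxon", "role") %in% names(tx)))
      msg <- c(msg, "taxa must have columns accession_id, taxon, role")
    else if (any(tx$role == "REFERENCE" & is.na(tx$taxon)))
      msg <- c(msg, "REFERENCE accessions must have a taxon")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TaxaGenotypes object
#'
#' @param geno numeric matrix of alternate-allele dosages (0/1/2/NA).
#'   Accessions in columns (named), markers in rows. A transposed
#'   accessions-by-markers matrix is accepted when `markersInRows = FALSE`.
#' @param markers data.frame of marker metadata (`marker_id`, `chrom`, `pos`,
#'   `ref`, `alt`, optional `fragment_id`).
#' @param fragments optional data.frame of fragment intervals (`fragment_id`,
#'   `chrom`, `start`, `end` 1-based inclusive, optional `length_bp`).
#' @param taxa optional taxon map data.frame (`accession_id`, `taxon`,
#'   `role`).
#' @param markersInRows logical; set `FALSE` if `geno` is
#'   accessions-by-markers.
#' @return A validated [TaxaGenotypes-class] object.
#' @examples
#' g <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("m1", "m2"), c("acc1", "acc2")))
#' mk <- data.frame(marker_id = c("m1", "m2"), chrom = "chr1",
#'                  pos = c(10L, 20L), ref = "A", alt = "G")
#' TaxaGenotypes(g, mk)
#' @export
TaxaGenotypes <- function(geno, markers, fragments = NULL, taxa = NULL,
                          markersInRows = TRUE) {
  if (!markersInRows) geno <- t(geno)
  storage.mode(geno) <- "integer"
  if (!"fragment_id" %in% names(markers)) markers$fragment_id <- NA_character_
  markers$marker_id <- as.character(markers$marker_id)
  markers$chrom <- as.character(markers$chrom)
  markers$fragment_id <- as.character(markers$fragment_id)
  rownames(geno) <- markers$marker_id
  rownames(markers) <- NULL
  if (is.null(fragments)) fragments <- emptyFragments()
  if (nrow(fragments) && !"length_bp" %in% names(fragments))
    fragments$length_bp <- fragments$end - fragments$start + 1L
  if (is.null(taxa)) taxa <- emptyTaxa()
  new("TaxaGenotypes", geno = geno, markers = markers,
      fragments = fragments, taxa = taxa)
}

#' @describeIn TaxaGenotypes-class number of markers and accessions
#' @param object,x a `TaxaGenotypes` object
#' @export
setMethod("show", "TaxaGenotypes", function(object) {
  cat("TaxaGenotypes:", nrow(object@geno), "markers x",
      ncol(object@geno), "accessions\n")
  nmiss <- sum(is.na(object@geno))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nmiss,
              100 * nmiss / max(1, length(object@geno))))
  if (nrow(object@fragments))
    cat("  fragments:", nrow(object@fragments), "on",
        length(unique(object@fragments$chrom)), "chromosome(s)\n")
  if (nrow(object@taxa)) {
    refs <- object@taxa[object@taxa$role == "REFERENCE", ]
    cat("  taxa:", paste(sprintf("%s (%d)", names(table(refs$taxon)),
                                 as.integer(table(refs$taxon))),
                         collapse = ", "), "\n")
    cat("  test accessions:", sum(object@taxa$role == "TEST"), "\n")
  }
})

#' Accessors for TaxaGenotypes
#'
#' `dosage()` returns the markers-by-accessions integer dosage matrix;
#' `markerInfo()`, `fragmentInfo()` and `taxonMap()` return the metadata
#' tables; `accessionIds()` and `markerIds()` the dimension labels.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @return the corresponding slot content (copies, never references).
#' @name accessors
NULL

#' @rdname accessors
#' @export
dosage <- function(x) x@geno

#' @rdname accessors
#' @export
markerInfo <- function(x) x@markers

#' @rdname accessors
#' @export
fragmentInfo <- function(x) x@fragments

#' @rdname accessors
#' @export
taxonMap <- function(x) x@taxa

#' @rdname accessors
#' @export
accessionIds <- function(x) colnames(x@geno)

#' @rdname accessors
#' @export
markerIds <- function(x) rownames(x@geno)

#' Attach or replace the taxon map
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param value taxon map data.frame as returned by [readTaxonMap()].
#' @return `x` with the taxa slot replaced.
#' @export
`taxonMap<-` <- function(x, value) {
  x@taxa <- value
  validObject(x)
  x
}

#' @describeIn TaxaGenotypes-class subset markers (i) and accessions (j) by
#'   index, logical or name
#' @param i,j,...,drop subsetting indices (drop is ignored)
#' @export
setMethod("[", "TaxaGenotypes", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@geno))
  if (missing(j)) j <- seq_len(ncol(x@geno))
  if (is.character(i)) i <- match(i, rownames(x@geno))
  geno <- x@geno[i, j, drop = FALSE]
  markers <- x@markers[i, , drop = FALSE]
  rownames(markers) <- NULL
  taxa <- x@taxa
  if (nrow(taxa)) taxa <- taxa[taxa$accession_id %in% colnames(geno), ,
                               drop = FALSE]
  keep <- unique(markers$fragment_id[!is.na(markers$fragment_id)])
  fragments <- x@fragments
  initialize(x, geno = geno, markers = markers, fragments = fragments,
             taxa = taxa)
})

#' Genotype calls as unordered allele pairs
#'
#' Converts the dosage view to two-letter genotype strings using each
#' marker's ref/alt alleles (e.g. dosage 1 at an A/G marker becomes `"AG"`,
#' alphabetically ordered). Missing calls become `NA`. The conversion is the
#' inverse of the dosage encoding, so pairs -> dosage -> pairs is the
#' identity for biallelic calls.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @return character matrix, markers x accessions.
#' @export
genotypePairs <- function(x) {
  g <- x@geno
  mk <- x@markers
  out <- matrix(NA_character_, nrow(g), ncol(g), dimnames = dimnames(g))
  hom_ref <- paste0(mk$ref, mk$ref)
  hom_alt <- paste0(mk$alt, mk$alt)
  het <- vapply(seq_len(nrow(mk)), function(i) {
    paste(sort(c(mk$ref[i], mk$alt[i])), collapse = "")
  }, character(1))
  for (j in seq_len(ncol(g))) {
    d <- g[, j]
    out[, j] <- ifelse(is.na(d), NA_character_,
                       ifelse(d == 0, hom_ref, ifelse(d == 1, het, hom_alt)))
  }
  out
}
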