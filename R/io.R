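# Input/output: VCF and wide-TSV genotype tables, BED fragments, taxon maps,
# and TSV result tables.

IUPAC_HET <- c(M = "AC", R = "AG", W = "AT", S = "CG", Y = "CT", K = "GT")
MISSING_CODES <- c("./.", ".|.", ".", "NN", "NA", "-", "")

#' Read a genotype dataset from VCF or wide TSV
#'
#' Loads diploid biallelic genotype calls plus marker metadata, optionally
#' assigning markers to gene fragments from a BED file. VCF positions are
#' 1-based; BED intervals are 0-based half-open and are converted once at
#' load. Records with more than two alleles are rejected (biallelic model).
#' Calls are treated as unphased: `0/1` and `1|0` are the same heterozygote.
#'
#' The wide TSV dialect has accessions in rows and markers in columns, with
#' a marker-metadata header block or a separate `markers=` table. Genotypes
#' may be two-letter strings (`"AC"`), IUPAC single-letter heterozygote codes
#' (`"M"`), or any of the missing codes `./.`, `NN`, `NA`, `-`.
#'
#' @param path path to the genotype file.
#' @param format `"vcf"` or `"tsv"`.
#' @param fragmentsPath optional BED3+name file of gene-fragment intervals.
#' @param markersPath for `format = "tsv"`: path to the marker metadata TSV
#'   (columns `marker_id`, `chrom`, `pos`, `ref`, `alt`). Required because a
#'   wide genotype table does not carry positions or allele codes.
#' @return a [TaxaGenotypes-class] object (taxon map empty; attach one with
#'   [readTaxonMap()] and `taxonMap<-`).
#' @export
readGenotypes <- function(path, format = c("vcf", "tsv"),
                          fragmentsPath = NULL, markersPath = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- switch(format,
              vcf = readGenotypesVcf(path),
              tsv = readGenotypesTsv(path, markersPath))
  if (!is.null(fragmentsPath)) {
    fr <- readFragments(fragmentsPath)
    x <- assignFragments(x, fr)
  }
  x
}

readGenotypesVcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF drops to vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | nchar(fix$ALT) == 0 | is.na(fix$ALT)
  if (any(multi))
    stop("biallelic-violation: marker(s) with more than two alleles: ",
         paste(ifelse(is.na(fix$ID[multi]) | fix$ID[multi] == ".",
                      paste0(fix$CHROM[multi], ":", fix$POS[multi]),
                      fix$ID[multi]), collapse = ", "))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt)) stop("parse error: no GT field in ", path)
  # unphased model: 0/1 == 1|0; count alt alleles
  clean <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow(clean), ncol(clean),
                dimnames = dimnames(clean))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  vals <- known[clean]
  bad <- !is.na(clean) & !(clean %in% c(names(known), MISSING_CODES))
  if (any(bad))
    stop("parse error: unrecognised GT value(s): ",
         paste(unique(clean[bad]), collapse = ", "))
  dos[] <- vals
  ids <- fix$ID
  auto <- is.na(ids) | ids == "."
  ids[auto] <- paste0(fix$CHROM[auto], "_", fix$POS[auto])
  markers <- data.frame(marker_id = ids, chrom = fix$CHROM,
                        pos = as.integer(fix$POS), ref = fix$REF,
                        alt = fix$ALT, fragment_id = NA_character_,
                        stringsAsFactors = FALSE)
  TaxaGenotypes(dos, markers)
}

normalizeCall <- function(s, ref, alt, marker, where) {
  s <- toupper(trimws(s))
  if (s %in% toupper(MISSING_CODES) || is.na(s)) return(NA_integer_)
  if (nchar(s) == 1 && s %in% names(IUPAC_HET)) s <- IUPAC_HET[[s]]
  if (nchar(s) == 1) s <- paste0(s, s)  # single base = homozygote shorthand
  if (nchar(s) != 2)
    stop("parse error at ", where, ": cannot interpret genotype '", s, "'")
  a <- strsplit(s, "")[[1]]
  if (!all(a %in% c(ref, alt)))
    stop("biallelic-violation at marker ", marker, ": call '", s,
         "' uses allele(s) outside {", ref, ",", alt, "}")
  sum(a == alt)
}

readGenotypesTsv <- function(path, markersPath) {
  if (is.null(markersPath))
    stop("markersPath is required for the wide TSV dialect")
  mk <- read.table(markersPath, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, colClasses = "character")
  need <- c("marker_id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(mk)))
    stop("parse error: marker table must have columns ",
         paste(need, collapse = ", "))
  mk$pos <- as.integer(mk$pos)
  wide <- read.table(path, header = TRUE, sep = "\t", row.names = 1,
                     stringsAsFactors = FALSE, colClasses = "character",
                     check.names = FALSE, na.strings = NULL)
  missing_mk <- setdiff(mk$marker_id, colnames(wide))
  if (length(missing_mk))
    stop("parse error: markers absent from genotype table: ",
         paste(missing_mk, collapse = ", "))
  wide <- wide[, mk$marker_id, drop = FALSE]
  dos <- matrix(NA_integer_, nrow(mk), nrow(wide),
                dimnames = list(mk$marker_id, rownames(wide)))
  for (i in seq_len(nrow(mk))) {
    dos[i, ] <- vapply(wide[[i]], normalizeCall, integer(1),
                       ref = mk$ref[i], alt = mk$alt[i],
                       marker = mk$marker_id[i],
                       where = paste0(path, " column ", mk$marker_id[i]))
  }
  mk$fragment_id <- NA_character_
  TaxaGenotypes(dos, mk)
}

#' Read gene-fragment intervals from BED
#'
#' BED is 0-based half-open; intervals are converted to 1-based inclusive
#' coordinates on load. The name column supplies the fragment id.
#'
#' @param path BED3+name file.
#' @return data.frame with `fragment_id`, `chrom`, `start`, `end` (1-based
#'   inclusive) and `length_bp` (the original `end - start`).
#' @export
readFragments <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    stop("parse error: BED fragments need a name column")
  if (anyDuplicated(nm)) stop("fragment_id values must be unique")
  data.frame(fragment_id = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),  # rtracklayer converts to 1-based
             end = GenomicRanges::end(gr),
             length_bp = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

assignFragments <- function(x, fr) {
  mk <- x@markers
  mgr <- GenomicRanges::GRanges(mk$chrom, IRanges::IRanges(mk$pos, mk$pos))
  fgr <- GenomicRanges::GRanges(fr$chrom, IRanges::IRanges(fr$start, fr$end))
  hit <- GenomicRanges::findOverlaps(mgr, fgr, select = "first")
  mk$fragment_id <- ifelse(is.na(hit), NA_character_, fr$fragment_id[hit])
  initialize(x, markers = mk, fragments = fr)
}

#' Read a taxon map
#'
#' Two- or three-column TSV (`accession_id`, `taxon`, optional `role`).
#' Accessions with an empty taxon default to role `TEST`; accessions with a
#' taxon default to `REFERENCE`. Unknown taxon labels are rejected, and every
#' configured taxon must have at least one reference accession.
#'
#' @param path taxon map TSV.
#' @param taxa character vector of configured ancestral-taxon labels.
#' @param genotypes optional [TaxaGenotypes-class]; accessions in the map but
#'   absent from the genotype matrix trigger a warning.
#' @return data.frame with `accession_id`, `taxon`, `role`.
#' @export
readTaxonMap <- function(path, taxa, genotypes = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
  if (!"accession_id" %in% names(tab) || !"taxon" %in% names(tab))
    stop("parse error: taxon map needs columns accession_id, taxon")
  unknown <- setdiff(tab$taxon[!is.na(tab$taxon)], taxa)
  if (length(unknown))
    stop("configuration error: unknown taxon label(s): ",
         paste(unknown, collapse = ", "))
  if (!"role" %in% names(tab) || all(is.na(tab$role)))
    tab$role <- ifelse(is.na(tab$taxon), "TEST", "REFERENCE")
  tab$role[is.na(tab$role)] <- ifelse(is.na(tab$taxon[is.na(tab$role)]),
                                      "TEST", "REFERENCE")
  refs <- tab[tab$role == "REFERENCE", ]
  missing_taxa <- setdiff(taxa, refs$taxon)
  if (length(missing_taxa))
    stop("configuration error: taxa with zero reference accessions: ",
         paste(missing_taxa, collapse = ", "))
  if (!is.null(genotypes)) {
    absent <- setdiff(tab$accession_id, accessionIds(genotypes))
    if (length(absent))
      warning("taxon-map accessions absent from genotype matrix: ",
              paste(absent, collapse = ", "))
  }
  tab[, c("accession_id", "taxon", "role")]
}

#' Write a result table as TSV
#'
#' Tab-separated UTF-8 with header; missing values encoded as `NA`; reals
#' written with 15 significant digits so a round-trip reproduces integers
#' bit-exactly and reals to at least 12 significant digits. Files are written
#' to a temporary name and renamed into place, so a crash never leaves a
#' partial artifact.
#'
#' @param df data.frame (may have zero rows; the header is still written).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  num <- vapply(df, is.double, logical(1))
  out <- df
  for (j in which(num)) out[[j]] <- formatC(df[[j]], digits = 15,
                                            format = "g")
  out[is.na(df)] <- NA
  ok <- tryCatch({
    write.table(out, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "NA", fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) stop("I/O error writing ", path, ": ",
                              conditionMessage(e)))
  file.rename(tmp, path)
  invisible(path)
}

#' Read back a TSV written by [writeTable()]
#'
#' @param path TSV path.
#' @return data.frame with column types inferred.
#' @export
readTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             na.strings = "NA", check.names = FALSE)
}

#' Write a genotype dataset as wide TSV plus side tables
#'
#' Writes the wide genotype table (`<stem>_genotypes.tsv`, accessions in
#' rows, two-letter genotype strings, missing as `NA`), the marker table
#' (`<stem>_markers.tsv`), the fragment table as BED (`<stem>_fragments.bed`,
#' converted back to 0-based half-open) and, when present, the taxon map
#' (`<stem>_taxa.tsv`). A written dataset re-read with [readGenotypes()]
#' reproduces every call including missing ones.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param stem output path stem.
#' @return named character vector of the files written, invisibly.
#' @export
writeGenotypes <- function(x, stem) {
  pairs <- t(genotypePairs(x))  # accessions x markers
  wide <- data.frame(accession_id = rownames(pairs), pairs,
                     check.names = FALSE, stringsAsFactors = FALSE)
  files <- c(genotypes = paste0(stem, "_genotypes.tsv"),
             markers = paste0(stem, "_markers.tsv"))
  writeTable(wide, files[["genotypes"]])
  mk <- x@markers
  writeTable(mk[, c("marker_id", "chrom", "pos", "ref", "alt")],
             files[["markers"]])
  if (nrow(x@fragments)) {
    files[["fragments"]] <- paste0(stem, "_fragments.bed")
    fr <- x@fragments
    bed <- data.frame(fr$chrom, fr$start - 1L, fr$end, fr$fragment_id)
    write.table(bed, files[["fragments"]], sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (nrow(x@taxa)) {
    files[["taxa"]] <- paste0(stem, "_taxa.tsv")
    writeTable(x@taxa, files[["taxa"]])
  }
  invisible(files)
}
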