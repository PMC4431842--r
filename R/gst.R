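# Focal-taxon versus pooled-rest G_ST, marker classification, assay
# proximity filtering and diagnostic-panel construction.

#' Expected heterozygosity of a biallelic frequency
#'
#' `He(p) = 1 - p^2 - (1 - p)^2 = 2 p (1 - p)` (no small-sample correction;
#' this is the form used inside the G_ST decomposition).
#'
#' @param p frequency vector in `[0, 1]`.
#' @return He values.
#' @export
heBiallelic <- function(p) 1 - p^2 - (1 - p)^2

#' Focal-taxon versus pooled-rest G_ST from frequencies
#'
#' The rest pool `T-i` takes the unweighted mean of the non-focal taxon
#' frequencies, and the total population weights the focal taxon and the
#' rest pool equally: `p_tot = (p_i + p_rest)/2`. Then
#' `G_ST = (He_tot - (He_i + He_rest)/2) / He_tot`, with `He(p) = 2p(1-p)`.
#' He is concave in p, so the statistic lies in `[0, 1]`; it is 1 when the
#' focal taxon is fixed for an allele absent from all other taxa, and 0 when
#' all taxa share the same frequency. Markers monomorphic across the pooled
#' population (`He_tot = 0`) are assigned `gst = 0` with `monomorphic = TRUE`
#' so tables stay rectangular; they can never enter a panel.
#'
#' @param pFocal frequency of the alternate allele in the focal taxon.
#' @param pOthers matrix (markers x non-focal taxa) or vector of non-focal
#'   frequencies.
#' @return data.frame with `gst`, `he_ti`, `he_tminus`, `he_tot`,
#'   `p_focal`, `p_rest`, `monomorphic` and `diagnostic_allele` (`"alt"`,
#'   `"ref"` or `NA` when not differentiated).
#' @export
gstFocalRest <- function(pFocal, pOthers) {
  pOthers <- as.matrix(pOthers)
  if (nrow(pOthers) != length(pFocal))
    pOthers <- matrix(pOthers, nrow = length(pFocal))
  pRest <- rowMeans(pOthers, na.rm = TRUE)
  pTot <- (pFocal + pRest) / 2
  heTi <- heBiallelic(pFocal)
  heRest <- heBiallelic(pRest)
  heTot <- heBiallelic(pTot)
  mono <- !is.na(heTot) & heTot == 0
  gst <- ifelse(mono, 0,
                (heTot - (heTi + heRest) / 2) / heTot)
  allele <- ifelse(is.na(gst) | gst <= 0 | pFocal == pRest, NA_character_,
                   ifelse(pFocal > pRest, "alt", "ref"))
  data.frame(gst = gst, he_ti = heTi, he_tminus = heRest, he_tot = heTot,
             p_focal = pFocal, p_rest = pRest, monomorphic = mono,
             diagnostic_allele = allele, stringsAsFactors = FALSE)
}

#' G_ST scan of every marker for every taxon
#'
#' Computes the focal-versus-rest G_ST of each marker for each taxon from
#' per-taxon reference allele frequencies. Markers whose focal-taxon
#' frequency is undefined (all calls missing) are skipped for that taxon.
#'
#' @param freqs named list of per-taxon [alleleFreqs()] tables (all on the
#'   same marker set).
#' @return data.frame with one row per (marker, taxon): `marker_id`,
#'   `taxon`, `gst`, component heterozygosities, the pool frequencies and
#'   `diagnostic_allele`.
#' @export
gstScan <- function(freqs) {
  taxa <- names(freqs)
  if (length(taxa) < 2) stop("need >= 2 taxa")
  ids <- freqs[[1]]$marker_id
  for (f in freqs) if (!identical(f$marker_id, ids))
    stop("frequency tables disagree on the marker set")
  pmat <- sapply(freqs, function(f) f$p)
  pmat <- matrix(pmat, ncol = length(taxa),
                 dimnames = list(NULL, taxa))
  out <- lapply(taxa, function(tx) {
    pF <- pmat[, tx]
    pO <- pmat[, setdiff(taxa, tx), drop = FALSE]
    keep <- !is.na(pF) & rowSums(!is.na(pO)) >= 1
    rec <- gstFocalRest(pF[keep], pO[keep, , drop = FALSE])
    cbind(data.frame(marker_id = ids[keep], taxon = tx,
                     stringsAsFactors = FALSE), rec)
  })
  do.call(rbind, out)
}

#' Classify markers from their G_ST profile
#'
#' Every marker gets exactly one class:
#' * `DIAGNOSTIC` when its highest taxon G_ST exceeds `diagThreshold`
#'   (default 0.9); the taxon is the argmax.
#' * `TAXON_SPECIFIC_POLYMORPHISM` when the highest G_ST is at most
#'   `specificMaxGst` (default 0.5) and the variant segregates in exactly
#'   one taxon while all other taxa are fixed for the same shared allele.
#' * `ND` (non-diagnostic) for the remaining markers at or below
#'   `specificMaxGst` (similar diversity in two or more taxa).
#' * `PARTIAL` for markers between the two thresholds.
#'
#' @param gst output of [gstScan()].
#' @param freqs the per-taxon frequency list used for the scan.
#' @param diagThreshold strict lower bound for `DIAGNOSTIC` (default 0.9).
#' @param specificMaxGst inclusive upper bound for the specific-polymorphism
#'   rule (default 0.5).
#' @return data.frame with `marker_id`, `class`, `taxon` (`NA` unless the
#'   class ties the marker to one taxon), `max_gst`, `diagnostic_allele`.
#' @export
classifyMarkers <- function(gst, freqs, diagThreshold = 0.9,
                            specificMaxGst = 0.5) {
  taxa <- names(freqs)
  ids <- freqs[[1]]$marker_id
  pmat <- sapply(freqs, function(f) f$p)
  pmat <- matrix(pmat, ncol = length(taxa), dimnames = list(ids, taxa))
  best <- do.call(rbind, lapply(split(gst, gst$marker_id), function(d) {
    i <- which.max(d$gst)
    d[i, c("marker_id", "taxon", "gst", "diagnostic_allele")]
  }))
  m <- match(ids, best$marker_id)
  max_gst <- best$gst[m]
  max_taxon <- best$taxon[m]
  max_allele <- best$diagnostic_allele[m]

  cls <- rep(NA_character_, length(ids))
  taxon_out <- rep(NA_character_, length(ids))
  allele_out <- rep(NA_character_, length(ids))
  for (i in seq_along(ids)) {
    p <- pmat[i, ]
    if (is.na(max_gst[i])) { cls[i] <- "ND"; next }
    if (max_gst[i] > diagThreshold) {
      cls[i] <- "DIAGNOSTIC"
      taxon_out[i] <- max_taxon[i]
      allele_out[i] <- max_allele[i]
    } else if (max_gst[i] <= specificMaxGst) {
      pd <- p[!is.na(p)]
      poly <- names(pd)[pd > 0 & pd < 1]
      fixed <- pd[pd == 0 | pd == 1]
      if (length(poly) == 1 && length(fixed) == length(pd) - 1 &&
          length(unique(fixed)) == 1) {
        cls[i] <- "TAXON_SPECIFIC_POLYMORPHISM"
        taxon_out[i] <- poly
        # the private variant is the allele absent from the fixed taxa
        allele_out[i] <- if (unique(fixed) == 0) "alt" else "ref"
      } else {
        cls[i] <- "ND"
      }
    } else {
      cls[i] <- "PARTIAL"
    }
  }
  data.frame(marker_id = ids, class = cls, taxon = taxon_out,
             max_gst = max_gst, diagnostic_allele = allele_out,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Reject assay candidates with nearby polymorphisms
#'
#' A candidate SNP is rejected when any other variant (SNP or indel) lies
#' within `window` bp on either side on the same chromosome; competitive
#' allele-specific PCR assays need clean flanking sequence. The rule is
#' symmetric: two candidates within one window reject each other.
#'
#' @param markers marker table (`marker_id`, `chrom`, `pos`).
#' @param candidates marker ids to screen (default all markers).
#' @param window flanking distance in bp (default 50, matching a ~50 nt
#'   assay arm).
#' @param indels optional data.frame of additional variants (`chrom`,
#'   `pos`).
#' @return list with `retained` (ids), `rejected` (data.frame `marker_id`,
#'   `offending_chrom`, `offending_pos`, `distance`).
#' @export
proximityFilter <- function(markers, candidates = markers$marker_id,
                            window = 50, indels = NULL) {
  vchrom <- markers$chrom
  vpos <- markers$pos
  vid <- markers$marker_id
  if (!is.null(indels) && nrow(indels)) {
    vchrom <- c(vchrom, indels$chrom)
    vpos <- c(vpos, indels$pos)
    vid <- c(vid, paste0("indel_", indels$chrom, "_", indels$pos))
  }
  rej <- list()
  retained <- character()
  for (cand in candidates) {
    k <- match(cand, markers$marker_id)
    if (is.na(k)) stop("unknown candidate: ", cand)
    near <- which(vchrom == markers$chrom[k] & vid != cand &
                    abs(vpos - markers$pos[k]) <= window)
    if (length(near)) {
      j <- near[which.min(abs(vpos[near] - markers$pos[k]))]
      rej[[cand]] <- data.frame(marker_id = cand,
                                offending = vid[j],
                                offending_pos = vpos[j],
                                distance = abs(vpos[j] - markers$pos[k]),
                                stringsAsFactors = FALSE)
    } else {
      retained <- c(retained, cand)
    }
  }
  list(retained = retained,
       rejected = if (length(rej)) do.call(rbind, c(rej, make.row.names = FALSE))
       else data.frame(marker_id = character(), offending = character(),
                       offending_pos = integer(), distance = integer(),
                       stringsAsFactors = FALSE))
}

#' Build the per-taxon diagnostic panel
#'
#' Groups `DIAGNOSTIC` and `TAXON_SPECIFIC_POLYMORPHISM` markers by taxon
#' and applies a cross-taxon QC screen: a marker is discarded when its
#' diagnostic allele is observed at frequency >= `qcThreshold` in any other
#' taxon (markers sharing a polymorphism between two taxa cannot trace a
#' single ancestry). After QC each marker belongs to at most one taxon and
#' its diagnostic allele is strictly more frequent in the focal taxon than
#' anywhere else.
#'
#' @param classification output of [classifyMarkers()].
#' @param freqs per-taxon frequency list.
#' @param qcThreshold tolerated diagnostic-allele frequency in a second
#'   taxon (default 0.1).
#' @param includeSpecific also admit `TAXON_SPECIFIC_POLYMORPHISM` markers
#'   (default TRUE).
#' @return data.frame panel (`taxon`, `marker_id`, `diagnostic_allele`,
#'   `class`, `p_focal`, `max_other_p`) with the QC removals in
#'   `attr(, "removed")`. Empty per-taxon panels produce a warning only.
#' @export
buildPanel <- function(classification, freqs, qcThreshold = 0.1,
                       includeSpecific = TRUE) {
  taxa <- names(freqs)
  ids <- freqs[[1]]$marker_id
  pmat <- sapply(freqs, function(f) f$p)
  pmat <- matrix(pmat, ncol = length(taxa), dimnames = list(ids, taxa))
  keep_cls <- c("DIAGNOSTIC", if (includeSpecific) "TAXON_SPECIFIC_POLYMORPHISM")
  cand <- classification[classification$class %in% keep_cls &
                           !is.na(classification$taxon) &
                           !is.na(classification$diagnostic_allele), ]
  rows <- list(); removed <- list()
  for (i in seq_len(nrow(cand))) {
    id <- cand$marker_id[i]; tx <- cand$taxon[i]
    al <- cand$diagnostic_allele[i]
    p <- pmat[id, ]
    pal <- if (al == "alt") p else 1 - p  # diagnostic-allele frequency
    others <- pal[setdiff(taxa, tx)]
    max_other <- suppressWarnings(max(others, na.rm = TRUE))
    if (!is.finite(max_other)) max_other <- NA_real_
    rec <- data.frame(taxon = tx, marker_id = id, diagnostic_allele = al,
                      class = cand$class[i], p_focal = pal[tx],
                      max_other_p = max_other, stringsAsFactors = FALSE)
    if (!is.na(max_other) && max_other >= qcThreshold) {
      rec$reason <- sprintf("diagnostic allele at p=%.3f in %s",
                            max_other,
                            names(which.max(others)))
      removed[[length(removed) + 1]] <- rec
    } else if (!is.na(pal[tx]) && (is.na(max_other) || pal[tx] > max_other)) {
      rows[[length(rows) + 1]] <- rec
    } else {
      rec$reason <- "diagnostic allele not enriched in focal taxon"
      removed[[length(removed) + 1]] <- rec
    }
  }
  panel <- if (length(rows)) do.call(rbind, rows) else
    data.frame(taxon = character(), marker_id = character(),
               diagnostic_allele = character(), class = character(),
               p_focal = numeric(), max_other_p = numeric(),
               stringsAsFactors = FALSE)
  empty <- setdiff(taxa, panel$taxon)
  if (length(empty))
    warning("no panel markers for taxa: ", paste(empty, collapse = ", "))
  attr(panel, "removed") <- if (length(removed))
    do.call(rbind, removed) else NULL
  panel
}
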