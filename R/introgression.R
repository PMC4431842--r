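# Fragment-level interspecific-heterozygosity detection, masking, and
# re-estimation of ancestral frequencies and the diagnostic panel.

#' Per-accession, per-fragment observed heterozygosity
#'
#' Ho over the markers of each gene fragment: heterozygous calls divided by
#' non-missing calls. Entries are `NA` when the accession has no call in the
#' fragment. Interspecific heterozygosity shows up as fragments with Ho near
#' 0.5 in otherwise near-homozygous reference accessions.
#'
#' @param x a [TaxaGenotypes-class] object with fragment assignments.
#' @return list with matrices `ho` and `n_markers`
#'   (accessions x fragments).
#' @export
fragmentHet <- function(x) {
  fr <- x@fragments
  if (!nrow(fr)) stop("no fragments attached")
  mk <- x@markers
  g <- x@geno
  acc <- accessionIds(x)
  ho <- matrix(NA_real_, length(acc), nrow(fr),
               dimnames = list(acc, fr$fragment_id))
  nm <- matrix(0L, length(acc), nrow(fr),
               dimnames = list(acc, fr$fragment_id))
  for (k in seq_len(nrow(fr))) {
    rows <- which(!is.na(mk$fragment_id) & mk$fragment_id == fr$fragment_id[k])
    if (!length(rows)) next
    sub <- g[rows, , drop = FALSE]
    n <- colSums(!is.na(sub))
    h <- colSums(sub == 1, na.rm = TRUE)
    nm[, k] <- n
    ho[, k] <- ifelse(n > 0, h / n, NA_real_)
  }
  list(ho = ho, n_markers = nm)
}

#' Classical principal coordinates analysis of a dissimilarity matrix
#'
#' Double-centering of squared dissimilarities followed by
#' eigendecomposition (classical metric scaling). Axes with non-positive
#' eigenvalues are dropped; each retained axis has its sign fixed so that
#' its first nonzero coordinate is positive, making output deterministic.
#'
#' @param d symmetric dissimilarity matrix with zero diagonal (e.g.
#'   `smDissimilarity(x)$d`).
#' @param nAxes number of axes to retain (default 2; capped by the number of
#'   positive eigenvalues).
#' @return list with `coords` (accessions x axes), `eig` (all eigenvalues,
#'   descending) and `var_explained` (fraction of the positive-eigenvalue
#'   sum per retained axis).
#' @export
pcoa <- function(d, nAxes = 2) {
  d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8))
    stop("dissimilarity matrix must be symmetric")
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(d, k = min(nAxes, n - 1), eig = TRUE))
  eig <- fit$eig
  pos <- which(eig[seq_len(ncol(fit$points))] > 1e-12)
  if (!length(pos)) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    return(list(coords = coords, eig = eig, var_explained = 0))
  }
  coords <- fit$points[, pos, drop = FALSE]
  coords <- fixAxisSigns(coords)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pos_sum <- sum(eig[eig > 0])
  list(coords = coords, eig = eig,
       var_explained = if (pos_sum > 0) eig[pos] / pos_sum else rep(0, length(pos)))
}

fixAxisSigns <- function(coords) {
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Flag reference accession x fragment interspecific heterozygosity
#'
#' Automates the combined ordination-plus-heterozygosity screen: a reference
#' accession is flagged for a fragment when
#' (a) its fragment Ho is at least `hetThreshold`, and
#' (b) it is heterozygous at `minDifferentialHets` or more of the fragment's
#' markers whose provisional frequency difference between the accession's
#' own taxon and some other taxon is at least `differentialDelta`.
#' The donor taxon is the other taxon supporting the most condition-(b)
#' markers. Test accessions are never flagged. A per-fragment PCoA is
#' available separately via [smDissimilarity()] + [pcoa()] for visual audit.
#'
#' @param x a [TaxaGenotypes-class] object with fragments and a taxon map.
#' @param freqs provisional per-taxon frequencies (default computed from all
#'   reference accessions).
#' @param hetThreshold fragment-Ho screen (default 0.3).
#' @param minDifferentialHets minimum heterozygous differential markers
#'   (default 2; guards against single genotyping errors).
#' @param differentialDelta minimum between-taxon frequency difference for a
#'   marker to count as differential (default 0.8; tolerates frequency
#'   dilution by the very introgressions being flagged).
#' @return data.frame with one row per flagged (accession, fragment):
#'   `accession_id`, `fragment_id`, `taxon`, `donor_taxon`, `fragment_ho`,
#'   `n_differential_hets`.
#' @export
flagIntrogressed <- function(x, freqs = NULL, hetThreshold = 0.3,
                             minDifferentialHets = 2,
                             differentialDelta = 0.8) {
  tx <- x@taxa
  if (!nrow(tx)) stop("no taxon map attached")
  if (is.null(freqs)) freqs <- taxonFreqs(x)
  taxa <- names(freqs)
  fh <- fragmentHet(x)
  mk <- x@markers
  g <- x@geno
  ids <- freqs[[1]]$marker_id
  pmat <- sapply(freqs, function(f) f$p)
  pmat <- matrix(pmat, ncol = length(taxa), dimnames = list(ids, taxa))
  ord <- match(markerIds(x), ids)
  if (anyNA(ord)) stop("freqs do not cover this marker set")
  pmat <- pmat[ord, , drop = FALSE]  # align rows with the genotype matrix
  refs <- tx[tx$role == "REFERENCE" & !is.na(tx$taxon), ]
  refs <- refs[refs$accession_id %in% accessionIds(x), ]
  out <- list()
  for (a in seq_len(nrow(refs))) {
    acc <- refs$accession_id[a]
    own <- refs$taxon[a]
    het_rows <- which(!is.na(g[, acc]) & g[, acc] == 1 &
                        !is.na(mk$fragment_id))
    if (!length(het_rows)) next
    # markers differential between own taxon and each other taxon
    delta <- abs(pmat[het_rows, own] -
                   pmat[het_rows, setdiff(taxa, own), drop = FALSE])
    for (frag in unique(mk$fragment_id[het_rows])) {
      ho <- fh$ho[acc, frag]
      if (is.na(ho) || ho < hetThreshold) next
      in_frag <- mk$fragment_id[het_rows] == frag
      counts <- colSums(delta[in_frag, , drop = FALSE] >= differentialDelta,
                        na.rm = TRUE)
      if (!length(counts) || max(counts) < minDifferentialHets) next
      donor <- names(counts)[which.max(counts)]
      out[[length(out) + 1]] <- data.frame(
        accession_id = acc, fragment_id = frag, taxon = own,
        donor_taxon = donor, fragment_ho = ho,
        n_differential_hets = max(counts), stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(accession_id = character(), fragment_id = character(),
               taxon = character(), donor_taxon = character(),
               fragment_ho = numeric(), n_differential_hets = integer(),
               stringsAsFactors = FALSE)
}

#' Mask flagged accession x fragment calls
#'
#' Sets every call of a flagged accession within a flagged fragment to
#' missing. Masking only removes data; no call is ever altered or added.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param flags data.frame from [flagIntrogressed()].
#' @return a new `TaxaGenotypes` with the flagged calls set to `NA`.
#' @export
maskFlagged <- function(x, flags) {
  g <- x@geno
  mk <- x@markers
  for (i in seq_len(nrow(flags))) {
    rows <- which(!is.na(mk$fragment_id) &
                    mk$fragment_id == flags$fragment_id[i])
    g[rows, flags$accession_id[i]] <- NA_integer_
  }
  initialize(x, geno = g)
}

#' Re-mine the diagnostic panel after introgression masking
#'
#' Full masking pipeline: provisional per-taxon frequencies -> introgression
#' flags -> masked genotypes -> re-estimated frequencies -> G_ST re-scan ->
#' panels before and after. Optionally iterates flagging and masking
#' `passes` times (flags accumulate); one pass is the default, matching a
#' single re-estimation. Markers left with zero callable gene copies in some
#' taxon after masking are dropped from the post panel and listed in the
#' report.
#'
#' @param x a [TaxaGenotypes-class] object with fragments and a taxon map.
#' @param hetThreshold,minDifferentialHets,differentialDelta flagging
#'   parameters, see [flagIntrogressed()].
#' @param diagThreshold,specificMaxGst,qcThreshold mining parameters, see
#'   [classifyMarkers()] and [buildPanel()].
#' @param passes number of flag-and-mask passes (default 1).
#' @return list with `pre_panel`, `post_panel`, `flags`, `gst_pre`,
#'   `gst_post`, `delta_report` (per-taxon diagnostic counts before/after),
#'   `dropped_markers` and the `masked` genotype object.
#' @export
remineWithMask <- function(x, hetThreshold = 0.3, minDifferentialHets = 2,
                           differentialDelta = 0.8, diagThreshold = 0.9,
                           specificMaxGst = 0.5, qcThreshold = 0.1,
                           passes = 1) {
  freq_pre <- taxonFreqs(x)
  gst_pre <- gstScan(freq_pre)
  cls_pre <- classifyMarkers(gst_pre, freq_pre, diagThreshold, specificMaxGst)
  pre_panel <- suppressWarnings(buildPanel(cls_pre, freq_pre, qcThreshold))

  masked <- x
  all_flags <- NULL
  for (pass in seq_len(passes)) {
    flags <- flagIntrogressed(masked, freqs = taxonFreqs(masked),
                              hetThreshold = hetThreshold,
                              minDifferentialHets = minDifferentialHets,
                              differentialDelta = differentialDelta)
    if (!nrow(flags)) break
    all_flags <- rbind(all_flags, flags)
    masked <- maskFlagged(masked, flags)
  }
  if (is.null(all_flags))
    all_flags <- flagIntrogressed(x)[0, ]

  freq_post <- taxonFreqs(masked)
  # markers with zero callable genes in some taxon post-mask are dropped
  dropped <- character()
  for (tx in names(freq_post)) {
    z <- freq_post[[tx]]$n_genes == 0 & freq_pre[[tx]]$n_genes > 0
    dropped <- union(dropped, freq_post[[tx]]$marker_id[z])
  }
  gst_post <- gstScan(freq_post)
  cls_post <- classifyMarkers(gst_post, freq_post, diagThreshold,
                              specificMaxGst)
  cls_post$class[cls_post$marker_id %in% dropped] <- "ND"
  cls_post$taxon[cls_post$marker_id %in% dropped] <- NA_character_
  post_panel <- suppressWarnings(buildPanel(cls_post, freq_post, qcThreshold))
  post_panel <- post_panel[!post_panel$marker_id %in% dropped, , drop = FALSE]

  taxa <- names(freq_pre)
  delta <- data.frame(
    taxon = taxa,
    diagnostic_pre = vapply(taxa, function(t)
      sum(cls_pre$class == "DIAGNOSTIC" & cls_pre$taxon == t, na.rm = TRUE),
      integer(1)),
    diagnostic_post = vapply(taxa, function(t)
      sum(cls_post$class == "DIAGNOSTIC" & cls_post$taxon == t,
          na.rm = TRUE), integer(1)),
    panel_pre = vapply(taxa, function(t)
      sum(pre_panel$taxon == t), integer(1)),
    panel_post = vapply(taxa, function(t)
      sum(post_panel$taxon == t), integer(1)),
    stringsAsFactors = FALSE)
  list(pre_panel = pre_panel, post_panel = post_panel, flags = all_flags,
       gst_pre = gst_pre, gst_post = gst_post,
       classification_pre = cls_pre, classification_post = cls_post,
       delta_report = delta, dropped_markers = dropped, masked = masked)
}
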