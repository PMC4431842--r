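# Admixture profiling from diagnostic-allele zygosity, direct contribution
# estimation, and dosage PCA ordination.

#' Diagnostic-allele zygosity profile of accessions
#'
#' For each accession and each taxon's panel markers with a non-missing
#' call: `FHom`, `FHet` and `FAbs` are the fractions of markers at which
#' the accession carries two, one and zero copies of the taxon's diagnostic
#' allele. The three fractions always partition to one where calls exist;
#' taxa with no called panel marker get `NA` fractions. A sample F1 between
#' two taxa shows `FHet = 1` on both parental panels and `FAbs = 1`
#' elsewhere.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param panel data.frame from [buildPanel()] (`taxon`, `marker_id`,
#'   `diagnostic_allele`).
#' @param accessions accession ids to profile (default: all accessions with
#'   role `TEST` if a taxon map is attached, else all).
#' @return data.frame with one row per (accession, taxon): `accession_id`,
#'   `taxon`, `n_markers_called`, `FHom`, `FHet`, `FAbs`.
#' @export
admixtureProfile <- function(x, panel, accessions = NULL) {
  if (!nrow(panel)) stop("empty panel")
  if (is.null(accessions)) {
    tx <- x@taxa
    accessions <- if (nrow(tx) && any(tx$role == "TEST"))
      intersect(tx$accession_id[tx$role == "TEST"], accessionIds(x))
    else accessionIds(x)
  }
  g <- x@geno
  taxa <- unique(panel$taxon)
  out <- list()
  for (acc in accessions) {
    for (t in taxa) {
      sub <- panel[panel$taxon == t, ]
      rows <- match(sub$marker_id, markerIds(x))
      d <- g[rows, acc]
      # dosage of the diagnostic allele (may be the ref allele)
      dd <- ifelse(sub$diagnostic_allele == "alt", d, 2 - d)
      dd <- dd[!is.na(dd)]
      n <- length(dd)
      out[[length(out) + 1]] <- data.frame(
        accession_id = acc, taxon = t, n_markers_called = n,
        FHom = if (n) mean(dd == 2) else NA_real_,
        FHet = if (n) mean(dd == 1) else NA_real_,
        FAbs = if (n) mean(dd == 0) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Direct ancestry-contribution estimate from a zygosity profile
#'
#' The raw share of taxon t is its mean diagnostic-allele dosage over the
#' panel divided by two, `s_t = FHom_t + FHet_t / 2`, normalised across
#' taxa: `c_t = s_t / sum(s)`. Per-taxon normalisation happens before the
#' cross-taxon division, so unequal panel sizes do not bias the estimate.
#' Accessions whose shares are all zero (or all panels uncalled) get `NA`
#' contributions.
#'
#' @param profile data.frame from [admixtureProfile()].
#' @return the profile with a `contribution` column appended.
#' @export
contributionEstimate <- function(profile) {
  res <- lapply(split(profile, profile$accession_id), function(d) {
    s <- ifelse(is.na(d$FHom), NA_real_, d$FHom + d$FHet / 2)
    tot <- sum(s, na.rm = TRUE)
    d$contribution <- if (all(is.na(s)) || tot == 0) NA_real_
      else ifelse(is.na(s), 0, s) / tot
    d
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(match(paste(out$accession_id, out$taxon),
                  paste(profile$accession_id, profile$taxon))), ,
      drop = FALSE]
}

#' PCA of accessions on alternate-allele dosage
#'
#' Centers the accessions-by-markers dosage matrix (missing calls imputed
#' to the marker mean, zero-information markers dropped) and decomposes it
#' by singular values. Axis signs are fixed as in [pcoa()] so output is
#' deterministic.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param markers marker ids to use (default all).
#' @param nAxes axes to return (default 4).
#' @return list with `coords` (accessions x axes) and `var_explained`.
#' @export
dosagePca <- function(x, markers = markerIds(x), nAxes = 4) {
  g <- t(x@geno[markers, , drop = FALSE])  # accessions x markers
  if (nrow(g) < 2) stop("need >= 2 accessions")
  storage.mode(g) <- "double"
  for (j in seq_len(ncol(g))) {
    m <- mean(g[, j], na.rm = TRUE)
    if (is.nan(m)) m <- 0
    g[is.na(g[, j]), j] <- m
  }
  gc <- scale(g, center = TRUE, scale = FALSE)
  sv <- svd(gc)
  lambda <- sv$d^2
  keep <- which(lambda > 1e-9 * max(lambda, 1e-300))
  k <- min(nAxes, length(keep))
  if (k == 0) {
    coords <- matrix(0, nrow(g), 1, dimnames = list(rownames(g), "Axis1"))
    return(list(coords = coords, var_explained = 0))
  }
  coords <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  rownames(coords) <- rownames(g)
  coords <- fixAxisSigns(coords)
  colnames(coords) <- paste0("Axis", seq_len(k))
  list(coords = coords,
       var_explained = lambda[seq_len(k)] / sum(lambda))
}

#' Published WGS versus diagnostic-marker C. maxima contributions
#'
#' Six citrus varieties with a whole-genome-sequencing-derived C. maxima
#' genome proportion (Wu et al. 2014, Nat. Biotechnol. 32:656-662) alongside
#' the corresponding estimate from a species-diagnostic SNP marker panel.
#' Bundled as a cross-validation example for contribution estimates.
#'
#' @return data.frame with `variety`, `wgs` and `markers` columns.
#' @export
citrusWgsComparison <- function() {
  data.frame(
    variety = c("sour orange", "sweet orange", "clementine", "W. Murcott",
                "Ponkan", "Willowleaf"),
    wgs = c(0.49, 0.44, 0.21, 0.15, 0.077, 0.045),
    markers = c(0.509, 0.391, 0.236, 0.125, 0.035, 0.040),
    stringsAsFactors = FALSE)
}
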