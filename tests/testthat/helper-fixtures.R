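# Shared fixtures and independent oracles.

# small TaxaGenotypes built directly from a dosage matrix
toyGenotypes <- function(dos, chrom = "chr1", ref = "A", alt = "G",
                         fragments = NULL, taxa = NULL) {
  nm <- nrow(dos)
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("m%02d", seq_len(nm))
  if (is.null(colnames(dos))) colnames(dos) <- sprintf("acc%02d",
                                                       seq_len(ncol(dos)))
  mk <- data.frame(marker_id = rownames(dos), chrom = chrom,
                   pos = seq_len(nm) * 100L, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  if (!is.null(fragments)) {
    # fragments: named list fragment_id -> marker row indices
    mk$fragment_id <- NA_character_
    fr <- data.frame(fragment_id = names(fragments), chrom = chrom,
                     start = NA_integer_, end = NA_integer_,
                     stringsAsFactors = FALSE)
    for (i in seq_along(fragments)) {
      rows <- fragments[[i]]
      mk$fragment_id[rows] <- names(fragments)[i]
      fr$start[i] <- min(mk$pos[rows]) - 10L
      fr$end[i] <- max(mk$pos[rows]) + 10L
    }
    TaxaGenotypes(dos, mk, fr, taxa)
  } else {
    TaxaGenotypes(dos, mk, taxa = taxa)
  }
}

# literal term-by-term evaluation of the focal-vs-rest G_ST formula,
# kept scalar and spelled out independently of gstFocalRest()
oracleGst <- function(pFocal, pOthers) {
  he <- function(p) 1 - p^2 - (1 - p)^2
  pRest <- sum(pOthers) / length(pOthers)
  pTot <- (pFocal + pRest) / 2
  heTot <- he(pTot)
  if (heTot == 0) return(0)
  (heTot - (he(pFocal) + he(pRest)) / 2) / heTot
}

# scalar-loop Weir-Cockerham variance components over the same sums,
# independent of the vectorised implementation
oracleTheta <- function(genoList) {
  # genoList: list of integer dosage vectors (one per population), one locus
  genoList <- lapply(genoList, function(v) v[!is.na(v)])
  genoList <- genoList[vapply(genoList, length, 1L) > 0]
  r <- length(genoList)
  if (r < 2) return(NA_real_)
  n <- vapply(genoList, length, 1L)
  p <- vapply(genoList, function(v) sum(v) / (2 * length(v)), 1)
  h <- vapply(genoList, function(v) mean(v == 1), 1)
  nbar <- 0; for (i in 1:r) nbar <- nbar + n[i] / r
  if (nbar <= 1) return(NA_real_)
  ssq <- 0; for (i in 1:r) ssq <- ssq + n[i]^2
  nc <- (r * nbar - ssq / (r * nbar)) / (r - 1)
  pbar <- 0; for (i in 1:r) pbar <- pbar + n[i] * p[i] / (r * nbar)
  s2 <- 0; for (i in 1:r) s2 <- s2 + n[i] * (p[i] - pbar)^2 / ((r - 1) * nbar)
  hbar <- 0; for (i in 1:r) hbar <- hbar + n[i] * h[i] / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# scenario used for mining-recovery checks: planted fixed differences over
# an undifferentiated polymorphic background. Backgrounds that can
# legitimately reach sample fixation in 10 accessions (taxon-private or
# strongly structured classes) are excluded, because a marker fixed in the
# observed sample is operationally diagnostic there and recovery of the
# planted truth becomes ill-posed.
recoveryConfig <- function(seed, accessionsPerTaxon = 10) {
  scenarioConfig(accessionsPerTaxon = accessionsPerTaxon,
                 fragmentsPerChromosome = 6, markersPerFragment = 19,
                 fixedDiffFraction = 0.1, privateFraction = 0,
                 divergentFraction = 0, sharedFraction = 0.3,
                 seed = seed)
}

# strongly differentiated fragment panel with pummelo introgression into
# four mandarin references, emulating an amplicon set chosen for taxon
# divergence (introgressed fragments reach Ho ~ 0.5)
maskingConfig <- function(seed) {
  scenarioConfig(accessionsPerTaxon = c(11, 9, 5, 1),
                 fragmentsPerChromosome = 6, markersPerFragment = 50,
                 fragmentLength = 1000,
                 fixedDiffFraction = 0.15, privateFraction = 0.01,
                 divergentFraction = 0.34, sharedFraction = 0,
                 introgressions = lapply(sprintf("mandarin_%02d", 1:4),
                                         function(a)
                                           list(accession = a,
                                                donor = "pummelo",
                                                fraction = 0.2)),
                 seed = seed)
}

flagKey <- function(d) paste(d$accession_id, d$fragment_id)
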