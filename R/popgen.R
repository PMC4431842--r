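# Diversity and differentiation statistics: allele frequencies, Ho, unbiased
# He, Fw, Weir-Cockerham F_ST, SNP density, simple-matching dissimilarity,
# group reports and genotype-call concordance.

#' Per-marker alternate-allele frequencies in a group of accessions
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param accessions character vector of accession ids (the group).
#' @return data.frame with `marker_id`, `p` (alternate-allele frequency,
#'   `NA` when no call is available), and `n_genes` (non-missing gene copies,
#'   always even).
#' @examples
#' # genotypes {AA, AB} with alt = B give p = 0.25
#' @export
alleleFreqs <- function(x, accessions) {
  if (length(accessions) == 0) stop("empty group")
  miss <- setdiff(accessions, accessionIds(x))
  if (length(miss)) stop("unknown accession(s): ", paste(miss, collapse = ", "))
  g <- x@geno[, accessions, drop = FALSE]
  n_genes <- 2L * rowSums(!is.na(g))
  alt <- rowSums(g, na.rm = TRUE)
  p <- ifelse(n_genes > 0, alt / n_genes, NA_real_)
  data.frame(marker_id = markerIds(x), p = p, n_genes = n_genes,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Allele frequencies for every taxon's reference accessions
#'
#' @param x a [TaxaGenotypes-class] object with a taxon map attached.
#' @return named list of [alleleFreqs()] tables, one per taxon.
#' @export
taxonFreqs <- function(x) {
  tx <- x@taxa
  if (!nrow(tx)) stop("no taxon map attached")
  refs <- tx[tx$role == "REFERENCE" & !is.na(tx$taxon), ]
  split_acc <- split(refs$accession_id, refs$taxon)
  lapply(split_acc, function(acc) alleleFreqs(x, acc))
}

#' Observed and unbiased expected heterozygosity and the fixation index
#'
#' Per-marker within a group: `Ho` is the fraction of non-missing calls that
#' are heterozygous; `He_nei = 1 - sum(p_i^2)` on the group's allele
#' frequencies; the unbiased small-sample correction is
#' `He = 2n/(2n - 1) * He_nei` with `2n` the non-missing gene copies; and
#' `Fw = 1 - Ho/He` (Wright's fixation index, 0 at Hardy-Weinberg
#' proportions, undefined where `He = 0`). The multilocus summary is the
#' arithmetic mean over markers with defined values, with its standard
#' error.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param accessions accession ids forming the group.
#' @param freqs optional precomputed [alleleFreqs()] for the same group.
#' @return list with `per_marker` (data.frame `marker_id`, `Ho`, `He_nei`,
#'   `He`, `Fw`) and `summary` (one-row data.frame of means and standard
#'   errors).
#' @export
diversityStats <- function(x, accessions, freqs = NULL) {
  if (is.null(freqs)) freqs <- alleleFreqs(x, accessions)
  if (!identical(freqs$marker_id, markerIds(x)))
    stop("freqs were not computed on this marker set")
  g <- x@geno[, accessions, drop = FALSE]
  n_call <- rowSums(!is.na(g))
  if (!identical(as.integer(freqs$n_genes), as.integer(2L * n_call)))
    stop("freqs were not computed on this group")
  ho <- ifelse(n_call > 0, rowSums(g == 1, na.rm = TRUE) / n_call, NA_real_)
  p <- freqs$p
  he_nei <- 2 * p * (1 - p)
  n2 <- freqs$n_genes
  he <- ifelse(n2 > 1, n2 / (n2 - 1) * he_nei, NA_real_)
  fw <- ifelse(!is.na(he) & he > 0, 1 - ho / he, NA_real_)
  per <- data.frame(marker_id = freqs$marker_id, Ho = ho, He_nei = he_nei,
                    He = he, Fw = fw, stringsAsFactors = FALSE)
  mean_se <- function(v) {
    v <- v[!is.na(v)]
    c(mean = mean(v), se = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_)
  }
  s <- c(Ho = mean_se(ho), He = mean_se(he), Fw = mean_se(fw))
  list(per_marker = per,
       summary = as.data.frame(as.list(s), check.names = TRUE))
}

#' Weir-Cockerham F_ST (theta) across a partition of accessions
#'
#' Standard diploid variance-components estimator with components `a`
#' (among populations), `b` (among individuals within populations) and `c`
#' (within individuals). The multilocus estimate is
#' `sum(a) / sum(a + b + c)` over markers with defined components. Sample
#' sizes are per-marker non-missing counts, so missing calls are handled
#' marker-wise. The estimator can go slightly negative when there is no
#' between-group variance.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param groups named list of accession-id vectors (the populations).
#' @return list with `per_marker` (data.frame `marker_id`, `a`, `b`, `c`,
#'   `theta`) and `theta` (multilocus estimate).
#' @export
wcFst <- function(x, groups) {
  if (length(groups) < 2) stop("need at least two groups")
  g <- x@geno
  r <- length(groups)
  nm <- nrow(g)
  n_mat <- sapply(groups, function(acc)
    rowSums(!is.na(g[, acc, drop = FALSE])))
  p_mat <- sapply(groups, function(acc) {
    sub <- g[, acc, drop = FALSE]
    n <- rowSums(!is.na(sub))
    ifelse(n > 0, rowSums(sub, na.rm = TRUE) / (2 * n), NA_real_)
  })
  h_mat <- sapply(groups, function(acc) {
    sub <- g[, acc, drop = FALSE]
    n <- rowSums(!is.na(sub))
    ifelse(n > 0, rowSums(sub == 1, na.rm = TRUE) / n, NA_real_)
  })
  n_mat <- matrix(n_mat, nrow = nm); p_mat <- matrix(p_mat, nrow = nm)
  h_mat <- matrix(h_mat, nrow = nm)
  a <- b <- cc <- rep(NA_real_, nm)
  for (i in seq_len(nm)) {
    ni <- n_mat[i, ]; keep <- ni > 0
    ri <- sum(keep)
    if (ri < 2) next
    ni <- ni[keep]; pi <- p_mat[i, keep]; hi <- h_mat[i, keep]
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
    pbar <- sum(ni * pi) / (ri * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((ri - 1) * nbar)
    hbar <- sum(ni * hi) / (ri * nbar)
    if (nc <= 0) next
    a[i] <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((ri - 1) / ri) * s2 -
                                  hbar / 4))
    b[i] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((ri - 1) / ri) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc[i] <- hbar / 2
  }
  tot <- a + b + cc
  theta_marker <- ifelse(!is.na(tot) & tot != 0, a / tot, NA_real_)
  ok <- !is.na(tot) & tot != 0
  theta <- if (any(ok)) sum(a[ok]) / sum(tot[ok]) else NA_real_
  list(per_marker = data.frame(marker_id = markerIds(x), a = a, b = b,
                               c = cc, theta = theta_marker,
                               stringsAsFactors = FALSE),
       theta = theta)
}

#' SNP density per fragment and per chromosome
#'
#' Density is `1000 * markers / length_bp`; per-chromosome values pool
#' marker counts and fragment lengths before dividing.
#'
#' @param markers marker table (needs `marker_id`, `fragment_id`).
#' @param fragments fragment table (needs `fragment_id`, `chrom`,
#'   `length_bp`).
#' @return list of data.frames `per_fragment`, `per_chromosome` and `total`
#'   (one row: pooled count, pooled length, SNP/kb).
#' @export
snpDensity <- function(markers, fragments) {
  if (any(fragments$length_bp <= 0)) stop("fragment lengths must be > 0")
  assigned <- markers$fragment_id[!is.na(markers$fragment_id)]
  unknown <- setdiff(assigned, fragments$fragment_id)
  if (length(unknown))
    stop("marker assigned to unknown fragment: ",
         paste(unknown, collapse = ", "))
  cnt <- table(factor(assigned, levels = fragments$fragment_id))
  per_frag <- data.frame(fragment_id = fragments$fragment_id,
                         chrom = fragments$chrom,
                         n_snps = as.integer(cnt),
                         length_bp = fragments$length_bp,
                         snp_per_kb = 1000 * as.integer(cnt) /
                           fragments$length_bp,
                         stringsAsFactors = FALSE)
  agg_n <- tapply(per_frag$n_snps, per_frag$chrom, sum)
  agg_l <- tapply(per_frag$length_bp, per_frag$chrom, sum)
  per_chr <- data.frame(chrom = names(agg_n),
                        n_snps = as.integer(agg_n),
                        length_bp = as.integer(agg_l),
                        snp_per_kb = 1000 * as.integer(agg_n) /
                          as.integer(agg_l),
                        row.names = NULL, stringsAsFactors = FALSE)
  total <- data.frame(n_snps = sum(per_frag$n_snps),
                      length_bp = sum(per_frag$length_bp),
                      snp_per_kb = 1000 * sum(per_frag$n_snps) /
                        sum(per_frag$length_bp))
  list(per_fragment = per_frag, per_chromosome = per_chr, total = total)
}

#' Simple-matching dissimilarity between accessions
#'
#' Per locus the similarity between two diploid genotypes is the number of
#' shared allele copies (counting multiplicity) divided by two; for dosages
#' `d1`, `d2` at a biallelic marker this is `(2 - |d1 - d2|)/2`. The
#' dissimilarity is one minus the mean similarity over loci where both
#' accessions are called. Pairs with zero comparable loci get `NA`.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param accessions accession ids (default all).
#' @return list with `d` (symmetric dissimilarity matrix, zero diagonal) and
#'   `n_loci` (per-pair count of loci compared).
#' @export
smDissimilarity <- function(x, accessions = accessionIds(x)) {
  g <- x@geno[, accessions, drop = FALSE]
  n <- ncol(g)
  d <- matrix(0, n, n, dimnames = list(accessions, accessions))
  nl <- matrix(0L, n, n, dimnames = list(accessions, accessions))
  for (i in seq_len(n)) {
    nl[i, i] <- sum(!is.na(g[, i]))
    for (j in seq_len(n)[-seq_len(i)]) {
      ok <- !is.na(g[, i]) & !is.na(g[, j])
      m <- sum(ok)
      nl[i, j] <- nl[j, i] <- m
      if (m == 0) {
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        sim <- (2 - abs(g[ok, i] - g[ok, j])) / 2
        d[i, j] <- d[j, i] <- 1 - mean(sim)
      }
    }
  }
  list(d = d, n_loci = nl)
}

#' Per-group summary report
#'
#' For each group: sample size `Na`, missing data percentage `MD`, number of
#' polymorphic loci `PL` (>= 2 alleles observed within the group), mean
#' observed heterozygosity `Ho`, mean unbiased expected heterozygosity `He`,
#' mean fixation index `Fw`, and the number of distinct multilocus genotypes
#' `NSG`. Genotype identity treats missing calls as compatible with any call
#' (accessions are pooled greedily against group representatives); set
#' `strictNSG = TRUE` to require exact vector equality instead.
#'
#' @param x a [TaxaGenotypes-class] object.
#' @param groups named list of accession-id vectors.
#' @param strictNSG logical; see above.
#' @return data.frame with columns `group`, `Na`, `MD`, `PL`, `Ho`, `He`,
#'   `Fw`, `NSG`.
#' @export
groupReport <- function(x, groups, strictNSG = FALSE) {
  rows <- lapply(names(groups), function(nm) {
    acc <- groups[[nm]]
    if (!length(acc)) stop("empty group: ", nm)
    g <- x@geno[, acc, drop = FALSE]
    md <- 100 * sum(is.na(g)) / length(g)
    pl <- sum(apply(g, 1, function(v) {
      v <- v[!is.na(v)]
      length(v) > 0 && (any(v == 1) || (any(v == 0) && any(v == 2)))
    }))
    ds <- diversityStats(x, acc)
    nsg <- countMultilocusGenotypes(g, strict = strictNSG)
    data.frame(group = nm, Na = length(acc), MD = md, PL = pl,
               Ho = ds$summary$Ho.mean, He = ds$summary$He.mean,
               Fw = ds$summary$Fw.mean, NSG = nsg,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

countMultilocusGenotypes <- function(g, strict = FALSE) {
  n <- ncol(g)
  if (n == 0) return(0L)
  if (strict) {
    return(length(unique(apply(g, 2, paste, collapse = ","))))
  }
  reps <- list(g[, 1])
  for (j in seq_len(n)[-1]) {
    v <- g[, j]
    placed <- FALSE
    for (k in seq_along(reps)) {
      r <- reps[[k]]
      ok <- is.na(v) | is.na(r) | v == r
      if (all(ok)) {
        # merge information: fill the representative's missing calls
        r[is.na(r)] <- v[is.na(r)]
        reps[[k]] <- r
        placed <- TRUE
        break
      }
    }
    if (!placed) reps[[length(reps) + 1]] <- v
  }
  length(reps)
}

#' Genotype-call concordance between two matrices
#'
#' Compares calls over the shared accessions and markers; pairs with a
#' missing call in either matrix are excluded. Returns per-marker discrepancy
#' rates for ranking problem assays plus the overall rate.
#'
#' @param x1,x2 [TaxaGenotypes-class] objects (e.g. two genotyping methods).
#' @return list with `overall` (fraction in `[0,1]`, `NA` when nothing is
#'   comparable), `n_compared`, and `per_marker` data.frame (`marker_id`,
#'   `n_compared`, `discrepancy`).
#' @export
callConcordance <- function(x1, x2) {
  acc <- intersect(accessionIds(x1), accessionIds(x2))
  mks <- intersect(markerIds(x1), markerIds(x2))
  if (!length(acc) || !length(mks))
    stop("no overlapping accessions/markers between the two matrices")
  g1 <- x1@geno[mks, acc, drop = FALSE]
  g2 <- x2@geno[mks, acc, drop = FALSE]
  ok <- !is.na(g1) & !is.na(g2)
  diff <- ok & (g1 != g2)
  per <- data.frame(marker_id = mks,
                    n_compared = rowSums(ok),
                    discrepancy = ifelse(rowSums(ok) > 0,
                                         rowSums(diff) / rowSums(ok),
                                         NA_real_),
                    stringsAsFactors = FALSE)
  list(overall = if (sum(ok) > 0) sum(diff) / sum(ok) else NA_real_,
       n_compared = sum(ok), per_marker = per)
}
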