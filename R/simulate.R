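# Synthetic genotype simulator: differentiated ancestral taxa under
# Hardy-Weinberg, pedigreed hybrids with whole-fragment gamete transmission,
# fragment-level introgression injection, and truth tables for every
# planted feature.

#' Scenario configuration for the genotype simulator
#'
#' Defaults emulate a four-taxon amplicon-resequencing design: 26 reference
#' accessions (11/9/5/1 per taxon), 9 chromosomes carrying short gene
#' fragments, and a marker-class mix in which roughly a quarter of markers
#' are per-taxon fixed differences, half are taxon-private polymorphisms and
#' the rest are shared or monomorphic.
#'
#' Marker generating classes:
#' * `fixed_<taxon>`: diagnostic allele at frequency 1 in the focal taxon,
#'   0 elsewhere.
#' * `private_<taxon>`: minor allele segregating in one taxon only, at a
#'   frequency drawn from `Beta(mafShape1, mafShape2)`.
#' * `divergent`: frequency drawn independently per taxon from a high arm
#'   `Beta(8, 2)` or low arm `Beta(2, 8)` (arms assigned at random,
#'   never all taxa on one arm), emulating strongly structured shared
#'   polymorphism.
#' * `shared`: one frequency drawn from `Beta(mafShape1, mafShape2)` and
#'   used in every taxon.
#' * `monomorphic`: frequency 0 everywhere.
#'
#' @param taxa taxon labels (default the four ancestral citrus gene pools).
#' @param accessionsPerTaxon integer vector recycled over taxa
#'   (default `c(11, 9, 5, 1)`).
#' @param nChromosomes default 9.
#' @param fragmentsPerChromosome default 6 (54 fragments, close to a
#'   57-fragment panel).
#' @param markersPerFragment default 18 (about 37 SNP/kb on 500-bp
#'   fragments).
#' @param fragmentLength fragment length in bp (default 500).
#' @param fixedDiffFraction per-taxon fixed-difference fraction
#'   (default 0.065; four taxa give ~26% diagnostic markers).
#' @param privateFraction per-taxon private-polymorphism fraction
#'   (default 0.12).
#' @param divergentFraction strongly structured shared polymorphism
#'   (default 0.09).
#' @param sharedFraction undifferentiated shared polymorphism
#'   (default 0.05).
#' @param mafShape1,mafShape2 Beta parameters of the within-taxon minor
#'   allele frequency distribution (default `Beta(0.5, 3)`, a skewed site
#'   frequency spectrum).
#' @param missingRate per-call missing probability (default 0).
#' @param hybrids list of pedigree entries, each a list with `id`, `type`
#'   (`"F1"`, `"BC1"` or `"CROSS"`) and parent specs: for `F1` two taxon
#'   labels (`parentA`, `parentB`, gametes drawn from random reference
#'   accessions of those taxa); for `BC1`/`CROSS` two accession ids
#'   (`parentA`, `parentB`) that must already exist (earlier hybrids may be
#'   parents).
#' @param introgressions list of entries with `accession` (a reference
#'   accession id), `donor` (taxon label) and `fraction` (share of fragments
#'   replaced by a donor-heterozygous state).
#' @param seed integer RNG seed; identical configs reproduce identical
#'   datasets.
#' @return validated config (class `scenario_config`).
#' @export
scenarioConfig <- function(taxa = c("mandarin", "pummelo", "citron",
                                    "micrantha"),
                           accessionsPerTaxon = c(11, 9, 5, 1),
                           nChromosomes = 9, fragmentsPerChromosome = 6,
                           markersPerFragment = 18, fragmentLength = 500,
                           fixedDiffFraction = 0.065,
                           privateFraction = 0.12,
                           divergentFraction = 0.09,
                           sharedFraction = 0.05,
                           mafShape1 = 0.5, mafShape2 = 3,
                           missingRate = 0, hybrids = list(),
                           introgressions = list(), seed = 1) {
  k <- length(taxa)
  cfg <- list(taxa = taxa,
              accessionsPerTaxon = rep_len(accessionsPerTaxon, k),
              nChromosomes = nChromosomes,
              fragmentsPerChromosome = fragmentsPerChromosome,
              markersPerFragment = markersPerFragment,
              fragmentLength = fragmentLength,
              fixedDiffFraction = fixedDiffFraction,
              privateFraction = privateFraction,
              divergentFraction = divergentFraction,
              sharedFraction = sharedFraction,
              mafShape1 = mafShape1, mafShape2 = mafShape2,
              missingRate = missingRate, hybrids = hybrids,
              introgressions = introgressions, seed = as.integer(seed))
  tot <- k * (fixedDiffFraction + privateFraction) + divergentFraction +
    sharedFraction
  if (tot > 1 + 1e-9)
    stop("config error: class fractions sum to ", round(tot, 3), " > 1")
  fracs <- c(fixedDiffFraction, privateFraction, divergentFraction,
             sharedFraction, missingRate)
  if (any(fracs < 0 | fracs > 1)) stop("config error: fractions must be in [0,1]")
  structure(cfg, class = "scenario_config")
}

# deterministic sub-seed per stage, kept below 2^31
subSeed <- function(seed, stage) {
  (as.double(seed) * 48271 + stage * 9973) %% 2147483647
}

#' Sample per-taxon allele frequencies and marker truth classes
#'
#' Assigns every marker a generating class (see [scenarioConfig()]) by a
#' seeded multinomial draw and samples the per-taxon alternate-allele
#' frequencies accordingly.
#'
#' @param config a [scenarioConfig()] object.
#' @return list with `freq` (markers x taxa matrix), `truth` (data.frame
#'   `marker_id`, `true_class`, `true_taxon`) and `marker_ids`.
#' @export
sampleTaxonFrequencies <- function(config) {
  set.seed(subSeed(config$seed, 1))
  k <- length(config$taxa)
  n_mk <- config$nChromosomes * config$fragmentsPerChromosome *
    config$markersPerFragment
  classes <- c(paste0("fixed_", config$taxa),
               paste0("private_", config$taxa),
               "divergent", "shared", "monomorphic")
  probs <- c(rep(config$fixedDiffFraction, k),
             rep(config$privateFraction, k),
             config$divergentFraction, config$sharedFraction,
             1 - k * (config$fixedDiffFraction + config$privateFraction) -
               config$divergentFraction - config$sharedFraction)
  cls <- sample(classes, n_mk, replace = TRUE, prob = probs)
  freq <- matrix(0, n_mk, k, dimnames = list(NULL, config$taxa))
  for (i in seq_len(n_mk)) {
    c_i <- cls[i]
    if (startsWith(c_i, "fixed_")) {
      freq[i, sub("fixed_", "", c_i)] <- 1
    } else if (startsWith(c_i, "private_")) {
      freq[i, sub("private_", "", c_i)] <-
        rbeta(1, config$mafShape1, config$mafShape2)
    } else if (c_i == "divergent") {
      repeat {
        arm <- runif(k) < 0.5
        if (length(unique(arm)) == 2) break
      }
      freq[i, ] <- ifelse(arm, rbeta(k, 8, 2), rbeta(k, 2, 8))
    } else if (c_i == "shared") {
      freq[i, ] <- rbeta(1, config$mafShape1, config$mafShape2)
    }  # monomorphic: all zero
  }
  ids <- sprintf("m%05d", seq_len(n_mk))
  truth <- data.frame(
    marker_id = ids,
    true_class = ifelse(startsWith(cls, "fixed_"), "fixed",
                        ifelse(startsWith(cls, "private_"), "private", cls)),
    true_taxon = ifelse(grepl("^(fixed|private)_", cls),
                        sub("^(fixed|private)_", "", cls), NA_character_),
    stringsAsFactors = FALSE)
  list(freq = freq, truth = truth, marker_ids = ids)
}

#' Sample reference accessions under Hardy-Weinberg proportions
#'
#' Genotypes are drawn independently across markers within each taxon:
#' dosage ~ Binomial(2, p). Missingness is injected uniformly at the
#' configured rate.
#'
#' @param freq markers x taxa frequency matrix.
#' @param config a [scenarioConfig()] object.
#' @return list with `geno` (markers x accessions dosage matrix) and
#'   `taxa_map` data.frame.
#' @export
sampleReferenceAccessions <- function(freq, config) {
  set.seed(subSeed(config$seed, 2))
  n_mk <- nrow(freq)
  acc_ids <- character(); acc_tax <- character()
  for (t in seq_along(config$taxa)) {
    n <- config$accessionsPerTaxon[t]
    acc_ids <- c(acc_ids, sprintf("%s_%02d", config$taxa[t], seq_len(n)))
    acc_tax <- c(acc_tax, rep(config$taxa[t], n))
  }
  geno <- matrix(NA_integer_, n_mk, length(acc_ids),
                 dimnames = list(rownames(freq), acc_ids))
  for (j in seq_along(acc_ids)) {
    p <- freq[, acc_tax[j]]
    geno[, j] <- rbinom(n_mk, 2, p)
  }
  if (config$missingRate > 0) {
    drop <- runif(length(geno)) < config$missingRate
    geno[drop] <- NA_integer_
  }
  list(geno = geno,
       taxa_map = data.frame(accession_id = acc_ids, taxon = acc_tax,
                             role = "REFERENCE", stringsAsFactors = FALSE))
}

# one gamete: per fragment pick one of the parent's two haplotypes.
# Without phase, within a fragment the gamete takes, marker-wise, a random
# allele at heterozygous sites of the chosen... transmission here is
# haplotype-free: dosage 0 -> 0, dosage 2 -> 1, dosage 1 -> Bernoulli(0.5)
# drawn ONCE PER FRAGMENT jointly is impossible without phase, so
# heterozygous sites segregate independently only BETWEEN fragments when the
# parent is an F1 whose fragments are internally non-recombinant. For
# reference parents (unphased HWE draws) marker-wise segregation is exact;
# for pedigree parents we carry phased haplotypes explicitly instead.
gameteFromDosage <- function(d, frag_index) {
  g <- integer(length(d))
  hom2 <- !is.na(d) & d == 2
  het <- !is.na(d) & d == 1
  g[hom2] <- 1L
  g[het] <- rbinom(sum(het), 1, 0.5)
  g[is.na(d)] <- NA_integer_
  g
}

# phased gamete: parent as two haplotype vectors, one whole haplotype
# chosen per fragment (free recombination between fragments, none within)
gameteFromHaplotypes <- function(hapA, hapB, frag_index) {
  frag_ids <- unique(frag_index)
  pick <- setNames(rbinom(length(frag_ids), 1, 0.5), frag_ids)
  unname(ifelse(pick[frag_index] == 1, hapA, hapB))
}

#' Cross two accessions with whole-fragment gamete transmission
#'
#' Each gamete transmits one parental haplotype per gene fragment: free
#' recombination between fragments, none within. Parents are given as
#' phased haplotype pairs; [buildScenario()] maintains phase for every
#' simulated accession (reference accessions are phased at random, which is
#' exchangeable under Hardy-Weinberg sampling).
#'
#' @param parentA,parentB lists with elements `hap1` and `hap2` (0/1
#'   haplotype vectors over the shared marker set).
#' @param fragIndex fragment id per marker.
#' @return list with `hap1`, `hap2` (the two inherited gametes) and
#'   `dosage`.
#' @export
makeCross <- function(parentA, parentB, fragIndex) {
  g1 <- gameteFromHaplotypes(parentA$hap1, parentA$hap2, fragIndex)
  g2 <- gameteFromHaplotypes(parentB$hap1, parentB$hap2, fragIndex)
  list(hap1 = g1, hap2 = g2, dosage = g1 + g2)
}

#' Build a complete synthetic scenario
#'
#' Composes frequency sampling, Hardy-Weinberg reference sampling, pedigree
#' crosses and introgression injection, and returns a loadable
#' [TaxaGenotypes-class] plus truth tables for every planted feature.
#' Introgression replaces one haplotype of the target accession with a
#' donor-taxon gamete on the selected fragments, producing the
#' donor-heterozygous signature of interspecific introgression.
#'
#' @param config a [scenarioConfig()] object.
#' @return list with `genotypes` (a `TaxaGenotypes` with taxon map
#'   attached), `truth` (list: `markers`, `accessions` with per-taxon
#'   expected genome fractions, `introgression` with the injected
#'   (accession, fragment, donor) triples), and `freq` (the generating
#'   frequencies).
#' @export
buildScenario <- function(config) {
  sf <- sampleTaxonFrequencies(config)
  refs <- sampleReferenceAccessions(sf$freq, config)
  n_mk <- nrow(sf$freq)
  k <- length(config$taxa)

  # marker map: fragments laid consecutively along chromosomes
  n_frag <- config$nChromosomes * config$fragmentsPerChromosome
  frag_ids <- sprintf("frag%03d", seq_len(n_frag))
  frag_chrom <- rep(sprintf("chr%d", seq_len(config$nChromosomes)),
                    each = config$fragmentsPerChromosome)
  frag_offset <- rep(seq_len(config$fragmentsPerChromosome) - 1,
                     config$nChromosomes)
  frag_start <- 10000L + frag_offset * (config$fragmentLength + 5000L) + 1L
  fragments <- data.frame(fragment_id = frag_ids, chrom = frag_chrom,
                          start = frag_start,
                          end = frag_start + config$fragmentLength - 1L,
                          length_bp = config$fragmentLength,
                          stringsAsFactors = FALSE)
  frag_index <- rep(frag_ids, each = config$markersPerFragment)
  within <- ave(seq_len(n_mk), frag_index, FUN = seq_along)
  step <- max(1L, config$fragmentLength %/% (config$markersPerFragment + 1L))
  markers <- data.frame(
    marker_id = sf$marker_ids,
    chrom = rep(frag_chrom, each = config$markersPerFragment),
    pos = fragments$start[match(frag_index, frag_ids)] + within * step,
    ref = "A", alt = "G", fragment_id = frag_index,
    stringsAsFactors = FALSE)

  set.seed(subSeed(config$seed, 3))
  # phase the reference accessions (exchangeable under HWE)
  haplos <- list()
  for (acc in colnames(refs$geno)) {
    d <- refs$geno[, acc]
    h1 <- gameteFromDosage(d, frag_index)
    h2 <- ifelse(is.na(d), NA_integer_, d - h1)
    haplos[[acc]] <- list(hap1 = h1, hap2 = h2)
  }
  geno <- refs$geno
  taxa_map <- refs$taxa_map
  frac <- stats::setNames(
    lapply(taxa_map$taxon, function(t)
      stats::setNames(as.numeric(config$taxa == t), config$taxa)),
    taxa_map$accession_id)

  # pedigree crosses
  set.seed(subSeed(config$seed, 4))
  for (h in config$hybrids) {
    pick_parent <- function(spec) {
      if (spec %in% names(haplos)) return(spec)
      if (spec %in% config$taxa) {
        cand <- taxa_map$accession_id[taxa_map$taxon == spec &
                                        taxa_map$role == "REFERENCE"]
        return(sample(cand, 1))
      }
      stop("config error: pedigree references unknown accession ", spec)
    }
    pa <- pick_parent(h$parentA); pb <- pick_parent(h$parentB)
    off <- makeCross(haplos[[pa]], haplos[[pb]], frag_index)
    haplos[[h$id]] <- off[c("hap1", "hap2")]
    geno <- cbind(geno, setNames(data.frame(off$dosage), h$id)[[1]])
    colnames(geno)[ncol(geno)] <- h$id
    taxa_map <- rbind(taxa_map,
                      data.frame(accession_id = h$id, taxon = NA_character_,
                                 role = "TEST", stringsAsFactors = FALSE))
    frac[[h$id]] <- (frac[[pa]] + frac[[pb]]) / 2
  }

  # introgression injection: one resident haplotype + one donor gamete on
  # the selected fragments
  set.seed(subSeed(config$seed, 5))
  intro_truth <- list()
  for (sp in config$introgressions) {
    acc <- sp$accession
    if (!acc %in% colnames(geno))
      stop("config error: introgression targets unknown accession ", acc)
    n_sel <- max(1L, round(sp$fraction * n_frag))
    sel <- sample(frag_ids, n_sel)
    donor_p <- sf$freq[, sp$donor]
    for (fg in sel) {
      rows <- which(frag_index == fg)
      donor_hap <- rbinom(length(rows), 1, donor_p[rows])
      haplos[[acc]]$hap2[rows] <- donor_hap
      geno[rows, acc] <- haplos[[acc]]$hap1[rows] + donor_hap
      intro_truth[[length(intro_truth) + 1]] <-
        data.frame(accession_id = acc, fragment_id = fg,
                   donor_taxon = sp$donor, stringsAsFactors = FALSE)
    }
  }
  storage.mode(geno) <- "integer"

  tg <- TaxaGenotypes(geno, markers, fragments, taxa_map)
  acc_truth <- do.call(rbind, lapply(names(frac), function(a) {
    data.frame(accession_id = a,
               taxon = names(frac[[a]]),
               genome_fraction = as.numeric(frac[[a]]),
               stringsAsFactors = FALSE)
  }))
  list(genotypes = tg,
       truth = list(markers = sf$truth,
                    accessions = acc_truth,
                    introgression = if (length(intro_truth))
                      do.call(rbind, intro_truth)
                    else data.frame(accession_id = character(),
                                    fragment_id = character(),
                                    donor_taxon = character(),
                                    stringsAsFactors = FALSE)),
       freq = sf$freq)
}
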