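test_that("frequency sampling plants the configured marker classes", {
  cfg <- scenarioConfig(fragmentsPerChromosome = 6, markersPerFragment = 19,
                        fixedDiffFraction = 0.1, privateFraction = 0.05,
                        divergentFraction = 0.1, sharedFraction = 0.1,
                        seed = 2)
  sf <- sampleTaxonFrequencies(cfg)
  n <- nrow(sf$freq)
  expect_equal(n, 9 * 6 * 19)
  tab <- table(sf$truth$true_class)
  # ~10% per taxon fixed differences (binomial around 0.4 * n overall)
  expect_gt(tab[["fixed"]], 0.4 * n - 4 * sqrt(n))
  expect_lt(tab[["fixed"]], 0.4 * n + 4 * sqrt(n))
  # fixed markers: p = 1 in the focal taxon, 0 elsewhere
  fixed <- sf$truth$true_class == "fixed"
  for (i in which(fixed)[1:10]) {
    t <- sf$truth$true_taxon[i]
    expect_equal(unname(sf$freq[i, t]), 1)
    expect_equal(unname(sf$freq[i, setdiff(colnames(sf$freq), t)]),
                 rep(0, 3))
  }
  # private markers segregate in exactly one taxon
  priv <- which(sf$truth$true_class == "private")
  for (i in priv[1:5]) {
    t <- sf$truth$true_taxon[i]
    expect_gt(sf$freq[i, t], 0)
    expect_equal(unname(sf$freq[i, setdiff(colnames(sf$freq), t)]),
                 rep(0, 3))
  }
  cfg0 <- scenarioConfig(fixedDiffFraction = 0, seed = 2)
  expect_equal(sum(sampleTaxonFrequencies(cfg0)$truth$true_class == "fixed"),
               0)
  expect_error(scenarioConfig(fixedDiffFraction = 0.3), "sum to")
})

test_that("reference sampling follows Hardy-Weinberg and missingness", {
  cfg <- scenarioConfig(accessionsPerTaxon = 50, fragmentsPerChromosome = 2,
                        markersPerFragment = 10, seed = 9,
                        missingRate = 0.05)
  sf <- sampleTaxonFrequencies(cfg)
  sf$freq[1, ] <- 1   # force a fixed marker
  sf$freq[2, ] <- 0.5 # and an intermediate one
  refs <- sampleReferenceAccessions(sf$freq, cfg)
  g <- refs$geno
  expect_equal(unname(g[1, !is.na(g[1, ])]),
               rep(2L, sum(!is.na(g[1, ]))))
  ho <- mean(g[2, ] == 1, na.rm = TRUE)
  expect_lt(abs(ho - 0.5), 0.1)  # 200 diploids
  miss <- mean(is.na(g))
  expect_lt(abs(miss - 0.05), 0.01)
})

test_that("crosses transmit whole fragments; selfing a homozygote is a
           no-op; BC1 dosage follows Mendelian expectation", {
  frag_index <- rep(c("f1", "f2"), each = 5)
  homA <- list(hap1 = rep(0L, 10), hap2 = rep(0L, 10))
  homB <- list(hap1 = rep(1L, 10), hap2 = rep(1L, 10))
  set.seed(1)
  f1 <- makeCross(homA, homB, frag_index)
  expect_equal(f1$dosage, rep(1L, 10))  # fixed difference -> always het
  selfed <- makeCross(homA, homA, frag_index)
  expect_equal(selfed$dosage, homA$hap1 + homA$hap2)
  # BC1 = F1 x A: per fragment the F1 gamete carries the B haplotype with
  # probability 1/2, so the A-homozygous fraction averages 0.5
  set.seed(2)
  homs <- replicate(200, {
    bc1 <- makeCross(f1, homA, frag_index)
    mean(bc1$dosage == 0)
  })
  expect_lt(abs(mean(homs) - 0.5), 0.05)
  # and within a fragment transmission is all-or-nothing
  set.seed(3)
  for (i in 1:20) {
    bc1 <- makeCross(f1, homA, frag_index)
    perfrag <- tapply(bc1$dosage, frag_index, function(v)
      length(unique(v)))
    expect_true(all(perfrag == 1))
  }
})

test_that("scenarios are deterministic and internally consistent", {
  cfg <- recoveryConfig(seed = 12)
  a <- buildScenario(cfg)
  b <- buildScenario(cfg)
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(a$truth, b$truth)
  expect_no_error(validObject(a$genotypes))
  # truth introgression table matches the injected pairs exactly
  cfg2 <- maskingConfig(seed = 12)
  scen <- buildScenario(cfg2)
  truth <- scen$truth$introgression
  expect_equal(nrow(truth),
               4 * round(0.2 * nrow(fragmentInfo(scen$genotypes))))
  # injected fragments are heterozygous at focal/donor fixed differences
  mk <- markerInfo(scen$genotypes)
  planted <- scen$truth$markers
  man_fixed <- planted$marker_id[planted$true_class == "fixed" &
                                   planted$true_taxon == "mandarin"]
  one <- truth[1, ]
  rows <- mk$marker_id[!is.na(mk$fragment_id) &
                         mk$fragment_id == one$fragment_id]
  hit <- intersect(rows, man_fixed)
  if (length(hit))
    expect_true(all(dosage(scen$genotypes)[hit, one$accession_id] == 1L))
  # written files load back through the standard reader
  tmp <- withr::local_tempdir()
  files <- writeGenotypes(a$genotypes, file.path(tmp, "scen"))
  y <- readGenotypes(files[["genotypes"]], "tsv",
                     markersPath = files[["markers"]],
                     fragmentsPath = files[["fragments"]])
  expect_identical(dosage(y), dosage(a$genotypes))
  expect_equal(fragmentInfo(y)$fragment_id,
               fragmentInfo(a$genotypes)$fragment_id)
})

test_that("pedigree referencing an unknown accession is a config error", {
  cfg <- scenarioConfig(hybrids = list(
    list(id = "bad", type = "CROSS", parentA = "nope_01",
         parentB = "mandarin_01")), seed = 1)
  expect_error(buildScenario(cfg), "unknown accession")
})
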