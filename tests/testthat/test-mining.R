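test_that("focal-vs-rest G_ST reproduces the analytic anchors", {
  # fixed difference: focal at 1, the three others at 0
  expect_equal(gstFocalRest(1, matrix(c(0, 0, 0), 1))$gst, 1)
  # heterozygous single-accession taxon: p = 0.5 vs fixed rest -> 1/3
  r <- gstFocalRest(0.5, matrix(c(0, 0, 0), 1))
  expect_equal(r$gst, 1 / 3)
  expect_gte(r$gst, 0.3)
  expect_lte(r$gst, 0.4)
  # identical frequencies everywhere: no differentiation
  expect_equal(gstFocalRest(0.3, matrix(c(0.3, 0.3, 0.3), 1))$gst, 0)
  # monomorphic marker: defined as 0 and flagged
  m <- gstFocalRest(0, matrix(c(0, 0, 0), 1))
  expect_equal(m$gst, 0)
  expect_true(m$monomorphic)
  # the diagnostic allele is the one enriched in the focal taxon
  expect_equal(gstFocalRest(1, matrix(c(0, 0, 0), 1))$diagnostic_allele,
               "alt")
  expect_equal(gstFocalRest(0, matrix(c(1, 1, 1), 1))$diagnostic_allele,
               "ref")
})

test_that("G_ST stays in [0,1] over random draws and matches the literal
           formula on an exhaustive grid", {
  set.seed(99)
  n <- 1e5
  pf <- runif(n)
  po <- matrix(runif(3 * n), n, 3)
  g <- gstFocalRest(pf, po)$gst
  expect_true(all(g >= -1e-12 & g <= 1 + 1e-12))

  grid <- seq(0, 1, by = 0.1)
  combos <- expand.grid(p1 = grid, p2 = grid, p3 = grid, p4 = grid)
  got <- gstFocalRest(combos$p1,
                      as.matrix(combos[, c("p2", "p3", "p4")]))$gst
  want <- mapply(oracleGst, combos$p1,
                 asplit(as.matrix(combos[, c("p2", "p3", "p4")]), 1))
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("classification is exhaustive, exclusive, and threshold-faithful", {
  freqs <- list(
    mandarin = data.frame(marker_id = c("d1", "s1", "n1", "p1", "mono"),
                          p = c(1, 0.2, 0.3, 0.9, 0), n_genes = 20L),
    pummelo = data.frame(marker_id = c("d1", "s1", "n1", "p1", "mono"),
                         p = c(0, 0, 0.3, 0, 0), n_genes = 20L),
    citron = data.frame(marker_id = c("d1", "s1", "n1", "p1", "mono"),
                        p = c(0, 0, 0, 0, 0), n_genes = 20L),
    micrantha = data.frame(marker_id = c("d1", "s1", "n1", "p1", "mono"),
                           p = c(0, 0, 0, 0, 0), n_genes = 20L))
  g <- gstScan(freqs)
  cls <- classifyMarkers(g, freqs)
  got <- setNames(cls$class, cls$marker_id)
  expect_equal(got[["d1"]], "DIAGNOSTIC")
  # private variant at p = 0.2, other three fixed for the shared allele
  expect_equal(got[["s1"]], "TAXON_SPECIFIC_POLYMORPHISM")
  expect_equal(cls$taxon[cls$marker_id == "s1"], "mandarin")
  # same minor allele segregating in two taxa
  expect_equal(got[["n1"]], "ND")
  expect_equal(got[["mono"]], "ND")
  # 0.5 < max gst <= 0.9 is partial differentiation
  expect_equal(got[["p1"]], "PARTIAL")
  expect_gt(cls$max_gst[cls$marker_id == "p1"], 0.5)
  expect_lte(cls$max_gst[cls$marker_id == "p1"], 0.9)
  # exactly one class per marker, always
  expect_true(all(table(cls$marker_id) == 1))
  expect_false(anyNA(cls$class))
})

test_that("proximity filter rejects flanked candidates symmetrically", {
  mk <- data.frame(marker_id = c("a", "b", "c"), chrom = "chr1",
                   pos = c(100L, 140L, 1000L), ref = "A", alt = "G",
                   stringsAsFactors = FALSE)
  res <- proximityFilter(mk, window = 50)
  expect_setequal(res$rejected$marker_id, c("a", "b"))  # 40 bp apart
  expect_true("c" %in% res$retained)
  # an indel in the flank also rejects
  res2 <- proximityFilter(mk, candidates = "c", window = 50,
                          indels = data.frame(chrom = "chr1", pos = 1030L))
  expect_equal(res2$rejected$marker_id, "c")
  expect_equal(res2$rejected$distance, 30L)
  res3 <- proximityFilter(mk, candidates = "c", window = 25,
                          indels = data.frame(chrom = "chr2", pos = 1030L))
  expect_equal(res3$retained, "c")  # other chromosome never offends
})

test_that("panel QC discards markers whose allele recurs in a second taxon", {
  ids <- c("good", "sharedpoly")
  freqs <- lapply(c(mandarin = 1, pummelo = 2, citron = 3, micrantha = 4),
                  function(i) data.frame(marker_id = ids, p = 0,
                                         n_genes = 20L))
  freqs$mandarin$p <- c(1, 0.4)
  freqs$pummelo$p <- c(0, 0.4)  # diagnostic allele shared with pummelo
  g <- gstScan(freqs)
  cls <- classifyMarkers(g, freqs)
  cls$class[cls$marker_id == "sharedpoly"] <- "TAXON_SPECIFIC_POLYMORPHISM"
  cls$taxon[cls$marker_id == "sharedpoly"] <- "mandarin"
  cls$diagnostic_allele[cls$marker_id == "sharedpoly"] <- "alt"
  panel <- suppressWarnings(buildPanel(cls, freqs, qcThreshold = 0.1))
  expect_equal(panel$marker_id, "good")
  removed <- attr(panel, "removed")
  expect_equal(removed$marker_id, "sharedpoly")
  expect_match(removed$reason, "pummelo")
  # panel invariants: one taxon per marker, focal frequency strictly higher
  expect_true(all(table(panel$marker_id) == 1))
  expect_true(all(panel$p_focal > panel$max_other_p))
})

test_that("planted fixed differences are recovered exactly from clean data", {
  cfg <- scenarioConfig(accessionsPerTaxon = 10, fragmentsPerChromosome = 2,
                        markersPerFragment = 10, fixedDiffFraction = 0.1,
                        privateFraction = 0, divergentFraction = 0,
                        sharedFraction = 0, seed = 31)
  scen <- buildScenario(cfg)
  freqs <- taxonFreqs(scen$genotypes)
  cls <- classifyMarkers(gstScan(freqs), freqs)
  panel <- suppressWarnings(buildPanel(cls, freqs))
  truth <- scen$truth$markers
  for (t in cfg$taxa) {
    planted <- truth$marker_id[truth$true_class == "fixed" &
                                 truth$true_taxon == t]
    got <- panel$marker_id[panel$taxon == t]
    expect_setequal(got, planted)
  }
})
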