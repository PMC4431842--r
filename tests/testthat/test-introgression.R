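test_that("fragment heterozygosity is Ho over the fragment's markers", {
  dos <- matrix(c(1L, 0L, 1L, 0L,   # acc1: het at 2 of 4 in fragA
                  0L, 0L, 0L, 0L,   # acc2: fully homozygous
                  NA, NA, NA, NA),  # acc3: nothing called
                4, 3)
  x <- toyGenotypes(dos, fragments = list(fragA = 1:4))
  fh <- fragmentHet(x)
  expect_equal(unname(fh$ho[, "fragA"]), c(0.5, 0, NA))
  expect_equal(unname(fh$n_markers[, "fragA"]), c(4L, 4L, 0L))
})

test_that("classical PCoA embeds collinear points and reproduces input
           distances", {
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, 3,
              dimnames = list(paste0("a", 1:3), paste0("a", 1:3)))
  res <- pcoa(d, nAxes = 2)
  # one positive eigenvalue; collinear coordinates (-1, 0, 1) up to sign
  expect_equal(sum(res$eig > 1e-9), 1)
  expect_equal(sort(unname(res$coords[, 1])), c(-1, 0, 1),
               tolerance = 1e-9)
  # sign convention: first nonzero loading positive
  expect_gt(res$coords[1, 1], 0)
  # identical points collapse to zero
  z <- matrix(0, 3, 3)
  expect_true(all(abs(pcoa(z, 2)$coords) < 1e-12))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  # full-rank embedding reproduces Euclidean-embeddable dissimilarities
  set.seed(21)
  pts <- matrix(rnorm(20), 5, 4)
  dd <- as.matrix(dist(pts))
  emb <- pcoa(dd, nAxes = 4)$coords
  expect_equal(as.matrix(dist(emb)), dd, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("flagging needs both high fragment Ho and differential hets", {
  # 6 markers in one fragment; mandarin/pummelo fixed differences at 1-4
  freqs <- list(
    mandarin = data.frame(marker_id = sprintf("m%02d", 1:6),
                          p = c(1, 1, 1, 1, 0, 0), n_genes = 8L),
    pummelo = data.frame(marker_id = sprintf("m%02d", 1:6),
                         p = c(0, 0, 0, 0, 0, 0), n_genes = 8L))
  taxa <- data.frame(accession_id = c("acc01", "acc02", "acc03"),
                     taxon = c("mandarin", "mandarin", "mandarin"),
                     role = "REFERENCE", stringsAsFactors = FALSE)
  # acc01 introgressed (het at the differential markers), acc02 pure,
  # acc03 heterozygous only at non-differential markers (private variance)
  dos <- cbind(acc01 = c(1L, 1L, 1L, 1L, 0L, 0L),
               acc02 = c(2L, 2L, 2L, 2L, 0L, 0L),
               acc03 = c(2L, 2L, 2L, 2L, 1L, 1L))
  x <- toyGenotypes(dos, fragments = list(fragA = 1:6), taxa = taxa)
  flags <- flagIntrogressed(x, freqs = freqs, hetThreshold = 0.3,
                            minDifferentialHets = 2,
                            differentialDelta = 0.8)
  expect_equal(flags$accession_id, "acc01")
  expect_equal(flags$donor_taxon, "pummelo")
  expect_equal(flags$fragment_ho, 4 / 6)
  expect_equal(flags$n_differential_hets, 4L)
})

test_that("masking removes data only and re-mining recovers diagnostics", {
  cfg <- maskingConfig(seed = 7)
  scen <- buildScenario(cfg)
  x <- scen$genotypes
  res <- remineWithMask(x)
  pre <- dosage(x); post <- dosage(res$masked)
  # every call used post-mask was present pre-mask
  expect_true(all(is.na(post) | post == pre))
  expect_gt(sum(is.na(post)), sum(is.na(pre)))
  # flags against truth
  truth <- scen$truth$introgression
  tp <- sum(flagKey(res$flags) %in% flagKey(truth))
  expect_gte(tp / nrow(res$flags), 0.95)
  expect_gte(tp / nrow(truth), 0.95)
  # planted focal-taxon fixed differences never lose G_ST when the flagged
  # fragments are the injected ones
  planted <- scen$truth$markers
  fixed_ids <- planted$marker_id[planted$true_class == "fixed"]
  for (t in unique(planted$true_taxon[planted$true_class == "fixed"])) {
    ids <- planted$marker_id[planted$true_class == "fixed" &
                               planted$true_taxon == t]
    pre_g <- res$gst_pre[res$gst_pre$taxon == t &
                           res$gst_pre$marker_id %in% ids, ]
    post_g <- res$gst_post[res$gst_post$taxon == t &
                             res$gst_post$marker_id %in% ids, ]
    m <- match(pre_g$marker_id, post_g$marker_id)
    keep <- !is.na(m)
    expect_true(all(post_g$gst[m[keep]] >= pre_g$gst[keep] - 1e-12))
  }
  # mandarin diagnostic count strictly increases after masking
  d <- res$delta_report
  expect_gt(d$diagnostic_post[d$taxon == "mandarin"],
            d$diagnostic_pre[d$taxon == "mandarin"])
})

test_that("masking is a no-op without introgression and drops fully-masked
           markers with a reason", {
  cfg <- scenarioConfig(accessionsPerTaxon = 10, fragmentsPerChromosome = 6,
                        markersPerFragment = 19, fixedDiffFraction = 0.1,
                        privateFraction = 0.12, divergentFraction = 0,
                        sharedFraction = 0.1, seed = 17)
  scen <- buildScenario(cfg)
  res <- remineWithMask(scen$genotypes)
  expect_equal(nrow(res$flags), 0)
  expect_identical(res$pre_panel, res$post_panel)
  expect_identical(dosage(res$masked), dosage(scen$genotypes))
})
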