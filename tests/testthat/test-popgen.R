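test_that("allele frequencies count gene copies and flag all-missing", {
  # {AA, AB} with alt allele -> p = 0.25; {NA, BB} -> p = 1 on 2 copies
  dos <- matrix(c(0L, 1L,
                  NA, 2L,
                  NA, NA), 3, 2, byrow = TRUE)
  x <- toyGenotypes(dos)
  f <- alleleFreqs(x, accessionIds(x))
  expect_equal(f$p, c(0.25, 1, NA))
  expect_equal(f$n_genes, c(4L, 2L, 0L))
  expect_true(all(f$n_genes %% 2 == 0))
  expect_error(alleleFreqs(x, character(0)), "empty group")
})

test_that("Ho, unbiased He and Fw follow their definitions", {
  # {AA, AB, AB, BB}: Ho = 0.5, p = 0.5
  x <- toyGenotypes(matrix(c(0L, 1L, 1L, 2L), 1, 4))
  ds <- diversityStats(x, accessionIds(x))
  expect_equal(ds$per_marker$Ho, 0.5)
  # two diploids at p = 0.5: unbiased correction 2n/(2n-1) = 4/3
  y <- toyGenotypes(matrix(c(0L, 2L), 1, 2))
  dy <- diversityStats(y, accessionIds(y))
  expect_equal(dy$per_marker$He, (4 / 3) * 0.5)
  # Ho equal to He gives Fw = 0
  expect_equal(dy$per_marker$Fw, 1 - 0 / dy$per_marker$He)
  z <- toyGenotypes(matrix(c(1L, 1L, 1L, 1L), 1, 4))  # all het, p = 0.5
  dz <- diversityStats(z, accessionIds(z))
  he <- (8 / 7) * 0.5
  expect_equal(dz$per_marker$Fw, 1 - 1 / he)
})

test_that("He_nei peaks at p = 0.5 and decreases with |p - 0.5|", {
  p <- seq(0, 1, by = 0.01)
  he <- heBiallelic(p)
  expect_equal(max(he), 0.5)
  expect_equal(p[which.max(he)], 0.5)
  ord <- order(abs(p - 0.5))
  expect_true(all(diff(he[ord]) <= 1e-12))
})

test_that("Weir-Cockerham theta hits analytic anchors", {
  # two groups fixed for alternative alleles: theta = 1
  x <- toyGenotypes(matrix(c(0L, 0L, 2L, 2L), 1, 4))
  g <- list(A = c("acc01", "acc02"), B = c("acc03", "acc04"))
  expect_equal(wcFst(x, g)$theta, 1)
  # identical composition in both groups: no between-group variance
  y <- toyGenotypes(matrix(c(0L, 2L, 0L, 2L), 1, 4))
  expect_lte(wcFst(y, g)$theta, 0)
  expect_error(wcFst(x, g[1]), "two groups")
})

test_that("theta matches the scalar-loop oracle on exhaustive small cases", {
  # all 2-group assignments of dosages over <= 4 diploids per group
  set.seed(11)
  for (rep in 1:200) {
    nA <- sample(2:4, 1); nB <- sample(2:4, 1)
    dA <- sample(0:2, nA, replace = TRUE)
    dB <- sample(0:2, nB, replace = TRUE)
    x <- toyGenotypes(matrix(as.integer(c(dA, dB)), 1))
    g <- list(A = accessionIds(x)[seq_len(nA)],
              B = accessionIds(x)[nA + seq_len(nB)])
    got <- wcFst(x, g)$theta
    want <- oracleTheta(list(dA, dB))
    expect_equal(got, want, tolerance = 1e-12)
  }
  # a fixed 3-group toy table of 6 diploids
  d <- list(c(0L, 1L), c(2L, 2L), c(1L, 0L))
  x <- toyGenotypes(matrix(unlist(d), 1))
  g <- list(A = accessionIds(x)[1:2], B = accessionIds(x)[3:4],
            C = accessionIds(x)[5:6])
  expect_equal(wcFst(x, g)$theta, oracleTheta(d), tolerance = 1e-12)
})

test_that("SNP density divides per fragment and pools per chromosome", {
  mk <- data.frame(marker_id = sprintf("m%d", 1:10), chrom = "chr1",
                   pos = 1:10, ref = "A", alt = "G", fragment_id = "f1")
  fr <- data.frame(fragment_id = c("f1", "f2"), chrom = "chr1",
                   start = c(1L, 1000L), end = c(500L, 1499L),
                   length_bp = c(500L, 500L))
  d <- snpDensity(mk, fr)
  expect_equal(d$per_fragment$snp_per_kb, c(20, 0))
  # pooled before division: (10 + 0) SNPs over 1000 bp
  expect_equal(d$per_chromosome$snp_per_kb, 10)
  mk$fragment_id[1] <- "nope"
  expect_error(snpDensity(mk, fr), "unknown fragment")
})

test_that("simple-matching dissimilarity counts shared allele copies", {
  # identical genotypes -> 0; AA vs BB -> 1
  x <- toyGenotypes(matrix(c(0L, 0L, 2L), 1, 3))
  d <- smDissimilarity(x)$d
  expect_equal(d[1, 2], 0)
  expect_equal(d[1, 3], 1)
  # loci {(AA vs AB), (BB vs BB)} -> 1 - (0.5 + 1)/2 = 0.25
  y <- toyGenotypes(matrix(c(0L, 1L,
                             2L, 2L), 2, 2, byrow = TRUE))
  expect_equal(smDissimilarity(y)$d[1, 2], 0.25)
  # loci with a missing call are excluded pair-wise
  z <- toyGenotypes(matrix(c(0L, NA,
                             2L, 2L), 2, 2, byrow = TRUE))
  expect_equal(smDissimilarity(z)$d[1, 2], 0)
  expect_equal(smDissimilarity(z)$n_loci[1, 2], 1L)
})

test_that("dissimilarity is symmetric with zero diagonal on random data", {
  set.seed(5)
  for (rep in 1:10) {
    dos <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6)
    x <- toyGenotypes(dos)
    d <- smDissimilarity(x)$d
    expect_equal(d, t(d))
    expect_equal(unname(diag(d)), rep(0, 6))
    expect_true(all(d[!is.na(d)] >= 0 & d[!is.na(d)] <= 1))
  }
})

test_that("group report: MD, PL, NSG semantics", {
  dos <- matrix(c(0L, 0L, 0L,
                  1L, 1L, NA,
                  2L, 2L, 2L), 3, 3, byrow = TRUE)
  x <- toyGenotypes(dos)
  rep1 <- groupReport(x, list(all = accessionIds(x)))
  expect_equal(rep1$MD, 100 * 1 / 9)
  expect_equal(rep1$MD + 100 * sum(!is.na(dos)) / 9, 100)
  expect_equal(rep1$PL, 1L)  # only the het row segregates
  # missing treated as wildcard: acc3 compatible with acc1/acc2
  expect_equal(rep1$NSG, 1L)
  expect_equal(groupReport(x, list(all = accessionIds(x)),
                           strictNSG = TRUE)$NSG, 2L)
  mono <- toyGenotypes(matrix(c(0L, 2L, 0L, 2L), 2, 2))
  expect_equal(groupReport(mono, list(g = accessionIds(mono)))$PL, 0L)
  expect_equal(groupReport(mono, list(g = accessionIds(mono)))$MD, 0)
})

test_that("concordance compares only doubly-called genotype pairs", {
  x <- toyGenotypes(matrix(rep(0L, 10), 5, 2))
  expect_equal(callConcordance(x, x)$overall, 0)
  dos2 <- dosage(x); dos2[1, 1] <- 1L
  y <- toyGenotypes(dos2)
  expect_equal(callConcordance(x, y)$overall, 0.1)
  dos3 <- dosage(x); dos3[] <- NA_integer_
  z <- toyGenotypes(dos3)
  expect_true(is.na(callConcordance(x, z)$overall))
})
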