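test_that("high-coverage selection keeps exactly the loci covered everywhere", {
  truth <- twoStrainTruth(4)
  pile <- simulatePooledReads(truth,
    design = poolDesign(pools = list(p = c("s1", "s2")),
                        depthPerStrain = 200), seed = 1)
  ct <- pileupData(pile)
  # depress one substrain at locus 2 to depth 99 (boundary) and locus 3 to 100
  i2 <- which(ct$pos == 200 & ct$substrain == "s1")
  ct[i2, c("A", "C", "G", "T")] <- c(99, 0, 0, 0)
  i3 <- which(ct$pos == 300 & ct$substrain == "s2")
  ct[i3, c("A", "C", "G", "T")] <- c(0, 100, 0, 0)
  pile2 <- new("PileupCounts", counts = ct, pools = poolAssignments(pile))
  kept <- selectHighCoverage(pile2, 100)
  expect_setequal(kept$pos, c(100, 300, 400))
  # brute-force filter agrees
  brute <- Filter(function(p) {
    sub <- ct[ct$pos == p, ]
    all(rowSums(sub[, c("A", "C", "G", "T")]) >= 100)
  }, unique(ct$pos))
  expect_setequal(kept$pos, brute)
  expect_error(selectHighCoverage(pile2, 0), class = "parameterError")
})

test_that("noiseless pools produce zero artifact rates", {
  truth <- twoStrainTruth(5)
  pile <- simulatePooledReads(truth,
    design = poolDesign(pools = list(p = c("s1", "s2")),
                        depthPerStrain = 300, errorRate = 0, jumpRate = 0),
    seed = 2)
  ar <- estimateArtifactRates(pile, selectHighCoverage(pile), truth)
  expect_true(all(ar$cells$jumpFreq == 0))
  expect_true(all(ar$cells$errorFreq == 0))
  expect_true(all(ar$cells$focalFreq == 1))
})

test_that("rates are recovered from the generative model in a 2-strain pool", {
  # jump bucket mass j + e/3 (the in-pool allele also absorbs 1 of 3
  # miscall targets); error bucket mass 2e/3
  j <- 0.016; e <- 5e-4; depth <- 5000; nLoci <- 22
  truth <- twoStrainTruth(nLoci)
  pile <- simulatePooledReads(truth,
    design = poolDesign(pools = list(p = c("s1", "s2")),
                        depthPerStrain = depth, errorRate = e, jumpRate = j),
    seed = 3)
  ar <- estimateArtifactRates(pile, selectHighCoverage(pile), truth)
  nCells <- nrow(ar$cells)
  expect_equal(nCells, nLoci * 2)
  pJump <- j + e / 3
  seJump <- sqrt(pJump * (1 - pJump) / (depth * nCells))
  expect_lt(abs(ar$summary$jump$mean - pJump), 3 * seJump)
  pErr <- 2 * e / 3
  seErr <- sqrt(pErr * (1 - pErr) / (depth * nCells))
  expect_lt(abs(ar$summary$error$mean - pErr), 3 * seErr)
  # the per-base rescaling recovers e itself
  seE <- 3 / 2 * seErr
  expect_lt(abs(ar$summary$errorRateMean - e), 3 * seE)
})

test_that("cells without an informative pool mate leave the jump summaries", {
  truth <- twoStrainTruth(3)
  calls <- callsMatrix(truth)
  calls[2, "s2"] <- 0L                     # locus 2: both strains share ref
  truth2 <- new("GenotypeTable", variants = variantInfo(truth), calls = calls)
  pile <- simulatePooledReads(truth2,
    design = poolDesign(pools = list(p = c("s1", "s2")),
                        depthPerStrain = 500, errorRate = 0.01,
                        jumpRate = 0.02), seed = 4)
  ar <- estimateArtifactRates(pile, selectHighCoverage(pile), truth2)
  cells <- ar$cells
  shared <- cells[cells$pos == 200, ]
  expect_true(all(!shared$jumpDefined))
  expect_true(all(shared$errorFreq > 0))
  expect_equal(ar$summary$jump$nCells, 4L)
  expect_equal(ar$summary$error$nCells, 6L)
})

test_that("bucket counts conserve reads exactly", {
  sim <- simulateDrift(nodSchedule(), seed = 6)
  pile <- simulatePooledReads(sim$table, design = poolDesign(), seed = 7)
  ar <- estimateArtifactRates(pile, selectHighCoverage(pile), sim$table)
  with(ar$cells, {
    expect_identical(focalCount + jumpCount + errorCount, depth)
    expect_equal(focalFreq + jumpFreq + errorFreq, rep(1, nrow(ar$cells)),
                 tolerance = 1e-15)
  })
})

test_that("estimated jump frequency increases monotonically with the true rate", {
  truth <- twoStrainTruth(10)
  grid <- c(0.005, 0.01, 0.02, 0.04)
  means <- vapply(seq_along(grid), function(g) {
    est <- vapply(1:25, function(s) {
      pile <- simulatePooledReads(truth,
        design = poolDesign(pools = list(p = c("s1", "s2")),
                            depthPerStrain = 1000, errorRate = 5e-4,
                            jumpRate = grid[g]), seed = s * 10 + g)
      estimateArtifactRates(pile, selectHighCoverage(pile),
                            truth)$summary$jump$mean
    }, 0)
    mean(est)
  }, 0)
  expect_true(all(diff(means) > 0))
})

test_that("jumping responds only to same-pool allele differences", {
  # two pools; the focal strain's own pool is monomorphic, the other pool
  # carries a different allele: jump signal must stay at the error floor
  variants <- data.frame(chrom = "chr1", pos = c(100, 200) * 1.0,
                         ref = c("A", "C"), alt = c("G", "T"),
                         class = "SNP", consequence = NA_character_,
                         coding = FALSE)
  calls <- matrix(c(0L, 0L, 1L, 1L,
                    0L, 0L, 1L, 1L), 2, 4, byrow = TRUE,
                  dimnames = list(NULL, c("s1", "s2", "s3", "s4")))
  truth <- new("GenotypeTable", variants = variants, calls = calls)
  e <- 0.003
  pile <- simulatePooledReads(truth,
    design = poolDesign(pools = list(pA = c("s1", "s2"), pB = c("s3", "s4")),
                        depthPerStrain = 5000, errorRate = e,
                        jumpRate = 0.05), seed = 9)
  ar <- estimateArtifactRates(pile, selectHighCoverage(pile), truth)
  cells <- ar$cells
  expect_true(all(!cells$jumpDefined))
  # every non-focal base frequency is at the error floor e, despite the
  # large configured jump rate
  pErr <- e                                 # all 3 alternatives in bucket
  seErr <- sqrt(pErr * (1 - pErr) / (5000 * nrow(cells)))
  expect_lt(abs(mean(cells$errorFreq) - pErr), 3 * seErr)
  expect_error(
    estimateArtifactRates(pile, data.frame(chrom = "chr1", pos = 999), truth),
    class = "inputError")
})
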