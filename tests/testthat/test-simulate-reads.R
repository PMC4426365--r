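test_that("noiseless pooled reads carry only the focal allele", {
  truth <- twoStrainTruth(5)
  des <- poolDesign(pools = list(p = c("s1", "s2")), depthPerStrain = 200,
                    errorRate = 0, jumpRate = 0)
  pile <- simulatePooledReads(truth, design = des, seed = 1)
  ct <- pileupData(pile)
  v <- variantInfo(truth)
  for (i in seq_len(nrow(ct))) {
    vi <- which(v$pos == ct$pos[i])
    own <- if (ct$substrain[i] == "s2") v$alt[vi] else v$ref[vi]
    expect_equal(as.numeric(ct[i, own]), 200)
    expect_equal(sum(ct[i, c("A", "C", "G", "T")]), 200)
  }
})

test_that("jump-rate recovery matches the binomial oracle in a 2-strain pool", {
  truth <- twoStrainTruth(8)
  des <- poolDesign(pools = list(p = c("s1", "s2")), depthPerStrain = 10000,
                    errorRate = 0, jumpRate = 0.02)
  pile <- simulatePooledReads(truth, design = des, seed = 5)
  ct <- pileupData(pile)
  v <- variantInfo(truth)
  minor <- vapply(seq_len(nrow(ct)), function(i) {
    vi <- which(v$pos == ct$pos[i])
    other <- if (ct$substrain[i] == "s2") v$ref[vi] else v$alt[vi]
    as.numeric(ct[i, other]) / 10000
  }, 0)
  se <- sqrt(0.02 * 0.98 / (10000 * length(minor)))
  expect_lt(abs(mean(minor) - 0.02), 3 * se)
})

test_that("sequencing errors are uniform over the three alternative bases", {
  truth <- twoStrainTruth(6)
  # same allele in both strains so no jump is visible
  calls <- callsMatrix(truth); calls[, "s2"] <- 0L
  truth2 <- new("GenotypeTable", variants = variantInfo(truth), calls = calls)
  des <- poolDesign(pools = list(p = c("s1", "s2")), depthPerStrain = 10000,
                    errorRate = 0.003, jumpRate = 0)
  pile <- simulatePooledReads(truth2, design = des, seed = 9)
  ct <- pileupData(pile)
  v <- variantInfo(truth2)
  perBase <- unlist(lapply(seq_len(nrow(ct)), function(i) {
    vi <- which(v$pos == ct$pos[i])
    others <- setdiff(c("A", "C", "G", "T"), v$ref[vi])
    as.numeric(ct[i, others]) / 10000
  }))
  se <- sqrt(0.001 * 0.999 / (10000 * length(perBase)))
  expect_lt(abs(mean(perBase) - 0.001), 3 * se)
})

test_that("per-cell counts always sum to the configured depth", {
  sim <- simulateDrift(nodSchedule(), seed = 2)
  pile <- simulatePooledReads(sim$table, design = poolDesign(), seed = 3)
  ct <- pileupData(pile)
  expect_true(all(rowSums(ct[, c("A", "C", "G", "T")]) == 500))
})

test_that("pool designs are validated", {
  expect_error(poolDesign(errorRate = 0.6, jumpRate = 0.5),
               class = "parameterError")
  expect_error(poolDesign(pools = list(a = "s1", b = "s1")),
               class = "parameterError")
  truth <- twoStrainTruth(3)
  v <- variantInfo(truth)
  v$class[2] <- "indel"; v$alt[2] <- "AT"
  indelTruth <- new("GenotypeTable", variants = v,
                    calls = callsMatrix(truth))
  expect_error(
    simulatePooledReads(indelTruth, loci = 2,
                        design = poolDesign(pools = list(p = c("s1", "s2")))),
    class = "inputError")
})

test_that("pileups round-trip through TSV with pool membership", {
  truth <- twoStrainTruth(4)
  pile <- simulatePooledReads(truth,
                              design = poolDesign(pools = list(p = c("s1", "s2")),
                                                  depthPerStrain = 50),
                              seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePileupTsv(pile, path)
  pile2 <- readPileupTsv(path)
  expect_equal(pileupData(pile2), pileupData(pile))
  expect_equal(poolAssignments(pile2), poolAssignments(pile))
})
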