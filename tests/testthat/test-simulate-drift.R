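twoTipSchedule <- function() {
  # 25 years per lineage at 4 generations/year = 100 generations per branch
  scheduleFromNewick("(A:25,B:25);", rootYear = 0)
}

test_that("a zero fixation rate yields an empty table and zero distances", {
  sim <- simulateDrift(nodSchedule(), lambdaFix = 0, seed = 1)
  expect_equal(nVariants(sim$table), 0L)
  expect_true(all(sim$branchCounts == 0L))
  d <- pairwiseDistance(sim$table, "all")
  expect_true(all(distanceValues(d) == 0L))
  expect_equal(dim(distanceValues(d)), c(5L, 5L))
})

test_that("pairwise distance matches Poisson expectation on a two-tip genealogy", {
  # E[distance] = lambda * path generations = 0.25 * 200 = 50
  sch <- twoTipSchedule()
  lam <- 0.25
  nRep <- 300
  dists <- vapply(seq_len(nRep), function(i) {
    sim <- simulateDrift(sch, lambdaFix = lam, seed = i)
    as.numeric(distanceValues(pairwiseDistance(sim$table, "all"))["A", "B"])
  }, 0)
  expected <- 2 * 100 * lam
  se <- sqrt(expected / nRep)          # variance of a Poisson total
  expect_lt(abs(mean(dists) - expected), 3 * se)
})

test_that("every variant is carried by exactly the tips below its branch", {
  sch <- nodSchedule()
  sim <- simulateDrift(sch, seed = 42)
  tr <- scheduleTree(sch)
  nTip <- length(tr$tip.label)
  cm <- callsMatrix(sim$table)
  for (i in seq_len(nVariants(sim$table))) {
    child <- tr$edge[sim$variantEdge[i], 2L]
    tips <- if (child <= nTip) tr$tip.label[child]
            else ape::extract.clade(tr, child)$tip.label
    expect_setequal(colnames(cm)[cm[i, ] == 1L], tips)
  }
  # per-branch counts are consistent with the emitted variants
  expect_equal(as.integer(base::table(factor(sim$variantEdge,
                                             levels = seq_len(nrow(tr$edge))))),
               as.integer(sim$branchCounts))
})

test_that("the cherry pair is the closest pair on average", {
  sch <- nodSchedule()
  tot <- matrix(0, 5, 5)
  for (s in 1:40) {
    sim <- simulateDrift(sch, seed = s)
    tot <- tot + distanceValues(pairwiseDistance(sim$table, "all"))
  }
  labs <- substrainNames(sch)
  dimnames(tot) <- list(labs, labs)
  offdiag <- tot[upper.tri(tot)]
  expect_equal(min(offdiag), tot["ShiLt", "ShiLtDvs"])
})

test_that("simulation is bit-reproducible and seeds are explicit", {
  a <- simulateDrift(nodSchedule(), seed = 7)
  b <- simulateDrift(nodSchedule(), seed = 7)
  c <- simulateDrift(nodSchedule(), seed = 8)
  expect_identical(variantInfo(a$table), variantInfo(b$table))
  expect_identical(callsMatrix(a$table), callsMatrix(b$table))
  expect_false(identical(variantInfo(a$table), variantInfo(c$table)))
  # seed 0 is valid
  expect_s4_class(simulateDrift(nodSchedule(), seed = 0)$table, "GenotypeTable")
})

test_that("invalid drift parameters are refused", {
  expect_error(simulateDrift(nodSchedule(), lambdaFix = -1),
               class = "parameterError")
  expect_error(simulateDrift(nodSchedule(), codingFraction = 1.5),
               class = "parameterError")
})

test_that("no heterozygous calls are ever emitted and positions are unique", {
  sim <- simulateDrift(nodSchedule(), lambdaFix = 2, seed = 3)
  cm <- callsMatrix(sim$table)
  expect_true(all(cm %in% c(0L, 1L)))
  v <- variantInfo(sim$table)
  expect_false(anyDuplicated(paste(v$chrom, v$pos)) > 0)
  # class consistent with allele lengths
  snp <- v$class == "SNP"
  expect_true(all(nchar(v$ref[snp]) == 1 & nchar(v$alt[snp]) == 1))
  expect_true(all(nchar(v$ref[!snp]) != nchar(v$alt[!snp])))
})
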