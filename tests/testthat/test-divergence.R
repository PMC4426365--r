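toyTable <- function() {
  # three substrains, four variants; v3 is carried by everyone
  variants <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40) * 1.0,
                         ref = c("A", "C", "T", "A"),
                         alt = c("T", "G", "A", "C"),
                         class = c("SNP", "SNP", "SNP", "SNP"),
                         consequence = c("missense_variant", NA, NA,
                                         "synonymous_variant"),
                         coding = c(TRUE, FALSE, FALSE, TRUE))
  calls <- matrix(c(0L, 0L, 1L,
                    0L, 1L, 1L,
                    1L, 1L, 1L,
                    0L, 1L, 0L), 4, 3, byrow = TRUE,
                  dimnames = list(NULL, c("s1", "s2", "s3")))
  new("GenotypeTable", variants = variants, calls = calls)
}

test_that("pairwise distances match a hand count on a toy table", {
  d <- distanceValues(pairwiseDistance(toyTable(), "all"))
  expect_equal(d["s1", "s2"], 2L)
  expect_equal(d["s1", "s3"], 2L)
  expect_equal(d["s2", "s3"], 2L)
  expect_equal(diag(d), setNames(rep(0L, 3), c("s1", "s2", "s3")))
})

test_that("identical substrains are at distance zero", {
  tbl <- toyTable()
  cm <- callsMatrix(tbl); cm[, "s2"] <- cm[, "s1"]
  tbl2 <- new("GenotypeTable", variants = variantInfo(tbl), calls = cm)
  expect_equal(distanceValues(pairwiseDistance(tbl2, "all"))["s1", "s2"], 0L)
})

test_that("distances split additively by variant class", {
  sim <- simulateDrift(nodSchedule(), seed = 21)
  dAll <- distanceValues(pairwiseDistance(sim$table, "all"))
  dSnp <- distanceValues(pairwiseDistance(sim$table, "SNP"))
  dInd <- distanceValues(pairwiseDistance(sim$table, "indel"))
  expect_equal(dAll, dSnp + dInd)
  expect_true(all(dAll == t(dAll)))
  # triangle inequality, guaranteed for Hamming counts
  n <- nrow(dAll)
  for (k in seq_len(n))
    expect_true(all(dAll <= outer(dAll[, k], dAll[k, ], `+`)))
})

test_that("distance equals the count of variants whose branch separates a pair", {
  sch <- nodSchedule()
  sim <- simulateDrift(sch, seed = 22)
  tr <- scheduleTree(sch)
  nTip <- length(tr$tip.label)
  d <- distanceValues(pairwiseDistance(sim$table, "all"))
  tipsBelow <- lapply(seq_len(nrow(tr$edge)), function(e) {
    ch <- tr$edge[e, 2L]
    if (ch <= nTip) tr$tip.label[ch]
    else ape::extract.clade(tr, ch)$tip.label
  })
  for (a in tr$tip.label) for (b in tr$tip.label) {
    if (a == b) next
    sep <- vapply(tipsBelow, function(tp) xor(a %in% tp, b %in% tp), TRUE)
    expect_equal(d[a, b], sum(sim$branchCounts[sep]))
  }
})

test_that("distance summaries report extremes with lexicographic tie-breaking", {
  m <- matrix(5L, 3, 3, dimnames = list(c("b", "a", "c"), c("b", "a", "c")))
  diag(m) <- 0L
  dm <- new("DistanceMatrix", values = m, variantClass = "all")
  s <- distanceSummary(dm)
  expect_equal(s$min, 5); expect_equal(s$max, 5)
  expect_equal(s$minPair, c("a", "b"))
  expect_equal(s$maxPair, c("a", "b"))
  one <- new("DistanceMatrix",
             values = matrix(0L, 1, 1, dimnames = list("x", "x")),
             variantClass = "all")
  expect_error(distanceSummary(one), class = "inputError")
})

test_that("SDPs identify unique and non-informative variants", {
  tbl <- toyTable()
  sdp <- sdpTable(tbl)
  expect_equal(sdp$patterns$pattern[1], "s3")
  expect_false(sdp$patterns$informative[3])      # carried by everyone
  expect_equal(sdp$uniqueCounts[["s3"]], 1L)
  expect_equal(sdp$uniqueCounts[["s2"]], 1L)
  # complement-unique: variant 2 is carried by all but s1
  expect_equal(sdp$complementUniqueCounts[["s1"]], 1L)
  # simulator truth: SDP equals the tip set below the variant's branch
  sch <- nodSchedule()
  sim <- simulateDrift(sch, seed = 23)
  tr <- scheduleTree(sch)
  nTip <- length(tr$tip.label)
  pats <- sdpTable(sim$table)$patterns$pattern
  for (i in seq_len(nVariants(sim$table))) {
    ch <- tr$edge[sim$variantEdge[i], 2L]
    tips <- if (ch <= nTip) tr$tip.label[ch]
            else ape::extract.clade(tr, ch)$tip.label
    expect_setequal(strsplit(pats[i], ",")[[1]], tips)
  }
})

test_that("consequence tallies conserve counts and percentages", {
  tbl <- toyTable()
  ct <- consequenceTally(tbl)
  expect_equal(sum(ct$tally$count), nVariants(tbl))
  expect_equal(sum(ct$tally$percent), 100)
  expect_true("unannotated" %in% ct$tally$consequence)
  empty <- simulateDrift(nodSchedule(), lambdaFix = 0, seed = 1)$table
  expect_equal(consequenceTally(empty)$total, 0L)
})

test_that("fixation rates follow the documented divisor conventions", {
  # one pair, 10 coding differences, separated 10 years, 4 generations/year
  sch <- scheduleFromNewick("(A:10,B:10);", rootYear = 0)
  m <- matrix(c(0L, 10L, 10L, 0L), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  dm <- new("DistanceMatrix", values = m, variantClass = "coding")
  r <- fixationRate(dm, sch)
  expect_equal(r$perYearMin, 0.5)                 # 10 / (2 x 10)
  expect_equal(r$perGenerationMin, 0.125)
  r1 <- fixationRate(dm, sch, singleLineage = TRUE)
  expect_equal(r1$perYearMax, 1.0)
  zero <- new("DistanceMatrix", values = m * 0L, variantClass = "coding")
  expect_equal(fixationRate(zero, sch)$perYearMax, 0)
})

test_that("per-generation endpoints reproduce half-up 2-decimal reporting", {
  r <- rateRange(0.74, 1.22, generationsPerYear = 4)
  expect_equal(roundHalfUp(r$perGenerationMin, 2), 0.19)
  expect_equal(roundHalfUp(r$perGenerationMax, 2), 0.31)
  expect_equal(roundHalfUp(0.305, 2), 0.31)       # half rounds away from zero
  expect_error(rateRange(2, 1), class = "parameterError")
})

test_that("distance matrices round-trip through labeled TSV", {
  sim <- simulateDrift(nodSchedule(), seed = 24)
  d <- pairwiseDistance(sim$table, "SNP")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDistanceTsv(d, path)
  d2 <- readDistanceTsv(path, "SNP")
  expect_equal(distanceValues(d2), distanceValues(d))
})
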