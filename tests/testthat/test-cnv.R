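strains5 <- c("BomTac", "MrkTac", "ShiJcl", "ShiLtDvs", "ShiLt")

test_that("median centering removes shared structure and flags majority shifts", {
  m <- matrix(rep(1:20, 5), 20, 5, dimnames = list(NULL, strains5)) * 0.1
  raw <- new("IntensityTrack",
             probes = data.frame(chrom = "chr1", pos = 1:20 * 100.0),
             intensities = m)
  sc <- scaleIntensities(raw)
  expect_true(all(intensityValues(sc) == 0))
  # single-substrain shift survives centering
  m2 <- m; m2[10:15, "ShiLt"] <- m2[10:15, "ShiLt"] - 2
  raw2 <- new("IntensityTrack", probes = probeInfo(raw), intensities = m2)
  sc2 <- scaleIntensities(raw2)
  expect_equal(unname(intensityValues(sc2)[10:15, "ShiLt"]), rep(-2, 6),
               tolerance = 1e-12)
  expect_true(all(abs(intensityValues(sc2)[, "BomTac"]) < 1e-12))
  # majority shift is absorbed and triggers the masking warning
  m3 <- m; m3[5:12, c("BomTac", "MrkTac", "ShiJcl")] <-
    m3[5:12, c("BomTac", "MrkTac", "ShiJcl")] - 2
  raw3 <- new("IntensityTrack", probes = probeInfo(raw), intensities = m3)
  expect_warning(scaleIntensities(raw3), "masked")
  expect_error(scaleIntensities(
    new("IntensityTrack", probes = probeInfo(raw),
        intensities = m[, 1:2, drop = FALSE])), class = "inputError")
})

test_that("a planted 13-probe deletion is called with its exact span", {
  hits <- 0L
  nSeed <- 40
  for (s in seq_len(nSeed)) {
    tr <- simulateIntensities(seq(24272052, by = 9254, length.out = 40),
      strains5,
      deletions = list(list(substrains = "ShiLtDvs", from = 14, to = 26,
                            shift = -2)),
      noiseSd = 0.1, seed = s)
    calls <- callDeletions(tr)
    ok <- nrow(calls) == 1 && calls$startIndex == 14 && calls$endIndex == 26 &&
      calls$substrains == "ShiLtDvs" && calls$nProbes == 13
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits / nSeed, 0.95)
})

test_that("reported span positions are the first and last probe positions", {
  pos <- seq(24272052, by = 9254, length.out = 40)
  tr <- simulateIntensities(pos, strains5,
    deletions = list(list(substrains = "ShiLtDvs", from = 14, to = 26,
                          shift = -2)),
    noiseSd = 0.05, seed = 1)
  calls <- callDeletions(tr)
  expect_equal(calls$startPos, pos[14])
  expect_equal(calls$endPos, pos[26])
})

test_that("a deletion shared by two substrains merges into one call", {
  tr <- simulateIntensities(1:40 * 1000, strains5,
    deletions = list(list(substrains = c("ShiLt", "ShiLtDvs"), from = 10,
                          to = 22, shift = -2)),
    noiseSd = 0.1, seed = 2)
  calls <- callDeletions(tr)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$substrains, "ShiLt,ShiLtDvs")
})

test_that("pure noise produces no calls and runs never overlap", {
  falsePos <- 0L
  for (s in 1:50) {
    tr <- simulateIntensities(1:50 * 1000, strains5, noiseSd = 0.1, seed = s)
    if (nrow(callDeletions(tr)) > 0) falsePos <- falsePos + 1L
  }
  expect_lte(falsePos / 50, 0.01 + 1e-9)
  # maximal-run construction: per substrain, calls never overlap
  tr <- simulateIntensities(1:80 * 1000, strains5,
    deletions = list(list(substrains = "ShiLt", from = 5, to = 12, shift = -2),
                     list(substrains = "ShiLt", from = 30, to = 40,
                          shift = -2.5)),
    noiseSd = 0.1, seed = 3)
  calls <- callDeletions(tr)
  own <- calls[grepl("ShiLt(,|$)", calls$substrains), ]
  own <- own[order(own$startIndex), ]
  if (nrow(own) > 1)
    expect_true(all(own$startIndex[-1] > own$endIndex[-nrow(own)]))
  expect_equal(nrow(calls), 2L)
})

test_that("gains are only reported when requested", {
  tr <- simulateIntensities(1:30 * 1000, strains5,
    noiseSd = 0.1, seed = 4)
  m <- intensityValues(tr)
  m[8:14, "BomTac"] <- m[8:14, "BomTac"] + 2
  up <- new("IntensityTrack", probes = probeInfo(tr), intensities = m)
  expect_equal(nrow(callDeletions(up)), 0L)
  g <- callDeletions(up, gains = TRUE)
  expect_equal(nrow(g), 1L)
  expect_equal(g$type, "gain")
  expect_error(callDeletions(tr, threshold = 0.5), class = "parameterError")
  expect_error(callDeletions(tr, minRun = 1), class = "parameterError")
})

test_that("calls export to BED with half-open coordinates", {
  tr <- simulateIntensities(1:40 * 1000, strains5,
    deletions = list(list(substrains = "ShiLtDvs", from = 14, to = 26,
                          shift = -2)),
    noiseSd = 0.05, seed = 5)
  calls <- callDeletions(tr)
  path <- withr::local_tempfile(fileext = ".bed")
  writeCnvBed(calls, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(bed$V2, calls$startPos - 1)
  expect_equal(bed$V3, calls$endPos)
  expect_true(file.exists(paste0(path, ".json")))
})
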