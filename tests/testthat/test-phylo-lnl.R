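test_that("two-taxon single-site likelihood matches the JC closed form", {
  tr <- ape::read.tree(text = "(a:0.05,b:0.05);")
  aln <- matrix(c("A", "C"), 2, 1, dimnames = list(c("a", "b"), NULL))
  ll <- gtrLoglik(aln, tr, gtrParams())       # equal-rate GTR = JC69
  t <- 0.1
  pChange <- 3 / 4 - 3 / 4 * exp(-4 * t / 3)
  expect_equal(ll, log(0.25 * pChange / 3), tolerance = 1e-12)
  same <- matrix(c("G", "G"), 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(gtrLoglik(same, tr, gtrParams()),
               log(0.25 * (1 - pChange)), tolerance = 1e-12)
})

test_that("pruning equals brute-force state enumeration on small trees", {
  cases <- list(
    list(nTip = 4, seed = 1, freqs = c(0.25, 0.25, 0.25, 0.25),
         rates = rep(1, 6)),
    list(nTip = 4, seed = 2, freqs = c(0.1, 0.2, 0.3, 0.4),
         rates = c(1, 4, 0.5, 2, 6, 1)),
    list(nTip = 5, seed = 3, freqs = c(0.35, 0.15, 0.2, 0.3),
         rates = c(0.7, 3, 1.2, 0.9, 4.5, 1)))
  for (cs in cases) {
    tr <- withSeed(cs$seed, ape::rtree(cs$nTip))
    p <- gtrParams(cs$freqs, cs$rates)
    aln <- simulateAlignment(tr, p, 5, seed = cs$seed + 100)
    expect_lt(abs(gtrLoglik(aln, tr, p) -
                  bruteForceLnl(aln, tr, cs$freqs, cs$rates)), 1e-10)
  }
})

test_that("likelihood is invariant under re-rooting (reversibility)", {
  p <- gtrParams(c(0.3, 0.2, 0.3, 0.2), c(1, 4, 1, 1, 4, 1))
  tr <- withSeed(7, ape::rtree(6))
  aln <- simulateAlignment(tr, p, 300, seed = 11)
  base <- gtrLoglik(aln, tr, p)
  un <- ape::unroot(tr)
  expect_lt(abs(gtrLoglik(aln, un, p) - base), 1e-9)
  for (tip in tr$tip.label[1:3]) {
    re <- ape::root(un, outgroup = tip, resolve.root = TRUE)
    expect_lt(abs(gtrLoglik(aln, re, p) - base), 1e-9)
  }
})

test_that("pruning agrees with an independent phylogenetics library", {
  p <- gtrParams(c(0.28, 0.22, 0.26, 0.24), c(0.8, 3.2, 1.1, 0.9, 3.9, 1))
  tr <- withSeed(13, ape::rtree(5))
  aln <- simulateAlignment(tr, p, 400, seed = 17)
  ours <- gtrLoglik(aln, tr, p)
  dat <- phangorn::phyDat(aln)
  # phangorn's GTR: rates relative to the last exchangeability, same scaling
  fitp <- phangorn::pml(tr, dat, bf = p$freqs, Q = p$rates)
  expect_equal(ours, fitp$logLik, tolerance = 1e-6)
})

test_that("SNP alignments mirror the genotype table", {
  sim <- simulateDrift(nodSchedule(), seed = 31)
  aln <- genotypeToAlignment(sim$table)
  v <- variantInfo(sim$table)
  expect_equal(ncol(aln), sum(v$class == "SNP"))
  expect_equal(nrow(aln), 5L)
  # Hamming distances of the alignment equal the SNP distance matrix
  dSnp <- distanceValues(pairwiseDistance(sim$table, "SNP"))
  for (a in rownames(aln)) for (b in rownames(aln))
    expect_equal(sum(aln[a, ] != aln[b, ]), dSnp[a, b])
  # no monomorphic column can arise from tabulated variants
  expect_true(all(apply(aln, 2, function(col) length(unique(col)) > 1)))
  empty <- simulateDrift(nodSchedule(), lambdaFix = 0, seed = 1)$table
  expect_error(genotypeToAlignment(empty), class = "inputError")
})

test_that("invalid model parameters and label mismatches are refused", {
  expect_error(gtrParams(c(0.5, 0.5, 0, 0)), class = "parameterError")
  expect_error(gtrParams(rates = rep(-1, 6)), class = "parameterError")
  tr <- ape::read.tree(text = "(a:1,b:1,c:1);")
  aln <- matrix("A", 3, 2, dimnames = list(c("a", "b", "x"), NULL))
  expect_error(gtrLoglik(aln, tr, gtrParams()), class = "inputError")
})
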