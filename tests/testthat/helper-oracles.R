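# independent oracles used across tests

# GTR rate matrix built from scratch (no package internals) and
# exponentiated by scaling-and-squaring via eigen of the plain matrix
oracleQ <- function(freqs, rates) {
  S <- matrix(0, 4, 4)
  S[1, 2] <- S[2, 1] <- rates[1]; S[1, 3] <- S[3, 1] <- rates[2]
  S[1, 4] <- S[4, 1] <- rates[3]; S[2, 3] <- S[3, 2] <- rates[4]
  S[2, 4] <- S[4, 2] <- rates[5]; S[3, 4] <- S[4, 3] <- rates[6]
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  Q / -sum(freqs * diag(Q))
}

oracleP <- function(Q, t) Matrix::as.matrix(Matrix::expm(Q * t))

# full-likelihood by explicit summation over all internal-state
# assignments; independent of the pruning implementation
bruteForceLnl <- function(aln, tree, freqs, rates) {
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  nNode <- max(tr$edge)
  internals <- (nTip + 1L):nNode
  Q <- oracleQ(freqs, rates)
  P <- lapply(tr$edge.length, function(t) oracleP(Q, t))
  states <- match(aln[tr$tip.label, , drop = FALSE], c("A", "C", "G", "T"))
  dim(states) <- dim(aln)
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  lnl <- 0
  for (s in seq_len(ncol(aln))) {
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      assign <- integer(nNode)
      assign[seq_len(nTip)] <- states[, s]
      assign[internals] <- grid[g, ]
      term <- freqs[assign[nTip + 1L]]
      for (e in seq_len(nrow(tr$edge)))
        term <- term * P[[e]][assign[tr$edge[e, 1L]], assign[tr$edge[e, 2L]]]
      lik <- lik + term
    }
    lnl <- lnl + log(lik)
  }
  lnl
}

# random dated ultrametric tree for clock-true simulations
randomClockTree <- function(nTip, seed) {
  withSeed(seed, {
    tr <- ape::rcoal(nTip, tip.label = paste0("t", seq_len(nTip)))
    tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 0.08
    tr
  })
}

# two-substrain genotype table differing at every locus (one pool)
twoStrainTruth <- function(nLoci) {
  variants <- data.frame(chrom = "chr1", pos = seq_len(nLoci) * 100,
                         ref = rep(c("A", "C", "G", "T"), length.out = nLoci),
                         alt = rep(c("G", "T", "A", "C"), length.out = nLoci),
                         class = "SNP", consequence = NA_character_,
                         coding = FALSE)
  calls <- cbind(s1 = rep(0L, nLoci), s2 = rep(1L, nLoci))
  new("GenotypeTable", variants = variants, calls = calls)
}
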