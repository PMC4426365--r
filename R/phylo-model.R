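# GTR substitution model: rate matrix, pruning likelihood, simulation

#' General time-reversible model parameters
#'
#' Base order is A, C, G, T; exchangeabilities are in the order AC, AG,
#' AT, CG, CT, GT with the last (GT) conventionally fixed at 1 for
#' identifiability. The rate matrix is scaled so branch lengths are in
#' expected substitutions per site.
#'
#' @param freqs base frequencies, length 4, positive, summing to 1.
#' @param rates exchangeabilities, length 6, positive.
#' @return A validated list of class `gtrParams`.
#' @export
gtrParams <- function(freqs = rep(0.25, 4), rates = rep(1, 6)) {
  if (length(freqs) != 4L || any(freqs <= 0) || abs(sum(freqs) - 1) > 1e-8)
    sdStop("freqs must be 4 positive numbers summing to 1", "parameterError")
  if (length(rates) != 6L || any(rates <= 0))
    sdStop("rates must be 6 positive numbers", "parameterError")
  structure(list(freqs = as.numeric(freqs), rates = as.numeric(rates)),
            class = "gtrParams")
}

# scaled GTR rate matrix and its symmetric eigendecomposition;
# P(t) = A exp(Lambda t) Ainv
gtrEigen <- function(params) {
  pi <- params$freqs; r <- params$rates
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S[1, 2] <- S[2, 1] <- r[1]; S[1, 3] <- S[3, 1] <- r[2]
  S[1, 4] <- S[4, 1] <- r[3]; S[2, 3] <- S[3, 2] <- r[4]
  S[2, 4] <- S[4, 2] <- r[5]; S[3, 4] <- S[4, 3] <- r[6]
  Q <- S * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  sq <- sqrt(pi)
  B <- Q * outer(sq, 1 / sq)          # diag(sq) Q diag(1/sq), symmetric
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(Q = Q, A = eig$vectors / sq, Ainv = t(eig$vectors) * rep(sq, each = 4),
       lam = eig$values, pi = pi)
}

# collapse an alignment (taxa x sites character matrix) to site patterns
alignmentPatterns <- function(aln) {
  states <- matrix(match(toupper(aln), BASES) - 1L, nrow(aln), ncol(aln))
  states[is.na(states)] <- -1L
  key <- apply(states, 2L, paste, collapse = ",")
  u <- !duplicated(key)
  w <- as.numeric(base::table(factor(key, levels = key[u])))
  list(states = states[, u, drop = FALSE], weights = w)
}

# tree in the node-numbering layout the C++ pruner expects
preparedTree <- function(tree, labels) {
  if (!setequal(tree$tip.label, labels))
    sdStop("tree tips and alignment labels differ", "inputError")
  tr <- ape::reorder.phylo(tree, "postorder")
  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  if (!root %in% tr$edge[, 1L] || root %in% tr$edge[, 2L])
    sdStop("tree root must be node ntip+1 (standard ape numbering)",
           "inputError")
  tr
}

#' GTR log-likelihood of an alignment on a tree
#'
#' Computes the pruning (Felsenstein) log-likelihood of aligned sites on
#' a tree with branch lengths in expected substitutions/site, under a
#' general time-reversible model. Works for rooted and unrooted trees;
#' reversibility makes the result independent of root placement.
#'
#' @param aln character matrix, taxa x sites, entries A/C/G/T, rownames
#'   are taxon labels.
#' @param tree an [ape::phylo] whose tip labels equal the alignment
#'   labels; branch lengths >= 0.
#' @param params a [gtrParams()] object.
#' @return The log-likelihood (numeric scalar).
#' @export
gtrLoglik <- function(aln, tree, params) {
  stopifnot(inherits(params, "gtrParams"))
  if (is.null(rownames(aln))) sdStop("alignment needs rownames", "inputError")
  if (any(tree$edge.length < 0))
    sdStop("branch lengths must be >= 0", "inputError")
  tr <- preparedTree(tree, rownames(aln))
  pat <- alignmentPatterns(aln[tr$tip.label, , drop = FALSE])
  eig <- gtrEigen(params)
  cppGtrLnl(tr$edge, length(tr$tip.label), tr$edge.length, pat$states,
            pat$weights, eig$A, eig$Ainv, eig$lam, eig$pi)
}

#' Concatenate SNP calls into a site alignment
#'
#' One alignment column per SNP; each substrain contributes its
#' homozygous allele (ref or alt base). Indels are excluded. Columns are
#' polymorphic by construction since every tabulated variant
#' distinguishes at least one substrain.
#'
#' @param table a [GenotypeTable-class] with at least one SNP.
#' @return Character matrix, substrains x SNP sites.
#' @export
genotypeToAlignment <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  v <- variantInfo(table)
  snp <- which(v$class == "SNP")
  if (length(snp) == 0L) sdStop("no SNPs in the genotype table", "inputError")
  cm <- callsMatrix(table)[snp, , drop = FALSE]
  ref <- v$ref[snp]; alt <- v$alt[snp]
  aln <- vapply(seq_len(ncol(cm)),
                function(j) ifelse(cm[, j] == 1L, alt, ref),
                character(length(snp)))
  aln <- t(aln)
  rownames(aln) <- colnames(cm)
  aln
}

#' Simulate an alignment under GTR on a tree
#'
#' Draws the root state from the stationary frequencies and evolves it
#' down the tree with transition probabilities from the scaled GTR rate
#' matrix. Used for molecular-clock calibration and power studies.
#'
#' @param tree an [ape::phylo] with branch lengths in substitutions/site.
#' @param params a [gtrParams()] object.
#' @param nSites number of independent sites.
#' @param seed integer RNG seed.
#' @return Character matrix, tips x sites.
#' @export
simulateAlignment <- function(tree, params, nSites, seed = 0) {
  stopifnot(inherits(params, "gtrParams"))
  tr <- ape::reorder.phylo(tree, "cladewise")
  nTip <- length(tr$tip.label)
  root <- nTip + 1L
  eig <- gtrEigen(params)
  nNode <- max(tr$edge)
  withSeed(seed, {
    states <- matrix(NA_integer_, nNode, nSites)
    states[root, ] <- sample.int(4L, nSites, replace = TRUE, prob = eig$pi)
    for (e in seq_len(nrow(tr$edge))) {
      P <- eig$A %*% (exp(eig$lam * tr$edge.length[e]) * eig$Ainv)
      P[P < 0] <- 0
      pa <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
      for (x in 1:4) {
        idx <- which(states[pa, ] == x)
        if (length(idx))
          states[ch, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                        prob = P[x, ])
      }
    }
    aln <- matrix(BASES[states[seq_len(nTip), , drop = FALSE]], nTip, nSites)
    rownames(aln) <- tr$tip.label
    aln
  })
}

#' Empirical base frequencies of an alignment
#'
#' A half-count per base is added so that a base absent from the sampled
#' sites still gets positive stationary frequency.
#'
#' @param aln character matrix of bases.
#' @return Numeric vector of 4 frequencies (A, C, G, T) summing to 1.
#' @export
baseFrequencies <- function(aln) {
  ct <- base::table(factor(toupper(aln), levels = BASES))
  f <- (as.numeric(ct) + 0.5) / (sum(ct) + 2)
  setNames(f / sum(f), BASES)
}

#' Read or write an alignment as FASTA
#'
#' @param aln character matrix, taxa x sites.
#' @param path file path.
#' @return `readFasta` returns a character matrix; `writeFasta` returns
#'   `path` invisibly.
#' @export
writeFasta <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", rownames(aln)[i]), con)
    writeLines(paste(aln[i, ], collapse = ""), con)
  }
  invisible(path)
}

#' @rdname writeFasta
#' @export
readFasta <- function(path) {
  x <- ape::read.FASTA(path)
  m <- as.character(as.matrix(x))
  m[] <- toupper(m)
  rownames(m) <- names(x)
  m
}
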