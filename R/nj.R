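# neighbor joining on a fixed-difference distance matrix

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken
#' by lexicographic pair order (clusters ordered by their smallest tip
#' label), so the result is deterministic. A negative branch length at a
#' join is clamped to zero and the deficit moved to the sister edge,
#' preserving the pair's summed length. On an additive matrix the true
#' tree and its branch lengths are recovered exactly.
#'
#' @param m a [DistanceMatrix-class] or a plain symmetric numeric matrix
#'   with labels, at least 3 taxa.
#' @return An unrooted [ape::phylo] tree; edge lengths are in the units
#'   of the input distances.
#' @export
#' @examples
#' njTree(table1Matrices()$SNP)
njTree <- function(m) {
  d <- if (is(m, "DistanceMatrix")) distanceValues(m) else as.matrix(m)
  labs <- rownames(d)
  if (is.null(labs)) sdStop("distance matrix must be labeled", "inputError")
  n <- nrow(d)
  if (n < 3L) sdStop("neighbor joining needs at least 3 taxa", "inputError")
  if (any(d != t(d)) || any(d < 0))
    sdStop("distance matrix must be symmetric and nonnegative", "inputError")
  d <- d + 0.0
  sub <- labs          # newick fragment per active cluster
  key <- labs          # lexicographic sort key (smallest tip label)

  while (length(key) > 3L) {
    r <- length(key)
    R <- rowSums(d)
    Qm <- (r - 2) * d - outer(R, R, `+`)
    diag(Qm) <- Inf
    best <- NULL; bestQ <- Inf
    ord <- order(key)
    for (ii in seq_len(r - 1L)) for (jj in (ii + 1L):r) {
      i <- ord[ii]; j <- ord[jj]     # pairs visited in lexicographic order
      if (Qm[i, j] < bestQ - 1e-12) { bestQ <- Qm[i, j]; best <- c(i, j) }
    }
    i <- best[1L]; j <- best[2L]
    bi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    newSub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], bi, sub[j], bj)
    newKey <- min(key[i], key[j])
    dNew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dNew[keep]),
                c(dNew[keep], 0))
    sub <- c(sub[keep], newSub)
    key <- c(key[keep], newKey)
    d <- d2
  }
  # final three-way join around the central node
  ordIdx <- order(key)
  a <- ordIdx[1L]; b <- ordIdx[2L]; c3 <- ordIdx[3L]
  ba <- max((d[a, b] + d[a, c3] - d[b, c3]) / 2, 0)
  bb <- max((d[a, b] + d[b, c3] - d[a, c3]) / 2, 0)
  bc <- max((d[a, c3] + d[b, c3] - d[a, b]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 sub[a], ba, sub[b], bb, sub[c3], bc)
  ape::read.tree(text = nwk)
}
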