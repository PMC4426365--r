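# pooled indexed libraries: per-base sequencing error and inter-library
# template switching ("jumping PCR")

#' Capture-pool design for pooled exome libraries
#'
#' @param pools named list of character vectors partitioning the
#'   substrains into capture pools. The default mirrors the two NOD exome
#'   capture pools: {ShiLt, ShiLtDvs, MrkTac} and {BomTac, ShiJcl}.
#' @param depthPerStrain sequencing reads per substrain per locus.
#' @param errorRate per-read probability of a miscall, uniform over the
#'   three alternative bases.
#' @param jumpRate per-read probability that the template switches to a
#'   uniformly chosen other library in the same capture pool during
#'   post-capture PCR, so the read reports that library's allele.
#' @return A validated list of class `poolDesign`.
#' @export
poolDesign <- function(pools = list(poolA = c("ShiLt", "ShiLtDvs", "MrkTac"),
                                    poolB = c("BomTac", "ShiJcl")),
                       depthPerStrain = 500, errorRate = 0.0005,
                       jumpRate = 0.016) {
  if (errorRate < 0 || jumpRate < 0)
    sdStop("error and jump rates must be >= 0", "parameterError")
  if (errorRate + jumpRate > 1)
    sdStop("errorRate + jumpRate must not exceed 1", "parameterError")
  if (depthPerStrain < 1) sdStop("depthPerStrain must be >= 1", "parameterError")
  members <- unlist(pools, use.names = FALSE)
  if (anyDuplicated(members)) sdStop("pools must be disjoint", "parameterError")
  structure(list(pools = pools, depthPerStrain = as.integer(depthPerStrain),
                 errorRate = errorRate, jumpRate = jumpRate),
            class = "poolDesign")
}

#' Simulate read-level base counts for pooled capture libraries
#'
#' For each read drawn from substrain s at locus l: with probability
#' `jumpRate` the emitted base is the true allele of a uniformly chosen
#' other substrain in s's capture pool (template switching); otherwise
#' with probability `errorRate` it is a uniformly chosen base other than
#' s's true allele; otherwise it is s's true allele. Loci must be SNPs.
#'
#' @param truth a [GenotypeTable-class] giving each substrain's homozygous
#'   allele per locus.
#' @param loci integer indices of variants in `truth` to sequence
#'   (default: all SNP rows).
#' @param design a [poolDesign()] covering all substrains of `truth`.
#' @param seed integer RNG seed.
#' @return A [PileupCounts-class] whose per-(locus, substrain) counts sum
#'   to `depthPerStrain`.
#' @export
simulatePooledReads <- function(truth, loci = NULL, design = poolDesign(),
                                seed = 0) {
  stopifnot(is(truth, "GenotypeTable"), inherits(design, "poolDesign"))
  v <- variantInfo(truth)
  if (is.null(loci)) loci <- which(v$class == "SNP")
  if (length(loci) == 0) sdStop("no loci to sequence", "inputError")
  if (any(loci < 1 | loci > nrow(v)))
    sdStop("loci must index rows of the genotype table", "inputError")
  if (any(v$class[loci] != "SNP"))
    sdStop("pileup simulation requires SNP loci", "inputError")
  strains <- substrainNames(truth)
  members <- unlist(design$pools, use.names = FALSE)
  if (!all(strains %in% members))
    sdStop("every substrain must belong to a capture pool", "inputError")
  poolOf <- setNames(rep(names(design$pools),
                         lengths(design$pools)), members)
  calls <- callsMatrix(truth)
  e <- design$errorRate; j <- design$jumpRate
  depth <- design$depthPerStrain

  withSeed(seed, {
    rows <- vector("list", length(loci) * length(strains))
    k <- 0L
    for (li in loci) {
      alleles <- ifelse(calls[li, strains] == 1L, v$alt[li], v$ref[li])
      names(alleles) <- strains
      for (s in strains) {
        own <- alleles[[s]]
        mates <- setdiff(members[poolOf[members] == poolOf[[s]]], s)
        mates <- intersect(mates, strains)
        p <- setNames(numeric(4), BASES)
        p[own] <- 1 - e - j
        p[setdiff(BASES, own)] <- p[setdiff(BASES, own)] + e / 3
        if (length(mates) > 0)
          for (m in mates) p[alleles[[m]]] <- p[alleles[[m]]] + j / length(mates)
        else p[own] <- p[own] + j  # no pool mate: template switching is a no-op
        cnt <- as.integer(rmultinom(1L, depth, p))
        k <- k + 1L
        rows[[k]] <- data.frame(chrom = v$chrom[li], pos = v$pos[li],
                                substrain = s, A = cnt[1L], C = cnt[2L],
                                G = cnt[3L], T = cnt[4L])
      }
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- NULL
    new("PileupCounts", counts = counts, pools = design$pools)
  })
}
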