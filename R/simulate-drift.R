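# Poisson accumulation of fixed homozygous mutations along a genealogy

#' Mouse-like genome model for simulated variant positions
#'
#' Approximate mm10 chromosome lengths (19 autosomes plus X), used to draw
#' variant positions uniformly across the genome. Any named vector of
#' chromosome lengths can be substituted.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
mouseGenome <- function() {
  c(chr1 = 195e6, chr2 = 182e6, chr3 = 160e6, chr4 = 157e6, chr5 = 152e6,
    chr6 = 150e6, chr7 = 145e6, chr8 = 129e6, chr9 = 125e6, chr10 = 131e6,
    chr11 = 122e6, chr12 = 120e6, chr13 = 121e6, chr14 = 125e6,
    chr15 = 104e6, chr16 = 98e6, chr17 = 95e6, chr18 = 91e6, chr19 = 61e6,
    chrX = 171e6)
}

# n distinct (chrom, pos) pairs drawn uniformly over the genome;
# collisions (recurrent mutation) are redrawn
samplePositions <- function(n, genome) {
  chrom <- character(0); pos <- numeric(0)
  while (length(chrom) < n) {
    k <- n - length(chrom)
    ch <- sample(names(genome), k, replace = TRUE,
                 prob = genome / sum(genome))
    ps <- floor(runif(k, 1, genome[ch] + 1))
    chrom <- c(chrom, ch); pos <- c(pos, ps)
    keep <- !duplicated(paste(chrom, pos))
    chrom <- chrom[keep]; pos <- pos[keep]
  }
  data.frame(chrom = chrom, pos = as.numeric(pos))
}

# VEP-style consequence labels used by the simulator
CODING_CONSEQUENCES <- c("missense_variant", "synonymous_variant",
                         "stop_gained", "stop_lost")
CODING_INDEL_CONSEQUENCES <- c("frameshift_variant", "inframe_deletion",
                               "inframe_insertion")
NONCODING_CONSEQUENCES <- c("intron_variant", "intergenic_variant",
                            "3_prime_UTR_variant", "5_prime_UTR_variant",
                            "upstream_gene_variant", "downstream_gene_variant")

#' Simulate fixed-mutation accumulation along a substrain genealogy
#'
#' New mutations are fixed to homozygosity by continued inbreeding; the
#' process is modeled as instantaneous fixation, with the number of
#' mutations fixed on each branch Poisson-distributed with mean
#' `lambdaFix` times the branch length in generations. A mutation arising
#' on a branch is carried, homozygous, by exactly the substrains
#' descending from that branch; no heterozygous call is ever emitted.
#'
#' Defaults for `lambdaFix`, `codingFraction` and `indelFraction` are
#' calibrated so the five-substrain NOD genealogy yields on the order of
#' the observed exome totals (about 227 variants, roughly a quarter of
#' them indels and 29\% coding).
#'
#' @param schedule a [SeparationSchedule-class] with at least 2 tips.
#' @param lambdaFix expected fixed mutations per lineage per generation
#'   (>= 0) visible to the assay.
#' @param codingFraction fraction of mutations labeled with a coding
#'   consequence.
#' @param indelFraction fraction of mutations that are short indels.
#' @param genome named chromosome-length vector, see [mouseGenome()].
#' @param seed integer RNG seed (0 is valid).
#' @return List with elements \describe{
#'   \item{table}{a [GenotypeTable-class] of the simulated variants,
#'     sorted by chromosome and position;}
#'   \item{branchCounts}{integer vector of true mutation counts per edge
#'     of `scheduleTree(schedule)` (edge order of the phylo object);}
#'   \item{variantEdge}{integer vector giving, for each variant row of
#'     `table`, the edge on which it arose.}}
#' @export
#' @examples
#' sim <- simulateDrift(nodSchedule(), seed = 1)
#' sim$table
simulateDrift <- function(schedule, lambdaFix = 0.4, codingFraction = 0.29,
                          indelFraction = 0.24, genome = mouseGenome(),
                          seed = 0) {
  stopifnot(is(schedule, "SeparationSchedule"))
  if (lambdaFix < 0) sdStop("lambdaFix must be >= 0", "parameterError")
  if (codingFraction < 0 || codingFraction > 1 ||
      indelFraction < 0 || indelFraction > 1)
    sdStop("fractions must lie in [0, 1]", "parameterError")
  tr <- schedule@tree
  nTip <- length(tr$tip.label)
  if (nTip < 2L) sdStop("schedule must have at least 2 substrains", "inputError")

  gens <- branchGenerations(schedule)
  nEdge <- nrow(tr$edge)
  # tips descending from the child node of each edge
  tipsBelow <- lapply(seq_len(nEdge), function(e) {
    child <- tr$edge[e, 2L]
    if (child <= nTip) child
    else which(tr$tip.label %in% ape::extract.clade(tr, child)$tip.label)
  })

  withSeed(seed, {
    branchCounts <- rpois(nEdge, lambdaFix * gens)
    nVar <- sum(branchCounts)
    if (nVar == 0) {
      variants <- data.frame(chrom = character(0), pos = numeric(0),
                             ref = character(0), alt = character(0),
                             class = character(0), consequence = character(0),
                             coding = logical(0))
      calls <- matrix(integer(0), 0, nTip,
                      dimnames = list(NULL, tr$tip.label))
      out <- list(table = new("GenotypeTable", variants = variants,
                              calls = calls),
                  branchCounts = branchCounts,
                  variantEdge = integer(0))
      return(out)
    }
    edgeOf <- rep(seq_len(nEdge), branchCounts)
    loc <- samplePositions(nVar, genome)
    isIndel <- runif(nVar) < indelFraction
    isCoding <- runif(nVar) < codingFraction
    ref <- sample(BASES, nVar, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1L), "",
                  USE.NAMES = FALSE)
    # indels: half short insertions, half short deletions (1-3 bp)
    ins <- runif(nVar) < 0.5
    extra <- vapply(seq_len(nVar), function(i)
      paste(sample(BASES, sample(1:3, 1L), replace = TRUE), collapse = ""), "")
    ref[isIndel & !ins] <- paste0(ref[isIndel & !ins], extra[isIndel & !ins])
    alt[isIndel & !ins] <- substr(ref[isIndel & !ins], 1L, 1L)
    alt[isIndel & ins] <- paste0(ref[isIndel & ins], extra[isIndel & ins])
    consequence <- character(nVar)
    consequence[!isIndel & isCoding] <-
      sample(CODING_CONSEQUENCES, sum(!isIndel & isCoding), replace = TRUE)
    consequence[isIndel & isCoding] <-
      sample(CODING_INDEL_CONSEQUENCES, sum(isIndel & isCoding), replace = TRUE)
    consequence[!isCoding] <-
      sample(NONCODING_CONSEQUENCES, sum(!isCoding), replace = TRUE)

    calls <- matrix(0L, nVar, nTip, dimnames = list(NULL, tr$tip.label))
    for (i in seq_len(nVar)) calls[i, tipsBelow[[edgeOf[i]]]] <- 1L

    variants <- data.frame(chrom = loc$chrom, pos = loc$pos, ref = ref,
                           alt = alt,
                           class = ifelse(isIndel, "indel", "SNP"),
                           consequence = consequence, coding = isCoding)
    ord <- order(factor(variants$chrom, levels = names(genome)), variants$pos)
    variants <- variants[ord, , drop = FALSE]
    rownames(variants) <- NULL
    list(table = new("GenotypeTable", variants = variants,
                     calls = calls[ord, , drop = FALSE]),
         branchCounts = branchCounts,
         variantEdge = edgeOf[ord])
  })
}
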