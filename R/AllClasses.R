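setOldClass("phylo")

#' SeparationSchedule: a dated substrain genealogy
#'
#' A rooted genealogy of substrain colonies whose node dates are calendar
#' years. Edge lengths of `tree` are in years; `rootYear` dates the first
#' split and all tips are sampled in `samplingYear` (the tree is
#' ultrametric in years). `generationsPerYear` converts elapsed years to
#' breeding generations (the conventional four generations per year for
#' mouse colonies is the default in constructors).
#'
#' @slot tree an [ape::phylo] tree, edge lengths in years, possibly
#'   multifurcating.
#' @slot rootYear numeric calendar year of the root split.
#' @slot samplingYear numeric calendar year at which all tips are sampled.
#' @slot generationsPerYear positive numeric.
#' @name SeparationSchedule-class
#' @exportClass SeparationSchedule
setClass("SeparationSchedule",
  representation(tree = "phylo", rootYear = "numeric",
                 samplingYear = "numeric", generationsPerYear = "numeric"))

setValidity("SeparationSchedule", function(object) {
  tr <- object@tree
  msg <- character()
  if (is.null(tr$edge.length)) msg <- c(msg, "tree must have edge lengths (years)")
  else if (any(tr$edge.length <= 0))
    msg <- c(msg, "node dates must strictly increase from root to tips (all edge lengths > 0)")
  if (length(object@generationsPerYear) != 1L || object@generationsPerYear <= 0)
    msg <- c(msg, "generationsPerYear must be a single positive number")
  if (length(object@rootYear) != 1L || length(object@samplingYear) != 1L)
    msg <- c(msg, "rootYear and samplingYear must be single years")
  if (!length(msg) && !is.null(tr$edge.length)) {
    d <- nodeDepths(tr)
    tipd <- d[seq_len(length(tr$tip.label))]
    span <- object@samplingYear - object@rootYear
    if (max(abs(tipd - span)) > 1e-6)
      msg <- c(msg, "every tip must be sampled in samplingYear (root-to-tip years must equal samplingYear - rootYear)")
  }
  if (length(msg)) msg else TRUE
})

#' GenotypeTable: homozygous variant calls across substrains
#'
#' Variants by substrains table of fixed homozygous calls. Every call is
#' either the reference or the alternate allele; heterozygous and missing
#' calls are excluded at load time, mirroring how fully inbred lines are
#' analysed. `calls` is an integer matrix with 0 = ref, 1 = alt.
#'
#' @slot variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `class` ("SNP" or "indel"), `consequence` (character, may be
#'   NA), `coding` (logical).
#' @slot calls integer matrix, variants x substrains, values in {0, 1},
#'   column names are substrain names.
#' @name GenotypeTable-class
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(variants = "data.frame", calls = "matrix"))

setValidity("GenotypeTable", function(object) {
  v <- object@variants; m <- object@calls
  msg <- character()
  need <- c("chrom", "pos", "ref", "alt", "class", "consequence", "coding")
  if (!all(need %in% names(v)))
    msg <- c(msg, paste("variants must have columns:", paste(need, collapse = ", ")))
  if (nrow(v) != nrow(m)) msg <- c(msg, "variants and calls row counts differ")
  if (is.null(colnames(m))) msg <- c(msg, "calls must have substrain column names")
  if (nrow(m) > 0) {
    if (!all(m %in% c(0L, 1L)))
      msg <- c(msg, "calls must be 0 (ref) or 1 (alt); no heterozygous or missing calls")
    if (all(need %in% names(v))) {
      if (!all(v$class %in% c("SNP", "indel")))
        msg <- c(msg, "variant class must be 'SNP' or 'indel'")
      isSnpLen <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
      if (any((v$class == "SNP") != isSnpLen))
        msg <- c(msg, "class 'SNP' iff ref and alt are both single bases")
    }
  }
  if (length(msg)) msg else TRUE
})

#' DistanceMatrix: pairwise fixed-difference counts
#'
#' Symmetric nonnegative integer matrix counting, for one variant class,
#' the sites at which each pair of substrains carries different homozygous
#' alleles. As a Hamming-type count it has zero diagonal and satisfies the
#' triangle inequality.
#'
#' @slot values square integer matrix with substrain dimnames.
#' @slot variantClass one of "SNP", "indel", "coding", "all".
#' @name DistanceMatrix-class
#' @exportClass DistanceMatrix
setClass("DistanceMatrix",
  representation(values = "matrix", variantClass = "character"))

setValidity("DistanceMatrix", function(object) {
  m <- object@values
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    msg <- c(msg, "matrix must have identical row and column substrain names")
  if (any(m < 0)) msg <- c(msg, "distances must be nonnegative")
  if (any(m != round(m))) msg <- c(msg, "distances must be integer counts")
  if (nrow(m) == ncol(m)) {
    if (any(diag(m) != 0)) msg <- c(msg, "diagonal must be zero")
    if (any(m != t(m))) msg <- c(msg, "matrix must be symmetric")
    n <- nrow(m)
    if (n >= 3) {
      for (k in seq_len(n)) {
        if (any(m > outer(m[, k], m[k, ], `+`) + 1e-9)) {
          msg <- c(msg, "matrix violates the triangle inequality")
          break
        }
      }
    }
  }
  if (!object@variantClass %in% c("SNP", "indel", "coding", "all"))
    msg <- c(msg, "variantClass must be one of SNP, indel, coding, all")
  if (length(msg)) msg else TRUE
})

#' PileupCounts: read-level base counts per locus and substrain
#'
#' For each biallelic SNP locus and substrain, the number of sequencing
#' reads carrying each base, together with the capture-pool membership of
#' every substrain. This is the input to pooled-capture artifact-rate
#' estimation.
#'
#' @slot counts data.frame with columns `chrom`, `pos`, `substrain`,
#'   `A`, `C`, `G`, `T`.
#' @slot pools named list of character vectors partitioning the substrains
#'   into capture pools.
#' @name PileupCounts-class
#' @exportClass PileupCounts
setClass("PileupCounts",
  representation(counts = "data.frame", pools = "list"))

setValidity("PileupCounts", function(object) {
  ct <- object@counts
  msg <- character()
  need <- c("chrom", "pos", "substrain", "A", "C", "G", "T")
  if (!all(need %in% names(ct)))
    msg <- c(msg, paste("counts must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(as.matrix(ct[, BASES]) < 0)) msg <- c(msg, "counts must be nonnegative")
    key <- paste(ct$chrom, ct$pos, ct$substrain)
    if (anyDuplicated(key))
      msg <- c(msg, "each (locus, substrain) may appear at most once")
    members <- unlist(object@pools, use.names = FALSE)
    if (anyDuplicated(members)) msg <- c(msg, "pools must be disjoint")
    if (!all(unique(ct$substrain) %in% members))
      msg <- c(msg, "every substrain in counts must belong to a pool")
  }
  if (length(msg)) msg else TRUE
})

#' IntensityTrack: ordered array probe intensities per substrain
#'
#' Scaled probe intensities along the genome, one column per substrain,
#' centered near zero for copy-neutral probes. Runs of strongly negative
#' values in one substrain indicate a deletion.
#'
#' @slot probes data.frame with columns `chrom` and `pos`, positions
#'   strictly increasing within each chromosome.
#' @slot intensities numeric matrix, probes x substrains, no missing cells.
#' @name IntensityTrack-class
#' @exportClass IntensityTrack
setClass("IntensityTrack",
  representation(probes = "data.frame", intensities = "matrix"))

setValidity("IntensityTrack", function(object) {
  p <- object@probes; m <- object@intensities
  msg <- character()
  if (!all(c("chrom", "pos") %in% names(p)))
    msg <- c(msg, "probes must have columns chrom, pos")
  else if (nrow(p) != nrow(m)) msg <- c(msg, "probes and intensities row counts differ")
  else {
    for (ch in unique(p$chrom)) {
      pos <- p$pos[p$chrom == ch]
      if (any(diff(pos) <= 0)) {
        msg <- c(msg, "probe positions must be strictly increasing within a chromosome")
        break
      }
    }
  }
  if (anyNA(m)) msg <- c(msg, "intensities must have no missing cells")
  if (is.null(colnames(m))) msg <- c(msg, "intensities must have substrain column names")
  if (length(msg)) msg else TRUE
})
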