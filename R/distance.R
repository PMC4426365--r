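# pairwise fixed-difference distances and substrain distribution patterns

#' Pairwise fixed-difference distance matrix
#'
#' Counts, for each pair of substrains, the variants of the requested
#' class at which the two carry different homozygous alleles — the
#' Hamming distance over the 0/1 call matrix restricted to that class.
#'
#' @param table a [GenotypeTable-class].
#' @param variantClass one of `"all"`, `"SNP"`, `"indel"`, `"coding"`.
#'   `"coding"` selects variants whose consequence label is in
#'   `codingSet`.
#' @param codingSet labels counted as coding, see [defaultCodingSet()].
#' @return A [DistanceMatrix-class].
#' @export
#' @examples
#' sim <- simulateDrift(nodSchedule(), seed = 1)
#' pairwiseDistance(sim$table, "SNP")
pairwiseDistance <- function(table, variantClass = c("all", "SNP", "indel",
                                                     "coding"),
                             codingSet = defaultCodingSet()) {
  stopifnot(is(table, "GenotypeTable"))
  variantClass <- match.arg(variantClass)
  v <- variantInfo(table)
  keep <- switch(variantClass,
    all = rep(TRUE, nrow(v)),
    SNP = v$class == "SNP",
    indel = v$class == "indel",
    coding = !is.na(v$consequence) & v$consequence %in% codingSet)
  x <- callsMatrix(table)[keep, , drop = FALSE]
  storage.mode(x) <- "double"
  d <- crossprod(x, 1 - x)
  d <- d + t(d)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(colnames(callsMatrix(table)),
                      colnames(callsMatrix(table)))
  new("DistanceMatrix", values = d, variantClass = variantClass)
}

#' Extremes of a distance matrix
#'
#' The smallest and largest off-diagonal entry, with the substrain pair
#' attaining each; ties are broken by lexicographic pair order.
#'
#' @param m a [DistanceMatrix-class] with at least 2 substrains.
#' @return List with `min`, `minPair`, `max`, `maxPair`; pairs are sorted
#'   character vectors of length 2.
#' @export
distanceSummary <- function(m) {
  stopifnot(is(m, "DistanceMatrix"))
  vals <- distanceValues(m)
  labs <- rownames(vals)
  if (length(labs) < 2L)
    sdStop("distance summary needs at least 2 substrains", "inputError")
  ord <- order(labs)
  pairs <- combn(labs[ord], 2L)           # lexicographic pair order
  pv <- vals[cbind(pairs[1L, ], pairs[2L, ])]
  iMin <- which(pv == min(pv))[1L]
  iMax <- which(pv == max(pv))[1L]
  list(min = as.numeric(min(pv)), minPair = pairs[, iMin],
       max = as.numeric(max(pv)), maxPair = pairs[, iMax])
}

#' Substrain distribution patterns
#'
#' For each variant, the subset of substrains carrying the alternate
#' allele (its SDP). Variants whose alternate is carried by no substrain
#' or by all substrains are flagged non-informative: they distinguish no
#' pair and contribute nothing to distances. "Unique" variants are those
#' carried by exactly one substrain; because polarity against the
#' reference is arbitrary, variants carried by all but one substrain are
#' reported separately as complement-unique.
#'
#' @param table a [GenotypeTable-class].
#' @return List with \describe{
#'   \item{patterns}{data.frame with one row per variant: `pattern`
#'     (comma-separated carrier names), `nCarriers`, `informative`;}
#'   \item{uniqueCounts}{named integer vector, variants unique to each
#'     substrain;}
#'   \item{complementUniqueCounts}{named integer vector, variants carried
#'     by all substrains except the named one.}}
#' @export
sdpTable <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  cm <- callsMatrix(table)
  strains <- colnames(cm)
  n <- ncol(cm)
  carriers <- apply(cm, 1L, function(r) paste(strains[r == 1L], collapse = ","))
  if (nrow(cm) == 0L) carriers <- character(0)
  k <- if (nrow(cm)) rowSums(cm) else integer(0)
  uniq <- colSums(cm[k == 1L, , drop = FALSE])
  compUniq <- colSums(1L - cm[k == n - 1L, , drop = FALSE])
  list(patterns = data.frame(pattern = carriers, nCarriers = k,
                             informative = k > 0L & k < n),
       uniqueCounts = setNames(as.integer(uniq), strains),
       complementUniqueCounts = setNames(as.integer(compUniq), strains))
}

#' Tally variant consequences
#'
#' Counts and percentages of variants per consequence category, with
#' totals split by variant class. Labels are taken as input (annotation
#' itself is upstream of this package); variants without a label are
#' counted under "unannotated".
#'
#' @param table a [GenotypeTable-class].
#' @return List with `tally` (data.frame: consequence, count, percent),
#'   `total`, `totalByClass` (named vector over SNP/indel).
#' @export
consequenceTally <- function(table) {
  stopifnot(is(table, "GenotypeTable"))
  v <- variantInfo(table)
  lab <- ifelse(is.na(v$consequence) | v$consequence == "", "unannotated",
                v$consequence)
  total <- nrow(v)
  if (total == 0L) {
    return(list(tally = data.frame(consequence = character(0),
                                   count = integer(0), percent = numeric(0)),
                total = 0L,
                totalByClass = c(SNP = 0L, indel = 0L)))
  }
  tab <- sort(base::table(lab), decreasing = TRUE)
  list(tally = data.frame(consequence = names(tab),
                          count = as.integer(tab),
                          percent = 100 * as.integer(tab) / total),
       total = total,
       totalByClass = c(SNP = sum(v$class == "SNP"),
                        indel = sum(v$class == "indel")))
}

#' Read or write a DistanceMatrix as labeled TSV
#'
#' The layout matches a printed pairwise table: substrain row and column
#' labels around a square integer matrix.
#'
#' @param m a [DistanceMatrix-class].
#' @param path file path.
#' @param variantClass class recorded when reading.
#' @return `readDistanceTsv` returns a [DistanceMatrix-class];
#'   `writeDistanceTsv` returns `path` invisibly.
#' @export
writeDistanceTsv <- function(m, path) {
  stopifnot(is(m, "DistanceMatrix"))
  df <- data.frame(substrain = rownames(distanceValues(m)),
                   distanceValues(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeDistanceTsv
#' @export
readDistanceTsv <- function(path, variantClass = "all") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  labs <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- labs
  storage.mode(vals) <- "integer"
  new("DistanceMatrix", values = vals, variantClass = variantClass)
}
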