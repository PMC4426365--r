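# array probe intensity tracks with planted deletions

#' Simulate scaled probe intensities with planted deletions
#'
#' Copy-neutral probe intensities are Normal(0, `noiseSd`); each planted
#' deletion shifts the affected (substrain, probe) cells by `shift` < 0,
#' emulating the depressed invariant-probe intensities a hemizygous or
#' homozygous deletion produces on a genotyping array.
#'
#' @param positions strictly increasing integer probe positions.
#' @param substrains character vector of substrain names.
#' @param deletions list of deletions, each a list with elements
#'   `substrains` (character subset), `from`, `to` (1-based probe index
#'   range) and `shift` (negative intensity shift).
#' @param noiseSd positive noise standard deviation.
#' @param chrom chromosome label for the track.
#' @param seed integer RNG seed.
#' @return An [IntensityTrack-class].
#' @export
#' @examples
#' tr <- simulateIntensities(seq(24272052, 24383100, length.out = 13),
#'   substrains = c("BomTac", "MrkTac", "ShiJcl", "ShiLtDvs", "ShiLt"),
#'   deletions = list(list(substrains = "ShiLtDvs", from = 1, to = 13,
#'                         shift = -2)),
#'   seed = 7)
simulateIntensities <- function(positions, substrains, deletions = list(),
                                noiseSd = 0.1, chrom = "chr11", seed = 0) {
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0))
    sdStop("probe positions must be strictly increasing", "inputError")
  if (noiseSd <= 0) sdStop("noiseSd must be positive", "parameterError")
  n <- length(positions)
  for (d in deletions) {
    if (!all(c("substrains", "from", "to", "shift") %in% names(d)))
      sdStop("each deletion needs substrains, from, to, shift", "inputError")
    if (d$from < 1 || d$to > n || d$from > d$to)
      sdStop("deletion probe range out of bounds", "inputError")
    if (d$shift >= 0) sdStop("deletion shift must be negative", "inputError")
    if (!all(d$substrains %in% substrains))
      sdStop("deletion names an unknown substrain", "inputError")
  }
  withSeed(seed, {
    m <- matrix(rnorm(n * length(substrains), 0, noiseSd), n,
                length(substrains), dimnames = list(NULL, substrains))
    for (d in deletions)
      m[d$from:d$to, d$substrains] <- m[d$from:d$to, d$substrains] + d$shift
    new("IntensityTrack",
        probes = data.frame(chrom = chrom, pos = positions),
        intensities = m)
  })
}
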