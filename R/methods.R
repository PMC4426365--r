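# accessor and show methods

#' @rdname accessors
#' @export
setMethod("substrainNames", "GenotypeTable", function(x) colnames(x@calls))
#' @rdname accessors
#' @export
setMethod("substrainNames", "DistanceMatrix", function(x) rownames(x@values))
#' @rdname accessors
#' @export
setMethod("substrainNames", "PileupCounts",
          function(x) sort(unique(x@counts$substrain)))
#' @rdname accessors
#' @export
setMethod("substrainNames", "IntensityTrack", function(x) colnames(x@intensities))
#' @rdname accessors
#' @export
setMethod("substrainNames", "SeparationSchedule", function(x) x@tree$tip.label)

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeTable", function(x) x@variants)
#' @rdname accessors
#' @export
setMethod("callsMatrix", "GenotypeTable", function(x) x@calls)
#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeTable", function(x) nrow(x@variants))

#' @rdname accessors
#' @export
setMethod("distanceValues", "DistanceMatrix", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("variantClass", "DistanceMatrix", function(x) x@variantClass)

#' @rdname accessors
#' @export
setMethod("pileupData", "PileupCounts", function(x) x@counts)
#' @rdname accessors
#' @export
setMethod("poolAssignments", "PileupCounts", function(x) x@pools)

#' @rdname accessors
#' @export
setMethod("probeInfo", "IntensityTrack", function(x) x@probes)
#' @rdname accessors
#' @export
setMethod("intensityValues", "IntensityTrack", function(x) x@intensities)

#' @rdname accessors
#' @export
setMethod("scheduleTree", "SeparationSchedule", function(x) x@tree)
#' @rdname accessors
#' @export
setMethod("samplingYear", "SeparationSchedule", function(x) x@samplingYear)
#' @rdname accessors
#' @export
setMethod("generationsPerYear", "SeparationSchedule",
          function(x) x@generationsPerYear)
#' @rdname accessors
#' @export
setMethod("rootYear", "SeparationSchedule", function(x) x@rootYear)

setMethod("show", "SeparationSchedule", function(object) {
  cat("SeparationSchedule:", length(object@tree$tip.label), "substrains\n")
  cat("  root split:", object@rootYear, " sampled:", object@samplingYear,
      " generations/year:", object@generationsPerYear, "\n")
  cat("  tips:", paste(object@tree$tip.label, collapse = ", "), "\n")
})

setMethod("show", "GenotypeTable", function(object) {
  v <- object@variants
  cat("GenotypeTable:", nrow(v), "variants x", ncol(object@calls),
      "substrains\n")
  if (nrow(v)) {
    cat("  classes:", paste(names(table(v$class)), table(v$class),
                            sep = "=", collapse = ", "), "\n")
    cat("  coding:", sum(v$coding), "\n")
  }
  cat("  substrains:", paste(colnames(object@calls), collapse = ", "), "\n")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix (", object@variantClass, "), ",
      nrow(object@values), " substrains\n", sep = "")
  print(object@values)
})

setMethod("show", "PileupCounts", function(object) {
  nl <- nrow(unique(object@counts[, c("chrom", "pos")]))
  cat("PileupCounts:", nl, "loci x",
      length(unique(object@counts$substrain)), "substrains\n")
  cat("  pools:", paste(vapply(object@pools, paste, "", collapse = "+"),
                        collapse = " | "), "\n")
})

setMethod("show", "IntensityTrack", function(object) {
  cat("IntensityTrack:", nrow(object@probes), "probes x",
      ncol(object@intensities), "substrains\n")
  cat("  chrom:", paste(unique(object@probes$chrom), collapse = ", "), "\n")
})
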