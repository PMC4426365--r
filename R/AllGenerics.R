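#' @name accessors
#' @title Accessors for SubstrainDrift classes
#' @description Slot access goes through these accessors; the slots
#'   themselves are implementation detail.
#' @param x an object of the documented class.
#' @return The requested component (see the individual generic).
NULL

#' @describeIn accessors Substrain names carried by an object.
#' @export
setGeneric("substrainNames", function(x) standardGeneric("substrainNames"))

#' @describeIn accessors Per-variant metadata of a GenotypeTable.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @describeIn accessors 0/1 (ref/alt) call matrix of a GenotypeTable.
#' @export
setGeneric("callsMatrix", function(x) standardGeneric("callsMatrix"))

#' @describeIn accessors Number of variants in a GenotypeTable.
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @describeIn accessors Integer matrix of a DistanceMatrix.
#' @export
setGeneric("distanceValues", function(x) standardGeneric("distanceValues"))

#' @describeIn accessors Variant class of a DistanceMatrix.
#' @export
setGeneric("variantClass", function(x) standardGeneric("variantClass"))

#' @describeIn accessors Base-count data.frame of a PileupCounts.
#' @export
setGeneric("pileupData", function(x) standardGeneric("pileupData"))

#' @describeIn accessors Capture-pool membership of a PileupCounts.
#' @export
setGeneric("poolAssignments", function(x) standardGeneric("poolAssignments"))

#' @describeIn accessors Probe coordinate data.frame of an IntensityTrack.
#' @export
setGeneric("probeInfo", function(x) standardGeneric("probeInfo"))

#' @describeIn accessors Intensity matrix of an IntensityTrack.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @describeIn accessors Dated genealogy tree of a SeparationSchedule.
#' @export
setGeneric("scheduleTree", function(x) standardGeneric("scheduleTree"))

#' @describeIn accessors Sampling year of a SeparationSchedule.
#' @export
setGeneric("samplingYear", function(x) standardGeneric("samplingYear"))

#' @describeIn accessors Generations per year of a SeparationSchedule.
#' @export
setGeneric("generationsPerYear", function(x) standardGeneric("generationsPerYear"))

#' @describeIn accessors Calendar year of the root split.
#' @export
setGeneric("rootYear", function(x) standardGeneric("rootYear"))
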