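#' Accessors for ClusteredMutations result objects
#'
#' Small accessor layer so downstream code never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors sample identifier of an [ImdProfile].
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @describeIn accessors accepted global IMD cutoff in bp (`NA` when no
#'   clustering is detectable).
#' @export
setGeneric("globalCutoff", function(x) standardGeneric("globalCutoff"))

#' @describeIn accessors flagged 1-Mb regional windows as a [GRanges].
#' @export
setGeneric("regionalWindows", function(x) standardGeneric("regionalWindows"))

#' @describeIn accessors candidate-cutoff sweep table.
#' @export
setGeneric("thresholdSweepTable", function(x) standardGeneric("thresholdSweepTable"))

#' @describeIn accessors per-event summary table of a [ClusterEventSet].
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @describeIn accessors per-mutation [GRanges] of a [ClusterEventSet]
#'   (clustered and non-clustered mutations; `eventId` is `NA` for the
#'   latter).
#' @export
setGeneric("eventMutations", function(x) standardGeneric("eventMutations"))

#' @describeIn accessors channel counts of a [MutationSpectrum].
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @describeIn accessors classification name of a [MutationSpectrum].
#' @export
setGeneric("classificationName", function(x) standardGeneric("classificationName"))

#' @describeIn accessors ordered component means of a mixture fit.
#' @export
setGeneric("mixtureMeans", function(x) standardGeneric("mixtureMeans"))

#' @describeIn accessors mixing weights of a mixture fit.
#' @export
setGeneric("mixtureWeights", function(x) standardGeneric("mixtureWeights"))

#' @rdname accessors
#' @export
setMethod("sampleId", "ImdProfile", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("globalCutoff", "ImdProfile", function(x) x@globalCutoff)

#' @rdname accessors
#' @export
setMethod("regionalWindows", "ImdProfile", function(x) x@regional)

#' @rdname accessors
#' @export
setMethod("thresholdSweepTable", "ImdProfile", function(x) x@sweep)

#' @rdname accessors
#' @export
setMethod("events", "ClusterEventSet", function(x) x@events)

#' @rdname accessors
#' @export
setMethod("eventMutations", "ClusterEventSet", function(x) x@mutations)

#' @rdname accessors
#' @export
setMethod("spectrumCounts", "MutationSpectrum", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("classificationName", "MutationSpectrum", function(x) x@classification)

#' @rdname accessors
#' @export
setMethod("mixtureMeans", "PoissonMixtureFit", function(x) x@means)

#' @rdname accessors
#' @export
setMethod("mixtureMeans", "DistanceMixture", function(x) x@means)

#' @rdname accessors
#' @export
setMethod("mixtureWeights", "PoissonMixtureFit", function(x) x@weights)

#' @rdname accessors
#' @export
setMethod("mixtureWeights", "DistanceMixture", function(x) x@weights)
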