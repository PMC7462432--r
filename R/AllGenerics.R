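#' @name accessors
#' @title Accessors for AdhereNet S4 containers
#' @description Slot access for the core containers; user code should use
#'   these rather than `@`.
#' @param object An AdhereNet S4 object.
#' @return The requested component.
NULL

#' @rdname accessors
#' @export
setGeneric("participantId", function(object) standardGeneric("participantId"))
#' @rdname accessors
#' @export
setGeneric("roiLabels", function(object) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setGeneric("seriesMatrix", function(object) standardGeneric("seriesMatrix"))
#' @rdname accessors
#' @export
setGeneric("connectivityMatrix", function(object) standardGeneric("connectivityMatrix"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(object) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("thresholdOf", function(object) standardGeneric("thresholdOf"))
#' @rdname accessors
#' @export
setGeneric("affiliations", function(object) standardGeneric("affiliations"))
#' @rdname accessors
#' @export
setGeneric("networkNames", function(object) standardGeneric("networkNames"))

#' @rdname accessors
#' @export
setMethod("participantId", "RoiTimeSeriesSet", function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("participantId", "WeightedConnectome", function(object) object@participantId)
#' @rdname accessors
#' @export
setMethod("participantId", "BinaryGraph", function(object) object@participantId)

#' @rdname accessors
#' @export
setMethod("roiLabels", "RoiTimeSeriesSet", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "WeightedConnectome", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "BinaryGraph", function(object) object@roiLabels)
#' @rdname accessors
#' @export
setMethod("roiLabels", "AffiliationVector", function(object) names(object@affiliations))

#' @rdname accessors
#' @export
setMethod("seriesMatrix", "RoiTimeSeriesSet", function(object) object@series)
#' @rdname accessors
#' @export
setMethod("connectivityMatrix", "WeightedConnectome", function(object) object@r)
#' @rdname accessors
#' @export
setMethod("adjacencyMatrix", "BinaryGraph", function(object) object@adjacency)
#' @rdname accessors
#' @export
setMethod("thresholdOf", "BinaryGraph", function(object) object@threshold)
#' @rdname accessors
#' @export
setMethod("affiliations", "AffiliationVector", function(object) object@affiliations)
#' @rdname accessors
#' @export
setMethod("networkNames", "AffiliationVector",
          function(object) sort(unique(unname(object@affiliations))))

setMethod("show", "RoiTimeSeriesSet", function(object) {
  cat(sprintf("RoiTimeSeriesSet '%s': %d timepoints x %d ROIs\n",
              object@participantId, nrow(object@series), ncol(object@series)))
})

setMethod("show", "AffiliationVector", function(object) {
  tab <- table(object@affiliations)
  cat(sprintf("AffiliationVector: %d ROIs in %d networks\n",
              length(object@affiliations), length(tab)))
  print(tab)
})

setMethod("show", "WeightedConnectome", function(object) {
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("WeightedConnectome '%s': %d nodes, r in [%.3f, %.3f]\n",
              object@participantId, nrow(object@r), min(off), max(off)))
})

setMethod("show", "BinaryGraph", function(object) {
  cat(sprintf("BinaryGraph '%s': %d nodes, %d edges at T = %s\n",
              object@participantId, nrow(object@adjacency),
              sum(object@adjacency) / 2L, format(object@threshold)))
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig\n")
  cat("  thresholds:       ", paste(format(object@thresholdGrid), collapse = " "), "\n")
  cat("  nPerm:            ", object@nPerm, "\n")
  cat("  fdrQ:             ", object@fdrQ, "\n")
  cat("  minSigThresholds: ", object@minSigThresholds, "\n")
  cat("  homeworkCutoff:   ", object@homeworkCutoff, "\n")
  cat("  holdoutFraction:  ", object@holdoutFraction, "\n")
  cat("  seeds:            ", paste(object@seeds, collapse = " "), "\n")
  cat("  louvainReps:      ", object@louvainReps, "\n")
  cat("  binarization:     ", if (object@absoluteThreshold) "|r| > T" else "r > T", "\n")
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf("SimParams: %d participants (%s), %d ROIs x %d timepoints, seed %d\n",
              object@nParticipants,
              paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
                    collapse = ", "),
              object@nRoi, object@nTimepoints, object@seed))
  cat(sprintf("  coupling ~ N(%.2f, %.2f^2), global %.2f, noise %.2f\n",
              object@couplingMean, object@couplingSd, object@globalWeight,
              object@noiseSd))
  cat(sprintf("  homework slope %.2f (noise %.2f), attendance slope %.2f (noise %.2f)\n",
              object@effectSlope, object@effectNoiseSd,
              object@attendanceSlope, object@attendanceNoiseSd))
})
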