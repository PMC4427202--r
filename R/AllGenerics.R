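#' Accessors for package classes
#'
#' Small accessor family so downstream code never reaches into slots:
#' `pixels()` returns the count matrix of a frame, `frameMask()` its logical
#' invalid-pixel mask (a full all-FALSE matrix when nothing is masked),
#' `frameId()` its identifier, `peaks()` the peak table of a [PeakList-class],
#' `scanPositions()` the shot table of a [ScanPlan-class] and `reference()`
#' the background image of a [BackgroundModel-class].
#'
#' @param x object to access.
#' @return See the method descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname accessors
#' @export
setMethod("pixels", "ImageFrame", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))

#' @rdname accessors
#' @export
setMethod("frameMask", "ImageFrame", function(x) {
  if (length(x@mask)) x@mask
  else matrix(FALSE, nrow(x@pixels), ncol(x@pixels))
})

#' @rdname accessors
#' @export
setGeneric("frameId", function(x) standardGeneric("frameId"))

#' @rdname accessors
#' @export
setMethod("frameId", "ImageFrame", function(x) x@frameId)

#' @rdname accessors
#' @export
setMethod("frameId", "PeakList", function(x) x@frameId)

#' @rdname accessors
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname accessors
#' @export
setMethod("peaks", "PeakList", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("scanPositions", function(x) standardGeneric("scanPositions"))

#' @rdname accessors
#' @export
setMethod("scanPositions", "ScanPlan", function(x) x@positions)

#' @rdname accessors
#' @export
setGeneric("reference", function(x) standardGeneric("reference"))

#' @rdname accessors
#' @export
setMethod("reference", "BackgroundModel", function(x) x@reference)

#' @rdname accessors
#' @export
setGeneric("spacingValid", function(x) standardGeneric("spacingValid"))

#' @rdname accessors
#' @export
setMethod("spacingValid", "ScanPlan", function(x) x@spacingValid)

#' @rdname accessors
#' @export
setGeneric("groundTruthPeaks", function(x) standardGeneric("groundTruthPeaks"))

#' @rdname accessors
#' @export
setMethod("groundTruthPeaks", "GroundTruth", function(x) x@peaks)

#' @rdname accessors
#' @export
setGeneric("hitLabels", function(x) standardGeneric("hitLabels"))

#' @rdname accessors
#' @export
setMethod("hitLabels", "GroundTruth", function(x) x@hits)

#' @rdname accessors
#' @export
setGeneric("trueIntensities", function(x) standardGeneric("trueIntensities"))

#' @rdname accessors
#' @export
setMethod("trueIntensities", "GroundTruth", function(x) x@intensities)
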