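#' @rdname SRHImage-class
#' @param x an object.
#' @export
setGeneric("srhRGB", function(x) standardGeneric("srhRGB"))

#' @rdname SRHImage-class
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' @rdname SyntheticSlide-class
#' @param x an object.
#' @export
setGeneric("slideLabel", function(x) standardGeneric("slideLabel"))

#' @rdname PatchGrid-class
#' @param x an object.
#' @export
setGeneric("gridOrigins", function(x) standardGeneric("gridOrigins"))

#' @rdname PatchGrid-class
#' @export
setGeneric("nPatches", function(x) standardGeneric("nPatches"))

#' @rdname SlidePrediction-class
#' @param x an object.
#' @export
setGeneric("slideProbs", function(x) standardGeneric("slideProbs"))

#' @rdname SlidePrediction-class
#' @export
setGeneric("finalClass", function(x) standardGeneric("finalClass"))

#' @rdname ProbabilityHeatmap-class
#' @param x an object.
#' @export
setGeneric("heatmapArray", function(x) standardGeneric("heatmapArray"))

#' @rdname SRHModel-class
#' @param x an object.
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))

#' @rdname SRHImage-class
setMethod("srhRGB", "SRHImage", function(x) x@rgb)
#' @rdname SRHImage-class
setMethod("regionMask", "SRHImage", function(x) x@regionMask)
#' @rdname SyntheticSlide-class
setMethod("regionMask", "SyntheticSlide", function(x) x@regionMask)
#' @rdname SyntheticSlide-class
setMethod("slideLabel", "SyntheticSlide", function(x) x@label)
#' @rdname PatchGrid-class
setMethod("gridOrigins", "PatchGrid", function(x) x@origins)
#' @rdname PatchGrid-class
setMethod("nPatches", "PatchGrid", function(x) x@nX * x@nY)
#' @rdname SlidePrediction-class
setMethod("slideProbs", "SlidePrediction", function(x) x@P)
#' @rdname SlidePrediction-class
setMethod("finalClass", "SlidePrediction", function(x) x@finalClass)
#' @rdname ProbabilityHeatmap-class
setMethod("heatmapArray", "ProbabilityHeatmap", function(x) x@map)
#' @rdname SRHModel-class
setMethod("trainHistory", "SRHModel", function(x) x@trainState$history)

setMethod("show", "SRHImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("SRHImage %d x %d px (3-channel virtual H&E)%s\n", d[2], d[1],
              if (is.null(object@regionMask)) "" else ", with region mask"))
})

setMethod("show", "SyntheticSlide", function(object) {
  d <- dim(object@ch2845)
  cat(sprintf("SyntheticSlide %d x %d px, label '%s', seed %d%s\n",
              d[2], d[1], object@label, as.integer(object@seed),
              if (is.null(object@regionMask)) "" else ", mixed regions"))
})

setMethod("show", "PatchGrid", function(object) {
  cat(sprintf("PatchGrid: %d x %d windows of %d px, step %d px (%d patches)\n",
              object@nX, object@nY, object@windowPx, object@stepPx,
              object@nX * object@nY))
})

setMethod("show", "SlidePrediction", function(object) {
  cat(sprintf(
    "SlidePrediction: %s  [P = %.3f / %.3f / %.3f; %d/%d low-quality patches excluded]\n",
    object@finalClass, object@P[1], object@P[2], object@P[3],
    object@nExcluded, object@nTotal))
})

setMethod("show", "ProbabilityHeatmap", function(object) {
  d <- dim(object@map)
  cat(sprintf("ProbabilityHeatmap %d x %d px (%s from %d x %d grid)\n",
              d[2], d[1], object@method, object@gridDim[2], object@gridDim[1]))
})

setMethod("show", "SRHModel", function(object) {
  cfg <- object@config
  np <- sum(vapply(object@params, length, integer(1)))
  st <- object@trainState
  cat(sprintf("SRHModel: %d-stage pre-activation residual net, widths [%s], %d parameters\n",
              length(cfg$stage_widths),
              paste(cfg$stage_widths, collapse = ", "), np))
  if (length(st$history))
    cat(sprintf("  trained %d epochs, val acc %.3f, val loss %.3f, stopped = %s\n",
                nrow(st$history), st$val_accuracy, st$val_loss, st$stopped))
  else cat("  untrained\n")
})
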