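#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' Two-channel Raman intensity pair
#'
#' Raw SRH acquisition at the two Raman shift wavenumbers:
#' 2845 cm-1 (CH2, lipid channel) and 2940 cm-1 (CH3, protein and nucleic
#' acids). Both channels are numeric matrices of identical dimensions with
#' finite, non-negative intensities; the package keeps intensities in
#' \[0, 1\] internally and quantizes to 8/16 bit only at file boundaries.
#'
#' @slot ch2845 numeric matrix, lipid-channel intensities.
#' @slot ch2940 numeric matrix, protein-channel intensities.
#' @export
setClass("RamanPair",
  representation(ch2845 = "matrix", ch2940 = "matrix"),
  validity = function(object) {
    a <- object@ch2845; b <- object@ch2940
    if (!identical(dim(a), dim(b)))
      return("ch2845 and ch2940 must have identical dimensions")
    if (!all(is.finite(a)) || !all(is.finite(b)))
      return("channel intensities must be finite")
    if (min(a) < 0 || min(b) < 0)
      return("channel intensities must be non-negative")
    TRUE
  })

#' Three-channel virtual H&E SRH image
#'
#' A whole-slide SRH image rendered from a [RamanPair-class] by channel
#' subtraction and a linear virtual-H&E color map (see [buildSRH()]), or read
#' from disk. Values lie in \[0, 1\]; the optional region mask carries
#' per-pixel class codes (0 = tumor, 1 = non-tumor, 2 = low quality) for
#' synthetic slides with known ground truth.
#'
#' @slot rgb numeric array height x width x 3 in \[0, 1\].
#' @slot provenance list describing how the image was formed (source id,
#'   subtraction gains).
#' @slot regionMask integer matrix of per-pixel class codes, or `NULL`.
#' @export
setClass("SRHImage",
  representation(rgb = "array", provenance = "list",
                 regionMask = "matrixOrNULL"),
  validity = function(object) {
    d <- dim(object@rgb)
    if (length(d) != 3L || d[3] != 3L)
      return("rgb must be a height x width x 3 array")
    if (!all(is.finite(object@rgb)))
      return("rgb values must be finite")
    if (min(object@rgb) < -1e-9 || max(object@rgb) > 1 + 1e-9)
      return("rgb values must lie in [0, 1]")
    if (!is.null(object@regionMask) &&
        !identical(dim(object@regionMask), d[1:2]))
      return("regionMask dimensions must match the image")
    TRUE
  })

#' Synthetic SRH slide with known ground truth
#'
#' A simulated two-channel acquisition (extends [RamanPair-class]) plus its
#' generating class label, texture parameters, seed, and — for mixed slides —
#' the exact per-pixel region mask.
#'
#' @slot label one of `srhClasses()`; for mixed slides, the modal class of
#'   the region mask.
#' @slot regionMask integer matrix of class codes, or `NULL` for homogeneous
#'   slides.
#' @slot seed integer seed the slide was generated from.
#' @slot params the `TextureParams` list used (per class for mixed slides).
#' @export
setClass("SyntheticSlide",
  contains = "RamanPair",
  representation(label = "character", regionMask = "matrixOrNULL",
                 seed = "numeric", params = "list"),
  validity = function(object) {
    if (!(object@label %in% srhClasses()))
      return("label must be one of tumor/non_tumor/low_quality")
    if (max(object@ch2845) > 1 || max(object@ch2940) > 1)
      return("synthetic channel intensities must lie in [0, 1]")
    if (!is.null(object@regionMask)) {
      if (!identical(dim(object@regionMask), dim(object@ch2845)))
        return("regionMask dimensions must match the channels")
      modal <- srhClasses()[which.max(tabulate(object@regionMask + 1L, 3L))]
      if (modal != object@label)
        return("modal class of regionMask must equal the slide label")
    }
    TRUE
  })

#' Sliding-window patch grid
#'
#' Geometry of 300 x 300 px windows over a slide: step 100 px for training
#' (overlapping) or 300 px for testing (non-overlapping tiling). Origins are
#' 0-based top-left corners of half-open windows.
#'
#' @slot windowPx window side length (default 300).
#' @slot stepPx step in both x and y.
#' @slot nX,nY number of windows per axis, `floor((size - window)/step) + 1`.
#' @slot origins data.frame with 0-based columns `x`, `y` in row-major order
#'   (y outer, x inner).
#' @export
setClass("PatchGrid",
  representation(windowPx = "integer", stepPx = "integer",
                 nX = "integer", nY = "integer", origins = "data.frame"),
  validity = function(object) {
    if (object@windowPx < 1L || object@stepPx < 1L)
      return("window and step must be positive")
    if (nrow(object@origins) != object@nX * object@nY)
      return("origin count must equal nX * nY")
    TRUE
  })

#' Per-patch class probabilities on a test grid
#'
#' The softmax output of the CNN for every patch of a non-overlapping test
#' grid, stored as an nY x nX x 3 array in canonical class order.
#'
#' @slot probs numeric array nY x nX x 3; each patch's 3-vector sums to 1.
#' @export
setClass("PatchPredictions",
  representation(probs = "array"),
  validity = function(object) {
    d <- dim(object@probs)
    if (length(d) != 3L || d[3] != 3L)
      return("probs must be an nY x nX x 3 array")
    s <- apply(object@probs, c(1, 2), sum)
    if (any(abs(s - 1) > 1e-6))
      return("each patch probability vector must sum to 1 (within 1e-6)")
    if (min(object@probs) < -1e-9)
      return("probabilities must be non-negative")
    TRUE
  })

#' Aggregated whole-slide prediction
#'
#' Result of low-quality-exclusion averaging of patch probabilities
#' ([aggregateSlide()]): the renormalized whole-slide probability triple, the
#' final argmax class, and exclusion bookkeeping.
#'
#' @slot P named numeric(3), whole-slide class probabilities (sum 1).
#' @slot finalClass argmax of `P` under the documented tie rule.
#' @slot nTotal,nExcluded total patches and patches excluded because their
#'   top-1 class was low quality.
#' @slot patches the underlying [PatchPredictions-class].
#' @export
setClass("SlidePrediction",
  representation(P = "numeric", finalClass = "character",
                 nTotal = "integer", nExcluded = "integer",
                 patches = "PatchPredictions"),
  validity = function(object) {
    if (length(object@P) != 3L) return("P must have length 3")
    if (abs(sum(object@P) - 1) > 1e-6) return("P must sum to 1 (within 1e-6)")
    if (object@nExcluded > object@nTotal)
      return("nExcluded cannot exceed nTotal")
    if (!(object@finalClass %in% srhClasses()))
      return("finalClass must be a valid class")
    TRUE
  })

#' Interpolated per-pixel class-probability map
#'
#' Full-resolution 3-channel probability map obtained by interpolating the
#' patch-grid predictions (values anchored at patch centers, edges clamped)
#' and renormalizing pixel-wise to the simplex. Rendered red = tumor,
#' green = non-tumor, blue = low quality by [overlayHeatmap()].
#'
#' @slot map numeric array height x width x 3 in \[0, 1\].
#' @slot method interpolation method, `"bilinear"` or `"nearest"`.
#' @slot gridDim integer(2), the source grid (nY, nX).
#' @export
setClass("ProbabilityHeatmap",
  representation(map = "array", method = "character", gridDim = "integer"),
  validity = function(object) {
    d <- dim(object@map)
    if (length(d) != 3L || d[3] != 3L)
      return("map must be a height x width x 3 array")
    if (min(object@map) < -1e-9 || max(object@map) > 1 + 1e-9)
      return("map values must lie in [0, 1]")
    TRUE
  })

#' Residual CNN classifier
#'
#' A compact pre-activation residual network (identity shortcuts,
#' batch normalization, global average pooling, 3-way softmax head) together
#' with its configuration, parameters and training state. Built by
#' [buildModel()]; trained by [trainCNN()].
#'
#' @slot config the `ModelConfig` list (see [modelConfig()]).
#' @slot params named list of parameter arrays.
#' @slot state list: RMSProp caches, batch-norm running moments.
#' @slot trainState list: per-epoch history, stopping flag (see [trainCNN()]).
#' @export
setClass("SRHModel",
  representation(config = "list", params = "list", state = "list",
                 trainState = "list"))
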