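#' Construct a Raman channel pair
#'
#' Bundles the two grayscale acquisitions — 2845 cm-1 (CH2/lipid) and
#' 2940 cm-1 (CH3/protein and nucleic acids) — into a validated
#' [RamanPair-class]. Channels must be equal-sized matrices of finite,
#' non-negative intensities.
#'
#' @param ch2845,ch2940 numeric matrices of identical dimensions.
#' @return A [RamanPair-class].
#' @export
#' @examples
#' p <- ramanPair(matrix(0.2, 4, 4), matrix(0.5, 4, 4))
ramanPair <- function(ch2845, ch2940) {
  if (is.null(dim(ch2845)) || is.null(dim(ch2940)))
    stop("channels must be matrices", call. = FALSE)
  if (!identical(dim(ch2845), dim(ch2940)))
    stop("channel dimensions differ: ",
         paste(dim(ch2845), collapse = "x"), " vs ",
         paste(dim(ch2940), collapse = "x"), call. = FALSE)
  if (anyNA(ch2845) || anyNA(ch2940) ||
      !all(is.finite(ch2845)) || !all(is.finite(ch2940)))
    stop("channel intensities must be finite (no NaN/NA)", call. = FALSE)
  new("RamanPair", ch2845 = ch2845, ch2940 = ch2940)
}

#' Virtual H&E stain color vectors
#'
#' RGB absorbance directions used by the linear virtual-H&E map: nuclear
#' (protein) signal is rendered with a hematoxylin-like vector and lipid
#' signal with an eosin-like vector. Defaults follow the standard
#' hematoxylin/eosin stain separation vectors used in digital pathology.
#'
#' @return list with unit-scale numeric(3) components `hematoxylin`, `eosin`.
#' @export
srhStainVectors <- function()
  list(hematoxylin = c(0.65, 0.70, 0.29), eosin = c(0.07, 0.99, 0.11))

#' Form the three-channel virtual H&E image from the two Raman channels
#'
#' Computes the nuclear/protein signal `N = max(ch2940 - ch2845, 0)` (channel
#' subtraction; negative values are clipped because the protein signal is an
#' intensity) and the lipid signal `L = ch2845`, then renders
#' `rgb = 1 - gain_h * N * hematoxylin - gain_e * L * eosin`, clipped to
#' \[0, 1\]. More stain means a darker pixel, so increasing the protein
#' channel at fixed lipid never brightens any RGB channel. The map is linear
#' and, for the documented gains, invertible up to the clipping.
#'
#' @param pair a [RamanPair-class] (a [SyntheticSlide-class] also works; its
#'   region mask is carried over).
#' @param gains numeric(2), scalar gains for the hematoxylin (protein) and
#'   eosin (lipid) components.
#' @param stains list of color vectors as from [srhStainVectors()].
#' @return An [SRHImage-class].
#' @export
#' @examples
#' pair <- ramanPair(matrix(0.2, 8, 8), matrix(0.6, 8, 8))
#' img <- buildSRH(pair)
setGeneric("buildSRH", function(pair, gains = c(1, 1),
                                stains = srhStainVectors())
  standardGeneric("buildSRH"))

#' @rdname buildSRH
setMethod("buildSRH", "RamanPair", function(pair, gains = c(1, 1),
                                            stains = srhStainVectors()) {
  validObject(pair)
  stopifnot(length(gains) == 2L, all(is.finite(gains)), all(gains >= 0))
  L <- pair@ch2845
  N <- pair@ch2940 - pair@ch2845
  N[N < 0] <- 0
  d <- dim(L)
  rgb <- array(0, c(d[1], d[2], 3))
  for (c in 1:3)
    rgb[, , c] <- 1 - gains[1] * N * stains$hematoxylin[c] -
                      gains[2] * L * stains$eosin[c]
  rgb <- clip01(rgb)
  mask <- if (is(pair, "SyntheticSlide")) pair@regionMask else NULL
  new("SRHImage", rgb = rgb,
      provenance = list(source = "channel_subtraction", gains = gains,
                        stains = stains),
      regionMask = mask)
})

#' Construct an SRHImage from an RGB array
#'
#' @param rgb numeric array height x width x 3 in \[0, 1\].
#' @param provenance list recorded in the object.
#' @param regionMask optional integer matrix of class codes.
#' @return An [SRHImage-class].
#' @export
srhImage <- function(rgb, provenance = list(source = "array"),
                     regionMask = NULL) {
  new("SRHImage", rgb = rgb, provenance = provenance, regionMask = regionMask)
}
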