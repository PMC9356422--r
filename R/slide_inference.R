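## Whole-slide prediction: low-quality-exclusion averaging of patch
## probabilities (renormalized summation), argmax binarization with a fixed
## tie rule, and interpolated RGB probability heatmaps.

#' Construct patch predictions on a test grid
#'
#' @param probs matrix n x 3 (row-major grid order, y outer) or array
#'   nY x nX x 3 of patch class probabilities.
#' @param grid the [PatchGrid-class] the patches came from (required for
#'   matrix input).
#' @return A [PatchPredictions-class].
#' @export
patchPredictions <- function(probs, grid = NULL) {
  if (length(dim(probs)) == 2L) {
    stopifnot(!is.null(grid), nrow(probs) == nPatches(grid))
    a <- array(0, c(grid@nY, grid@nX, 3L))
    for (c in 1:3)
      a[, , c] <- matrix(probs[, c], grid@nY, grid@nX, byrow = TRUE)
    probs <- a
  }
  new("PatchPredictions", probs = probs)
}

patchProbMatrix <- function(pp) {
  ## rows in row-major grid order (y outer, x inner)
  a <- pp@probs
  d <- dim(a)
  m <- matrix(0, d[1] * d[2], 3L)
  for (c in 1:3) m[, c] <- as.vector(t(a[, , c]))
  m
}

#' Aggregate patch probabilities into a whole-slide prediction
#'
#' Patches whose top-1 class is low quality are excluded; the remaining
#' probability vectors are averaged and renormalized to the simplex
#' (renormalized summation). If every patch is excluded the slide is
#' reported as `P = (0, 0, 1)` with final class low quality — the situation
#' that triggers a re-scan of another specimen area in practice.
#'
#' @param patch_preds a [PatchPredictions-class], or an n x 3 probability
#'   matrix.
#' @return A [SlidePrediction-class].
#' @export
#' @examples
#' m <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6))
#' aggregateSlide(m)
aggregateSlide <- function(patch_preds) {
  if (is(patch_preds, "PatchPredictions")) {
    pp <- patch_preds
    m <- patchProbMatrix(pp)
  } else {
    m <- as.matrix(patch_preds)
    if (nrow(m) < 1L || ncol(m) != 3L)
      stop("need at least one patch prediction with 3 class probabilities",
           call. = FALSE)
    pp <- new("PatchPredictions",
              probs = array(as.vector(m), c(nrow(m), 1L, 3L)))
  }
  if (nrow(m) < 1L) stop("empty patch prediction set", call. = FALSE)
  top1 <- max.col(m, ties.method = "first")   # first max = canonical tie rule
  keep <- top1 != 3L
  n_total <- nrow(m)
  n_excl <- sum(!keep)
  if (!any(keep)) {
    P <- c(0, 0, 1)
  } else {
    P <- colMeans(m[keep, , drop = FALSE])
    P <- P / sum(P)
  }
  names(P) <- srhClasses()
  new("SlidePrediction", P = P,
      finalClass = srhClasses()[which.max(P)],
      nTotal = as.integer(n_total), nExcluded = as.integer(n_excl),
      patches = pp)
}

#' Binarize a slide prediction to its final class
#'
#' The class with the highest aggregated probability is chosen (the direct
#' comparison form used against the rater's categorical call). Ties break by
#' fixed priority tumor > non-tumor > low quality — clinically conservative,
#' favouring flagging tumor.
#'
#' @param pred a [SlidePrediction-class] or a probability 3-vector.
#' @return Class label string.
#' @export
#' @examples
#' binarizeSlide(c(0.5, 0.5, 0))  # "tumor" by the tie rule
binarizeSlide <- function(pred) {
  P <- if (is(pred, "SlidePrediction")) pred@P else as.numeric(pred)
  stopifnot(length(P) == 3L)
  srhClasses()[which.max(P)]
}

## 1-D linear interpolation matrix from grid anchors to pixel rows/cols.
## Anchor pixel of patch i (1-based grid index) is the 0-based pixel
## (i - 1) * step + window %/% 2; edges are clamped.
interpMatrix <- function(n_pix, n_grid, step, window, method) {
  anchor0 <- window %/% 2L
  g <- ((seq_len(n_pix) - 1L) - anchor0) / step + 1
  g[g < 1] <- 1
  g[g > n_grid] <- n_grid
  M <- matrix(0, n_pix, n_grid)
  if (method == "nearest") {
    i0 <- pmin(pmax(round(g), 1L), n_grid)
    M[cbind(seq_len(n_pix), i0)] <- 1
  } else {
    i0 <- pmin(floor(g), n_grid - 1L)
    if (n_grid == 1L) i0 <- rep(1L, n_pix)
    t <- g - i0
    M[cbind(seq_len(n_pix), i0)] <- 1 - t
    if (n_grid > 1L) M[cbind(seq_len(n_pix), i0 + 1L)] <-
        M[cbind(seq_len(n_pix), i0 + 1L)] + t
  }
  M
}

#' Interpolate patch predictions into a full-resolution probability heatmap
#'
#' Each class channel is interpolated independently from the nY x nX patch
#' grid (values anchored at patch centers, edges extended by clamping) to
#' the slide resolution, then the three channels are renormalized pixel-wise
#' to the simplex.
#'
#' @param patch_preds a [PatchPredictions-class].
#' @param slide_dim integer(2), slide (height, width) in pixels.
#' @param grid the test [PatchGrid-class] the predictions came from; its
#'   dimensions must match `patch_preds`.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return A [ProbabilityHeatmap-class].
#' @export
probabilityHeatmap <- function(patch_preds, slide_dim, grid,
                               method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  stopifnot(is(patch_preds, "PatchPredictions"), is(grid, "PatchGrid"))
  d <- dim(patch_preds@probs)
  if (d[1] != grid@nY || d[2] != grid@nX)
    stop("patch grid (", grid@nY, " x ", grid@nX,
         ") does not match predictions (", d[1], " x ", d[2], ")",
         call. = FALSE)
  h <- slide_dim[1]; w <- slide_dim[2]
  My <- interpMatrix(h, grid@nY, grid@stepPx, grid@windowPx, method)
  Mx <- interpMatrix(w, grid@nX, grid@stepPx, grid@windowPx, method)
  map <- array(0, c(h, w, 3L))
  for (c in 1:3)
    map[, , c] <- My %*% patch_preds@probs[, , c] %*% t(Mx)
  s <- map[, , 1] + map[, , 2] + map[, , 3]
  for (c in 1:3) map[, , c] <- map[, , c] / s
  new("ProbabilityHeatmap", map = clip01(map), method = method,
      gridDim = c(grid@nY, grid@nX))
}

#' Overlay a probability heatmap on the SRH image
#'
#' RGB color coding red = tumor, green = non-tumor, blue = low quality:
#' `out = (1 - alpha) * image + alpha * heatmap`, clipped to \[0, 1\].
#'
#' @param image an [SRHImage-class].
#' @param hm a [ProbabilityHeatmap-class] of matching dimensions.
#' @param alpha overlay transparency in \[0, 1\].
#' @return An [SRHImage-class] with the rendered overlay.
#' @export
overlayHeatmap <- function(image, hm, alpha = 0.5) {
  stopifnot(is(image, "SRHImage"), is(hm, "ProbabilityHeatmap"),
            alpha >= 0, alpha <= 1)
  if (!identical(dim(image@rgb), dim(hm@map)))
    stop("image and heatmap dimensions differ", call. = FALSE)
  out <- clip01((1 - alpha) * image@rgb + alpha * hm@map)
  srhImage(out, provenance = c(image@provenance,
                               list(overlay_alpha = alpha)),
           regionMask = image@regionMask)
}

#' Fraction of heatmap pixels whose argmax matches the region mask
#'
#' Quantifies heatmap segmentation quality on synthetic ground truth. Pixels
#' within half a patch (`window/2` px, Euclidean) of a region boundary are
#' excluded — the interpolation blur zone where no hard assignment is
#' meaningful. Argmax ties break by the canonical priority
#' (tumor > non-tumor > low quality).
#'
#' @param hm a [ProbabilityHeatmap-class].
#' @param region_mask integer matrix of class codes (0/1/2), same size.
#' @param exclude_px boundary exclusion radius, default 150.
#' @return Accuracy in \[0, 1\]; `NaN` if the exclusion zone covers
#'   everything.
#' @export
heatmapRegionAccuracy <- function(hm, region_mask, exclude_px = 150) {
  stopifnot(is(hm, "ProbabilityHeatmap"))
  d <- dim(hm@map)
  if (!identical(dim(region_mask), d[1:2]))
    stop("region mask dimensions do not match the heatmap", call. = FALSE)
  m <- matrix(hm@map, d[1] * d[2], 3L)
  argmax <- max.col(m, ties.method = "first") - 1L
  classes_present <- sort(unique(as.vector(region_mask)))
  if (length(classes_present) == 1L) {
    keep <- rep(TRUE, length(region_mask))
  } else {
    keep <- rep(FALSE, length(region_mask))
    for (cc in classes_present) {
      own <- region_mask == cc
      dmap <- EBImage::imageData(EBImage::distmap(arrayToEb(own * 1)))
      dmap <- t(dmap)   # back to [row, col]
      keep <- keep | (as.vector(own) & as.vector(dmap > exclude_px))
    }
  }
  if (!any(keep)) return(NaN)
  mean(argmax[keep] == as.vector(region_mask)[keep])
}

#' Classify one whole slide end to end
#'
#' Builds the non-overlapping test grid, pools each 300 px window to the
#' model input size, predicts every patch, and aggregates with low-quality
#' exclusion.
#'
#' @param model a trained [SRHModel-class].
#' @param image an [SRHImage-class].
#' @param step_px,window_px test grid geometry (defaults 300/300: disjoint
#'   windows).
#' @return List with `prediction` ([SlidePrediction-class]), `patches`
#'   ([PatchPredictions-class]) and `grid` ([PatchGrid-class]).
#' @export
classifySlide <- function(model, image, step_px = 300L, window_px = 300L) {
  d <- dim(image@rgb)
  grid <- patchGrid(d[2], d[1], step_px = step_px, window_px = window_px)
  x <- patchTensor(image, grid, out_px = model@config$input_px)
  probs <- predictPatches(model, x)
  pp <- patchPredictions(probs, grid)
  list(prediction = aggregateSlide(pp), patches = pp, grid = grid)
}

#' Write a slide report as JSON
#'
#' Per-class aggregated probabilities, final class, exclusion counts and the
#' per-patch probability grid.
#'
#' @param pred a [SlidePrediction-class].
#' @param path output JSON path.
#' @export
writeSlideReport <- function(pred, path) {
  stopifnot(is(pred, "SlidePrediction"))
  rep <- list(P = as.list(pred@P), final_class = pred@finalClass,
              n_patches_total = pred@nTotal,
              n_excluded_low_quality = pred@nExcluded,
              patch_grid = pred@patches@probs)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
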