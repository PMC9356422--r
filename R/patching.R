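## Sliding-window patch geometry and labeled patch extraction. Training uses
## overlapping 300 px windows with a 100 px step; whole-slide testing uses a
## 300 px step so windows tile the slide with no overlap. Right/bottom
## remainders smaller than one window are discarded (floor formula).

#' Build a sliding-window patch grid
#'
#' Window origins are 0-based top-left corners of half-open windows
#' `[x, x + window) x [y, y + window)`; counts follow
#' `floor((size - window) / step) + 1` per axis. With `step_px = window_px`
#' the windows are pairwise disjoint (whole-slide testing); `step_px = 100`
#' gives the overlapping training grid.
#'
#' @param width_px,height_px slide dimensions; each at least `window_px`.
#' @param step_px window step in both directions (100 training, 300 testing).
#' @param window_px window side length, default 300.
#' @return A [PatchGrid-class] with origins in row-major order
#'   (y outer, x inner).
#' @export
#' @examples
#' patchGrid(3600, 3900, step_px = 300)  # 12 x 13 windows
patchGrid <- function(width_px, height_px, step_px = 300L,
                      window_px = 300L) {
  stopifnot(step_px >= 1L, window_px >= 1L)
  if (width_px < window_px || height_px < window_px)
    stop("image (", width_px, " x ", height_px, ") is smaller than one ",
         window_px, " x ", window_px, " px window", call. = FALSE)
  nx <- floor((width_px - window_px) / step_px) + 1L
  ny <- floor((height_px - window_px) / step_px) + 1L
  ox <- as.integer((seq_len(nx) - 1L) * step_px)
  oy <- as.integer((seq_len(ny) - 1L) * step_px)
  origins <- data.frame(x = rep(ox, times = ny), y = rep(oy, each = nx))
  new("PatchGrid", windowPx = as.integer(window_px),
      stepPx = as.integer(step_px), nX = as.integer(nx), nY = as.integer(ny),
      origins = origins)
}

assertGridFits <- function(image_dim, grid) {
  w <- image_dim[2]; h <- image_dim[1]
  o <- grid@origins
  if (max(o$x) + grid@windowPx > w || max(o$y) + grid@windowPx > h)
    stop("patch grid does not fit the image (", w, " x ", h, " px)",
         call. = FALSE)
}

#' Extract labeled patches from a slide
#'
#' One patch per grid origin, in row-major order (y outer, x inner); pixel
#' data are copied. The patch label is inherited from the slide-level
#' annotation (whole images are annotated; per-patch ground truth exists
#' only synthetically via the region mask and is used for diagnostics only).
#'
#' @param image an [SRHImage-class].
#' @param grid a [PatchGrid-class] built for this image's dimensions.
#' @param label optional class label attached to every patch.
#' @param slide_id optional identifier recorded in each patch.
#' @return List of patches; each has `pixels` (window x window x 3), `label`,
#'   `slide_id` and grid position `i` (x), `j` (y), 1-based.
#' @export
extractPatches <- function(image, grid, label = NULL, slide_id = NA) {
  stopifnot(is(image, "SRHImage"), is(grid, "PatchGrid"))
  if (!is.null(label)) assertClassLabel(label)
  rgb <- image@rgb
  assertGridFits(dim(rgb), grid)
  w <- grid@windowPx
  o <- grid@origins
  lapply(seq_len(nrow(o)), function(k) {
    xs <- o$x[k] + seq_len(w)
    ys <- o$y[k] + seq_len(w)
    list(pixels = rgb[ys, xs, , drop = FALSE],
         label = label, slide_id = slide_id,
         i = as.integer(o$x[k] %/% grid@stepPx) + 1L,
         j = as.integer(o$y[k] %/% grid@stepPx) + 1L)
  })
}

## Mean-pool one window x window x 3 patch to out_px (window must be a
## multiple of out_px). Used to feed the desk-profile CNN.
poolPatch <- function(px, out_px) {
  w <- dim(px)[1]
  if (w == out_px) return(px)
  if (w %% out_px != 0)
    stop("window (", w, ") must be a multiple of the model input (",
         out_px, ")", call. = FALSE)
  f <- w %/% out_px
  dim(px) <- c(f, out_px, f * out_px * 3L)
  p1 <- colMeans(px)                      # (out, f, out, 3)
  dim(p1) <- c(out_px, f, out_px * 3L)
  p2 <- colMeans(aperm(p1, c(2, 1, 3)))   # (out, out, 3)
  dim(p2) <- c(out_px, out_px, 3L)
  p2
}

#' Extract a pooled patch tensor for CNN input
#'
#' Extracts every grid window and mean-pools it to the model input size in
#' one pass, avoiding full-resolution patch lists.
#'
#' @param image an [SRHImage-class].
#' @param grid a [PatchGrid-class] for this image.
#' @param out_px model input side; must divide the window size.
#' @return Array `out_px x out_px x 3 x n_patches`, patches in row-major
#'   grid order.
#' @export
patchTensor <- function(image, grid, out_px = 25L) {
  stopifnot(is(image, "SRHImage"), is(grid, "PatchGrid"))
  rgb <- image@rgb
  assertGridFits(dim(rgb), grid)
  w <- grid@windowPx
  o <- grid@origins
  out <- array(0, c(out_px, out_px, 3L, nrow(o)))
  for (k in seq_len(nrow(o))) {
    xs <- o$x[k] + seq_len(w)
    ys <- o$y[k] + seq_len(w)
    out[, , , k] <- poolPatch(rgb[ys, xs, , drop = FALSE], out_px)
  }
  out
}

#' Inverse-class-frequency loss weights
#'
#' Class imbalance is handled by weighting the categorical cross-entropy
#' with inverse class frequencies: `w_c = (N / n_c)`, normalized so the mean
#' weight over the three classes is exactly 1.
#'
#' @param counts named integer vector of training-patch counts per class
#'   (names from `srhClasses()`), all positive.
#' @return Named numeric(3) of weights in canonical class order, mean 1.
#' @export
#' @examples
#' classWeights(c(tumor = 10, non_tumor = 30, low_quality = 60))
classWeights <- function(counts) {
  cls <- srhClasses()
  if (is.null(names(counts))) names(counts) <- cls[seq_along(counts)]
  if (!setequal(names(counts), cls))
    stop("counts must be named with the three classes", call. = FALSE)
  counts <- counts[cls]
  zero <- cls[counts <= 0]
  if (length(zero))
    stop("class '", zero[1], "' has no training patches; ",
         "inverse-frequency weights are undefined", call. = FALSE)
  inv <- sum(counts) / counts
  w <- inv / mean(inv)
  stats::setNames(as.numeric(w), cls)
}

#' Slide-level stratified train/validation split
#'
#' Splits by slide (all patches of one slide fall on one side, avoiding
#' leakage between overlapping patches), stratified by class, seeded.
#'
#' @param slide_labels named character vector: slide id -> class label, or a
#'   data.frame with columns `slide_id`, `label` (one row per slide).
#' @param fraction training fraction, default 0.9.
#' @param seed integer seed.
#' @return List with character vectors `train` and `val` of slide ids. A
#'   warning (not an error) is raised if a class is absent from either side.
#' @export
splitTrainVal <- function(slide_labels, fraction = 0.9, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  if (is.data.frame(slide_labels)) {
    lab <- stats::setNames(slide_labels$label, slide_labels$slide_id)
  } else lab <- slide_labels
  if (length(lab) < 2L) stop("need at least 2 slides to split", call. = FALSE)
  ids <- names(lab)
  val <- withSeed(seed, {
    unlist(lapply(split(ids, lab), function(g) {
      n_val <- round((1 - fraction) * length(g))
      if (n_val >= length(g)) n_val <- length(g) - 1L
      sample(g, n_val)
    }), use.names = FALSE)
  })
  train <- setdiff(ids, val)
  missing_val <- setdiff(unique(lab), unique(lab[val]))
  missing_train <- setdiff(unique(lab), unique(lab[train]))
  if (length(missing_val))
    warning("class(es) absent from the validation split at fraction ",
            fraction, ": ", paste(missing_val, collapse = ", "),
            call. = FALSE)
  if (length(missing_train))
    warning("class(es) absent from the training split: ",
            paste(missing_train, collapse = ", "), call. = FALSE)
  list(train = train, val = val)
}
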