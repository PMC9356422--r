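## Image and annotation I/O. PNG (8-bit RGB) for rendered slides, paired
## 16-bit grayscale TIFF for raw Raman channels (suffixes _2845 / _2940),
## CSV for annotations. Internal representation is float in [0, 1]; bit
## depth applies only at the file boundary.

channelPairPaths <- function(prefix) {
  prefix <- sub("(_2845|_2940)?\\.tiff?$", "", prefix)
  list(ch2845 = paste0(prefix, "_2845.tif"),
       ch2940 = paste0(prefix, "_2940.tif"))
}

## EBImage stores images [x, y, c]; the package uses [row = y, col = x, c].
ebToArray <- function(img) {
  a <- EBImage::imageData(img)
  if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
}
arrayToEb <- function(a) {
  if (length(dim(a)) == 2L)
    EBImage::Image(t(a))
  else
    EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
}

#' Write a rendered SRH image as 8-bit RGB PNG
#'
#' @param image an [SRHImage-class].
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
writeSlide <- function(image, path) {
  stopifnot(is(image, "SRHImage"))
  EBImage::writeImage(arrayToEb(image@rgb), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' Write a Raman channel pair as 16-bit grayscale TIFFs
#'
#' Files are written as `<prefix>_2845.tif` and `<prefix>_2940.tif`.
#'
#' @param pair a [RamanPair-class] (intensities in \[0, 1\]).
#' @param prefix path prefix (without channel suffix).
#' @return Named list of the two file paths, invisibly.
#' @export
writeChannelPair <- function(pair, prefix) {
  stopifnot(is(pair, "RamanPair"))
  p <- channelPairPaths(prefix)
  EBImage::writeImage(arrayToEb(clip01(pair@ch2845)), p$ch2845,
                      type = "tiff", bits.per.sample = 16L)
  EBImage::writeImage(arrayToEb(clip01(pair@ch2940)), p$ch2940,
                      type = "tiff", bits.per.sample = 16L)
  invisible(p)
}

#' Read a Raman channel pair from 16-bit TIFFs
#'
#' @param prefix path prefix, or the path of either channel file.
#' @return A [RamanPair-class].
#' @export
readChannelPair <- function(prefix) {
  p <- channelPairPaths(prefix)
  for (f in unlist(p))
    if (!file.exists(f))
      stop("channel file not found: ", f, call. = FALSE)
  a <- ebToArray(EBImage::readImage(p$ch2845))
  b <- ebToArray(EBImage::readImage(p$ch2940))
  if (length(dim(a)) != 2L || length(dim(b)) != 2L)
    stop("expected 1-channel grayscale TIFFs for the Raman pair: ",
         p$ch2845, call. = FALSE)
  ramanPair(a, b)
}

#' Read a whole-slide SRH image
#'
#' Reads either a 3-channel RGB file directly, or a `_2845`/`_2940` grayscale
#' TIFF pair (given either channel path or the common prefix), in which case
#' the virtual H&E image is formed with [buildSRH()].
#'
#' @param path RGB image path, a channel-pair path, or a pair prefix.
#' @param gains,stains forwarded to [buildSRH()] for channel pairs.
#' @return An [SRHImage-class].
#' @export
readSlide <- function(path, gains = c(1, 1), stains = srhStainVectors()) {
  is_pair <- grepl("(_2845|_2940)\\.tiff?$", path) ||
    (!file.exists(path) && file.exists(channelPairPaths(path)$ch2845))
  if (is_pair)
    return(buildSRH(readChannelPair(path), gains = gains, stains = stains))
  if (!file.exists(path))
    stop("cannot read slide, file not found: ", path, call. = FALSE)
  a <- ebToArray(EBImage::readImage(path))
  nc <- if (length(dim(a)) == 2L) 1L else dim(a)[3]
  if (nc < 3L)
    stop("expected a 3-channel RGB image but found ", nc, " channel(s): ",
         path, call. = FALSE)
  if (nc > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  srhImage(clip01(a), provenance = list(source = path))
}

#' Read / write per-image class annotations
#'
#' Annotation CSVs have columns `path,label` with labels in
#' `tumor`, `non_tumor`, `low_quality`.
#'
#' @param path CSV path.
#' @return data.frame with columns `path`, `label`.
#' @export
readAnnotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("path", "label") %in% names(df)))
    stop("annotation CSV must have columns 'path' and 'label': ", path,
         call. = FALSE)
  bad <- setdiff(unique(df$label), srhClasses())
  if (length(bad))
    stop("unknown labels in ", path, ": ", paste(bad, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname readAnnotations
#' @param annotations data.frame with columns `path`, `label`.
#' @export
writeAnnotations <- function(annotations, path) {
  stopifnot(all(c("path", "label") %in% names(annotations)))
  utils::write.csv(annotations[, c("path", "label")], path, row.names = FALSE)
  invisible(path)
}

#' Write a region mask as a paletted single-channel PNG
#'
#' Class codes 0 = tumor, 1 = non-tumor, 2 = low quality are stored as
#' gray levels 0, 1, 2 (of 255).
#'
#' @param mask integer matrix of class codes.
#' @param path output PNG path.
#' @export
writeRegionMask <- function(mask, path) {
  EBImage::writeImage(arrayToEb(mask / 255), path, type = "png",
                      bits.per.sample = 8L)
  invisible(path)
}

#' @rdname writeRegionMask
#' @export
readRegionMask <- function(path) {
  a <- ebToArray(EBImage::readImage(path))
  if (length(dim(a)) == 3L) a <- a[, , 1]
  m <- round(a * 255)
  storage.mode(m) <- "integer"
  m
}
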