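## Internal helpers shared across modules.

#' The three diagnostic classes, in canonical order
#'
#' Class order is fixed throughout the package: tumor, non-tumor, low quality.
#' Probability vectors, confusion tables and heatmap channels all follow it
#' (red = tumor, green = non-tumor, blue = low quality).
#'
#' @return Character vector of length 3.
#' @export
#' @examples
#' srhClasses()
srhClasses <- function() c("tumor", "non_tumor", "low_quality")

`%||%` <- function(x, y) if (is.null(x)) y else x

## Run code under a temporary RNG state; restores .Random.seed afterwards so
## generators are bit-reproducible from (args, seed) without disturbing the
## caller's stream.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

assertClassLabel <- function(label) {
  if (!(is.character(label) && length(label) == 1L && label %in% srhClasses()))
    stop("'label' must be one of ", paste(srhClasses(), collapse = ", "),
         call. = FALSE)
  label
}

## Stable content hash of an R object (used to stamp experiment outputs).
objectHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, connection = NULL, version = 3L), f)
  unname(tools::md5sum(f))
}

## round-half-up at `digits` decimals, matching how percentages are printed
## in clinical tables (base round() is half-to-even).
roundHalfUp <- function(x, digits = 1L) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
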