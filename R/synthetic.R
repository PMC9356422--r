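## Synthetic SRH simulator: two-channel virtual slides with known class
## labels, mixed-region slides for heatmap ground truth, and cohorts with the
## study's multi-area specimen structure (three random areas A/B/C per
## specimen sharing one texture-parameter draw).

#' Texture parameters for a synthetic slide class
#'
#' The minimal texture model expressing the cellular and nuclear morphology
#' the classifier relies on: nuclei are dark-center ellipses with elevated
#' protein-channel (2940 cm-1) rims; non-tumor tissue carries oriented
#' low-frequency fiber texture in the lipid channel; low-quality areas are
#' near-blank or noise-dominated. Pixels are treated as unitless; densities
#' are expressed per patch area (300 x 300 px).
#'
#' @param nucleus_density expected nuclei per 300 x 300 px patch area.
#' @param nucleus_radius_mean_px,nucleus_radius_sd_px ellipse semi-axis mean
#'   and spread in pixels.
#' @param pleomorphism coefficient of variation of the per-nucleus size
#'   factor (0 = monomorphic).
#' @param fiber_strength amplitude of the oriented low-frequency lipid
#'   texture, in intensity units.
#' @param background_lipid,background_protein baseline channel intensities in
#'   \[0, 1\].
#' @param noise_sd additive Gaussian noise level.
#' @param blank_fraction fraction of the slide area left acellular.
#' @return A named list of class `"TextureParams"`.
#' @export
#' @examples
#' textureParams(nucleus_density = 150)
textureParams <- function(nucleus_density = 150,
                          nucleus_radius_mean_px = 6,
                          nucleus_radius_sd_px = 1.2,
                          pleomorphism = 0.35,
                          fiber_strength = 0,
                          background_lipid = 0.15,
                          background_protein = 0.30,
                          noise_sd = 0.02,
                          blank_fraction = 0) {
  p <- list(nucleus_density = nucleus_density,
            nucleus_radius_mean_px = nucleus_radius_mean_px,
            nucleus_radius_sd_px = nucleus_radius_sd_px,
            pleomorphism = pleomorphism,
            fiber_strength = fiber_strength,
            background_lipid = background_lipid,
            background_protein = background_protein,
            noise_sd = noise_sd,
            blank_fraction = blank_fraction)
  stopifnot(nucleus_density >= 0, nucleus_radius_mean_px > 0,
            nucleus_radius_sd_px >= 0, pleomorphism >= 0)
  for (f in c("fiber_strength", "background_lipid", "background_protein",
              "noise_sd", "blank_fraction"))
    if (p[[f]] < 0 || p[[f]] > 1)
      stop("'", f, "' must lie in [0, 1]", call. = FALSE)
  class(p) <- c("TextureParams", "list")
  p
}

#' Default texture parameters per diagnostic class
#'
#' Easy-mode class archetypes: hypercellular pleomorphic tumor, sparse
#' fibrous non-tumor, and low quality in one of two sub-modes (`"blank"`,
#' acellular near-white field; `"artifact"`, structureless noise).
#'
#' @param label one of `srhClasses()`.
#' @param lq_mode low-quality sub-mode, `"blank"` or `"artifact"`.
#' @return A `TextureParams` list.
#' @export
defaultTextureParams <- function(label, lq_mode = c("blank", "artifact")) {
  assertClassLabel(label)
  lq_mode <- match.arg(lq_mode)
  switch(label,
    tumor = textureParams(nucleus_density = 150, nucleus_radius_mean_px = 6,
                          nucleus_radius_sd_px = 1.2, pleomorphism = 0.35,
                          fiber_strength = 0, background_lipid = 0.15,
                          background_protein = 0.30, noise_sd = 0.02),
    non_tumor = textureParams(nucleus_density = 15,
                              nucleus_radius_mean_px = 5,
                              nucleus_radius_sd_px = 1.0, pleomorphism = 0.10,
                              fiber_strength = 0.15, background_lipid = 0.35,
                              background_protein = 0.25, noise_sd = 0.02),
    low_quality = if (lq_mode == "blank")
      textureParams(nucleus_density = 0, pleomorphism = 0,
                    fiber_strength = 0, background_lipid = 0.05,
                    background_protein = 0.05, noise_sd = 0.01,
                    blank_fraction = 1)
    else
      textureParams(nucleus_density = 0, pleomorphism = 0,
                    fiber_strength = 0, background_lipid = 0.20,
                    background_protein = 0.20, noise_sd = 0.15,
                    blank_fraction = 0))
}

#' Draw per-specimen texture parameters
#'
#' Easy mode jitters the class archetypes narrowly (well-separated classes);
#' hard mode widens and overlaps the distributions. For low quality the
#' sub-mode is sampled 50/50 blank/artifact. Uses the current RNG stream.
#'
#' @param label one of `srhClasses()`.
#' @param difficulty `"easy"` or `"hard"`.
#' @return A `TextureParams` list.
#' @export
drawTextureParams <- function(label, difficulty = c("easy", "hard")) {
  assertClassLabel(label)
  difficulty <- match.arg(difficulty)
  if (label == "low_quality") {
    mode <- sample(c("blank", "artifact"), 1L)
    p <- defaultTextureParams(label, lq_mode = mode)
    if (difficulty == "hard")
      p$noise_sd <- clip01(p$noise_sd * exp(stats::rnorm(1, 0, 0.4)))
    return(p)
  }
  base <- defaultTextureParams(label)
  jd <- if (difficulty == "easy") 0.08 else 0.45   # density/radius log-jitter
  jb <- if (difficulty == "easy") 0.01 else 0.05   # background jitter
  if (difficulty == "hard") {
    # pull class means together so pixel statistics overlap
    if (label == "tumor") {
      base$nucleus_density <- 70
      base$background_lipid <- 0.22; base$background_protein <- 0.27
    } else {
      base$nucleus_density <- 30
      base$background_lipid <- 0.28; base$background_protein <- 0.26
      base$fiber_strength <- 0.08
    }
    base$noise_sd <- 0.05
  }
  base$nucleus_density <- base$nucleus_density * exp(stats::rnorm(1, 0, jd))
  base$nucleus_radius_mean_px <-
    base$nucleus_radius_mean_px * exp(stats::rnorm(1, 0, jd / 2))
  base$background_lipid <- clip01(base$background_lipid +
                                    stats::rnorm(1, 0, jb))
  base$background_protein <- clip01(base$background_protein +
                                      stats::rnorm(1, 0, jb))
  base
}

## Render both channels for one homogeneous region. Runs inside an
## established RNG state (callers wrap in withSeed).
renderChannels <- function(label, params, width_px, height_px) {
  h <- height_px; w <- width_px
  ch_l <- matrix(params$background_lipid, h, w)
  ch_p <- matrix(params$background_protein, h, w)

  ## acellular blank band (rows from a random edge)
  bf <- params$blank_fraction
  blank_rows <- integer(0)
  if (bf >= 1) {
    blank_rows <- seq_len(h)
  } else if (bf > 0) {
    nb <- round(h * bf)
    blank_rows <- if (stats::runif(1) < 0.5) seq_len(nb)
                  else seq.int(h - nb + 1L, h)
  }
  active_rows <- setdiff(seq_len(h), blank_rows)

  ## oriented low-frequency fiber texture in the lipid channel (zero-mean)
  if (params$fiber_strength > 0 && length(active_rows)) {
    theta <- stats::runif(1, 0, pi)
    lambda <- stats::runif(1, 60, 140)
    phase <- stats::runif(1, 0, 2 * pi)
    xs <- matrix(seq_len(w), h, w, byrow = TRUE)
    ys <- matrix(seq_len(h), h, w)
    field <- sin(2 * pi * (xs * cos(theta) + ys * sin(theta)) / lambda + phase)
    if (length(blank_rows)) field[blank_rows, ] <- 0
    ch_l <- ch_l + 0.5 * params$fiber_strength * field
  }

  ## nuclei: dark-center ellipses with elevated protein rims; nuclei also
  ## displace lipid slightly (cytoplasm exclusion)
  if (params$nucleus_density > 0 && length(active_rows)) {
    active_frac <- length(active_rows) / h
    n_exp <- params$nucleus_density * (w * h * active_frac) / (300 * 300)
    n <- stats::rpois(1, n_exp)
    if (n > 0) {
      cx <- stats::runif(n, 1, w)
      cy <- stats::runif(n, min(active_rows), max(active_rows))
      size <- exp(stats::rnorm(n, 0, params$pleomorphism))
      a <- pmax(1.5, size * params$nucleus_radius_mean_px +
                  stats::rnorm(n, 0, params$nucleus_radius_sd_px))
      b <- pmax(1.5, size * params$nucleus_radius_mean_px +
                  stats::rnorm(n, 0, params$nucleus_radius_sd_px))
      ang <- stats::runif(n, 0, pi)
      rim_amp <- 0.45; center_amp <- 0.18; lipid_dip <- 0.08
      for (i in seq_len(n)) {
        r <- ceiling(max(a[i], b[i])) + 1L
        x0 <- max(1L, floor(cx[i]) - r); x1 <- min(w, ceiling(cx[i]) + r)
        y0 <- max(1L, floor(cy[i]) - r); y1 <- min(h, ceiling(cy[i]) + r)
        if (x1 < x0 || y1 < y0) next
        dx <- outer(rep(1, y1 - y0 + 1L), (x0:x1) - cx[i])
        dy <- outer((y0:y1) - cy[i], rep(1, x1 - x0 + 1L))
        u <- (dx * cos(ang[i]) + dy * sin(ang[i])) / a[i]
        v <- (-dx * sin(ang[i]) + dy * cos(ang[i])) / b[i]
        e <- u * u + v * v
        inside <- e <= 1
        rim <- inside & e > 0.5
        core <- e <= 0.5
        blk <- ch_p[y0:y1, x0:x1]
        blk[rim] <- blk[rim] + rim_amp
        blk[core] <- blk[core] + center_amp
        ch_p[y0:y1, x0:x1] <- blk
        blk <- ch_l[y0:y1, x0:x1]
        blk[inside] <- blk[inside] - lipid_dip
        ch_l[y0:y1, x0:x1] <- blk
      }
    }
  }

  if (length(blank_rows) && bf < 1) {
    ch_l[blank_rows, ] <- params$background_lipid
    ch_p[blank_rows, ] <- params$background_protein
  }

  if (params$noise_sd > 0) {
    ch_l <- ch_l + matrix(stats::rnorm(w * h, 0, params$noise_sd), h, w)
    ch_p <- ch_p + matrix(stats::rnorm(w * h, 0, params$noise_sd), h, w)
  }
  list(ch2845 = clip01(ch_l), ch2940 = clip01(ch_p))
}

assertSlideDims <- function(width_px, height_px) {
  if (width_px < 300 || height_px < 300)
    stop("slide dimensions must be at least 300 x 300 px ",
         "(one classification patch); got ", width_px, " x ", height_px,
         call. = FALSE)
}

#' Generate a homogeneous synthetic SRH slide
#'
#' Renders the two Raman channels for one class: tumor slides are
#' hypercellular with pleomorphic nuclei concentrated in the protein channel;
#' non-tumor slides are sparse with fiber texture in the lipid channel;
#' low-quality slides are near-blank or noise-dominated. Bit-reproducible
#' from `(label, params, dimensions, seed)`.
#'
#' @param label one of `srhClasses()`.
#' @param params a `TextureParams` list; `NULL` uses
#'   [defaultTextureParams()] for the label.
#' @param width_px,height_px slide dimensions, each at least 300 px.
#' @param seed integer seed.
#' @return A [SyntheticSlide-class].
#' @export
#' @examples
#' s <- generateSlide("tumor", width_px = 300, height_px = 300, seed = 1)
generateSlide <- function(label, params = NULL, width_px = 1200,
                          height_px = 1200, seed = 1L) {
  assertClassLabel(label)
  assertSlideDims(width_px, height_px)
  if (is.null(params)) params <- defaultTextureParams(label)
  ch <- withSeed(seed, renderChannels(label, params, width_px, height_px))
  new("SyntheticSlide", ch2845 = ch$ch2845, ch2940 = ch$ch2940,
      label = label, regionMask = NULL, seed = as.numeric(seed),
      params = list(params))
}

#' Generate a mixed-region synthetic slide
#'
#' Composes rectangular regions of different classes into one slide; the
#' per-pixel region mask records the layout exactly and is the ground truth
#' for heatmap evaluation. Regions must tile the slide without overlap.
#' Each region's texture is rendered with seed `seed + region_index - 1`, so
#' a single full-slide region reproduces [generateSlide()] exactly.
#'
#' @param layout list of regions, each a list with 0-based `x0`, `y0` and
#'   `w`, `h` in pixels plus `class`.
#' @param params named list mapping class to `TextureParams` (missing classes
#'   use defaults).
#' @param width_px,height_px slide dimensions.
#' @param seed integer seed.
#' @return A [SyntheticSlide-class] whose label is the modal class of the
#'   mask.
#' @export
#' @examples
#' lay <- list(list(x0 = 0, y0 = 0, w = 300, h = 300, class = "tumor"))
#' s <- generateMixedSlide(lay, width_px = 300, height_px = 300, seed = 1)
generateMixedSlide <- function(layout, params = list(), width_px = 1200,
                               height_px = 1200, seed = 1L) {
  assertSlideDims(width_px, height_px)
  stopifnot(length(layout) >= 1L)
  cover <- matrix(0L, height_px, width_px)
  for (r in layout) {
    assertClassLabel(r$class)
    if (r$x0 < 0 || r$y0 < 0 || r$x0 + r$w > width_px ||
        r$y0 + r$h > height_px)
      stop("region exceeds the slide bounds", call. = FALSE)
    cover[r$y0 + seq_len(r$h), r$x0 + seq_len(r$w)] <-
      cover[r$y0 + seq_len(r$h), r$x0 + seq_len(r$w)] + 1L
  }
  if (any(cover > 1L)) stop("regions overlap", call. = FALSE)
  if (any(cover == 0L)) stop("regions do not tile the slide", call. = FALSE)

  ch_l <- matrix(0, height_px, width_px)
  ch_p <- matrix(0, height_px, width_px)
  mask <- matrix(0L, height_px, width_px)
  codes <- stats::setNames(0:2, srhClasses())
  for (i in seq_along(layout)) {
    r <- layout[[i]]
    p <- params[[r$class]] %||% defaultTextureParams(r$class)
    ch <- withSeed(seed + i - 1L, renderChannels(r$class, p, r$w, r$h))
    ry <- r$y0 + seq_len(r$h); rx <- r$x0 + seq_len(r$w)
    ch_l[ry, rx] <- ch$ch2845
    ch_p[ry, rx] <- ch$ch2940
    mask[ry, rx] <- codes[[r$class]]
  }
  label <- srhClasses()[which.max(tabulate(mask + 1L, 3L))]
  new("SyntheticSlide", ch2845 = ch_l, ch2940 = ch_p, label = label,
      regionMask = mask, seed = as.numeric(seed), params = params)
}

## Largest-remainder allocation of specimen labels to match the class prior,
## with a floor of one specimen per nonzero-prior class (when room allows) so
## that rare classes are represented even in small cohorts.
allocateLabels <- function(n, class_mix) {
  classes <- srhClasses()
  nz <- which(class_mix > 0)
  counts <- integer(3)
  if (n >= length(nz)) counts[nz] <- 1L
  rem <- n - sum(counts)
  if (rem > 0) {
    ideal <- class_mix / sum(class_mix) * n
    extra <- pmax(ideal - counts, 0)
    fl <- floor(extra)
    fl <- pmin(fl, rem)  # guard tiny n
    left <- rem - sum(fl)
    frac <- extra - floor(extra)
    ord <- order(frac, ideal, decreasing = TRUE)
    add <- integer(3)
    for (i in ord) {
      if (left <= 0) break
      add[i] <- 1L; left <- left - 1L
    }
    counts <- counts + fl + add
    while (sum(counts) > n) {  # safety, should not trigger
      i <- which.max(counts); counts[i] <- counts[i] - 1L
    }
  }
  rep(classes, counts)
}

setClassUnion("functionOrNULL", c("function", "NULL"))

#' Synthetic cohort of multi-area specimens
#'
#' A cohort of patients with one or more specimens each; every specimen is
#' scanned as three random areas (A, B, C) that share a single
#' texture-parameter draw and differ only in their placement/noise seeds —
#' the structure behind the internal-consistency (Cronbach's alpha) analysis.
#' Slides are materialized lazily with [cohortSlide()] to keep memory flat.
#'
#' @slot manifest data.frame: `patient_id`, `specimen_id`, `area`, `label`,
#'   `seed`, `path`.
#' @slot specimenParams list of `TextureParams`, one per specimen.
#' @slot classMix numeric(3) class prior.
#' @slot difficulty `"easy"` or `"hard"`.
#' @slot slidePx slide side length in pixels.
#' @slot seed cohort seed.
#' @export
setClass("SyntheticCohort",
  representation(manifest = "data.frame", specimenParams = "list",
                 classMix = "numeric", difficulty = "character",
                 slidePx = "numeric", seed = "numeric"))

setMethod("show", "SyntheticCohort", function(object) {
  m <- object@manifest
  cat(sprintf(
    "SyntheticCohort: %d patients, %d specimens x 3 areas = %d slides (%s mode, %d px, seed %d)\n",
    length(unique(m$patient_id)), length(unique(m$specimen_id)), nrow(m),
    object@difficulty, as.integer(object@slidePx), as.integer(object@seed)))
  print(table(m$label[m$area == "A"]))
})

#' Generate a synthetic specimen cohort
#'
#' Draws one class label and one texture-parameter set per specimen, then
#' assigns three area slides (A, B, C) per specimen with independent
#' rendering seeds. Labels are allocated to match `class_mix` by largest
#' remainder, with every nonzero-prior class receiving at least one specimen,
#' and are shuffled by the seed. Bit-reproducible from the arguments.
#'
#' @param n_patients number of patients (at least 1).
#' @param specimens_per_patient specimens per patient.
#' @param class_mix numeric(3) prior over (tumor, non-tumor, low quality);
#'   must sum to 1. Default mirrors a clinical ground-truth distribution
#'   (78, 19 and 3 percent).
#' @param difficulty `"easy"` (well-separated textures) or `"hard"`
#'   (overlapping).
#' @param seed integer cohort seed.
#' @param slide_px slide side length (default 1200, a 4 x 4 test-patch grid).
#' @return A [SyntheticCohort-class].
#' @export
#' @examples
#' co <- generateCohort(2, seed = 7)
#' cohortManifest(co)
generateCohort <- function(n_patients, specimens_per_patient = 1L,
                           class_mix = c(0.78, 0.19, 0.03),
                           difficulty = c("easy", "hard"), seed = 1L,
                           slide_px = 1200L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n_patients >= 1L, specimens_per_patient >= 1L)
  if (length(class_mix) != 3L || any(class_mix < 0) ||
      abs(sum(class_mix) - 1) > 1e-8)
    stop("'class_mix' must be 3 non-negative proportions summing to 1",
         call. = FALSE)
  n_spec <- n_patients * specimens_per_patient
  out <- withSeed(seed, {
    labels <- sample(allocateLabels(n_spec, class_mix))
    sp <- lapply(labels, drawTextureParams, difficulty = difficulty)
    seeds <- sample.int(.Machine$integer.max - 1L, n_spec * 3L)
    list(labels = labels, sp = sp, seeds = seeds)
  })
  manifest <- data.frame(
    patient_id = sprintf("P%03d", rep(rep(seq_len(n_patients),
                                          each = specimens_per_patient),
                                      each = 3L)),
    specimen_id = sprintf("S%03d", rep(seq_len(n_spec), each = 3L)),
    area = rep(c("A", "B", "C"), n_spec),
    label = rep(out$labels, each = 3L),
    seed = out$seeds,
    path = NA_character_,
    stringsAsFactors = FALSE)
  new("SyntheticCohort", manifest = manifest, specimenParams = out$sp,
      classMix = class_mix, difficulty = difficulty,
      slidePx = as.numeric(slide_px), seed = as.numeric(seed))
}

#' @rdname generateCohort
#' @param cohort a [SyntheticCohort-class].
#' @export
cohortManifest <- function(cohort) cohort@manifest

#' Materialize one cohort slide
#'
#' @param cohort a [SyntheticCohort-class].
#' @param i manifest row index.
#' @return A [SyntheticSlide-class].
#' @export
cohortSlide <- function(cohort, i) {
  m <- cohort@manifest
  stopifnot(i >= 1L, i <= nrow(m))
  spec <- as.integer(sub("^S", "", m$specimen_id[i]))
  generateSlide(m$label[i], params = cohort@specimenParams[[spec]],
                width_px = cohort@slidePx, height_px = cohort@slidePx,
                seed = m$seed[i])
}

#' Write a cohort to disk
#'
#' Writes each slide as a 16-bit grayscale TIFF channel pair
#' (`<id>_2845.tif`, `<id>_2940.tif`) plus the manifest CSV
#' (`patient_id,specimen_id,area,label,path,seed`).
#'
#' @param cohort a [SyntheticCohort-class].
#' @param dir output directory (created if needed).
#' @return The manifest data.frame (with paths), invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- cohort@manifest
  for (i in seq_len(nrow(m))) {
    prefix <- file.path(dir, paste0(m$specimen_id[i], "_", m$area[i]))
    writeChannelPair(cohortSlide(cohort, i), prefix)
    m$path[i] <- prefix
  }
  utils::write.csv(m[, c("patient_id", "specimen_id", "area", "label",
                         "path", "seed")],
                   file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(m)
}
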