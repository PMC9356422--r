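test_that("aggregation implements low-quality-exclusion averaging", {
  ## constant field
  m <- matrix(rep(c(0.8, 0.1, 0.1), each = 6), 6, 3)
  agg <- aggregateSlide(m)
  expect_equal(unname(slideProbs(agg)), c(0.8, 0.1, 0.1), tolerance = 1e-12)
  expect_identical(finalClass(agg), "tumor")
  expect_equal(agg@nExcluded, 0L)

  ## hand-computed exclusion: third patch is low-quality top-1
  m2 <- rbind(c(0.9, 0.05, 0.05), c(0.1, 0.8, 0.1), c(0.2, 0.2, 0.6))
  agg2 <- aggregateSlide(m2)
  expect_equal(agg2@nExcluded, 1L)
  expect_equal(unname(slideProbs(agg2)), c(0.5, 0.425, 0.075),
               tolerance = 1e-12)
  expect_identical(finalClass(agg2), "tumor")

  ## all patches excluded: the re-scan situation
  m3 <- matrix(rep(c(0.1, 0.2, 0.7), each = 4), 4, 3)
  agg3 <- aggregateSlide(m3)
  expect_equal(unname(slideProbs(agg3)), c(0, 0, 1))
  expect_identical(finalClass(agg3), "low_quality")
  expect_equal(agg3@nExcluded, 4L)

  expect_error(aggregateSlide(matrix(numeric(0), 0, 3)), "at least one|empty")
})

test_that("aggregation is permutation-invariant and exclusion-neutral", {
  set.seed(41)
  m <- rsimplex(20)
  a <- aggregateSlide(m)
  b <- aggregateSlide(m[sample(20), ])
  expect_equal(slideProbs(a), slideProbs(b), tolerance = 1e-12)

  ## excluded patches equal to the mean of the rest leave P unchanged
  rest <- rbind(c(0.5, 0.1, 0.4), c(0.1, 0.5, 0.4))
  mu <- colMeans(rest)                 # (0.3, 0.3, 0.4): top-1 low quality
  expect_equal(unname(which.max(mu)), 3L)
  with_lq <- rbind(rest, mu, mu, mu)
  expect_equal(slideProbs(aggregateSlide(with_lq)),
               slideProbs(aggregateSlide(rest)), tolerance = 1e-12)
  expect_equal(aggregateSlide(with_lq)@nExcluded, 3L)
})

test_that("binarization is argmax with the fixed tumor-first tie rule", {
  expect_identical(binarizeSlide(c(0.7, 0.2, 0.1)), "tumor")
  expect_identical(binarizeSlide(c(0.5, 0.5, 0.0)), "tumor")
  expect_identical(binarizeSlide(c(0.2, 0.4, 0.4)), "non_tumor")

  set.seed(12)
  m <- rsimplex(1000)
  for (i in 1:1000) {
    ## independent max scan with explicit priority
    best <- 1L
    for (j in 2:3) if (m[i, j] > m[i, best]) best <- j
    expect_identical(binarizeSlide(m[i, ]), srhClasses()[best])
  }
})

test_that("heatmaps preserve constants, anchor patch centers and the simplex", {
  grid <- patchGrid(600, 600, 300)
  ## constant grid
  const <- patchPredictions(matrix(rep(c(0.6, 0.3, 0.1), each = 4), 4, 3),
                            grid)
  hm <- probabilityHeatmap(const, c(600, 600), grid)
  expect_equal(max(abs(heatmapArray(hm)[, , 1] - 0.6)), 0, tolerance = 1e-12)

  ## varying 2x2 grid
  set.seed(3)
  probs <- rsimplex(4)
  pp <- patchPredictions(probs, grid)
  hm2 <- probabilityHeatmap(pp, c(600, 600), grid)
  a <- heatmapArray(hm2)
  ## anchor pixels carry their grid values (0-based anchor 150 -> index 151)
  g <- pp@probs
  for (c in 1:3) {
    expect_equal(a[151, 151, c], g[1, 1, c], tolerance = 1e-6)
    expect_equal(a[151, 451, c], g[1, 2, c], tolerance = 1e-6)
    expect_equal(a[451, 451, c], g[2, 2, c], tolerance = 1e-6)
  }
  ## bilinear midpoint: center pixel is the mean of the four grid values
  for (c in 1:3)
    expect_equal(a[301, 301, c], mean(g[, , c]), tolerance = 1e-6)
  ## pixel-wise simplex
  s <- a[, , 1] + a[, , 2] + a[, , 3]
  expect_lt(max(abs(s - 1)), 1e-6)

  ## nearest-neighbour alternative keeps blocky grid values
  hm3 <- probabilityHeatmap(pp, c(600, 600), grid, method = "nearest")
  expect_equal(heatmapArray(hm3)[1, 1, ], g[1, 1, ], tolerance = 1e-12)

  expect_error(probabilityHeatmap(const, c(600, 600),
                                  patchGrid(900, 900, 300)), "match")
})

test_that("overlays blend linearly and clip", {
  set.seed(9)
  rgb <- array(runif(2 * 2 * 3), c(2, 2, 3))
  img <- srhImage(rgb)
  map <- array(rep(c(1, 0, 0), each = 4), c(2, 2, 3))
  hm <- new("ProbabilityHeatmap", map = map, method = "bilinear",
            gridDim = c(1L, 1L))
  expect_equal(srhRGB(overlayHeatmap(img, hm, alpha = 0)), rgb)
  red <- srhRGB(overlayHeatmap(img, hm, alpha = 1))
  expect_true(all(red[, , 1] == 1) && all(red[, , 2:3] == 0))
  half <- srhRGB(overlayHeatmap(img, hm, alpha = 0.5))
  expect_equal(half, 0.5 * rgb + 0.5 * map, tolerance = 1e-12)

  small <- srhImage(array(0.5, c(3, 3, 3)))
  expect_error(overlayHeatmap(small, hm), "dimensions")
})

test_that("region accuracy excludes the interpolation blur zone", {
  ## perfect one-hot heatmap scores 1 against its own mask
  mask <- matrix(0L, 600, 600)
  mask[, 301:600] <- 1L
  map <- array(0, c(600, 600, 3))
  map[, , 1][mask == 0L] <- 1
  map[, , 2][mask == 1L] <- 1
  hm <- new("ProbabilityHeatmap", map = map, method = "bilinear",
            gridDim = c(2L, 2L))
  expect_equal(heatmapRegionAccuracy(hm, mask), 1.0)

  ## uniform heatmap: tie rule favors tumor, accuracy = kept tumor fraction
  uni <- new("ProbabilityHeatmap", map = array(1 / 3, c(600, 600, 3)),
             method = "bilinear", gridDim = c(2L, 2L))
  acc <- heatmapRegionAccuracy(uni, mask, exclude_px = 150)
  keep_tumor <- sum(mask == 0L) - 600 * 150   # strip within 150 px of the edge
  keep_non <- sum(mask == 1L) - 600 * 150
  expect_equal(acc, keep_tumor / (keep_tumor + keep_non), tolerance = 0.01)

  ## single-class mask: nothing is excluded
  expect_equal(heatmapRegionAccuracy(uni, matrix(0L, 600, 600)), 1.0)

  expect_error(heatmapRegionAccuracy(hm, matrix(0L, 10, 10)), "match")
})

test_that("whole-slide classification is invariant to PNG round-trips", {
  m <- desk_model(1L)
  sl <- generateSlide("non_tumor", width_px = 600, height_px = 600,
                      seed = 55)
  img <- buildSRH(sl)
  direct <- classifySlide(m, img)
  f <- tempfile(fileext = ".png")
  writeSlide(img, f)
  reread <- classifySlide(m, readSlide(f))
  expect_identical(finalClass(direct$prediction),
                   finalClass(reread$prediction))
  expect_equal(slideProbs(direct$prediction),
               slideProbs(reread$prediction), tolerance = 0.05)
})
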