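tiny_cfg <- function(seed = 1L)
  modelConfig(stage_widths = 8L, blocks_per_stage = 1L, input_px = 12L,
              seed = seed)

test_that("model construction is seeded and outputs live on the simplex", {
  m1 <- buildModel(tiny_cfg(seed = 7))
  m2 <- buildModel(tiny_cfg(seed = 7))
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(tiny_cfg(seed = 8))
  expect_false(identical(m1@params$stem, m3@params$stem))

  set.seed(2)
  x <- array(runif(12 * 12 * 3 * 5), c(12, 12, 3, 5))
  p <- predictPatches(m1, x)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-6)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("parameter count matches the closed-form layer arithmetic", {
  m <- buildModel(tiny_cfg())
  w <- 8L
  ## stem 3x3x3xw; one basic block: bn1(2w) + conv1 9*w*w + bn2(2w) +
  ## conv2 9*w*w; head bn 2w; dense 3*w + 3
  want <- 3 * 3 * 3 * w + (2 * w + 9 * w * w + 2 * w + 9 * w * w) +
    2 * w + (3 * w + 3)
  expect_equal(sum(vapply(m@params, length, integer(1))), want)

  ## two stages add a stride-2 projection block: bn1(2*w1) + convs on the
  ## wider width + 1x1 projection
  m2 <- buildModel(modelConfig(stage_widths = c(4L, 6L),
                               blocks_per_stage = 1L, input_px = 12L))
  want2 <- 3 * 3 * 3 * 4 +                      # stem
    (2 * 4 + 9 * 4 * 4 + 2 * 4 + 9 * 4 * 4) +   # stage-1 identity block
    (2 * 4 + 9 * 4 * 6 + 2 * 6 + 9 * 6 * 6 + 1 * 1 * 4 * 6) +  # transition
    2 * 6 + (3 * 6 + 3)
  expect_equal(sum(vapply(m2@params, length, integer(1))), want2)
})

test_that("incompatible input/downsampling combinations are rejected", {
  expect_error(modelConfig(stage_widths = c(8, 16, 32, 64, 128),
                           input_px = 12L), "incompatible")
  expect_error(modelConfig(stage_widths = integer(0)), "stage")
})

test_that("weighted cross-entropy reproduces hand arithmetic", {
  expect_equal(weightedCrossEntropy(c(1, 0, 0), "tumor"), 0)
  expect_equal(
    weightedCrossEntropy(c(0.5, 0.25, 0.25), "tumor",
                         c(tumor = 2, non_tumor = 1, low_quality = 1)),
    2 * -log(0.5), tolerance = 1e-12)
  ## clamped, never infinite
  expect_true(is.finite(weightedCrossEntropy(c(0, 1, 0), "tumor")))

  set.seed(4)
  for (i in 1:100) {
    p <- rexp(3); p <- p / sum(p)
    y <- sample(srhClasses(), 1)
    expect_equal(weightedCrossEntropy(p, y),
                 -log(p[match(y, srhClasses())]), tolerance = 1e-12)
  }
})

test_that("inverse-frequency weights equalize per-class loss contributions", {
  ## fixed batch: 10/30/60 labels, every sample has the same probability on
  ## its true class, so raw per-sample losses are equal within class
  counts <- c(tumor = 10, non_tumor = 30, low_quality = 60)
  w <- classWeights(counts)
  y <- rep(1:3, counts)
  contrib <- vapply(1:3, function(cls) {
    sum(w[cls] * -log(0.4) * (y == cls))
  }, numeric(1))
  expect_equal(contrib[1], contrib[2], tolerance = 1e-12)
  expect_equal(contrib[2], contrib[3], tolerance = 1e-12)
})

test_that("the stopping rule is a strict conjunction", {
  expect_true(stopCriterion(0.96, 0.05))
  expect_false(stopCriterion(0.96, 0.20))   # accuracy alone is not enough
  expect_false(stopCriterion(0.90, 0.05))
  expect_false(stopCriterion(0.95, 0.10))   # thresholds are strict
})

test_that("ensemble training requires distinct seeds", {
  expect_error(retrainEnsemble(tiny_cfg(), list(), seeds = c(1, 1, 2)),
               "distinct")
})

test_that("patch prediction is deterministic and validates shape", {
  m <- desk_model(1L)
  sl <- generateSlide("tumor", width_px = 300, height_px = 300, seed = 61)
  patch <- srhRGB(buildSRH(sl))
  p1 <- predictPatch(m, patch)
  p2 <- predictPatch(m, patch)
  expect_identical(p1$p, p2$p)
  expect_equal(sum(p1$p), 1, tolerance = 1e-6)
  ## batched and single evaluation agree
  x2 <- array(c(patch, patch), c(dim(patch), 2))
  pb <- predictPatches(m, x2)
  expect_equal(unname(pb[1, ]), unname(p1$p), tolerance = 1e-5)
  expect_error(predictPatch(m, patch[, , 1]), "s x s x 3")
})

test_that("training reaches the stopping criterion on easy data, all seeds", {
  exp <- desk_experiment()
  for (ts in exp$train_reports) {
    expect_true(ts$stopped)
    expect_gt(ts$val_accuracy, 0.95)
    expect_lt(ts$val_loss, 0.10)
    expect_lte(nrow(ts$history), 30L)
  }
  ## optimization wiring: loss decreases on average over the first epochs
  h <- exp$train_reports[[1]]$history
  n <- nrow(h)
  if (n >= 3)
    expect_lt(h$train_loss[n], h$train_loss[1])
  ## different seeds produce different parameters
  expect_false(identical(exp$models[[1]]@params$stem,
                         exp$models[[2]]@params$stem))
})

test_that("patch-level accuracy on synthetic region ground truth is high", {
  m <- desk_model(1L)
  ## bands aligned to the 300 px test grid: every patch is class-pure
  lay <- list(list(x0 = 0, y0 = 0, w = 1200, h = 600, class = "tumor"),
              list(x0 = 0, y0 = 600, w = 1200, h = 600,
                   class = "non_tumor"))
  mx <- generateMixedSlide(lay, width_px = 1200, height_px = 1200, seed = 33)
  img <- buildSRH(mx)
  grid <- patchGrid(1200, 1200, 300)
  probs <- predictPatches(m, patchTensor(img, grid, m@config$input_px))
  top1 <- srhClasses()[max.col(probs, ties.method = "first")]
  truth <- ifelse(gridOrigins(grid)$y < 600, "tumor", "non_tumor")
  expect_gte(mean(top1 == truth), 0.9)
})
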