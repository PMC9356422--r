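test_that("slide generation is bit-reproducible and honors degenerate params", {
  a <- generateSlide("tumor", width_px = 320, height_px = 340, seed = 42)
  b <- generateSlide("tumor", width_px = 320, height_px = 340, seed = 42)
  expect_identical(a@ch2845, b@ch2845)
  expect_identical(a@ch2940, b@ch2940)
  expect_false(identical(
    a@ch2940,
    generateSlide("tumor", width_px = 320, height_px = 340, seed = 43)@ch2940))

  p <- textureParams(nucleus_density = 0, blank_fraction = 1, noise_sd = 0,
                     background_lipid = 0.07, background_protein = 0.12)
  s <- generateSlide("low_quality", p, 300, 300, seed = 1)
  expect_true(all(s@ch2845 == 0.07))
  expect_true(all(s@ch2940 == 0.12))

  expect_error(generateSlide("tumor", width_px = 200, height_px = 600),
               "300")
  expect_error(generateSlide("weird", width_px = 300, height_px = 300),
               "label")
})

test_that("nucleus density drives protein-channel intensity (Monte Carlo)", {
  d <- 120
  base <- textureParams(nucleus_density = d, fiber_strength = 0,
                        background_lipid = 0.2, background_protein = 0.25,
                        noise_sd = 0.02)
  sparse <- base; sparse$nucleus_density <- d / 10
  wins <- 0L
  for (s in 1:50) {
    hi <- generateSlide("tumor", base, 300, 300, seed = 1000 + s)
    lo <- generateSlide("non_tumor", sparse, 300, 300, seed = 2000 + s)
    if (mean(hi@ch2940) > mean(lo@ch2940)) wins <- wins + 1L
  }
  expect_gte(wins, 49L)
})

test_that("mixed slides record the layout exactly and reject bad layouts", {
  ## single full-image region reproduces the homogeneous generator
  lay <- list(list(x0 = 0, y0 = 0, w = 300, h = 300, class = "tumor"))
  mx <- generateMixedSlide(lay, width_px = 300, height_px = 300, seed = 5)
  hom <- generateSlide("tumor", width_px = 300, height_px = 300, seed = 5)
  expect_identical(mx@ch2940, hom@ch2940)
  expect_identical(mx@ch2845, hom@ch2845)
  expect_true(all(mx@regionMask == 0L))

  ## left-half tumor / right-half non-tumor
  lay2 <- list(list(x0 = 0, y0 = 0, w = 300, h = 600, class = "tumor"),
               list(x0 = 300, y0 = 0, w = 300, h = 600, class = "non_tumor"))
  mx2 <- generateMixedSlide(lay2, width_px = 600, height_px = 600, seed = 1)
  expect_true(all(mx2@regionMask[, 1:300] == 0L))
  expect_true(all(mx2@regionMask[, 301:600] == 1L))
  expect_identical(slideLabel(mx2), "tumor")  # modal class, tie -> tumor

  ## three-band layout: per-band statistics ordered per the texture contract
  lay3 <- list(list(x0 = 0, y0 = 0, w = 900, h = 300, class = "tumor"),
               list(x0 = 0, y0 = 300, w = 900, h = 300, class = "non_tumor"),
               list(x0 = 0, y0 = 600, w = 900, h = 300,
                    class = "low_quality"))
  mx3 <- generateMixedSlide(lay3, width_px = 900, height_px = 900, seed = 2)
  prot <- c(tumor = mean(mx3@ch2940[1:300, ]),
            non_tumor = mean(mx3@ch2940[301:600, ]),
            lq = mean(mx3@ch2940[601:900, ]))
  expect_gt(prot["tumor"], prot["non_tumor"])
  expect_gt(prot["non_tumor"], prot["lq"])
  lip <- mean(mx3@ch2845[301:600, ])
  expect_gt(lip, mean(mx3@ch2845[1:300, ]))  # fibrous lipid band

  over <- list(list(x0 = 0, y0 = 0, w = 400, h = 600, class = "tumor"),
               list(x0 = 200, y0 = 0, w = 400, h = 600,
                    class = "non_tumor"))
  expect_error(generateMixedSlide(over, width_px = 600, height_px = 600),
               "overlap")
  gap <- list(list(x0 = 0, y0 = 0, w = 200, h = 600, class = "tumor"))
  expect_error(generateMixedSlide(gap, width_px = 600, height_px = 600),
               "tile")
})

test_that("cohorts have the multi-area structure and match the class prior", {
  co <- generateCohort(1, seed = 3, slide_px = 300)
  m <- cohortManifest(co)
  expect_equal(nrow(m), 3L)
  expect_equal(length(unique(m$specimen_id)), 1L)
  expect_setequal(m$area, c("A", "B", "C"))
  expect_equal(length(unique(m$label)), 1L)  # areas share the specimen label

  all_t <- generateCohort(4, class_mix = c(1, 0, 0), seed = 1,
                          slide_px = 300)
  expect_true(all(cohortManifest(all_t)$label == "tumor"))

  ## label frequencies within exact binomial 99% bounds of the prior
  mix <- c(0.78, 0.19, 0.03)
  co20 <- generateCohort(20, class_mix = mix, seed = 11, slide_px = 300)
  lab <- cohortManifest(co20)$label[cohortManifest(co20)$area == "A"]
  for (ci in 1:3) {
    n_c <- sum(lab == srhClasses()[ci])
    expect_gte(n_c, qbinom(0.005, 20, mix[ci]))
    expect_lte(n_c, qbinom(0.995, 20, mix[ci]))
  }
  ## every nonzero-prior class is represented
  expect_setequal(unique(lab), srhClasses())

  ## bit-identical reproduction from the seed
  co20b <- generateCohort(20, class_mix = mix, seed = 11, slide_px = 300)
  expect_identical(cohortManifest(co20), cohortManifest(co20b))
  expect_identical(co20@specimenParams, co20b@specimenParams)
})

test_that("areas of one specimen share texture parameters but not textures", {
  co <- generateCohort(2, seed = 8, slide_px = 300)
  m <- cohortManifest(co)
  s1 <- cohortSlide(co, 1)  # area A of specimen 1
  s2 <- cohortSlide(co, 2)  # area B of specimen 1
  expect_identical(s1@params, s2@params)
  expect_false(identical(s1@ch2940, s2@ch2940))  # different placement seeds
  expect_identical(slideLabel(s1), slideLabel(s2))
})

test_that("easy-mode classes separate with a linear pixel-statistics rule", {
  skip_if_not_installed("MASS")
  co <- generateCohort(20, seed = 21, slide_px = 300)
  m <- cohortManifest(co)
  feats <- t(vapply(seq_len(nrow(m)), function(i) {
    s <- cohortSlide(co, i)
    c(mean(s@ch2845), mean(s@ch2940), sd(s@ch2845), sd(s@ch2940))
  }, numeric(4)))
  fit <- MASS::lda(feats, grouping = factor(m$label), CV = TRUE)
  expect_gte(mean(fit$class == m$label), 0.95)
})

test_that("cohorts round-trip through TIFF channel pairs and manifest CSV", {
  co <- generateCohort(1, seed = 17, slide_px = 300)
  dir <- file.path(tempdir(), "srh-cohort-io")
  man <- writeCohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(all(file.exists(paste0(man$path, "_2845.tif"))))
  sl <- cohortSlide(co, 1)
  rt <- readChannelPair(man$path[1])
  expect_lt(max(abs(rt@ch2940 - sl@ch2940)), 1 / 65535 + 1e-9)
})
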