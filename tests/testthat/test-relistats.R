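ratings_fixture <- matrix(c(9, 2, 5, 8,
                            6, 1, 3, 2,
                            8, 4, 6, 8,
                            7, 1, 2, 6,
                            10, 5, 6, 9,
                            6, 2, 4, 7), nrow = 6, byrow = TRUE)

test_that("ICC matches the independent sums-of-squares oracle", {
  set.seed(19)
  for (rep in 1:10) {
    m <- matrix(sample(1:9, 18, replace = TRUE), 6, 3)
    if (var(as.vector(m)) == 0) next
    expect_equal(iccSingleAbsolute(m)$icc, icc_oracle(m), tolerance = 1e-10)
  }
  expect_equal(iccSingleAbsolute(ratings_fixture)$icc,
               icc_oracle(ratings_fixture), tolerance = 1e-10)

  ## perfect agreement
  m1 <- cbind(1:6, 1:6, 1:6)
  expect_equal(iccSingleAbsolute(m1)$icc, 1, tolerance = 1e-10)

  ## absolute agreement penalizes a constant rater offset
  m <- matrix(c(4, 7, 2, 9, 5, 3,
                5, 6, 2, 8, 5, 4,
                4, 8, 3, 9, 6, 3), 6, 3)
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 3
  expect_lt(iccSingleAbsolute(shifted)$icc, iccSingleAbsolute(m)$icc)
  expect_lt(icc_oracle(shifted), icc_oracle(m))   # oracle agrees

  ## degenerate: zero total variance
  deg <- iccSingleAbsolute(matrix(5, 4, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$icc, 1)
})

test_that("ICC confidence limits follow the F-distribution method", {
  ## frozen against an independent implementation of the
  ## absolute-agreement single-measure interval (verified externally)
  r <- iccSingleAbsolute(ratings_fixture, ci_level = 0.95)
  expect_equal(r$icc, 0.289764, tolerance = 1e-5)
  expect_equal(r$lower, 0.018787, tolerance = 1e-4)
  expect_equal(r$upper, 0.761084, tolerance = 1e-4)
  ## wider level, wider interval
  r99 <- iccSingleAbsolute(ratings_fixture, ci_level = 0.99)
  expect_lt(r99$lower, r$lower)
  expect_gt(r99$upper, r$upper)
})

test_that("Cohen's kappa reproduces hand arithmetic and its limits", {
  k <- cohensKappa(matrix(c(20, 10, 5, 15), 2))
  expect_equal(k$po, 0.7)
  expect_equal(k$pe, 0.5)
  expect_equal(k$kappa, 0.4, tolerance = 1e-12)

  ## perfect agreement
  expect_equal(cohensKappa(diag(c(5, 3, 2)))$kappa, 1)

  ## statistically independent raters: outer-product table, kappa = 0
  indep <- matrix(c(6, 12, 4, 8), 2)   # rows (10, 20) x cols (0.6, 0.4)
  expect_equal(cohensKappa(indep)$kappa, 0, tolerance = 1e-12)

  ## both raters constant and identical: defined as 1 with flag
  kd <- cohensKappa(rep("tumor", 5), rep("tumor", 5))
  expect_true(kd$degenerate)
  expect_equal(kd$kappa, 1)

  expect_error(cohensKappa(matrix(0, 2, 2)), "empty")
  expect_error(cohensKappa(matrix(1:6, 2, 3)), "square")
})

test_that("kappa from a confusion table equals kappa from label vectors", {
  set.seed(8)
  a <- sample(srhClasses(), 60, replace = TRUE)
  b <- sample(srhClasses(), 60, replace = TRUE)
  tab <- table(factor(a, srhClasses()), factor(b, srhClasses()))
  expect_equal(cohensKappa(unclass(tab))$kappa, cohensKappa(a, b)$kappa,
               tolerance = 1e-12)
})

test_that("Cronbach's alpha follows the variance formula", {
  ## identical columns
  expect_equal(cronbachAlpha(cbind(1:5, 1:5, 1:5))$alpha, 1,
               tolerance = 1e-12)

  ## 4x3 integer table vs direct hand computation
  m <- matrix(c(3, 5, 1, 7,
                4, 5, 2, 8,
                3, 6, 2, 6), 4, 3)
  k <- 3
  hand <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbachAlpha(m)$alpha, hand, tolerance = 1e-10)

  ## independent noise has alpha near 0
  set.seed(101)
  noise <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(abs(cronbachAlpha(noise)$alpha), 0.05)

  deg <- cronbachAlpha(matrix(2, 5, 3))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$alpha))
})

test_that("AUC equals exhaustive pair counting and handles ties", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)

  scores <- c(0.9, 0.8, 0.8, 0.6, 0.5, 0.4, 0.4, 0.1)
  truth <- c(1, 0, 1, 1, 0, 1, 0, 0)
  expect_equal(rocAuc(scores, truth)$auc, auc_oracle(scores, truth),
               tolerance = 1e-12)

  set.seed(6)
  for (rep in 1:10) {
    s <- round(runif(20), 1)   # force ties
    y <- rbinom(20, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(rocAuc(s, y)$auc, auc_oracle(s, y), tolerance = 1e-12)
  }
  expect_error(rocAuc(1:5, rep(1, 5)), "both")
})

test_that("AUC interval uses the Hanley-McNeil SE, untruncated", {
  scores <- c(0.95, 0.9, 0.85, 0.8, 0.55, 0.6, 0.4, 0.3, 0.2, 0.1)
  truth <- c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0)
  r <- rocAuc(scores, truth, ci_level = 0.99)
  a <- r$auc
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 4 * (q1 - a^2) + 4 * (q2 - a^2)) / 25)
  expect_equal(r$se, se, tolerance = 1e-12)
  expect_equal(r$upper, a + qnorm(0.995) * se, tolerance = 1e-12)
  expect_gt(r$upper, 1)   # deliberately not truncated at 1
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(77)
  s <- rnorm(50)
  y <- rbinom(50, 1, plogis(s))
  if (length(unique(y)) == 2)
    expect_equal(rocAuc(s, y)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
                 tolerance = 1e-10)
})

test_that("Kendall's W matches the tie-corrected formula", {
  ## identical rankings, no ties
  perfect <- cbind(c(3, 1, 4, 2), c(30, 10, 40, 20), c(0.3, 0.1, 0.4, 0.2))
  kw <- kendallsW(perfect)
  expect_equal(kw$W, 1, tolerance = 1e-12)
  expect_equal(kw$chi2, 3 * 3 * 1)        # k (n-1) W
  expect_equal(kw$df, 3)

  ## toy table with ties, hand computation
  m <- matrix(c(1, 2, 2, 4,
                1, 3, 2, 4,
                2, 2, 3, 4), 4, 3)
  ranks <- apply(m, 2, rank)
  R <- rowSums(ranks)
  S <- sum((R - mean(R))^2)
  Tj <- apply(m, 2, function(col) { t <- table(col); sum(t^3 - t) })
  W_hand <- 12 * S / (9 * (64 - 4) - 3 * sum(Tj))
  expect_equal(kendallsW(m)$W, W_hand, tolerance = 1e-10)

  ## null expectation: E[W] = 1/k for independent continuous ratings
  set.seed(55)
  ws <- replicate(500, kendallsW(matrix(rnorm(150), 50, 3))$W)
  expect_lt(abs(mean(ws) - 1 / 3), 0.02)

  expect_true(kendallsW(matrix(c(1, 2, 2, 1), 2, 2))$small_n)
})

test_that("reliability statistics have the expected invariances", {
  set.seed(13)
  m <- matrix(rnorm(30), 10, 3)
  perm <- sample(10)
  expect_equal(iccSingleAbsolute(m)$icc, iccSingleAbsolute(m[perm, ])$icc,
               tolerance = 1e-10)
  expect_equal(cronbachAlpha(m)$alpha, cronbachAlpha(m[perm, ])$alpha,
               tolerance = 1e-10)
  expect_equal(kendallsW(m)$W, kendallsW(m[perm, ])$W, tolerance = 1e-10)
  ## common constant added to ALL cells
  expect_equal(iccSingleAbsolute(m + 7)$icc, iccSingleAbsolute(m)$icc,
               tolerance = 1e-9)
  expect_equal(cronbachAlpha(m + 7)$alpha, cronbachAlpha(m)$alpha,
               tolerance = 1e-10)
})

test_that("agreement reports compute counts, percentages and kappa", {
  ref <- rep(srhClasses(), c(6, 3, 1))
  good <- ref
  rep1 <- ref; rep1[c(1, 7)] <- c("non_tumor", "tumor")  # two mistakes
  out <- agreementReport(list(cnn1 = rep1, cnn2 = good), ref)
  o1 <- out$overall[out$overall$model == "cnn1", ]
  expect_equal(o1$correct, 8L)
  expect_equal(o1$percent, 80)
  expect_equal(out$overall$kappa[out$overall$model == "cnn2"], 1)
  pc <- out$per_class[out$per_class$model == "cnn1", ]
  expect_equal(pc$correct[pc$class == "tumor"], 5L)
  expect_equal(pc$percent_1dp[pc$class == "tumor"], 83.3)
  expect_error(agreementReport(list(a = ref[-1]), ref), "length")
})

test_that("end-to-end reliability mirrors the clinical analysis qualitatively", {
  exp <- desk_experiment()
  s <- exp$stats
  expect_gte(s$icc$tumor$icc, 0.9)
  for (kp in s$kappa) expect_gte(kp, 0.6)
})
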