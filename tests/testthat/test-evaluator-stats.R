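table3Accuracies <- c(74.63, 68.66, 71.64, 49.25, 58.21, 94.03, 95.52,
                      97.01)

test_that("confusion metrics count the four cells correctly", {
  truth <- rep(c("AD", "control"), times = c(36, 29))
  perfect <- confusionMetrics(truth, truth)
  expect_equal(unlist(perfect[c("accuracy", "sensitivity", "specificity",
                                "ppv", "npv")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1,
                 ppv = 1, npv = 1))
  allAd <- confusionMetrics(rep("AD", 65), truth)
  expect_equal(allAd$sensitivity, 1)
  expect_equal(allAd$specificity, 0)
  expect_equal(allAd$accuracy, 36 / 65)
  expect_true(is.na(allAd$npv))      # undefined, not zero
  inverted <- ifelse(truth == "AD", "control", "AD")
  expect_equal(confusionMetrics(inverted, truth)$accuracy,
               1 - perfect$accuracy)
  # missing ratings shrink the denominator
  r <- truth; r[1:5] <- NA
  expect_equal(confusionMetrics(r, truth)$nEvaluated, 60)
})

test_that("probability-matching chance level follows p^2 + (1-p)^2", {
  expect_equal(chanceLevel(36, 29), 0.5058, tolerance = 1e-4)
  expect_equal(chanceLevel(50, 50), 0.5)
  expect_equal(chanceLevel(100, 0), 1)
})

test_that("exact binomial p-values match exhaustive enumeration", {
  enumTwoTailed <- function(k, n, p0) {
    pr <- dbinom(0:n, n, p0)
    sum(pr[pr <= pr[k + 1] * (1 + 1e-7)])
  }
  for (n in c(1, 5, 12, 20)) {
    for (p0 in c(0.3, 0.5, 0.5058)) {
      for (k in 0:n) {
        expect_equal(binomialVsChance(k, n, p0), enumTwoTailed(k, n, p0),
                     tolerance = 1e-12)
      }
    }
  }
  expect_lt(binomialVsChance(65, 65, 0.5058), 1e-15)
  expect_gt(binomialVsChance(round(65 * 0.5058), 65, 0.5058), 0.5)
  expect_equal(binomialVsChance(0, 1, 0.5), 1)
})

test_that("Holm adjustment matches the hand-worked step-down", {
  expect_equal(holmAdjust(0.02), 0.02)
  expect_equal(holmAdjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))
  expect_equal(holmAdjust(rep(1, 4)), rep(1, 4))
  p <- withr::with_seed(1, runif(10))
  expect_true(all(holmAdjust(p) >= p))
})

test_that("panel evaluation combines metrics, binomial and Holm", {
  truth <- rep(c("AD", "control"), times = c(36, 29))
  rm <- generateRatingMatrix(truth, c(0.95, 0.55, 0.75), seed = 4)
  panel <- evaluatePanel(rm)
  expect_equal(nrow(panel), 3)
  expect_true(all(panel$p_holm >= panel$p_raw))
  expect_lt(panel$p_holm[1], 0.01)   # a 95%-accurate rater is clearly above chance
  k <- sum(ratings(rm)[, 1] == truth)
  expect_equal(panel$p_raw[1],
               binomialVsChance(k, 65, chanceLevel(36, 29)))
})

test_that("panel summary reports mean, sample SD, min and max", {
  s <- summarizePanel(table3Accuracies)
  expect_equal(round(s$mean, 2), 76.12)
  expect_equal(round(s$sd, 2), 17.95)
  expect_equal(s$min, 49.25)
  expect_equal(s$max, 97.01)
  expect_warning(s1 <- summarizePanel(data.frame(accuracy = 0.8)),
                 "undefined")
  expect_true(is.na(s1$sd))
  expect_equal(summarizePanel(rep(0.7, 5))$sd, 0)
})

test_that("permutation test is small for perfect panels, valid under null", {
  truth <- rep(c("AD", "control"), times = c(12, 10))
  perfect <- ratingMatrix(truth, matrix(rep(truth, 4), ncol = 4))
  pt <- permutationTestMeanAccuracy(perfect, nPerm = 999, seed = 1)
  expect_equal(pt$observed, 1)
  expect_lte(pt$p, 5 / 1000)
  expect_gte(pt$p, 1 / 1000)
  # observed at the null mean -> unremarkable p
  rmNull <- generateRatingMatrix(truth, rep(0.5, 6), seed = 8)
  ptNull <- permutationTestMeanAccuracy(rmNull, nPerm = 499, seed = 2)
  expect_gt(ptNull$p, 0.05)
  expect_error(permutationTestMeanAccuracy(
    ratingMatrix(rep("AD", 5), matrix("AD", 5, 2)), nPerm = 100),
    "degenerate")
})

test_that("permutation p-values are calibrated under the null", {
  truth <- rep(c("AD", "control"), times = c(36, 29))
  ps <- vapply(1:200, function(s) {
    rm <- generateRatingMatrix(truth, rep(0.5, 8),
                               seed = substreamSeed(900, s))
    permutationTestMeanAccuracy(rm, nPerm = 199,
                                seed = substreamSeed(901, s))$p
  }, numeric(1))
  expect_lt(abs(mean(ps) - 0.5), 0.06)
  expect_lte(mean(ps <= 0.05), 0.06)
})

test_that("Fleiss' kappa matches hand-worked small panels", {
  # 2 raters, 4 items (AA, AB, BA, BB): P_bar = 1/2, P_e = 1/2 -> kappa 0
  rm4 <- ratingMatrix(rep("AD", 4),
                      matrix(c("AD", "AD",
                               "AD", "control",
                               "control", "AD",
                               "control", "control"),
                             ncol = 2, byrow = TRUE))
  expect_equal(fleissKappa(rm4)$kappa, 0)
  # 2 raters, 3 items (AA, AA, AB): P_bar = 2/3, P_e = 13/18 -> -1/5
  rm3 <- ratingMatrix(rep("AD", 3),
                      matrix(c("AD", "AD",
                               "AD", "AD",
                               "AD", "control"),
                             ncol = 2, byrow = TRUE))
  expect_equal(fleissKappa(rm3)$kappa, -0.2)
  # perfect agreement with both categories present
  truth <- rep(c("AD", "control"), times = c(6, 5))
  rmP <- ratingMatrix(truth, matrix(rep(truth, 5), ncol = 5))
  expect_equal(fleissKappa(rmP)$kappa, 1)
  # unanimous single category: expected agreement 1, undefined
  rmU <- ratingMatrix(rep("AD", 4), matrix("AD", 4, 3))
  expect_warning(fk <- fleissKappa(rmU), "undefined")
  expect_true(is.na(fk$kappa))
  # chance-level agreement for independent uniform raters
  big <- withr::with_seed(10, matrix(sample(c("AD", "control"), 400 * 4,
                                            TRUE), ncol = 4))
  rmR <- ratingMatrix(rep(c("AD", "control"), 200), big)
  expect_lt(abs(fleissKappa(rmR)$kappa), 0.08)
})

test_that("kappa uses only complete items and reports their count", {
  truth <- rep(c("AD", "control"), times = c(4, 4))
  rt <- matrix(rep(truth, 3), ncol = 3)
  rt[2, 1] <- NA; rt[5, 3] <- NA
  rm <- ratingMatrix(truth, rt)
  fk <- fleissKappa(rm)
  expect_equal(fk$nItemsUsed, 6)
  expect_equal(fk$kappa, 1)
})

test_that("bootstrap kappa CI is seeded and covers the estimate", {
  truth <- rep(c("AD", "control"), times = c(6, 5))
  rmP <- ratingMatrix(truth, matrix(rep(truth, 5), ncol = 5))
  ci <- bootstrapKappaCI(rmP, nBoot = 200, seed = 3)
  expect_equal(ci, c(1, 1))
  expect_identical(bootstrapKappaCI(rmP, nBoot = 200, seed = 3), ci)
  # the percentile CI brackets the point estimate for imperfect panels
  covered <- 0L
  for (s in 1:20) {
    truth2 <- rep(c("AD", "control"), times = c(33, 28))
    rm <- generateRatingMatrix(truth2, rep(0.8, 6),
                               seed = substreamSeed(700, s))
    k <- fleissKappa(rm)$kappa
    ci <- bootstrapKappaCI(rm, nBoot = 200, seed = substreamSeed(701, s))
    if (ci[1] <= k && k <= ci[2]) covered <- covered + 1L
  }
  expect_gte(covered, 19L)
})

test_that("power simulation is calibrated at the null and saturates", {
  p0 <- chanceLevel(36, 29)
  powNull <- powerSimulation(65, 8, effectMeanAccuracy = p0,
                             effectSd = 0, nSims = 200, seed = 1,
                             nPerm = 199)
  expect_lt(powNull, 0.12)
  powBig <- powerSimulation(65, 8, effectMeanAccuracy = 0.99,
                            effectSd = 0.01, nSims = 100, seed = 2,
                            nPerm = 199)
  expect_gte(powBig, 0.99)
})
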