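test_that("class-weight arithmetic reproduces the cohort bookkeeping", {
  expect_equal(computeClassWeights(137, 58, 21), 9.3)
  expect_equal(computeClassWeights(68, 28, 10), 9.6)
  expect_equal(computeClassWeights(10, 0, 10), 1.0)
  expect_equal(balancedCount(21, 9.3), 195)
  expect_equal(balancedCount(10, 9.6), 96)
  expect_error(computeClassWeights(10, 10, 0), "division error")
})

test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1Score(0.81, 0.90), 0.85)
  expect_equal(f1Score(0.75, 0.90), 0.82)
  expect_equal(f1Score(0.77, 0.90), 0.83)
  expect_equal(f1Score(0.33, 0.78), 0.46)
  expect_equal(f1Score(1, 1), 1)
  expect_warning(z <- f1Score(0, 0), "both zero")
  expect_equal(z, 0)
})

toySeparable <- function(n = 30, gap = 4, seed = 2) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(2 * n), n, 2),
             matrix(rnorm(2 * n, mean = gap), n, 2))
  colnames(X) <- c("u", "v")
  list(X = X, y = rep(c("rest", "LQT3"), each = n))
}

test_that("the weighted RBF SVM separates a separable toy set deterministically", {
  toy <- toySeparable()
  m <- trainWeightedSvm(toy$X, toy$y, C = 1, KS = 1, weightLqt3 = 1)
  expect_equal(as.character(predictGenotypeGroup(m, toy$X)),
               ifelse(toy$y == "LQT3", "LQT3", "rest"))
  m2 <- trainWeightedSvm(toy$X, toy$y, C = 1, KS = 1, weightLqt3 = 1)
  expect_equal(m@fit$coefs, m2@fit$coefs)
  expect_error(trainWeightedSvm(toy$X[1:30, ], toy$y[1:30]),
               "training error")
})

test_that("an extreme class weight drives minority recall to one", {
  set.seed(9)
  n1 <- 60; n3 <- 6
  X <- rbind(matrix(rnorm(2 * n1), n1, 2),
             matrix(rnorm(2 * n3, mean = 1.2), n3, 2))
  colnames(X) <- c("u", "v")
  y <- c(rep("rest", n1), rep("LQT3", n3))
  mHuge <- trainWeightedSvm(X, y, C = 1, KS = 1, weightLqt3 = 1e6)
  predHuge <- predictGenotypeGroup(mHuge, X)
  expect_equal(sum(predHuge == "LQT3" & y == "LQT3") / n3, 1)
})

test_that("grid search returns the argmax with deterministic folds", {
  toy <- toySeparable(n = 25)
  g1 <- gridSearchCv(toy$X, toy$y, CGrid = 1, KSGrid = 0.9, seed = 4)
  expect_equal(g1$C, 1)
  expect_equal(g1$KS, 0.9)

  g <- gridSearchCv(toy$X, toy$y, CGrid = c(0.5, 1), KSGrid = c(0.5, 1, 2),
                    seed = 4)
  expect_equal(g$score, max(g$grid$score))
  gRepeat <- gridSearchCv(toy$X, toy$y, CGrid = c(0.5, 1),
                          KSGrid = c(0.5, 1, 2), seed = 4)
  expect_equal(g$grid$score, gRepeat$grid$score)
  expect_equal(c(g$C, g$KS), c(gRepeat$C, gRepeat$KS))
})

test_that("weighted confusion metrics match the constructed example", {
  met <- weightedConfusionMetrics(tp = 9, fn = 1, fp = 20, tn = 76,
                                  weight = 9.6)
  expect_equal(met$precision, 86.4 / 106.4)
  expect_equal(met$accuracy, 162.4 / 192)
  expect_equal(met$recall, 0.9)

  # all weights 1 reduce to unweighted definitions
  u <- weightedConfusionMetrics(9, 1, 20, 76, weight = 1)
  expect_equal(u$precision, 9 / 29)
  expect_equal(u$accuracy, 85 / 106)

  # recall is weight-invariant; precision and accuracy are not
  expect_equal(met$recall, u$recall)
  expect_false(isTRUE(all.equal(met$precision, u$precision)))
  expect_false(isTRUE(all.equal(met$accuracy, u$accuracy)))
})

test_that("weighted evaluation spans the perfect and degenerate cases", {
  toy <- toySeparable()
  m <- trainWeightedSvm(toy$X, toy$y, C = 1, KS = 1)
  rep <- evaluateWeighted(m, toy$X, toy$y, testWeightLqt3 = 9.6)
  expect_equal(rep@accuracy, 1)
  expect_equal(rep@precision, 1)
  expect_equal(rep@recall, 1)
  expect_equal(rep@f1, 1)
  expect_equal(rep@auc, 1)

  # far-away LQT3 points are all predicted rest: recall 0, precision flagged 0
  XFar <- matrix(rnorm(20, mean = -30), 10, 2,
                 dimnames = list(NULL, c("u", "v")))
  expect_warning(
    repBad <- evaluateWeighted(m, XFar, rep("LQT3", 10), 9.6),
    "precision")
  expect_equal(repBad@recall, 0)
  expect_equal(repBad@precision, 0)
})

test_that("exact Shapley obeys the closed form and the axioms", {
  set.seed(6)
  bg <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  xe <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, c("a", "b", "c")))

  # linear model: phi_i = x_i - mean(background_i) exactly
  lin <- function(Z) rowSums(Z)
  sh <- exactShapley(lin, xe, bg)
  expect_equal(sh$phi, xe - rep(colMeans(bg), each = 5), tolerance = 1e-9,
               ignore_attr = TRUE)
  # local accuracy
  expect_lt(max(abs(rowSums(sh$phi) - (sh$fx - sh$vEmpty))), 1e-9)

  # symmetry: duplicated coordinates get equal attributions
  sym <- function(Z) Z[, 1] * Z[, 2] + Z[, 1] + Z[, 2]
  xs <- matrix(c(1.3, 1.3, 0.2), 1, 3)
  bgs <- cbind(bg[, 1], bg[, 1], bg[, 3])
  shS <- exactShapley(sym, xs, bgs)
  expect_lt(abs(shS$phi[1, 1] - shS$phi[1, 2]), 1e-9)

  # dummy: a feature the score ignores gets zero
  dum <- function(Z) Z[, 1]^2 - Z[, 2]
  shD <- exactShapley(dum, xe, bg)
  expect_lt(max(abs(shD$phi[, 3])), 1e-9)

  expect_error(exactShapley(lin, matrix(0, 1, 9), matrix(0, 5, 9)),
               "refused")
})

test_that("the Shapley report groups attributions by predicted class", {
  toy <- toySeparable()
  m <- trainWeightedSvm(toy$X[, 1:2], toy$y, C = 1, KS = 1)
  Xr <- cbind(toy$X, w = rnorm(nrow(toy$X)))
  m3 <- trainWeightedSvm(Xr, toy$y, C = 1, KS = 1)
  rep <- exactShapleyReport(m3, Xr)
  expect_equal(dim(rep), c(3, 2))
  expect_true(all(rep >= 0))
  phi <- attr(rep, "phi")
  scores <- decisionScores(m3, Xr)
  base <- mean(scores)
  expect_lt(max(abs(rowSums(phi) - (scores - base))), 1e-8)
})
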