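#' @importFrom e1071 svm
#' @importFrom stats predict
NULL

#' Class-weight arithmetic for the imbalanced LQT3 group
#'
#' The LQT3 class weight is the number of LQT1 and LQT2 carriers combined
#' divided by the number of LQT3 carriers, rounded to `decimals`; the other
#' classes keep weight 1. `balancedCount` gives the weighted (balanced)
#' LQT3 signal count this weight implies.
#'
#' @param nLqt1,nLqt2,nLqt3 class counts.
#' @param decimals rounding of the weight.
#' @return `computeClassWeights`: the LQT3 weight (numeric scalar).
#' @examples
#' computeClassWeights(137, 58, 21)  # 9.3
#' computeClassWeights(68, 28, 10)   # 9.6
#' balancedCount(21, 9.3)            # 195
#' @export
computeClassWeights <- function(nLqt1, nLqt2, nLqt3, decimals = 1) {
  if (nLqt3 == 0) stop("division error: no LQT3 examples")
  round((nLqt1 + nLqt2) / nLqt3, decimals)
}

#' @rdname computeClassWeights
#' @param weight the LQT3 class weight.
#' @return `balancedCount`: the rounded weighted LQT3 count.
#' @export
balancedCount <- function(nLqt3, weight) round(nLqt3 * weight)

binarizeLabels <- function(y) {
  factor(ifelse(as.character(y) == "LQT3", "LQT3", "rest"),
         levels = c("LQT3", "rest"))
}

#' Train the class-weighted Gaussian-kernel SVM
#'
#' Soft-margin SVM with kernel \eqn{K(x,x') = \exp(-\lVert x-x'\rVert^2 /
#' KS^2)} (the kernel scale divides the distance, so the underlying radial
#' kernel parameter is \eqn{\gamma = 1/KS^2}) and per-class box constraint
#' \eqn{C \cdot w}. Features are standardized to training mean 0 / sd 1 when
#' `standardize` is set; the standardization constants live in the fit and
#' are applied at prediction time.
#'
#' @param X numeric matrix/data.frame of the (three) selected features.
#' @param y labels; anything other than "LQT3" is the rest class.
#' @param C box constraint.
#' @param KS kernel scale.
#' @param weightLqt3 class weight of the LQT3 group.
#' @param standardize standardize features on the training split.
#' @return an [LqtSvmModel-class].
#' @export
trainWeightedSvm <- function(X, y, C = 1, KS = 0.9, weightLqt3 = 1,
                             standardize = TRUE) {
  X <- as.matrix(X)
  yb <- binarizeLabels(y)
  if (length(unique(yb)) < 2)
    stop("training error: single-class input")
  fit <- svm(X, yb, scale = standardize, kernel = "radial",
             gamma = 1 / KS^2, cost = C,
             class.weights = c(LQT3 = weightLqt3, rest = 1))
  model <- new("LqtSvmModel", fit = fit, features = colnames(X),
               KS = KS, weightLqt3 = weightLqt3,
               levels = c("LQT3", "rest"))
  model@C <- C   # assigned post hoc: `C =` would partially match new(Class=)
  ## orient the decision score so that positive votes for LQT3
  pr <- predict(fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  ref <- if (length(unique(pr)) == 2) pr else yb
  orient <- sign(mean(dv[ref == "LQT3"]) - mean(dv[ref == "rest"]))
  attr(model@fit, "orientation") <- if (is.na(orient) || orient == 0) 1 else
    orient
  model
}

#' Decision scores of a trained model
#'
#' @param model an [LqtSvmModel-class].
#' @param X feature matrix (columns as at training).
#' @return numeric signed scores; positive favours LQT3.
#' @export
decisionScores <- function(model, X) {
  X <- as.matrix(X)
  pr <- predict(model@fit, X, decision.values = TRUE)
  as.numeric(attr(pr, "decision.values")) * attr(model@fit, "orientation")
}

#' Predicted class labels
#'
#' @inheritParams decisionScores
#' @return factor with levels `LQT3`, `rest`.
#' @export
predictGenotypeGroup <- function(model, X) {
  factor(ifelse(decisionScores(model, X) > 0, "LQT3", "rest"),
         levels = c("LQT3", "rest"))
}

#' Grid search with 5-fold cross-validation
#'
#' Folds are random non-stratified partitions fixed by `seed`. Each
#' configuration is scored by weighted CV accuracy (LQT3 examples carry
#' `weightLqt3`); folds whose training part is single-class are skipped with
#' a warning. Ties go to the smallest C, then the smallest KS.
#'
#' @inheritParams trainWeightedSvm
#' @param CGrid,KSGrid candidate values.
#' @param folds number of CV folds.
#' @param seed integer seed fixing the folds.
#' @return list with `C`, `KS`, `score` and the full `grid` data.frame.
#' @export
gridSearchCv <- function(X, y, CGrid, KSGrid, folds = 5, seed = 1,
                         weightLqt3 = 1, standardize = TRUE) {
  stopifnot(length(CGrid) > 0, length(KSGrid) > 0)
  X <- as.matrix(X)
  yb <- binarizeLabels(y)
  n <- nrow(X)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  grid <- expand.grid(C = CGrid, KS = KSGrid)
  grid$score <- NA_real_
  for (g in seq_len(nrow(grid))) {
    accs <- c()
    for (k in seq_len(folds)) {
      tr <- fold != k
      if (length(unique(yb[tr])) < 2 || !any(!tr)) {
        warning("fold ", k, " skipped: single-class training part")
        next
      }
      m <- trainWeightedSvm(X[tr, , drop = FALSE], yb[tr], C = grid$C[g],
                            KS = grid$KS[g], weightLqt3 = weightLqt3,
                            standardize = standardize)
      pred <- predictGenotypeGroup(m, X[!tr, , drop = FALSE])
      wts <- ifelse(yb[!tr] == "LQT3", weightLqt3, 1)
      accs <- c(accs, sum(wts * (pred == yb[!tr])) / sum(wts))
    }
    grid$score[g] <- mean(accs)
  }
  best <- grid[order(-grid$score, grid$C, grid$KS), ][1, ]
  list(C = best$C, KS = best$KS, score = best$score, grid = grid)
}

#' Weighted confusion-matrix metrics
#'
#' LQT3 (positive) examples accumulate `weight` in the confusion counts;
#' the rest class counts 1. Precision and accuracy depend on the weight;
#' recall is class-internal and does not.
#'
#' @param tp,fn,fp,tn unweighted confusion counts (positive class = LQT3).
#' @param weight LQT3 test weight.
#' @return list with the weighted `confusion` matrix and `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @examples
#' weightedConfusionMetrics(tp = 9, fn = 1, fp = 20, tn = 76, weight = 9.6)
#' @export
weightedConfusionMetrics <- function(tp, fn, fp, tn, weight = 1) {
  wtp <- weight * tp; wfn <- weight * fn
  conf <- matrix(c(wtp, fp, wfn, tn), 2, 2,
                 dimnames = list(predicted = c("LQT3", "rest"),
                                 truth = c("LQT3", "rest")))
  accuracy <- (wtp + tn) / (wtp + wfn + fp + tn)
  precision <- if (wtp + fp == 0) {
    warning("no positive predictions; precision reported as 0")
    0
  } else wtp / (wtp + fp)
  recall <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  f1 <- if (precision == 0 && (is.na(recall) || recall == 0)) 0 else
    2 * precision * recall / (precision + recall)
  list(confusion = conf, accuracy = accuracy, precision = precision,
       recall = recall, f1 = f1)
}

#' F1 score from precision and recall
#'
#' Harmonic mean \eqn{2PR/(P+R)}, rounded to `digits` for reporting; both
#' zero yields 0 with a warning.
#'
#' @param precision,recall values in [0, 1].
#' @param digits reporting precision.
#' @return F1 score.
#' @examples
#' f1Score(0.81, 0.90)  # 0.85
#' @export
f1Score <- function(precision, recall, digits = 2) {
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision == 0 && recall == 0) {
    warning("precision and recall both zero; F1 reported as 0")
    return(0)
  }
  round(2 * precision * recall / (precision + recall), digits)
}

#' Weighted out-of-sample evaluation
#'
#' Accumulates the weighted confusion matrix (LQT3 examples carry
#' `testWeightLqt3`), derives accuracy/precision/recall/F1, and builds the
#' ROC curve by sweeping the decision threshold over the weighted samples,
#' with the AUC by trapezoid.
#'
#' @param model an [LqtSvmModel-class].
#' @param X,y test features and labels.
#' @param testWeightLqt3 LQT3 weight of the test set.
#' @return an [EvalReport-class].
#' @export
evaluateWeighted <- function(model, X, y, testWeightLqt3 = 1) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty test set")
  yb <- binarizeLabels(y)
  pred <- predictGenotypeGroup(model, X)
  tp <- sum(pred == "LQT3" & yb == "LQT3")
  fn <- sum(pred == "rest" & yb == "LQT3")
  fp <- sum(pred == "LQT3" & yb == "rest")
  tn <- sum(pred == "rest" & yb == "rest")
  met <- weightedConfusionMetrics(tp, fn, fp, tn, testWeightLqt3)

  scores <- decisionScores(model, X)
  wts <- ifelse(yb == "LQT3", testWeightLqt3, 1)
  ord <- order(scores, decreasing = TRUE)
  pos <- yb[ord] == "LQT3"
  wPos <- sum(wts[yb == "LQT3"]); wNeg <- sum(wts[yb == "rest"])
  tpr <- c(0, cumsum(wts[ord] * pos) / wPos)
  fpr <- c(0, cumsum(wts[ord] * !pos) / wNeg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)

  new("EvalReport", confusion = met$confusion, accuracy = met$accuracy,
      precision = met$precision,
      recall = if (is.na(met$recall)) 0 else met$recall,
      f1 = if (is.na(met$f1)) 0 else met$f1, auc = auc,
      roc = data.frame(fpr = fpr, tpr = tpr))
}

#' Exact Shapley values of a scoring function
#'
#' Interventional Shapley attribution with exact coalition enumeration:
#' the value of coalition S for an explained row x is the mean score over
#' the background rows with the features in S fixed to x. With p features
#' all \eqn{2^p} coalitions are enumerated (refused above 8 features);
#' local accuracy \eqn{\sum_i \phi_i = f(x) - v(\emptyset)} holds exactly.
#'
#' @param scoreFun function taking a feature matrix, returning scores.
#' @param XExplain rows to explain.
#' @param XBackground background (reference) rows.
#' @return list with `phi` (matrix, rows = explained rows), `fx` (scores of
#'   the explained rows) and `vEmpty` (the base value).
#' @export
exactShapley <- function(scoreFun, XExplain, XBackground) {
  XExplain <- as.matrix(XExplain)
  XBackground <- as.matrix(XBackground)
  p <- ncol(XExplain)
  if (p > 8) stop("exact Shapley refused for more than 8 features")
  nB <- nrow(XBackground)
  subsets <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  wgt <- function(s) factorial(s) * factorial(p - s - 1) / factorial(p)

  phi <- matrix(0, nrow(XExplain), p, dimnames = list(NULL,
                                                      colnames(XExplain)))
  vEmpty <- mean(scoreFun(XBackground))
  for (r in seq_len(nrow(XExplain))) {
    x <- XExplain[r, ]
    v <- vapply(subsets, function(S) {
      if (!length(S)) return(vEmpty)
      Z <- XBackground
      Z[, S] <- matrix(x[S], nB, length(S), byrow = TRUE)
      mean(scoreFun(Z))
    }, numeric(1))
    names(v) <- vapply(subsets, paste, character(1), collapse = ",")
    for (i in seq_len(p)) {
      for (k in seq_along(subsets)) {
        S <- subsets[[k]]
        if (i %in% S) next
        vS <- v[[k]]
        Si <- sort(c(S, i))
        vSi <- v[[paste(Si, collapse = ",")]]
        phi[r, i] <- phi[r, i] + wgt(length(S)) * (vSi - vS)
      }
    }
  }
  fx <- scoreFun(XExplain)
  list(phi = phi, fx = fx, vEmpty = vEmpty)
}

#' Mean absolute Shapley report per predicted group
#'
#' Runs [exactShapley()] on the model's decision score and summarizes mean
#' absolute attributions per feature, grouped by the model's predicted
#' class of each explained row.
#'
#' @param model an [LqtSvmModel-class].
#' @param XBackground background rows.
#' @param XExplain rows to explain (defaults to the background).
#' @return matrix features x predicted groups (`LQT3`, `LQT1,2`) of mean
#'   absolute Shapley values, with the per-row `phi` as attribute `"phi"`.
#' @export
exactShapleyReport <- function(model, XBackground, XExplain = XBackground) {
  sh <- exactShapley(function(Z) decisionScores(model, Z), XExplain,
                     XBackground)
  pred <- predictGenotypeGroup(model, XExplain)
  groups <- list("LQT1,2" = pred == "rest", "LQT3" = pred == "LQT3")
  out <- vapply(groups, function(sel) {
    if (!any(sel)) return(rep(NA_real_, ncol(sh$phi)))
    colMeans(abs(sh$phi[sel, , drop = FALSE]))
  }, numeric(ncol(sh$phi)))
  rownames(out) <- colnames(sh$phi)
  attr(out, "phi") <- sh$phi
  out
}

#' Random non-stratified 2:1 train/test split
#'
#' @param n number of examples.
#' @param seed integer seed.
#' @param trainFraction fraction assigned to training.
#' @return list with integer index vectors `train` and `test`.
#' @export
splitTrainTest <- function(n, seed = 1, trainFraction = 2 / 3) {
  set.seed(seed)
  idx <- sample(n)
  nTrain <- round(trainFraction * n)
  list(train = sort(idx[seq_len(nTrain)]), test = sort(idx[-seq_len(nTrain)]))
}
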