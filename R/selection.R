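#' @importFrom stats cor pnorm median complete.cases
NULL

#' Two-sided Wilcoxon rank-sum test
#'
#' Mid-ranks are used for ties. For small groups (both sizes below 9 and a
#' feasible enumeration) the p-value is computed by exact enumeration of all
#' group assignments of the observed values, which remains exact under ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction is used. All observations identical yields p = 1.
#'
#' @param groupA,groupB numeric vectors.
#' @return list with `p` (two-sided p-value), `statistic` (rank sum of
#'   `groupA`) and `method`.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p  # exact: 2 / choose(6, 3) = 0.1
#' @export
rankSumTest <- function(groupA, groupB) {
  stopifnot(length(groupA) > 0, length(groupB) > 0)
  nA <- length(groupA); nB <- length(groupB); N <- nA + nB
  pooled <- c(groupA, groupB)
  if (length(unique(pooled)) == 1)
    return(list(p = 1, statistic = nA * (N + 1) / 2, method = "degenerate"))
  r <- rank(pooled)
  W <- sum(r[seq_len(nA)])

  if (min(nA, nB) < 9 && choose(N, nA) <= 200000) {
    combs <- utils::combn(N, nA)
    allW <- colSums(matrix(r[combs], nrow = nA))
    pLo <- mean(allW <= W); pHi <- mean(allW >= W)
    return(list(p = min(1, 2 * min(pLo, pHi)), statistic = W,
                method = "exact"))
  }
  mu <- nA * (N + 1) / 2
  ties <- table(pooled)
  tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
  sigma2 <- nA * nB / 12 * ((N + 1) - tieCorr)
  z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
  list(p = min(1, 2 * pnorm(-abs(z))), statistic = W, method = "normal")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Zero rank variance in either variable
#' yields `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return rho in [-1, 1], or `NA`.
#' @examples
#' spearmanRho(1:4, c(2, 1, 4, 3))  # 0.6
#' @export
spearmanRho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

#' Select the best uncorrelated feature triad
#'
#' Features discriminating LQT3 from the combined LQT1+LQT2 group at
#' rank-sum p below `pGate` are candidates; candidates are ordered by
#' ascending p (ties broken by the larger absolute median difference, then
#' by name), and greedily accepted when their absolute Spearman correlation
#' with every already-accepted feature stays below `rhoThreshold`, stopping
#' at three.
#'
#' @param features feature table (as from [extractCohortFeatures()]) with a
#'   `genotype` column.
#' @param pGate candidate p-value gate.
#' @param rhoThreshold absolute Spearman redundancy threshold.
#' @return a [SelectionResult-class].
#' @export
selectFeatureTriad <- function(features, pGate = 0.005, rhoThreshold = 0.6) {
  stopifnot("genotype" %in% names(features))
  isLqt3 <- features$genotype == "LQT3"
  if (sum(isLqt3) < 2 || sum(!isLqt3) < 2)
    stop("selection error: need >= 2 signals per class")
  feats <- intersect(featureNames(), names(features))
  pv <- vapply(feats, function(f) {
    x <- features[[f]][isLqt3]; y <- features[[f]][!isLqt3]
    ok <- is.finite(x); oky <- is.finite(y)
    if (sum(ok) < 2 || sum(oky) < 2) return(NA_real_)
    rankSumTest(x[ok], y[oky])$p
  }, numeric(1))
  medDiff <- vapply(feats, function(f)
    abs(median(features[[f]][isLqt3], na.rm = TRUE) -
          median(features[[f]][!isLqt3], na.rm = TRUE)), numeric(1))

  cand <- feats[!is.na(pv) & pv < pGate]
  if (length(cand) < 3)
    stop("selection error: only ", length(cand),
         " feature(s) pass the p < ", pGate, " gate; 3 required")
  cand <- cand[order(pv[cand], -medDiff[cand], cand)]

  sub <- features[cand]
  rho <- matrix(NA_real_, length(cand), length(cand),
                dimnames = list(cand, cand))
  for (i in seq_along(cand)) for (j in seq_along(cand)) {
    cc <- complete.cases(sub[[i]], sub[[j]])
    rho[i, j] <- spearmanRho(sub[[i]][cc], sub[[j]][cc])
  }

  selected <- character(0)
  for (f in cand) {
    if (length(selected) == 3) break
    if (all(abs(rho[f, selected]) < rhoThreshold, na.rm = TRUE))
      selected <- c(selected, f)
  }
  if (length(selected) < 3)
    stop("selection error: only ", length(selected),
         " mutually uncorrelated candidate(s) at |rho| < ", rhoThreshold)
  new("SelectionResult", pValues = pv, rhoMatrix = rho, selected = selected)
}
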