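# Independent oracles used across test files.

# Brute-force rank-sum p-value: enumerate every assignment of the pooled
# observations to group A and count rank sums at least as extreme.
bruteRankSumP <- function(a, b) {
  pooled <- c(a, b)
  nA <- length(a)
  r <- rank(pooled)
  W <- sum(r[seq_len(nA)])
  allW <- apply(utils::combn(length(pooled), nA), 2,
                function(ix) sum(r[ix]))
  min(1, 2 * min(mean(allW <= W), mean(allW >= W)))
}

# Monte-Carlo permutation estimator of interventional Shapley values: each
# draw picks a random feature order and a random background row, and
# accumulates the marginal score changes as the explained row's features are
# switched in one by one.
samplingShapley <- function(f, x, bg, nDraws = 1e5, seed = 1) {
  set.seed(seed)
  p <- length(x)
  perms <- replicate(nDraws, sample(p))
  bgIdx <- sample(nrow(bg), nDraws, replace = TRUE)
  Z <- matrix(0, nDraws * (p + 1), p)
  for (d in seq_len(nDraws)) {
    z <- bg[bgIdx[d], ]
    base <- (d - 1) * (p + 1)
    Z[base + 1, ] <- z
    for (k in seq_len(p)) {
      z[perms[k, d]] <- x[perms[k, d]]
      Z[base + 1 + k, ] <- z
    }
  }
  v <- f(Z)
  phi <- numeric(p)
  for (d in seq_len(nDraws)) {
    base <- (d - 1) * (p + 1)
    for (k in seq_len(p))
      phi[perms[k, d]] <- phi[perms[k, d]] + v[base + 1 + k] - v[base + k]
  }
  phi / nDraws
}

# Trapezoid-free analytic integral of a linear ramp segment used as the
# clipped-area reference.
rampAreaOracle <- function(height, duration) height * duration / 2
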