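test_that("group-A durations and ST rise follow the fiducial arithmetic", {
  # fiducial times: QRS_end 0.00, T_on 0.12, T_peak 0.22, T_end 0.34 s
  A <- rep(0, 80)
  A[25] <- 0.1; A[45] <- 0.5   # A(T_on), A(T_peak); A(QRS_end) = 0
  rec <- EcgRecord(A, fs = 200)
  beat <- list(qrs_end = 0L, t_on = 24L, t_peak = 44L, t_end = 68L,
               rr_s = 0.8)
  gA <- timeAmplitudeFeatures(rec, beat)
  expect_equal(gA$tDuration, 0.22)
  expect_equal(gA$tDurationUp, 0.10)
  expect_equal(gA$tDurationDown, 0.12)
  expect_equal(gA$stDuration, 0.12)
  expect_equal(gA$st_rrRatio, 0.15)
  expect_equal(gA$stRise_perc, 0.2)

  # zero numerator and degenerate denominator
  A0 <- A; A0[25] <- 0
  expect_equal(timeAmplitudeFeatures(EcgRecord(A0, 200), beat)$stRise_perc, 0)
  Aflat <- A; Aflat[45] <- 0
  expect_true(is.na(timeAmplitudeFeatures(EcgRecord(Aflat, 200),
                                          beat)$stRise_perc))
})

test_that("clipped rectangle areas track the analytic integral", {
  fs <- 200
  ramp <- seq(0.2, 0.7, length.out = round(0.1 * fs) + 1)
  a <- clippedRectArea(ramp, 0, length(ramp) - 1, baseline = 0.2,
                       polarity = 1, fs = fs, anchor = "end")
  expect_lt(abs(a - rampAreaOracle(0.5, 0.1)), 0.5 / fs * 0.5 + 1e-12)

  aNeg <- clippedRectArea(-ramp, 0, length(ramp) - 1, baseline = -0.2,
                          polarity = -1, fs = fs, anchor = "end")
  expect_equal(aNeg, -a)

  below <- clippedRectArea(rep(0.1, 21), 0, 20, baseline = 0.2,
                           polarity = 1, fs = fs)
  expect_equal(below, 0)
  expect_warning(z <- clippedRectArea(ramp, 5, 5, 0, 1, fs), "empty")
  expect_equal(z, 0)
})

test_that("rectangle areas converge to the integral at rate O(1/fs)", {
  errs <- vapply(c(100, 200, 1000), function(fs) {
    n <- round(0.1 * fs)
    ramp <- seq(0, 0.5, length.out = n + 1)
    a <- clippedRectArea(ramp, 0, n, baseline = 0, polarity = 1, fs = fs,
                         anchor = "end")
    abs(a - rampAreaOracle(0.5, 0.1))
  }, numeric(1))
  expect_true(all(errs <= 0.5 * 0.5 / c(100, 200, 1000) + 1e-12))
  expect_true(all(diff(errs) < 0))
})

test_that("triangular T-waves give symmetric clipped areas and unit ratio", {
  tb <- triangleBeat()
  gB <- curveAreaFeatures(tb$record, tb$beat, polarity = 1)
  expect_equal(gB$tAreaUpc, gB$tAreaDownc)
  expect_lt(abs(gB$tAreaUpc - 0.025), 0.0025)
  expect_lt(abs(gB$tAreac - 0.05), 0.005)
  expect_equal(gB$tAreacUpDownRatio, 1)
  expect_equal(gB$stAreac, 0)  # flat ST at baseline

  # inverted triangle: areas flip sign before the absolute-value rule
  inv <- EcgRecord(-ecgSamples(tb$record), fs = 200)
  gBn <- curveAreaFeatures(inv, tb$beat, polarity = -1)
  expect_equal(gBn$tAreac, -gB$tAreac)
})

test_that("the unit-circle transform maps anchors exactly and is affine-invariant", {
  tb <- triangleBeat()
  A <- ecgSamples(tb$record)
  up <- unitCircleTransform(A, tb$beat$t_on, tb$beat$t_peak, 200)
  expect_equal(up$x[1], -1)
  expect_equal(up$y[1], 0)
  expect_equal(up$x[nrow(up)], 0)
  expect_equal(up$y[nrow(up)], 1)

  upGain <- unitCircleTransform(2 * A + 0.3, tb$beat$t_on, tb$beat$t_peak,
                                200)
  expect_equal(upGain$y, up$y, tolerance = 1e-12)
  expect_equal(upGain$x, up$x, tolerance = 1e-12)

  # uniform time dilation: same samples read at half the sampling rate
  upDilated <- unitCircleTransform(A, tb$beat$t_on, tb$beat$t_peak, 100)
  expect_equal(upDilated$y, up$y, tolerance = 1e-12)
  expect_equal(upDilated$x, up$x, tolerance = 1e-12)

  expect_error(unitCircleTransform(rep(1, 50), 10, 30, 200),
               "degenerate-beat")
})

test_that("unit-circle areas recover known shapes", {
  m <- 200
  # linear ascent: triangle of area 1/2 in the unit square
  ramp <- seq(0, 1, length.out = m + 1)
  rec <- c(0, ramp)  # index 0 unused padding
  xy <- unitCircleTransform(rec, 1, m + 1, 1)
  expect_lt(abs(lqtmorph:::unitArea(xy) - 0.5), 0.5 / m + 1e-9)

  # ascent tracing a quarter circle: area pi/4
  x <- seq(-1, 0, length.out = m + 1)
  quarter <- sqrt(1 - x^2)
  xyq <- unitCircleTransform(quarter, 0, m, 1)
  expect_lt(abs(lqtmorph:::unitArea(xyq) - pi / 4), 2 / m)

  # time-symmetric T-wave: up/down ratio 1
  tb <- triangleBeat()
  gC <- unitCircleFeatures(tb$record, tb$beat)
  expect_lt(abs(gC$ratioUpDown_perc - 1), 1e-6)
  expect_true(gC$oneAreaUp >= 0 && gC$oneAreaDown >= 0 &&
                gC$oneSTTAreaUp >= 0)
})

test_that("rate features are the stated quotients and satisfy their identity", {
  gA <- list(tDuration = 0.22, tDurationUp = 0.1, tDurationDown = 0.12,
             stDuration = 0.12)
  gB <- list(tAreac = 0.05, tAreaUpc = 0.02, tAreaDownc = 0.03, stAreac = 0)
  gD <- rateFeatures(gA, gB)
  expect_equal(gD$tAreacPerSec, 0.05 / 0.22)
  expect_equal(gD$stAreacPerSec, 0)
  lhs <- gD$tAreacUpPerSec
  rhs <- gD$tAreacDownPerSec * (gA$tDurationDown / gA$tDurationUp) *
    (gB$tAreaUpc / gB$tAreaDownc)
  expect_lt(abs(lhs - rhs), 1e-9)
})

test_that("outlier rejection removes exactly the corrupted beats", {
  subj <- gaussianSubject()
  rb <- repeatedBeatRecord(subj, n = 10)
  A <- ecgSamples(rb$record)
  len <- length(A) / 10
  corrupt <- c(3, 7)
  for (k in corrupt) {
    span <- ((k - 1) * len + 30):((k - 1) * len + 90)
    A[span] <- A[span] + 0.8
  }
  rec <- EcgRecord(A, fs = 200)
  kept <- filterOutlierBeats(rec, rb$fiducials, fraction = 0.2)
  expect_equal(setdiff(seq_len(10), kept), corrupt)

  # identical beats: count rule only, feature means unchanged
  keptAll <- filterOutlierBeats(rb$record, rb$fiducials, fraction = 0.2)
  expect_length(keptAll, 8)
  expect_warning(filterOutlierBeats(rb$record, rb$fiducials[1:3, ]),
                 "fewer than 5")
  # n = 60 -> 12 removed
  expect_equal(ceiling(0.2 * 60), 12)
})

test_that("aggregation applies the absolute-value rule and is mirror-symmetric", {
  subj <- gaussianSubject()
  subj$stRise <- 0.03
  rb <- repeatedBeatRecord(subj, n = 3)
  feats <- lapply(seq_len(3), function(i)
    beatFeatures(rb$record, rb$fiducials[i, ]))
  beatMat <- as.data.frame(do.call(rbind, lapply(feats, function(f)
    unlist(f[featureNames()]))))
  pol <- vapply(feats, function(f) as.integer(f$polarity), integer(1))
  aggPos <- aggregateFeatures(beatMat, pol)
  # identical beats: the mean equals any single beat's features
  expect_equal(unname(aggPos$features),
               unname(unlist(feats[[1]][featureNames()])), tolerance = 1e-12)

  # mirror the record around the T-onset amplitude
  aOn <- ecgSamples(rb$record)[rb$fiducials$t_on[1] + 1]
  mir <- EcgRecord(2 * aOn - ecgSamples(rb$record), fs = 200)
  featsM <- lapply(seq_len(3), function(i)
    beatFeatures(mir, rb$fiducials[i, ]))
  beatMatM <- as.data.frame(do.call(rbind, lapply(featsM, function(f)
    unlist(f[featureNames()]))))
  polM <- vapply(featsM, function(f) as.integer(f$polarity), integer(1))
  expect_equal(polM, rep(-1L, 3))
  aggNeg <- aggregateFeatures(beatMatM, polM)
  expect_equal(aggNeg$features, aggPos$features, tolerance = 1e-9)
})

test_that("a hand-computed three-beat mean matches the aggregation", {
  tb <- triangleBeat()
  f1 <- unlist(beatFeatures(tb$record, tb$beat)[featureNames()])
  tb2 <- triangleBeat(height = 0.3)
  f2 <- unlist(beatFeatures(tb2$record, tb2$beat)[featureNames()])
  tb3 <- triangleBeat(halfDur = 0.15)
  f3 <- unlist(beatFeatures(tb3$record, tb3$beat)[featureNames()])
  beatMat <- as.data.frame(rbind(f1, f2, f3))
  agg <- aggregateFeatures(beatMat, c(1L, 1L, 1L))
  expect_equal(agg$features, (f1 + f2 + f3) / 3)
  expect_equal(agg$nBeatsUsed, 3)
})
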