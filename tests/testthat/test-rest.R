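test_that("RR series construction flags out-of-band intervals", {
  fid <- fiducialTable(r_peak = c(0, 160, 320), qrs_end = c(7, 167, 327),
                       t_on = c(30, 190, 350), t_peak = c(50, 210, 370),
                       t_end = c(70, 230, 390), rr_s = c(0.8, 0.8, 0.8))
  rr <- buildRrSeries(fid, 200)
  expect_equal(rr$rr, c(0.8, 0.8))
  expect_true(all(rr$valid))
  expect_equal(rr$nBeats, 3)

  oneBeat <- fid[1, ]
  expect_error(buildRrSeries(oneBeat, 200), "insufficient-data")

  gap <- fiducialTable(r_peak = c(0, 160, 760), qrs_end = c(7, 167, 767),
                       t_on = c(30, 190, 790), t_peak = c(50, 210, 810),
                       t_end = c(70, 230, 830), rr_s = c(0.8, 3.0, 0.8))
  expect_equal(buildRrSeries(gap, 200)$valid, c(TRUE, FALSE))
})

test_that("LF/HF places pure and mixed RR tones in the right bands", {
  t <- cumsum(rep(0.8, 200)); t <- t - t[1]
  hfTone <- lfHfRatio(t, 0.8 + 0.05 * sin(2 * pi * 0.25 * t))$ratio
  lfTone <- lfHfRatio(t, 0.8 + 0.05 * sin(2 * pi * 0.10 * t))$ratio
  mixed <- lfHfRatio(t, 0.8 + 0.05 * sin(2 * pi * 0.10 * t) +
                       0.05 * sin(2 * pi * 0.25 * t))$ratio
  expect_lt(hfTone, 0.1)
  expect_gt(lfTone, 10)
  expect_lt(abs(mixed - 1), 0.3)
  expect_error(lfHfRatio(t[1:10], rep(0.8, 10)), "insufficient-data")
})

test_that("sliding window arithmetic matches the 200/100 beat scheme", {
  mkSeries <- function(n) {
    tt <- cumsum(rep(0.8, n)) - 0.8
    list(time = tt[-n], rr = rep(0.8, n - 1) +
           0.02 * sin(2 * pi * 0.1 * tt[-n]), valid = rep(TRUE, n - 1),
         nBeats = n)
  }
  expect_equal(nrow(slidingLfHf(mkSeries(1000))), 9)
  expect_equal(slidingLfHf(mkSeries(1000))$first_beat, seq(0, 800, 100))
  expect_equal(nrow(slidingLfHf(mkSeries(200))), 1)
  expect_error(slidingLfHf(mkSeries(199)), "insufficient-data")
})

test_that("rest-segment selection follows the quantile/merge/midpoint rules", {
  windows <- data.frame(first_beat = seq(0, 800, 100),
                        last_beat = seq(199, 999, 100),
                        lf_power = 1, hf_power = 1,
                        lf_hf = c(5, 5, 1, 1, 1, 5, 5, 5, 5))
  fid <- data.frame(r_peak = seq(0, by = 160, length.out = 1000))
  seg <- selectRestSegments(windows, startClock = 11 * 3600, fid = fid,
                            fs = 200)
  # rest windows 200-399, 300-499, 400-599 merge to 200-599; mid = 399
  expect_equal(nrow(seg), 1)
  expect_equal(seg$first_beat, 369)
  expect_equal(seg$last_beat, 428)

  # degenerate tie: every window at the quantile -> one maximal section
  windows$lf_hf <- 2
  segAll <- selectRestSegments(windows, 11 * 3600, fid, 200)
  expect_equal(nrow(segAll), 1)
  mid <- (0 + 999) %/% 2
  expect_equal(segAll$first_beat, mid - 30)

  # windows outside the clock window are discarded
  expect_warning(
    none <- selectRestSegments(windows, startClock = 21 * 3600, fid, 200),
    "clock")
  expect_equal(nrow(none), 0)
})

test_that("the rest quantile marks ceil(0.25 n) windows when ratios are distinct", {
  set.seed(11)
  for (n in 4:12) {
    ratios <- sample(seq(0.5, 9.5, length.out = n))
    windows <- data.frame(first_beat = seq(0, by = 100, length.out = n),
                          last_beat = seq(199, by = 100, length.out = n),
                          lf_power = 1, hf_power = 1, lf_hf = ratios)
    q <- quantile(ratios, 0.25, names = FALSE)
    expect_equal(sum(ratios <= q), ceiling(0.25 * n))
  }
})

test_that("window ranking by LF/HF is invariant to RR amplitude scaling", {
  n <- 450
  tt <- cumsum(rep(0.8, n)) - 0.8
  dev <- 0.03 * sin(2 * pi * 0.1 * tt) * (tt < 180) +
    0.03 * sin(2 * pi * 0.25 * tt) * (tt >= 180)
  mk <- function(scale) list(time = tt[-n], rr = 0.8 + scale * dev[-n],
                             valid = rep(TRUE, n - 1), nBeats = n)
  r1 <- slidingLfHf(mk(1))$lf_hf
  r2 <- slidingLfHf(mk(2))$lf_hf
  expect_equal(order(r1), order(r2))
})

test_that("selected segments land inside the generator's designed rest blocks", {
  for (seed in 1:6) {
    spec <- CohortSpec(seed = seed)
    subj <- generateSubjectRecord(spec, defaultArchetypes()$LQT1,
                                  seed = 100 + seed)
    rr <- buildRrSeries(subj$fiducials, 200)
    win <- slidingLfHf(rr)
    seg <- selectRestSegments(win, startClock(subj$record), subj$fiducials,
                              200)
    expect_gte(nrow(seg), 1)
    blocks <- attr(subj$fiducials, "restBeats")
    inside <- any(seg$first_beat[1] >= blocks[, 1] &
                    seg$last_beat[1] <= blocks[, 2])
    expect_true(inside)
  }
})
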