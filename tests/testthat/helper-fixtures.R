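# Shared fixtures, built in code.

# A record holding a single symmetric triangular T-wave: flat baseline, ramp
# 0 -> `height` over `halfDur` seconds, ramp back down. Returns the record
# and the matching fiducial row (0-based indices).
triangleBeat <- function(fs = 200, height = 0.5, halfDur = 0.1, pad = 5) {
  nHalf <- round(halfDur * fs)
  up <- seq(0, height, length.out = nHalf + 1)
  samples <- c(rep(0, pad), up, rev(up)[-1], rep(0, pad))
  tOn <- pad
  list(
    record = EcgRecord(samples, fs = fs),
    beat = list(r_peak = 0L, qrs_end = 2L, t_on = tOn,
                t_peak = tOn + nHalf, t_end = tOn + 2L * nHalf, rr_s = 0.8)
  )
}

# Noise-free Gaussian-flank subject for delineation tests.
gaussianSubject <- function(st = 0.15, sigmaUp = 0.04, sigmaDown = 0.05,
                            tAmp = 0.4, polarity = 1) {
  list(st = st, tAmp = tAmp, sigmaUp = sigmaUp, sigmaDown = sigmaDown,
       bifidOffset = 0, bifidAmpFrac = 0, stRise = 0, polarity = polarity,
       qUp = 2, qDown = 2)
}

# A record of `n` identical noise-free beats plus its fiducials.
repeatedBeatRecord <- function(subject, n = 4, rr = 1.0, fs = 200) {
  b <- generateBeat(defaultArchetypes()$LQT3, rr = rr, fs = fs,
                    subject = subject)
  len <- length(b$samples)
  fid <- do.call(rbind, lapply(seq_len(n), function(i) {
    f <- b$fiducials
    f$beat <- i - 1L
    f[c("r_peak", "qrs_end", "t_on", "t_peak", "t_end")] <-
      f[c("r_peak", "qrs_end", "t_on", "t_peak", "t_end")] + (i - 1L) * len
    f
  }))
  list(record = EcgRecord(rep(b$samples, n), fs = fs),
       fiducials = fid, beat = b)
}

# Small reference cohort shared across statistical tests; generated once per
# session.
.fixtureCache <- new.env(parent = emptyenv())
cachedCohortFeatures <- function() {
  if (is.null(.fixtureCache$features)) {
    cohort <- generateCohort(CohortSpec(nPerGenotype = c(20, 20, 20),
                                        seed = 42))
    .fixtureCache$features <- suppressMessages(extractCohortFeatures(cohort))
  }
  .fixtureCache$features
}
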