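#' Names of the 20 morphology features
#'
#' Group A: times/amplitudes (`tDuration`, `tDurationUp`, `tDurationDown`,
#' `stDuration`, `st_rrRatio`, `stRise_perc`); group B: sign-clipped
#' rectangle areas (`tAreaUpc`, `tAreaDownc`, `tAreac`, `tAreacUpDownRatio`,
#' `stAreac`); group C: unit-circle shape areas (`oneAreaUp`, `oneAreaDown`,
#' `ratioUpDown_perc`, `oneSTTAreaUp`, `ratioSTTUpDown_perc`); group D: rate
#' combinations (`tAreacPerSec`, `tAreacUpPerSec`, `tAreacDownPerSec`,
#' `stAreacPerSec`).
#'
#' @return character vector of length 20.
#' @export
featureNames <- function() c(
  "tDuration", "tDurationUp", "tDurationDown", "stDuration", "st_rrRatio",
  "stRise_perc", "tAreaUpc", "tAreaDownc", "tAreac", "tAreacUpDownRatio",
  "stAreac", "oneAreaUp", "oneAreaDown", "ratioUpDown_perc", "oneSTTAreaUp",
  "ratioSTTUpDown_perc", "tAreacPerSec", "tAreacUpPerSec",
  "tAreacDownPerSec", "stAreacPerSec")

#' Group-A time and amplitude features of one beat
#'
#' Durations are index differences divided by the sampling rate; the ST rise
#' fraction is \eqn{(A(T_{on}) - A(QRS_{end})) / (A(T_{peak}) -
#' A(QRS_{end}))}, `NA` when its denominator vanishes.
#'
#' @param record an [EcgRecord-class].
#' @param beat one fiducial-table row.
#' @return named list: tDuration, tDurationUp, tDurationDown, stDuration,
#'   st_rrRatio, stRise_perc.
#' @export
timeAmplitudeFeatures <- function(record, beat) {
  fs <- samplingRate(record)
  A <- ecgSamples(record)
  tOn <- beat$t_on / fs; tPeak <- beat$t_peak / fs; tEnd <- beat$t_end / fs
  qrsEnd <- beat$qrs_end / fs
  denom <- A[beat$t_peak + 1] - A[beat$qrs_end + 1]
  list(
    tDuration = tEnd - tOn,
    tDurationUp = tPeak - tOn,
    tDurationDown = tEnd - tPeak,
    stDuration = tOn - qrsEnd,
    st_rrRatio = (tOn - qrsEnd) / beat$rr_s,
    stRise_perc = if (denom == 0) NA_real_ else
      (A[beat$t_on + 1] - A[beat$qrs_end + 1]) / denom
  )
}

#' Sign-clipped rectangle area of a waveform interval
#'
#' The samples are shifted by `baseline`; values on the wrong side of the
#' baseline for the given polarity are clipped to zero; the remaining
#' rectangles (width 1/fs, anchored at sample points walking outward from
#' the peak-side endpoint) are summed. The sign of the result follows the
#' polarity.
#'
#' @param samples amplitude series, mV.
#' @param iStart,iEnd 0-based sample indices, `iStart < iEnd`.
#' @param baseline baseline amplitude, mV.
#' @param polarity `+1` (area above baseline) or `-1` (below).
#' @param fs sampling rate, Hz.
#' @param anchor which endpoint is the peak side: `"end"` (rectangles carry
#'   the right-hand sample of each step) or `"start"`.
#' @return area in mV.s.
#' @examples
#' ramp <- seq(0.2, 0.7, length.out = 21)  # 0.1 s at 200 Hz
#' clippedRectArea(ramp, 0, 20, baseline = 0.2, polarity = 1, fs = 200)
#' @export
clippedRectArea <- function(samples, iStart, iEnd, baseline, polarity, fs,
                            anchor = c("end", "start")) {
  anchor <- match.arg(anchor)
  if (iStart >= iEnd) {
    warning("empty interval in clippedRectArea")
    return(0)
  }
  s <- samples[(iStart:iEnd) + 1] - baseline
  if (polarity >= 0) s[s < 0] <- 0 else s[s > 0] <- 0
  s <- if (anchor == "end") s[-1] else s[-length(s)]
  sum(s) / fs
}

#' Group-B clipped-area features of one beat
#'
#' The ascending T area uses the interval \[T_on, T_peak\] with the T-onset
#' amplitude as baseline; the descending area uses \[T_peak, T_end\] with
#' the T-offset amplitude as its own baseline (each limb is shifted so that
#' its outer anchor sits at zero). The ST area spans \[QRS_end, T_on\] with
#' the QRS-end amplitude as baseline, its polarity following the ST
#' direction (rising positive, decreasing negative). Both T areas follow the
#' T polarity. The up/down ratio is `NA` for a beat whose descending area is
#' zero.
#'
#' @inheritParams timeAmplitudeFeatures
#' @param polarity T polarity, +1 or -1 (see [tWavePolarity()]).
#' @return named list: tAreaUpc, tAreaDownc, tAreac, tAreacUpDownRatio,
#'   stAreac.
#' @export
curveAreaFeatures <- function(record, beat, polarity) {
  A <- ecgSamples(record)
  fs <- samplingRate(record)
  up <- clippedRectArea(A, beat$t_on, beat$t_peak, A[beat$t_on + 1],
                        polarity, fs, anchor = "end")
  down <- clippedRectArea(A, beat$t_peak, beat$t_end, A[beat$t_end + 1],
                          polarity, fs, anchor = "start")
  stDir <- if (A[beat$t_on + 1] >= A[beat$qrs_end + 1]) 1 else -1
  st <- clippedRectArea(A, beat$qrs_end, beat$t_on, A[beat$qrs_end + 1],
                        stDir, fs, anchor = "end")
  list(tAreaUpc = up, tAreaDownc = down, tAreac = up + down,
       tAreacUpDownRatio = if (down == 0) NA_real_ else up / down,
       stAreac = st)
}

#' Transform a wave limb onto the unit circle
#'
#' Affine mapping of a monotone limb between an anchor fiducial and the wave
#' peak onto the unit square: the point (time of peak, amplitude of anchor)
#' maps to (0, 0), the peak to (0, 1), and the anchor to (-1, 0) for an
#' ascending limb (anchor before peak) or (1, 0) for a descending one. The
#' transform is invariant to amplitude gain/offset and to uniform time
#' dilation, and handles either T polarity (the normalized amplitude runs 0
#' at the anchor to 1 at the peak in both cases).
#'
#' @param samples amplitude series, mV.
#' @param iAnchor,iPeak 0-based indices of the limb's anchor and peak.
#' @param fs sampling rate, Hz.
#' @return data.frame with columns `x`, `y`.
#' @export
unitCircleTransform <- function(samples, iAnchor, iPeak, fs) {
  if (iAnchor == iPeak)
    stop("degenerate-beat error: anchor and peak coincide")
  aAnchor <- samples[iAnchor + 1]; aPeak <- samples[iPeak + 1]
  span <- aPeak - aAnchor
  if (span == 0)
    stop("degenerate-beat error: zero amplitude span")
  idx <- if (iAnchor < iPeak) iAnchor:iPeak else iPeak:iAnchor
  t <- idx / fs
  x <- (t - iPeak / fs) / abs(iPeak / fs - iAnchor / fs)
  y <- (samples[idx + 1] - aAnchor) / span
  data.frame(x = x, y = y)
}

## Clipped rectangle area of a transformed limb inside the unit square:
## uniform dx, values below y = 0 clipped, rectangles anchored at the peak
## (x = 0) side. Non-negative by construction.
unitArea <- function(xy) {
  y <- xy$y
  y[y < 0] <- 0
  m <- length(y) - 1
  ascending <- xy$x[1] < 0
  dx <- 1 / m
  if (ascending) sum(y[-1]) * dx else sum(y[-length(y)]) * dx
}

#' Group-C unit-circle shape features of one beat
#'
#' Areas of the transformed limbs, always non-negative: `oneAreaUp` for
#' T_on -> T_peak, `oneAreaDown` for T_end -> T_peak, `oneSTTAreaUp` for the
#' whole ST-T ascent anchored at QRS_end, plus the two ratios. Ratios are
#' `NA` for beats with a zero descending area; degenerate (zero amplitude
#' span) limbs make all five values `NA` for the beat.
#'
#' @inheritParams timeAmplitudeFeatures
#' @return named list: oneAreaUp, oneAreaDown, ratioUpDown_perc,
#'   oneSTTAreaUp, ratioSTTUpDown_perc.
#' @export
unitCircleFeatures <- function(record, beat) {
  A <- ecgSamples(record)
  fs <- samplingRate(record)
  res <- tryCatch({
    up <- unitArea(unitCircleTransform(A, beat$t_on, beat$t_peak, fs))
    down <- unitArea(unitCircleTransform(A, beat$t_end, beat$t_peak, fs))
    stt <- unitArea(unitCircleTransform(A, beat$qrs_end, beat$t_peak, fs))
    list(oneAreaUp = up, oneAreaDown = down,
         ratioUpDown_perc = if (down == 0) NA_real_ else up / down,
         oneSTTAreaUp = stt,
         ratioSTTUpDown_perc = if (down == 0) NA_real_ else stt / down)
  }, error = function(e) list(oneAreaUp = NA_real_, oneAreaDown = NA_real_,
                              ratioUpDown_perc = NA_real_,
                              oneSTTAreaUp = NA_real_,
                              ratioSTTUpDown_perc = NA_real_))
  res
}

#' Group-D rate features
#'
#' Area-per-duration quotients that suppress RR-interval influence. A zero
#' duration yields `NA` for the affected quotient.
#'
#' @param groupA result of [timeAmplitudeFeatures()].
#' @param groupB result of [curveAreaFeatures()].
#' @return named list: tAreacPerSec, tAreacUpPerSec, tAreacDownPerSec,
#'   stAreacPerSec (mV).
#' @export
rateFeatures <- function(groupA, groupB) {
  safeDiv <- function(a, b) if (is.na(b) || b == 0) NA_real_ else a / b
  list(
    tAreacPerSec = safeDiv(groupB$tAreac, groupA$tDuration),
    tAreacUpPerSec = safeDiv(groupB$tAreaUpc, groupA$tDurationUp),
    tAreacDownPerSec = safeDiv(groupB$tAreaDownc, groupA$tDurationDown),
    stAreacPerSec = safeDiv(groupB$stAreac, groupA$stDuration)
  )
}

#' All 20 features of one beat
#'
#' @inheritParams timeAmplitudeFeatures
#' @return named list of the 20 features plus `polarity`; a beat whose T
#'   polarity is degenerate returns all-`NA` features.
#' @export
beatFeatures <- function(record, beat) {
  pol <- tryCatch(tWavePolarity(record, beat), error = function(e) NA_integer_)
  if (is.na(pol)) {
    out <- as.list(rep(NA_real_, 20))
    names(out) <- featureNames()
    out$polarity <- NA_integer_
    return(out)
  }
  gA <- timeAmplitudeFeatures(record, beat)
  gB <- curveAreaFeatures(record, beat, pol)
  gC <- unitCircleFeatures(record, beat)
  gD <- rateFeatures(gA, gB)
  out <- c(gA[c("tDuration", "tDurationUp", "tDurationDown", "stDuration",
                "st_rrRatio", "stRise_perc")],
           gB[c("tAreaUpc", "tAreaDownc", "tAreac", "tAreacUpDownRatio",
                "stAreac")],
           gC, gD)
  out <- out[featureNames()]
  out$polarity <- pol
  out
}

#' Reject outlier beats by template RMSE
#'
#' Beats are aligned on the R peak, linearly resampled to a common length,
#' compared against the pointwise mean-beat template, and the
#' `ceil(fraction * n)` beats with the highest root-mean-square error are
#' removed. With fewer than 5 beats no filtering is applied (warning).
#'
#' @param record an [EcgRecord-class].
#' @param fid fiducial table rows to consider.
#' @param fraction fraction of beats to remove.
#' @return integer indices (rows of `fid`) of the retained beats.
#' @export
filterOutlierBeats <- function(record, fid, fraction = 0.2) {
  n <- nrow(fid)
  if (n < 5) {
    warning("fewer than 5 beats; outlier filtering skipped")
    return(seq_len(n))
  }
  A <- ecgSamples(record)
  fs <- samplingRate(record)
  m <- 100
  mat <- t(vapply(seq_len(n), function(i) {
    len <- max(2, round(fid$rr_s[i] * fs))
    i0 <- fid$r_peak[i] + 1
    i1 <- min(length(A), i0 + len - 1)
    seg <- A[i0:i1]
    stats::approx(seq_along(seg), seg, n = m)$y
  }, numeric(m)))
  template <- colMeans(mat)
  rmse <- sqrt(rowMeans((mat - rep(template, each = n))^2))
  drop <- order(rmse, decreasing = TRUE)[seq_len(ceiling(fraction * n))]
  sort(setdiff(seq_len(n), drop))
}

#' Aggregate per-beat features to one signal row
#'
#' Every feature of a negative-T beat is replaced by its absolute value
#' before averaging; the per-feature mean is then taken over the retained
#' beats, with missing per-beat values (vanished ratio denominators,
#' degenerate limbs) excluded pairwise.
#'
#' @param beatMat data.frame of per-beat features (one row per beat, columns
#'   [featureNames()]).
#' @param polarities per-beat polarity vector (+1/-1).
#' @return list with `features` (named numeric vector of length 20) and
#'   `nBeatsUsed`; `NULL` when every beat is degenerate.
#' @export
aggregateFeatures <- function(beatMat, polarities) {
  keep <- !is.na(polarities)
  if (!any(keep)) return(NULL)
  m <- as.matrix(beatMat[keep, featureNames(), drop = FALSE])
  neg <- polarities[keep] == -1
  m[neg, ] <- abs(m[neg, , drop = FALSE])
  means <- colMeans(m, na.rm = TRUE)
  means[!is.finite(means)] <- NA_real_
  list(features = means, nBeatsUsed = sum(keep))
}

#' Extract the signal-level feature row from selected segments
#'
#' Computes per-beat features inside each resting segment, applies the
#' template-RMSE outlier rejection, aggregates, and keeps the segment that
#' retained the most beats (ties broken by segment order), replacing the
#' manual best-signal choice with a deterministic rule.
#'
#' @param record an [EcgRecord-class].
#' @param fid fiducial table.
#' @param segments data.frame from [selectRestSegments()].
#' @param outlierFraction fraction of beats rejected as outliers.
#' @return one-row data.frame (`record_id`, 20 features, `n_beats_used`), or
#'   `NULL` when no segment yields usable beats.
#' @export
extractSignalFeatures <- function(record, fid, segments,
                                  outlierFraction = 0.2) {
  best <- NULL
  for (k in seq_len(nrow(segments))) {
    rows <- which(fid$beat >= segments$first_beat[k] &
                    fid$beat <= segments$last_beat[k])
    if (!length(rows)) next
    sub <- fid[rows, , drop = FALSE]
    retained <- filterOutlierBeats(record, sub, outlierFraction)
    sub <- sub[retained, , drop = FALSE]
    feats <- lapply(seq_len(nrow(sub)), function(i)
      beatFeatures(record, sub[i, ]))
    beatMat <- as.data.frame(do.call(rbind, lapply(feats, function(f)
      unlist(f[featureNames()]))))
    pol <- vapply(feats, function(f) as.integer(f$polarity), integer(1))
    agg <- aggregateFeatures(beatMat, pol)
    if (is.null(agg)) next
    if (is.null(best) || agg$nBeatsUsed > best$nBeatsUsed) best <- agg
  }
  if (is.null(best)) {
    logWarn("signal ", recordId(record), " excluded: no usable beats")
    return(NULL)
  }
  out <- data.frame(record_id = recordId(record), t(best$features))
  out$n_beats_used <- best$nBeatsUsed
  out
}

#' Feature table for a whole cohort
#'
#' Runs RR-series construction, sliding LF/HF windows, resting-segment
#' selection and feature extraction for every record and stacks the
#' per-signal rows with their genotype labels.
#'
#' @param cohort list of per-subject lists (`record`, `fiducials`, `label`),
#'   as produced by [generateCohort()].
#' @param outlierFraction outlier-beat fraction.
#' @param restFraction,segmentBeats,windowBeats,offsetBeats rest-selection
#'   constants, see [selectRestSegments()] and [slidingLfHf()].
#' @return data.frame: `record_id`, `genotype`, 20 features, `n_beats_used`.
#' @export
extractCohortFeatures <- function(cohort, outlierFraction = 0.2,
                                  restFraction = 0.25, segmentBeats = 60,
                                  windowBeats = 200, offsetBeats = 100) {
  rows <- list()
  for (subj in cohort) {
    row <- tryCatch({
      rr <- buildRrSeries(subj$fiducials, samplingRate(subj$record))
      win <- slidingLfHf(rr, windowBeats, offsetBeats)
      seg <- selectRestSegments(win, startClock(subj$record),
                                subj$fiducials, samplingRate(subj$record),
                                restFraction, segmentBeats)
      if (nrow(seg) == 0) NULL else
        extractSignalFeatures(subj$record, subj$fiducials, seg,
                              outlierFraction)
    }, error = function(e) {
      logWarn("record ", recordId(subj$record), " skipped: ",
              conditionMessage(e))
      NULL
    })
    if (!is.null(row)) {
      row$genotype <- subj$label
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  out[c("record_id", "genotype", featureNames(), "n_beats_used")]
}
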