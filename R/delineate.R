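## Baseline delineator: deliberately simple, swappable behind the fiducial
## table interface. The pipeline's scientific core consumes fiducials, not
## this algorithm; externally produced fiducial files bypass it entirely.

#' Delineate beats with a simple baseline algorithm
#'
#' Given R-peak positions, locates per beat: QRS end (first point after R
#' where the absolute slope stays below 10\% of the maximal QRS slope for at
#' least 20 ms), the T apex (extremum of the baseline-subtracted amplitude in
#' a window from QRS end + 80 ms to the next R - 160 ms), and T onset/offset
#' by the tangent method (intersection of the maximum-slope tangent of each
#' T flank with the local baseline, taken at the QRS-end amplitude). Beats
#' whose T window is flat relative to the noise floor are marked
#' undelineatable and excluded. The last beat (no following R) is dropped.
#'
#' @param record an [EcgRecord-class].
#' @param rPeaks integer 0-based R-peak sample indices.
#' @return a validated fiducial table; excluded beats are absent. The number
#'   of excluded beats is reported via the log.
#' @export
baselineDelineate <- function(record, rPeaks) {
  fs <- samplingRate(record)
  A <- ecgSamples(record)
  n <- length(A)
  ms <- function(x) round(x * fs / 1000)
  slope <- c(diff(A), 0) * fs

  rows <- list()
  excluded <- 0L
  for (i in seq_len(length(rPeaks) - 1)) {
    r <- rPeaks[i]; nextR <- rPeaks[i + 1]
    row <- tryCatch({
      qlo <- max(1, r + 1 - ms(40)); qhi <- min(n, r + 1 + ms(60))
      maxSlope <- max(abs(slope[qlo:qhi]))
      w <- max(1, ms(20))
      qrsEnd <- NA_integer_
      for (j in (r + 1 + ms(10)):(r + 1 + ms(150))) {
        if (j + w - 1 > n) break
        if (all(abs(slope[j:(j + w - 1)]) < 0.1 * maxSlope)) {
          qrsEnd <- j - 1L  # 0-based
          break
        }
      }
      if (is.na(qrsEnd)) stop("no QRS end")
      baseline <- A[qrsEnd + 1]

      wLo <- qrsEnd + ms(80); wHi <- nextR - ms(160)
      if (wHi - wLo < ms(40)) stop("T window too short")
      win <- (wLo:wHi) + 1
      sm <- stats::filter(A[win], rep(1 / 5, 5), sides = 2)
      resid <- A[win] - sm
      noiseFloor <- mad(resid, na.rm = TRUE)
      dev <- A[win] - baseline
      if (max(abs(dev)) < max(2 * noiseFloor, 0.02)) stop("flat T window")

      tPeak <- wLo + which.max(abs(dev)) - 1L
      pol <- sign(A[tPeak + 1] - baseline)

      tangentCross <- function(idx, flankSign) {
        s <- slope[idx + 1] * flankSign * pol
        m <- idx[which.max(s)]
        sm <- slope[m + 1]
        tx <- m / fs + (baseline - A[m + 1]) / sm
        as.integer(round(tx * fs))
      }
      up <- seq(qrsEnd + 1, tPeak - 1)
      tOn <- tangentCross(up, +1)
      tOn <- max(qrsEnd + 1L, min(tOn, tPeak - 1L))
      down <- seq(tPeak, min(wHi + ms(120), nextR - 1))
      tEnd <- tangentCross(down, -1)
      tEnd <- max(tPeak + 1L, min(tEnd, nextR - 1L))

      data.frame(beat = i - 1L, r_peak = r, qrs_end = qrsEnd, t_on = tOn,
                 t_peak = tPeak, t_end = tEnd, rr_s = (nextR - r) / fs)
    }, error = function(e) NULL)
    if (is.null(row)) excluded <- excluded + 1L else
      rows[[length(rows) + 1L]] <- row
  }
  if (excluded > 0)
    logWarn(excluded, " beat(s) undelineatable and excluded")
  if (!length(rows))
    return(validateFiducials(data.frame(beat = integer(0),
      r_peak = integer(0), qrs_end = integer(0), t_on = integer(0),
      t_peak = integer(0), t_end = integer(0), rr_s = numeric(0))))
  validateFiducials(do.call(rbind, rows))
}

#' T-wave polarity of a beat
#'
#' @param record an [EcgRecord-class].
#' @param beat one row of a fiducial table.
#' @return `+1` for an upright T (apex above onset), `-1` for an inverted T.
#'   Equal amplitudes raise a degenerate-beat error.
#' @export
tWavePolarity <- function(record, beat) {
  A <- ecgSamples(record)
  aPeak <- A[beat$t_peak + 1]; aOn <- A[beat$t_on + 1]
  if (aPeak == aOn) stop("degenerate-beat error: flat T-wave")
  if (aPeak > aOn) 1L else -1L
}
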