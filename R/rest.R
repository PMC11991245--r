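#' @importFrom stats lm mad quantile sd spline fft
NULL

#' Build an RR series from fiducials
#'
#' RR intervals are successive R-peak differences; intervals outside the
#' physiological band [0.3, 2.0] s are flagged invalid and excluded from the
#' spectral windows downstream.
#'
#' @param fid fiducial table (see [fiducialTable()]).
#' @param fs sampling rate, Hz.
#' @return list with `time` (seconds from record start, at the interval's
#'   first beat), `rr` (seconds), `valid` (logical), `nBeats` (number of
#'   beats in the fiducial table).
#' @export
buildRrSeries <- function(fid, fs) {
  if (nrow(fid) < 2)
    stop("insufficient-data error: need at least 2 beats for an RR series")
  rp <- fid$r_peak
  rr <- diff(rp) / fs
  valid <- rr >= 0.3 & rr <= 2.0
  if (any(!valid))
    logWarn(sum(!valid), " RR interval(s) outside [0.3, 2.0] s flagged")
  list(time = rp[-length(rp)] / fs, rr = rr, valid = valid,
       nBeats = nrow(fid))
}

## Welch PSD: Hann-windowed segments of `segLen` samples with 50% overlap,
## one-sided, normalized so that band integrals approximate variance. Series
## shorter than a segment fall back to a single full-length segment.
welchPsd <- function(x, fsr, segLen = 256, overlap = 0.5) {
  n <- length(x)
  L <- min(segLen, n)
  step <- max(1, floor(L * (1 - overlap)))
  starts <- seq(1, n - L + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(L - 1)) / (L - 1)))
  norm <- fsr * sum(w^2)
  nf <- floor(L / 2) + 1
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + L - 1)] * w
    p <- Mod(fft(seg))[1:nf]^2 / norm
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
    acc <- acc + p
  }
  list(freq = (0:(nf - 1)) * fsr / L, psd = acc / length(starts))
}

trapzBand <- function(freq, psd, lo, hi) {
  keep <- freq >= lo & freq <= hi
  if (sum(keep) < 2) return(0)
  f <- freq[keep]; p <- psd[keep]
  sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
}

#' LF/HF sympathovagal ratio of an RR window
#'
#' The RR tachogram is linearly detrended, resampled at 4 Hz by cubic
#' interpolation, and its Welch power spectral density (64-s Hann segments,
#' 50\% overlap) integrated by trapezoid over the low-frequency
#' (0.04--0.15 Hz) and high-frequency (0.15--0.40 Hz) bands.
#'
#' @param time beat times of the RR intervals, seconds.
#' @param rr RR intervals, seconds.
#' @return list with `lf`, `hf` (band powers, ms^2) and `ratio` (LF/HF;
#'   `Inf` with a warning when the HF power is zero).
#' @examples
#' t <- cumsum(rep(0.8, 200)); t <- t - t[1]
#' rr <- 0.8 + 0.05 * sin(2 * pi * 0.25 * t)
#' lfHfRatio(t, rr)$ratio   # pure HF tone: ratio well below 1
#' @export
lfHfRatio <- function(time, rr) {
  if (length(rr) < 30)
    stop("insufficient-data error: need >= 30 beats for LF/HF")
  detr <- stats::residuals(lm(rr ~ time))
  grid <- seq(min(time), max(time), by = 0.25)
  x <- spline(time, detr, xout = grid, method = "fmm")$y
  ps <- welchPsd(x, fsr = 4, segLen = 256, overlap = 0.5)
  lf <- trapzBand(ps$freq, ps$psd, 0.04, 0.15) * 1e6
  hf <- trapzBand(ps$freq, ps$psd, 0.15, 0.40) * 1e6
  if (hf == 0) {
    warning("HF power is zero; LF/HF reported as Inf")
    return(list(lf = lf, hf = hf, ratio = Inf))
  }
  list(lf = lf, hf = hf, ratio = lf / hf)
}

#' Sliding LF/HF windows over a record
#'
#' Computes the LF/HF ratio in windows of `windowBeats` beats advanced by
#' `offsetBeats`; a trailing partial window is discarded.
#'
#' @param rrSeries result of [buildRrSeries()].
#' @param windowBeats,offsetBeats window length and hop, in beats.
#' @return data.frame with columns `first_beat`, `last_beat` (0-based,
#'   inclusive), `lf_power`, `hf_power`, `lf_hf`.
#' @export
slidingLfHf <- function(rrSeries, windowBeats = 200, offsetBeats = 100) {
  n <- rrSeries$nBeats
  if (n < windowBeats)
    stop("insufficient-data error: ", n, " beats < window of ", windowBeats)
  starts <- seq(0, n - windowBeats, by = offsetBeats)
  rows <- lapply(starts, function(s) {
    idx <- seq(s + 1, s + windowBeats - 1)   # intervals inside the window
    keep <- idx[rrSeries$valid[idx]]
    res <- lfHfRatio(rrSeries$time[keep], rrSeries$rr[keep])
    data.frame(first_beat = s, last_beat = s + windowBeats - 1,
               lf_power = res$lf, hf_power = res$hf, lf_hf = res$ratio)
  })
  do.call(rbind, rows)
}

#' Select resting 60-beat segments from LF/HF windows
#'
#' Windows whose beats fall entirely inside the 10:00--20:00 vigilance clock
#' window and whose LF/HF lies at or below the empirical `restFraction`
#' quantile are declared resting. Overlapping or adjacent resting windows are
#' merged into maximal resting sections; from the two most extended sections
#' (ties broken by earlier start) the `segmentBeats` beats centred on the
#' section's floor-midpoint are returned. Sections shorter than
#' `segmentBeats` are skipped.
#'
#' @param windows data.frame from [slidingLfHf()].
#' @param startClock record start, seconds since midnight.
#' @param fid fiducial table (for beat wall-clock times).
#' @param fs sampling rate, Hz.
#' @param restFraction quantile declaring rest (0.25 = lowest quartile).
#' @param segmentBeats segment length in beats.
#' @return data.frame with columns `segment_index`, `first_beat`,
#'   `last_beat` (0-based, inclusive); zero rows, with a warning, when no
#'   resting section is long enough.
#' @export
selectRestSegments <- function(windows, startClock, fid, fs,
                               restFraction = 0.25, segmentBeats = 60) {
  beatClock <- startClock + fid$r_peak / fs
  inClock <- function(first, last) {
    t0 <- beatClock[first + 1]; t1 <- beatClock[last + 1]
    t0 >= 10 * 3600 && t1 < 20 * 3600
  }
  keep <- mapply(inClock, windows$first_beat, windows$last_beat)
  windows <- windows[keep, , drop = FALSE]
  empty <- data.frame(segment_index = integer(0), first_beat = integer(0),
                      last_beat = integer(0))
  if (nrow(windows) == 0) {
    warning("no LF/HF windows inside the 10:00-20:00 clock window")
    return(empty)
  }
  finite <- is.finite(windows$lf_hf)
  q <- quantile(windows$lf_hf[finite], restFraction, names = FALSE)
  rest <- windows[finite & windows$lf_hf <= q, , drop = FALSE]
  rest <- rest[order(rest$first_beat), , drop = FALSE]

  sections <- list()
  for (i in seq_len(nrow(rest))) {
    f <- rest$first_beat[i]; l <- rest$last_beat[i]
    if (length(sections) && f <= sections[[length(sections)]][2] + 1)
      sections[[length(sections)]][2] <-
        max(sections[[length(sections)]][2], l)
    else sections[[length(sections) + 1L]] <- c(f, l)
  }
  lens <- vapply(sections, function(s) s[2] - s[1] + 1, numeric(1))
  ok <- lens >= segmentBeats
  if (!any(ok)) {
    warning("no resting section of at least ", segmentBeats, " beats")
    return(empty)
  }
  sections <- sections[ok]; lens <- lens[ok]
  ord <- order(-lens, vapply(sections, `[`, numeric(1), 1))
  sections <- sections[ord][seq_len(min(2, length(sections)))]

  half <- segmentBeats %/% 2
  out <- lapply(seq_along(sections), function(k) {
    s <- sections[[k]]
    mid <- (s[1] + s[2]) %/% 2
    data.frame(segment_index = k - 1L, first_beat = mid - half,
               last_beat = mid + half - 1L)
  })
  do.call(rbind, out)
}
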