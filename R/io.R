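#' @importFrom utils read.csv write.csv
NULL

## Conventions used throughout: amplitudes in mV, time in seconds, fiducials
## as 0-based sample indices (converted with +1 only at the point of
## subscripting a sample vector).

pkgLog <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}
logInfo <- function(...) pkgLog("INFO", ...)
logWarn <- function(...) pkgLog("WARN", ...)

fiducialCols <- c("beat", "r_peak", "qrs_end", "t_on", "t_peak", "t_end",
                  "rr_s")

#' Build and validate a fiducial table
#'
#' A fiducial table carries, per beat, the 0-based sample indices of the five
#' landmarks the whole feature system is anchored on (R peak, QRS end, T
#' onset, T apex, T offset) plus the RR interval in seconds. Within a beat
#' the ordering \code{qrs_end < t_on <= t_peak <= t_end} must hold, indices
#' must increase strictly from beat to beat, and RR must be positive.
#'
#' @param r_peak,qrs_end,t_on,t_peak,t_end integer 0-based sample indices.
#' @param rr_s numeric RR interval per beat, seconds.
#' @param beat optional beat numbers (0-based; default sequential).
#' @return A validated \code{data.frame} with columns
#'   \code{beat, r_peak, qrs_end, t_on, t_peak, t_end, rr_s}.
#' @examples
#' fiducialTable(r_peak = 10, qrs_end = 30, t_on = 50, t_peak = 70,
#'               t_end = 100, rr_s = 0.8)
#' @export
fiducialTable <- function(r_peak, qrs_end, t_on, t_peak, t_end, rr_s,
                          beat = seq_along(r_peak) - 1L) {
  fid <- data.frame(beat = as.integer(beat), r_peak = as.integer(r_peak),
                    qrs_end = as.integer(qrs_end), t_on = as.integer(t_on),
                    t_peak = as.integer(t_peak), t_end = as.integer(t_end),
                    rr_s = as.numeric(rr_s))
  validateFiducials(fid)
}

#' @rdname fiducialTable
#' @param fid a candidate fiducial data.frame.
#' @export
validateFiducials <- function(fid) {
  stopifnot(is.data.frame(fid))
  missing <- setdiff(fiducialCols, names(fid))
  if (length(missing))
    stop("fiducial table lacks columns: ", paste(missing, collapse = ", "))
  fid <- fid[fiducialCols]
  if (nrow(fid) == 0) return(fid)
  bad <- with(fid, !(r_peak < qrs_end & qrs_end < t_on & t_on <= t_peak &
                       t_peak <= t_end))
  if (any(bad))
    stop("fiducial-order error: beats ",
         paste(fid$beat[bad], collapse = ", "),
         " violate r_peak < qrs_end < t_on <= t_peak <= t_end")
  if (any(fid$rr_s <= 0))
    stop("fiducial table has non-positive RR intervals")
  if (nrow(fid) > 1) {
    prev_end <- fid$t_end[-nrow(fid)]
    if (any(fid$r_peak[-1] <= prev_end))
      stop("fiducial indices must increase strictly across beats")
  }
  fid
}

#' Read / write a single-lead ECG record
#'
#' The signal CSV format has columns \code{time_s, amplitude_mV}; record
#' metadata (id, sampling rate, start clock, lead) travels in commented
#' header lines of the form \code{# key=value}. When a time column is
#' present, sampling must be uniform to within 1e-6 s, and the sampling rate
#' is inferred from it unless the header states one.
#'
#' @param path file path.
#' @return `readEcg`: an [EcgRecord-class]; `writeEcg`: `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeEcg(EcgRecord(c(0.1, 0.2, 0.1), fs = 200), f)
#' readEcg(f)
#' @export
readEcg <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  header <- character()
  con <- file(path, "r")
  on.exit(close(con))
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || !startsWith(line, "#")) break
    header <- c(header, sub("^#\\s*", "", line))
  }
  meta <- list()
  for (h in header) {
    kv <- strsplit(h, "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  dat <- tryCatch(read.csv(path, comment.char = "#"),
                  error = function(e) stop("format error: ",
                                           conditionMessage(e)))
  if (!"amplitude_mV" %in% names(dat))
    stop("format error: signal CSV needs an 'amplitude_mV' column")
  fs <- if (!is.null(meta$fs)) as.numeric(meta$fs) else NA_real_
  if ("time_s" %in% names(dat) && nrow(dat) >= 2) {
    dt <- diff(dat$time_s)
    if (max(dt) - min(dt) > 1e-6 || any(dt <= 0))
      stop("sampling error: time column is not uniform within 1e-6 s")
    if (is.na(fs)) fs <- 1 / mean(dt)
  }
  if (is.na(fs))
    stop("format error: sampling rate not given and no time column")
  EcgRecord(dat$amplitude_mV, fs = fs,
            recordId = meta$record_id %||% "record",
            startClock = as.numeric(meta$start_clock_s %||% 0),
            lead = meta$lead %||% "I")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname readEcg
#' @param record an [EcgRecord-class] to write.
#' @export
writeEcg <- function(record, path) {
  stopifnot(is(record, "EcgRecord"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# record_id=", recordId(record)),
    paste0("# fs=", format(samplingRate(record), digits = 15)),
    paste0("# start_clock_s=", format(startClock(record), digits = 15)),
    paste0("# lead=", leadName(record)),
    "time_s,amplitude_mV"), con)
  t <- (seq_along(ecgSamples(record)) - 1) / samplingRate(record)
  writeLines(paste(format(t, digits = 12, trim = TRUE, scientific = FALSE),
                   format(ecgSamples(record), digits = 15, trim = TRUE),
                   sep = ","), con)
  invisible(path)
}

#' Read / write a fiducial table
#'
#' Fiducial CSVs have the columns
#' \code{beat, r_peak, qrs_end, t_on, t_peak, t_end, rr_s} with 0-based
#' sample indices. Reading validates the per-beat ordering invariants; an
#' empty file yields an empty table with a warning.
#'
#' @param path file path.
#' @return `readFiducials`: a validated fiducial \code{data.frame};
#'   `writeFiducials`: `path`, invisibly.
#' @export
readFiducials <- function(path) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  dat <- tryCatch(read.csv(path),
                  error = function(e) stop("format error: ",
                                           conditionMessage(e)))
  if (nrow(dat) == 0) {
    warning("empty fiducial file: ", path)
    return(validateFiducials(cbind(dat[0, , drop = FALSE],
      as.data.frame(sapply(setdiff(fiducialCols, names(dat)),
                           function(x) numeric(0), simplify = FALSE)))))
  }
  validateFiducials(dat)
}

#' @rdname readFiducials
#' @param fid a fiducial table.
#' @export
writeFiducials <- function(fid, path) {
  write.csv(validateFiducials(fid), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
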