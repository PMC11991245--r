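#' @importFrom stats rnorm runif
NULL

## Beat-construction constants (seconds). The stylized beat places the R apex
## at T_R and closes the QRS a fixed 35 ms later; both are far enough from the
## ST-T complex that the QRS Gaussians are numerically zero there.
T_R <- 0.05
QRS_END_OFFSET <- 0.035
ENV_THRESHOLD <- 0.01          # T onset/offset = 1% of the T amplitude
K_ENV <- sqrt(2 * log(1 / ENV_THRESHOLD))  # Gaussian half-width to the 1% point

#' Default genotype archetypes
#'
#' Stylized ST-T morphologies for the three major LQTS genotypes: LQT1 with a
#' short ST segment and a broad-based T-wave, LQT2 with a low-amplitude bifid
#' T, and LQT3 with a long isoelectric ST followed by a late, narrow, peaked
#' T. Between-subject spreads are deliberately wide enough that genotypes
#' overlap partially — mirroring the documented overlap of LQT1 and LQT3
#' repolarization patterns — so that downstream feature statistics face a
#' realistic, not a trivially separable, cohort.
#'
#' @return Named list of three [GenotypeArchetype-class] objects.
#' @export
defaultArchetypes <- function() {
  list(
    LQT1 = GenotypeArchetype("LQT1",
      stDuration = c(0.050, 0.045), tAmp = c(0.33, 0.06),
      sigmaUp = c(0.075, 0.012), sigmaDown = c(0.055, 0.016),
      stRiseMv = c(0.016, 0.009), negTProb = 0.05),
    LQT2 = GenotypeArchetype("LQT2",
      stDuration = c(0.065, 0.045), tAmp = c(0.15, 0.04),
      sigmaUp = c(0.055, 0.015), sigmaDown = c(0.055, 0.016),
      bifidOffset = 0.06, bifidAmpFrac = 0.75,
      stRiseMv = c(0.016, 0.009), negTProb = 0.15),
    LQT3 = GenotypeArchetype("LQT3",
      stDuration = c(0.155, 0.060), tAmp = c(0.42, 0.05),
      sigmaUp = c(0.038, 0.016), sigmaDown = c(0.055, 0.016),
      stRiseMv = c(0.036, 0.009), negTProb = 0.05)
  )
}

## Truncated-normal draw: +-1.8 sd, then floored at `lo`. Keeps extreme
## subjects off the infeasible tail without reshaping the bulk.
rnormClip <- function(mean, sd, lo) {
  z <- max(-1.8, min(1.8, rnorm(1)))
  max(lo, mean + sd * z)
}

## Draw one subject's morphology parameters from an archetype. Subjects whose
## combined ST-T extent would not fit the resting RR budget are redrawn.
drawSubjectParams <- function(archetype, maxExtent = 0.77) {
  for (i in 1:50) {
    p <- list(
      st = rnormClip(archetype@stDuration[1], archetype@stDuration[2], 0.015),
      tAmp = rnormClip(archetype@tAmp[1], archetype@tAmp[2], 0.05),
      sigmaUp = rnormClip(archetype@sigmaUp[1], archetype@sigmaUp[2], 0.015),
      sigmaDown = rnormClip(archetype@sigmaDown[1], archetype@sigmaDown[2],
                            0.020),
      bifidOffset = archetype@bifidOffset,
      bifidAmpFrac = archetype@bifidAmpFrac,
      stRise = rnormClip(archetype@stRiseMv[1], archetype@stRiseMv[2], 0.004),
      polarity = if (runif(1) < archetype@negTProb) -1 else 1,
      ## flank convexity exponents: 2 = Gaussian; drawn per subject with no
      ## genotype dependence, so wave *shape* varies independently of the
      ## flank *widths* (the widths set the 1%-threshold durations exactly)
      qUp = min(4.0, max(1.25, 2 * exp(0.45 * rnorm(1)))),
      qDown = min(4.0, max(1.25, 2 * exp(0.45 * rnorm(1))))
    )
    p <- capBifidSigma(p)
    if (sttExtent(p) <= maxExtent) return(p)
  }
  p$st <- max(0.015, maxExtent - (sttExtent(p) - p$st))
  p
}

## Time from beat onset to the end of the T envelope.
sttExtent <- function(p) {
  down <- descendExtent(p)
  T_R + QRS_END_OFFSET + p$st + K_ENV * p$sigmaUp + down
}

descendExtent <- function(p) {
  ext <- K_ENV * p$sigmaDown
  if (p$bifidOffset > 0 && p$bifidAmpFrac > 0)
    ext <- max(ext, p$bifidOffset + K_ENV * p$sigmaDown)
  ext
}

## Per-beat multiplicative jitter around the subject's values.
jitterParams <- function(p) {
  p$st <- max(0.012, p$st * (1 + 0.04 * rnorm(1)))
  p$tAmp <- max(0.04, p$tAmp * (1 + 0.05 * rnorm(1)))
  p$sigmaUp <- max(0.012, p$sigmaUp * (1 + 0.03 * rnorm(1)))
  p$sigmaDown <- max(0.015, p$sigmaDown * (1 + 0.03 * rnorm(1)))
  p$stRise <- max(0.002, p$stRise * (1 + 0.08 * rnorm(1)))
  capBifidSigma(p)
}

## For bifid T-waves the second hump's ascending tail must stay below the 1%
## envelope threshold at the designed T onset, otherwise the onset fiducial
## would jump to the ST segment; capping the descending width enforces this.
capBifidSigma <- function(p) {
  if (p$bifidOffset > 0 && p$bifidAmpFrac > 0)
    p$sigmaDown <- min(p$sigmaDown,
                       (K_ENV * p$sigmaUp + p$bifidOffset) / 3.2)
  p
}

#' Generate one stylized ECG beat with ground-truth fiducials
#'
#' Constructs a single beat: a narrow stylized QRS (R spike with Q/S dips),
#' an isoelectric-to-gently-rising ST segment of the drawn duration, and a
#' T-wave with generalized-Gaussian flanks whose widths are parameterized by
#' their 1%-threshold extent and whose convexity exponents vary per subject
#' (a second hump is added when the archetype is bifid). The emitted
#' fiducials are the exact construction points: QRS end a fixed 35 ms after
#' the R apex, T onset/offset where the T envelope crosses
#' 1\% of the T amplitude, T apex at the envelope maximum.
#'
#' @param archetype a [GenotypeArchetype-class].
#' @param rr beat length, seconds; must exceed the ST-T extent.
#' @param fs sampling rate, Hz.
#' @param subject optional pre-drawn subject parameter list (internal); when
#'   `NULL` the beat draws its own parameters from the archetype.
#' @param jitter logical, apply per-beat morphology jitter.
#' @return list with `samples` (numeric, `round(rr * fs)` values, mV),
#'   `fiducials` (one-row data.frame of 0-based indices within the beat plus
#'   `rr_s`), and `params` (the realized parameter list).
#' @examples
#' b <- generateBeat(defaultArchetypes()$LQT3, rr = 1.0, fs = 200)
#' b$fiducials
#' @export
generateBeat <- function(archetype, rr, fs, subject = NULL, jitter = FALSE) {
  p <- if (is.null(subject)) drawSubjectParams(archetype) else subject
  if (jitter) p <- jitterParams(p)
  core <- beatCore(p, rr, fs)
  fid <- data.frame(beat = 0L, r_peak = core$fid[1], qrs_end = core$fid[2],
                    t_on = core$fid[3], t_peak = core$fid[4],
                    t_end = core$fid[5], rr_s = length(core$samples) / fs)
  list(samples = core$samples, fiducials = fid, params = p)
}

## Vectorized beat construction; QRS and T-wave exponentials are evaluated
## only on the sample ranges where they are non-negligible.
beatCore <- function(p, rr, fs) {
  if (sttExtent(p) + 0.01 > rr)
    stop("infeasible-beat error: rr = ", signif(rr, 3),
         " s too short for ST-T extent ", signif(sttExtent(p), 3), " s")
  n <- round(rr * fs)
  samples <- numeric(n)

  iq <- seq_len(min(n, round(0.13 * fs) + 1))
  tq <- (iq - 1) / fs
  samples[iq] <- exp(-(tq - T_R)^2 / (2 * 0.009^2)) -
    0.12 * exp(-(tq - T_R + 0.02)^2 / (2 * 0.005^2)) -
    0.15 * exp(-(tq - T_R - 0.02)^2 / (2 * 0.005^2))

  tQrsEnd <- T_R + QRS_END_OFFSET
  tOn <- tQrsEnd + p$st
  tc <- tOn + K_ENV * p$sigmaUp
  tEndEnv <- tc + descendExtent(p)

  i0 <- round(tQrsEnd * fs) + 1L
  i1 <- min(n, ceiling((tEndEnv + 2 * p$sigmaDown) * fs) + 1L)
  idx <- i0:i1
  t <- (idx - 1) / fs

  ## Generalized-Gaussian flanks parameterized by their 1%-threshold width
  ## W = K_ENV * sigma: env = exp(-ln(100) * (|dt|/W)^q), so that env = 1%
  ## at |dt| = W for every convexity exponent q (q = 2 is the Gaussian).
  qUp <- p$qUp %||% 2; qDown <- p$qDown %||% 2
  wUp <- K_ENV * p$sigmaUp; wDown <- K_ENV * p$sigmaDown
  ln100 <- log(1 / ENV_THRESHOLD)
  env <- numeric(length(idx))
  asc <- t < tc
  env[asc] <- exp(-ln100 * ((tc - t[asc]) / wUp)^qUp)
  env[!asc] <- exp(-ln100 * ((t[!asc] - tc) / wDown)^qDown)
  env <- p$tAmp * env
  if (p$bifidOffset > 0 && p$bifidAmpFrac > 0)
    env <- env + p$tAmp * p$bifidAmpFrac *
      exp(-ln100 * (abs(t - tc - p$bifidOffset) / wDown)^qDown)

  stComp <- numeric(length(idx))
  rise <- t >= tQrsEnd & t < tOn
  stComp[rise] <- 0.5 * (1 - cos(pi * (t[rise] - tQrsEnd) / p$st))
  stComp[t >= tOn & t <= tc] <- 1
  fall <- t > tc & t <= tEndEnv
  stComp[fall] <- 0.5 * (1 + cos(pi * (t[fall] - tc) / (tEndEnv - tc)))

  samples[idx] <- samples[idx] + p$polarity * (p$stRise * stComp + env)

  thr <- ENV_THRESHOLD * p$tAmp
  above <- which(env > thr)
  fid <- c(as.integer(round(T_R * fs)), as.integer(round(tQrsEnd * fs)),
           idx[above[1]] - 1L, idx[which.max(env)] - 1L,
           idx[above[length(above)]] - 1L)
  list(samples = samples, fid = fid)
}

#' Generate a full subject record with LF/HF-structured RR variability
#'
#' Builds one synthetic Holter excerpt: the RR series is
#' \eqn{RR(t) = RR_0 + a_{LF}\sin(2\pi\,0.1\,t) + a_{HF}\sin(2\pi\,0.25\,t)}
#' plus a small white jitter, with the \eqn{(a_{LF}, a_{HF})} split switched
#' between an active regime (high LF/HF, shorter base RR) and a resting
#' regime (low LF/HF, longer base RR) in alternating 350-beat blocks
#' (active, rest, active, ...). Beats are concatenated `generateBeat` outputs
#' with per-beat morphology jitter; additive Gaussian noise of sd
#' `noiseSd(spec)` is applied to the whole record; the record is stamped with
#' a start clock inside 10:00--20:00.
#'
#' @param spec a [CohortSpec-class].
#' @param archetype a [GenotypeArchetype-class].
#' @param recordId record identifier.
#' @param seed optional integer; when given, seeds the RNG for a
#'   reproducible record (otherwise the current RNG stream is used).
#' @return list with `record` ([EcgRecord-class]), `fiducials` (fiducial
#'   data.frame, with attribute `"restBeats"` = 0-based first/last beat of
#'   each designed resting block), and `label` (genotype).
#' @export
generateSubjectRecord <- function(spec, archetype, recordId = archetype@label,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fs <- spec@fs
  totalSec <- spec@recordHours * 3600
  blockBeats <- 350L
  baseRR <- c(active = 0.85, rest = 1.0)
  aTot <- 0.04

  subject <- drawSubjectParams(archetype)

  rrDrawn <- numeric(0)
  regimes <- character(0)
  tCum <- 0
  i <- 0L
  while (TRUE) {
    regime <- if ((i %/% blockBeats) %% 2L == 1L) "rest" else "active"
    ratio <- if (regime == "rest") spec@restLfHf else spec@activeLfHf
    aLF <- aTot * sqrt(ratio / (1 + ratio))
    aHF <- aTot * sqrt(1 / (1 + ratio))
    rr <- baseRR[[regime]] + aLF * sin(2 * pi * 0.10 * tCum) +
      aHF * sin(2 * pi * 0.25 * tCum) + rnorm(1, 0, 0.003)
    rr <- max(0.80, rr)
    if (tCum + rr > totalSec) break
    rrDrawn <- c(rrDrawn, rr)
    regimes <- c(regimes, regime)
    tCum <- tCum + rr
    i <- i + 1L
  }
  nBeats <- length(rrDrawn)
  if (nBeats < 2) stop("record too short: fewer than 2 beats")

  beats <- vector("list", nBeats)
  fidMat <- matrix(0L, nBeats, 5)
  for (b in seq_len(nBeats)) {
    jp <- jitterParams(subject)
    ## a short beat falls back to the subject's mean morphology, which the
    ## subject draw guarantees to fit the minimum RR
    if (sttExtent(jp) + 0.01 > rrDrawn[b]) jp <- subject
    core <- beatCore(jp, rrDrawn[b], fs)
    beats[[b]] <- core$samples
    fidMat[b, ] <- core$fid
  }
  lens <- vapply(beats, length, integer(1))
  offsets <- cumsum(c(0L, lens[-nBeats]))
  samples <- unlist(beats, use.names = FALSE)
  if (spec@noiseSd > 0)
    samples <- samples + rnorm(length(samples), 0, spec@noiseSd)

  fidMat <- fidMat + offsets
  fid <- validateFiducials(data.frame(
    beat = seq_len(nBeats) - 1L, r_peak = fidMat[, 1],
    qrs_end = fidMat[, 2], t_on = fidMat[, 3], t_peak = fidMat[, 4],
    t_end = fidMat[, 5], rr_s = lens / fs))

  restIdx <- which(regimes == "rest")
  restBlocks <- if (length(restIdx)) {
    brk <- c(0, which(diff(restIdx) > 1), length(restIdx))
    t(vapply(seq_len(length(brk) - 1), function(k)
      c(restIdx[brk[k] + 1] - 1L, restIdx[brk[k + 1]] - 1L), numeric(2)))
  } else matrix(numeric(0), 0, 2)
  attr(fid, "restBeats") <- restBlocks

  duration <- length(samples) / fs
  startClock <- 10 * 3600 + runif(1) * max(0, 10 * 3600 - duration)
  rec <- EcgRecord(samples, fs = fs, recordId = recordId,
                   startClock = startClock, lead = "I")
  list(record = rec, fiducials = fid, label = archetype@label)
}

#' Generate a genotype-balanced synthetic cohort
#'
#' Deterministic given `seed(spec)`: a single RNG stream is seeded once and
#' every subject draws from it in a fixed order.
#'
#' @param spec a [CohortSpec-class].
#' @param archetypes named list of archetypes, as [defaultArchetypes()].
#' @return list of per-subject lists (`record`, `fiducials`, `label`), with
#'   the spec attached as attribute `"spec"`.
#' @examples
#' cohort <- generateCohort(CohortSpec(nPerGenotype = c(1, 1, 1),
#'                                     recordHours = 0.02, seed = 3))
#' length(cohort)
#' @export
generateCohort <- function(spec, archetypes = defaultArchetypes()) {
  stopifnot(is(spec, "CohortSpec"))
  set.seed(spec@seed)
  out <- list()
  for (g in seq_along(archetypes)) {
    arch <- archetypes[[g]]
    for (j in seq_len(spec@nPerGenotype[g])) {
      id <- sprintf("%s_%03d", arch@label, j)
      out[[length(out) + 1L]] <- generateSubjectRecord(spec, arch,
                                                       recordId = id)
    }
  }
  attr(out, "spec") <- spec
  out
}

#' Write a synthetic cohort to CSV files
#'
#' Writes one signal CSV and one fiducial CSV per record plus a `labels.csv`
#' (record_id, genotype) into `outDir`.
#'
#' @param cohort result of [generateCohort()].
#' @param outDir output directory (created if missing).
#' @return `outDir`, invisibly.
#' @export
writeCohortCsv <- function(cohort, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  labels <- data.frame(record_id = character(0), genotype = character(0))
  for (subj in cohort) {
    id <- recordId(subj$record)
    writeEcg(subj$record, file.path(outDir, paste0(id, ".csv")))
    writeFiducials(subj$fiducials, file.path(outDir, paste0(id, ".fid.csv")))
    labels <- rbind(labels,
                    data.frame(record_id = id, genotype = subj$label))
  }
  utils::write.csv(labels, file.path(outDir, "labels.csv"),
                   row.names = FALSE, quote = FALSE)
  logInfo("wrote ", length(cohort), " records to ", outDir)
  invisible(outDir)
}
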