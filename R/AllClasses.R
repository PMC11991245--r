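#' @import methods
NULL

#' Single-lead ECG record
#'
#' Container for a uniformly sampled single-lead ECG amplitude series.
#' Amplitudes are in millivolts, time in seconds; \code{startClock} is the
#' wall-clock time of sample 0 expressed as seconds since midnight, so that
#' diurnal selection rules (the 10:00--20:00 vigilance window) can be applied.
#'
#' @slot recordId character record identifier.
#' @slot fs numeric sampling rate in Hz (200 Hz for Holter data of the kind
#'   this package targets).
#' @slot samples numeric amplitude series in mV.
#' @slot startClock numeric wall-clock time of the first sample, seconds
#'   since midnight.
#' @slot lead character lead label (Lead "I" by default).
#'
#' @seealso [EcgRecord()] for the validating constructor, [readEcg()].
#' @export
setClass("EcgRecord",
  representation(
    recordId = "character",
    fs = "numeric",
    samples = "numeric",
    startClock = "numeric",
    lead = "character"
  ),
  prototype(recordId = "record", fs = 200, startClock = 0, lead = "I")
)

setValidity("EcgRecord", function(object) {
  msg <- character()
  if (length(object@fs) != 1 || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "'fs' must be a single positive number")
  if (length(object@samples) < 2)
    msg <- c(msg, "'samples' must contain at least 2 values")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "'samples' must be finite")
  if (length(object@startClock) != 1 || !is.finite(object@startClock) ||
      object@startClock < 0 || object@startClock >= 86400)
    msg <- c(msg, "'startClock' must be in [0, 86400) seconds since midnight")
  if (length(msg)) msg else TRUE
})

#' Construct an EcgRecord
#'
#' @param samples numeric amplitude series (mV).
#' @param fs sampling rate in Hz.
#' @param recordId record identifier.
#' @param startClock wall-clock time of sample 0 (seconds since midnight).
#' @param lead lead label.
#' @return An [EcgRecord-class] object.
#' @examples
#' rec <- EcgRecord(sin(seq(0, 2 * pi, length.out = 400)), fs = 200)
#' samplingRate(rec)
#' @export
EcgRecord <- function(samples, fs = 200, recordId = "record",
                      startClock = 0, lead = "I") {
  new("EcgRecord", recordId = as.character(recordId), fs = as.numeric(fs),
      samples = as.numeric(samples), startClock = as.numeric(startClock),
      lead = as.character(lead))
}

setMethod("show", "EcgRecord", function(object) {
  cat("EcgRecord '", object@recordId, "' (lead ", object@lead, ")\n",
      sep = "")
  cat("  ", length(object@samples), " samples @ ", object@fs, " Hz (",
      sprintf("%.1f", length(object@samples) / object@fs), " s), start ",
      sprintf("%02d:%02d:%02.0f", object@startClock %/% 3600,
              (object@startClock %% 3600) %/% 60, object@startClock %% 60),
      "\n", sep = "")
})

#' Genotype-specific ST-T archetype
#'
#' Parameter bundle describing the stylized ST-T morphology of one LQTS
#' genotype used by the synthetic generator: the isoelectric ST duration, the
#' T-wave amplitude, asymmetric-Gaussian T widths, an optional second (bifid)
#' hump, the ST elevation reached at T onset, and the probability of a
#' negative (inverted) T-wave. Means are paired with between-subject standard
#' deviations; each simulated subject draws its own values once.
#'
#' @slot label genotype label, one of "LQT1", "LQT2", "LQT3".
#' @slot stDuration numeric c(mean, sd) of the isoelectric ST duration (s).
#' @slot tAmp numeric c(mean, sd) of T amplitude (mV).
#' @slot sigmaUp,sigmaDown numeric c(mean, sd) Gaussian widths of the
#'   ascending/descending T flanks (s).
#' @slot bifidOffset numeric delay of the second T hump (s); 0 disables it.
#' @slot bifidAmpFrac numeric amplitude of the second hump relative to the
#'   first.
#' @slot stRiseMv numeric c(mean, sd) ST amplitude reached at T onset (mV);
#'   real ST segments are not perfectly isoelectric and this is what gives
#'   the ST area its genotype signal.
#' @slot negTProb numeric probability that the subject's T-waves are negative.
#' @export
setClass("GenotypeArchetype",
  representation(
    label = "character",
    stDuration = "numeric",
    tAmp = "numeric",
    sigmaUp = "numeric",
    sigmaDown = "numeric",
    bifidOffset = "numeric",
    bifidAmpFrac = "numeric",
    stRiseMv = "numeric",
    negTProb = "numeric"
  )
)

setValidity("GenotypeArchetype", function(object) {
  msg <- character()
  if (!object@label %in% c("LQT1", "LQT2", "LQT3"))
    msg <- c(msg, "'label' must be LQT1, LQT2 or LQT3")
  for (nm in c("stDuration", "tAmp", "sigmaUp", "sigmaDown", "stRiseMv")) {
    v <- slot(object, nm)
    if (length(v) != 2 || !all(is.finite(v)) || v[2] < 0)
      msg <- c(msg, sprintf("'%s' must be c(mean, sd) with sd >= 0", nm))
  }
  if (object@sigmaUp[1] <= 0 || object@sigmaDown[1] <= 0)
    msg <- c(msg, "mean sigmaUp and sigmaDown must be > 0")
  if (object@negTProb < 0 || object@negTProb > 1)
    msg <- c(msg, "'negTProb' must be in [0, 1]")
  if (object@bifidOffset < 0)
    msg <- c(msg, "'bifidOffset' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname GenotypeArchetype-class
#' @param label,stDuration,tAmp,sigmaUp,sigmaDown,bifidOffset,bifidAmpFrac,stRiseMv,negTProb
#'   see the corresponding slots.
#' @return A \code{GenotypeArchetype}.
#' @export
GenotypeArchetype <- function(label, stDuration, tAmp, sigmaUp, sigmaDown,
                              bifidOffset = 0, bifidAmpFrac = 0,
                              stRiseMv = c(0.02, 0.008), negTProb = 0.05) {
  new("GenotypeArchetype", label = label, stDuration = stDuration,
      tAmp = tAmp, sigmaUp = sigmaUp, sigmaDown = sigmaDown,
      bifidOffset = bifidOffset, bifidAmpFrac = bifidAmpFrac,
      stRiseMv = stRiseMv, negTProb = negTProb)
}

setMethod("show", "GenotypeArchetype", function(object) {
  cat("GenotypeArchetype", object@label, "\n")
  cat(sprintf("  ST %.3f±%.3f s, T amp %.2f±%.2f mV, sigma up/down %.3f/%.3f s\n",
              object@stDuration[1], object@stDuration[2], object@tAmp[1],
              object@tAmp[2], object@sigmaUp[1], object@sigmaDown[1]))
  if (object@bifidOffset > 0)
    cat(sprintf("  bifid hump: +%.3f s at %.0f%% amplitude\n",
                object@bifidOffset, 100 * object@bifidAmpFrac))
})

#' Synthetic cohort specification
#'
#' Describes one simulated study cohort: how many records per genotype, the
#' sampling rate, record duration, the additive noise level, the target LF/HF
#' sympathovagal ratios of the resting and active RR regimes, and the seed
#' that makes the whole cohort reproducible.
#'
#' @slot nPerGenotype integer vector of length 3 (LQT1, LQT2, LQT3 counts).
#' @slot fs sampling rate, Hz.
#' @slot recordHours record duration in hours.
#' @slot seed integer RNG seed.
#' @slot noiseSd additive Gaussian noise sd, mV.
#' @slot restLfHf,activeLfHf target LF/HF ratio of the rest and active RR
#'   modulation regimes; rest must be below active.
#' @export
setClass("CohortSpec",
  representation(
    nPerGenotype = "integer",
    fs = "numeric",
    recordHours = "numeric",
    seed = "integer",
    noiseSd = "numeric",
    restLfHf = "numeric",
    activeLfHf = "numeric"
  )
)

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (length(object@nPerGenotype) != 3 || any(object@nPerGenotype < 1))
    msg <- c(msg, "'nPerGenotype' must be 3 counts >= 1")
  if (object@restLfHf >= object@activeLfHf)
    msg <- c(msg, "'restLfHf' must be < 'activeLfHf'")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@recordHours <= 0) msg <- c(msg, "'recordHours' must be > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CohortSpec-class
#' @param nPerGenotype,fs,recordHours,seed,noiseSd,restLfHf,activeLfHf see
#'   the corresponding slots.
#' @return A \code{CohortSpec}.
#' @examples
#' spec <- CohortSpec(nPerGenotype = c(2, 2, 2), recordHours = 0.02, seed = 7)
#' @export
CohortSpec <- function(nPerGenotype = c(40, 40, 40), fs = 200,
                       recordHours = 0.25, seed = 1, noiseSd = 0.02,
                       restLfHf = 0.3, activeLfHf = 5) {
  new("CohortSpec", nPerGenotype = as.integer(nPerGenotype),
      fs = as.numeric(fs), recordHours = as.numeric(recordHours),
      seed = as.integer(seed), noiseSd = as.numeric(noiseSd),
      restLfHf = as.numeric(restLfHf), activeLfHf = as.numeric(activeLfHf))
}

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", paste(object@nPerGenotype, collapse = "/"),
      "records (LQT1/LQT2/LQT3),", object@recordHours, "h @", object@fs,
      "Hz, seed", object@seed, "\n")
})

#' Feature-triad selection result
#'
#' Result of the nonparametric feature screen: two-sided Wilcoxon rank-sum
#' p-values per feature (LQT3 vs LQT1+LQT2), the pairwise Spearman rank
#' correlation matrix, and the greedily selected uncorrelated triad.
#'
#' @slot pValues named numeric vector of two-sided rank-sum p-values.
#' @slot rhoMatrix Spearman correlation matrix of the candidate features.
#' @slot selected character vector of the 3 chosen feature names, in
#'   selection order.
#' @export
setClass("SelectionResult",
  representation(
    pValues = "numeric",
    rhoMatrix = "matrix",
    selected = "character"
  )
)

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult: selected triad", paste(object@selected, collapse = ", "),
      "\n")
  p <- sort(object@pValues)
  cat("  smallest p-values:",
      paste(sprintf("%s=%.2g", names(p)[seq_len(min(5, length(p)))],
                    p[seq_len(min(5, length(p)))]), collapse = ", "), "\n")
})

#' Class-weighted Gaussian-kernel SVM model
#'
#' Wrapper around a fitted soft-margin SVM with kernel
#' \eqn{K(x, x') = \exp(-\lVert x - x'\rVert^2 / KS^2)} and per-class cost
#' weighting, together with the feature names it was trained on and its
#' hyperparameters. The decision score is oriented so that positive values
#' vote for LQT3.
#'
#' @slot fit the underlying [e1071::svm] fit.
#' @slot features character names of the (three) input features.
#' @slot C,KS numeric box constraint and kernel scale.
#' @slot weightLqt3 numeric training class weight of the LQT3 group.
#' @slot levels character class levels, positive class first.
#' @export
setClass("LqtSvmModel",
  representation(
    fit = "ANY",
    features = "character",
    C = "numeric",
    KS = "numeric",
    weightLqt3 = "numeric",
    levels = "character"
  )
)

setMethod("show", "LqtSvmModel", function(object) {
  cat("LqtSvmModel on (", paste(object@features, collapse = ", "), ")\n",
      sep = "")
  cat(sprintf("  C = %g, KS = %g, LQT3 weight = %g, %d support vectors\n",
              object@C, object@KS, object@weightLqt3, object@fit$tot.nSV))
})

#' Weighted classifier evaluation report
#'
#' Weighted confusion matrix and derived metrics for the binary LQT3-vs-rest
#' task. LQT3 test examples carry the test class weight; the other genotypes
#' count 1. Recall is class-internal and therefore weight-invariant;
#' precision and accuracy are not.
#'
#' @slot confusion 2x2 weighted confusion matrix (rows = predicted,
#'   columns = truth, LQT3 first).
#' @slot accuracy,precision,recall,f1,auc numeric metrics in [0, 1].
#' @slot roc data.frame with columns fpr, tpr.
#' @slot meanAbsShapley matrix of mean absolute Shapley values (features x
#'   predicted groups), or a 0x0 matrix when not computed.
#' @export
setClass("EvalReport",
  representation(
    confusion = "matrix",
    accuracy = "numeric",
    precision = "numeric",
    recall = "numeric",
    f1 = "numeric",
    auc = "numeric",
    roc = "data.frame",
    meanAbsShapley = "matrix"
  ),
  prototype(meanAbsShapley = matrix(numeric(0), 0, 0))
)

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport (weighted, LQT3 vs LQT1+LQT2)\n")
  print(round(object@confusion, 1))
  cat(sprintf("  accuracy %.3f | precision %.3f | recall %.3f | F1 %.2f | AUC %.3f\n",
              object@accuracy, object@precision, object@recall, object@f1,
              object@auc))
})
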