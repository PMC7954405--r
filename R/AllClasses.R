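setClassUnion("data.frameOrNULL", c("data.frame", "NULL"))

#' Canonical vital-sign panel
#'
#' Internal constant fixing the identity, order and units of the six vital
#' signs used throughout the package: diastolic blood pressure (mmHg),
#' systolic blood pressure (mmHg), heart rate (beats/min), respiratory rate
#' (breaths/min), oxygen saturation SpO2 (%), temperature (degrees C).
#'
#' @return Character vector of the six vital-sign codes, in canonical order.
#' @export
vitalNames <- function() c("dbp", "sbp", "hr", "rr", "spo2", "temp")

#' Names of the nine actigraphy window features
#'
#' Column order of [ActivityFeatureMatrix-class] values: minimum, maximum,
#' mean, variance, standard deviation, immobile fraction, interquartile range,
#' RMSSD (root mean square of successive differences), and the standard
#' deviation of per-hour RMSSD values within the window.
#'
#' @return Character vector of length 9.
#' @export
activityFeatureNames <- function()
  c("min", "max", "mean", "variance", "sd", "immobile", "iqr", "rmssd", "rmssd_sd")

#' Configuration of a synthetic ICU cohort
#'
#' Parameters of the synthetic cohort generator. Severity-to-signal couplings
#' (`vitalsEffect`, `activityEffect`) are nonnegative dials; setting both to
#' zero produces label-independent data (a null cohort).
#'
#' @slot nStays Number of ICU stays (>= 2).
#' @slot prevalence Probability in (0,1) of an unsuccessful discharge label.
#' @slot includeActivity Whether stays carry a per-minute activity-count series.
#' @slot losLogMean,losLogSd Lognormal parameters of ICU length of stay in
#'   hours; draws are truncated from below at 24 h.
#' @slot vitalsEffect Nonnegative scaling of the severity-driven shift of each
#'   vital sign (1 = default coupling).
#' @slot activityEffect Nonnegative scaling of severity-driven activity
#'   suppression (both the immobility odds and the nonzero-count mean).
#' @slot missingRate Probability that a given vital is unobserved in a given
#'   hour.
#' @slot linkSlope Slope of the logistic link from mean last-24-h severity to
#'   the discharge label.
#' @slot calendarStart,calendarDays Admission times are drawn uniformly over
#'   `[calendarStart, calendarStart + calendarDays]`, giving the chronological
#'   holdout a meaningful time axis.
#' @slot epochMinutes Activity epoch length in minutes.
#' @slot seed Integer seed; the cohort is a pure function of this object.
#' @seealso [cohortConfig()], [generateCohort()]
#' @export
setClass("CohortConfig",
  representation(
    nStays = "integer", prevalence = "numeric", includeActivity = "logical",
    losLogMean = "numeric", losLogSd = "numeric",
    vitalsEffect = "numeric", activityEffect = "numeric",
    missingRate = "numeric", linkSlope = "numeric",
    calendarStart = "POSIXct", calendarDays = "numeric",
    epochMinutes = "numeric", seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nStays < 2L) msg <- c(msg, "nStays must be >= 2")
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie strictly in (0,1)")
  if (object@vitalsEffect < 0 || object@activityEffect < 0)
    msg <- c(msg, "effect sizes must be nonnegative")
  if (object@missingRate < 0 || object@missingRate > 1)
    msg <- c(msg, "missingRate must lie in [0,1]")
  if (object@losLogSd < 0) msg <- c(msg, "losLogSd must be nonnegative")
  if (object@epochMinutes <= 0) msg <- c(msg, "epochMinutes must be positive")
  if (length(msg)) msg else TRUE
})

#' One intensive-care episode
#'
#' @slot stayId Unique identifier.
#' @slot admitTime,dischargeTime ICU admission and discharge timestamps.
#' @slot vitals Long-format data.frame with columns `time` (POSIXct),
#'   `variable` (one of [vitalNames()]), `value` (numeric, native units).
#' @slot activity Per-epoch activity counts: data.frame with columns `time`
#'   (POSIXct) and `count` (nonnegative), or `NULL` when the stay was not
#'   monitored with a wrist sensor.
#' @slot label Integer 0/1; 1 = unsuccessful hospital discharge.
#' @slot latentMean Mean latent severity over the final 24 h (the generator's
#'   ground truth, retained for diagnostics; `NA` for real data).
#' @export
setClass("ICUStay",
  representation(
    stayId = "character", admitTime = "POSIXct", dischargeTime = "POSIXct",
    vitals = "data.frame", activity = "data.frameOrNULL",
    label = "integer", latentMean = "numeric"
  )
)

setValidity("ICUStay", function(object) {
  msg <- character()
  if (object@dischargeTime <= object@admitTime)
    msg <- c(msg, "dischargeTime must follow admitTime")
  if (!object@label %in% c(0L, 1L)) msg <- c(msg, "label must be 0 or 1")
  if (nrow(object@vitals)) {
    if (any(object@vitals$time < object@admitTime) ||
        any(object@vitals$time > object@dischargeTime))
      msg <- c(msg, "vitals timestamps must fall inside the stay window")
    if (!all(object@vitals$variable %in% vitalNames()))
      msg <- c(msg, "unknown vital-sign variable")
  }
  if (!is.null(object@activity) && nrow(object@activity) &&
      any(object@activity$count < 0))
    msg <- c(msg, "activity counts must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' A collection of ICU stays
#'
#' Thin list-like container over [ICUStay-class] objects with the generating
#' configuration (if synthetic) attached.
#'
#' @slot stays List of [ICUStay-class].
#' @slot config The [CohortConfig-class] used to generate the cohort, or `NULL`.
#' @export
setClass("ICUCohort",
  representation(stays = "list", config = "ANY")
)

setValidity("ICUCohort", function(object) {
  ok <- vapply(object@stays, is, logical(1), class2 = "ICUStay")
  if (!all(ok)) "all elements of 'stays' must be ICUStay objects" else TRUE
})

#' Hourly resampled vital signs for one stay
#'
#' @slot stayId Stay identifier.
#' @slot values hours x 6 numeric matrix in canonical [vitalNames()] order;
#'   unobserved cells hold `NA` (never a silent zero).
#' @slot mask hours x 6 logical matrix, `TRUE` where at least one measurement
#'   fell in the hour bin.
#' @export
setClass("VitalsMatrix",
  representation(stayId = "character", values = "matrix", mask = "matrix")
)

setValidity("VitalsMatrix", function(object) {
  msg <- character()
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must share dimensions")
  if (ncol(object@values) != 6L) msg <- c(msg, "values must have 6 columns")
  if (any(is.na(object@values) & object@mask))
    msg <- c(msg, "mask claims observation where value is NA")
  if (length(msg)) msg else TRUE
})

#' Daily actigraphy feature matrix for one stay
#'
#' @slot stayId Stay identifier.
#' @slot values days x 9 numeric matrix in [activityFeatureNames()] order;
#'   features undefined on a window (e.g. RMSSD-SD on a short trailing window)
#'   hold `NA` and are later median-imputed by [applyPreprocess()].
#' @slot windowStart POSIXct vector of window start times.
#' @export
setClass("ActivityFeatureMatrix",
  representation(stayId = "character", values = "matrix", windowStart = "POSIXct")
)

setValidity("ActivityFeatureMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != 9L) msg <- c(msg, "values must have 9 columns")
  if (nrow(object@values) != length(object@windowStart))
    msg <- c(msg, "one windowStart per row required")
  v <- object@values
  imm <- v[, 6L]
  if (any(imm < -1e-12 | imm > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "immobile fraction must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' Development-set preprocessing statistics
#'
#' Per-feature capping bounds (1st/99th percentiles), imputation median and
#' standardization constants, all fitted on a development set only and applied
#' unchanged to validation stays.
#'
#' @slot features Feature names (6 vitals or 9 activity features).
#' @slot p01,p99 Cap bounds in native units.
#' @slot center Imputation median (native units).
#' @slot mean,sd Standardization constants computed on the capped development
#'   pool; a degenerate (constant) feature gets sd 1.
#' @export
setClass("PreprocessStats",
  representation(features = "character", p01 = "numeric", p99 = "numeric",
                 center = "numeric", mean = "numeric", sd = "numeric")
)

setValidity("PreprocessStats", function(object) {
  n <- length(object@features)
  lens <- c(length(object@p01), length(object@p99), length(object@center),
            length(object@mean), length(object@sd))
  msg <- character()
  if (any(lens != n)) msg <- c(msg, "all statistic vectors must match features")
  if (any(object@p01 > object@p99)) msg <- c(msg, "p01 must not exceed p99")
  if (any(object@sd <= 0)) msg <- c(msg, "sd must be positive")
  if (length(msg)) msg else TRUE
})

#' GRU model configuration
#'
#' Defaults follow the canonical training protocol: 128 hidden units in every recurrent
#' branch, 25% dropout on branch inputs and on the pre-head hidden
#' representation, Adam with learning rate 1e-3 and L2 weight decay 1e-3,
#' batches of 32 stays, and a random 20% early-stopping carve-out of the
#' development set.
#'
#' @slot hiddenDim Hidden state dimension per branch.
#' @slot dropout Dropout probability in [0,1).
#' @slot learningRate,weightDecay,batchSize Adam optimizer settings.
#' @slot maxEpochs,patience Early-stopping schedule (held-out loss).
#' @slot earlyStopFraction Fraction of development stays carved out for early
#'   stopping.
#' @slot superviseWindows If `TRUE`, the per-24-h-window predictions are also
#'   supervised; by default only the final prediction enters the loss.
#' @slot seed Seed controlling initialization, carve-out, shuffling, dropout.
#' @export
setClass("ModelConfig",
  representation(hiddenDim = "integer", dropout = "numeric",
                 learningRate = "numeric", weightDecay = "numeric",
                 batchSize = "integer", maxEpochs = "integer",
                 patience = "integer", earlyStopFraction = "numeric",
                 superviseWindows = "logical", seed = "integer")
)

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0,1)")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (object@weightDecay < 0) msg <- c(msg, "weightDecay must be >= 0")
  if (object@batchSize < 1L || object@maxEpochs < 1L || object@patience < 1L)
    msg <- c(msg, "batchSize, maxEpochs and patience must be positive")
  if (object@earlyStopFraction <= 0 || object@earlyStopFraction >= 1)
    msg <- c(msg, "earlyStopFraction must lie strictly in (0,1)")
  if (object@hiddenDim < 1L) msg <- c(msg, "hiddenDim must be positive")
  if (length(msg)) msg else TRUE
})

#' GRU discharge-disposition classifier
#'
#' Either a single-branch model over hourly vitals or a parallel two-branch
#' model whose second branch consumes daily actigraphy features; the final
#' hidden state(s) feed a sigmoid linear head (concatenated to 256 dimensions
#' in the parallel case).
#'
#' @slot type `"single"` or `"parallel"`.
#' @slot inputDim EHR-branch input dimension (6 vitals).
#' @slot actInputDim Activity-branch input dimension (9 features; 0 for
#'   single-branch models).
#' @slot hiddenDim Hidden units per branch.
#' @slot params Named list of parameter matrices/vectors (see
#'   [modelParameters()]).
#' @slot config [ModelConfig-class] used to build/train the model.
#' @slot history Training history (epoch, training loss, held-out loss).
#' @slot transferAudit Names of parameter groups overwritten by
#'   [initializeFromSource()] (empty if never transferred).
#' @export
setClass("GRUModel",
  representation(type = "character", inputDim = "integer",
                 actInputDim = "integer", hiddenDim = "integer",
                 params = "list", config = "ModelConfig",
                 history = "data.frame", transferAudit = "character")
)

setValidity("GRUModel", function(object) {
  msg <- character()
  if (!object@type %in% c("single", "parallel"))
    msg <- c(msg, "type must be 'single' or 'parallel'")
  bad <- !vapply(object@params, function(p) all(is.finite(p)), logical(1))
  if (any(bad))
    msg <- c(msg, paste("non-finite parameters:",
                        paste(names(object@params)[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Repeated cross-validation summary
#'
#' @slot repAuroc One value per repetition: the unweighted mean AUROC across
#'   the k validation folds of that repetition.
#' @slot meanAuroc Mean of `repAuroc`.
#' @slot ciLower,ciUpper 2.5th / 97.5th percentiles of `repAuroc` (linear
#'   interpolation between order statistics; no normal approximation).
#' @slot k Number of folds.
#' @export
setClass("CVSummary",
  representation(repAuroc = "numeric", meanAuroc = "numeric",
                 ciLower = "numeric", ciUpper = "numeric", k = "integer")
)

setValidity("CVSummary", function(object) {
  msg <- character()
  if (any(object@repAuroc < 0 | object@repAuroc > 1))
    msg <- c(msg, "repetition AUROCs must lie in [0,1]")
  if (object@ciLower > object@ciUpper)
    msg <- c(msg, "ciLower must not exceed ciUpper")
  if (length(msg)) msg else TRUE
})

#' Transfer-learning specification
#'
#' @slot checkpoint A checkpoint list produced by [saveCheckpoint()] /
#'   [modelCheckpoint()] holding the source model's named parameters.
#' @slot transferHead If `TRUE`, also copy the prediction head (legal only
#'   when head shapes match, i.e. single-branch target).
#' @slot freezeTransferred If `TRUE`, transferred parameters receive no
#'   gradient updates during fine-tuning.
#' @export
setClass("TransferSpec",
  representation(checkpoint = "list", transferHead = "logical",
                 freezeTransferred = "logical")
)
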