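#' Create a synthetic cohort configuration
#'
#' @param nStays Number of stays to generate.
#' @param prevalence Target prevalence of unsuccessful discharge, in (0,1).
#' @param includeActivity Attach a per-minute wrist activity series?
#' @param losLogMean,losLogSd Lognormal length-of-stay parameters (hours);
#'   draws are truncated from below at 24 h.
#' @param vitalsEffect,activityEffect Nonnegative severity couplings.
#' @param missingRate Per-hour, per-vital probability of no observation.
#' @param linkSlope Logistic slope from mean last-24-h severity to the label.
#' @param calendarStart Start of the synthetic admission window.
#' @param calendarDays Length of the admission window in days.
#' @param epochMinutes Activity epoch length in minutes.
#' @param seed Integer seed; cohorts are pure functions of the configuration.
#' @return A validated [CohortConfig-class] object.
#' @examples
#' cfg <- cohortConfig(nStays = 10, seed = 1)
#' @export
cohortConfig <- function(nStays,
                         prevalence = 0.35,
                         includeActivity = TRUE,
                         losLogMean = log(96),
                         losLogSd = 0.5,
                         vitalsEffect = 0.7,
                         activityEffect = 0.8,
                         missingRate = 0.3,
                         linkSlope = 2,
                         calendarStart = as.POSIXct("2018-01-01", tz = "UTC"),
                         calendarDays = 730,
                         epochMinutes = 1,
                         seed = 1L) {
  new("CohortConfig",
      nStays = as.integer(nStays), prevalence = prevalence,
      includeActivity = includeActivity,
      losLogMean = losLogMean, losLogSd = losLogSd,
      vitalsEffect = vitalsEffect, activityEffect = activityEffect,
      missingRate = missingRate, linkSlope = linkSlope,
      calendarStart = as.POSIXct(calendarStart, tz = "UTC"),
      calendarDays = calendarDays, epochMinutes = epochMinutes,
      seed = as.integer(seed))
}

#' Default configurations for the two analysis cohorts
#'
#' `sourceCohortConfig()` mirrors a large conventional-ICU cohort: vitals only,
#' 24.8% unsuccessful discharges, shorter stays. `targetCohortConfig()` mirrors
#' a small multi-modal cohort: vitals plus wrist actigraphy, 35.3% unsuccessful
#' discharges, longer stays. Stay-length medians (2 d source, 4 d target) keep
#' the source/target ordering of the real cohorts at a desk-runnable scale.
#'
#' @param nStays Cohort size (defaults: 2000 source, 51 target).
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohortConfig()].
#' @return A [CohortConfig-class] object.
#' @export
sourceCohortConfig <- function(nStays = 2000L, seed = 1L, ...) {
  cohortConfig(nStays = nStays, prevalence = 0.248, includeActivity = FALSE,
               losLogMean = log(48), losLogSd = 0.6, seed = seed, ...)
}

#' @rdname sourceCohortConfig
#' @export
targetCohortConfig <- function(nStays = 51L, seed = 2L, ...) {
  cohortConfig(nStays = nStays, prevalence = 0.353, includeActivity = TRUE,
               losLogMean = log(96), losLogSd = 0.5, seed = seed, ...)
}

#' Create a model configuration
#'
#' Defaults are the canonical protocol settings; `maxEpochs` and `patience` govern
#' early stopping on the held-out 20% carve-out loss.
#'
#' @param hiddenDim Hidden units per recurrent branch.
#' @param dropout Dropout probability on branch inputs and the pre-head state.
#' @param learningRate,weightDecay Adam settings (L2 coupled decay).
#' @param batchSize Stays per minibatch.
#' @param maxEpochs Maximum training epochs.
#' @param patience Epochs without held-out-loss improvement before stopping.
#' @param earlyStopFraction Fraction of development stays carved out for early
#'   stopping.
#' @param superviseWindows Supervise per-24-h-window predictions too?
#' @param seed Integer seed for initialization and training randomness.
#' @return A validated [ModelConfig-class] object.
#' @export
modelConfig <- function(hiddenDim = 128L, dropout = 0.25,
                        learningRate = 1e-3, weightDecay = 1e-3,
                        batchSize = 32L, maxEpochs = 100L, patience = 10L,
                        earlyStopFraction = 0.20, superviseWindows = FALSE,
                        seed = 1L) {
  new("ModelConfig",
      hiddenDim = as.integer(hiddenDim), dropout = dropout,
      learningRate = learningRate, weightDecay = weightDecay,
      batchSize = as.integer(batchSize), maxEpochs = as.integer(maxEpochs),
      patience = as.integer(patience), earlyStopFraction = earlyStopFraction,
      superviseWindows = superviseWindows, seed = as.integer(seed))
}

#' Create a transfer-learning specification
#'
#' @param checkpoint Source-model checkpoint (see [modelCheckpoint()]).
#' @param transferHead Also copy the prediction head (default `FALSE`; the
#'   protocol transfers only the internal recurrent weights and biases).
#' @param freezeTransferred Freeze transferred parameters during fine-tuning
#'   (default `FALSE`: plain fine-tuning).
#' @return A [TransferSpec-class] object.
#' @export
transferSpec <- function(checkpoint, transferHead = FALSE,
                         freezeTransferred = FALSE) {
  new("TransferSpec", checkpoint = checkpoint,
      transferHead = transferHead, freezeTransferred = freezeTransferred)
}

# ---- basic accessors & show methods ----------------------------------------

#' @describeIn ICUCohort Number of stays.
#' @param x An `ICUCohort`.
#' @export
setMethod("length", "ICUCohort", function(x) length(x@stays))

#' @describeIn ICUCohort Extract one stay.
#' @param i Index.
#' @export
setMethod("[[", "ICUCohort", function(x, i) x@stays[[i]])

#' @describeIn ICUCohort Subset to an `ICUCohort`.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "ICUCohort", function(x, i, j, ..., drop = FALSE)
  new("ICUCohort", stays = x@stays[i], config = x@config))

#' Stay-level accessors
#'
#' @param x An [ICUCohort-class] or [ICUStay-class].
#' @return `cohortLabels()`: integer vector of 0/1 labels. `admitTimes()`:
#'   POSIXct vector. `stayIds()`: character vector.
#' @export
cohortLabels <- function(x) {
  if (is(x, "ICUCohort")) vapply(x@stays, function(s) s@label, integer(1))
  else x@label
}

#' @rdname cohortLabels
#' @export
admitTimes <- function(x) {
  if (is(x, "ICUCohort"))
    as.POSIXct(vapply(x@stays, function(s) as.numeric(s@admitTime), numeric(1)),
               origin = "1970-01-01", tz = "UTC")
  else x@admitTime
}

#' @rdname cohortLabels
#' @export
stayIds <- function(x) {
  if (is(x, "ICUCohort")) vapply(x@stays, function(s) s@stayId, character(1))
  else x@stayId
}

setMethod("show", "ICUStay", function(object) {
  hrs <- as.numeric(difftime(object@dischargeTime, object@admitTime, units = "hours"))
  cat(sprintf("ICUStay %s: %.0f h, %d vitals records, %s activity, label=%d\n",
              object@stayId, hrs, nrow(object@vitals),
              if (is.null(object@activity)) "no" else
                sprintf("%d-epoch", nrow(object@activity)),
              object@label))
})

setMethod("show", "ICUCohort", function(object) {
  lab <- cohortLabels(object)
  cat(sprintf("ICUCohort with %d stays (%d unsuccessful, %.1f%%); activity: %s\n",
              length(object), sum(lab), 100 * mean(lab),
              if (length(object) && !is.null(object@stays[[1]]@activity)) "yes" else "no"))
})

setMethod("show", "PreprocessStats", function(object) {
  cat("PreprocessStats for", length(object@features), "features\n")
  print(data.frame(feature = object@features, p01 = object@p01, p99 = object@p99,
                   median = object@center, mean = object@mean, sd = object@sd,
                   row.names = NULL))
})

setMethod("show", "GRUModel", function(object) {
  cat(sprintf("GRUModel (%s): EHR input %d%s, hidden %d, %d parameter groups%s\n",
              object@type, object@inputDim,
              if (object@type == "parallel")
                sprintf(", activity input %d", object@actInputDim) else "",
              object@hiddenDim, length(object@params),
              if (length(object@transferAudit))
                sprintf(" (transferred: %d groups)", length(object@transferAudit))
              else ""))
})

setMethod("show", "CVSummary", function(object) {
  cat(sprintf("CVSummary: %d repetitions of %d-fold CV; mean AUROC %.3f (95%% CI %.3f-%.3f)\n",
              length(object@repAuroc), object@k, object@meanAuroc,
              object@ciLower, object@ciUpper))
})

#' CVSummary accessors
#'
#' @param object A [CVSummary-class].
#' @return `repetitionAurocs()`: numeric vector of per-repetition mean AUROCs;
#'   `meanAuroc()`: its mean; `aurocCI()`: length-2 percentile 95% CI.
#' @export
repetitionAurocs <- function(object) object@repAuroc

#' @rdname repetitionAurocs
#' @export
meanAuroc <- function(object) object@meanAuroc

#' @rdname repetitionAurocs
#' @export
aurocCI <- function(object) c(lower = object@ciLower, upper = object@ciUpper)

#' Model parameter access
#'
#' @param model A [GRUModel-class].
#' @return `modelParameters()`: the named list of parameter arrays;
#'   `trainingHistory()`: data.frame of per-epoch losses; `transferAudit()`:
#'   names of parameter groups overwritten by transfer.
#' @export
modelParameters <- function(model) model@params

#' @rdname modelParameters
#' @export
trainingHistory <- function(model) model@history

#' @rdname modelParameters
#' @export
transferAudit <- function(model) model@transferAudit
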