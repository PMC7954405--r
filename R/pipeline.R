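# Per-stay feature preparation and the end-to-end pipeline factory used by
# cross-validation: everything fold-dependent (caps, medians, standardization,
# model, early stopping) is fitted inside the factory on development stays
# only.

#' Prepare model inputs for every stay of a cohort
#'
#' Resamples each stay's vital-sign records to the hourly grid and, where an
#' activity series is present, computes the daily nine-feature actigraphy
#' matrix. Both are kept on the raw scale; capping/imputation/standardization
#' happen per experiment inside the pipeline factory, because their statistics
#' are development-set specific.
#'
#' @param cohort An [ICUCohort-class] (or list of [ICUStay-class]).
#' @return List of prepared stays: each a list with `stayId`, `admit`,
#'   `label`, `vitals` ([VitalsMatrix-class]), `act`
#'   ([ActivityFeatureMatrix-class] or `NULL`) and `latentMean`.
#' @export
prepareStays <- function(cohort) {
  stays <- asStayList(cohort)
  lapply(stays, function(s) {
    vm <- resampleHourly(s@vitals, s@admitTime, s@dischargeTime)
    vm@stayId <- s@stayId
    af <- if (!is.null(s@activity)) activityFeatures(s) else NULL
    list(stayId = s@stayId, admit = s@admitTime, label = s@label,
         vitals = vm, act = af, latentMean = s@latentMean)
  })
}

#' Pipeline factory for cross-validated experiments
#'
#' Returns a `function(devStays, seed)` suitable for [repeatedCV()]: called on
#' the development stays of a fold, it fits preprocessing statistics on them,
#' builds a model (seeded for reproducibility), optionally initializes the EHR
#' branch from a source checkpoint, trains with the standard protocol, and
#' returns an object whose `$predict(stays)` scores arbitrary stays with the
#' fold's own fitted statistics.
#'
#' @param type `"single"` (vitals only) or `"parallel"` (vitals + activity).
#' @param config A [ModelConfig-class]; its seed is replaced by the per-fold
#'   seed supplied by the evaluator.
#' @param checkpoint Optional source checkpoint for transfer learning.
#' @param transferHead Passed to [transferSpec()].
#' @return A pipeline factory function.
#' @export
acuityPipeline <- function(type = c("single", "parallel"),
                           config = modelConfig(), checkpoint = NULL,
                           transferHead = FALSE) {
  type <- match.arg(type)
  force(config); force(checkpoint); force(transferHead)
  function(devStays, seed) {
    cfg <- config
    cfg@seed <- as.integer(seed)
    vStats <- fitPreprocessStats(lapply(devStays, function(s) s$vitals))
    xs <- lapply(devStays, function(s) applyPreprocess(s$vitals, vStats)@values)
    y <- vapply(devStays, function(s) s$label, numeric(1))
    if (type == "parallel") {
      acts <- lapply(devStays, function(s) {
        if (is.null(s$act))
          stop(sprintf("stay %s lacks activity features", s$stayId), call. = FALSE)
        s$act
      })
      aStats <- fitPreprocessStats(acts)
      xa <- lapply(acts, function(a) applyPreprocess(a, aStats)@values)
      model <- buildParallelRNN(6L, 9L, cfg)
    } else {
      xa <- NULL
      aStats <- NULL
      model <- buildSingleRNN(6L, cfg)
    }
    if (!is.null(checkpoint))
      model <- initializeFromSource(model, transferSpec(checkpoint, transferHead))
    model <- trainModel(model, list(x = xs, xAct = xa, y = y))
    list(
      model = model,
      vitalsStats = vStats,
      activityStats = aStats,
      predict = function(stays) {
        nx <- lapply(stays, function(s) applyPreprocess(s$vitals, vStats)@values)
        na <- if (type == "parallel")
          lapply(stays, function(s) applyPreprocess(s$act, aStats)@values)
        predictScores(model, nx, na)
      }
    )
  }
}
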