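# Orchestration of the five-row experiment matrix:
#   1. source cohort,  EHR,            single cohort   (chronological + bootstrap)
#   2. target cohort,  EHR,            single cohort   (repeated stratified CV)
#   3. target cohort,  EHR + activity, single cohort   (repeated stratified CV)
#   4. target cohort,  EHR,            transfer        (repeated stratified CV)
#   5. target cohort,  EHR + activity, transfer        (repeated stratified CV)
# One pretraining run feeds both transfer rows, and all four target rows share
# fold assignments within a repetition (paired seeds), so row differences
# reflect modality and training scheme only.

#' Experiment matrix configuration
#'
#' @slot source [CohortConfig-class] of the large vitals-only cohort
#'   (`includeActivity` must be `FALSE`).
#' @slot target [CohortConfig-class] of the small multi-modal cohort
#'   (`includeActivity` must be `TRUE`).
#' @slot model [ModelConfig-class] shared by all rows.
#' @slot reps Cross-validation repetitions for the target rows.
#' @slot k Folds per repetition.
#' @slot nBoot Bootstrap iterations for the source row.
#' @slot baseSeed Master seed; the whole matrix is reproducible from it.
#' @slot outputDir Optional directory for results, logs and the source
#'   checkpoint (`NA` = no files written).
#' @export
setClass("ExperimentConfig",
  representation(source = "CohortConfig", target = "CohortConfig",
                 model = "ModelConfig", reps = "integer", k = "integer",
                 nBoot = "integer", baseSeed = "integer",
                 outputDir = "character")
)

setValidity("ExperimentConfig", function(object) {
  msg <- character()
  if (object@target@includeActivity != TRUE)
    msg <- c(msg, "target cohort must include activity")
  if (object@source@includeActivity != FALSE)
    msg <- c(msg, "source cohort must be vitals-only")
  if (object@reps < 1L || object@k < 2L) msg <- c(msg, "reps >= 1 and k >= 2 required")
  if (length(msg)) msg else TRUE
})

#' @rdname ExperimentConfig-class
#' @param source,target,model,reps,k,nBoot,baseSeed,outputDir See slots.
#' @return An `ExperimentConfig`.
#' @export
experimentConfig <- function(source = sourceCohortConfig(),
                             target = targetCohortConfig(),
                             model = modelConfig(),
                             reps = 10L, k = 5L, nBoot = 100L,
                             baseSeed = 1L, outputDir = NA_character_) {
  new("ExperimentConfig", source = source, target = target, model = model,
      reps = as.integer(reps), k = as.integer(k), nBoot = as.integer(nBoot),
      baseSeed = as.integer(baseSeed), outputDir = outputDir)
}

#' Run the five-row experiment matrix
#'
#' Generates both synthetic cohorts, pretrains the source model once on the
#' chronological 80% of the source cohort (row 1: validation AUROC with
#' bootstrap CI), then evaluates the four target-cohort variants — single /
#' parallel model, with / without transfer of the pretrained EHR-branch
#' weights — by repeated stratified 5-fold cross-validation with percentile
#' CIs. All four target rows use identical fold assignments within each
#' repetition.
#'
#' @param config An [ExperimentConfig-class].
#' @param verbose Emit progress messages with seeds and timings.
#' @return data.frame with columns `cohort`, `input`, `scheme`, `auroc`,
#'   `ciLower`, `ciUpper`, `n`; per-repetition AUROCs of the target rows are
#'   attached as attribute `repAuroc` (named list) and the full CV summaries
#'   as attribute `summaries`.
#' @export
runMatrix <- function(config, verbose = FALSE) {
  validObject(config)
  say <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  t0 <- Sys.time()
  say("matrix: baseSeed=%d reps=%d k=%d", config@baseSeed, config@reps, config@k)

  src <- generateCohort(config@source)
  tgt <- generateCohort(config@target)
  srcPrep <- prepareStays(src)
  tgtPrep <- prepareStays(tgt)
  say("cohorts generated: source n=%d (prev %.3f), target n=%d (prev %.3f) [%.1fs]",
      length(src), mean(cohortLabels(src)), length(tgt),
      mean(cohortLabels(tgt)), as.numeric(Sys.time() - t0, units = "secs"))

  preCfg <- config@model
  preCfg@seed <- childSeed(config@baseSeed, 0L)
  pre <- pretrainSource(srcPrep, preCfg, nBoot = config@nBoot,
                        seed = childSeed(config@baseSeed, 0L, 1L))
  say("source pretrained: val AUROC %.3f (%.3f-%.3f) [%.1fs]",
      pre$auroc, pre$ci[["lower"]], pre$ci[["upper"]],
      as.numeric(Sys.time() - t0, units = "secs"))

  factories <- list(
    ehr_single    = acuityPipeline("single", config@model),
    multi_single  = acuityPipeline("parallel", config@model),
    ehr_transfer  = acuityPipeline("single", config@model,
                                   checkpoint = pre$checkpoint),
    multi_transfer = acuityPipeline("parallel", config@model,
                                    checkpoint = pre$checkpoint)
  )
  summaries <- vector("list", length(factories))
  names(summaries) <- names(factories)
  for (nm in names(factories)) {
    summaries[[nm]] <- repeatedCV(tgtPrep, factories[[nm]],
                                  reps = config@reps, k = config@k,
                                  baseSeed = config@baseSeed)
    say("target row %s: mean AUROC %.3f (%.3f-%.3f) [%.1fs]", nm,
        summaries[[nm]]@meanAuroc, summaries[[nm]]@ciLower,
        summaries[[nm]]@ciUpper, as.numeric(Sys.time() - t0, units = "secs"))
  }

  results <- data.frame(
    cohort = c("source", rep("target", 4L)),
    input = c("EHR", "EHR", "EHR+activity", "EHR", "EHR+activity"),
    scheme = c("single cohort", "single cohort", "single cohort",
               "transfer", "transfer"),
    auroc = c(pre$auroc,
              vapply(summaries, function(s) s@meanAuroc, numeric(1))),
    ciLower = c(pre$ci[["lower"]],
                vapply(summaries, function(s) s@ciLower, numeric(1))),
    ciUpper = c(pre$ci[["upper"]],
                vapply(summaries, function(s) s@ciUpper, numeric(1))),
    n = c(length(src), rep(length(tgt), 4L))
  )
  attr(results, "repAuroc") <- lapply(summaries, repetitionAurocs)
  attr(results, "summaries") <- summaries
  attr(results, "sourceCheckpoint") <- pre$checkpoint

  if (!is.na(config@outputDir)) {
    dir.create(config@outputDir, showWarnings = FALSE, recursive = TRUE)
    write.csv(results, file.path(config@outputDir, "results.csv"),
              row.names = FALSE)
    reportMatrix(results, jsonPath = file.path(config@outputDir, "results.json"),
                 print = FALSE)
    saveCheckpoint(pre$checkpoint,
                   file.path(config@outputDir, "source_checkpoint.rds"))
    statsToJSON(pre$stats, file.path(config@outputDir, "source_stats.json"))
    write.csv(trainingHistory(pre$model),
              file.path(config@outputDir, "source_history.csv"),
              row.names = FALSE)
    repDf <- do.call(rbind, lapply(names(summaries), function(nm)
      data.frame(row = nm, rep = seq_along(summaries[[nm]]@repAuroc),
                 auroc = summaries[[nm]]@repAuroc)))
    write.csv(repDf, file.path(config@outputDir, "rep_auroc.csv"),
              row.names = FALSE)
    writeLines(sprintf("baseSeed=%d reps=%d k=%d elapsed=%.1fs",
                       config@baseSeed, config@reps, config@k,
                       as.numeric(Sys.time() - t0, units = "secs")),
               file.path(config@outputDir, "run.log"))
  }
  results
}

#' Render and serialize an experiment matrix
#'
#' @param results data.frame from [runMatrix()].
#' @param jsonPath Optional path for a machine-readable JSON report including
#'   per-repetition AUROCs.
#' @param print Print the formatted table?
#' @return The JSON string, invisibly.
#' @export
reportMatrix <- function(results, jsonPath = NULL, print = TRUE) {
  need <- c("cohort", "input", "scheme", "auroc", "ciLower", "ciUpper")
  missingCols <- setdiff(need, names(results))
  if (length(missingCols))
    stop(sprintf("results table lacks column(s): %s",
                 paste(missingCols, collapse = ", ")), call. = FALSE)
  if (any(!is.finite(results$ciLower)) || any(!is.finite(results$ciUpper)))
    stop("results table has missing confidence-interval fields", call. = FALSE)
  fmt <- data.frame(
    `Target cohort` = results$cohort,
    `Input data` = results$input,
    `Training scheme` = results$scheme,
    `AUROC (95% CI)` = sprintf("%.3f (%.3f-%.3f)", results$auroc,
                               results$ciLower, results$ciUpper),
    check.names = FALSE
  )
  if (print) print(fmt, row.names = FALSE)
  obj <- list(rows = results[need], repAuroc = attr(results, "repAuroc"))
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE, dataframe = "rows")
  if (!is.null(jsonPath)) writeLines(js, jsonPath)
  invisible(js)
}
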