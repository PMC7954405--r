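# Transfer-learning protocol: pretrain a single-branch model on the large
# vitals-only source cohort, copy its recurrent weights AND biases into the
# EHR branch of the target model, then fine-tune on the small target cohort.

#' Create / save / load a model checkpoint
#'
#' A checkpoint is a flat named-parameter archive plus shape metadata, the
#' interchange format between pretraining and transfer.
#'
#' @param model A [GRUModel-class].
#' @return `modelCheckpoint()`: a list with `params`, `type`, `inputDim`,
#'   `actInputDim`, `hiddenDim`.
#' @export
modelCheckpoint <- function(model) {
  list(params = model@params, type = model@type, inputDim = model@inputDim,
       actInputDim = model@actInputDim, hiddenDim = model@hiddenDim)
}

#' @rdname modelCheckpoint
#' @param checkpoint A checkpoint list.
#' @param path File path.
#' @export
saveCheckpoint <- function(checkpoint, path) {
  if (is(checkpoint, "GRUModel")) checkpoint <- modelCheckpoint(checkpoint)
  saveRDS(checkpoint, path)
  invisible(path)
}

#' @rdname modelCheckpoint
#' @export
loadCheckpoint <- function(path) readRDS(path)

#' Initialize a target model's EHR branch from a source checkpoint
#'
#' Copies the source model's EHR-branch GRU weights and biases into the target
#' model exactly; activity-branch parameters and the prediction head keep
#' their random initialization (unless `transferHead` is set, which is legal
#' only when head shapes match, i.e. a single-branch target). The operation is
#' idempotent and records which parameter groups were overwritten in
#' [transferAudit()].
#'
#' @param targetModel A [GRUModel-class].
#' @param spec A [TransferSpec-class] (or a checkpoint list, for convenience).
#' @return The target model with transferred parameters.
#' @export
initializeFromSource <- function(targetModel, spec) {
  if (!is(spec, "TransferSpec")) spec <- transferSpec(spec)
  src <- spec@checkpoint$params
  copied <- character()
  for (nm in gruParamNames("ehr.")) {
    if (is.null(src[[nm]]))
      stop(sprintf("transfer error: source checkpoint lacks parameter '%s'", nm),
           call. = FALSE)
    if (!identical(dim(src[[nm]]), dim(targetModel@params[[nm]])) ||
        length(src[[nm]]) != length(targetModel@params[[nm]]))
      stop(sprintf("transfer error: shape mismatch for parameter '%s'", nm),
           call. = FALSE)
    targetModel@params[[nm]] <- src[[nm]]
    copied <- c(copied, nm)
  }
  if (spec@transferHead) {
    if (length(src$head.w) != length(targetModel@params$head.w))
      stop("transfer error: head shapes differ (head transfer is only legal for a single-branch target)",
           call. = FALSE)
    targetModel@params$head.w <- src$head.w
    targetModel@params$head.b <- src$head.b
    copied <- c(copied, "head.w", "head.b")
  }
  targetModel@transferAudit <- copied
  validObject(targetModel)
  targetModel
}

#' Pretrain the source model on a vitals-only cohort
#'
#' Splits the source stays chronologically (development = earliest 80%),
#' fits preprocessing statistics on the development stays, trains a
#' single-branch GRU (with its internal early-stopping carve-out), scores the
#' chronological validation stays and summarizes their AUROC with a bootstrap
#' confidence interval.
#'
#' @param prepared Prepared stays from [prepareStays()] (vitals required).
#' @param config A [ModelConfig-class].
#' @param holdoutFraction Chronological validation fraction (0.20).
#' @param nBoot Bootstrap iterations for the validation CI.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `model`, `checkpoint`, `stats`, `auroc`, `ci`,
#'   `valScores`, `valLabels`.
#' @export
pretrainSource <- function(prepared, config = modelConfig(),
                           holdoutFraction = 0.20, nBoot = 100L, seed = 1L) {
  sp <- chronologicalSplit(prepared, holdoutFraction)
  dev <- sp$development; val <- sp$validation
  stats <- fitPreprocessStats(lapply(dev, function(s) s$vitals))
  xsDev <- lapply(dev, function(s) applyPreprocess(s$vitals, stats)@values)
  yDev <- vapply(dev, function(s) s$label, numeric(1))
  model <- buildSingleRNN(6L, config)
  model <- trainModel(model, list(x = xsDev, y = yDev))
  xsVal <- lapply(val, function(s) applyPreprocess(s$vitals, stats)@values)
  yVal <- vapply(val, function(s) s$label, numeric(1))
  scores <- predictScores(model, xsVal)
  ci <- bootstrapCI(scores, yVal, nBoot = nBoot, seed = seed)
  list(model = model, checkpoint = modelCheckpoint(model), stats = stats,
       auroc = aurocScore(scores, yVal), ci = ci,
       valScores = scores, valLabels = yVal)
}

#' Serialize a model's transfer audit to JSON
#'
#' Records which parameter groups [initializeFromSource()] overwrote, with
#' their shapes — the audit trail of a transfer run.
#'
#' @param model A [GRUModel-class].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to file).
#' @export
transferAuditJSON <- function(model, path = NULL) {
  audit <- transferAudit(model)
  obj <- list(
    transferred = audit,
    untouched = setdiff(names(model@params), audit),
    shapes = lapply(model@params[audit], function(p) dim(p) %||% length(p))
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Fine-tune a (transferred) model on the target cohort
#'
#' Identical contract to [trainModel()]: plain fine-tuning with a fresh
#' optimizer, all parameters trainable unless the transfer specification
#' freezes the transferred group.
#'
#' @param targetModel A [GRUModel-class], typically after
#'   [initializeFromSource()].
#' @param data Training data as in [trainModel()].
#' @param config A [ModelConfig-class]; defaults to the model's own.
#' @param spec Optional [TransferSpec-class]; when `freezeTransferred` is set
#'   the audited parameter groups receive no updates.
#' @return The fine-tuned [GRUModel-class].
#' @export
fineTune <- function(targetModel, data, config = NULL, spec = NULL) {
  freeze <- if (!is.null(spec) && spec@freezeTransferred)
    targetModel@transferAudit else character()
  trainModel(targetModel, data, config, freezeNames = freeze)
}
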