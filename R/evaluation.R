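# Evaluation protocols: AUROC, stratified k-fold, repeated CV with percentile
# confidence intervals, chronological split, bootstrap CI.

stayLabelOf <- function(s) {
  if (is(s, "ICUStay")) s@label
  else if (is.list(s) && !is.null(s$label)) s$label
  else stop("cannot extract a label from this stay object", call. = FALSE)
}

stayAdmitOf <- function(s) {
  if (is(s, "ICUStay")) s@admitTime
  else if (is.list(s) && !is.null(s$admit)) s$admit
  else stop("cannot extract an admission time", call. = FALSE)
}

stayIdOf <- function(s) {
  if (is(s, "ICUStay")) s@stayId
  else if (is.list(s) && !is.null(s$stayId)) s$stayId
  else stop("cannot extract a stay id", call. = FALSE)
}

asStayList <- function(stays) if (is(stays, "ICUCohort")) stays@stays else stays

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen positive
#' case outranks a uniformly chosen negative case, with ties counted one half.
#'
#' @param scores Numeric risk scores.
#' @param labels 0/1 labels (1 = positive class), same length.
#' @return AUROC in [0,1].
#' @export
aurocScore <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified k-fold partition
#'
#' Shuffles each class and deals its members round-robin across folds with a
#' class-continuing pointer, so per-fold class counts differ from exact
#' proportionality by less than one stay per class and fold sizes differ by at
#' most one.
#'
#' @param labels 0/1 labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffles.
#' @return List of `k` disjoint integer index vectors covering `seq_along(labels)`.
#' @export
stratifiedKfold <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  counts <- table(labels)
  if (any(counts < k))
    stop(sprintf("stratification error: every class needs >= %d members", k),
         call. = FALSE)
  withSeed(seed, {
    folds <- vector("list", k)
    ptr <- 0L
    for (cl in classes) {
      idx <- sample(which(labels == cl))
      for (i in idx) {
        f <- (ptr %% k) + 1L
        folds[[f]] <- c(folds[[f]], i)
        ptr <- ptr + 1L
      }
    }
    folds
  })
}

#' Repeated stratified k-fold cross-validation
#'
#' For each repetition a fresh random stratified fold assignment is drawn; for
#' each fold, `pipelineFactory` builds and fits a complete pipeline
#' (preprocessing statistics and model, including the internal early-stopping
#' carve-out) on the development stays only, then scores the held-out fold.
#' The repetition value is the unweighted mean of the k fold AUROCs; the
#' summary reports the mean over repetitions and percentile 2.5/97.5 bounds.
#' Fully reproducible from `baseSeed`.
#'
#' @param stays List of stays (prepared stays from [prepareStays()],
#'   [ICUStay-class] objects, or an [ICUCohort-class]).
#' @param pipelineFactory `function(devStays, seed)` returning an object with
#'   a `$predict(stays)` function mapping stays to risk scores.
#' @param reps Number of repetitions.
#' @param k Folds per repetition.
#' @param baseSeed Master seed.
#' @return A [CVSummary-class].
#' @export
repeatedCV <- function(stays, pipelineFactory, reps = 100L, k = 5L,
                       baseSeed = 1L) {
  stays <- asStayList(stays)
  labels <- vapply(stays, stayLabelOf, numeric(1))
  repAuroc <- numeric(reps)
  for (r in seq_len(reps)) {
    folds <- stratifiedKfold(labels, k, seed = childSeed(baseSeed, r))
    foldAuc <- numeric(k)
    for (j in seq_len(k)) {
      foldAuc[j] <- tryCatch({
        devIdx <- setdiff(seq_along(stays), folds[[j]])
        pipe <- pipelineFactory(stays[devIdx], childSeed(baseSeed, r, j))
        scores <- pipe$predict(stays[folds[[j]]])
        aurocScore(scores, labels[folds[[j]]])
      }, error = function(e)
        stop(sprintf("repetition %d, fold %d: %s", r, j, conditionMessage(e)),
             call. = FALSE))
    }
    repAuroc[r] <- mean(foldAuc)
  }
  new("CVSummary", repAuroc = repAuroc, meanAuroc = mean(repAuroc),
      ciLower = pctl(repAuroc, 0.025), ciUpper = pctl(repAuroc, 0.975),
      k = as.integer(k))
}

#' Chronological development/validation split
#'
#' Sorts stays by admission time (ties broken by stay id) and assigns the
#' final `ceiling(holdoutFraction * n)` stays to validation.
#'
#' @param stays List of stays or an [ICUCohort-class].
#' @param holdoutFraction Validation fraction (0.20).
#' @return List with `development`, `validation` (stay lists) and the
#'   corresponding index vectors `devIdx`, `valIdx` into the input order.
#' @export
chronologicalSplit <- function(stays, holdoutFraction = 0.20) {
  stays <- asStayList(stays)
  n <- length(stays)
  adm <- vapply(stays, function(s) as.numeric(stayAdmitOf(s)), numeric(1))
  ids <- vapply(stays, stayIdOf, character(1))
  ord <- order(adm, ids)
  nVal <- as.integer(ceiling(holdoutFraction * n))
  valIdx <- ord[seq.int(n - nVal + 1L, n)]
  devIdx <- ord[seq_len(n - nVal)]
  list(development = stays[devIdx], validation = stays[valIdx],
       devIdx = devIdx, valIdx = valIdx)
}

#' Bootstrap confidence interval for a validation AUROC
#'
#' Resamples (score, label) pairs with replacement `nBoot` times, computes the
#' AUROC of each resample (single-class resamples are redrawn), and reports
#' the mean of the bootstrap AUROCs with percentile 2.5/97.5 bounds. The
#' point-estimate AUROC on the original sample is attached as attribute
#' `point`.
#'
#' @param scores,labels Validation predictions and 0/1 labels.
#' @param nBoot Bootstrap iterations.
#' @param seed Seed for resampling.
#' @return Named numeric vector `c(mean, lower, upper)`.
#' @export
bootstrapCI <- function(scores, labels, nBoot = 100L, seed = 1L) {
  point <- aurocScore(scores, labels)  # also validates both classes present
  n <- length(scores)
  withSeed(seed, {
    aucs <- numeric(nBoot)
    for (b in seq_len(nBoot)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (length(unique(labels[idx])) == 2L) break
      }
      aucs[b] <- aurocScore(scores[idx], labels[idx])
    }
    out <- c(mean = mean(aucs), lower = pctl(aucs, 0.025),
             upper = pctl(aucs, 0.975))
    attr(out, "point") <- point
    out
  })
}

#' Serialize a CV summary to JSON
#'
#' @param summary A [CVSummary-class].
#' @param path Optional output path.
#' @return The JSON string (invisibly when written to file).
#' @export
cvSummaryToJSON <- function(summary, path = NULL) {
  obj <- list(mean_auroc = summary@meanAuroc, ci_lower = summary@ciLower,
              ci_upper = summary@ciUpper, k = summary@k,
              rep_auroc = summary@repAuroc)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
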