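# Model construction and forward evaluation.
#
# A branch is a standard single-layer GRU; its parameters are stored flat in
# model@params under a branch prefix ("ehr." or "act."):
#   Wz, Wr, Wc (hidden x input), Uz, Ur, Uc (hidden x hidden),
#   bz, br, bc (hidden)
# plus a sigmoid linear head "head.w" (length hidden, or 2*hidden for the
# parallel model) and "head.b". The numerical core lives in src/gru.cpp.

gruParamNames <- function(prefix)
  paste0(prefix, c("Wz", "Wr", "Wc", "Uz", "Ur", "Uc", "bz", "br", "bc"))

# Uniform(-1/sqrt(hidden), 1/sqrt(hidden)) initialization for all weights and
# biases of one branch; draw order is fixed for reproducibility.
initBranch <- function(inputDim, hiddenDim, prefix) {
  k <- 1 / sqrt(hiddenDim)
  p <- list()
  for (nm in c("Wz", "Wr", "Wc"))
    p[[paste0(prefix, nm)]] <- matrix(runif(hiddenDim * inputDim, -k, k),
                                      hiddenDim, inputDim)
  for (nm in c("Uz", "Ur", "Uc"))
    p[[paste0(prefix, nm)]] <- matrix(runif(hiddenDim * hiddenDim, -k, k),
                                      hiddenDim, hiddenDim)
  for (nm in c("bz", "br", "bc"))
    p[[paste0(prefix, nm)]] <- runif(hiddenDim, -k, k)
  p
}

initHead <- function(concatDim) {
  k <- 1 / sqrt(concatDim)
  list(head.w = runif(concatDim, -k, k), head.b = runif(1, -k, k))
}

#' Build a single-branch GRU classifier over hourly vitals
#'
#' One GRU branch consumes the hourly vital-sign matrix; a sigmoid linear head
#' on the final hidden state produces the discharge risk. Per-24-h-window risk
#' scores (the head applied to the hidden state at each window boundary) are
#' exposed by [predictRisk()].
#'
#' @param inputDim Number of vital-sign channels (6).
#' @param config A [ModelConfig-class]; its seed makes initialization
#'   deterministic.
#' @return An untrained [GRUModel-class].
#' @export
buildSingleRNN <- function(inputDim = 6L, config = modelConfig()) {
  validObject(config)
  params <- withSeed(config@seed, {
    c(initBranch(inputDim, config@hiddenDim, "ehr."),
      initHead(config@hiddenDim))
  })
  new("GRUModel", type = "single", inputDim = as.integer(inputDim),
      actInputDim = 0L, hiddenDim = config@hiddenDim, params = params,
      config = config, history = data.frame(), transferAudit = character())
}

#' Build a parallel two-branch GRU classifier
#'
#' Branch A consumes hourly vitals, branch B consumes daily actigraphy
#' features on its own time scale; the two final hidden states (hidden units
#' each) are concatenated and passed to the sigmoid linear head. The branches
#' share no parameters.
#'
#' @param ehrInputDim Vital-sign channels (6).
#' @param actInputDim Actigraphy features per day (9).
#' @param config A [ModelConfig-class].
#' @return An untrained [GRUModel-class].
#' @export
buildParallelRNN <- function(ehrInputDim = 6L, actInputDim = 9L,
                             config = modelConfig()) {
  validObject(config)
  params <- withSeed(config@seed, {
    c(initBranch(ehrInputDim, config@hiddenDim, "ehr."),
      initBranch(actInputDim, config@hiddenDim, "act."),
      initHead(2L * config@hiddenDim))
  })
  new("GRUModel", type = "parallel", inputDim = as.integer(ehrInputDim),
      actInputDim = as.integer(actInputDim), hiddenDim = config@hiddenDim,
      params = params, config = config, history = data.frame(),
      transferAudit = character())
}

# Pad a list of (T_i x D) matrices into a (D, B, Tmax) array with lengths.
padToCube <- function(xs) {
  B <- length(xs)
  D <- ncol(xs[[1]])
  lens <- vapply(xs, nrow, integer(1))
  if (any(lens < 1L)) stop("empty sequence", call. = FALSE)
  Tmax <- max(lens)
  X <- array(0, dim = c(D, B, Tmax))
  for (i in seq_len(B)) X[, i, seq_len(lens[i])] <- t(xs[[i]])
  list(X = X, lens = as.integer(lens))
}

branchForward <- function(params, prefix, X, lens, cache = FALSE,
                          returnH = FALSE) {
  cppGruForward(params[[paste0(prefix, "Wz")]], params[[paste0(prefix, "Wr")]],
                params[[paste0(prefix, "Wc")]], params[[paste0(prefix, "Uz")]],
                params[[paste0(prefix, "Ur")]], params[[paste0(prefix, "Uc")]],
                params[[paste0(prefix, "bz")]], params[[paste0(prefix, "br")]],
                params[[paste0(prefix, "bc")]], X, lens, cache, returnH)
}

branchBackward <- function(params, prefix, X, lens, fwd, dHsteps, dHvals) {
  g <- cppGruBackward(params[[paste0(prefix, "Wz")]], params[[paste0(prefix, "Wr")]],
                      params[[paste0(prefix, "Wc")]], params[[paste0(prefix, "Uz")]],
                      params[[paste0(prefix, "Ur")]], params[[paste0(prefix, "Uc")]],
                      X, lens, fwd$cache, dHsteps, dHvals)
  names(g) <- gruParamNames(prefix)
  for (nm in paste0(prefix, c("bz", "br", "bc"))) g[[nm]] <- drop(g[[nm]])
  g
}

headScore <- function(params, h) {
  drop(plogis(crossprod(h, params$head.w) + params$head.b))
}

checkModality <- function(model, hasAct) {
  if (model@type == "parallel" && !hasAct)
    stop("parallel model requires an activity feature matrix for every stay",
         call. = FALSE)
  if (model@type == "single" && hasAct)
    return(invisible(TRUE))  # extra modality is ignored, not an error
  invisible(TRUE)
}

# Final risk scores for a batch of preprocessed stays (evaluation mode).
predictScores <- function(model, xs, xActs = NULL) {
  checkModality(model, !is.null(xActs))
  ord <- order(vapply(xs, nrow, integer(1)), decreasing = TRUE)
  pe <- padToCube(xs[ord])
  fe <- branchForward(model@params, "ehr.", pe$X, pe$lens)
  hfin <- fe$Hfinal
  if (model@type == "parallel") {
    pa <- padToCube(xActs[ord])
    fa <- branchForward(model@params, "act.", pa$X, pa$lens)
    hfin <- rbind(hfin, fa$Hfinal)
  }
  scores <- headScore(model@params, hfin)
  out <- numeric(length(xs))
  out[ord] <- scores
  out
}

#' Predict discharge risk for one preprocessed stay
#'
#' Deterministic evaluation-mode forward pass (dropout off). Besides the final
#' risk (head applied to the hidden state at the stay's last hour), the score
#' trajectory after each 24-h window is returned: entry `d` applies the head
#' to the vitals-branch state at hour `min(24 d, T)` and, for parallel models,
#' the activity-branch state at window `min(d, D)`.
#'
#' @param model A [GRUModel-class].
#' @param x Preprocessed hourly vitals matrix (T x 6) for the stay.
#' @param xAct Preprocessed daily activity feature matrix (D x 9); required
#'   for parallel models.
#' @param windowHours Window length in hours (24).
#' @return List with `final` (risk in (0,1)) and `trajectory` (one score per
#'   24-h window).
#' @export
predictRisk <- function(model, x, xAct = NULL, windowHours = 24L) {
  checkModality(model, !is.null(xAct))
  Th <- nrow(x)
  pe <- padToCube(list(x))
  fe <- branchForward(model@params, "ehr.", pe$X, pe$lens, returnH = TRUE)
  nWin <- as.integer(ceiling(Th / windowHours))
  bHours <- pmin(windowHours * seq_len(nWin), Th)
  hE <- fe$H[, 1, , drop = TRUE]          # hidden x T
  if (is.null(dim(hE))) hE <- matrix(hE, ncol = Th)
  if (model@type == "parallel") {
    pa <- padToCube(list(xAct))
    fa <- branchForward(model@params, "act.", pa$X, pa$lens, returnH = TRUE)
    Da <- nrow(xAct)
    hA <- fa$H[, 1, , drop = TRUE]
    if (is.null(dim(hA))) hA <- matrix(hA, ncol = Da)
    bDays <- pmin(seq_len(nWin), Da)
    traj <- vapply(seq_len(nWin), function(d)
      headScore(model@params, matrix(c(hE[, bHours[d]], hA[, bDays[d]]))),
      numeric(1))
    final <- headScore(model@params, matrix(c(hE[, Th], hA[, Da])))
  } else {
    traj <- vapply(seq_len(nWin), function(d)
      headScore(model@params, matrix(hE[, bHours[d]])), numeric(1))
    final <- headScore(model@params, matrix(hE[, Th]))
  }
  list(final = unname(final), trajectory = unname(traj))
}
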