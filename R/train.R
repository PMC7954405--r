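# Training: Adam with L2 weight decay, binary cross-entropy on the final
# prediction per stay (optionally also on per-window predictions), dropout on
# branch inputs and on the pre-head hidden representation, early stopping on
# the loss of a random carve-out of the development stays.

bce <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

# Window boundary steps for supervision/trajectories.
windowSteps <- function(len, windowHours = 24L) {
  nWin <- as.integer(ceiling(len / windowHours))
  pmin(windowHours * seq_len(nWin), len)
}

# Loss and parameter gradients on one padded batch. maskE/maskA are inverted
# input-dropout masks matching the cubes (or NULL); maskH the pre-head mask.
batchGrads <- function(params, type, pe, pa, y, maskE = NULL, maskA = NULL,
                       maskH = NULL, superviseWindows = FALSE) {
  Xe <- if (is.null(maskE)) pe$X else pe$X * maskE
  fe <- branchForward(params, "ehr.", Xe, pe$lens, cache = TRUE)
  B <- length(y)
  Hd <- length(params$head.w)
  hdim <- nrow(fe$Hfinal)
  parallel <- type == "parallel"
  if (parallel) {
    Xa <- if (is.null(maskA)) pa$X else pa$X * maskA
    fa <- branchForward(params, "act.", Xa, pa$lens, cache = TRUE)
  }
  if (is.null(maskH)) maskH <- matrix(1, Hd, B)

  if (!superviseWindows) {
    W <- 1L
    stepList <- list(list(e = pe$lens, a = if (parallel) pa$lens,
                          wt = rep(1 / B, B)))
  } else {
    nWinE <- ceiling(pe$lens / 24)
    W <- max(nWinE)
    stepList <- lapply(seq_len(W), function(w) {
      list(e = pmin(24L * w, pe$lens),
           a = if (parallel) pmin(w, pa$lens),
           wt = ifelse(nWinE >= w, 1 / (B * nWinE), 0))
    })
  }

  dHstepsE <- matrix(1L, W, B)
  dHvalsE <- array(0, c(hdim, B, W))
  if (parallel) {
    dHstepsA <- matrix(1L, W, B)
    dHvalsA <- array(0, c(hdim, B, W))
  }
  gW <- numeric(Hd); gB <- 0; lossAcc <- 0

  for (w in seq_len(W)) {
    sl <- stepList[[w]]
    hfin <- cppGruGather(fe$cache, as.integer(sl$e))
    if (parallel) hfin <- rbind(hfin, cppGruGather(fa$cache, as.integer(sl$a)))
    hd <- hfin * maskH
    p <- drop(plogis(crossprod(hd, params$head.w) + params$head.b))
    dlogit <- (p - y) * sl$wt
    gW <- gW + drop(hd %*% dlogit)
    gB <- gB + sum(dlogit)
    dh <- (params$head.w %o% dlogit) * maskH
    dHstepsE[w, ] <- as.integer(sl$e)
    dHvalsE[, , w] <- dh[seq_len(hdim), , drop = FALSE]
    if (parallel) {
      dHstepsA[w, ] <- as.integer(sl$a)
      dHvalsA[, , w] <- dh[(hdim + 1):Hd, , drop = FALSE]
    }
    lossAcc <- lossAcc + sum(sl$wt * (-(y * log(pmax(p, 1e-12)) +
                                        (1 - y) * log(pmax(1 - p, 1e-12)))))
  }

  grads <- branchBackward(params, "ehr.", Xe, pe$lens, fe, dHstepsE, dHvalsE)
  if (parallel)
    grads <- c(grads, branchBackward(params, "act.", Xa, pa$lens, fa,
                                     dHstepsA, dHvalsA))
  grads$head.w <- gW
  grads$head.b <- gB
  list(loss = lossAcc, grads = grads)
}

evalLoss <- function(params, type, xs, xActs, y) {
  ord <- order(vapply(xs, nrow, integer(1)), decreasing = TRUE)
  xs <- xs[ord]; y <- y[ord]
  if (!is.null(xActs)) xActs <- xActs[ord]
  pe <- padToCube(xs)
  fe <- branchForward(params, "ehr.", pe$X, pe$lens)
  hfin <- fe$Hfinal
  if (type == "parallel") {
    pa <- padToCube(xActs)
    fa <- branchForward(params, "act.", pa$X, pa$lens)
    hfin <- rbind(hfin, fa$Hfinal)
  }
  bce(drop(plogis(crossprod(hfin, params$head.w) + params$head.b)), y)
}

dropMask <- function(dims, p) {
  if (p <= 0) return(NULL)
  array(rbinom(prod(dims), 1L, 1 - p) / (1 - p), dim = dims)
}

#' Train a GRU classifier
#'
#' Binary cross-entropy on the final per-stay prediction (per-window
#' supervision optional via the configuration), Adam with the configured
#' learning rate and L2 weight decay, minibatches of `batchSize` stays, 25%
#' dropout (training only) on branch inputs and the pre-head hidden state. A
#' random `earlyStopFraction` of the supplied development stays is held out;
#' training stops after `patience` epochs without held-out-loss improvement
#' and the best parameters are restored. Variable-length stays contribute
#' their own final hidden state, never a padded step.
#'
#' @param model An untrained (or transferred) [GRUModel-class].
#' @param data List with `x` (list of T x 6 preprocessed vitals matrices),
#'   `xAct` (list of D x 9 matrices, parallel models only) and `y` (0/1).
#' @param config A [ModelConfig-class]; defaults to the model's own.
#' @param freezeNames Parameter names excluded from updates.
#' @return The trained [GRUModel-class] with `trainingHistory()` filled in.
#' @export
trainModel <- function(model, data, config = NULL, freezeNames = character()) {
  config <- config %||% model@config
  validObject(config)
  y <- data$y
  n <- length(y)
  if (n < 2L || length(unique(y)) < 2L)
    stop("training requires both outcome classes", call. = FALSE)
  if (model@type == "parallel" && is.null(data$xAct))
    stop("parallel model requires activity features ('xAct')", call. = FALSE)

  withSeed(config@seed, {
    nHold <- max(1L, round(config@earlyStopFraction * n))
    holdIdx <- sample.int(n, nHold)
    trIdx <- setdiff(seq_len(n), holdIdx)
    if (length(unique(y[trIdx])) < 2L) {
      # degenerate carve-out on tiny data: swap one stay of the missing class
      miss <- setdiff(unique(y), y[trIdx])
      swap <- holdIdx[which(y[holdIdx] == miss[1])[1]]
      give <- trIdx[1]
      holdIdx <- c(setdiff(holdIdx, swap), give)
      trIdx <- c(setdiff(trIdx, give), swap)
    }

    params <- model@params
    mAdam <- lapply(params, function(p) p * 0)
    vAdam <- lapply(params, function(p) p * 0)
    step <- 0
    b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
    lr <- config@learningRate; wd <- config@weightDecay
    parallel <- model@type == "parallel"

    xsH <- data$x[holdIdx]; yH <- y[holdIdx]
    xaH <- if (parallel) data$xAct[holdIdx]

    best <- list(loss = Inf, params = params, epoch = 0L)
    sincBest <- 0L
    hist <- vector("list", config@maxEpochs)

    for (epoch in seq_len(config@maxEpochs)) {
      ord <- sample(trIdx)
      starts <- seq(1L, length(ord), by = config@batchSize)
      trLoss <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config@batchSize - 1L, length(ord))]
        # process the batch longest-first so padded steps cost nothing
        idx <- idx[order(vapply(data$x[idx], nrow, integer(1)),
                         decreasing = TRUE)]
        pe <- padToCube(data$x[idx])
        pa <- if (parallel) padToCube(data$xAct[idx])
        maskE <- dropMask(dim(pe$X), config@dropout)
        maskA <- if (parallel) dropMask(dim(pa$X), config@dropout)
        maskH <- if (config@dropout > 0)
          matrix(rbinom(length(params$head.w) * length(idx), 1L,
                        1 - config@dropout) / (1 - config@dropout),
                 length(params$head.w), length(idx))
        bg <- batchGrads(params, model@type, pe, pa, y[idx],
                         maskE, maskA, maskH, config@superviseWindows)
        trLoss <- trLoss + bg$loss * length(idx)
        step <- step + 1
        for (nm in names(params)) {
          if (nm %in% freezeNames) next
          g <- bg$grads[[nm]] + wd * params[[nm]]
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g * g
          mh <- mAdam[[nm]] / (1 - b1^step)
          vh <- vAdam[[nm]] / (1 - b2^step)
          params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + epsA)
        }
      }
      hLoss <- evalLoss(params, model@type, xsH, xaH, yH)
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = trLoss / length(trIdx),
                                  heldoutLoss = hLoss)
      if (hLoss < best$loss - 1e-12) {
        best <- list(loss = hLoss, params = params, epoch = epoch)
        sincBest <- 0L
      } else {
        sincBest <- sincBest + 1L
        if (sincBest >= config@patience) break
      }
    }

    model@params <- best$params
    model@config <- config
    model@history <- do.call(rbind, hist[!vapply(hist, is.null, logical(1))])
    validObject(model)
    model
  })
}
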