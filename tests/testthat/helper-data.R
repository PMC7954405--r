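# Small in-code fixtures shared across test files.

tinyModelConfig <- function(seed = 1L, dropout = 0, ...) {
  modelConfig(hiddenDim = 8L, dropout = dropout, batchSize = 16L,
              maxEpochs = 3L, patience = 2L, seed = seed, ...)
}

# Synthetic preprocessed training data with a direct score-label relationship,
# bypassing the cohort generator (for model-level tests).
toyTrainingData <- function(n = 40L, tMin = 24L, tMax = 60L, signal = 1,
                            withActivity = FALSE, seed = 1L) {
  set.seed(seed)
  y <- rep(c(0, 1), length.out = n)
  lens <- sample(tMin:tMax, n, replace = TRUE)
  xs <- lapply(seq_len(n), function(i) {
    base <- matrix(rnorm(lens[i] * 6), lens[i], 6)
    base + signal * (2 * y[i] - 1) * 0.5
  })
  xa <- if (withActivity) lapply(seq_len(n), function(i) {
    D <- max(1L, ceiling(lens[i] / 24))
    matrix(rnorm(D * 9) + signal * (2 * y[i] - 1) * 0.5, D, 9)
  })
  list(x = xs, xAct = xa, y = y)
}

# A stay with hand-written vitals records.
manualStay <- function(records, admitHours = 48, label = 0L, stayId = "s1",
                       admit = as.POSIXct("2020-01-01 00:00:00", tz = "UTC"),
                       activity = NULL) {
  new("ICUStay", stayId = stayId, admitTime = admit,
      dischargeTime = admit + admitHours * 3600,
      vitals = records, activity = activity, label = label,
      latentMean = NA_real_)
}

emptyVitals <- function() {
  data.frame(time = as.POSIXct(character(), tz = "UTC"),
             variable = character(), value = numeric())
}
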