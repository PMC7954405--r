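# Independent naive-loop oracles, kept deliberately dumb and separate from the
# package implementations they check.

naiveRmssd <- function(x) {
  ss <- 0
  for (i in seq_len(length(x) - 1)) ss <- ss + (x[i + 1] - x[i])^2
  sqrt(ss / (length(x) - 1))
}

naiveRmssdSD <- function(x, sub = 60L) {
  n <- floor(length(x) / sub)
  vals <- numeric(n)
  for (s in seq_len(n)) vals[s] <- naiveRmssd(x[((s - 1) * sub + 1):(s * sub)])
  m <- sum(vals) / n
  sqrt(sum((vals - m)^2) / (n - 1))
}

naiveImmobile <- function(x, thr = 0) {
  k <- 0
  for (v in x) if (v <= thr) k <- k + 1
  k / length(x)
}

naiveFeatures <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  v <- sum((x - m)^2) / (n - 1)
  c(min = min(x), max = max(x), mean = m, variance = v, sd = sqrt(v),
    immobile = naiveImmobile(x),
    iqr = unname(quantile(x, 0.75, type = 7) - quantile(x, 0.25, type = 7)),
    rmssd = naiveRmssd(x),
    rmssd_sd = if (floor(n / 60) >= 2) naiveRmssdSD(x) else NA_real_)
}

# Pairwise AUROC: every positive-negative pair, ties counted one half.
naiveAuroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Plain-R reference GRU forward pass (same gate equations as the package,
# evaluated step by step with scalar-friendly code).
refGruForward <- function(Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc, x) {
  h <- rep(0, nrow(Wz))
  H <- matrix(0, nrow(Wz), nrow(x))
  for (t in seq_len(nrow(x))) {
    xt <- x[t, ]
    z <- plogis(Wz %*% xt + Uz %*% h + bz)
    r <- plogis(Wr %*% xt + Ur %*% h + br)
    c_ <- tanh(Wc %*% xt + Uc %*% (r * h) + bc)
    h <- drop((1 - z) * c_ + z * h)
    H[, t] <- h
  }
  H
}
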