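test_that("zeroed parameters score exactly 0.5 everywhere", {
  m <- buildSingleRNN(6L, tinyModelConfig())
  m@params <- lapply(m@params, function(p) p * 0)
  x <- matrix(rnorm(50 * 6), 50, 6)
  out <- predictRisk(m, x)
  expect_identical(out$final, 0.5)
  expect_true(all(out$trajectory == 0.5))
  expect_length(out$trajectory, ceiling(50 / 24))
})

test_that("the compiled forward pass reproduces a plain-R GRU reference", {
  # 1-dimensional, 2-step network with hand-set weights
  Wz <- matrix(0.5); Wr <- matrix(-0.3); Wc <- matrix(0.8)
  Uz <- matrix(0.2); Ur <- matrix(0.4); Uc <- matrix(-0.6)
  bz <- 0.1; br <- -0.2; bc <- 0.05
  x <- matrix(c(1, -0.5), 2, 1)
  # pencil-and-paper recurrence
  h1 <- {
    z <- plogis(0.5 * 1 + 0.1); r <- plogis(-0.3 * 1 - 0.2)
    cc <- tanh(0.8 * 1 + 0.05)
    (1 - z) * cc
  }
  h2 <- {
    z <- plogis(0.5 * -0.5 + 0.2 * h1 + 0.1)
    r <- plogis(-0.3 * -0.5 + 0.4 * h1 - 0.2)
    cc <- tanh(0.8 * -0.5 - 0.6 * (r * h1) + 0.05)
    (1 - z) * cc + z * h1
  }
  fwd <- AcuityTransfer:::cppGruForward(Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc,
                                        AcuityTransfer:::padToCube(list(x))$X,
                                        2L, FALSE, TRUE)
  expect_equal(fwd$H[1, 1, 1], h1, tolerance = 1e-10)
  expect_equal(fwd$H[1, 1, 2], h2, tolerance = 1e-10)
  expect_equal(fwd$Hfinal[1, 1], h2, tolerance = 1e-10)
})

test_that("batched forward equals the R reference on random multi-dim inputs", {
  set.seed(101)
  H <- 5L; D <- 3L
  k <- 1 / sqrt(H)
  Wz <- matrix(runif(H * D, -k, k), H); Wr <- matrix(runif(H * D, -k, k), H)
  Wc <- matrix(runif(H * D, -k, k), H)
  Uz <- matrix(runif(H * H, -k, k), H); Ur <- matrix(runif(H * H, -k, k), H)
  Uc <- matrix(runif(H * H, -k, k), H)
  bz <- runif(H, -k, k); br <- runif(H, -k, k); bc <- runif(H, -k, k)
  xs <- lapply(c(9, 4, 7), function(T) matrix(rnorm(T * D), T, D))
  pc <- AcuityTransfer:::padToCube(xs)
  fwd <- AcuityTransfer:::cppGruForward(Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc,
                                        pc$X, pc$lens, FALSE, TRUE)
  for (i in seq_along(xs)) {
    ref <- refGruForward(Wz, Wr, Wc, Uz, Ur, Uc, bz, br, bc, xs[[i]])
    Ti <- nrow(xs[[i]])
    expect_equal(fwd$H[, i, seq_len(Ti)], ref, tolerance = 1e-12)
    expect_equal(fwd$Hfinal[, i], ref[, Ti], tolerance = 1e-12)
  }
})

test_that("initialization is deterministic and branch-structured", {
  cfg <- modelConfig(seed = 99L)
  m1 <- buildSingleRNN(6L, cfg)
  m2 <- buildSingleRNN(6L, cfg)
  expect_identical(m1@params, m2@params)
  mp <- buildParallelRNN(6L, 9L, cfg)
  expect_identical(length(mp@params$head.w), 256L)   # concat of two 128-d states
  expect_identical(dim(mp@params$ehr.Wz), c(128L, 6L))
  expect_identical(dim(mp@params$act.Wz), c(128L, 9L))
  expect_true(all(sort(names(mp@params)) ==
    sort(c(AcuityTransfer:::gruParamNames("ehr."),
           AcuityTransfer:::gruParamNames("act."), "head.w", "head.b"))))
})

test_that("a dead activity branch leaves the score a function of vitals only", {
  cfg <- tinyModelConfig(seed = 4L)
  m <- buildParallelRNN(3L, 2L, cfg)
  for (nm in AcuityTransfer:::gruParamNames("act."))
    m@params[[nm]] <- m@params[[nm]] * 0
  x <- matrix(rnorm(30 * 3), 30, 3)
  aZero <- matrix(0, 2, 2)
  aOther <- matrix(rnorm(4), 2, 2)
  expect_identical(predictRisk(m, x, aZero)$final, predictRisk(m, x, aOther)$final)
  # with live branches, swapping inputs between branches changes the score
  m2 <- buildParallelRNN(3L, 3L, tinyModelConfig(seed = 6L))
  xa <- matrix(rnorm(9), 3, 3)
  xb <- matrix(rnorm(9), 3, 3)
  expect_false(isTRUE(all.equal(predictRisk(m2, xa, xb)$final,
                                predictRisk(m2, xb, xa)$final)))
})

test_that("prediction is deterministic in evaluation mode and prefix-consistent", {
  set.seed(21)
  m <- buildParallelRNN(6L, 9L, tinyModelConfig(seed = 31L))
  for (i in 1:50) {
    Ti <- sample(25:80, 1)
    x <- matrix(rnorm(Ti * 6), Ti, 6)
    xa <- matrix(rnorm(ceiling(Ti / 24) * 9), ceiling(Ti / 24), 9)
    o1 <- predictRisk(m, x, xa)
    o2 <- predictRisk(m, x, xa)
    expect_identical(o1, o2)
    expect_length(o1$trajectory, ceiling(Ti / 24))
    # truncating to the first 24 h reproduces the first trajectory entry
    oTrunc <- predictRisk(m, x[1:24, , drop = FALSE], xa[1, , drop = FALSE])
    expect_equal(oTrunc$final, o1$trajectory[1], tolerance = 1e-12)
  }
})

test_that("training errors on single-class data and is frozen at zero learning rate", {
  d <- toyTrainingData(n = 20L, seed = 2L)
  dBad <- d; dBad$y <- rep(1, 20)
  m <- buildSingleRNN(6L, tinyModelConfig(seed = 7L))
  expect_error(trainModel(m, dBad), "both outcome classes")

  cfg0 <- tinyModelConfig(seed = 7L, learningRate = 0)
  m0 <- buildSingleRNN(6L, cfg0)
  t0 <- trainModel(m0, d, cfg0)
  expect_identical(t0@params, m0@params)
})

test_that("training separates strongly separable data and not shuffled labels", {
  d <- toyTrainingData(n = 120L, signal = 1.5, seed = 5L)
  cfg <- modelConfig(hiddenDim = 32L, dropout = 0.25, maxEpochs = 25L,
                     patience = 5L, seed = 8L)
  m <- trainModel(buildSingleRNN(6L, cfg), d, cfg)
  auc <- aurocScore(AcuityTransfer:::predictScores(m, d$x), d$y)
  expect_gte(auc, 0.9)
  expect_true(all(c("epoch", "trainLoss", "heldoutLoss") %in%
                  colnames(trainingHistory(m))))

  # permutation null: shuffled labels give held-out chance performance
  set.seed(99)
  dNull <- d
  dNull$y <- sample(d$y)
  half <- 1:60
  mN <- trainModel(buildSingleRNN(6L, cfg), list(x = dNull$x[half],
                                                 y = dNull$y[half]), cfg)
  aucN <- aurocScore(AcuityTransfer:::predictScores(mN, dNull$x[-half]),
                     dNull$y[-half])
  expect_lt(abs(aucN - 0.5), 0.1)
})

test_that("a train/predict cycle is bitwise reproducible from its seeds", {
  d <- toyTrainingData(n = 24L, seed = 3L)
  cfg <- tinyModelConfig(seed = 11L, dropout = 0.25)
  m1 <- trainModel(buildSingleRNN(6L, cfg), d, cfg)
  m2 <- trainModel(buildSingleRNN(6L, cfg), d, cfg)
  expect_identical(m1@params, m2@params)
  expect_identical(AcuityTransfer:::predictScores(m1, d$x),
                   AcuityTransfer:::predictScores(m2, d$x))
})
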