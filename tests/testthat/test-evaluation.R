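test_that("AUROC handles perfect ranking, ties and degenerate labels", {
  expect_identical(aurocScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_identical(aurocScore(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(aurocScore(1:4, rep(1, 4)), "both classes")
  expect_error(aurocScore(1:3, 1:2), "equal length")
})

test_that("AUROC matches the brute-force pairwise oracle on random instances", {
  set.seed(202)
  for (i in 1:200) {
    n <- sample(10:40, 1)
    labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
    scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
    expect_equal(aurocScore(scores, labels), naiveAuroc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(100)
  labels <- rbinom(100, 1, plogis(scores))
  if (length(unique(labels)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(aurocScore(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("complement symmetry holds for tie-free scores", {
  set.seed(14)
  scores <- rnorm(60)
  labels <- c(0, 1, rbinom(58, 1, 0.5))
  expect_equal(aurocScore(scores, labels) + aurocScore(-scores, labels), 1,
               tolerance = 1e-12)
})

test_that("stratified folds partition the data with near-proportional classes", {
  labels <- c(rep(0, 33), rep(1, 18))   # the target cohort's 33/18 split
  folds <- stratifiedKfold(labels, k = 5L, seed = 3L)
  expect_identical(sort(unlist(folds)), 1:51)
  expect_identical(sort(lengths(folds), decreasing = TRUE),
                   c(11L, 10L, 10L, 10L, 10L))
  for (f in folds) {
    expect_true(sum(labels[f] == 1) %in% 3:4)
    expect_true(sum(labels[f] == 0) %in% 6:7)
  }
  # pairwise disjoint
  for (a in 1:4) for (b in (a + 1):5)
    expect_length(intersect(folds[[a]], folds[[b]]), 0L)
  # different seeds give different assignments
  expect_false(identical(stratifiedKfold(labels, 5L, seed = 1L),
                         stratifiedKfold(labels, 5L, seed = 2L)))
  expect_error(stratifiedKfold(c(rep(0, 10), rep(1, 3)), k = 5L), "class")
})

test_that("proportionality holds across random label mixes", {
  set.seed(88)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    labels <- c(rep(0, 6), rep(1, 6), rbinom(n - 12, 1, runif(1, 0.2, 0.8)))
    k <- 5L
    folds <- stratifiedKfold(labels, k, seed = i)
    expect_identical(sort(unlist(folds)), seq_along(labels))
    for (cl in 0:1) {
      cnt <- vapply(folds, function(f) sum(labels[f] == cl), numeric(1))
      expect_lt(max(cnt) - min(cnt), 2)  # within one of proportionality
    }
    expect_lt(max(lengths(folds)) - min(lengths(folds)), 2)
  }
})

test_that("repeated CV is deterministic, leakage-free and degenerate-safe", {
  set.seed(5)
  stays <- lapply(1:30, function(i)
    list(stayId = sprintf("s%02d", i), label = rep(c(0, 1), 15)[i],
         score = rnorm(1)))
  constantFactory <- function(devStays, seed)
    list(predict = function(ss) rep(0.5, length(ss)))
  cv <- repeatedCV(stays, constantFactory, reps = 4L, k = 5L, baseSeed = 2L)
  expect_identical(repetitionAurocs(cv), rep(0.5, 4))
  expect_identical(unname(aurocCI(cv)), c(0.5, 0.5))

  # determinism
  seen <- new.env(); seen$dev <- list()
  recordingFactory <- function(devStays, seed) {
    seen$dev[[length(seen$dev) + 1L]] <- vapply(devStays, `[[`, "", "stayId")
    list(predict = function(ss) vapply(ss, `[[`, numeric(1), "score"))
  }
  cv1 <- repeatedCV(stays, recordingFactory, reps = 2L, k = 5L, baseSeed = 9L)
  cv2 <- repeatedCV(stays, recordingFactory, reps = 2L, k = 5L, baseSeed = 9L)
  expect_identical(repetitionAurocs(cv1), repetitionAurocs(cv2))

  # no fitting component ever sees the held-out fold
  allIds <- vapply(stays, `[[`, "", "stayId")
  labels <- vapply(stays, `[[`, numeric(1), "label")
  for (r in 1:2) {
    folds <- stratifiedKfold(labels, 5L,
                             seed = AcuityTransfer:::childSeed(9L, r))
    for (j in 1:5) {
      devSeen <- seen$dev[[(r - 1) * 5 + j]]
      expect_length(intersect(devSeen, allIds[folds[[j]]]), 0L)
    }
  }

  # an informative scorer strictly beats the constant pipeline
  oracleFactory <- function(devStays, seed)
    list(predict = function(ss)
      vapply(ss, function(s) plogis(2 * s$score + s$label), numeric(1)))
  cvO <- repeatedCV(stays, oracleFactory, reps = 2L, k = 5L, baseSeed = 2L)
  expect_gt(meanAuroc(cvO), meanAuroc(cv))
})

test_that("chronological splits hold out the latest stays with stable tie-breaks", {
  admit <- as.POSIXct("2020-01-01", tz = "UTC") + (10:1) * 86400
  stays <- lapply(1:10, function(i)
    list(stayId = sprintf("s%02d", i), admit = admit[i], label = i %% 2))
  sp <- chronologicalSplit(stays, 0.20)
  expect_length(sp$validation, 2L)
  expect_identical(sort(vapply(sp$validation, `[[`, "", "stayId")),
                   c("s01", "s02"))   # latest admissions
  # all-tied admissions: deterministic by stay id
  staysT <- lapply(stays, function(s) { s$admit <- admit[1]; s })
  spT1 <- chronologicalSplit(staysT, 0.20)
  spT2 <- chronologicalSplit(staysT, 0.20)
  expect_identical(vapply(spT1$validation, `[[`, "", "stayId"),
                   vapply(spT2$validation, `[[`, "", "stayId"))
  expect_identical(vapply(spT1$validation, `[[`, "", "stayId"),
                   c("s09", "s10"))
  # ceiling arithmetic at the study's source-cohort size
  expect_identical(as.integer(ceiling(0.20 * 48400)), 9680L)
  bigAdmit <- as.POSIXct("2011-01-01", tz = "UTC") + seq_len(500) * 3600
  staysB <- lapply(seq_len(500), function(i)
    list(stayId = sprintf("b%03d", i), admit = bigAdmit[i], label = i %% 2))
  expect_length(chronologicalSplit(staysB, 0.20)$validation, 100L)
})

test_that("bootstrap CIs are deterministic, degenerate-exact and shrink with n", {
  scores <- c(rep(0.9, 20), rep(0.1, 20))
  labels <- c(rep(1, 20), rep(0, 20))
  ci <- bootstrapCI(scores, labels, nBoot = 50L, seed = 4L)
  expect_identical(as.numeric(ci), c(1, 1, 1))
  expect_identical(bootstrapCI(scores, labels, nBoot = 50L, seed = 7L),
                   bootstrapCI(scores, labels, nBoot = 50L, seed = 7L))

  set.seed(11)
  widths <- vapply(c(200, 800, 3200), function(n) {
    s <- rnorm(n)
    l <- rbinom(n, 1, plogis(1.5 * s))
    ci <- bootstrapCI(s, l, nBoot = 100L, seed = 13L)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # ~1/sqrt(n) scaling: quadrupling n roughly halves the width
  expect_lt(widths[3] / widths[1], 0.7)
})

test_that("CV summaries serialize to JSON with their repetition values", {
  cv <- new("CVSummary", repAuroc = c(0.6, 0.7, 0.8), meanAuroc = 0.7,
            ciLower = 0.6, ciUpper = 0.8, k = 5L)
  js <- jsonlite::fromJSON(cvSummaryToJSON(cv))
  expect_equal(js$rep_auroc, c(0.6, 0.7, 0.8))
  expect_equal(js$mean_auroc, 0.7)
})
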