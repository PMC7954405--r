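test_that("severity path handles degenerate noise, determinism and short stays", {
  expect_equal(severityPath(30, theta = 0, vol = 0, mu = 0, s0 = 0, seed = 1),
               rep(0, 30))
  expect_identical(severityPath(48, seed = 42), severityPath(48, seed = 42))
  expect_error(severityPath(23, seed = 1), "at least 24")
  expect_length(severityPath(24, seed = 1), 24L)
})

test_that("severity path has the AR(1) lag-1 autocorrelation of its mean reversion", {
  theta <- 0.1
  s <- severityPath(10000, theta = theta, vol = 1, mu = 0, s0 = 0, seed = 7)
  ac1 <- cor(s[-1], s[-length(s)])
  expect_lt(abs(ac1 - (1 - theta)), 0.05)
})

test_that("vitals emission respects missingness, zero-noise and baseline anchoring", {
  cfgAll <- cohortConfig(nStays = 2, missingRate = 1, seed = 1)
  sev <- severityPath(30, seed = 2)
  expect_identical(nrow(emitVitals(sev, cfgAll, seed = 3)), 0L)

  # no severity coupling, no noise: every heart-rate record sits on baseline
  cfg0 <- cohortConfig(nStays = 2, vitalsEffect = 0, missingRate = 0, seed = 1)
  v <- emitVitals(sev, cfg0, noiseScale = 0, seed = 4)
  hr <- v$value[v$variable == "hr"]
  konst <- vitalGeneratorConstants()
  expect_true(all(hr == konst$baseline[konst$variable == "hr"]))

  # default cohort: median heart rate near the configured baseline
  coh <- generateCohort(cohortConfig(nStays = 500, seed = 11))
  allv <- do.call(rbind, lapply(coh@stays, function(s) s@vitals))
  medHr <- median(allv$value[allv$variable == "hr"])
  expect_lt(abs(medHr - konst$baseline[konst$variable == "hr"]), 5)
})

test_that("activity emission is deterministic, saturates, and matches its immobility model", {
  cfg <- cohortConfig(nStays = 2, seed = 1)
  sev <- severityPath(48, seed = 5)
  a1 <- emitActivity(sev, cfg, seed = 6)
  a2 <- emitActivity(sev, cfg, seed = 6)
  expect_identical(a1, a2)
  expect_true(all(a1$count >= 0))

  # saturation: overwhelming immobility odds produce an all-zero series
  cfgSat <- cohortConfig(nStays = 2, activityEffect = 1e6, seed = 1)
  sevPos <- rep(5, 24)
  aSat <- emitActivity(sevPos, cfgSat, immobileIntercept = 0, seed = 7)
  expect_true(all(aSat$count == 0))

  # zero fraction tracks the average logistic immobility probability
  sevLong <- severityPath(167, seed = 8)   # ~10,000 minutes
  aLong <- emitActivity(sevLong, cfg, immobileIntercept = qlogis(0.6), seed = 9)
  pBar <- mean(plogis(qlogis(0.6) + cfg@activityEffect * rep(sevLong, each = 60)))
  expect_lt(abs(mean(aLong$count == 0) - pBar), 0.03)
})

test_that("label assignment respects boundary, calibration and saturation", {
  sev <- severityPath(48, seed = 1)
  expect_identical(assignLabel(sev, -Inf, 0, seed = 2), 0L)

  # slope 0, intercept logit(0.35): prevalence recovered within binomial error
  lab2 <- vapply(1:10000, function(i) assignLabel(sev, qlogis(0.35), 0, seed = i),
                 integer(1))
  expect_lt(abs(mean(lab2) - 0.35), 0.01)

  # huge slope: label is the indicator of terminal severity sign
  sevHi <- rep(3, 24); sevLo <- rep(-3, 24)
  expect_identical(assignLabel(sevHi, 0, 1e8, seed = 4), 1L)
  expect_identical(assignLabel(sevLo, 0, 1e8, seed = 4), 0L)
})

test_that("cohort generation honors size, modality flag, determinism and prevalence", {
  cfg <- targetCohortConfig(nStays = 51L, seed = 21L)
  coh <- generateCohort(cfg)
  expect_identical(length(coh), 51L)
  expect_true(all(vapply(coh@stays, function(s) !is.null(s@activity), logical(1))))
  expect_true(all(vapply(coh@stays, function(s) nrow(s@vitals) > 0, logical(1))))

  cohNoAct <- generateCohort(cohortConfig(nStays = 5, includeActivity = FALSE,
                                          seed = 3))
  expect_true(all(vapply(cohNoAct@stays, function(s) is.null(s@activity),
                         logical(1))))

  # stay-length floor: every stay spans >= 24 h
  hrs <- vapply(coh@stays, function(s)
    as.numeric(difftime(s@dischargeTime, s@admitTime, units = "hours")),
    numeric(1))
  expect_true(all(hrs >= 24))

  # byte-identical serialization from equal seeds
  c1 <- generateCohort(cohortConfig(nStays = 8, seed = 5))
  c2 <- generateCohort(cohortConfig(nStays = 8, seed = 5))
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  writeCohort(c1, d1); writeCohort(c2, d2)
  for (f in c("vitals.csv", "activity.csv", "labels.csv"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))

  # prevalence recovery at n = 1000 within a 99% binomial CI
  big <- generateCohort(cohortConfig(nStays = 1000, prevalence = 0.35, seed = 9))
  phat <- mean(cohortLabels(big))
  expect_lt(abs(phat - 0.35), 2.58 * sqrt(0.35 * 0.65 / 1000))
})

test_that("cohorts round-trip through the long-table interchange format", {
  coh <- generateCohort(cohortConfig(nStays = 4, seed = 13))
  d <- file.path(tempdir(), "rt")
  writeCohort(coh, d)
  back <- readCohort(d)
  expect_identical(length(back), 4L)
  expect_identical(stayIds(back), stayIds(coh))
  expect_identical(cohortLabels(back), cohortLabels(coh))
  expect_equal(admitTimes(back), admitTimes(coh))
  v0 <- coh[[2]]@vitals; v1 <- back[[2]]@vitals
  expect_equal(v1$value, v0$value, tolerance = 1e-12)
  expect_equal(v1$time, v0$time)
  expect_equal(back[[2]]@activity$count, coh[[2]]@activity$count)
})
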