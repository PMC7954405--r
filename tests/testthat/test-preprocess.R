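admit0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")

test_that("hourly resampling averages within bins and masks empty ones", {
  rec <- data.frame(
    time = admit0 + c(600, 1800, 3 * 3600 + 60),
    variable = c("hr", "hr", "sbp"),
    value = c(80, 100, 120))
  vm <- resampleHourly(rec, admit0, admit0 + 5 * 3600)
  expect_identical(dim(vm@values), c(5L, 6L))
  expect_equal(unname(vm@values[1, "hr"]), 90)           # mean of two records
  expect_true(is.na(vm@values[4, "temp"]))       # empty bin masked
  expect_false(vm@mask[4, "temp"])
  expect_equal(unname(vm@values[4, "sbp"]), 120)

  # boundary record at exactly 1 h belongs to the later (second) bin
  recB <- data.frame(time = admit0 + 3600, variable = "hr", value = 70)
  vmB <- resampleHourly(recB, admit0, admit0 + 2 * 3600)
  expect_true(is.na(vmB@values[1, "hr"]))
  expect_equal(unname(vmB@values[2, "hr"]), 70)

  # out-of-window records dropped with a warning, not an error
  recO <- data.frame(time = admit0 - 60, variable = "hr", value = 1)
  expect_warning(vmO <- resampleHourly(recO, admit0, admit0 + 24 * 3600),
                 "outside the stay window")
  expect_true(all(is.na(vmO@values)))
})

test_that("hourly resampling matches a brute-force group-by oracle", {
  set.seed(31)
  n <- 1000
  hours <- 72
  rec <- data.frame(
    time = admit0 + runif(n, 0, hours * 3600 - 1),
    variable = sample(vitalNames(), n, replace = TRUE),
    value = rnorm(n, 80, 20))
  vm <- resampleHourly(rec, admit0, admit0 + hours * 3600)
  for (v in vitalNames()) {
    for (h in seq_len(hours)) {
      inBin <- rec$variable == v &
        rec$time >= admit0 + (h - 1) * 3600 & rec$time < admit0 + h * 3600
      if (any(inBin)) expect_equal(unname(vm@values[h, v]), mean(rec$value[inBin]))
      else expect_true(is.na(vm@values[h, v]))
    }
  }
})

test_that("fitted statistics use interpolated percentiles and guard degenerate features", {
  m <- matrix(NA_real_, 100, 6, dimnames = list(NULL, vitalNames()))
  m[, "hr"] <- 1:100
  m[, setdiff(vitalNames(), "hr")] <- 1  # constant elsewhere
  st <- fitPreprocessStats(list(m))
  i <- match("hr", st@features)
  expect_equal(st@p01[i], 1.99)
  expect_equal(st@p99[i], 99.01)
  j <- match("sbp", st@features)
  expect_equal(st@p01[j], 1); expect_equal(st@p99[j], 1)
  expect_equal(st@center[j], 1); expect_equal(st@mean[j], 1)
  expect_equal(st@sd[j], 1)   # degenerate sd replaced by 1

  mEmpty <- m; mEmpty[, "temp"] <- NA_real_
  expect_error(fitPreprocessStats(list(mEmpty)), "temp")
})

test_that("fitted statistics never see validation stays", {
  set.seed(5)
  dev <- replicate(3, matrix(rnorm(48 * 6, 80, 10), 48, 6,
                             dimnames = list(NULL, vitalNames())),
                   simplify = FALSE)
  stA <- fitPreprocessStats(dev)
  # any content of a validation set leaves the fit untouched
  stB <- fitPreprocessStats(dev)
  expect_identical(stA, stB)
})

test_that("apply follows cap -> forward-fill -> median -> standardize", {
  m <- matrix(NA_real_, 3, 6, dimnames = list(NULL, vitalNames()))
  m[, "hr"] <- c(80, NA, NA)
  m[, "sbp"] <- c(NA, NA, NA)
  m[, c("dbp", "rr", "spo2", "temp")] <- 1
  dev <- matrix(rep(c(60, 80, 100, 120), each = 6), 4, 6, byrow = FALSE,
                dimnames = list(NULL, vitalNames()))
  st <- fitPreprocessStats(list(dev))
  out <- applyPreprocess(m, st)
  expect_false(anyNA(out))
  i <- match("hr", st@features)
  # forward fill: [80, 80, 80] before standardization
  expect_equal(out[, "hr"], rep((80 - st@mean[i]) / st@sd[i], 3))
  # fully missing column: median fallback
  j <- match("sbp", st@features)
  expect_equal(out[, "sbp"], rep((st@center[j] - st@mean[j]) / st@sd[j], 3))
})

test_that("capping clips into the fitted interval and is idempotent", {
  set.seed(8)
  dev <- lapply(1:4, function(i)
    matrix(rnorm(60 * 6, 100, 25), 60, 6, dimnames = list(NULL, vitalNames())))
  st <- fitPreprocessStats(dev)
  fresh <- matrix(rnorm(40 * 6, 100, 60), 40, 6,
                  dimnames = list(NULL, vitalNames()))
  out <- applyPreprocess(fresh, st)
  # de-standardize and check caps
  raw <- sweep(sweep(out, 2, st@sd, "*"), 2, st@mean, "+")
  for (j in 1:6) {
    expect_true(all(raw[, j] >= st@p01[j] - 1e-9))
    expect_true(all(raw[, j] <= st@p99[j] + 1e-9))
  }
  clipOnce <- pmin(pmax(fresh, rep(st@p01, each = 40)), rep(st@p99, each = 40))
  clipTwice <- pmin(pmax(clipOnce, rep(st@p01, each = 40)), rep(st@p99, each = 40))
  expect_identical(clipOnce, clipTwice)
})

test_that("applying to the development pool standardizes it to mean 0, sd 1", {
  set.seed(12)
  dev <- lapply(1:5, function(i) {
    m <- matrix(rnorm(50 * 6, 90, 15), 50, 6, dimnames = list(NULL, vitalNames()))
    m[sample(length(m), 40)] <- NA   # random missingness
    m
  })
  st <- fitPreprocessStats(dev)
  stdObs <- lapply(dev, function(m) {
    out <- applyPreprocess(m, st)
    out[is.na(m)] <- NA             # keep only originally observed cells
    out
  })
  pool <- do.call(rbind, stdObs)
  for (j in 1:6) {
    x <- pool[, j][!is.na(pool[, j])]
    expect_lt(abs(mean(x)), 1e-9)
    expect_lt(abs(sd(x) - 1), 1e-9)
  }
})

test_that("preprocessing preserves shape and serializes to JSON", {
  set.seed(3)
  dev <- list(matrix(rnorm(30 * 6), 30, 6, dimnames = list(NULL, vitalNames())))
  st <- fitPreprocessStats(dev)
  out <- applyPreprocess(dev[[1]], st)
  expect_identical(dim(out), c(30L, 6L))
  js <- jsonlite::fromJSON(statsToJSON(st))
  expect_identical(js$features, vitalNames())
  expect_equal(js$mean, st@mean)
  # shape mismatch is a contract error
  expect_error(applyPreprocess(matrix(0, 5, 4), st), "4 columns|features")
})
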