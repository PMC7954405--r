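# Synthetic ICU cohort generator.
#
# Real multi-modal ICU data are access-restricted, so the package generates
# cohorts with the statistical structure the analysis assumes: an unobserved
# per-patient severity process drives (a) shifts in six vital signs, (b)
# suppression of wrist activity, and (c) the discharge-disposition label.
# All generator distributions are artifact choices, tuned only so that cohort
# summaries land near typical adult ICU magnitudes.

#' Vital-sign generator constants
#'
#' Baseline level, severity coupling (per unit latent severity, at
#' `vitalsEffect = 1`), measurement noise SD, and the SD of the per-patient
#' baseline offset for each vital sign, in native units. Baselines sit near
#' typical adult ICU medians (heart rate 88 bpm, SpO2 97%, ...); couplings
#' encode the direction a deteriorating patient moves (heart and respiratory
#' rate rise, pressures and SpO2 fall). The zero-mean patient offsets model
#' inter-individual baseline physiology, which in real cohorts masks
#' severity-related shifts and is the main reason small-cohort models benefit
#' from pretraining on a larger one.
#'
#' @return data.frame with columns `variable`, `baseline`, `coef`, `noiseSd`,
#'   `patientSd`.
#' @export
vitalGeneratorConstants <- function() {
  data.frame(
    variable = vitalNames(),
    baseline  = c(62, 122, 88, 18, 97, 37),
    coef      = c(-2, -3.5, 3.5, 1.2, -0.8, 0.15),
    noiseSd   = c(8, 12, 8, 3, 1.5, 0.4),
    patientSd = c(6, 10, 8, 2.5, 1.2, 0.3)
  )
}

#' Latent severity path for one stay
#'
#' Hourly mean-reverting (discrete Ornstein-Uhlenbeck) severity series:
#' \eqn{s_{t+1} = s_t + \theta(\mu - s_t) + vol \cdot \epsilon_t} with standard
#' normal innovations. The patient-level attractor \eqn{\mu} is drawn once
#' (standard normal) unless supplied.
#'
#' @param losHours Stay length in hours (>= 24).
#' @param theta Mean-reversion rate in [0,1]; the centered process is AR(1)
#'   with lag-1 coefficient `1 - theta`.
#' @param vol Innovation SD per hour.
#' @param mu Patient attractor; drawn `rnorm(1)` when `NULL`.
#' @param s0 Initial severity.
#' @param seed Optional seed; when supplied the path is a pure function of the
#'   arguments.
#' @return Numeric vector of length `losHours`.
#' @export
severityPath <- function(losHours, theta = 0.1, vol = 0.3, mu = NULL,
                         s0 = 0, seed = NULL) {
  if (losHours < 24)
    stop("invalid stay: length of stay must be at least 24 hours", call. = FALSE)
  if (!is.null(seed))
    return(withSeed(seed, severityPath(losHours, theta, vol, mu, s0)))
  if (is.null(mu)) mu <- rnorm(1)
  eps <- rnorm(losHours - 1L)
  s <- numeric(losHours)
  s[1L] <- s0
  for (t in seq_len(losHours - 1L))
    s[t + 1L] <- s[t] + theta * (mu - s[t]) + vol * eps[t]
  s
}

#' Emit raw vital-sign records along a severity path
#'
#' For each hour of stay and each of the six vitals, with probability
#' `1 - missingRate` between one and three measurements are charted at random
#' minute offsets within the hour. Each record's value is
#' `baseline + offset + coef * vitalsEffect * s_t + noise`, where `offset` is
#' a zero-mean per-patient baseline offset (drawn once per stay) and the other
#' per-variable constants come from [vitalGeneratorConstants()].
#'
#' @param severity Hourly severity vector from [severityPath()].
#' @param config A [CohortConfig-class].
#' @param admitTime Stay admission time anchoring record timestamps.
#' @param noiseScale Multiplier on all non-severity variability (both the
#'   measurement noise SD and the patient-offset SD); 0 makes every record of
#'   a vital equal `baseline + coef * vitalsEffect * s_t` exactly.
#' @param seed Optional seed.
#' @return data.frame with columns `time`, `variable`, `value`, time-ordered.
#' @export
emitVitals <- function(severity, config,
                       admitTime = as.POSIXct("2018-01-01", tz = "UTC"),
                       noiseScale = 1, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, emitVitals(severity, config, admitTime, noiseScale)))
  stopifnot(all(is.finite(severity)))
  konst <- vitalGeneratorConstants()
  H <- length(severity)
  offsets <- rnorm(6L, sd = konst$patientSd * noiseScale)
  out <- vector("list", 6L)
  for (v in seq_len(6L)) {
    observed <- which(runif(H) >= config@missingRate)
    if (!length(observed)) { out[[v]] <- NULL; next }
    nRec <- sample.int(3L, length(observed), replace = TRUE)
    hour <- rep(observed, nRec)
    minute <- sample.int(60L, length(hour), replace = TRUE) - 1L
    value <- konst$baseline[v] + offsets[v] +
      konst$coef[v] * config@vitalsEffect * severity[hour] +
      rnorm(length(hour), sd = konst$noiseSd[v] * noiseScale)
    out[[v]] <- data.frame(
      time = admitTime + (hour - 1L) * 3600 + minute * 60,
      variable = konst$variable[v],
      value = value
    )
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    return(data.frame(time = as.POSIXct(character(), tz = "UTC"),
                      variable = character(), value = numeric()))
  out <- out[order(out$time, out$variable), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Emit a per-epoch activity-count series along a severity path
#'
#' Zero-inflated counts dominated by immobility: each epoch is immobile (count
#' 0) with probability `plogis(immobileIntercept + activityEffect * s)`, and
#' otherwise draws a zero-truncated negative-binomial count whose mean
#' declines with severity. Hourly severity is step-held to epochs.
#'
#' @param severity Hourly severity vector.
#' @param config A [CohortConfig-class].
#' @param admitTime Stay admission time.
#' @param immobileIntercept Logit of the immobility probability at severity 0.
#'   By default it is drawn once per stay as
#'   `rnorm(1, qlogis(0.6), interceptSd)`: patients differ widely in baseline
#'   mobility, and the population center reproduces the ~0.6 immobile fraction
#'   typical of critically ill wrist actigraphy. Supply a value to fix it.
#' @param interceptSd SD of the per-patient immobility intercept; the default
#'   puts per-patient immobile-fraction quartiles near (0.4, 0.8).
#' @param countLogMean Log mean of the nonzero count distribution at severity 0
#'   for an average patient.
#' @param countLevelSd SD of the per-patient offset on the log nonzero-count
#'   mean (overall activity volume varies between patients independently of
#'   acuity).
#' @param countSlope Per-unit-severity decline of the log nonzero-count mean
#'   (scaled by `activityEffect`).
#' @param size Negative-binomial dispersion of nonzero counts.
#' @param seed Optional seed.
#' @return data.frame with columns `time`, `count` (one row per epoch).
#' @export
emitActivity <- function(severity, config,
                         admitTime = as.POSIXct("2018-01-01", tz = "UTC"),
                         immobileIntercept = NULL, interceptSd = 1.0,
                         countLogMean = log(6), countLevelSd = 0.5,
                         countSlope = 0.35, size = 1.2, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, emitActivity(severity, config, admitTime,
                                       immobileIntercept, interceptSd,
                                       countLogMean, countLevelSd,
                                       countSlope, size)))
  stopifnot(all(is.finite(severity)))
  if (is.null(immobileIntercept))
    immobileIntercept <- rnorm(1, qlogis(0.6), interceptSd)
  countLevel <- rnorm(1, 0, countLevelSd)
  perHour <- as.integer(round(60 / config@epochMinutes))
  sev <- rep(severity, each = perHour)
  M <- length(sev)
  pImm <- plogis(immobileIntercept + config@activityEffect * sev)
  immobile <- runif(M) < pImm
  counts <- integer(M)
  idx <- which(!immobile)
  if (length(idx)) {
    mu <- exp(countLogMean + countLevel -
              countSlope * config@activityEffect * sev[idx])
    p0 <- pnbinom(0, size = size, mu = mu)
    # inverse-CDF draw from the zero-truncated negative binomial
    u <- p0 + runif(length(idx)) * (1 - p0)
    counts[idx] <- qnbinom(pmin(u, 1 - 1e-12), size = size, mu = mu)
    counts[idx] <- pmax(counts[idx], 1L)
  }
  data.frame(
    time = admitTime + (seq_len(M) - 1L) * config@epochMinutes * 60,
    count = counts
  )
}

#' Draw a discharge-disposition label from a severity path
#'
#' `label ~ Bernoulli(plogis(linkIntercept + linkSlope * m))` where `m` is the
#' mean severity over the final 24 h of the stay.
#'
#' @param severity Hourly severity vector (length >= 24).
#' @param linkIntercept,linkSlope Logistic link parameters.
#' @param seed Optional seed.
#' @return Integer 0/1; 1 = unsuccessful discharge.
#' @export
assignLabel <- function(severity, linkIntercept, linkSlope, seed = NULL) {
  if (!is.null(seed))
    return(withSeed(seed, assignLabel(severity, linkIntercept, linkSlope)))
  m <- mean(tail(severity, 24L))
  p <- plogis(linkIntercept + linkSlope * m)
  as.integer(runif(1) < p)
}

#' Calibrate the label-link intercept to a target prevalence
#'
#' Finds the intercept such that the cohort-average label probability
#' `mean(plogis(intercept + slope * m))` over the realized severity summaries
#' `m` equals the configured prevalence.
#'
#' @param m Vector of per-stay mean last-24-h severities.
#' @param linkSlope Logistic slope.
#' @param prevalence Target prevalence in (0,1).
#' @return The calibrated intercept.
#' @export
calibrateLinkIntercept <- function(m, linkSlope, prevalence) {
  uniroot(function(b) mean(plogis(b + linkSlope * m)) - prevalence,
          interval = c(-50, 50), tol = 1e-10)$root
}

#' Generate a synthetic ICU cohort
#'
#' Draws admission times uniformly over the configured calendar window (so a
#' chronological holdout is meaningful), lognormal lengths of stay truncated
#' at 24 h, one latent severity path per stay, vital-sign records, optional
#' per-epoch activity counts, and discharge labels whose link intercept is
#' calibrated so the realized prevalence matches the configuration. The
#' result is a pure function of the configuration (including its seed).
#'
#' @param config A [CohortConfig-class].
#' @return An [ICUCohort-class].
#' @examples
#' coh <- generateCohort(cohortConfig(nStays = 5, seed = 7))
#' coh
#' @export
generateCohort <- function(config) {
  validObject(config)
  withSeed(config@seed, {
    n <- config@nStays
    losHours <- pmax(24, round(rlnorm(n, config@losLogMean, config@losLogSd)))
    admit <- config@calendarStart +
      round(runif(n, 0, config@calendarDays * 86400) / 60) * 60
    sevs <- vector("list", n)
    stays <- vector("list", n)
    mLast <- numeric(n)
    for (i in seq_len(n)) {
      mu <- rnorm(1)
      sev <- severityPath(losHours[i], theta = 0.1, vol = 0.3, mu = mu, s0 = mu)
      sevs[[i]] <- sev
      mLast[i] <- mean(tail(sev, 24L))
      vit <- emitVitals(sev, config, admitTime = admit[i])
      act <- if (config@includeActivity)
        emitActivity(sev, config, admitTime = admit[i]) else NULL
      stays[[i]] <- list(vitals = vit, activity = act)
    }
    intercept <- calibrateLinkIntercept(mLast, config@linkSlope, config@prevalence)
    labels <- as.integer(runif(n) < plogis(intercept + config@linkSlope * mLast))
    out <- vector("list", n)
    for (i in seq_len(n)) {
      out[[i]] <- new("ICUStay",
        stayId = sprintf("stay_%05d", i),
        admitTime = admit[i],
        dischargeTime = admit[i] + losHours[i] * 3600,
        vitals = stays[[i]]$vitals,
        activity = stays[[i]]$activity,
        label = labels[i],
        latentMean = mLast[i])
    }
    new("ICUCohort", stays = out, config = config)
  })
}
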