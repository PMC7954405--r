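# Actigraphy feature extraction: nine statistics per consecutive 24-h window
# after ICU admission.

#' Split an activity series into consecutive 24-h windows
#'
#' Window `d` covers the half-open interval
#' `[admitTime + (d-1) * 24 h, admitTime + d * 24 h)`, anchored at ICU
#' admission (not calendar midnight). A trailing partial window is kept if it
#' holds at least two epochs, otherwise dropped.
#'
#' @param activity data.frame with columns `time`, `count`.
#' @param admitTime Stay admission time.
#' @return List of numeric count vectors, with attribute `windowStart`
#'   (POSIXct). An empty series yields an empty list.
#' @export
window24h <- function(activity, admitTime) {
  if (is.null(activity) || !nrow(activity)) {
    out <- list()
    attr(out, "windowStart") <- as.POSIXct(character(), tz = "UTC")
    return(out)
  }
  if (any(activity$count < 0)) stop("activity counts must be nonnegative",
                                    call. = FALSE)
  hrs <- as.numeric(difftime(activity$time, admitTime, units = "hours"))
  if (any(hrs < 0)) stop("activity timestamps precede admission", call. = FALSE)
  d <- floor(hrs / 24) + 1L
  windows <- split(activity$count, d)
  keep <- vapply(windows, length, integer(1)) >= 2L
  # only a trailing partial window may be short; interior windows always have
  # a full epoch complement
  starts <- admitTime + (as.integer(names(windows))[keep] - 1L) * 86400
  windows <- unname(windows[keep])
  attr(windows, "windowStart") <- starts
  windows
}

#' Root mean square of successive differences
#'
#' `sqrt(mean((x[i+1] - x[i])^2))`, i.e. the square root of the sum of squared
#' successive differences divided by `length(x) - 1`.
#'
#' @param x Numeric vector of epoch counts, length >= 2.
#' @return Nonnegative scalar; 0 iff `x` is constant.
#' @export
rmssd <- function(x) {
  if (length(x) < 2L)
    stop("RMSSD is undefined for fewer than 2 epochs", call. = FALSE)
  sqrt(mean(diff(x)^2))
}

#' Fraction of immobile epochs
#'
#' Proportion of epochs whose count is at or below `threshold`. This bounded
#' statistic implements the "immobile count" of wrist-actigraphy summaries
#' (its reported magnitudes lie in [0,1], consistent with a fraction rather
#' than a raw count over 24 h).
#'
#' @param x Numeric vector of epoch counts, length >= 1.
#' @param threshold Immobility threshold (default 0).
#' @return Scalar in [0,1].
#' @export
immobileFraction <- function(x, threshold = 0) {
  if (!length(x)) stop("empty window", call. = FALSE)
  mean(x <= threshold)
}

#' Standard deviation of per-sub-window RMSSD
#'
#' Partitions the window into consecutive complete sub-windows of
#' `subwindowEpochs` epochs (default 60, i.e. hourly sub-windows at 1-min
#' epochs), computes the RMSSD of each, and returns the sample SD (ddof = 1)
#' of those values. This between-hour dispersion construction matches the
#' order-of-magnitude gap between reported RMSSD (~7) and its "standard
#' deviation" (~1) and is well-defined at any epoch length.
#'
#' @param x Numeric vector of epoch counts.
#' @param subwindowEpochs Sub-window length in epochs (>= 2).
#' @return Nonnegative scalar.
#' @export
rmssdSD <- function(x, subwindowEpochs = 60L) {
  if (subwindowEpochs < 2L) stop("sub-windows need >= 2 epochs", call. = FALSE)
  nSub <- floor(length(x) / subwindowEpochs)
  if (nSub < 2L)
    stop("RMSSD-SD is undefined with fewer than 2 complete sub-windows",
         call. = FALSE)
  vals <- vapply(seq_len(nSub), function(s) {
    rmssd(x[((s - 1L) * subwindowEpochs + 1L):(s * subwindowEpochs)])
  }, numeric(1))
  sd(vals)
}

#' Extract the nine window features
#'
#' Returns, in fixed column order: minimum, maximum, mean, variance (ddof = 1),
#' standard deviation (ddof = 1), immobile fraction, IQR (75th - 25th
#' percentile, linear interpolation), RMSSD, and RMSSD-SD. A sub-feature
#' undefined on the window (e.g. RMSSD-SD with fewer than two complete
#' sub-windows) propagates as `NA` and is later median-imputed by
#' [applyPreprocess()].
#'
#' @param window Numeric vector of epoch counts, length >= 2.
#' @param immobileThreshold Threshold for [immobileFraction()].
#' @param subwindowEpochs Sub-window length for [rmssdSD()].
#' @return Named numeric vector of length 9 ([activityFeatureNames()]).
#' @export
extractFeatures <- function(window, immobileThreshold = 0, subwindowEpochs = 60L) {
  if (length(window) < 2L)
    stop("window features need at least 2 epochs", call. = FALSE)
  rsd <- tryCatch(rmssdSD(window, subwindowEpochs), error = function(e) NA_real_)
  out <- c(min(window), max(window), mean(window), var(window), sd(window),
           immobileFraction(window, immobileThreshold),
           pctl(window, 0.75) - pctl(window, 0.25),
           rmssd(window), rsd)
  names(out) <- activityFeatureNames()
  out
}

#' Daily actigraphy feature matrix for a stay
#'
#' Windows the per-epoch count series into consecutive 24-h intervals from
#' admission and computes the nine features per window.
#'
#' @param activity data.frame with columns `time`, `count`, or an
#'   [ICUStay-class] carrying one.
#' @param admitTime Admission time (taken from the stay when omitted).
#' @param stayId Identifier for the result.
#' @param ... Passed to [extractFeatures()].
#' @return An [ActivityFeatureMatrix-class] (0 rows if no window qualifies).
#' @export
activityFeatures <- function(activity, admitTime = NULL, stayId = "", ...) {
  if (is(activity, "ICUStay")) {
    if (is.null(activity@activity))
      stop(sprintf("stay %s carries no activity series", activity@stayId),
           call. = FALSE)
    admitTime <- activity@admitTime
    stayId <- activity@stayId
    activity <- activity@activity
  }
  stopifnot(!is.null(admitTime))
  wins <- window24h(activity, admitTime)
  vals <- matrix(NA_real_, length(wins), 9L,
                 dimnames = list(NULL, activityFeatureNames()))
  for (d in seq_along(wins)) vals[d, ] <- extractFeatures(wins[[d]], ...)
  new("ActivityFeatureMatrix", stayId = stayId, values = vals,
      windowStart = attr(wins, "windowStart"))
}
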