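# Hourly resampling and development-set-only preprocessing of vital signs
# (and, with the same machinery, of the daily actigraphy features).

#' Resample raw vital-sign records to a fixed hourly grid
#'
#' Hour bin `h` covers the half-open interval
#' `[admitTime + (h-1) h, admitTime + h h)`, anchored at ICU admission; a
#' record lying exactly on a bin boundary belongs to the later bin. The cell
#' value is the arithmetic mean of all records of that variable in the bin;
#' bins without records are `NA` with `mask = FALSE`. Records outside the stay
#' window are dropped with a warning, never an error.
#'
#' @param records data.frame with columns `time`, `variable`, `value`.
#' @param admitTime,dischargeTime Stay window; the matrix has
#'   `ceiling(stay hours)` rows.
#' @return A [VitalsMatrix-class].
#' @export
resampleHourly <- function(records, admitTime, dischargeTime) {
  hours <- as.integer(ceiling(as.numeric(
    difftime(dischargeTime, admitTime, units = "hours")) - 1e-9))
  hours <- max(hours, 1L)
  vals <- matrix(NA_real_, hours, 6L, dimnames = list(NULL, vitalNames()))
  if (nrow(records)) {
    bin <- floor(as.numeric(difftime(records$time, admitTime, units = "hours"))) + 1L
    bad <- bin < 1L | bin > hours
    if (any(bad)) {
      warning(sprintf("%d record(s) outside the stay window were dropped",
                      sum(bad)), call. = FALSE)
      records <- records[!bad, , drop = FALSE]
      bin <- bin[!bad]
    }
    if (nrow(records)) {
      col <- match(records$variable, vitalNames())
      key <- (bin - 1L) * 6L + col
      sums <- rowsum(records$value, key)
      cnts <- rowsum(rep(1, length(key)), key)
      uk <- as.integer(rownames(sums))
      vals[cbind((uk - 1L) %/% 6L + 1L, (uk - 1L) %% 6L + 1L)] <- sums / cnts
    }
  }
  new("VitalsMatrix", stayId = "", values = vals, mask = !is.na(vals))
}

matrixValues <- function(x) {
  if (is(x, "VitalsMatrix") || is(x, "ActivityFeatureMatrix")) x@values else x
}

#' Fit preprocessing statistics on a development set
#'
#' Pools the observed (unmasked) values of each feature across development
#' stays and fits, per feature: 1st/99th percentile cap bounds and the
#' imputation median on the raw pool (linear-interpolation percentiles), then
#' standardization mean/SD on the pool \emph{after} capping. A constant
#' feature gets SD 1 so tiny folds never divide by zero.
#'
#' @param devMatrices List of [VitalsMatrix-class], [ActivityFeatureMatrix-class]
#'   or plain matrices (NA = unobserved), all with the same columns.
#' @return A [PreprocessStats-class].
#' @export
fitPreprocessStats <- function(devMatrices) {
  if (!length(devMatrices)) stop("empty development set", call. = FALSE)
  mats <- lapply(devMatrices, matrixValues)
  features <- colnames(mats[[1]])
  if (is.null(features)) features <- paste0("f", seq_len(ncol(mats[[1]])))
  nf <- length(features)
  pooled <- do.call(rbind, mats)
  p01 <- p99 <- center <- mn <- sdv <- numeric(nf)
  for (j in seq_len(nf)) {
    x <- pooled[, j]
    x <- x[!is.na(x)]
    if (!length(x))
      stop(sprintf("feature '%s' has no observed values in the development set",
                   features[j]), call. = FALSE)
    p01[j] <- pctl(x, 0.01)
    p99[j] <- pctl(x, 0.99)
    center[j] <- pctl(x, 0.5)
    xc <- pmin(pmax(x, p01[j]), p99[j])
    mn[j] <- mean(xc)
    s <- sd(xc)
    sdv[j] <- if (is.na(s) || s <= 0) 1 else s
  }
  new("PreprocessStats", features = features, p01 = p01, p99 = p99,
      center = center, mean = mn, sd = sdv)
}

# Core cap -> forward-fill -> standardize transform on a plain matrix.
applyPreprocessCore <- function(vals, stats) {
  if (ncol(vals) != length(stats@features))
    stop(sprintf("matrix has %d columns but stats describe %d features",
                 ncol(vals), length(stats@features)), call. = FALSE)
  if (!is.null(colnames(vals)) &&
      !identical(colnames(vals), stats@features))
    stop("feature names of matrix and statistics disagree", call. = FALSE)
  out <- vals
  for (j in seq_len(ncol(vals))) {
    x <- vals[, j]
    obs <- which(!is.na(x))
    x[obs] <- pmin(pmax(x[obs], stats@p01[j]), stats@p99[j])
    if (length(obs)) {
      # forward-fill from the most recent observed (capped) value
      pos <- findInterval(seq_along(x), obs)
      filled <- ifelse(pos >= 1L, x[obs][pmax(pos, 1L)], NA_real_)
      x <- filled
    }
    x[is.na(x)] <- stats@center[j]
    out[, j] <- (x - stats@mean[j]) / stats@sd[j]
  }
  out
}

#' Apply fitted preprocessing statistics
#'
#' Per feature column, in order: (1) clip observed values into `[p01, p99]`;
#' (2) forward-fill unobserved cells from the most recent observed (capped)
#' value within the same stay, with remaining leading gaps set to the
#' development-set median; (3) standardize with the development mean/SD. The
#' output has the input's shape and no missing cells. Because the statistics
#' come from the development set only, a validation stay's output depends on
#' validation data only through that stay's own records.
#'
#' @param x A [VitalsMatrix-class], [ActivityFeatureMatrix-class], or plain
#'   matrix with `NA` marking unobserved cells.
#' @param stats A [PreprocessStats-class] fitted with [fitPreprocessStats()].
#' @return Same class as `x`, fully observed and standardized.
#' @export
setGeneric("applyPreprocess", function(x, stats) standardGeneric("applyPreprocess"))

#' @rdname applyPreprocess
#' @export
setMethod("applyPreprocess", "matrix", function(x, stats) {
  applyPreprocessCore(x, stats)
})

#' @rdname applyPreprocess
#' @export
setMethod("applyPreprocess", "VitalsMatrix", function(x, stats) {
  new("VitalsMatrix", stayId = x@stayId,
      values = applyPreprocessCore(x@values, stats), mask = x@mask)
})

#' @rdname applyPreprocess
#' @export
setMethod("applyPreprocess", "ActivityFeatureMatrix", function(x, stats) {
  out <- applyPreprocessCore(x@values, stats)
  # standardized immobile fraction may leave [0,1]; keep the class invariant
  # on the raw scale only
  obj <- new("ActivityFeatureMatrix", stayId = x@stayId, values = x@values,
             windowStart = x@windowStart)
  obj@values <- out
  obj
})

#' Serialize preprocessing statistics to JSON
#'
#' @param stats A [PreprocessStats-class].
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
statsToJSON <- function(stats, path = NULL) {
  obj <- list(features = stats@features, p01 = stats@p01, p99 = stats@p99,
              median = stats@center, mean = stats@mean, sd = stats@sd)
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = FALSE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
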