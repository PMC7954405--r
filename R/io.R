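# Long-format table interchange for cohorts.
#
# Three tables: vitals (stay_id, timestamp, variable, value), activity
# (stay_id, timestamp, count), labels (stay_id, admit_time, discharge_time,
# label). Timestamps are ISO-8601 UTC. CSV is the default dialect; Parquet is
# available through the arrow package.

fmtTime <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
parseTime <- function(x) as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

writeTable <- function(df, path, format) {
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Parquet output", call. = FALSE)
    arrow::write_parquet(df, path)
  } else {
    data.table::fwrite(df, path)
  }
}

readTable <- function(path, format) {
  if (format == "parquet") {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("the 'arrow' package is required for Parquet input", call. = FALSE)
    as.data.frame(arrow::read_parquet(path))
  } else {
    as.data.frame(data.table::fread(path))
  }
}

#' Write a cohort to long-format tables
#'
#' @param cohort An [ICUCohort-class].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` (default) or `"parquet"`.
#' @return Invisibly, the paths written (`vitals`, `activity`, `labels`).
#' @seealso [readCohort()]
#' @export
writeCohort <- function(cohort, dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (format == "parquet") ".parquet" else ".csv"
  ids <- stayIds(cohort)

  vit <- do.call(rbind, lapply(seq_along(ids), function(i) {
    v <- cohort[[i]]@vitals
    if (!nrow(v)) return(NULL)
    data.frame(stay_id = ids[i], timestamp = fmtTime(v$time),
               variable = v$variable, value = v$value)
  }))
  if (is.null(vit))
    vit <- data.frame(stay_id = character(), timestamp = character(),
                      variable = character(), value = numeric())

  act <- do.call(rbind, lapply(seq_along(ids), function(i) {
    a <- cohort[[i]]@activity
    if (is.null(a) || !nrow(a)) return(NULL)
    data.frame(stay_id = ids[i], timestamp = fmtTime(a$time), count = a$count)
  }))
  if (is.null(act))
    act <- data.frame(stay_id = character(), timestamp = character(),
                      count = numeric())

  lab <- data.frame(
    stay_id = ids,
    admit_time = fmtTime(admitTimes(cohort)),
    discharge_time = fmtTime(as.POSIXct(
      vapply(cohort@stays, function(s) as.numeric(s@dischargeTime), numeric(1)),
      origin = "1970-01-01", tz = "UTC")),
    label = cohortLabels(cohort)
  )

  paths <- c(vitals = file.path(dir, paste0("vitals", ext)),
             activity = file.path(dir, paste0("activity", ext)),
             labels = file.path(dir, paste0("labels", ext)))
  writeTable(vit, paths[["vitals"]], format)
  writeTable(act, paths[["activity"]], format)
  writeTable(lab, paths[["labels"]], format)
  invisible(paths)
}

#' Read a cohort from long-format tables
#'
#' Reconstructs an [ICUCohort-class] from the tables written by
#' [writeCohort()]. The latent severity diagnostic is not part of the
#' interchange format and is `NA` on read.
#'
#' @param dir Directory holding `vitals`, `activity` and `labels` tables.
#' @param format `"csv"` (default) or `"parquet"`.
#' @return An [ICUCohort-class].
#' @export
readCohort <- function(dir, format = c("csv", "parquet")) {
  format <- match.arg(format)
  ext <- if (format == "parquet") ".parquet" else ".csv"
  vit <- readTable(file.path(dir, paste0("vitals", ext)), format)
  actPath <- file.path(dir, paste0("activity", ext))
  act <- if (file.exists(actPath)) readTable(actPath, format) else NULL
  lab <- readTable(file.path(dir, paste0("labels", ext)), format)

  vitSplit <- split(vit, vit$stay_id)
  actSplit <- if (!is.null(act) && nrow(act)) split(act, act$stay_id) else list()
  stays <- lapply(seq_len(nrow(lab)), function(i) {
    id <- lab$stay_id[i]
    v <- vitSplit[[id]]
    vdf <- if (is.null(v))
      data.frame(time = as.POSIXct(character(), tz = "UTC"),
                 variable = character(), value = numeric())
    else data.frame(time = parseTime(v$timestamp), variable = v$variable,
                    value = v$value)
    a <- actSplit[[id]]
    adf <- if (is.null(a)) NULL
    else data.frame(time = parseTime(a$timestamp), count = a$count)
    new("ICUStay", stayId = id,
        admitTime = parseTime(lab$admit_time[i]),
        dischargeTime = parseTime(lab$discharge_time[i]),
        vitals = vdf, activity = adf,
        label = as.integer(lab$label[i]), latentMean = NA_real_)
  })
  new("ICUCohort", stays = stays, config = NULL)
}
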