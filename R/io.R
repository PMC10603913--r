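## CSV schema shared by the generator and the analysis stages.
##
## Timestamps are serialized as ISO 8601 UTC; internally everything runs on
## integer minutes from subject start. A blank cell is a missing value;
## validity flags are 0/1. Numeric cells are written with 17 significant
## digits so write -> read round-trips are lossless.

iso_time <- function(start, minutes) {
  format(start + minutes * 60, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_iso <- function(x) {
  out <- as.POSIXct(x, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (anyNA(out)) {
    stop("unparsable timestamp in row ", which(is.na(out))[1], ": ",
         x[is.na(out)][1])
  }
  out
}

num_chr <- function(x) {
  out <- ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  out
}

flag_chr <- function(x) ifelse(is.na(x), "0", as.character(as.integer(x)))

#' Write a vital series to CSV
#'
#' Schema: `timestamp,spo2,spo2_valid,hr,hr_valid,temp,temp_valid` (plus
#' `*_filled` flags when present after [forward_fill()]).
#'
#' @param series A [vital_series()].
#' @param path Output file.
#' @param drop_blank_rows Omit rows where all channels are blank, producing
#'   the raw missing-timestamp form that [normalize_timeline()] repairs.
#' @return `path`, invisibly.
#' @export
write_vitals <- function(series, path, drop_blank_rows = FALSE) {
  stopifnot(inherits(series, "vital_series"))
  start <- attr(series, "start") %||% as.POSIXct("2023-01-01", tz = "UTC")
  df <- data.frame(timestamp = iso_time(start, series$t),
                   spo2 = num_chr(series$spo2),
                   spo2_valid = flag_chr(series$spo2_valid),
                   spo2_filled = flag_chr(series$spo2_filled),
                   hr = num_chr(series$hr),
                   hr_valid = flag_chr(series$hr_valid),
                   hr_filled = flag_chr(series$hr_filled),
                   temp = num_chr(series$temp),
                   temp_valid = flag_chr(series$temp_valid),
                   temp_filled = flag_chr(series$temp_filled))
  if (drop_blank_rows) {
    blank <- is.na(series$spo2) & is.na(series$hr) & is.na(series$temp)
    df <- df[!blank, , drop = FALSE]
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a vital series from CSV
#'
#' Inverse of [write_vitals()]: exact round trip of values, blanks and
#' flags. Minutes are measured from the first timestamp in the file.
#'
#' @param path CSV file.
#' @param interval Expected grid spacing in minutes; a differing spacing in
#'   the file raises a warning (regrid with [normalize_timeline()]).
#' @param subject_id Identifier carried on the result.
#' @return A [vital_series()].
#' @export
read_vitals <- function(path, interval = 1, subject_id = NULL) {
  need <- c("timestamp", "spo2", "spo2_valid", "hr", "hr_valid",
            "temp", "temp_valid")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  if (is.null(subject_id)) {
    subject_id <- sub("^vitals_", "", sub("[.]csv$", "", basename(path)))
  }
  if (nrow(df) == 0) {
    return(vital_series(numeric(0), interval = interval,
                        subject_id = subject_id))
  }
  ts <- parse_iso(df$timestamp)
  t <- as.numeric(difftime(ts, ts[1], units = "mins"))
  num <- function(col) suppressWarnings(as.numeric(ifelse(df[[col]] == "",
                                                          NA, df[[col]])))
  flg <- function(col) {
    if (col %in% names(df)) df[[col]] == "1" else rep(FALSE, nrow(df))
  }
  records <- data.frame(t = t, spo2 = num("spo2"),
                        spo2_valid = flg("spo2_valid"),
                        spo2_filled = flg("spo2_filled"),
                        hr = num("hr"), hr_valid = flg("hr_valid"),
                        hr_filled = flg("hr_filled"),
                        temp = num("temp"), temp_valid = flg("temp_valid"),
                        temp_filled = flg("temp_filled"))
  if (length(t) >= 2 &&
      (length(unique(diff(t))) > 1 || diff(t)[1] != interval)) {
    ## raw form with missing timestamps: return plain records for regridding
    warning("file grid differs from the expected ", interval,
            "-min interval; returning raw records -- regrid with ",
            "normalize_timeline()")
    return(records)
  }
  vital_series(t, spo2 = records$spo2, hr = records$hr, temp = records$temp,
               spo2_valid = records$spo2_valid, hr_valid = records$hr_valid,
               temp_valid = records$temp_valid,
               spo2_filled = records$spo2_filled,
               hr_filled = records$hr_filled,
               temp_filled = records$temp_filled,
               interval = interval, subject_id = subject_id, start = ts[1])
}

#' Write a pressure-grid series to CSV
#'
#' Schema: `timestamp,r0c0,...,r{R-1}c{C-1}` (row-major element order).
#'
#' @param series A [pressure_series()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pressure <- function(series, path) {
  stopifnot(inherits(series, "pressure_series"))
  d <- dim(series$grid)
  start <- as.POSIXct("2023-01-01", tz = "UTC")
  cols <- list(timestamp = iso_time(start, series$t))
  for (r in seq_len(d[2])) {
    for (cc in seq_len(d[3])) {
      cols[[sprintf("r%dc%d", r - 1, cc - 1)]] <- num_chr(series$grid[, r, cc])
    }
  }
  utils::write.csv(as.data.frame(cols), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a pressure-grid series from CSV
#'
#' @param path CSV file with the [write_pressure()] schema.
#' @param interval Frame spacing in minutes (default 5).
#' @param subject_id,weight,shoe_group Metadata carried onto the result.
#' @return A [pressure_series()].
#' @export
read_pressure <- function(path, interval = 5, subject_id = NULL,
                          weight = NA_real_, shoe_group = NA_character_) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"timestamp" %in% names(df)) stop("schema error: no timestamp column")
  el <- grep("^r[0-9]+c[0-9]+$", names(df), value = TRUE)
  if (length(el) == 0) stop("schema error: no element columns")
  rr <- as.integer(sub("^r([0-9]+)c[0-9]+$", "\\1", el))
  cc <- as.integer(sub("^r[0-9]+c([0-9]+)$", "\\1", el))
  rows <- max(rr) + 1L
  cols <- max(cc) + 1L
  if (is.null(subject_id)) {
    subject_id <- sub("^pressure_", "", sub("[.]csv$", "", basename(path)))
  }
  ts <- parse_iso(df$timestamp)
  t <- as.numeric(difftime(ts, ts[1], units = "mins"))
  grid <- array(0, dim = c(nrow(df), rows, cols))
  for (j in seq_along(el)) {
    grid[, rr[j] + 1L, cc[j] + 1L] <- as.numeric(df[[el[j]]])
  }
  pressure_series(t, grid, interval = interval, subject_id = subject_id,
                  weight = weight, shoe_group = shoe_group)
}

#' Write / read the subject metadata table
#'
#' @param dataset A `cohort_dataset`.
#' @param path CSV file.
#' @return `path` invisibly (writer); a data frame (reader).
#' @export
write_subjects <- function(dataset, path) {
  rows <- lapply(dataset$subjects, function(s) {
    p <- s$profile
    flags <- as.list(p$conditions)
    flags[] <- lapply(flags, as.integer)
    cbind(data.frame(subject_id = p$subject_id, group = p$group, age = p$age,
                     height = p$height, weight = p$weight),
          as.data.frame(flags))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_subjects
#' @export
read_subjects <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
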