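## File formats: vendor-style raw CSV (header block + x,y,z body), epoch-count
## CSV exports, and sleep-diary CSV. Timestamps are naive local clock time.

#' Read a raw tri-axial acceleration CSV
#'
#' Parses a vendor-style export: a header block declaring at least the sampling
#' rate and the start time, followed by one x,y,z sample per row in g. Both
#' comma and semicolon delimiters are accepted, and the start time may be
#' given either as a single ISO-8601 date-time (`Start Time: 2019-06-03
#' 00:00:00`) or as separate `Start Date` (ISO `2019-06-03` or US `6/3/2019`)
#' and `Start Time` (`HH:MM:SS`) lines.
#'
#' @param path path to the CSV file.
#' @return A [raw_recording()].
#' @export
read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("format error: empty file")

  is_body <- function(ln) {
    f <- strsplit(trimws(ln), "[,;]")[[1]]
    length(f) == 3L && !any(is.na(suppressWarnings(as.numeric(f))))
  }
  body_start <- NA_integer_
  for (i in seq_along(lines)) {
    if (is_body(lines[i])) { body_start <- i; break }
  }
  if (is.na(body_start)) stop("format error: no numeric x,y,z body found")
  header <- lines[seq_len(body_start - 1L)]

  grab <- function(pattern) {
    hit <- grep(pattern, header, ignore.case = TRUE, value = TRUE)
    if (length(hit)) hit[1] else NA_character_
  }
  num_in <- function(s) {
    m <- regmatches(s, regexpr("[0-9]+\\.?[0-9]*", s))
    if (length(m)) as.numeric(m) else NA_real_
  }

  rate_line <- grab("sample\\s*rate")
  if (is.na(rate_line)) stop("format error: missing header field 'Sample Rate'")
  sampling_rate <- num_in(sub("(?i).*sample\\s*rate[^0-9]*", "", rate_line,
                              perl = TRUE))
  if (is.na(sampling_rate) || sampling_rate <= 0) {
    stop("format error: could not parse 'Sample Rate'")
  }

  start_time <- parse_start_time(header)
  if (is.na(start_time)) {
    stop("format error: missing header field 'Start Time'/'Start Date'")
  }

  pid_line  <- grab("participant")
  site_line <- grab("^\\s*site")
  pid  <- if (!is.na(pid_line)) trimws(sub(".*?[:]", "", pid_line)) else "P01"
  site <- if (!is.na(site_line)) trimws(sub(".*?[:]", "", site_line)) else
    "non_dominant_wrist"
  dr_line <- grab("dynamic\\s*range")
  dr <- if (!is.na(dr_line)) num_in(sub(".*?[:]", "", dr_line)) else 6

  body <- lines[body_start:length(lines)]
  body <- body[nzchar(trimws(body))]
  sep <- if (grepl(";", body[1], fixed = TRUE)) ";" else ","
  parts <- strsplit(body, sep, fixed = TRUE)
  bad_len <- which(lengths(parts) != 3L)
  if (length(bad_len)) {
    stop("format error: row ", body_start + bad_len[1] - 1L,
         " does not have 3 columns")
  }
  vals <- suppressWarnings(as.numeric(unlist(parts, use.names = FALSE)))
  mat <- matrix(vals, ncol = 3L, byrow = TRUE)
  bad <- which(!stats::complete.cases(mat) | !is.finite(rowSums(mat)))
  if (length(bad)) {
    stop("format error: non-numeric sample in row ",
         body_start + bad[1] - 1L)
  }
  raw_recording(mat, start_time, sampling_rate,
                participant_id = pid, site = site, dynamic_range = dr)
}

## Resolve the start timestamp from a header block; returns NA on failure.
parse_start_time <- function(header) {
  iso <- grep("start\\s*time", header, ignore.case = TRUE, value = TRUE)
  if (length(iso)) {
    s <- sub("(?i).*start\\s*time[^0-9]*", "", iso[1], perl = TRUE)
    t <- tryCatch(
      as.POSIXct(s, tz = "UTC",
                 tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                "%Y-%m-%dT%H:%M:%OS")),
      error = function(e) as.POSIXct(NA))
    if (!is.na(t)) return(t)
  }
  date_line <- grep("start\\s*date", header, ignore.case = TRUE, value = TRUE)
  time_line <- grep("start\\s*time", header, ignore.case = TRUE, value = TRUE)
  if (length(date_line) && length(time_line)) {
    d_str <- trimws(sub("(?i).*start\\s*date[:\\s]*", "", date_line[1],
                        perl = TRUE))
    t_str <- regmatches(time_line[1],
                        regexpr("[0-9]{1,2}:[0-9]{2}(:[0-9]{2})?",
                                time_line[1]))
    d <- suppressWarnings(as.Date(d_str,
                                  tryFormats = c("%Y-%m-%d", "%m/%d/%Y",
                                                 "%d/%m/%Y")))
    if (!is.na(d) && length(t_str)) {
      if (nchar(t_str) == 5L) t_str <- paste0(t_str, ":00")
      return(as.POSIXct(paste(format(d), t_str), tz = "UTC"))
    }
  }
  as.POSIXct(NA)
}

#' Write a raw recording as CSV
#'
#' Writes a self-describing header followed by one `x,y,z` row per sample with
#' six decimal places, so output bytes are stable for a given recording.
#'
#' @param rec a [raw_recording()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(rec, path) {
  stopifnot(inherits(rec, "raw_recording"))
  if (nrow(rec$data) < 1L) stop("cannot write an empty recording")
  header <- c(
    "Raw acceleration export",
    paste0("Participant: ", rec$participant_id),
    paste0("Site: ", rec$site),
    paste0("Sample Rate: ", format(rec$sampling_rate)),
    paste0("Start Time: ", format(rec$start_time, "%Y-%m-%d %H:%M:%S")),
    paste0("Dynamic Range (g): ", format(rec$dynamic_range)),
    "------------------------------")
  body <- sprintf("%.6f,%.6f,%.6f",
                  rec$data[, 1], rec$data[, 2], rec$data[, 3])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con = con, sep = "\n")
  invisible(path)
}

#' Read an activity-counts epoch CSV
#'
#' Reads vendor-exported activity counts on a fixed epoch grid. The file must
#' have a timestamp column followed by either a vector-magnitude column or
#' per-axis columns (combined as the Euclidean norm). Epoch spacing must equal
#' `epoch_length`.
#'
#' @param path path to the CSV file.
#' @param epoch_length expected epoch length in seconds (default 5).
#' @param participant_id,site metadata attached to the returned series.
#' @return An [epoch_series()] with metric `"counts"`.
#' @export
read_epoch_counts <- function(path, epoch_length = 5,
                              participant_id = "P01",
                              site = "non_dominant_wrist") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a timestamp and a value column")
  t <- suppressWarnings(as.POSIXct(df[[1]], tz = "UTC",
                                   tryFormats = c("%Y-%m-%d %H:%M:%OS",
                                                  "%Y-%m-%dT%H:%M:%OS")))
  if (any(is.na(t))) stop("unparsable epoch timestamp in counts file")
  if (length(t) > 1L) {
    dt <- diff(as.numeric(t))
    if (any(abs(dt - epoch_length) > 1e-6)) {
      stop("counts epochs are not spaced ", epoch_length,
           " s apart (found ", dt[which(abs(dt - epoch_length) > 1e-6)[1]],
           " s)")
    }
  }
  vm_col <- grep("^(vm|vector)", names(df), ignore.case = TRUE)
  if (length(vm_col)) {
    counts <- as.numeric(df[[vm_col[1]]])
  } else {
    axis_cols <- df[, -1, drop = FALSE]
    axis_cols <- axis_cols[vapply(axis_cols, is.numeric, logical(1))]
    if (ncol(axis_cols) >= 3L) {
      counts <- sqrt(rowSums(as.matrix(axis_cols[, 1:3])^2))
    } else if (ncol(axis_cols) >= 1L) {
      counts <- as.numeric(axis_cols[[1]])
    } else {
      stop("no numeric counts columns found")
    }
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and non-negative")
  }
  epoch_series(t, counts, metric = "counts", participant_id = participant_id,
               site = site, epoch_length = epoch_length)
}

#' Read a sleep diary CSV
#'
#' Expects columns `date`, `bed_time`, `rise_time`. A rise time at or before
#' the bed time is resolved to the following calendar day (nights crossing
#' midnight).
#'
#' @param path path to the CSV file.
#' @return A data frame of class `sleep_diary` with columns `date`, `bed`,
#'   `rise` (POSIXct) and `duration_h`.
#' @export
read_sleep_diary <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "bed_time", "rise_time")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sleep diary is missing column(s): ",
                         paste(miss, collapse = ", "))
  parse_clock <- function(s, row) {
    s <- trimws(s)
    if (!nzchar(s) || is.na(s)) stop("unparsable time in diary row ", row)
    if (grepl("^[0-9]{1,2}:[0-9]{2}$", s)) s <- paste0(s, ":00")
    if (!grepl("^[0-9]{1,2}:[0-9]{2}:[0-9]{2}$", s)) {
      stop("unparsable time in diary row ", row)
    }
    p <- as.numeric(strsplit(s, ":")[[1]])
    p[1] * 3600 + p[2] * 60 + p[3]
  }
  n <- nrow(df)
  date <- suppressWarnings(as.Date(df$date,
                                   tryFormats = c("%Y-%m-%d", "%m/%d/%Y")))
  if (any(is.na(date))) {
    stop("unparsable date in diary row ", which(is.na(date))[1])
  }
  bed_s  <- vapply(seq_len(n), function(i) parse_clock(df$bed_time[i], i),
                   numeric(1))
  rise_s <- vapply(seq_len(n), function(i) parse_clock(df$rise_time[i], i),
                   numeric(1))
  day0 <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  bed  <- day0 + bed_s
  rise <- day0 + rise_s + ifelse(rise_s <= bed_s, 86400, 0)
  out <- data.frame(date = date, bed = bed, rise = rise,
                    duration_h = as.numeric(rise - bed, units = "hours"))
  class(out) <- c("sleep_diary", "data.frame")
  out
}

#' Write a sleep diary CSV
#'
#' @param diary a `sleep_diary` data frame (or any data frame with `date`,
#'   `bed`, `rise` POSIXct columns).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sleep_diary <- function(diary, path) {
  out <- data.frame(date = format(as.Date(diary$date)),
                    bed_time = format(diary$bed, "%H:%M:%S"),
                    rise_time = format(diary$rise, "%H:%M:%S"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write epoch metric series to a combined CSV
#'
#' One row per epoch with a `<metric>_mg` (or `counts_5s`) column per series,
#' plus the shared wear/imputed/label flags of the first series.
#'
#' @param series_list a list of [epoch_series()] on identical epoch grids.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_epoch_csv <- function(series_list, path) {
  if (inherits(series_list, "epoch_series")) series_list <- list(series_list)
  s1 <- series_list[[1]]
  for (s in series_list) {
    if (length(s$time) != length(s1$time) ||
        abs(as.numeric(s$time[1]) - as.numeric(s1$time[1])) > 1e-6) {
      stop("all series must share one epoch grid")
    }
  }
  cols <- lapply(series_list, `[[`, "value")
  names(cols) <- vapply(series_list, function(s) {
    if (s$metric == "counts") "counts_5s" else paste0(tolower(s$metric), "_mg")
  }, character(1))
  out <- cbind(data.frame(time = format(s1$time, "%Y-%m-%d %H:%M:%S")),
               as.data.frame(cols),
               data.frame(wear = s1$wear, imputed = s1$imputed,
                          label = s1$label))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
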