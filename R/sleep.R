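## Diary-guided separation of waking and sleeping hours. Sleep is detected on
## the non-dominant wrist from the posture angle of the z axis relative to the
## horizontal plane: periods in which the angle changes by less than 5 degrees
## between successive 5-s steps, sustained for at least 5 min, are sleep
## candidates; candidates separated by less than 60 min are merged; the
## longest merged block inside the diary window (expanded by 2 h on each
## side) gives the night's sleep period. The resulting segmentation is
## projected onto the other wear sites of the same participant.

#' Posture angle of the z axis
#'
#' Per 5-s window, the angle (degrees) of the rolling-median-smoothed axis
#' means: `atan(z / sqrt(x^2 + y^2)) * 180 / pi`. +90 is z pointing straight
#' up (against gravity), -90 straight down.
#'
#' @param rec a calibrated [raw_recording()].
#' @param smooth window length in seconds for the per-window axis means
#'   (default 5).
#' @param k rolling-median span, in windows, applied to the axis means
#'   (default 5; must be odd).
#' @return A data frame with `time` (window starts) and `angle` (degrees).
#' @export
z_angle <- function(rec, smooth = 5, k = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  sl <- epoch_slices(rec, smooth)
  ax <- vapply(1:3, function(a) epoch_means(rec$data[, a], sl),
               numeric(sl$n_ep))
  ax <- matrix(ax, nrow = sl$n_ep)
  if (sl$n_ep > k) {
    ax <- apply(ax, 2, stats::runmed, k = k, endrule = "median")
  }
  angle <- atan2(ax[, 3], sqrt(ax[, 1]^2 + ax[, 2]^2)) * 180 / pi
  data.frame(time = sl$time, angle = angle)
}

#' Detect one night's sleep period from the posture angle
#'
#' Within the diary-guided search window (`[bed - expand, rise + expand]`),
#' marks 5-s steps whose successive absolute angle change is below
#' `angle_threshold` sustained for at least `min_block` minutes as candidate
#' sleep, merges candidates separated by less than `merge_gap` minutes, and
#' returns the bounds of the longest merged block. When no candidate block
#' exists the diary times are returned with a warning.
#'
#' @param angles data frame from [z_angle()].
#' @param night one row of a sleep diary (with POSIXct `bed` and `rise`).
#' @param angle_threshold stillness threshold in degrees (default 5).
#' @param min_block minimum sustained stillness in minutes (default 5).
#' @param merge_gap merge candidates closer than this many minutes
#'   (default 60).
#' @param expand search-window expansion around the diary times in hours
#'   (default 2).
#' @return A list with `onset`, `wake` (POSIXct) and `fallback` (logical).
#' @export
detect_sleep_period <- function(angles, night, angle_threshold = 5,
                                min_block = 5, merge_gap = 60, expand = 2) {
  w0 <- night$bed - expand * 3600
  w1 <- night$rise + expand * 3600
  sel <- which(angles$time >= w0 & angles$time <= w1)
  fallback <- list(onset = night$bed, wake = night$rise, fallback = TRUE)
  if (length(sel) < 2L) {
    warning("angle series does not cover the diary night; using diary times")
    return(fallback)
  }
  t <- angles$time[sel]
  dt <- as.numeric(diff(as.numeric(t)))
  step <- stats::median(dt)
  still <- c(FALSE, abs(diff(angles$angle[sel])) < angle_threshold)

  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- ceiling(min_block * 60 / step)
  cand <- which(r$values & r$lengths >= need)
  if (!length(cand)) {
    warning("no sustained still period found; falling back to diary times")
    return(fallback)
  }
  blocks <- data.frame(start = as.numeric(t[starts[cand]]),
                       end = as.numeric(t[ends[cand]]) + step)
  ## merge candidate blocks separated by < merge_gap minutes
  merged <- blocks[1, , drop = FALSE]
  if (nrow(blocks) > 1L) {
    for (i in 2:nrow(blocks)) {
      if (blocks$start[i] - merged$end[nrow(merged)] < merge_gap * 60) {
        merged$end[nrow(merged)] <- blocks$end[i]
      } else {
        merged <- rbind(merged, blocks[i, ])
      }
    }
  }
  best <- which.max(merged$end - merged$start)
  list(onset = as.POSIXct(merged$start[best], origin = "1970-01-01",
                          tz = "UTC"),
       wake = as.POSIXct(merged$end[best], origin = "1970-01-01", tz = "UTC"),
       fallback = FALSE)
}

#' Segment days into waking and sleeping hours
#'
#' Runs [detect_sleep_period()] for every diary night on a non-dominant-wrist
#' recording's posture angle.
#'
#' @param rec the non-dominant-wrist [raw_recording()].
#' @param diary a `sleep_diary` from [read_sleep_diary()].
#' @param ... passed on to [detect_sleep_period()].
#' @return An object of class `day_segmentation`: data frame with `date`,
#'   `onset`, `wake`, `fallback`, plus attributes `span` (recording span) and
#'   `source` (wear site).
#' @export
segment_days <- function(rec, diary, ...) {
  stopifnot(inherits(rec, "raw_recording"))
  ang <- z_angle(rec)
  rows <- lapply(seq_len(nrow(diary)), function(i) {
    p <- detect_sleep_period(ang, diary[i, ], ...)
    data.frame(date = as.Date(diary$date[i]), onset = p$onset,
               wake = p$wake, fallback = p$fallback)
  })
  out <- do.call(rbind, rows)
  if (any(out$onset >= out$wake)) stop("detected sleep onset at/after wake")
  attr(out, "span") <- c(rec$start_time,
                         rec$start_time + recording_duration(rec))
  attr(out, "source") <- rec$site
  class(out) <- c("day_segmentation", "data.frame")
  out
}

#' Project a segmentation onto an epoch series
#'
#' Labels every epoch `"sleep"` if it starts inside any detected sleep period
#' and `"wake"` otherwise, regardless of the series' own wear site, so that
#' the non-dominant-wrist segmentation drives all three sites identically.
#' The series must span the same period the segmentation was derived from.
#'
#' @param seg a `day_segmentation` from [segment_days()].
#' @param series an [epoch_series()].
#' @param tol allowed span mismatch in seconds (default one epoch).
#' @return The labeled [epoch_series()].
#' @export
apply_segmentation <- function(seg, series, tol = NULL) {
  stopifnot(inherits(seg, "day_segmentation"),
            inherits(series, "epoch_series"))
  if (is.null(tol)) tol <- series$epoch_length
  span <- attr(seg, "span")
  s0 <- as.numeric(series$time[1])
  s1 <- as.numeric(series$time[length(series$time)]) + series$epoch_length
  if (abs(s0 - as.numeric(span[1])) > tol ||
      abs(s1 - as.numeric(span[2])) > tol) {
    stop("series span does not match the segmentation span")
  }
  t <- as.numeric(series$time)
  lab <- rep("wake", length(t))
  for (i in seq_len(nrow(seg))) {
    lab[t >= as.numeric(seg$onset[i]) & t < as.numeric(seg$wake[i])] <- "sleep"
  }
  series$label <- lab
  series
}
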