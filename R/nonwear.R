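## Non-wear and abnormal-acceleration handling. The device is considered not
## worn during a 15-min block when, over the surrounding 60-min window, at
## least 2 of the 3 axes show a standard deviation below 13 mg or a value
## range below 50 mg. Epochs containing sustained accelerations above 5.5 g
## are treated as invalid, and invalid epochs are imputed from the mean of
## valid epochs at the same clock time on the other recorded days.

#' Detect non-wear blocks from the raw signal
#'
#' Classifies each 15-min block (aligned to local midnight) as non-wear if,
#' over the 60-min window centred on the block (truncated at the recording
#' edges), at least 2 of the 3 axes have a standard deviation strictly below
#' `sd_threshold` mg or at least 2 of the 3 axes have a value range strictly
#' below `range_threshold` mg.
#'
#' @param rec a [raw_recording()].
#' @param sd_threshold per-axis SD threshold in mg (default 13).
#' @param range_threshold per-axis range threshold in mg (default 50).
#' @param block block length in minutes (default 15).
#' @param window moving-window length in minutes (default 60).
#' @return A data frame with `block_start` (POSIXct) and `nonwear` (logical),
#'   one row per block overlapping the recording.
#' @export
detect_nonwear <- function(rec, sd_threshold = 13, range_threshold = 50,
                           block = 15, window = 60) {
  stopifnot(inherits(rec, "raw_recording"))
  fs <- rec$sampling_rate
  block_s <- block * 60
  half_extra <- (window - block) * 60 / 2  # window overhang on each side
  start_abs <- as.numeric(rec$start_time)
  end_abs <- start_abs + nrow(rec$data) / fs
  if (end_abs - start_abs < block_s) stop("recording shorter than one block")
  first_block <- floor(start_abs / block_s) * block_s
  block_starts <- seq(first_block, end_abs - 1e-9, by = block_s)

  sub_s <- block_s / 2
  fast <- abs(half_extra / sub_s - round(half_extra / sub_s)) < 1e-9
  if (fast) {
    ## aggregate per half-block subblocks (midnight-anchored), then combine
    ## the exact subblocks covered by each 60-min window
    n_samp <- nrow(rec$data)
    sub_len <- sub_s * fs
    if (abs(sub_len - round(sub_len)) > 1e-9) {
      stop("subblock length x sampling rate must be an integer")
    }
    sub_len <- as.integer(round(sub_len))
    first_sub <- floor(start_abs / sub_s)
    lead <- as.integer(round((start_abs - first_sub * sub_s) * fs))
    n_sub <- as.integer(ceiling((lead + n_samp) / sub_len))
    sub_ids <- first_sub + seq_len(n_sub) - 1
    pad <- n_sub * sub_len - lead - n_samp
    agg <- function(v, fun) {
      m <- matrix(c(rep(NA_real_, lead), v, rep(NA_real_, pad)),
                  nrow = sub_len)
      fun(m)
    }
    cnt <- agg(rec$data[, 1], function(m) colSums(!is.na(m)))
    sums <- vapply(1:3, function(a) {
      agg(rec$data[, a], function(m) colSums(m, na.rm = TRUE))
    }, numeric(n_sub))
    sqs <- vapply(1:3, function(a) {
      agg(rec$data[, a]^2, function(m) colSums(m, na.rm = TRUE))
    }, numeric(n_sub))
    mins <- vapply(1:3, function(a) {
      agg(rec$data[, a], function(m) suppressWarnings(
        apply(m, 2, min, na.rm = TRUE)))
    }, numeric(n_sub))
    maxs <- vapply(1:3, function(a) {
      agg(rec$data[, a], function(m) suppressWarnings(
        apply(m, 2, max, na.rm = TRUE)))
    }, numeric(n_sub))
    sums <- matrix(sums, nrow = n_sub); sqs <- matrix(sqs, nrow = n_sub)
    mins <- matrix(mins, nrow = n_sub); maxs <- matrix(maxs, nrow = n_sub)
    overhang <- as.integer(round(half_extra / sub_s))
    nonwear <- vapply(seq_along(block_starts), function(i) {
      b0 <- block_starts[i] / sub_s
      want <- (b0 - overhang):(b0 + 1 + overhang)
      j <- match(want, sub_ids)
      j <- j[!is.na(j)]
      n <- sum(cnt[j])
      if (n < 2) return(FALSE)
      mu <- colSums(sums[j, , drop = FALSE]) / n
      varr <- (colSums(sqs[j, , drop = FALSE]) - n * mu^2) / (n - 1)
      sds <- sqrt(pmax(varr, 0)) * 1000
      rngs <- (apply(maxs[j, , drop = FALSE], 2, max) -
                 apply(mins[j, , drop = FALSE], 2, min)) * 1000
      sum(sds < sd_threshold) >= 2L || sum(rngs < range_threshold) >= 2L
    }, logical(1))
  } else {
    nonwear <- logical(length(block_starts))
    for (i in seq_along(block_starts)) {
      w0 <- max(block_starts[i] - half_extra, start_abs)
      w1 <- min(block_starts[i] + block_s + half_extra, end_abs)
      i0 <- max(1L, as.integer(floor((w0 - start_abs) * fs)) + 1L)
      i1 <- min(nrow(rec$data), as.integer(ceiling((w1 - start_abs) * fs)))
      seg <- rec$data[i0:i1, , drop = FALSE]
      sds <- apply(seg, 2, stats::sd) * 1000
      rngs <- (apply(seg, 2, max) - apply(seg, 2, min)) * 1000
      nonwear[i] <- sum(sds < sd_threshold) >= 2L ||
        sum(rngs < range_threshold) >= 2L
    }
  }
  data.frame(block_start = as.POSIXct(block_starts, origin = "1970-01-01",
                                      tz = "UTC"),
             nonwear = nonwear)
}

#' Flag epochs containing abnormal high accelerations
#'
#' An epoch is flagged when any of its samples exceeds `limit` in absolute
#' value on any axis or in vector norm (strictly greater than).
#'
#' @param rec a [raw_recording()].
#' @param limit clipping limit in g (default 5.5).
#' @param epoch_length epoch length in seconds (default 5).
#' @return A data frame with `time` (epoch starts) and `clipped` (logical).
#' @export
detect_clipping <- function(rec, limit = 5.5, epoch_length = 5) {
  stopifnot(inherits(rec, "raw_recording"))
  sl <- epoch_slices(rec, epoch_length)
  over <- pmax(abs(rec$data[, 1]), abs(rec$data[, 2]), abs(rec$data[, 3]),
               sqrt(rowSums(rec$data^2))) > limit
  m <- matrix(over[sl$skip + seq_len(sl$n_ep * sl$spe)], nrow = sl$spe)
  data.frame(time = sl$time, clipped = colSums(m) > 0L)
}

#' Build the combined epoch-level wear mask
#'
#' Combines block-level non-wear detection and epoch-level clipping detection
#' into a per-epoch validity mask on the metric epoch grid.
#'
#' @param rec a [raw_recording()].
#' @param epoch_length epoch length in seconds (default 5).
#' @param ... passed on to [detect_nonwear()] and [detect_clipping()].
#' @return An object of class `nonwear_mask`: list with `block` (data frame
#'   from [detect_nonwear()]), `time` (epoch starts), `clipped` and `wear`
#'   logical vectors per epoch.
#' @export
nonwear_mask <- function(rec, epoch_length = 5, ...) {
  dots <- list(...)
  nw_args <- dots[names(dots) %in% c("sd_threshold", "range_threshold",
                                     "block", "window")]
  cl_args <- dots[names(dots) %in% "limit"]
  blocks <- do.call(detect_nonwear, c(list(rec), nw_args))
  clip <- do.call(detect_clipping,
                  c(list(rec, epoch_length = epoch_length), cl_args))
  block_s <- as.numeric(diff(as.numeric(blocks$block_start[1:2])))
  if (is.na(block_s) || !length(block_s)) block_s <- 900
  idx <- findInterval(as.numeric(clip$time),
                      as.numeric(blocks$block_start))
  in_nonwear_block <- blocks$nonwear[pmax(idx, 1L)]
  structure(list(block = blocks, time = clip$time, clipped = clip$clipped,
                 wear = !in_nonwear_block & !clip$clipped),
            class = "nonwear_mask")
}

#' @export
print.nonwear_mask <- function(x, ...) {
  cat(sprintf(
    "<nonwear_mask> %d blocks (%d non-wear) | %d epochs (%d clipped, wear %.1f%%)\n",
    nrow(x$block), sum(x$block$nonwear), length(x$time), sum(x$clipped),
    100 * mean(x$wear)))
  invisible(x)
}

#' Impute invalid epochs from the same clock time on other days
#'
#' Replaces each invalid (non-wear or clipped) epoch value by the mean of
#' valid epochs at the same clock time on all other recorded days, setting the
#' `imputed` flag. Epochs with no valid same-clock-time donor remain missing
#' (`NA`, `wear = FALSE`) and are excluded from summaries.
#'
#' @param series an [epoch_series()].
#' @param mask a `nonwear_mask` from [nonwear_mask()] covering the same grid.
#' @return The imputed [epoch_series()].
#' @export
impute_epochs <- function(series, mask) {
  stopifnot(inherits(series, "epoch_series"), inherits(mask, "nonwear_mask"))
  pos <- match(round(as.numeric(series$time)), round(as.numeric(mask$time)))
  if (any(is.na(pos))) stop("mask does not cover the series epoch grid")
  wear <- mask$wear[pos]
  series$wear <- wear
  invalid <- which(!wear)
  if (!length(invalid)) return(series)

  clock <- round(clock_seconds(series$time))
  valid <- which(wear & !is.na(series$value))
  donor_mean <- tapply(series$value[valid], clock[valid], mean)
  key <- as.character(clock[invalid])
  imp <- donor_mean[key]
  has_donor <- !is.na(imp)
  series$value[invalid] <- as.numeric(imp)
  series$imputed[invalid[has_donor]] <- TRUE
  series
}

#' Summarise wear time and apply inclusion criteria
#'
#' Per calendar day: hours of wear over 24 h and split into waking and
#' sleeping hours (requires wake/sleep labels on the series, see
#' [apply_segmentation()]), with a `valid_day` flag (wear >= `min_hours`) and
#' an overall participant `included` attribute (>= `min_days` valid days).
#'
#' @param series a labeled [epoch_series()] with wear flags.
#' @param min_hours minimum daily wear for a valid day (default 16).
#' @param min_days minimum number of valid days for inclusion (default 4).
#' @return A data frame of class `wear_summary`, one row per day, with
#'   attribute `included`.
#' @export
summarize_wear <- function(series, min_hours = 16, min_days = 4) {
  stopifnot(inherits(series, "epoch_series"))
  L <- series$epoch_length
  day <- day_index(series$time)
  days <- sort(unique(day))
  rows <- lapply(days, function(d) {
    sel <- day == d
    worn <- series$wear[sel]
    lab <- series$label[sel]
    n_day <- 86400 / L
    present <- sum(sel)
    data.frame(
      date = as.Date(as.POSIXct(d * 86400, origin = "1970-01-01", tz = "UTC")),
      wear_h = sum(worn) * L / 3600,
      waking_wear_h = sum(worn & lab %in% "wake") * L / 3600,
      sleeping_wear_h = sum(worn & lab %in% "sleep") * L / 3600,
      nonwear_h = sum(!worn) * L / 3600,
      missing_h = (n_day - present) * L / 3600)
  })
  out <- do.call(rbind, rows)
  out$valid_day <- out$wear_h >= min_hours
  attr(out, "included") <- sum(out$valid_day) >= min_days
  class(out) <- c("wear_summary", "data.frame")
  out
}
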