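#' @keywords internal
"_PACKAGE"

## Canonical wear-site labels used throughout the package.
WEAR_SITES <- c("hip", "dominant_wrist", "non_dominant_wrist")

#' Tri-axial raw acceleration recording
#'
#' Container for one device's raw tri-axial acceleration time series. Values
#' are in g; timestamps are naive local clock time (stored as POSIXct in UTC,
#' interpreted as local time) derivable as `start_time + (i - 1) / sampling_rate`.
#'
#' @param data numeric matrix with columns x, y, z in g.
#' @param start_time POSIXct start of the first sample.
#' @param sampling_rate sampling frequency in Hz.
#' @param participant_id participant label.
#' @param site one of `"hip"`, `"dominant_wrist"`, `"non_dominant_wrist"`.
#' @param dynamic_range absolute sensor range in g (default 6).
#' @param calibrated logical; whether gravity calibration has been applied.
#'
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(data, start_time, sampling_rate,
                          participant_id = "P01", site = "non_dominant_wrist",
                          dynamic_range = 6, calibrated = FALSE) {
  data <- as.matrix(data)
  if (ncol(data) != 3L) stop("raw recording needs exactly 3 axis columns")
  if (nrow(data) < 1L) stop("raw recording needs at least one sample")
  if (!site %in% WEAR_SITES) {
    stop("unknown wear site '", site, "'; expected one of: ",
         paste(WEAR_SITES, collapse = ", "))
  }
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (any(abs(data) > dynamic_range + 1e-9, na.rm = TRUE)) {
    stop("samples exceed the declared dynamic range of ±",
         dynamic_range, " g")
  }
  colnames(data) <- c("x", "y", "z")
  structure(
    list(participant_id = participant_id, site = site,
         start_time = as.POSIXct(start_time, tz = "UTC"),
         sampling_rate = sampling_rate, data = data,
         dynamic_range = dynamic_range, calibrated = calibrated),
    class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$data)
  cat(sprintf(
    "<raw_recording> %s @ %s | %d samples @ %g Hz (%.2f h) from %s%s\n",
    x$participant_id, x$site, n, x$sampling_rate,
    n / x$sampling_rate / 3600,
    format(x$start_time, "%Y-%m-%d %H:%M:%S"),
    if (isTRUE(x$calibrated)) " [calibrated]" else ""))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec a [raw_recording()].
#' @return numeric seconds.
#' @export
recording_duration <- function(rec) nrow(rec$data) / rec$sampling_rate

#' Per-sample timestamps of a recording
#' @param rec a [raw_recording()].
#' @return POSIXct vector.
#' @export
recording_times <- function(rec) {
  rec$start_time + (seq_len(nrow(rec$data)) - 1) / rec$sampling_rate
}

#' Epoch-aggregated metric series
#'
#' Per-epoch values of one acceleration metric on the contiguous, half-open
#' 5-s grid `[t, t + epoch_length)` anchored at local midnight. Units are mg
#' for ENMO/LFENMO/MAD and counts per epoch for imported activity counts.
#'
#' @param time POSIXct vector of epoch start times (contiguous grid).
#' @param value numeric epoch values (>= 0; NA allowed for missing).
#' @param metric metric name: `"ENMO"`, `"LFENMO"`, `"MAD"` or `"counts"`.
#' @param participant_id,site identification metadata.
#' @param epoch_length epoch length in seconds (default 5).
#' @param wear logical per-epoch wear flag.
#' @param imputed logical per-epoch imputation flag.
#' @param label optional per-epoch `"wake"`/`"sleep"` label.
#'
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(time, value, metric = "ENMO",
                         participant_id = "P01", site = "non_dominant_wrist",
                         epoch_length = 5,
                         wear = rep(TRUE, length(value)),
                         imputed = rep(FALSE, length(value)),
                         label = rep(NA_character_, length(value))) {
  stopifnot(length(time) == length(value),
            length(wear) == length(value),
            length(imputed) == length(value),
            length(label) == length(value))
  if (any(value < -1e-9, na.rm = TRUE)) stop("epoch values must be >= 0")
  if (length(time) > 1L) {
    dt <- as.numeric(diff(as.numeric(time)))
    if (any(abs(dt - epoch_length) > 1e-6)) {
      stop("epochs must be contiguous and non-overlapping (spacing of ",
           epoch_length, " s)")
    }
  }
  structure(
    list(participant_id = participant_id, site = site, metric = metric,
         epoch_length = epoch_length,
         time = as.POSIXct(time, tz = "UTC"),
         value = as.numeric(value),
         wear = as.logical(wear), imputed = as.logical(imputed),
         label = as.character(label)),
    class = "epoch_series")
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf(
    "<epoch_series> %s @ %s | %s, %d epochs x %g s from %s (wear %.1f%%, imputed %d)\n",
    x$participant_id, x$site, x$metric, length(x$value), x$epoch_length,
    format(x$time[1], "%Y-%m-%d %H:%M:%S"),
    100 * mean(x$wear, na.rm = TRUE), sum(x$imputed, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.epoch_series <- function(x, ...) {
  data.frame(participant_id = x$participant_id, site = x$site,
             metric = x$metric, time = x$time, value = x$value,
             wear = x$wear, imputed = x$imputed, label = x$label,
             stringsAsFactors = FALSE)
}

#' Intensity cut-point set
#'
#' Ordered ENMO thresholds (mg) splitting epochs into sedentary
#' `[0, sedentary_upper)`, light `[sedentary_upper, light_upper)`, moderate
#' `[light_upper, moderate_upper)` and vigorous `[moderate_upper, Inf)` —
#' lower bound inclusive, upper bound exclusive.
#'
#' @param sedentary_upper,light_upper,moderate_upper thresholds in mg,
#'   strictly increasing and positive.
#' @return An object of class `cut_points`.
#' @export
cut_points <- function(sedentary_upper, light_upper, moderate_upper) {
  if (!(sedentary_upper > 0 && light_upper > sedentary_upper &&
        moderate_upper > light_upper)) {
    stop("cut points must satisfy 0 < sedentary < light < moderate")
  }
  structure(list(sedentary_upper = sedentary_upper,
                 light_upper = light_upper,
                 moderate_upper = moderate_upper),
            class = "cut_points")
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf(
    "<cut_points> sedentary [0,%g) | light [%g,%g) | moderate [%g,%g) | vigorous [%g,Inf) mg\n",
    x$sedentary_upper, x$sedentary_upper, x$light_upper, x$light_upper,
    x$moderate_upper, x$moderate_upper))
  invisible(x)
}

#' Reference non-dominant-wrist ENMO cut points
#'
#' The validated non-dominant-wrist thresholds (45/100/430 mg) used as the
#' reference in the dominant-wrist translation.
#' @return A [cut_points()] object.
#' @export
reference_cutpoints <- function() cut_points(45, 100, 430)

#' Dominant-wrist ENMO cut points proposed by the translation
#'
#' The translated dominant-wrist set (50/110/440 mg).
#' @return A [cut_points()] object.
#' @export
dominant_wrist_cutpoints <- function() cut_points(50, 110, 440)

INTENSITY_LEVELS <- c("sedentary", "light", "moderate", "vigorous")

## seconds since local midnight for a POSIXct vector (naive clock convention)
clock_seconds <- function(t) as.numeric(t) %% 86400

## floor a POSIXct to a multiple of `sec` seconds since midnight
floor_time <- function(t, sec) {
  as.POSIXct(floor(as.numeric(t) / sec) * sec,
             origin = "1970-01-01", tz = "UTC")
}

## local calendar date index (days since epoch) for day-boundary accounting
day_index <- function(t) floor(as.numeric(t) / 86400)
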