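## Auto-calibration to local gravity: during genuinely still windows the
## acceleration vector magnitude must equal 1 g, so per-axis offsets and gains
## can be estimated by iteratively-reweighted least squares that pulls the
## still-window means onto the unit sphere.

#' Find still windows in a recording
#'
#' Splits the recording into consecutive non-overlapping windows and keeps
#' those whose per-axis standard deviation is below `sd_threshold` on *all*
#' three axes (stricter than the 2-of-3 non-wear rule, so that retained
#' windows are genuinely static).
#'
#' @param rec a [raw_recording()].
#' @param window window length in seconds (default 10).
#' @param sd_threshold stillness threshold in mg (default 13).
#' @return An object of class `still_windows`: list with `mean` (k x 3 matrix
#'   of window means, g), `sd` (k x 3, mg) and `window` (seconds). May contain
#'   zero windows.
#' @export
find_still_windows <- function(rec, window = 10, sd_threshold = 13) {
  stopifnot(inherits(rec, "raw_recording"))
  n_per <- as.integer(round(window * rec$sampling_rate))
  if (nrow(rec$data) < n_per) stop("recording shorter than one still window")
  k <- nrow(rec$data) %/% n_per
  idx <- rep(seq_len(k), each = n_per)
  m <- rec$data[seq_len(k * n_per), , drop = FALSE]
  means <- vapply(1:3, function(a) {
    rowsum(m[, a], idx)[, 1] / n_per
  }, numeric(k))
  sds <- vapply(1:3, function(a) {
    mu <- means[, a][idx]
    sqrt(rowsum((m[, a] - mu)^2, idx)[, 1] / (n_per - 1))
  }, numeric(k))
  means <- matrix(means, nrow = k)
  sds <- matrix(sds, nrow = k) * 1000  # mg
  keep <- rowSums(sds < sd_threshold) == 3L
  structure(list(mean = means[keep, , drop = FALSE],
                 sd = sds[keep, , drop = FALSE],
                 window = window),
            class = "still_windows")
}

#' @export
print.still_windows <- function(x, ...) {
  cat(sprintf("<still_windows> %d windows of %g s\n", nrow(x$mean), x$window))
  invisible(x)
}

#' Estimate gravity calibration parameters from still windows
#'
#' Iteratively-reweighted least-squares fit of a per-axis offset and gain that
#' minimises the distance of the still-window mean vectors to the unit sphere.
#' Estimation is only attempted when the window means cover the sphere well
#' enough to identify all six parameters: each axis must contribute means both
#' below -`coverage` and above +`coverage` mg. When coverage fails, identity
#' parameters are returned with `sphere_coverage_ok = FALSE` and a warning.
#'
#' @param windows a `still_windows` set from [find_still_windows()].
#' @param max_iter maximum number of reweighting iterations (default 1000).
#' @param tol stop when the calibration error improves by less than this many
#'   mg (default 1e-6).
#' @param coverage per-axis sphere-coverage requirement in mg (default 300).
#' @return A `calibration_params` object: `offset` (g), `gain`,
#'   `error_before`/`error_after` (mean absolute deviation of window-mean norm
#'   from 1 g, in mg), `n_windows`, `sphere_coverage_ok`.
#' @export
estimate_calibration <- function(windows, max_iter = 1000, tol = 1e-6,
                                 coverage = 300) {
  stopifnot(inherits(windows, "still_windows"))
  M <- windows$mean
  if (!nrow(M)) stop("cannot calibrate from an empty still-window set")

  cal_error <- function(X) {
    mean(abs(sqrt(rowSums(X^2)) - 1)) * 1000
  }
  err0 <- cal_error(M)
  cov_ok <- all(apply(M, 2, function(v) {
    any(v <= -coverage / 1000) && any(v >= coverage / 1000)
  }))
  identity_params <- structure(
    list(offset = c(0, 0, 0), gain = c(1, 1, 1),
         error_before = err0, error_after = err0,
         n_windows = nrow(M), sphere_coverage_ok = cov_ok),
    class = "calibration_params")
  if (!cov_ok) {
    warning("sphere coverage insufficient (need window means beyond ±",
            coverage, " mg on every axis); returning identity calibration")
    return(identity_params)
  }

  offset <- c(0, 0, 0)
  gain <- c(1, 1, 1)
  err <- err0
  for (it in seq_len(max_iter)) {
    X <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
    nrm <- sqrt(rowSums(X^2))
    target <- X / nrm
    w <- pmin(1 / pmax(abs(nrm - 1), 0.001), 100)  # downweight outliers
    for (a in 1:3) {
      fit <- stats::lm.wfit(cbind(1, X[, a]), target[, a], w)
      offset[a] <- offset[a] + fit$coefficients[1]
      gain[a] <- gain[a] * fit$coefficients[2]
    }
    Xn <- sweep(sweep(M, 2, gain, "*"), 2, offset, "+")
    new_err <- cal_error(Xn)
    if (err - new_err < tol) { err <- min(err, new_err); break }
    err <- new_err
  }
  structure(list(offset = offset, gain = gain,
                 error_before = err0, error_after = err,
                 n_windows = nrow(M), sphere_coverage_ok = TRUE),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat(sprintf(
    "<calibration_params> offset (mg): %s | gain: %s\n  error %.3f -> %.3f mg over %d windows (coverage %s)\n",
    paste(sprintf("%.2f", x$offset * 1000), collapse = ", "),
    paste(sprintf("%.4f", x$gain), collapse = ", "),
    x$error_before, x$error_after, x$n_windows,
    if (x$sphere_coverage_ok) "ok" else "FAILED"))
  invisible(x)
}

#' Apply calibration parameters to a recording
#'
#' Maps each sample to `sample * gain + offset`, axis-wise, and marks the
#' recording as calibrated. Re-applying calibration to an already-calibrated
#' recording is an error.
#'
#' @param rec a [raw_recording()].
#' @param params a `calibration_params` object.
#' @return The calibrated [raw_recording()].
#' @export
apply_calibration <- function(rec, params) {
  stopifnot(inherits(rec, "raw_recording"),
            inherits(params, "calibration_params"))
  if (isTRUE(rec$calibrated)) {
    stop("recording is already calibrated; refusing to calibrate twice")
  }
  if (any(params$gain <= 0)) stop("gains must be positive")
  rec$data <- sweep(sweep(rec$data, 2, params$gain, "*"), 2,
                    params$offset, "+")
  ## calibration may push samples marginally past the nominal range
  rec$data <- pmin(pmax(rec$data, -rec$dynamic_range), rec$dynamic_range)
  rec$calibrated <- TRUE
  rec
}

#' Write a calibration report as a JSON sidecar
#'
#' @param params a `calibration_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(params, path) {
  jsonlite::write_json(
    list(offset_g = params$offset, gain = params$gain,
         error_before_mg = params$error_before,
         error_after_mg = params$error_after,
         n_windows = params$n_windows,
         sphere_coverage_ok = params$sphere_coverage_ok),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
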