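## Epoch-level signal aggregation metrics. All three metrics summarise the
## tri-axial signal into a non-negative per-epoch value in mg on the half-open
## 5-s grid anchored at local midnight:
##   ENMO   - Euclidean norm minus 1 g, negatives truncated per sample, then
##            averaged per epoch;
##   LFENMO - ENMO of the low-pass filtered signal (Butterworth, 4th order,
##            20 Hz cutoff, applied per axis);
##   MAD    - mean absolute deviation of the vector norm around its epoch mean.

#' Metric configuration
#'
#' @param epoch_length epoch length in seconds (default 5); must divide 60 and
#'   give an integer number of samples per epoch.
#' @param lowpass_order Butterworth order for LFENMO (default 4).
#' @param lowpass_cutoff low-pass cutoff in Hz (default 20).
#' @param phase `"zero"` (forward-backward, zero-phase; default) or
#'   `"single"` (single forward pass) filtering for LFENMO.
#' @return A `metric_config` list.
#' @export
metric_config <- function(epoch_length = 5, lowpass_order = 4,
                          lowpass_cutoff = 20,
                          phase = c("zero", "single")) {
  stopifnot(epoch_length > 0, 60 %% epoch_length == 0,
            lowpass_order >= 1, lowpass_cutoff > 0)
  list(epoch_length = epoch_length, lowpass_order = lowpass_order,
       lowpass_cutoff = lowpass_cutoff, phase = match.arg(phase))
}

## Slice a per-sample vector into full epochs on the midnight-anchored grid.
## Returns the per-epoch sample matrix (samples x epochs) plus epoch times.
## Partial epochs at either end are dropped.
epoch_slices <- function(rec, epoch_length) {
  spe <- epoch_length * rec$sampling_rate
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_length x sampling_rate must be an integer")
  }
  spe <- as.integer(round(spe))
  start_abs <- as.numeric(rec$start_time)
  rem <- start_abs %% epoch_length
  skip <- if (rem > 1e-9) as.integer(round((epoch_length - rem) *
                                             rec$sampling_rate)) else 0L
  n_avail <- nrow(rec$data) - skip
  n_ep <- n_avail %/% spe
  if (n_ep < 1L) stop("recording shorter than one full epoch")
  first <- start_abs + skip / rec$sampling_rate
  list(spe = spe, skip = skip, n_ep = n_ep,
       time = as.POSIXct(first + epoch_length * (seq_len(n_ep) - 1),
                         origin = "1970-01-01", tz = "UTC"))
}

## Mean of a per-sample vector over each full epoch.
epoch_means <- function(v, sl) {
  m <- matrix(v[sl$skip + seq_len(sl$n_ep * sl$spe)], nrow = sl$spe)
  colMeans(m)
}

#' ENMO epoch metric
#'
#' Euclidean norm of each calibrated sample minus 1 g, negative values
#' truncated to zero per sample, then averaged over each epoch and expressed
#' in mg. Partial epochs at the recording edges are dropped.
#'
#' @param rec a calibrated [raw_recording()].
#' @param cfg a [metric_config()].
#' @return An [epoch_series()] with metric `"ENMO"`.
#' @export
enmo <- function(rec, cfg = metric_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  sl <- epoch_slices(rec, cfg$epoch_length)
  v <- pmax(sqrt(rowSums(rec$data^2)) - 1, 0)
  epoch_series(sl$time, epoch_means(v, sl) * 1000, metric = "ENMO",
               participant_id = rec$participant_id, site = rec$site,
               epoch_length = cfg$epoch_length)
}

#' LFENMO epoch metric
#'
#' ENMO computed on the per-axis low-pass filtered signal (Butterworth of
#' order `cfg$lowpass_order`, cutoff `cfg$lowpass_cutoff` Hz; zero-phase
#' forward-backward by default). When the cutoff is at or above the Nyquist
#' frequency the filter is skipped with a warning and LFENMO equals ENMO.
#'
#' @inheritParams enmo
#' @return An [epoch_series()] with metric `"LFENMO"`.
#' @export
lfenmo <- function(rec, cfg = metric_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  if (rec$sampling_rate <= 2 * cfg$lowpass_cutoff) {
    warning("low-pass cutoff (", cfg$lowpass_cutoff,
            " Hz) at or above Nyquist for a ", rec$sampling_rate,
            " Hz recording; filter skipped (LFENMO = ENMO)")
    filt <- rec$data
  } else {
    bf <- signal::butter(cfg$lowpass_order,
                         cfg$lowpass_cutoff / (rec$sampling_rate / 2),
                         type = "low")
    apply_f <- if (cfg$phase == "zero") {
      function(x) signal::filtfilt(bf, x)
    } else {
      function(x) as.numeric(signal::filter(bf, x))
    }
    filt <- vapply(1:3, function(a) apply_f(rec$data[, a]),
                   numeric(nrow(rec$data)))
  }
  sl <- epoch_slices(rec, cfg$epoch_length)
  v <- pmax(sqrt(rowSums(filt^2)) - 1, 0)
  epoch_series(sl$time, epoch_means(v, sl) * 1000, metric = "LFENMO",
               participant_id = rec$participant_id, site = rec$site,
               epoch_length = cfg$epoch_length)
}

#' MAD epoch metric (mean amplitude deviation)
#'
#' Per epoch, the mean over samples of the absolute deviation of the
#' acceleration vector norm from its epoch mean, in mg.
#'
#' @inheritParams enmo
#' @return An [epoch_series()] with metric `"MAD"`.
#' @export
mad_metric <- function(rec, cfg = metric_config()) {
  stopifnot(inherits(rec, "raw_recording"))
  sl <- epoch_slices(rec, cfg$epoch_length)
  r <- sqrt(rowSums(rec$data^2))
  m <- matrix(r[sl$skip + seq_len(sl$n_ep * sl$spe)], nrow = sl$spe)
  mu <- colMeans(m)
  val <- colMeans(abs(sweep(m, 2, mu, "-"))) * 1000
  epoch_series(sl$time, val, metric = "MAD",
               participant_id = rec$participant_id, site = rec$site,
               epoch_length = cfg$epoch_length)
}

#' Compute all epoch metrics for a recording
#'
#' Computes ENMO, LFENMO and MAD, and attaches imported activity counts
#' unchanged (if given) so that all four share the same downstream wear and
#' imputation processing. Counts must be aligned to the same epoch grid.
#'
#' @inheritParams enmo
#' @param counts optional counts [epoch_series()] aligned to the same grid.
#' @return A named list of [epoch_series()]: `ENMO`, `LFENMO`, `MAD` and
#'   optionally `counts`.
#' @export
compute_all_metrics <- function(rec, cfg = metric_config(), counts = NULL) {
  out <- list(ENMO = enmo(rec, cfg), LFENMO = lfenmo(rec, cfg),
              MAD = mad_metric(rec, cfg))
  if (!is.null(counts)) {
    stopifnot(inherits(counts, "epoch_series"))
    ref_t <- out$ENMO$time
    if (length(counts$time) != length(ref_t) ||
        any(abs(as.numeric(counts$time) - as.numeric(ref_t)) > 1e-6)) {
      stop("counts are not aligned to the recording's epoch grid (",
           length(counts$time), " vs ", length(ref_t), " epochs)")
    }
    out$counts <- counts
  }
  out
}
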