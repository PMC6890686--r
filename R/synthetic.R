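## Synthetic tri-axial cohort generator with known ground truth. The signal
## model is: a piecewise-constant (posture) / slowly-wandering gravity unit
## vector, plus a zero-mean sinusoidal dynamic component in the human
## locomotion band (0.5-4 Hz) directed along gravity and scaled so that the
## noiseless per-epoch ENMO equals the bout's target amplitude, plus
## isotropic Gaussian sensor noise, clipped to the sensor's ±6 g range.
## Dominant-wrist dynamic amplitude is the non-dominant amplitude times a
## fixed asymmetry ratio; the hip is attenuated by a fixed factor. Sleep has
## piecewise-constant orientation with occasional posture shifts; non-wear
## has frozen orientation and noise only.

SYNTH_START <- "2019-06-03 00:00:00"  # recordings start at local midnight

#' Cohort generation settings
#'
#' @param n_participants number of participants (>= 1).
#' @param n_days recording days per participant (>= 1, whole days).
#' @param sampling_rate sampling frequency in Hz (default 30; 100 Hz
#'   supported).
#' @param epoch_length epoch length in seconds; must divide 60 (default 5).
#' @param asymmetry_ratio dominant-wrist dynamic amplitude relative to the
#'   non-dominant wrist (default 1.1).
#' @param hip_attenuation hip dynamic amplitude relative to the non-dominant
#'   wrist (default 0.5).
#' @param noise_sd sensor noise SD in mg (default 5).
#' @param seed RNG seed (integer).
#' @param p_nonwear probability of one non-wear episode per day (default 0.2).
#' @param nonwear_minutes range of non-wear episode durations in minutes
#'   (default `c(45, 90)`).
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_participants = 6, n_days = 2, sampling_rate = 30,
                        epoch_length = 5, asymmetry_ratio = 1.1,
                        hip_attenuation = 0.5, noise_sd = 5, seed = 1,
                        p_nonwear = 0.2, nonwear_minutes = c(45, 90)) {
  stopifnot(n_participants >= 1, n_days >= 1, sampling_rate > 0,
            asymmetry_ratio > 0, hip_attenuation > 0, noise_sd >= 0,
            60 %% epoch_length == 0)
  structure(list(n_participants = as.integer(n_participants),
                 n_days = as.integer(n_days),
                 sampling_rate = sampling_rate,
                 epoch_length = epoch_length,
                 asymmetry_ratio = asymmetry_ratio,
                 hip_attenuation = hip_attenuation,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 p_nonwear = p_nonwear, nonwear_minutes = nonwear_minutes),
            class = "cohort_spec")
}

site_multiplier <- function(site, spec) {
  switch(site,
         dominant_wrist = spec$asymmetry_ratio,
         non_dominant_wrist = 1,
         hip = spec$hip_attenuation,
         stop("unknown wear site '", site, "'"))
}

## draw a bout amplitude (mg) for the everyday (non-exercise) repertoire:
## decreasing density, mostly sedentary, continuous across the intensity
## boundaries so minute counts identify thresholds
draw_base_amplitude <- function(n) {
  pmin(stats::rgamma(n, shape = 0.9, scale = 35), 245)
}

amp_class <- function(amp, reference = reference_cutpoints()) {
  br <- c(0, reference$sedentary_upper, reference$light_upper,
          reference$moderate_upper, Inf)
  INTENSITY_LEVELS[findInterval(amp, br)]
}

#' Randomise one participant's activity schedule
#'
#' Draws per-day sleep windows (~7-8 h), everyday activity bouts of 5-30 min
#' with amplitudes from a decreasing continuous distribution, 0-2 daily
#' exercise bouts (250-650 mg), and optional non-wear episodes; emits the
#' matching (slightly misreported) sleep diary. Uses the current RNG state;
#' [generate_cohort()] seeds it.
#'
#' @param spec a [cohort_spec()].
#' @return An `activity_schedule`: list with `bouts` (day, start_min,
#'   dur_min, amplitude_mg, class), `nonwear` (day, start_min, dur_min),
#'   `sleep` (day, rise_min, onset_min), `diary` (a `sleep_diary` data
#'   frame), `n_days`, `start_time`.
#' @export
random_schedule <- function(spec) {
  n_days <- spec$n_days
  rise <- round(stats::runif(n_days, 6.5 * 60, 8 * 60))       # minutes
  onset <- round(stats::runif(n_days, 22.75 * 60, 23.75 * 60))
  bouts <- list(); nonwear <- list()
  for (d in seq_len(n_days)) {
    day_bouts <- list(
      data.frame(day = d, start_min = 0, dur_min = rise[d],
                 amplitude_mg = 3, class = "sleep"))
    ## waking bout sequence: everyday bouts + 0-2 exercise bouts, shuffled
    wake_len <- onset[d] - rise[d]
    n_ex <- sample(1:3, 1, prob = c(0.3, 0.5, 0.2))
    ex_dur <- round(stats::runif(n_ex, 15, 40))
    ex_amp <- stats::runif(n_ex, 150, 500)
    ## keep every exercise bout; fill the remaining waking time with
    ## everyday bouts, then shuffle the order
    need_base <- wake_len - sum(ex_dur)
    n_base <- ceiling(need_base / 5) + 2L
    base_dur <- round(stats::runif(n_base, 5, 30))
    base_amp <- draw_base_amplitude(n_base)
    k <- which(cumsum(base_dur) >= need_base)[1]
    base_dur <- base_dur[seq_len(k)]
    base_amp <- base_amp[seq_len(k)]
    base_dur[k] <- need_base - sum(base_dur[-k])  # fill exactly
    dur <- c(ex_dur, base_dur)
    amp <- c(ex_amp, base_amp)
    ord <- sample(seq_along(dur))
    dur <- dur[ord]; amp <- amp[ord]
    zero <- dur <= 0
    dur <- dur[!zero]; amp <- amp[!zero]
    starts <- rise[d] + cumsum(c(0, dur[-length(dur)]))
    day_bouts[[2]] <- data.frame(day = d, start_min = starts, dur_min = dur,
                                 amplitude_mg = amp, class = amp_class(amp))
    day_bouts[[3]] <- data.frame(day = d, start_min = onset[d],
                                 dur_min = 1440 - onset[d],
                                 amplitude_mg = 3, class = "sleep")
    bouts[[d]] <- do.call(rbind, day_bouts)
    if (stats::runif(1) < spec$p_nonwear) {
      nw_dur <- round(stats::runif(1, spec$nonwear_minutes[1],
                                   spec$nonwear_minutes[2]))
      nw_start <- round(stats::runif(1, rise[d], onset[d] - nw_dur))
      if (nw_start >= rise[d] && nw_start + nw_dur <= onset[d]) {
        nonwear[[length(nonwear) + 1L]] <-
          data.frame(day = d, start_min = nw_start, dur_min = nw_dur)
      }
    }
  }
  start_time <- as.POSIXct(SYNTH_START, tz = "UTC")
  start_date <- as.Date(start_time)
  ## diary: night 0 precedes the recording; the last night runs past its end
  onset0 <- round(stats::runif(1, 22.75 * 60, 23.75 * 60))
  bed_true <- c(onset0, onset) # minutes within their calendar day
  rise_true <- c(rise, 7.5 * 60)
  diary_date <- start_date + (0:n_days) - 1
  bed_err <- round(stats::runif(n_days + 1, 0, 20))
  rise_err <- round(stats::runif(n_days + 1, 0, 25))
  day0 <- as.POSIXct(paste(format(diary_date), "00:00:00"), tz = "UTC")
  bed <- day0 + pmax(bed_true - bed_err, 0) * 60
  rise_log <- day0 + 86400 + pmin(rise_true + rise_err, 1439) * 60
  diary <- data.frame(date = diary_date, bed = bed, rise = rise_log,
                      duration_h = as.numeric(rise_log - bed,
                                              units = "hours"))
  class(diary) <- c("sleep_diary", "data.frame")
  nonwear <- if (length(nonwear)) do.call(rbind, nonwear) else
    data.frame(day = integer(0), start_min = numeric(0),
               dur_min = numeric(0))
  structure(list(bouts = do.call(rbind, bouts), nonwear = nonwear,
                 sleep = data.frame(day = seq_len(n_days), rise_min = rise,
                                    onset_min = onset),
                 diary = diary, n_days = n_days, start_time = start_time),
            class = "activity_schedule")
}

#' @export
print.activity_schedule <- function(x, ...) {
  cat(sprintf(
    "<activity_schedule> %d day(s), %d bouts, %d non-wear episode(s)\n",
    x$n_days, nrow(x$bouts), nrow(x$nonwear)))
  invisible(x)
}

## draw the next orientation in a posture walk: current + scale * noise,
## renormalised (scale 0.8 ~ 40 deg typical change, 0.45 ~ 25 deg)
next_orientation <- function(v, scale) {
  w <- v + scale * stats::rnorm(3)
  n <- sqrt(sum(w^2))
  if (n < 1e-6) return(next_orientation(v, scale))
  w / n
}

#' Generate one raw recording from a schedule
#'
#' Builds the tri-axial signal for one wear site from an activity schedule:
#' gravity orientation (posture changes every ~20 s while awake, every 8-20
#' min during sleep, frozen during non-wear), a locomotion-band sinusoid
#' along gravity scaled so the noiseless epoch ENMO equals the bout target
#' times the site multiplier, Gaussian noise, and ±6 g clipping. Uses the
#' current RNG state; [generate_cohort()] seeds it.
#'
#' @param schedule an `activity_schedule` from [random_schedule()].
#' @param site wear site (`"hip"`, `"dominant_wrist"`,
#'   `"non_dominant_wrist"`).
#' @param spec the [cohort_spec()].
#' @param participant_id participant label.
#' @return A calibrated [raw_recording()].
#' @export
generate_recording <- function(schedule, site, spec,
                               participant_id = "P01") {
  stopifnot(inherits(schedule, "activity_schedule"),
            inherits(spec, "cohort_spec"))
  if (!site %in% WEAR_SITES) stop("unknown wear site '", site, "'")
  mult <- site_multiplier(site, spec)
  fs <- spec$sampling_rate
  n_sec <- schedule$n_days * 86400L
  n <- as.integer(n_sec * fs)
  b <- schedule$bouts
  b_start_s <- (b$day - 1) * 86400 + b$start_min * 60
  b_dur_s <- b$dur_min * 60

  ## dynamic component along gravity, per bout; the frequency menu excludes
  ## f where a low harmonic of the rectified sinusoid aliases onto DC
  ## (fs / 2f integer and small), which would bias the epoch ENMO
  d <- numeric(n)
  menu <- seq(0.6, 4, by = 0.2)
  ratio <- fs / (2 * menu)
  menu <- menu[!(abs(ratio - round(ratio)) < 1e-9 & ratio <= 6)]
  freqs <- sample(menu, nrow(b), replace = TRUE)
  for (i in seq_len(nrow(b))) {
    if (b$amplitude_mg[i] <= 0) next
    i0 <- as.integer(b_start_s[i] * fs)
    len <- as.integer(b_dur_s[i] * fs)
    a <- pi * b$amplitude_mg[i] * mult / 1000
    t_rel <- (seq_len(len) - 1) / fs
    d[i0 + seq_len(len)] <- a * sin(2 * pi * freqs[i] * t_rel)
  }

  ## orientation change points (seconds): posture walk
  ch_times <- list(); ch_scale <- list()
  for (i in seq_len(nrow(b))) {
    t0 <- b_start_s[i]; t1 <- t0 + b_dur_s[i]
    if (b$class[i] == "sleep") {
      gaps <- stats::runif(ceiling(b_dur_s[i] / 480) + 2, 480, 1200)
    } else {
      gaps <- stats::rexp(ceiling(b_dur_s[i] / 10) + 2, rate = 1 / 20)
    }
    tt <- t0 + floor(cumsum(gaps))
    tt <- tt[tt < t1 - 1]
    ch_times[[i]] <- c(t0, tt)
    ch_scale[[i]] <- rep(if (b$class[i] == "sleep") 0.45 else 0.8,
                         length(tt) + 1L)
  }
  ch_times <- unlist(ch_times); ch_scale <- unlist(ch_scale)
  ord <- order(ch_times)
  ch_times <- ch_times[ord]; ch_scale <- ch_scale[ord]
  V <- matrix(0, nrow = length(ch_times), ncol = 3)
  v <- next_orientation(c(0, 0, 1), 1)  # random initial posture
  for (k in seq_along(ch_times)) {
    v <- next_orientation(v, ch_scale[k])
    V[k, ] <- v
  }
  seg_len <- diff(c(ch_times, n_sec))
  O_sec <- V[rep(seq_along(seg_len), seg_len), , drop = FALSE]

  ## non-wear: frozen orientation, no dynamic component
  if (nrow(schedule$nonwear)) {
    for (j in seq_len(nrow(schedule$nonwear))) {
      s0 <- (schedule$nonwear$day[j] - 1) * 86400 +
        schedule$nonwear$start_min[j] * 60
      secs <- (s0 + 1):(s0 + schedule$nonwear$dur_min[j] * 60)
      O_sec[secs, ] <- matrix(O_sec[secs[1], ], nrow = length(secs),
                              ncol = 3, byrow = TRUE)
      d[(s0 * fs + 1):((s0 + schedule$nonwear$dur_min[j] * 60) * fs)] <- 0
    }
  }

  one <- 1 + d
  sig <- matrix(0, nrow = n, ncol = 3)
  for (a in 1:3) {
    col <- rep(O_sec[, a], each = fs) * one
    if (spec$noise_sd > 0) {
      col <- col + stats::rnorm(n, sd = spec$noise_sd / 1000)
    }
    sig[, a] <- col
  }
  rng <- range(sig)
  if (rng[1] < -6 || rng[2] > 6) sig <- pmin(pmax(sig, -6), 6)
  rec <- raw_recording(sig[1:2, ], schedule$start_time, fs,
                       participant_id = participant_id, site = site,
                       dynamic_range = 6, calibrated = TRUE)
  rec$data <- sig  # bulk data validated above (range check + clipping)
  colnames(rec$data) <- c("x", "y", "z")
  rec
}

#' Ground-truth epoch table for a schedule
#'
#' The scheduled state of every epoch: target amplitude at a given site,
#' intensity/sleep class, and whether the epoch falls in an injected non-wear
#' episode.
#'
#' @param schedule an `activity_schedule`.
#' @param spec the [cohort_spec()].
#' @param site wear site whose amplitude multiplier to apply.
#' @return A data frame with `time`, `amplitude_mg`, `class`, `nonwear`.
#' @export
schedule_epochs <- function(schedule, spec, site = "non_dominant_wrist") {
  L <- spec$epoch_length
  mult <- site_multiplier(site, spec)
  n_ep <- schedule$n_days * 86400 / L
  t_s <- (seq_len(n_ep) - 1) * L
  b <- schedule$bouts
  b0 <- (b$day - 1) * 86400 + b$start_min * 60
  idx <- findInterval(t_s, b0)
  amp <- b$amplitude_mg[idx] * mult
  cls <- b$class[idx]
  nw <- rep(FALSE, n_ep)
  if (nrow(schedule$nonwear)) {
    for (j in seq_len(nrow(schedule$nonwear))) {
      s0 <- (schedule$nonwear$day[j] - 1) * 86400 +
        schedule$nonwear$start_min[j] * 60
      nw[t_s >= s0 & t_s < s0 + schedule$nonwear$dur_min[j] * 60] <- TRUE
    }
  }
  data.frame(time = schedule$start_time + t_s, amplitude_mg = amp,
             class = cls, nonwear = nw)
}

#' Generate a synthetic cohort
#'
#' Draws a schedule per participant and generates one recording per requested
#' wear site, deterministically for a given spec (identical specs give
#' identical cohorts).
#'
#' @param spec a [cohort_spec()].
#' @param sites wear sites to generate (default all three).
#' @param id_prefix prefix for participant ids (default `"P"`); use distinct
#'   prefixes for independent waves.
#' @return A list of class `synthetic_cohort`: `participants` (each with
#'   `id`, `schedule`, `recordings` named by site, `diary`), and `spec`.
#' @export
generate_cohort <- function(spec, sites = WEAR_SITES, id_prefix = "P") {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  participants <- lapply(seq_len(spec$n_participants), function(p) {
    id <- sprintf("%s%02d", id_prefix, p)
    schedule <- random_schedule(spec)
    recs <- lapply(sites, function(s) {
      generate_recording(schedule, s, spec, participant_id = id)
    })
    names(recs) <- sites
    list(id = id, schedule = schedule, recordings = recs,
         diary = schedule$diary)
  })
  structure(list(participants = participants, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participant(s) x %d day(s) @ %g Hz, sites: %s\n",
    length(x$participants), x$spec$n_days, x$spec$sampling_rate,
    paste(names(x$participants[[1]]$recordings), collapse = ", ")))
  invisible(x)
}

#' Inject a known calibration error into a recording
#'
#' Distorts each axis as `(sample - offset) / gain`, so that applying
#' calibration parameters exactly equal to `(offset, gain)` restores the
#' original signal. Marks the recording as uncalibrated.
#'
#' @param rec a [raw_recording()].
#' @param offset per-axis offset in g (length 3).
#' @param gain per-axis gain factors (length 3, positive).
#' @return The distorted [raw_recording()] with attribute `true_calibration`.
#' @export
inject_calibration_error <- function(rec, offset = c(0, 0, 0),
                                     gain = c(1, 1, 1)) {
  stopifnot(inherits(rec, "raw_recording"), length(offset) == 3,
            length(gain) == 3, all(gain > 0))
  rec$data <- sweep(sweep(rec$data, 2, offset, "-"), 2, gain, "/")
  rec$data <- pmin(pmax(rec$data, -rec$dynamic_range), rec$dynamic_range)
  rec$calibrated <- FALSE
  attr(rec, "true_calibration") <- list(offset = offset, gain = gain)
  rec
}

#' Static recording visiting a set of orientations
#'
#' A stand-in for the still periods of a free-living recording: the device
#' rests in each given orientation for `hold` seconds (with sensor noise),
#' giving the still-window detector a known, well-spread set of gravity
#' directions for calibration tests.
#'
#' @param orientations matrix of unit vectors (rows); defaults to the six
#'   axis directions plus the eight diagonals.
#' @param hold seconds per orientation (default 60).
#' @param sampling_rate Hz (default 30).
#' @param noise_sd noise SD in mg (default 3).
#' @param participant_id,site metadata.
#' @return A calibrated [raw_recording()].
#' @export
still_orientation_recording <- function(orientations = NULL, hold = 60,
                                        sampling_rate = 30, noise_sd = 3,
                                        participant_id = "CAL",
                                        site = "non_dominant_wrist") {
  if (is.null(orientations)) {
    ax <- rbind(diag(3), -diag(3))
    dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
    orientations <- rbind(ax, dg)
  }
  orientations <- orientations / sqrt(rowSums(orientations^2))
  n_per <- as.integer(hold * sampling_rate)
  O <- orientations[rep(seq_len(nrow(orientations)), each = n_per), ,
                    drop = FALSE]
  if (noise_sd > 0) {
    O <- O + matrix(stats::rnorm(length(O), sd = noise_sd / 1000), ncol = 3)
  }
  raw_recording(O, as.POSIXct(SYNTH_START, tz = "UTC"), sampling_rate,
                participant_id = participant_id, site = site,
                calibrated = TRUE)
}

#' Write a cohort participant to disk
#'
#' Writes each site's raw CSV, the sleep-diary CSV, and a ground-truth
#' sidecar (schedule table as CSV plus a JSON summary), in the dialects the
#' package reads back.
#'
#' @param participant one element of a `synthetic_cohort`'s `participants`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_participant <- function(participant, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(participant$recordings)) {
    write_raw_csv(participant$recordings[[s]],
                  file.path(dir, paste0(participant$id, "_", s, ".csv")))
  }
  write_sleep_diary(participant$diary,
                    file.path(dir, paste0(participant$id, "_diary.csv")))
  utils::write.csv(participant$schedule$bouts,
                   file.path(dir, paste0(participant$id, "_schedule.csv")),
                   row.names = FALSE)
  jsonlite::write_json(
    list(id = participant$id,
         n_days = participant$schedule$n_days,
         nonwear = participant$schedule$nonwear,
         sleep = participant$schedule$sleep),
    file.path(dir, paste0(participant$id, "_truth.json")),
    auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
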