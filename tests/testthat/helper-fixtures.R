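## Shared fixtures, built in code.

T0 <- as.POSIXct("2019-06-03 00:00:00", tz = "UTC")

## constant-orientation recording at `vec` (g) for `secs` seconds
const_recording <- function(vec = c(0, 0, 1), secs = 60, fs = 10,
                            start = T0, ...) {
  n <- as.integer(secs * fs)
  raw_recording(matrix(rep(vec, each = n), ncol = 3), start, fs, ...)
}

## recording whose norm is 1 + amp*sin(2*pi*f*t) along z
sin_norm_recording <- function(amp_g, freq = 1, secs = 60, fs = 100,
                               start = T0) {
  t <- (seq_len(secs * fs) - 1) / fs
  z <- 1 + amp_g * sin(2 * pi * freq * t)
  raw_recording(cbind(0, 0, z), start, fs, calibrated = TRUE)
}

## proper rotation matrix from Euler-like angles
rotation_matrix <- function(a, b, c) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  Ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  Rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

## hand-built nonwear_mask for imputation tests
manual_mask <- function(time, wear, clipped = rep(FALSE, length(time))) {
  structure(list(block = data.frame(block_start = time[1],
                                    nonwear = FALSE),
                 time = time, clipped = clipped, wear = wear),
            class = "nonwear_mask")
}

## paired smooth 1D Gaussian fields (rows = participants)
smooth_fields <- function(n, Q, sd_k = 8) {
  pad <- 3 * sd_k
  k <- stats::dnorm(seq(-pad, pad), sd = sd_k)
  k <- k / sqrt(sum(k^2))
  t(vapply(seq_len(n), function(i) {
    x <- stats::rnorm(Q + 2 * pad)
    as.numeric(stats::filter(x, k, sides = 2))[(pad + 1):(pad + Q)]
  }, numeric(Q)))
}

## labeled epoch series: `hours_wake` hours at `value` mg while awake,
## remainder sleeping at `sleep_value`, full days
labeled_series <- function(days = 1, value = 30, sleep_value = 3,
                           hours_wake = 16, L = 5, start = T0) {
  n_day <- 86400 / L
  n <- days * n_day
  time <- start + (seq_len(n) - 1) * L
  clock_h <- (as.numeric(time) %% 86400) / 3600
  lab <- ifelse(clock_h >= 7 & clock_h < 7 + hours_wake, "wake", "sleep")
  val <- ifelse(lab == "wake", value, sleep_value)
  epoch_series(time, val, epoch_length = L, label = lab)
}
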