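test_that("the posture angle matches the geometry of fixed orientations", {
  expect_equal(z_angle(const_recording(c(0, 0, 1), 30, 10))$angle,
               rep(90, 6), tolerance = 1e-9)
  expect_equal(z_angle(const_recording(c(1, 0, 0), 30, 10))$angle,
               rep(0, 6), tolerance = 1e-9)
  expect_equal(z_angle(const_recording(c(0, 0, -1), 30, 10))$angle,
               rep(-90, 6), tolerance = 1e-9)
})

## build an angle series: 5-s steps, `still` spans have constant angle,
## the rest jumps around by tens of degrees
angle_fixture <- function(still_spans, start = T0, hours = 24) {
  t <- start + seq(0, hours * 3600 - 5, by = 5)
  set.seed(99)
  ang <- runif(length(t), -80, 80)  # successive changes almost always > 5
  for (sp in still_spans) {
    sel <- t >= sp[[1]] & t < sp[[2]]
    ang[sel] <- sp[[3]]
  }
  data.frame(time = t, angle = ang)
}

test_that("a frozen-orientation night is detected close to its bounds", {
  night <- list(bed = T0 + 22 * 3600 + 50 * 60,   # diary 22:50
                rise = T0 + 24 * 3600 + 7 * 3600 + 20 * 60)  # 07:20 next day
  ang <- angle_fixture(list(list(T0 + 23 * 3600, T0 + 31 * 3600, 35)),
                       hours = 36)
  p <- detect_sleep_period(ang, night)
  expect_false(p$fallback)
  expect_lt(abs(as.numeric(p$onset - (T0 + 23 * 3600), units = "mins")), 10)
  expect_lt(abs(as.numeric(p$wake - (T0 + 31 * 3600), units = "mins")), 10)
})

test_that("continuous motion falls back to the diary times", {
  night <- list(bed = T0 + 23 * 3600, rise = T0 + 31 * 3600)
  ang <- angle_fixture(list(), hours = 36)
  expect_warning(p <- detect_sleep_period(ang, night), "diary")
  expect_true(p$fallback)
  expect_equal(p$onset, night$bed)
  expect_equal(p$wake, night$rise)
})

test_that("still blocks separated by less than an hour merge", {
  night <- list(bed = T0 + 22 * 3600, rise = T0 + 31 * 3600)
  ang <- angle_fixture(list(
    list(T0 + 22 * 3600, T0 + 23 * 3600, 40),          # 22:00-23:00
    list(T0 + 23.5 * 3600, T0 + 31 * 3600, -20)),      # 23:30-07:00
    hours = 36)
  p <- detect_sleep_period(ang, night)
  expect_false(p$fallback)
  expect_lt(abs(as.numeric(p$onset - (T0 + 22 * 3600), units = "mins")), 10)
  expect_lt(abs(as.numeric(p$wake - (T0 + 31 * 3600), units = "mins")), 10)
})

test_that("segmentation recovers synthetic sleep windows within 15 min", {
  spec <- cohort_spec(n_participants = 2, n_days = 2, sampling_rate = 10,
                      seed = 31, p_nonwear = 0)
  coh <- generate_cohort(spec, sites = "non_dominant_wrist")
  errs <- c()
  for (p in coh$participants) {
    seg <- segment_days(p$recordings[[1]], p$diary)
    sl <- p$schedule$sleep
    ## interior night: true onset day 1, true wake day 2
    true_onset <- T0 + sl$onset_min[1] * 60
    true_wake <- T0 + 86400 + sl$rise_min[2] * 60
    i <- which.min(abs(as.numeric(seg$onset) - as.numeric(true_onset)))
    errs <- c(errs,
              abs(as.numeric(seg$onset[i] - true_onset, units = "mins")),
              abs(as.numeric(seg$wake[i] - true_wake, units = "mins")))
  }
  expect_lt(median(errs), 15)
})

test_that("segmentation projects identically onto every site", {
  spec <- cohort_spec(n_participants = 1, n_days = 1, sampling_rate = 10,
                      seed = 41, p_nonwear = 0)
  coh <- generate_cohort(spec)
  p <- coh$participants[[1]]
  seg <- segment_days(p$recordings[["non_dominant_wrist"]], p$diary)
  labs <- lapply(p$recordings, function(r) {
    apply_segmentation(seg, enmo(r))$label
  })
  expect_identical(labs[[1]], labs[[2]])
  expect_identical(labs[[2]], labs[[3]])

  ## sleep + wake epochs partition the day
  expect_equal(sum(labs[[1]] %in% c("sleep", "wake")), 86400 / 5)

  ## number of detected sleep periods equals diary nights with data
  e <- enmo(p$recordings[[1]])
  lab <- apply_segmentation(seg, e)$label
  runs <- rle(lab)
  expect_equal(sum(runs$values == "sleep"), nrow(seg))

  ## shorter series is a span mismatch
  short <- epoch_series(e$time[1:100], e$value[1:100])
  expect_error(apply_segmentation(seg, short), "span")
})
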