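test_that("identical cohort specs give identical cohorts", {
  spec <- cohort_spec(n_participants = 2, n_days = 1, sampling_rate = 5,
                      seed = 7)
  c1 <- generate_cohort(spec, sites = "non_dominant_wrist")
  c2 <- generate_cohort(spec, sites = "non_dominant_wrist")
  expect_identical(c1$participants[[1]]$recordings[[1]]$data,
                   c2$participants[[1]]$recordings[[1]]$data)
  expect_identical(c1$participants[[2]]$schedule$bouts,
                   c2$participants[[2]]$schedule$bouts)
  expect_identical(c1$participants[[1]]$diary, c2$participants[[1]]$diary)
})

test_that("cohorts have one recording per site of the full duration", {
  spec <- cohort_spec(n_participants = 2, n_days = 2, sampling_rate = 1,
                      seed = 3)
  coh <- generate_cohort(spec)
  expect_length(coh$participants, 2)
  for (p in coh$participants) {
    expect_named(p$recordings,
                 c("hip", "dominant_wrist", "non_dominant_wrist"))
    for (r in p$recordings) {
      expect_equal(recording_duration(r), 2 * 86400)
      expect_true(all(abs(r$data) <= 6))
    }
  }
})

test_that("noiseless epoch ENMO recovers the scheduled bout amplitude", {
  spec <- cohort_spec(n_participants = 1, n_days = 1, sampling_rate = 30,
                      noise_sd = 0, seed = 5, p_nonwear = 0)
  coh <- generate_cohort(spec, sites = "non_dominant_wrist")
  p <- coh$participants[[1]]
  e <- enmo(p$recordings[[1]])
  truth <- schedule_epochs(p$schedule, spec)
  sel <- truth$amplitude_mg > 10
  rel_err <- abs(e$value[sel] - truth$amplitude_mg[sel]) /
    truth$amplitude_mg[sel]
  expect_lt(median(rel_err), 0.02)
  expect_lt(mean(rel_err > 0.02), 0.05)  # epochs straddling bout edges
})

test_that("dominant-wrist amplitudes scale by the asymmetry ratio", {
  spec <- cohort_spec(n_participants = 1, n_days = 1, sampling_rate = 10,
                      seed = 9, p_nonwear = 0, asymmetry_ratio = 1.1)
  coh <- generate_cohort(spec,
                         sites = c("non_dominant_wrist", "dominant_wrist"))
  p <- coh$participants[[1]]
  e_nd <- enmo(p$recordings[["non_dominant_wrist"]])
  e_dm <- enmo(p$recordings[["dominant_wrist"]])
  truth <- schedule_epochs(p$schedule, spec)
  act <- truth$class %in% c("light", "moderate", "vigorous")
  ratio <- mean(e_dm$value[act]) / mean(e_nd$value[act])
  expect_equal(ratio, 1.1, tolerance = 0.03)
})

test_that("waking site ordering is dominant > non-dominant > hip", {
  spec <- cohort_spec(n_participants = 2, n_days = 1, sampling_rate = 10,
                      seed = 21, p_nonwear = 0)
  coh <- generate_cohort(spec)
  waking_mean <- sapply(c("dominant_wrist", "non_dominant_wrist", "hip"),
    function(s) {
      mean(sapply(coh$participants, function(p) {
        e <- enmo(p$recordings[[s]])
        truth <- schedule_epochs(p$schedule, spec)
        mean(e$value[truth$class != "sleep"])
      }))
    })
  expect_gt(waking_mean["dominant_wrist"],
            waking_mean["non_dominant_wrist"])
  expect_gt(waking_mean["non_dominant_wrist"], waking_mean["hip"])
})

test_that("a symmetric cohort shows no systematic wrist difference", {
  p_vals <- sapply(1:3, function(seed) {
    spec <- cohort_spec(n_participants = 6, n_days = 1, sampling_rate = 5,
                        seed = 100 + seed, p_nonwear = 0,
                        asymmetry_ratio = 1)
    coh <- generate_cohort(spec,
                           sites = c("non_dominant_wrist",
                                     "dominant_wrist"))
    m <- t(sapply(coh$participants, function(p) {
      truth <- schedule_epochs(p$schedule, spec)
      wk <- truth$class != "sleep"
      c(nd = mean(enmo(p$recordings[["non_dominant_wrist"]])$value[wk]),
        dm = mean(enmo(p$recordings[["dominant_wrist"]])$value[wk]))
    }))
    stats::t.test(m[, "dm"], m[, "nd"], paired = TRUE)$p.value
  })
  expect_gte(sum(p_vals > 0.05), 2)
})

test_that("injected non-wear satisfies the non-wear rule, sleep does not", {
  spec <- cohort_spec(n_participants = 1, n_days = 1, sampling_rate = 10,
                      seed = 13, p_nonwear = 1,
                      nonwear_minutes = c(120, 150))
  coh <- generate_cohort(spec, sites = "non_dominant_wrist")
  p <- coh$participants[[1]]
  nw <- detect_nonwear(p$recordings[[1]])
  ep <- p$schedule$nonwear
  expect_equal(nrow(ep), 1)
  e0 <- as.numeric(T0) + (ep$day - 1) * 86400 + ep$start_min * 60
  e1 <- e0 + ep$dur_min * 60
  bs <- as.numeric(nw$block_start)
  interior <- bs - 1350 >= e0 & bs + 900 + 1350 <= e1
  expect_true(any(interior))
  expect_true(all(nw$nonwear[interior]))
  ## sleep blocks (posture shifts, but worn) must not be flagged
  outside <- !(bs + 900 + 1350 > e0 & bs - 1350 < e1)
  full_window <- bs - 1350 >= as.numeric(T0) &
    bs + 900 + 1350 <= as.numeric(T0) + 86400
  expect_true(all(!nw$nonwear[outside & full_window]))
})

test_that("calibration-error injection is the exact inverse of calibration", {
  rec <- const_recording(c(0.3, -0.4, 0.866), secs = 30, fs = 10)
  same <- inject_calibration_error(rec, c(0, 0, 0), c(1, 1, 1))
  expect_equal(same$data, rec$data)

  off <- c(0.05, -0.02, 0.01); gn <- c(1.02, 0.98, 1.01)
  bad <- inject_calibration_error(rec, off, gn)
  params <- structure(list(offset = off, gain = gn, error_before = NA,
                           error_after = NA, n_windows = 0,
                           sphere_coverage_ok = TRUE),
                      class = "calibration_params")
  restored <- apply_calibration(bad, params)
  expect_equal(restored$data, rec$data, tolerance = 1e-12)
})

test_that("a static x-offset moves still-window norms by the offset", {
  rec <- const_recording(c(1, 0, 0), secs = 100, fs = 10, calibrated = TRUE)
  bad <- inject_calibration_error(rec, offset = c(0.05, 0, 0))
  w <- find_still_windows(bad)
  expect_gt(nrow(w$mean), 0)
  norms <- sqrt(rowSums(w$mean^2))
  expect_equal(mean(abs(norms - 1)) * 1000, 50, tolerance = 1)
})

test_that("participant files round-trip through the readers", {
  spec <- cohort_spec(n_participants = 1, n_days = 1, sampling_rate = 2,
                      seed = 17)
  coh <- generate_cohort(spec, sites = "non_dominant_wrist")
  dir <- withr::local_tempdir()
  write_participant(coh$participants[[1]], dir)
  rec <- read_raw_csv(file.path(dir, "P01_non_dominant_wrist.csv"))
  expect_equal(rec$sampling_rate, 2)
  expect_equal(nrow(rec$data), 2 * 86400)
  diary <- read_sleep_diary(file.path(dir, "P01_diary.csv"))
  expect_equal(nrow(diary), nrow(coh$participants[[1]]$diary))
  expect_true(all(diary$duration_h > 0))
})
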