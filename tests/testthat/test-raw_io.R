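test_that("raw CSV round-trips samples to 6 decimals", {
  set.seed(1)
  rec <- raw_recording(matrix(round(runif(300, -1, 1), 6), ncol = 3),
                       T0 + 7200, 10, participant_id = "P07",
                       site = "hip")
  path <- withr::local_tempfile(fileext = ".csv")
  write_raw_csv(rec, path)
  back <- read_raw_csv(path)
  expect_equal(back$data, rec$data, tolerance = 1e-9)
  expect_equal(back$participant_id, "P07")
  expect_equal(back$site, "hip")
  expect_equal(back$sampling_rate, 10)
  expect_equal(back$start_time, rec$start_time)
  ## bit-stable output
  write_raw_csv(rec, paste0(path, "2"))
  expect_identical(readLines(path), readLines(paste0(path, "2")))
})

test_that("vendor-style headers with US dates and semicolons parse", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "------------ Data File Created By Motion Tracker ------------",
    "Serial Number: XYZ123",
    "Start Time 10:00:00",
    "Start Date 6/3/2019",
    "Sample Rate 30",
    "--------------------------------------------------",
    "0.1;0.2;0.97",
    "0.1;0.2;0.97",
    "-0.1;0.0;1.01"), path)
  rec <- read_raw_csv(path)
  expect_equal(rec$sampling_rate, 30)
  expect_equal(rec$start_time, as.POSIXct("2019-06-03 10:00:00", tz = "UTC"))
  expect_equal(nrow(rec$data), 3)
  expect_equal(unname(rec$data[3, 3]), 1.01)
})

test_that("malformed raw files give informative errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Start Time: 2019-06-03 00:00:00", "----",
               "0.1,0.2,0.97"), path)
  expect_error(read_raw_csv(path), "Sample Rate")

  writeLines(c("Sample Rate: 10", "Start Time: 2019-06-03 00:00:00", "----",
               "0.1,0.2,0.97", "0.9,NaN,0.1", "0.1,0.2,0.97"), path)
  expect_error(read_raw_csv(path), "row 5")

  rec <- const_recording(secs = 1, fs = 2)
  rec$data <- rec$data[0, , drop = FALSE]
  expect_error(write_raw_csv(rec, path), "empty")
})

test_that("epoch counts combine axes as the Euclidean norm", {
  path <- withr::local_tempfile(fileext = ".csv")
  t <- format(T0 + seq(0, 10, by = 5), "%Y-%m-%d %H:%M:%S")
  writeLines(c("time,axis1,axis2,axis3",
               paste0(t, ",3,4,0")), path)
  cs <- read_epoch_counts(path)
  expect_s3_class(cs, "epoch_series")
  expect_equal(cs$metric, "counts")
  expect_equal(cs$value, c(5, 5, 5))

  writeLines(c("time,vm", paste0(t, ",0")), path)
  expect_equal(read_epoch_counts(path)$value, c(0, 0, 0))

  t60 <- format(T0 + seq(0, 120, by = 60), "%Y-%m-%d %H:%M:%S")
  writeLines(c("time,vm", paste0(t60, ",5")), path)
  expect_error(read_epoch_counts(path), "not spaced 5")
})

test_that("sleep diaries resolve nights crossing midnight", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("date,bed_time,rise_time",
               "2019-01-01,23:30,07:15"), path)
  d <- read_sleep_diary(path)
  expect_equal(d$duration_h, 7.75)
  expect_equal(as.Date(format(d$rise, "%Y-%m-%d")), as.Date("2019-01-02"))

  writeLines(c("date,bed_time,rise_time",
               paste0("2019-01-0", 1:7, ",23:00,06:30")), path)
  expect_equal(nrow(read_sleep_diary(path)), 7)

  writeLines(c("date,bed_time,rise_time", "2019-01-01,23:30,"), path)
  expect_error(read_sleep_diary(path), "row 1")
})

test_that("epoch grids are anchored at multiples of 5 s from midnight", {
  rec <- const_recording(c(0, 0, 1.1), secs = 30, fs = 10,
                         start = T0 + 2)  # off-grid start
  e <- enmo(rec)
  expect_true(all(as.numeric(e$time) %% 5 == 0))
  expect_equal(as.numeric(e$time[1] - T0, units = "secs"), 5)
  expect_equal(length(e$value), 5)  # leading and trailing partials dropped
})

test_that("epoch CSV export carries all metrics on one grid", {
  rec <- const_recording(c(0, 0, 1.05), secs = 60, fs = 10,
                         calibrated = TRUE)
  ms <- suppressWarnings(compute_all_metrics(rec))  # low-rate filter notice
  path <- withr::local_tempfile(fileext = ".csv")
  write_epoch_csv(ms, path)
  df <- read.csv(path)
  expect_named(df, c("time", "enmo_mg", "lfenmo_mg", "mad_mg", "wear",
                     "imputed", "label"))
  expect_equal(df$enmo_mg, rep(50, 12), tolerance = 1e-9)
})
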