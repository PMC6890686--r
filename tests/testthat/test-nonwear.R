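test_that("the 2-of-3 axis rule classifies blocks as specified", {
  ## 3 h constant: zero SD and range on all axes -> all blocks non-wear
  rec <- const_recording(c(0, 0, 1), secs = 3 * 3600, fs = 5)
  nw <- detect_nonwear(rec)
  expect_true(all(nw$nonwear))

  ## vigorous oscillation on all axes -> all blocks wear
  t <- (seq_len(3 * 3600 * 5) - 1) / 5
  d <- pi * 0.3 * sin(2 * pi * t)
  act <- raw_recording((1 + d) %o% (c(1, 1, 1) / sqrt(3)), T0, 5)
  nw <- detect_nonwear(act)
  expect_true(all(!nw$nonwear))

  ## still on exactly one axis, active on two -> wear
  osc <- 0.1 * sin(2 * pi * t)
  one_still <- raw_recording(cbind(osc, osc, 1), T0, 5)
  nw <- detect_nonwear(one_still)
  expect_true(all(!nw$nonwear))

  ## still on two axes -> non-wear
  two_still <- raw_recording(cbind(osc, 0, 1), T0, 5)
  expect_true(all(detect_nonwear(two_still)$nonwear))
})

test_that("clipping flags only epochs with samples above the limit", {
  rec <- const_recording(c(0, 0, 1.2), secs = 60, fs = 10)
  expect_true(all(!detect_clipping(rec)$clipped))

  spiked <- rec
  spiked$data[75, 3] <- 6  # inside epoch 2 ([5, 10) s)
  cl <- detect_clipping(spiked)
  expect_equal(which(cl$clipped), 2L)

  ## exactly at the limit is not "higher than"
  at_limit <- const_recording(c(0, 0, 1), secs = 10, fs = 10)
  at_limit$data[5, 3] <- 5.5
  expect_true(all(!detect_clipping(at_limit)$clipped))
})

test_that("imputation uses same-clock-time donors across days", {
  L <- 300
  n_day <- 86400 / L
  time <- T0 + (seq_len(7 * n_day) - 1) * L
  value <- rep(10 * (1:7), each = n_day)  # day d has value 10*d
  s <- epoch_series(time, value, epoch_length = L)
  clock <- as.numeric(time) %% 86400
  target <- clock == 10 * 3600  # the 10:00:00 epoch of each day
  wear <- rep(TRUE, length(time))
  wear[target & value == 30] <- FALSE  # invalidate day 3 at 10:00
  mask <- manual_mask(time, wear)
  out <- impute_epochs(s, mask)
  imputed_idx <- which(target & value == 30)
  expect_equal(out$value[imputed_idx], mean(c(10, 20, 40, 50, 60, 70)))
  expect_true(out$imputed[imputed_idx])
  expect_false(out$wear[imputed_idx])

  ## all days invalid at 04:00 -> stays missing
  wear2 <- rep(TRUE, length(time))
  wear2[clock == 4 * 3600] <- FALSE
  out2 <- impute_epochs(s, manual_mask(time, wear2))
  expect_true(all(is.na(out2$value[clock == 4 * 3600])))
  expect_true(all(!out2$imputed[clock == 4 * 3600]))

  ## nothing invalid -> identity
  out3 <- impute_epochs(s, manual_mask(time, rep(TRUE, length(time))))
  expect_equal(out3$value, s$value)
  expect_equal(sum(out3$imputed), 0)
})

test_that("imputation preserves the cross-day mean at each clock time", {
  set.seed(3)
  L <- 300
  n_day <- 86400 / L
  time <- T0 + (seq_len(4 * n_day) - 1) * L
  value <- runif(length(time), 0, 100)
  wear <- runif(length(time)) > 0.2
  s <- epoch_series(time, value, epoch_length = L)
  out <- impute_epochs(s, manual_mask(time, wear))
  clock <- as.numeric(time) %% 86400
  for (cl in unique(clock)[c(1, 57, 200)]) {
    sel <- clock == cl
    donors <- value[sel & wear]
    if (length(donors) && any(sel & !wear)) {
      expect_equal(unique(out$value[sel & !wear]), mean(donors))
    }
  }
})

test_that("wear summaries enforce the 16 h / 4 day inclusion rule", {
  full <- labeled_series(days = 7, L = 300)
  ws <- summarize_wear(full)
  expect_equal(nrow(ws), 7)
  expect_equal(ws$wear_h, rep(24, 7))
  expect_true(all(ws$valid_day))
  expect_true(attr(ws, "included"))
  expect_equal(ws$waking_wear_h, rep(16, 7))
  expect_equal(ws$sleeping_wear_h, rep(8, 7))

  ## 2-h daily shower non-wear: still valid
  shower <- full
  clock_h <- (as.numeric(shower$time) %% 86400) / 3600
  shower$wear[clock_h >= 9 & clock_h < 11] <- FALSE
  ws2 <- summarize_wear(shower)
  expect_equal(ws2$wear_h, rep(22, 7))
  expect_true(all(ws2$valid_day))

  ## only 3 valid days -> excluded
  three <- labeled_series(days = 5, L = 300)
  day <- floor(as.numeric(three$time - T0) / 86400)
  three$wear[day >= 3] <- FALSE
  ws3 <- summarize_wear(three)
  expect_equal(sum(ws3$valid_day), 3)
  expect_false(attr(ws3, "included"))
})

test_that("wear + non-wear + missing hours account for each full day", {
  s <- labeled_series(days = 2, L = 300)
  s$wear[5:40] <- FALSE
  ws <- summarize_wear(s)
  expect_equal(ws$wear_h + ws$nonwear_h + ws$missing_h, rep(24, 2))
})
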