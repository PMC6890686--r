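test_that("LCCC matches closed-form values and guards degenerate input", {
  x <- c(1, 2, 3)
  expect_equal(lccc(x, x), 1)
  expect_equal(lccc(x, x + 1), 4 / 7)
  expect_equal(lccc(c(-1, 0, 1), c(1, 0, -1)), -1)
  expect_equal(lccc(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(lccc(c(2, 2, 2), c(3, 3, 3)), 0)
  ## LCCC <= |r| with equality iff equal means and SDs
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8) + rnorm(1)
    expect_lte(lccc(a, b), abs(cor(a, b)) + 1e-12)
  }
})

test_that("paired mean differences and CIs match the t construction", {
  x <- c(10, 12, 15, 9)
  expect_equal(mean_diff_ci(x, x)$diff, 0)
  expect_equal(mean_diff_ci(x, x)$ci, c(0, 0))
  shifted <- mean_diff_ci(x, x + 10)
  expect_equal(shifted$diff, 10)
  expect_equal(shifted$ci, c(10, 10))

  set.seed(5)
  a <- rnorm(12, 100, 20); b <- a + rnorm(12, 5, 8)
  got <- mean_diff_ci(a, b)
  tt <- t.test(b - a)
  expect_equal(got$diff, unname(tt$estimate))
  expect_equal(got$ci, as.numeric(tt$conf.int))
  expect_equal(got$p, tt$p.value)
})

test_that("group MAPE is |diff| / reference mean and rejects bad input", {
  expect_equal(mape_group(769, -25), 3.25)
  expect_equal(mape_group(147, 14), 9.52)
  expect_equal(mape_group(9, 0), 0)
  expect_error(mape_group(0, 1), "positive")
  expect_error(mape_group(-3, 1), "positive")
  expect_equal(mape_individual(c(100, 200), c(110, 180)), 10)
})

test_that("shared variance matches direct correlation and flags noise", {
  x <- c(1, 3, 4, 7, 9)
  sv <- suppressWarnings(shared_variance(x, 2 * x + 1))  # exact fit notice
  expect_equal(sv$r2, 1, tolerance = 1e-12)
  expect_lt(sv$p, 1e-6)

  y <- c(2.2, 2.9, 5.1, 6.8, 10.4)
  expect_equal(shared_variance(x, y)$r2, cor(x, y)^2)

  set.seed(6)
  hits <- sum(sapply(1:20, function(i) {
    shared_variance(rnorm(42), rnorm(42))$p > 0.05
  }))
  expect_gte(hits, 16)
  expect_error(shared_variance(rep(1, 5), 1:5), "variance")
})

test_that("epochs are binned by the half-open cut-point convention", {
  s <- labeled_series(value = 30, hours_wake = 16)
  cm <- classify_minutes(s, reference_cutpoints())
  expect_equal(unname(cm$mean["sedentary"]), 960)
  expect_equal(sum(cm$mean), unname(cm$daily$waking_wear_min[1]))

  ## exactly at a boundary goes up a category (lower bound inclusive)
  s50 <- labeled_series(value = 50, hours_wake = 16)
  cm50 <- classify_minutes(s50, cut_points(50, 110, 440))
  expect_equal(unname(cm50$mean["light"]), 960)
  expect_equal(unname(cm50$mean["sedentary"]), 0)

  expect_error(classify_minutes(
    epoch_series(s$time, s$value), reference_cutpoints()), "label")
})

test_that("category minutes always sum to waking wear minutes", {
  set.seed(14)
  s <- labeled_series(days = 2, L = 30)
  s$value <- runif(length(s$value), 0, 500)
  cm <- classify_minutes(s, reference_cutpoints())
  for (d in 1:2) {
    expect_equal(sum(cm$daily[d, c("sedentary", "light", "moderate",
                                   "vigorous")]),
                 cm$daily$waking_wear_min[d])
  }
})

## synthetic per-participant epoch-value lists with a known wrist ratio
scaled_cohort_values <- function(n, ratio, seed) {
  set.seed(seed)
  ref <- lapply(seq_len(n), function(i) {
    v <- c(rgamma(8000, shape = 0.9, scale = 35),
           runif(300, 250, 650))
    list(v)
  })
  names(ref) <- sprintf("P%02d", seq_len(n))
  comp <- lapply(ref, function(days) lapply(days, function(v) v * ratio))
  list(ref = ref, comp = comp)
}

test_that("the grid has the published candidate structure", {
  vals <- scaled_cohort_values(5, 1.1, seed = 3)
  g <- evaluate_grid(vals$ref, vals$comp)
  expect_equal(nrow(g), 24)
  expect_equal(as.integer(table(g$category)[c("sedentary", "light",
                                              "moderate", "vigorous")]),
               c(3L, 9L, 9L, 3L))
  expect_true(all(g$lccc >= -1 & g$lccc <= 1))
  expect_true(all(g$ci_lo <= g$diff & g$diff <= g$ci_hi))
  expect_true(all(g$mape >= 0, na.rm = TRUE))
})

test_that("an identical comparison wrist selects the reference set", {
  vals <- scaled_cohort_values(5, 1, seed = 4)
  g <- evaluate_grid(vals$ref, vals$comp)
  unshifted <- g[(g$category == "sedentary" & g$sed == 45) |
                   (g$category == "light" & g$sed == 45 &
                      g$light_upper == 100) |
                   (g$category == "moderate" & g$light_upper == 100 &
                      g$mod_upper == 430) |
                   (g$category == "vigorous" & g$mod_upper == 430), ]
  expect_equal(unshifted$diff, rep(0, 4))
  expect_equal(unshifted$lccc, rep(1, 4))
  sel <- select_cutpoints(g)
  expect_equal(unlist(sel),
               unlist(reference_cutpoints()))
})

test_that("a 10% asymmetric cohort shifts the selected thresholds up", {
  vals <- scaled_cohort_values(6, 1.1, seed = 5)
  g <- evaluate_grid(vals$ref, vals$comp)
  sel <- select_cutpoints(g)
  expect_equal(sel$sedentary_upper, 50)
  expect_gte(sel$light_upper, 105)
  expect_gte(sel$moderate_upper, 435)
  ## the shifted sedentary candidate dominates the unshifted one
  sed <- g[g$category == "sedentary", ]
  expect_lt(abs(sed$diff[sed$sed == 50]), abs(sed$diff[sed$sed == 45]))
})

test_that("selection is deterministic and order-independent", {
  ex <- translation_worked_example()
  cal <- ex[ex$block == "translation", ]
  sel1 <- select_cutpoints(cal)
  set.seed(2)
  for (i in 1:5) {
    shuffled <- cal[sample(nrow(cal)), ]
    expect_equal(unlist(select_cutpoints(shuffled)), unlist(sel1))
  }
  ## full symmetric ties return the reference itself
  tied <- cal
  tied$diff <- 0; tied$mape <- 0; tied$lccc <- 0.9
  expect_equal(unlist(select_cutpoints(tied)),
               unlist(reference_cutpoints()))
})

test_that("cross-validation reports fit the translated cut points", {
  vals <- scaled_cohort_values(6, 1.1, seed = 7)
  cuts <- dominant_wrist_cutpoints()
  cv <- cross_validate(cuts, vals$ref, vals$comp)
  expect_equal(cv$category, c("sedentary", "light", "moderate", "vigorous"))

  ## with reference cuts on the asymmetric wrist, sedentary time is lost
  cv_ref <- cross_validate(reference_cutpoints(), vals$ref, vals$comp)
  expect_lt(cv_ref$diff[1], 0)

  ## translated cuts reduce |diff| in at least 3 of 4 categories
  better <- sum(abs(cv$diff) < abs(cv_ref$diff) + 1e-9)
  expect_gte(better, 3)

  expect_error(
    cross_validate(cuts, vals$ref, vals$comp,
                   calibration_ids = names(vals$ref)),
    "overlap")
})

test_that("identical wrists cross-validate with near-perfect agreement", {
  vals <- scaled_cohort_values(6, 1, seed = 8)
  cv <- cross_validate(reference_cutpoints(), vals$ref, vals$comp)
  expect_true(all(abs(cv$diff) < 1e-9))
  expect_true(all(cv$lccc > 0.95))
})
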