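## Intensity classification and agreement statistics for the cut-point
## translation: daily minutes per intensity category, Lin's concordance
## correlation coefficient, paired mean differences with 95% CI, group-level
## MAPE, the candidate grid search, the three-step threshold selection, and
## cross-validation in an independent cohort.

#' Classify waking epochs into intensity categories
#'
#' Bins waking, worn-or-imputed epochs by the half-open cut-point convention
#' (lower bound inclusive) and accumulates minutes per participant-day;
#' per-participant means over valid days feed the agreement analysis.
#'
#' @param series a labeled ENMO [epoch_series()] (mg) with wear flags.
#' @param cuts a [cut_points()] set.
#' @param min_wear_hours minimum daily wear for a day to count (default 16).
#' @return A list of class `intensity_summary`: `daily` (data frame of
#'   minutes per participant-day), `mean` (named per-participant mean minutes
#'   over valid days), `participant_id`, `site`, `cuts`.
#' @export
classify_minutes <- function(series, cuts, min_wear_hours = 16) {
  stopifnot(inherits(series, "epoch_series"), inherits(cuts, "cut_points"))
  if (all(is.na(series$label))) {
    stop("series has no wake/sleep labels; run apply_segmentation() first")
  }
  L <- series$epoch_length
  usable <- (series$wear | series$imputed) & !is.na(series$value)
  day <- day_index(series$time)
  days <- sort(unique(day))
  br <- c(0, cuts$sedentary_upper, cuts$light_upper, cuts$moderate_upper, Inf)
  rows <- lapply(days, function(d) {
    sel <- day == d & usable & series$label %in% "wake"
    v <- series$value[sel]
    cat_idx <- findInterval(v, br, left.open = FALSE)  # [lo, hi)
    mins <- vapply(1:4, function(k) sum(cat_idx == k) * L / 60, numeric(1))
    wear_h <- sum(day == d & series$wear) * L / 3600
    data.frame(date = as.Date(as.POSIXct(d * 86400, origin = "1970-01-01",
                                         tz = "UTC")),
               sedentary = mins[1], light = mins[2], moderate = mins[3],
               vigorous = mins[4], waking_wear_min = sum(sel) * L / 60,
               wear_h = wear_h)
  })
  daily <- do.call(rbind, rows)
  valid <- daily$wear_h >= min_wear_hours
  if (!any(valid)) valid <- rep(TRUE, nrow(daily))  # degenerate short input
  means <- colMeans(daily[valid, INTENSITY_LEVELS, drop = FALSE])
  structure(list(daily = daily, mean = means,
                 participant_id = series$participant_id, site = series$site,
                 cuts = cuts),
            class = "intensity_summary")
}

#' @export
print.intensity_summary <- function(x, ...) {
  cat(sprintf("<intensity_summary> %s @ %s | min/day: %s\n",
              x$participant_id, x$site,
              paste(sprintf("%s %.1f", names(x$mean), x$mean),
                    collapse = ", ")))
  invisible(x)
}

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 s_xy / (s_x^2 + s_y^2 + (mean(x) - mean(y))^2)` with 1/n moment
#' estimators. Degenerate inputs are guarded: zero total variance with equal
#' means returns 1 (perfect agreement of constants), zero variance with
#' unequal means returns 0.
#'
#' @param x,y paired per-participant values (length >= 3).
#' @return The concordance coefficient in `[-1, 1]`.
#' @export
lccc <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- mean((x - mx) * (y - my))
  sx2 <- mean((x - mx)^2)
  sy2 <- mean((y - my)^2)
  denom <- sx2 + sy2 + (mx - my)^2
  if (denom < .Machine$double.eps) {
    return(if (abs(mx - my) < .Machine$double.eps) 1 else 0)
  }
  2 * sxy / denom
}

#' Paired mean difference with 95% confidence interval
#'
#' Difference is `mean(y) - mean(x)` (comparison minus reference); the CI is
#' the paired-t interval with n-1 degrees of freedom. With zero variance of
#' the differences the interval collapses to the point difference.
#'
#' @param x reference values; `y` comparison values, paired.
#' @param y see `x`.
#' @param conf confidence level (default 0.95).
#' @return A list with `diff`, `ci` (length 2), `p` (paired t-test) and `n`.
#' @export
mean_diff_ci <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs for a confidence interval")
  d <- y - x
  m <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  if (se < .Machine$double.eps) {
    p <- if (abs(m) < .Machine$double.eps) NA_real_ else 0
    return(list(diff = m, ci = c(m, m), p = p, n = n))
  }
  tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  tstat <- m / se
  list(diff = m, ci = c(m - tq * se, m + tq * se),
       p = 2 * stats::pt(-abs(tstat), df = n - 1), n = n)
}

#' Group-level mean absolute percent error
#'
#' `100 * |diff| / ref_mean`: the absolute group mean difference as a percent
#' of the reference group mean, reported to two decimals. This group-level
#' form is the one used for cut-point selection.
#'
#' @param ref_mean reference group mean (min/day); must be positive.
#' @param diff group mean difference (comparison minus reference).
#' @return MAPE in percent, rounded to 2 decimals.
#' @export
mape_group <- function(ref_mean, diff) {
  if (any(ref_mean <= 0)) stop("reference mean must be positive")
  round(100 * abs(diff) / ref_mean, 2)
}

#' Per-participant mean absolute percent error
#'
#' The mean over participants of `100 * |y_i - x_i| / x_i`. Provided for
#' completeness; the group-level [mape_group()] is what drives cut-point
#' selection.
#'
#' @param x reference per-participant values (all positive).
#' @param y comparison per-participant values.
#' @return Mean absolute percent error in percent.
#' @export
mape_individual <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x <= 0)) stop("reference values must be positive")
  mean(100 * abs(y - x) / x)
}

#' Shared variance (r-squared) between paired participant means
#'
#' Ordinary least-squares shared variance with a CI obtained by Fisher
#' z-transforming r, and the slope-test p-value.
#'
#' @param x,y paired values, `n >= 4`, non-degenerate.
#' @param conf confidence level (default 0.95).
#' @return A list with `r2`, `ci` (endpoints of the Fisher-z interval for r,
#'   squared), `p` and `n`.
#' @export
shared_variance <- function(x, y, conf = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (stats::sd(x) < .Machine$double.eps ||
      stats::sd(y) < .Machine$double.eps) {
    stop("zero variance input")
  }
  n <- length(x)
  r <- stats::cor(x, y)
  z <- atanh(min(max(r, -1 + 1e-12), 1 - 1e-12))
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci_r <- tanh(c(z - zq / sqrt(n - 3), z + zq / sqrt(n - 3)))
  fit <- stats::lm(y ~ x)
  p <- summary(fit)$coefficients[2, 4]
  list(r2 = r^2, ci = sort(ci_r^2), p = p, n = n)
}

## --- candidate grid -------------------------------------------------------

#' Default candidate threshold grid
#'
#' The reference thresholds incremented by 5 and 10 mg:
#' sedentary {45,50,55}, light-upper {100,105,110}, moderate-upper
#' {430,435,440}.
#' @param reference the reference [cut_points()].
#' @param increments added to each reference threshold (default `c(0, 5, 10)`).
#' @return A list with `sedentary`, `light`, `moderate` candidate vectors.
#' @export
default_grid <- function(reference = reference_cutpoints(),
                         increments = c(0, 5, 10)) {
  list(sedentary = reference$sedentary_upper + increments,
       light = reference$light_upper + increments,
       moderate = reference$moderate_upper + increments)
}

## minutes spent in [lo, hi) per participant, from per-participant lists of
## per-day waking epoch values (mg); mean over days
minutes_between <- function(day_values, lo, hi, epoch_length = 5) {
  per_day <- vapply(day_values, function(v) {
    sum(v >= lo & v < hi) * epoch_length / 60
  }, numeric(1))
  mean(per_day)
}

#' Extract per-day waking epoch values for grid evaluation
#'
#' @param series a labeled, imputed ENMO [epoch_series()].
#' @param min_wear_hours minimum daily wear for a valid day (default 16).
#' @return A list (one element per valid day) of numeric epoch values (mg)
#'   from waking, worn-or-imputed epochs.
#' @export
waking_epoch_values <- function(series, min_wear_hours = 16) {
  usable <- (series$wear | series$imputed) & !is.na(series$value)
  day <- day_index(series$time)
  days <- sort(unique(day))
  L <- series$epoch_length
  out <- list()
  for (d in days) {
    if (sum(day == d & series$wear) * L / 3600 < min_wear_hours) next
    out[[length(out) + 1L]] <-
      series$value[day == d & usable & series$label %in% "wake"]
  }
  if (!length(out)) stop("no valid days in series")
  out
}

## agreement statistics for one candidate in one category
candidate_report <- function(category, sed, light_upper, mod_upper,
                             ref_minutes, comp_minutes) {
  mdc <- mean_diff_ci(ref_minutes, comp_minutes)
  rm <- mean(ref_minutes)
  data.frame(
    category = category, sed = sed, light_upper = light_upper,
    mod_upper = mod_upper,
    ref_mean = rm, ref_sd = stats::sd(ref_minutes),
    comp_mean = mean(comp_minutes), comp_sd = stats::sd(comp_minutes),
    lccc = lccc(ref_minutes, comp_minutes),
    diff = mdc$diff, ci_lo = mdc$ci[1], ci_hi = mdc$ci[2],
    mape = if (rm > 0) mape_group(rm, mdc$diff) else NA_real_,
    p = mdc$p, stringsAsFactors = FALSE)
}

#' Evaluate the candidate cut-point grid
#'
#' Builds one agreement report per category-specific candidate, comparing
#' dominant-wrist minutes under the candidate thresholds with the reference
#' non-dominant-wrist minutes under the reference thresholds. Sedentary
#' candidates vary the sedentary threshold only; light candidates vary
#' (sedentary, light-upper) pairs; moderate candidates vary (light-upper,
#' moderate-upper) pairs; vigorous candidates vary the moderate-upper
#' threshold only. Non-monotone candidates are skipped with a warning.
#'
#' @param ref_values list over participants of per-day waking epoch value
#'   lists for the reference (non-dominant) wrist, see
#'   [waking_epoch_values()].
#' @param comp_values matching list for the comparison (dominant) wrist.
#' @param grid candidate grid from [default_grid()].
#' @param reference the reference [cut_points()].
#' @param epoch_length epoch length in seconds (default 5).
#' @return A data frame of agreement reports (class `agreement_grid`), one
#'   row per candidate.
#' @export
evaluate_grid <- function(ref_values, comp_values,
                          grid = default_grid(),
                          reference = reference_cutpoints(),
                          epoch_length = 5) {
  stopifnot(length(ref_values) == length(comp_values),
            length(ref_values) >= 3)
  n <- length(ref_values)
  ref_min <- function(lo, hi) vapply(ref_values, minutes_between, numeric(1),
                                     lo = lo, hi = hi,
                                     epoch_length = epoch_length)
  comp_min <- function(lo, hi) vapply(comp_values, minutes_between,
                                      numeric(1), lo = lo, hi = hi,
                                      epoch_length = epoch_length)
  rows <- list()
  add <- function(df) rows[[length(rows) + 1L]] <<- df

  ## reference per-category minutes (non-dominant wrist, reference cuts)
  ref_sed <- ref_min(0, reference$sedentary_upper)
  ref_light <- ref_min(reference$sedentary_upper, reference$light_upper)
  ref_mod <- ref_min(reference$light_upper, reference$moderate_upper)
  ref_vig <- ref_min(reference$moderate_upper, Inf)

  for (s in grid$sedentary) {
    add(candidate_report("sedentary", s, NA, NA, ref_sed, comp_min(0, s)))
  }
  for (s in grid$sedentary) for (l in grid$light) {
    if (!(s < l)) { warning("skipping non-monotone candidate ", s, "-", l)
      next }
    add(candidate_report("light", s, l, NA, ref_light, comp_min(s, l)))
  }
  for (l in grid$light) for (m in grid$moderate) {
    if (!(l < m)) { warning("skipping non-monotone candidate ", l, "-", m)
      next }
    add(candidate_report("moderate", NA, l, m, ref_mod, comp_min(l, m)))
  }
  for (m in grid$moderate) {
    add(candidate_report("vigorous", NA, NA, m, ref_vig, comp_min(m, Inf)))
  }
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  class(out) <- c("agreement_grid", "data.frame")
  out
}

## --- three-step selection -------------------------------------------------

## order candidate rows by |diff|, then MAPE, then -LCCC; values compared
## with a small tolerance so printed (rounded) inputs tie exactly
rank_candidates <- function(rows, tol = 1e-9) {
  key <- function(v) round(v / tol) * tol
  mape <- ifelse(is.na(rows$mape), Inf, rows$mape)
  ord <- order(key(abs(rows$diff)), key(mape), -key(rows$lccc))
  rows[ord, , drop = FALSE]
}

## rows tied with the best row on all three ranking keys
best_tied <- function(rows, tol = 1e-9) {
  r <- rank_candidates(rows, tol)
  mape <- ifelse(is.na(r$mape), Inf, r$mape)
  b_diff <- abs(r$diff[1]); b_mape <- mape[1]; b_lccc <- r$lccc[1]
  tied <- abs(abs(r$diff) - b_diff) <= tol &
    (abs(mape - b_mape) <= tol | (is.infinite(mape) & is.infinite(b_mape))) &
    abs(r$lccc - b_lccc) <= tol
  r[tied, , drop = FALSE]
}

#' Select translated cut points from candidate agreement reports
#'
#' Deterministic three-step selection: (1) pick the vigorous threshold
#' (moderate-upper) minimising |mean difference|, then MAPE, then maximising
#' LCCC — if every vigorous candidate ties on all three statistics the step
#' is deferred; (2) pick the moderate (light-upper, moderate-upper) pair the
#' same way among candidates consistent with step 1, breaking remaining ties
#' by matching the reference inter-threshold distance and then by staying
#' closest to the reference thresholds; (3) pick the light (sedentary,
#' light-upper) pair consistent with step 2 the same way.
#'
#' @param reports an `agreement_grid` data frame from [evaluate_grid()] (or
#'   equivalently structured candidate reports).
#' @param reference the reference [cut_points()].
#' @param tol numeric tolerance for treating two statistics as tied
#'   (default 1e-9).
#' @return The selected [cut_points()].
#' @export
select_cutpoints <- function(reports, reference = reference_cutpoints(),
                             tol = 1e-9) {
  need <- c("vigorous", "moderate", "light")
  for (cat in need) {
    if (!any(reports$category == cat)) {
      stop("reports are missing the '", cat, "' category")
    }
  }
  ## step 1: vigorous (moderate-upper threshold only)
  vig <- reports[reports$category == "vigorous", , drop = FALSE]
  vb <- best_tied(vig, tol)
  mod_upper_fixed <- NA_real_
  if (nrow(vb) < nrow(vig)) {
    ## a strict (possibly tied) winner exists; break residual ties by
    ## closeness to the reference threshold, then by the lower threshold
    vb <- vb[order(abs(vb$mod_upper - reference$moderate_upper),
                   vb$mod_upper), , drop = FALSE]
    mod_upper_fixed <- vb$mod_upper[1]
  }
  ## step 2: moderate pairs, restricted by step 1 when it decided
  mod <- reports[reports$category == "moderate", , drop = FALSE]
  if (!is.na(mod_upper_fixed)) {
    mod <- mod[abs(mod$mod_upper - mod_upper_fixed) <= tol, , drop = FALSE]
    if (!nrow(mod)) stop("no moderate candidate matches the vigorous choice")
  }
  mb <- best_tied(mod, tol)
  ref_dist_mod <- reference$moderate_upper - reference$light_upper
  mb <- mb[order(abs((mb$mod_upper - mb$light_upper) - ref_dist_mod),
                 abs(mb$light_upper - reference$light_upper) +
                   abs(mb$mod_upper - reference$moderate_upper),
                 mb$light_upper, mb$mod_upper), , drop = FALSE]
  light_upper <- mb$light_upper[1]
  mod_upper <- mb$mod_upper[1]

  ## step 3: light pairs with the chosen light-upper threshold
  light <- reports[reports$category == "light", , drop = FALSE]
  light <- light[abs(light$light_upper - light_upper) <= tol, , drop = FALSE]
  if (!nrow(light)) stop("no light candidate matches the moderate choice")
  lb <- best_tied(light, tol)
  ref_dist_light <- reference$light_upper - reference$sedentary_upper
  lb <- lb[order(abs((lb$light_upper - lb$sed) - ref_dist_light),
                 abs(lb$sed - reference$sedentary_upper), lb$sed), ,
           drop = FALSE]
  cut_points(lb$sed[1], light_upper, mod_upper)
}

#' Cross-validate translated cut points in an independent cohort
#'
#' One agreement report per intensity category comparing the reference wrist
#' under the reference thresholds with the comparison wrist under the
#' translated thresholds, in a cohort independent of the calibration sample.
#'
#' @param cuts the translated [cut_points()].
#' @param ref_values,comp_values per-participant waking epoch value lists for
#'   the independent cohort (see [waking_epoch_values()]).
#' @param reference the reference [cut_points()].
#' @param calibration_ids optional participant ids of the calibration cohort;
#'   overlap with `names(ref_values)` is an error.
#' @param epoch_length epoch length in seconds (default 5).
#' @return A data frame with one agreement report row per category.
#' @export
cross_validate <- function(cuts, ref_values, comp_values,
                           reference = reference_cutpoints(),
                           calibration_ids = NULL, epoch_length = 5) {
  stopifnot(length(ref_values) == length(comp_values))
  if (!is.null(calibration_ids) && !is.null(names(ref_values)) &&
      any(names(ref_values) %in% calibration_ids)) {
    stop("cross-validation cohort overlaps the calibration cohort")
  }
  ref_br <- c(0, reference$sedentary_upper, reference$light_upper,
              reference$moderate_upper, Inf)
  cmp_br <- c(0, cuts$sedentary_upper, cuts$light_upper, cuts$moderate_upper,
              Inf)
  rows <- lapply(1:4, function(k) {
    rv <- vapply(ref_values, minutes_between, numeric(1),
                 lo = ref_br[k], hi = ref_br[k + 1],
                 epoch_length = epoch_length)
    cv <- vapply(comp_values, minutes_between, numeric(1),
                 lo = cmp_br[k], hi = cmp_br[k + 1],
                 epoch_length = epoch_length)
    candidate_report(INTENSITY_LEVELS[k], cuts$sedentary_upper,
                     cuts$light_upper, cuts$moderate_upper, rv, cv)
  })
  do.call(rbind, rows)
}
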