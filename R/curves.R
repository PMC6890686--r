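## Diurnal 30-min profiles, sorted daily acceleration curves, and paired
## curve comparison by one-dimensional statistical parametric mapping (SPM):
## a pointwise t statistic, a smoothness (FWHM) estimate from the temporal
## gradient of the normalised residuals, a random-field-theory family-wise
## threshold, and cluster-level p-values; a permutation max-t threshold is
## available as an exact alternative for small samples.

#' Diurnal 30-min profile
#'
#' Mean metric value per 30-min clock bin: mean over epochs within a bin per
#' participant-day, then over days per participant, then over participants.
#' Empty bins propagate as `NA` and are excluded from z-scoring.
#'
#' @param series_list list of [epoch_series()], one per participant.
#' @param zscore standardise the 48-bin profile to mean 0, SD 1 (a zero-SD
#'   profile is returned as all zeros).
#' @param bin_minutes clock bin width in minutes (default 30).
#' @return A data frame with `bin_start` (seconds since midnight), `hour` and
#'   `mean`, plus attribute `per_participant` (participants x bins matrix).
#' @export
diurnal_profile <- function(series_list, zscore = FALSE, bin_minutes = 30) {
  if (inherits(series_list, "epoch_series")) series_list <- list(series_list)
  bin_s <- bin_minutes * 60
  n_bins <- as.integer(86400 / bin_s)
  per_part <- t(vapply(series_list, function(s) {
    ok <- !is.na(s$value)
    bin <- floor(clock_seconds(s$time)[ok] / bin_s) + 1
    day <- day_index(s$time)[ok]
    v <- s$value[ok]
    ## participant-day bin means, then mean over days
    pd <- tapply(v, list(day, bin), mean)
    out <- rep(NA_real_, n_bins)
    cols <- as.integer(colnames(pd))
    out[cols] <- colMeans(pd, na.rm = TRUE)
    out
  }, numeric(n_bins)))
  prof <- colMeans(per_part, na.rm = TRUE)
  prof[is.nan(prof)] <- NA
  if (zscore) {
    ok <- !is.na(prof)
    s <- stats::sd(prof[ok])
    prof[ok] <- if (s < .Machine$double.eps) 0 else
      (prof[ok] - mean(prof[ok])) / s
  }
  out <- data.frame(bin_start = (seq_len(n_bins) - 1) * bin_s,
                    hour = (seq_len(n_bins) - 1) * bin_s / 3600,
                    mean = prof)
  attr(out, "per_participant") <- per_part
  out
}

#' Sorted daily acceleration curve
#'
#' Per complete day, the day's epoch values sorted ascending and
#' down-averaged onto `Q` equal nodes; curves are averaged over days within a
#' participant. The curve starts at the day's quietest epochs and ends at its
#' most intense, making days comparable regardless of when activity occurred.
#' Incomplete days (missing epochs after imputation) are excluded with a
#' warning.
#'
#' @param series an [epoch_series()] for one participant.
#' @param Q number of curve nodes (default 1440).
#' @return A numeric vector of length `Q` (non-decreasing), or `NULL` when no
#'   complete day exists.
#' @export
sorted_curve <- function(series, Q = 1440) {
  stopifnot(inherits(series, "epoch_series"))
  L <- series$epoch_length
  n_day <- as.integer(86400 / L)
  day <- day_index(series$time)
  curves <- list()
  for (d in sort(unique(day))) {
    sel <- day == d
    v <- series$value[sel]
    ok <- (series$wear[sel] | series$imputed[sel]) & !is.na(v)
    if (sum(sel) < n_day || !all(ok)) {
      warning("skipping incomplete day ", format(series$time[sel][1], "%Y-%m-%d"))
      next
    }
    v <- sort(v)
    per_node <- length(v) / Q
    if (abs(per_node - round(per_node)) < 1e-9) {
      node_vals <- colMeans(matrix(v, nrow = as.integer(round(per_node))))
    } else {
      grp <- floor((seq_along(v) - 1) * Q / length(v)) + 1
      node_vals <- as.numeric(tapply(v, grp, mean))
    }
    curves[[length(curves) + 1L]] <- node_vals
  }
  if (!length(curves)) return(NULL)
  colMeans(do.call(rbind, curves))
}

## E[EC] density of a 1D t field per resel (two-tailed handled by caller)
rft_rho1 <- function(t, df) {
  sqrt(4 * log(2)) / (2 * pi) * (1 + t^2 / df)^(-(df - 1) / 2)
}

## FWHM (in nodes) from the temporal gradient of normalised residuals
estimate_fwhm <- function(resid) {
  ss <- colSums(resid^2)
  ss[ss < .Machine$double.eps] <- 1
  u <- sweep(resid, 2, sqrt(ss), "/")
  du <- t(diff(t(u)))  # gradient along nodes
  v <- mean(colSums(du^2))
  if (v < .Machine$double.eps) return(Inf)
  sqrt(4 * log(2) / v)
}

## two-sided RFT family-wise threshold for a 1D t field
rft_threshold <- function(df, resels, alpha = 0.05) {
  f <- function(t) {
    2 * (stats::pt(t, df, lower.tail = FALSE) + resels * rft_rho1(t, df)) -
      alpha
  }
  if (f(100) > 0) return(Inf)
  stats::uniroot(f, c(1e-3, 100), tol = 1e-10)$root
}

#' Paired-curve SPM t-test
#'
#' Node-wise paired t statistic for per-participant curve pairs, with the
#' family-wise critical threshold at level `alpha` from smooth-Gaussian-field
#' (random field theory, RFT) expectations — smoothness estimated as the
#' FWHM of the normalised paired-difference residuals — or from a
#' sign-permutation max-t distribution. Suprathreshold clusters are reported
#' with cluster-level p-values.
#'
#' @param curvesA,curvesB matrices, participants x nodes, paired by row.
#' @param alpha family-wise significance level (default 0.05, two-sided).
#' @param method `"rft"` (default) or `"perm"`.
#' @param n_perm permutations for `method = "perm"` (default 2000; all
#'   sign-flips are enumerated when feasible).
#' @param var_floor relative variance floor guarding zero-variance nodes
#'   (default 1e-12).
#' @return An object of class `spm_result`: `t` (node-wise statistic),
#'   `df`, `fwhm`, `resels`, `t_crit`, `clusters` (data frame with
#'   `start`, `end`, `extent`, `p`), `alpha`, `method`, and
#'   `guarded` (nodes where the variance floor was applied).
#' @export
spm_paired_t <- function(curvesA, curvesB, alpha = 0.05,
                         method = c("rft", "perm"), n_perm = 2000,
                         var_floor = 1e-12) {
  method <- match.arg(method)
  curvesA <- as.matrix(curvesA); curvesB <- as.matrix(curvesB)
  stopifnot(all(dim(curvesA) == dim(curvesB)), nrow(curvesA) >= 3)
  n <- nrow(curvesA); Q <- ncol(curvesA)
  d <- curvesB - curvesA
  m <- colMeans(d)
  sdev <- apply(d, 2, stats::sd)
  floor_val <- max(sdev) * sqrt(var_floor)
  guarded <- which(sdev <= floor_val)
  sdev_g <- pmax(sdev, max(floor_val, .Machine$double.eps))
  tval <- m / (sdev_g / sqrt(n))
  tval[sdev <= .Machine$double.eps & abs(m) <= .Machine$double.eps] <- 0
  df <- n - 1

  resid <- sweep(d, 2, m, "-")
  fwhm <- estimate_fwhm(resid)
  resels <- (Q - 1) / fwhm

  if (method == "rft") {
    t_crit <- rft_threshold(df, resels, alpha)
  } else {
    t_crit <- perm_max_t_threshold(d, alpha, n_perm)
  }

  clusters <- find_clusters(tval, t_crit)
  if (nrow(clusters)) {
    if (method == "rft") {
      clusters$p <- vapply(clusters$extent, function(k) {
        rft_cluster_p(k, t_crit, df, fwhm, Q)
      }, numeric(1))
    } else {
      clusters$p <- perm_cluster_p(d, t_crit, clusters$extent, n_perm)
    }
  }
  structure(list(t = tval, df = df, fwhm = fwhm, resels = resels,
                 t_crit = t_crit, clusters = clusters, alpha = alpha,
                 method = method, Q = Q, guarded = guarded),
            class = "spm_result")
}

## contiguous runs where |t| exceeds the threshold
find_clusters <- function(tval, t_crit) {
  over <- is.finite(tval) & abs(tval) > t_crit
  if (!any(over)) {
    return(data.frame(start = integer(0), end = integer(0),
                      extent = integer(0), p = numeric(0)))
  }
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = starts[keep], end = ends[keep],
             extent = r$lengths[keep], p = NA_real_)
}

## RFT cluster-level p for a cluster of `k` nodes at threshold u
rft_cluster_p <- function(k, u, df, fwhm, Q) {
  resels <- (Q - 1) / fwhm
  Em <- 2 * resels * rft_rho1(u, df)          # expected cluster count
  EN <- Q * 2 * stats::pt(u, df, lower.tail = FALSE)  # expected nodes above u
  if (Em < .Machine$double.eps) return(0)
  nbar <- max(EN / Em, .Machine$double.eps)   # expected nodes per cluster
  beta <- (gamma(1.5) / nbar)^2
  p_k <- exp(-beta * k^2)
  1 - exp(-Em * p_k)
}

## permutation (sign-flip) max-|t| threshold for paired differences
perm_max_t_threshold <- function(d, alpha = 0.05, n_perm = 2000) {
  n <- nrow(d)
  maxt <- perm_max_stats(d, n_perm)$maxt
  as.numeric(stats::quantile(maxt, 1 - alpha, type = 8))
}

perm_max_stats <- function(d, n_perm, t_crit = NULL) {
  n <- nrow(d)
  if (n <= 14) {
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
  } else {
    signs <- matrix(sample(c(1, -1), n * n_perm, replace = TRUE), ncol = n)
  }
  maxt <- numeric(nrow(signs))
  maxext <- integer(nrow(signs))
  for (i in seq_len(nrow(signs))) {
    ds <- d * signs[i, ]
    m <- colMeans(ds)
    s <- sqrt((colMeans(ds^2) - m^2) * n / (n - 1))
    s <- pmax(s, .Machine$double.eps)
    tv <- m / (s / sqrt(n))
    maxt[i] <- max(abs(tv))
    if (!is.null(t_crit)) {
      over <- abs(tv) > t_crit
      maxext[i] <- if (any(over)) max(rle(over)$lengths[rle(over)$values])
        else 0L
    }
  }
  list(maxt = maxt, maxext = maxext)
}

## permutation cluster p: share of permutations whose largest suprathreshold
## cluster is at least as long as the observed one
perm_cluster_p <- function(d, t_crit, extents, n_perm) {
  st <- perm_max_stats(d, n_perm, t_crit = t_crit)
  vapply(extents, function(k) mean(st$maxext >= k), numeric(1))
}

#' @export
print.spm_result <- function(x, ...) {
  cat(sprintf(
    "<spm_result> %d nodes, df = %d | FWHM %.1f nodes, %.1f resels | t* = %.3f (alpha %.2f, %s)\n",
    x$Q, x$df, x$fwhm, x$resels, x$t_crit, x$alpha, x$method))
  if (nrow(x$clusters)) {
    for (i in seq_len(nrow(x$clusters))) {
      cat(sprintf("  cluster %d: nodes %d-%d (p = %.4g)\n", i,
                  x$clusters$start[i], x$clusters$end[i], x$clusters$p[i]))
    }
  } else cat("  no suprathreshold clusters\n")
  invisible(x)
}

#' Report significant node ranges as percentiles
#'
#' Maps each suprathreshold cluster of an SPM result on a sorted curve to the
#' percentile range of the daily acceleration distribution it covers.
#'
#' @param result an `spm_result` from [spm_paired_t()].
#' @param Q number of nodes (defaults to the result's).
#' @return A character vector, one `"Xth-Yth percentile"` entry per cluster
#'   (empty when there are none).
#' @export
percentile_band_report <- function(result, Q = result$Q) {
  if (!nrow(result$clusters)) return(character(0))
  fmt <- function(p) paste0(round(p), "th")
  vapply(seq_len(nrow(result$clusters)), function(i) {
    lo <- (result$clusters$start[i] - 1) / Q * 100
    hi <- result$clusters$end[i] / Q * 100
    paste0(fmt(lo), "–", fmt(hi), " percentile")
  }, character(1))
}
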