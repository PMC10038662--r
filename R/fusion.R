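#' Time-resolved regression fusion of sensor data and a region response
#'
#' Links millisecond-resolved sensor recordings to a region's scalar
#' response by asking, separately at every timepoint, how well the sensor
#' pattern predicts the per-trial region response.  Cross-validation is
#' leave-one-session-out: for each held-out session an ordinary
#' least-squares model (with intercept) is fit on the remaining sessions'
#' sensor patterns at that timepoint, and the Pearson correlation between
#' predicted and true responses on the held-out session is recorded.  The
#' across-fold mean correlation is smoothed with a centered moving average
#' (default width 5 timepoints, truncated at the edges).
#'
#' When a fold has fewer training trials than sensors + 1 the OLS problem
#' is rank-deficient; the minimum-norm least-squares solution is used and a
#' warning logged.  Folds whose held-out truth is constant have undefined
#' correlation and are recorded as missing.
#'
#' @param data A `fusion_data` object (see [simulate_fusion_data()],
#'   [fusion_dataset()]).
#' @param roi Name of the region in `data$roi_responses`.
#' @param smoothing_window Width of the centered moving average, in
#'   timepoints (default 5).
#' @return An object of class `fusion_corr`: `time_ms`, `r_per_fold`
#'   (folds x timepoints), `r_mean` (smoothed across-fold mean),
#'   `smoothing_window`, `roi`, `sessions`, `baseline_window`.
#' @examples
#' fd <- simulate_fusion_data(90, 6, seq(-100, 300, 20), 3,
#'                            c(V1 = 100), snr = 3, seed = 1)
#' fit_fusion(fd, "V1")
#' @export
fit_fusion <- function(data, roi, smoothing_window = 5L) {
  stopifnot(inherits(data, "fusion_data"))
  if (!roi %in% names(data$roi_responses)) {
    abort(sprintf("Region '%s' not found in the dataset.", roi))
  }
  assert_count(smoothing_window, "smoothing_window")
  y <- data$roi_responses[[roi]]
  sessions <- data$session_labels
  fold_ids <- sort(unique(sessions))
  if (length(fold_ids) < 2) abort("Need at least 2 sessions.")
  n_tp <- length(data$time_ms)
  n_sensors <- dim(data$sensor_data)[2]

  r <- matrix(NA_real_, length(fold_ids), n_tp)
  warned_rank <- FALSE
  warned_const <- FALSE
  for (f in seq_along(fold_ids)) {
    test <- sessions == fold_ids[f]
    if (stats::sd(y[test]) == 0) {
      warned_const <- TRUE
      next
    }
    for (t in seq_len(n_tp)) {
      x_tr <- matrix(data$sensor_data[!test, , t], ncol = n_sensors)
      x_te <- matrix(data$sensor_data[test, , t], ncol = n_sensors)
      if (sum(!test) < n_sensors + 1) {
        warned_rank <- TRUE
        # minimum-norm least squares via the pseudoinverse
        xc <- scale(x_tr, scale = FALSE)
        yc <- y[!test] - mean(y[!test])
        sv <- svd(xc)
        pos <- sv$d > max(sv$d) * 1e-10
        beta <- sv$v[, pos, drop = FALSE] %*%
          ((crossprod(sv$u[, pos, drop = FALSE], yc)) / sv$d[pos])
        pred <- (x_te - rep(colMeans(x_tr), each = sum(test))) %*% beta +
          mean(y[!test])
      } else {
        fit <- stats::lm.fit(cbind(1, x_tr), y[!test])
        cf <- fit$coefficients
        cf[is.na(cf)] <- 0
        pred <- cbind(1, x_te) %*% cf
      }
      if (stats::sd(pred) == 0) {
        warned_const <- TRUE
        next
      }
      r[f, t] <- cor(pred, y[test])
    }
  }
  if (warned_rank) {
    warn("Training rows < sensors + 1 in some fold(s); minimum-norm solution used.")
  }
  if (warned_const) {
    warn("Constant prediction or truth in some fold(s); correlations recorded as missing.")
  }
  raw_mean <- colMeans(r, na.rm = TRUE)
  raw_mean[is.nan(raw_mean)] <- NA_real_
  structure(
    list(time_ms = data$time_ms, r_per_fold = r,
         r_mean = moving_average(raw_mean, smoothing_window),
         smoothing_window = as.integer(smoothing_window), roi = roi,
         sessions = fold_ids, baseline_window = data$baseline_window),
    class = "fusion_corr"
  )
}

# centered moving average, truncated at the edges (NAs ignored)
moving_average <- function(x, width) {
  if (width <= 1) return(x)
  half <- (width - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' @export
print.fusion_corr <- function(x, ...) {
  cat(sprintf(
    "<fusion_corr> region %s: %d folds x %d timepoints (%g-%g ms), peak r = %.3f\n",
    x$roi, nrow(x$r_per_fold), length(x$time_ms), min(x$time_ms),
    max(x$time_ms), max(x$r_mean, na.rm = TRUE)))
  invisible(x)
}

#' Largest supra-baseline time window
#'
#' Finds when a correlation time course carries real stimulus information:
#' the threshold is the maximum of the (smoothed) mean correlation during
#' the pre-stimulus baseline, and the result is the longest contiguous run
#' of timepoints strictly exceeding that threshold (ties go to the earliest
#' run).  An empty window is allowed when the series never exceeds its
#' baseline maximum.
#'
#' @param series A `fusion_corr`.
#' @param baseline Length-2 `(t0, t1)` in ms; defaults to the series'
#'   stored baseline window.
#' @return A list of class `supra_window`: `threshold`, `onset_ms`,
#'   `offset_ms` (both `NA` when empty), `member_timepoints` (indices into
#'   the time axis).
#' @export
supra_baseline_window <- function(series, baseline = NULL) {
  stopifnot(inherits(series, "fusion_corr"))
  baseline <- baseline %||% series$baseline_window
  tm <- series$time_ms
  in_base <- tm >= baseline[1] & tm <= baseline[2]
  if (!any(in_base)) abort("`baseline` lies outside the time axis.")
  threshold <- max(series$r_mean[in_base], na.rm = TRUE)
  above <- !is.na(series$r_mean) & series$r_mean > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  cand <- which(runs$values)
  if (!length(cand)) {
    return(structure(list(threshold = threshold, onset_ms = NA_real_,
                          offset_ms = NA_real_,
                          member_timepoints = integer(0)),
                     class = "supra_window"))
  }
  best <- cand[which.max(runs$lengths[cand])]  # ties -> earliest
  idx <- starts[best]:ends[best]
  structure(
    list(threshold = threshold, onset_ms = tm[starts[best]],
         offset_ms = tm[ends[best]], member_timepoints = idx),
    class = "supra_window"
  )
}

#' @export
print.supra_window <- function(x, ...) {
  if (length(x$member_timepoints)) {
    cat(sprintf("<supra_window> %g-%g ms above threshold %.3f (%d timepoints)\n",
                x$onset_ms, x$offset_ms, x$threshold,
                length(x$member_timepoints)))
  } else {
    cat(sprintf("<supra_window> empty (threshold %.3f never exceeded)\n",
                x$threshold))
  }
  invisible(x)
}

#' Bootstrap confidence band for a fusion correlation time course
#'
#' The exchangeable unit is the cross-validation fold: at each timepoint
#' the fold-wise correlations are resampled with replacement, the mean of
#' each draw is recorded, and the band is the (2.5, 97.5) percentile
#' interval.  Folds with missing correlations at a timepoint are excluded
#' from that timepoint's resampling.
#'
#' @param series A `fusion_corr`.
#' @param n_boot Number of draws (default 10,000).
#' @param seed Integer seed.
#' @return A tibble with `time_ms`, `r_mean` (smoothed), `ci_low`,
#'   `ci_high`.
#' @export
bootstrap_fusion_ci <- function(series, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(series, "fusion_corr"))
  assert_count(n_boot, "n_boot")
  r <- series$r_per_fold
  if (nrow(r) < 2) abort("Need at least 2 folds.")
  if (anyNA(r)) warn("Folds with missing correlations excluded per timepoint.")
  bands <- with_seed(seed, {
    apply(r, 2, function(rv) {
      rv <- rv[!is.na(rv)]
      if (length(rv) == 0) return(c(NA_real_, NA_real_))
      idx <- matrix(sample.int(length(rv), n_boot * length(rv),
                               replace = TRUE), n_boot)
      quantile(rowMeans(matrix(rv[idx], n_boot)), c(0.025, 0.975),
               names = FALSE)
    })
  })
  tibble::tibble(time_ms = series$time_ms, r_mean = series$r_mean,
                 ci_low = bands[1, ], ci_high = bands[2, ])
}

#' Contrast two regions' fusion time courses
#'
#' Computes the fold-paired difference between two correlation time courses
#' (e.g. an early visual versus a category-selective region) and a
#' bootstrap 95% confidence band obtained by resampling the paired
#' fold-wise differences; a timepoint is flagged significant when its band
#' excludes 0.
#'
#' @param series_a,series_b `fusion_corr` objects with identical time axes
#'   and fold structure.
#' @param n_boot Number of draws (default 10,000).
#' @param seed Integer seed.
#' @return A tibble with `time_ms`, `diff` (mean of `a - b` across folds),
#'   `ci_low`, `ci_high`, `significant`.
#' @export
roi_contrast <- function(series_a, series_b, n_boot = 10000L, seed = 1L) {
  stopifnot(inherits(series_a, "fusion_corr"),
            inherits(series_b, "fusion_corr"))
  if (!isTRUE(all.equal(series_a$time_ms, series_b$time_ms)) ||
      nrow(series_a$r_per_fold) != nrow(series_b$r_per_fold)) {
    abort("The two series must share the time axis and fold structure.")
  }
  d <- series_a$r_per_fold - series_b$r_per_fold
  diff_mean <- colMeans(d, na.rm = TRUE)
  bands <- with_seed(seed, {
    apply(d, 2, function(dv) {
      dv <- dv[!is.na(dv)]
      if (length(dv) == 0) return(c(NA_real_, NA_real_))
      idx <- matrix(sample.int(length(dv), n_boot * length(dv),
                               replace = TRUE), n_boot)
      quantile(rowMeans(matrix(dv[idx], n_boot)), c(0.025, 0.975),
               names = FALSE)
    })
  })
  tibble::tibble(time_ms = series_a$time_ms, diff = diff_mean,
                 ci_low = bands[1, ], ci_high = bands[2, ],
                 significant = !is.na(bands[1, ]) &
                   (bands[1, ] > 0 | bands[2, ] < 0))
}
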