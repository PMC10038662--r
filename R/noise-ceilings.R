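#' Explainable-variance noise ceiling for repeated measurements
#'
#' Estimates, per measurement channel, how much response variance any model
#' could at best explain given trial-to-trial measurement noise.  The noise
#' variance is the pooled variance over repeated responses to the same
#' image (unweighted mean of the per-image unbiased variances, repeats
#' being balanced by design); the signal variance is the variance over the
#' image-wise mean responses.  The ceiling is
#' `signal_var / (signal_var + noise_var / n_average)`, where `n_average`
#' is the number of trial repeats a downstream analysis will average over
#' (1 for single-trial responses, e.g. 12 for a 12-repeat test set).
#'
#' With `bias_correct = FALSE` (default) the variance of the image means is
#' used as the signal variance verbatim; it overestimates the true signal
#' variance by about `noise_var / n_repeats`.  `bias_correct = TRUE`
#' subtracts that term (floored at 0).
#'
#' @param data A `repeated_measures` object (see
#'   [simulate_repeated_measures()]) or an array
#'   `n_channels x n_images x n_repeats`.
#' @param n_average Number of repeats averaged in the downstream analysis.
#' @param bias_correct Subtract the noise contribution from the signal
#'   variance estimate?
#'
#' @return A tibble with one row per channel: `channel`, `signal_var`,
#'   `noise_var`, `n_average`, `ceiling` (fraction in `[0, 1]`).
#' @examples
#' rm <- simulate_repeated_measures(3, 500, 12, signal_sd = 1, noise_sd = 1,
#'                                  seed = 1)
#' neuro_noise_ceiling(rm, n_average = 12)
#' @export
neuro_noise_ceiling <- function(data, n_average = 1L, bias_correct = FALSE) {
  arr <- if (inherits(data, "repeated_measures")) data$responses else data
  if (!is.array(arr) || length(dim(arr)) != 3) {
    abort("`data` must be a repeated_measures object or a 3-d array.")
  }
  n_average <- assert_count(n_average, "n_average")
  n_repeats <- dim(arr)[3]
  if (n_repeats < 2) abort("Need at least 2 repeats per image.")
  if (any(!is.finite(arr))) abort("`data` must have no missing entries.")

  channel_ids <- if (inherits(data, "repeated_measures")) {
    data$channel_ids
  } else {
    sprintf("ch%03d", seq_len(dim(arr)[1]))
  }

  # per channel: mean over images of the unbiased across-repeat variance
  noise_var <- apply(arr, 1, function(ch) mean(apply(ch, 1, var)))
  signal_var <- apply(arr, 1, function(ch) var(rowMeans(ch)))
  if (bias_correct) {
    signal_var <- pmax(signal_var - noise_var / n_repeats, 0)
  }
  ceiling <- ifelse(signal_var + noise_var / n_average > 0,
                    signal_var / (signal_var + noise_var / n_average),
                    0)
  tibble::tibble(channel = channel_ids, signal_var = signal_var,
                 noise_var = noise_var, n_average = n_average,
                 ceiling = ceiling)
}

#' Choice-consistency noise ceiling for repeated behavioral triplets
#'
#' For triplets answered repeatedly, the consistency of a triplet is the
#' modal choice count divided by the number of repeats, in percent; the
#' noise ceiling is the mean consistency across triplets.  Because it is
#' based on the most consistent choice observed in the sample, this
#' estimator slightly overestimates the true ceiling (the caveat is carried
#' in the `"estimator"` attribute of the result).
#'
#' @param counts Per-triplet 3-way choice counts: a matrix or data frame
#'   with 3 count columns (e.g. `n_a`, `n_b`, `n_c` from
#'   [consistency_counts()]); each row must sum to at least 2.
#' @return The ceiling in percent, with attribute `per_triplet` (the
#'   per-triplet consistencies).
#' @examples
#' behavioral_noise_ceiling(rbind(c(12, 0, 0), c(4, 4, 4)))
#' @export
behavioral_noise_ceiling <- function(counts) {
  if (is.data.frame(counts)) {
    cols <- intersect(c("n_a", "n_b", "n_c"), names(counts))
    counts <- if (length(cols) == 3) as.matrix(counts[cols]) else {
      as.matrix(counts[vapply(counts, is.numeric, logical(1))])
    }
  }
  if (!is.matrix(counts) || ncol(counts) != 3 || nrow(counts) == 0) {
    abort("`counts` must be a non-empty matrix with 3 count columns.")
  }
  totals <- rowSums(counts)
  if (any(totals < 2)) abort("Every triplet must be repeated at least twice.")
  per_triplet <- 100 * apply(counts, 1, max) / totals
  structure(mean(per_triplet), per_triplet = per_triplet,
            estimator = "sample-modal consistency (upper-biased)")
}
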