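#' Simulate repeated measurements with a signal-plus-noise model
#'
#' Emulates repeated presentations of the same images in a neuroimaging
#' experiment: each channel-by-image cell has a fixed true response
#' `mu ~ Normal(0, signal_sd^2)`, and each repeat adds independent
#' measurement noise `Normal(0, noise_sd^2)`.  The resulting array is the
#' input expected by [neuro_noise_ceiling()].
#'
#' @param n_channels,n_images,n_repeats Array dimensions; `n_repeats >= 2`.
#' @param signal_sd,noise_sd Non-negative standard deviations of the true
#'   signal and of the per-repeat noise, in response units.
#' @param seed Integer seed.
#'
#' @return An object of class `repeated_measures`: a list with `responses`
#'   (array `n_channels x n_images x n_repeats`), `channel_ids`,
#'   `image_ids`, and the generating parameters.
#' @examples
#' rm <- simulate_repeated_measures(4, 100, 12, signal_sd = 1, noise_sd = 1,
#'                                  seed = 1)
#' dim(rm$responses)
#' @export
simulate_repeated_measures <- function(n_channels, n_images, n_repeats,
                                       signal_sd = 1, noise_sd = 1,
                                       seed = 1) {
  n_channels <- assert_count(n_channels, "n_channels")
  n_images <- assert_count(n_images, "n_images")
  n_repeats <- assert_count(n_repeats, "n_repeats", min = 2L)
  assert_positive(signal_sd, "signal_sd", strict = FALSE)
  assert_positive(noise_sd, "noise_sd", strict = FALSE)

  responses <- with_seed(seed, {
    mu <- matrix(rnorm(n_channels * n_images, sd = signal_sd),
                 n_channels, n_images)
    eps <- array(rnorm(n_channels * n_images * n_repeats, sd = noise_sd),
                 dim = c(n_channels, n_images, n_repeats))
    array(mu, dim = c(n_channels, n_images, n_repeats)) + eps
  })
  structure(
    list(responses = responses,
         channel_ids = sprintf("ch%03d", seq_len(n_channels)),
         image_ids = sprintf("img%04d", seq_len(n_images)),
         signal_sd = signal_sd, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "repeated_measures"
  )
}

#' Construct a fusion dataset
#'
#' Container coupling time-resolved sensor recordings (e.g. MEG) with scalar
#' per-trial responses of one or more regions of interest (e.g. fMRI V1 and
#' FFA responses to the same stimuli), plus the session structure used for
#' leave-one-session-out cross-validation.  This constructor validates the
#' invariants and is the conversion point for real data: build the
#' trials-by-sensors-by-timepoints array, one response vector per region,
#' and integer session labels, then pass them here.
#'
#' @param sensor_data Numeric array `n_trials x n_sensors x n_timepoints`.
#' @param roi_responses Named list of numeric vectors, each of length
#'   `n_trials`.
#' @param session_labels Integer vector of length `n_trials`; every session
#'   must appear at least twice.
#' @param time_ms Numeric vector of timepoints in milliseconds, length
#'   `n_timepoints`.
#' @param baseline_window Length-2 numeric `(t_start, t_end)` in ms; must
#'   lie within `time_ms` and end at or before 0 (pre-stimulus).
#'
#' @return An object of class `fusion_data`.
#' @export
fusion_dataset <- function(sensor_data, roi_responses, session_labels,
                           time_ms, baseline_window) {
  stopifnot(is.array(sensor_data), length(dim(sensor_data)) == 3)
  n_trials <- dim(sensor_data)[1]
  if (length(time_ms) != dim(sensor_data)[3]) {
    abort("`time_ms` length must match the third dimension of `sensor_data`.")
  }
  if (!is.list(roi_responses) || is.null(names(roi_responses)) ||
      any(!nzchar(names(roi_responses)))) {
    abort("`roi_responses` must be a named list of numeric vectors.")
  }
  if (any(vapply(roi_responses, length, integer(1)) != n_trials)) {
    abort("Every `roi_responses` vector must have length n_trials.")
  }
  if (length(session_labels) != n_trials) {
    abort("`session_labels` must have length n_trials.")
  }
  if (any(table(session_labels) < 2)) {
    abort("Every session label must appear at least twice.")
  }
  if (length(baseline_window) != 2 ||
      baseline_window[1] < min(time_ms) || baseline_window[2] > max(time_ms) ||
      baseline_window[2] > 0 || baseline_window[1] >= baseline_window[2]) {
    abort("`baseline_window` must lie within `time_ms` and precede 0 ms.")
  }
  structure(
    list(sensor_data = sensor_data, roi_responses = roi_responses,
         session_labels = as.integer(session_labels),
         time_ms = as.numeric(time_ms),
         baseline_window = as.numeric(baseline_window)),
    class = "fusion_data"
  )
}

#' Simulate a multimodal fusion dataset with region-specific latencies
#'
#' Generates the inputs for regression-based sensor-to-region fusion with a
#' known ground truth.  Each region of interest has one latent scalar
#' feature per trial; the region response is that feature plus noise, and
#' each sensor carries a fixed linear loading of the feature from the
#' region's onset latency onward.  Before all onsets the sensors contain
#' pure noise, so stimulus information becomes linearly decodable exactly at
#' the injected latencies.  Noise standard deviations are `1 / snr` (both in
#' the sensors and in the region responses); `snr = Inf` gives noiseless
#' data.  Trials are assigned to sessions in contiguous, near-equal blocks,
#' mirroring session-blocked acquisition.
#'
#' @param n_trials,n_sensors Dimensions of the sensor array.
#' @param time_ms Numeric vector of timepoints in ms; must include negative
#'   (pre-stimulus) times, which define the default baseline window.
#' @param n_sessions Number of recording sessions (contiguous trial blocks).
#' @param roi_onsets Named numeric vector or list: onset latency in ms per
#'   region; each must lie within `time_ms`.
#' @param snr Positive signal-to-noise ratio.
#' @param seed Integer seed.
#'
#' @return A `fusion_data` object (see [fusion_dataset()]) with extra fields
#'   `roi_features` (the latent ground-truth features), `roi_onsets`, `snr`
#'   and `seed`.
#' @examples
#' fd <- simulate_fusion_data(60, 8, time_ms = seq(-100, 300, by = 20),
#'                            n_sessions = 3,
#'                            roi_onsets = c(V1 = 100, FFA = 180),
#'                            snr = 2, seed = 1)
#' @export
simulate_fusion_data <- function(n_trials, n_sensors, time_ms, n_sessions,
                                 roi_onsets, snr = 1, seed = 1) {
  n_trials <- assert_count(n_trials, "n_trials", min = 4L)
  n_sensors <- assert_count(n_sensors, "n_sensors")
  n_sessions <- assert_count(n_sessions, "n_sessions")
  if (!(is.numeric(snr) && length(snr) == 1 && snr > 0)) {
    abort("`snr` must be a positive number (Inf allowed).")
  }
  roi_onsets <- unlist(roi_onsets)
  if (is.null(names(roi_onsets)) || any(!nzchar(names(roi_onsets)))) {
    abort("`roi_onsets` must be named by region.")
  }
  if (any(roi_onsets < min(time_ms)) || any(roi_onsets > max(time_ms))) {
    abort("Every onset must lie within `time_ms`.")
  }
  if (min(time_ms) >= 0) {
    abort("`time_ms` must include pre-stimulus (negative) timepoints.")
  }
  n_tp <- length(time_ms)
  n_rois <- length(roi_onsets)
  noise_sd <- 1 / snr

  sim <- with_seed(seed, {
    feats <- matrix(rnorm(n_trials * n_rois), n_trials, n_rois,
                    dimnames = list(NULL, names(roi_onsets)))
    loadings <- matrix(rnorm(n_sensors * n_rois), n_sensors, n_rois)
    sens <- array(rnorm(n_trials * n_sensors * n_tp, sd = noise_sd),
                  dim = c(n_trials, n_sensors, n_tp))
    for (r in seq_len(n_rois)) {
      active <- which(time_ms >= roi_onsets[r])
      signal <- feats[, r] %o% loadings[, r]      # trials x sensors
      for (t in active) sens[, , t] <- sens[, , t] + signal
    }
    rois <- lapply(seq_len(n_rois), function(r) {
      feats[, r] + rnorm(n_trials, sd = noise_sd)
    })
    names(rois) <- names(roi_onsets)
    list(sens = sens, rois = rois, feats = feats)
  })

  # contiguous near-equal session blocks
  sizes <- diff(round(seq(0, n_trials, length.out = n_sessions + 1)))
  sessions <- rep(seq_len(n_sessions), times = sizes)

  out <- fusion_dataset(sim$sens, sim$rois, sessions, time_ms,
                        baseline_window = c(min(time_ms), 0))
  out$roi_features <- sim$feats
  out$roi_onsets <- roi_onsets
  out$snr <- snr
  out$seed <- as.integer(seed)
  out
}
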