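#' Fit an exponential-decay model of dimensionality versus dataset size
#'
#' Embedding dimensionality grows with dataset size but saturates.  This
#' fits `dims = a + b * exp(-c * size)` by nonlinear least squares with
#' `c > 0`, so `a` is the asymptotic dimensionality as the dataset grows
#' without bound (for a saturating increase, `b < 0`).  Fitting uses
#' Levenberg-Marquardt with several starting points and returns the
#' converged fit with the lowest residual sum of squares.
#'
#' @param sizes Strictly increasing trial counts (at least 4 distinct).
#' @param mean_dims Mean retained dimensionality at each size.
#' @return An object of class `exp_decay_fit`: `a`, `b`, `c`,
#'   `residual_ss`, plus the input data for plotting.
#' @examples
#' sizes <- seq(1e5, 1.4e6, by = 1e5)
#' dims <- 67.5 - 35 * exp(-1.2e-6 * sizes)
#' fit_exp_decay(sizes, dims)
#' @export
fit_exp_decay <- function(sizes, mean_dims) {
  stopifnot(is.numeric(sizes), is.numeric(mean_dims),
            length(sizes) == length(mean_dims))
  if (length(unique(sizes)) < 4) abort("Need at least 4 distinct sizes.")
  if (any(!is.finite(sizes)) || any(!is.finite(mean_dims))) {
    abort("`sizes` and `mean_dims` must be finite.")
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    abort("`sizes` must be strictly increasing.")
  }
  y <- mean_dims
  if (stats::sd(y) < 1e-10) {
    abort("`mean_dims` is (near-)constant: b is unidentifiable.")
  }

  x_range <- diff(range(sizes))
  y_first <- y[1]; y_last <- y[length(y)]
  starts <- expand.grid(
    a0 = c(y_last, y_last + (y_last - y_first) / 4),
    c0 = c(1 / x_range, 5 / x_range)
  )
  df <- data.frame(x = sizes, y = y)

  fits <- lapply(seq_len(nrow(starts)), function(i) {
    a0 <- starts$a0[i]; c0 <- starts$c0[i]; b0 <- y_first - a0
    tryCatch(
      minpack.lm::nlsLM(
        y ~ a + b * exp(-cc * x), data = df,
        start = list(a = a0, b = b0, cc = c0),
        lower = c(a = -Inf, b = -Inf, cc = 1e-300),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                             ptol = 1e-14)
      ),
      error = function(e) NULL
    )
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) {
    abort(sprintf(
      "Exponential-decay fit failed to converge from all %d starts (n = %d).",
      nrow(starts), length(sizes)))
  }
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- coef(best)
  structure(
    list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["cc"]),
         residual_ss = min(rss), sizes = sizes, mean_dims = y),
    class = "exp_decay_fit"
  )
}

#' @export
print.exp_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<exp_decay_fit> dims = %.4g + %.4g * exp(-%.4g * size); asymptote %.4g\n",
    x$a, x$b, x$c, x$a))
  invisible(x)
}

#' Predict dimensionality at a dataset size
#'
#' Evaluates `a + b * exp(-c * size)`; `size = 0` gives `a + b` and
#' `size = Inf` gives the asymptote `a`.
#'
#' @param fit An `exp_decay_fit`.
#' @param size Trial count(s), non-negative.
#' @return Predicted dimensionality (vectorized over `size`).
#' @export
predict_dim <- function(fit, size) {
  stopifnot(inherits(fit, "exp_decay_fit"), all(size >= 0))
  fit$a + fit$b * exp(-fit$c * size)
}

#' @export
predict.exp_decay_fit <- function(object, newdata = NULL, ...) {
  size <- if (is.null(newdata)) object$sizes else newdata$size %||% newdata
  predict_dim(object, size)
}

#' Bootstrap the asymptotic dimensionality
#'
#' Replicate embeddings at each dataset size carry sampling noise.  Each
#' bootstrap draw resamples the replicate dimensionalities (with
#' replacement, per size), refits the exponential decay to the resampled
#' means, and records the asymptote `a`; the 95% confidence interval is the
#' (2.5, 97.5) percentile interval of the bootstrap asymptotes.  Draws
#' whose refit fails are skipped (an error is raised if more than 10%
#' fail).
#'
#' @param curve Data frame with a `size` column and one column per
#'   replicate dimensionality (at least 2 replicates).
#' @param n_boot Number of bootstrap draws (default 1000, minimum 100).
#' @param seed Integer seed.
#' @return A list of class `asymptote_boot`: `a_hat` (asymptote of the fit
#'   to the observed means), `ci_low`, `ci_high`, `boot_samples`,
#'   `n_failed`, and `fit` (the observed-means `exp_decay_fit`).
#' @examples
#' curve <- simulate_dim_curve(seed = 1)
#' bootstrap_asymptote(curve, n_boot = 200, seed = 2)
#' @export
bootstrap_asymptote <- function(curve, n_boot = 1000L, seed = 1L) {
  assert_count(n_boot, "n_boot", min = 100L)
  stopifnot(is.data.frame(curve), "size" %in% names(curve))
  reps <- as.matrix(curve[setdiff(names(curve), "size")])
  if (ncol(reps) < 2) abort("Need at least 2 replicates per size.")
  sizes <- curve$size
  obs_fit <- fit_exp_decay(sizes, rowMeans(reps))

  # each draw refits warm-started from the observed fit (bootstrap samples
  # are small perturbations of the observed curve); the full multi-start
  # search is the fallback when the warm start fails to converge
  warm <- list(a = obs_fit$a, b = obs_fit$b, cc = obs_fit$c)
  refit_a <- function(means) {
    f <- tryCatch(
      coef(minpack.lm::nlsLM(
        y ~ a + b * exp(-cc * x), data = data.frame(x = sizes, y = means),
        start = warm, lower = c(a = -Inf, b = -Inf, cc = 1e-300),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ))[["a"]],
      error = function(e) NULL
    )
    if (is.null(f)) {
      f <- tryCatch(fit_exp_decay(sizes, means)$a, error = function(e) NULL)
    }
    f %||% NA_real_
  }
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      refit_a(apply(reps, 1, function(r) mean(sample(r, replace = TRUE))))
    }, numeric(1))
  })
  n_failed <- sum(is.na(boot))
  if (n_failed > 0.1 * n_boot) {
    abort(sprintf("%d of %d bootstrap fits failed (> 10%%).",
                  n_failed, n_boot))
  }
  ci <- quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(
    list(a_hat = obs_fit$a, ci_low = ci[1], ci_high = ci[2],
         boot_samples = boot[!is.na(boot)], n_failed = n_failed,
         fit = obs_fit),
    class = "asymptote_boot"
  )
}

#' @export
print.asymptote_boot <- function(x, ...) {
  cat(sprintf(
    "<asymptote_boot> asymptote %.2f dims (95%% CI %.2f-%.2f; %d draws, %d failed)\n",
    x$a_hat, x$ci_low, x$ci_high, length(x$boot_samples), x$n_failed))
  invisible(x)
}

#' Simulate a dimensionality-versus-size curve with replicate noise
#'
#' Generates replicate dimensionality estimates around a known
#' exponential-decay curve for testing the extrapolation machinery.  The
#' defaults mirror the design used in large-scale triplet studies:
#' 14 dataset sizes in steps of 100,000 trials up to 1.4 million, 4
#' replicate embeddings per size, and a saturating curve with asymptote
#' 67.5.
#'
#' @param sizes Trial counts.
#' @param a,b,cc True curve parameters (`dims = a + b * exp(-cc * size)`).
#' @param n_replicates Replicate embeddings per size.
#' @param noise_sd Standard deviation of replicate noise, in dimensions.
#' @param seed Integer seed.
#' @return A tibble with `size` and `rep1` ... `repK` columns.
#' @export
simulate_dim_curve <- function(sizes = seq(1e5, 1.4e6, by = 1e5),
                               a = 67.5, b = -35, cc = 1.2e-6,
                               n_replicates = 4L, noise_sd = 2,
                               seed = 1L) {
  assert_count(n_replicates, "n_replicates", min = 2L)
  assert_positive(noise_sd, "noise_sd", strict = FALSE)
  truth <- a + b * exp(-cc * sizes)
  reps <- with_seed(seed, {
    matrix(rnorm(length(sizes) * n_replicates, mean = truth, sd = noise_sd),
           nrow = length(sizes))
  })
  colnames(reps) <- sprintf("rep%d", seq_len(n_replicates))
  dplyr::bind_cols(tibble::tibble(size = sizes), tibble::as_tibble(reps))
}
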