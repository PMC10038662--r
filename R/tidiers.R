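#' Tidy and glance methods for fitted objects
#'
#' Broom-style accessors: `tidy()` returns one row per estimated component,
#' `glance()` a one-row model summary.
#'
#' @param x A fitted object from this package.
#' @param ... Unused.
#' @return A tibble.
#' @name oddoneout-tidiers
NULL

#' @export
#' @importFrom generics tidy glance
generics::tidy

#' @export
generics::glance

#' @rdname oddoneout-tidiers
#' @method tidy spose_embedding
#' @export
tidy.spose_embedding <- function(x, ...) {
  w <- x$weights
  ids <- rownames(w) %||% sprintf("obj%03d", seq_len(nrow(w)))
  tibble::tibble(
    object = rep(ids, times = max(ncol(w), 0)),
    dimension = rep(seq_len(ncol(w)), each = nrow(w)),
    weight = as.vector(w)
  )
}

#' @rdname oddoneout-tidiers
#' @method glance spose_embedding
#' @export
glance.spose_embedding <- function(x, ...) {
  tibble::tibble(
    n_objects = nrow(x$weights), n_dims = ncol(x$weights),
    lambda = x$config$lambda, n_epochs = x$n_epochs,
    final_train_loss = tail(x$train_loss_history, 1) %||% NA_real_,
    final_val_ce = if (length(x$val_loss_history)) {
      tail(x$val_loss_history, 1)
    } else {
      NA_real_
    },
    seed = x$config$seed
  )
}

#' @rdname oddoneout-tidiers
#' @method tidy exp_decay_fit
#' @export
tidy.exp_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname oddoneout-tidiers
#' @method glance exp_decay_fit
#' @export
glance.exp_decay_fit <- function(x, ...) {
  tibble::tibble(asymptote = x$a, residual_ss = x$residual_ss,
                 n_sizes = length(x$sizes))
}

#' @rdname oddoneout-tidiers
#' @method tidy fusion_corr
#' @export
tidy.fusion_corr <- function(x, ...) {
  tibble::tibble(time_ms = x$time_ms, r_mean = x$r_mean,
                 roi = x$roi)
}

#' @rdname oddoneout-tidiers
#' @method tidy asymptote_boot
#' @export
tidy.asymptote_boot <- function(x, ...) {
  tibble::tibble(term = "asymptote", estimate = x$a_hat,
                 ci_low = x$ci_low, ci_high = x$ci_high)
}

#' Plot methods
#'
#' `autoplot()` methods return ggplot2 objects: the dimensionality curve
#' with its fitted saturation function for `exp_decay_fit`, the per-object
#' weight profile for `spose_embedding`, and the correlation time course
#' (optionally with a bootstrap band) for `fusion_corr`.
#'
#' @param object A fitted object.
#' @param ... Unused.
#' @return A ggplot.
#' @name oddoneout-autoplot
NULL

#' @rdname oddoneout-autoplot
#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_tile labs geom_hline
#' @method autoplot exp_decay_fit
#' @export
autoplot.exp_decay_fit <- function(object, ...) {
  pts <- tibble::tibble(size = object$sizes, dims = object$mean_dims)
  grid <- tibble::tibble(size = seq(0, max(object$sizes) * 3,
                                    length.out = 200))
  grid$dims <- predict_dim(object, grid$size)
  ggplot(pts, aes(x = .data$size, y = .data$dims)) +
    geom_line(data = grid, color = "steelblue") +
    geom_hline(yintercept = object$a, linetype = "dashed") +
    geom_point() +
    labs(x = "dataset size (trials)", y = "embedding dimensionality",
         title = sprintf("Saturation at %.1f dimensions", object$a))
}

#' @rdname oddoneout-autoplot
#' @method autoplot spose_embedding
#' @export
autoplot.spose_embedding <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = .data$dimension, y = .data$object, fill = .data$weight)) +
    geom_tile() +
    labs(x = "dimension (sorted by weight sum)", y = NULL, fill = "weight")
}

#' @rdname oddoneout-autoplot
#' @param band Optional tibble from [bootstrap_fusion_ci()].
#' @method autoplot fusion_corr
#' @export
autoplot.fusion_corr <- function(object, band = NULL, ...) {
  df <- tidy(object)
  p <- ggplot(df, aes(x = .data$time_ms, y = .data$r_mean))
  if (!is.null(band)) {
    p <- p + geom_ribbon(data = band,
                         aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         alpha = 0.25)
  }
  p + geom_line() +
    geom_hline(yintercept = 0, linetype = "dotted") +
    labs(x = "time (ms)", y = "Pearson r (predicted vs true)",
         title = sprintf("Region %s", object$roi))
}
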