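#' Training configuration for SPoSE embeddings
#'
#' Bundles the hyperparameters of the sparse positive similarity embedding
#' fit.  Defaults follow common practice for this model family: 90 random
#' initial dimensions drawn uniformly on `[0, 1)`, minibatches of 100
#' triplets, Adam with its default parameters (step 0.001, decay rates
#' 0.9/0.999, epsilon 1e-8), and a pruning cutoff of 0.1 below which a
#' dimension counts as dead.  The regularization weight `lambda` multiplies
#' an L1 penalty normalized by the number of objects; `0.00385` is a
#' reasonable order of magnitude for large datasets but should be selected
#' by cross-validation ([select_lambda()]) for new data.
#'
#' @param init_dims Number of random initial dimensions.
#' @param lambda Non-negative L1 regularization weight.
#' @param batch_size Minibatch size in triplets.
#' @param learning_rate Adam step size.
#' @param max_epochs Maximum number of passes over the training trials.
#' @param prune_threshold A dimension whose weights are all below this value
#'   after training is removed.
#' @param seed Integer seed controlling initialization, the validation
#'   split, and minibatch shuffling.
#' @param val_fraction Fraction of trials held out (within the training
#'   data) for early stopping; 0 disables early stopping.
#' @param patience Number of epochs without validation improvement before
#'   stopping.  The default (20) is deliberately generous: the L1 penalty
#'   keeps shrinking redundant dimensions after the validation
#'   cross-entropy has plateaued, so stopping too eagerly leaves
#'   near-duplicate dimensions above the pruning threshold.
#' @param val_tol Minimum decrease in validation cross-entropy that counts
#'   as an improvement.
#'
#' @return A list of class `spose_config`.
#' @export
spose_config <- function(init_dims = 90L, lambda = 0.00385, batch_size = 100L,
                         learning_rate = 0.001, max_epochs = 500L,
                         prune_threshold = 0.1, seed = 1L,
                         val_fraction = 0.1, patience = 20L,
                         val_tol = 1e-4) {
  assert_count(init_dims, "init_dims")
  assert_positive(lambda, "lambda", strict = FALSE)
  assert_count(batch_size, "batch_size")
  assert_positive(learning_rate, "learning_rate")
  assert_count(max_epochs, "max_epochs")
  assert_positive(prune_threshold, "prune_threshold")
  assert_fraction(val_fraction, "val_fraction", open_hi = TRUE)
  structure(
    list(init_dims = as.integer(init_dims), lambda = lambda,
         batch_size = as.integer(batch_size), learning_rate = learning_rate,
         max_epochs = as.integer(max_epochs),
         prune_threshold = prune_threshold, seed = as.integer(seed),
         val_fraction = val_fraction, patience = as.integer(patience),
         val_tol = val_tol),
    class = "spose_config"
  )
}

# Remove dimensions whose weights are all below the threshold, then sort
# the survivors by descending column sum.  Idempotent.
prune_and_sort <- function(w, prune_threshold) {
  keep <- apply(w, 2, function(col) any(col >= prune_threshold))
  w <- w[, keep, drop = FALSE]
  ord <- order(colSums(w), decreasing = TRUE)
  list(weights = w[, ord, drop = FALSE], kept = which(keep)[ord])
}

#' Fit a sparse positive similarity embedding from triplet choices
#'
#' Estimates non-negative object vectors whose pairwise dot products, passed
#' through a softmax over the three pairs of each triplet, model the
#' observed odd-one-out choices.  The objective is the cross-entropy of the
#' observed choices plus an L1 sparsity penalty (see [spose_loss()]),
#' minimized by minibatch Adam with the weights projected onto the
#' non-negative orthant after every update.  After optimization, dimensions
#' whose weights are all below `prune_threshold` are removed, and the
#' remaining dimensions are sorted in descending order of their weight sums.
#'
#' @param data Triplet table with columns `a`, `b`, `c`, `choice` (1-based
#'   object indices), e.g. from [simulate_choices()] or [read_triplets()].
#' @param config A [spose_config()].
#' @param n_objects Number of objects; defaults to the table's `n_objects`
#'   attribute or the largest index seen.
#'
#' @return An object of class `spose_embedding` with fields `weights`
#'   (objects x retained dimensions, non-negative), `dim_order` (original
#'   column indices of the retained dimensions), `config`,
#'   `train_loss_history`, `val_loss_history` and `n_epochs`.
#' @seealso [select_lambda()], [evaluate_accuracy()],
#'   [select_most_reproducible()]
#' @export
train_spose <- function(data, config = spose_config(), n_objects = NULL) {
  stopifnot(inherits(config, "spose_config"))
  data <- as_triplet_df(data, n_objects = n_objects)
  n_obj <- attr(data, "n_objects")
  if (n_obj < 3) abort("Need at least 3 objects.")
  seen <- tabulate(c(data$a, data$b, data$c), nbins = n_obj)
  if (any(seen == 0)) {
    warn(sprintf("%d object(s) never appear in the training trials.",
                 sum(seen == 0)))
  }

  fit <- with_seed(config$seed, {
    w0 <- matrix(runif(n_obj * config$init_dims), n_obj, config$init_dims)
    n <- nrow(data)
    n_val <- floor(config$val_fraction * n)
    val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
    tr <- if (n_val > 0) data[-val_idx, ] else data
    va <- data[val_idx, ]
    shuffle_seed <- sample.int(.Machine$integer.max, 1)
    cpp_spose_train(
      w0,
      tr$a - 1L, tr$b - 1L, tr$c - 1L, tr$choice - 1L,
      va$a - 1L, va$b - 1L, va$c - 1L, va$choice - 1L,
      lambda = config$lambda, lr = config$learning_rate,
      beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
      batch_size = config$batch_size, max_epochs = config$max_epochs,
      patience = config$patience, val_tol = config$val_tol,
      shuffle_seed = shuffle_seed
    )
  })

  ps <- prune_and_sort(fit$weights, config$prune_threshold)
  if (ncol(ps$weights) == 0) {
    warn("All dimensions were pruned; returning a 0-dimensional embedding.")
  }
  structure(
    list(weights = ps$weights, dim_order = ps$kept, config = config,
         train_loss_history = fit$train_loss,
         val_loss_history = fit$val_loss, n_epochs = fit$epochs_run),
    class = "spose_embedding"
  )
}

#' @export
print.spose_embedding <- function(x, ...) {
  cat(sprintf(
    "<spose_embedding> %d objects x %d dims (lambda %.4g, %d epochs, seed %d)\n",
    nrow(x$weights), ncol(x$weights), x$config$lambda, x$n_epochs,
    x$config$seed))
  invisible(x)
}

#' Select the L1 regularization weight by cross-validation
#'
#' Splits the trials into `n_folds` folds, trains on each complement and
#' scores the held-out cross-entropy (without the penalty term), and returns
#' the grid value with the lowest mean held-out cross-entropy.  Ties go to
#' the smaller lambda (more sparsity for equal fit).
#'
#' With `rule = "1se"` the largest (sparsest) grid value whose mean
#' cross-entropy lies within one standard error of the minimum is returned
#' instead -- the usual one-standard-error convention for sparse model
#' selection, useful when the goal is recovering a parsimonious
#' dimensionality rather than squeezing out the last bit of predictive
#' fit.
#'
#' @param data Triplet table with columns `a`, `b`, `c`, `choice`.
#' @param grid Non-negative candidate lambdas.
#' @param n_folds Number of cross-validation folds, at least 2.
#' @param config Base [spose_config()]; its `lambda` is overridden by each
#'   grid value and its `seed` controls the fold assignment.
#' @param rule `"min"` (default) for the cross-entropy minimizer, `"1se"`
#'   for the one-standard-error rule.
#'
#' @return A list of class `spose_cv`: `lambda` (the selected value),
#'   `losses` (tibble with columns `lambda`, `fold`, `ce`), and
#'   `mean_ce` (tibble with per-lambda means).
#' @export
select_lambda <- function(data, grid, n_folds = 5L, config = spose_config(),
                          rule = c("min", "1se")) {
  rule <- match.arg(rule)
  if (length(grid) == 0) abort("`grid` must be non-empty.")
  if (any(grid < 0)) abort("`grid` values must be non-negative.")
  assert_count(n_folds, "n_folds", min = 2L)
  data <- as_triplet_df(data)
  n <- nrow(data)
  folds <- with_seed(config$seed, sample(rep_len(seq_len(n_folds), n)))

  losses <- purrr::map(sort(unique(grid)), function(lam) {
    cfg <- config
    cfg$lambda <- lam
    purrr::map(seq_len(n_folds), function(k) {
      fit <- train_spose(data[folds != k, ], cfg,
                         n_objects = attr(data, "n_objects"))
      held <- data[folds == k, ]
      ce <- cpp_spose_ce(pad_weights(fit, attr(data, "n_objects")),
                         held$a - 1L, held$b - 1L, held$c - 1L,
                         held$choice - 1L)
      tibble::tibble(lambda = lam, fold = k, ce = ce)
    }) %>% dplyr::bind_rows()
  }) %>% dplyr::bind_rows()

  mean_ce <- losses %>%
    group_by(.data$lambda) %>%
    summarise(mean_ce = mean(.data$ce), .groups = "drop") %>%
    arrange(.data$lambda)
  best <- mean_ce$lambda[which.min(mean_ce$mean_ce)]
  if (rule == "1se") {
    se_best <- losses %>%
      filter(.data$lambda == best) %>%
      summarise(se = stats::sd(.data$ce) / sqrt(n())) %>%
      dplyr::pull(.data$se)
    thr <- min(mean_ce$mean_ce) + se_best
    best <- max(mean_ce$lambda[mean_ce$mean_ce <= thr])
  }
  structure(list(lambda = best, losses = losses, mean_ce = mean_ce,
                 rule = rule),
            class = "spose_cv")
}

# 0-dimensional embeddings still need a well-defined weight matrix
pad_weights <- function(embedding, n_objects) {
  w <- embedding_weights(embedding)
  if (ncol(w) == 0) matrix(0, n_objects, 1) else w
}

#' @export
print.spose_cv <- function(x, ...) {
  cat(sprintf("<spose_cv> selected lambda = %.5g\n", x$lambda))
  print(x$mean_ce)
  invisible(x)
}

#' Odd-one-out prediction accuracy of an embedding
#'
#' For each test triplet the predicted odd-one-out is the object excluded
#' from the maximum-probability pair (equivalently, the argmax of the three
#' odd-one-out probabilities); ties break toward the lowest object index.
#' Chance level is 33.3%.
#'
#' @param embedding A `spose_embedding`, `gt_embedding` or weight matrix.
#' @param test Triplet table with observed choices.
#' @return Percent of correctly predicted choices (0-100).
#' @export
evaluate_accuracy <- function(embedding, test) {
  w <- embedding_weights(embedding)
  test <- as_triplet_df(test, n_objects = nrow(w))
  if (nrow(test) == 0) abort("`test` must contain at least one trial.")
  pred <- simulate_choices(w, test[, c("a", "b", "c")], deterministic = TRUE)
  100 * mean(pred$choice == test$choice)
}

#' Bayes-optimal accuracy of the generative softmax model
#'
#' The best achievable odd-one-out prediction accuracy on choices sampled
#' from a known embedding: the expectation, over trials, of the largest of
#' the three generative choice probabilities.  Fitted models evaluated with
#' [evaluate_accuracy()] on data simulated from `gt` approach this value
#' from below.
#'
#' @param gt The generating embedding.
#' @param triples Trial triples the test set was built from.
#' @return Percent (0-100).
#' @export
bayes_accuracy <- function(gt, triples) {
  w <- embedding_weights(gt)
  p <- triplet_probabilities(w, triples)
  100 * mean(apply(p, 1, max))
}
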