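#' Softmax choice probabilities for triplet odd-one-out trials
#'
#' For a triple of objects `{a, b, c}` with embedding vectors `x_a`, `x_b`,
#' `x_c`, the model computes the three pairwise dot products and passes them
#' through a softmax (no temperature parameter).  The probability assigned
#' to a pair is the probability that this pair is judged most similar --
#' equivalently, that the remaining object is chosen as the odd-one-out:
#' `p_ab = exp(x_a . x_b) / (exp(x_a . x_b) + exp(x_a . x_c) + exp(x_b . x_c))`
#' is the probability that `c` is the odd-one-out.
#'
#' @param weights Non-negative embedding matrix (objects x dimensions), or a
#'   `gt_embedding` / `spose_embedding`.
#' @param triples Data frame with columns `a`, `b`, `c` of 1-based object
#'   indices, or a length-3 vector for a single triple.
#'
#' @return A numeric matrix with one row per trial and columns `p_ab`,
#'   `p_ac`, `p_bc`; each row sums to 1.  `p_ab` is the probability that `c`
#'   is the odd-one-out, `p_ac` that `b` is, `p_bc` that `a` is.
#' @examples
#' w <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2)
#' triplet_probabilities(w, c(1, 2, 3))
#' @export
triplet_probabilities <- function(weights, triples) {
  w <- embedding_weights(weights)
  if (any(!is.finite(w))) abort("Embedding weights must be finite.")
  if (is.numeric(triples) && length(triples) == 3) {
    triples <- tibble::tibble(a = triples[1], b = triples[2], c = triples[3])
  }
  triples <- as_triplet_df(triples, n_objects = nrow(w), need_choice = FALSE)
  s_ab <- rowSums(w[triples$a, , drop = FALSE] * w[triples$b, , drop = FALSE])
  s_ac <- rowSums(w[triples$a, , drop = FALSE] * w[triples$c, , drop = FALSE])
  s_bc <- rowSums(w[triples$b, , drop = FALSE] * w[triples$c, , drop = FALSE])
  m <- pmax(s_ab, s_ac, s_bc)
  e_ab <- exp(s_ab - m); e_ac <- exp(s_ac - m); e_bc <- exp(s_bc - m)
  z <- e_ab + e_ac + e_bc
  cbind(p_ab = e_ab / z, p_ac = e_ac / z, p_bc = e_bc / z)
}

# Probability of each trial's *observed* choice under the model.
observed_choice_prob <- function(w, trials) {
  p <- triplet_probabilities(w, trials)
  # choice == c -> surviving pair ab, etc.
  ifelse(trials$choice == trials$c, p[, "p_ab"],
         ifelse(trials$choice == trials$b, p[, "p_ac"], p[, "p_bc"]))
}

#' SPoSE loss: cross-entropy plus L1 sparsity penalty
#'
#' The training objective is the mean negative log probability of the
#' observed odd-one-out choices under the softmax model, plus a
#' sparsity-inducing L1 penalty `lambda * sum(|w|) / n_objects`.  The
#' per-object normalization of the penalty keeps the meaning of `lambda`
#' stable across object-set sizes.
#'
#' @param weights Embedding matrix (objects x dimensions).
#' @param batch Triplet table with columns `a`, `b`, `c`, `choice`.
#' @param lambda Non-negative regularization weight.
#'
#' @return The scalar loss.
#' @examples
#' w <- matrix(0, 5, 2)
#' trips <- tibble::tibble(a = 1, b = 2, c = 3, choice = 3)
#' spose_loss(w, trips, lambda = 0)  # -log(1/3)
#' @export
spose_loss <- function(weights, batch, lambda = 0) {
  w <- embedding_weights(weights)
  assert_positive(lambda, "lambda", strict = FALSE)
  batch <- as_triplet_df(batch, n_objects = nrow(w))
  if (nrow(batch) == 0) abort("`batch` must contain at least one trial.")
  ce <- -mean(log(observed_choice_prob(w, batch)))
  ce + lambda * sum(abs(w)) / nrow(w)
}

#' Analytic gradient of the SPoSE loss
#'
#' Reference implementation of the gradient of [spose_loss()] with respect
#' to the weight matrix.  For the L1 term the subgradient `lambda/n` is used
#' at strictly positive weights and 0 at exactly-zero weights (weights are
#' kept non-negative by projection during training, so zero weights sit at
#' the boundary).
#'
#' @inheritParams spose_loss
#' @return A gradient matrix of the same shape as `weights`.
#' @export
spose_gradient <- function(weights, batch, lambda = 0) {
  w <- embedding_weights(weights)
  assert_positive(lambda, "lambda", strict = FALSE)
  batch <- as_triplet_df(batch, n_objects = nrow(w))
  p <- triplet_probabilities(w, batch)
  n_trials <- nrow(batch)
  # residuals p - y for the three pairs (y indicates the surviving pair)
  g_ab <- p[, "p_ab"] - (batch$choice == batch$c)
  g_ac <- p[, "p_ac"] - (batch$choice == batch$b)
  g_bc <- p[, "p_bc"] - (batch$choice == batch$a)

  wa <- w[batch$a, , drop = FALSE]
  wb <- w[batch$b, , drop = FALSE]
  wc <- w[batch$c, , drop = FALSE]
  idx <- c(batch$a, batch$b, batch$c)
  contrib <- rbind(g_ab * wb + g_ac * wc,   # d/dx_a
                   g_ab * wa + g_bc * wc,   # d/dx_b
                   g_ac * wa + g_bc * wb)   # d/dx_c
  grad <- rowsum(contrib, group = idx, reorder = FALSE) / n_trials
  out <- matrix(0, nrow(w), ncol(w))
  out[as.integer(rownames(grad)), ] <- grad
  out + (lambda / nrow(w)) * (w > 0)
}
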