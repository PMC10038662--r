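#' Generate a sparse non-negative ground-truth embedding
#'
#' Draws an objects-by-dimensions weight matrix with the structure that
#' sparse positive similarity embeddings (SPoSE) recover from odd-one-out
#' judgments: entries are non-negative, most are exactly zero, and the
#' non-zero weights follow a right-skewed distribution.  Each entry is
#' independently set to zero with probability `sparsity` and otherwise drawn
#' from an exponential distribution with mean `scale`.
#'
#' @param n_objects Number of objects (rows), at least 3.
#' @param n_dims Number of latent dimensions (columns), at least 1.
#' @param sparsity Probability that an entry is exactly zero, in `[0, 1)`.
#' @param scale Mean of the exponential distribution of non-zero weights.
#' @param seed Integer seed; the same seed and parameters give bit-identical
#'   weights.
#' @param object_ids Optional character labels for the objects; defaults to
#'   `"obj001"`, `"obj002"`, ...
#'
#' @return An object of class `gt_embedding`: a list with `weights`
#'   (non-negative matrix, objects x dimensions, rownames = object ids),
#'   `object_ids`, `sparsity`, `scale` and `seed`.
#' @examples
#' gt <- make_ground_truth_embedding(20, 4, sparsity = 0.5, seed = 1)
#' mean(gt$weights == 0)
#' @export
make_ground_truth_embedding <- function(n_objects, n_dims, sparsity = 0.5,
                                        scale = 1, seed = 1,
                                        object_ids = NULL) {
  n_objects <- assert_count(n_objects, "n_objects", min = 3L)
  n_dims <- assert_count(n_dims, "n_dims", min = 1L)
  assert_fraction(sparsity, "sparsity", open_hi = TRUE)
  assert_positive(scale, "scale")
  if (is.null(object_ids)) {
    object_ids <- sprintf("obj%03d", seq_len(n_objects))
  }
  stopifnot(length(object_ids) == n_objects)

  w <- with_seed(seed, {
    zero <- matrix(runif(n_objects * n_dims) < sparsity, n_objects, n_dims)
    vals <- matrix(rexp(n_objects * n_dims, rate = 1 / scale),
                   n_objects, n_dims)
    vals[zero] <- 0
    vals
  })
  rownames(w) <- object_ids
  structure(
    list(weights = w, object_ids = object_ids, sparsity = sparsity,
         scale = scale, seed = as.integer(seed)),
    class = "gt_embedding"
  )
}

#' @export
print.gt_embedding <- function(x, ...) {
  cat(sprintf(
    "<gt_embedding> %d objects x %d dims, %.1f%% zeros (target %.1f%%), seed %d\n",
    nrow(x$weights), ncol(x$weights), 100 * mean(x$weights == 0),
    100 * x$sparsity, x$seed))
  invisible(x)
}
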