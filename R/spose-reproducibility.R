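#' Per-dimension reproducibility of an embedding across restarts
#'
#' Because the optimization is stochastic, independently restarted fits
#' recover similar but not identical dimensions.  For each dimension of the
#' target embedding, this finds the most similar dimension (largest Pearson
#' correlation over objects, matching with replacement) in every other
#' embedding, Fisher-z transforms those best-match correlations, averages
#' the z values, and back-transforms to r.  Correlations are clipped to
#' +/- (1 - 1e-7) before the z transform so exact matches stay finite.
#'
#' @param target A `spose_embedding` or weight matrix.
#' @param others Non-empty list of embeddings over the same objects.
#' @return Numeric vector of reproducibility scores, one per target
#'   dimension.
#' @export
dimension_reproducibility <- function(target, others) {
  tw <- embedding_weights(target)
  if (!length(others)) abort("`others` must be a non-empty list.")
  ows <- lapply(others, embedding_weights)
  if (any(vapply(ows, nrow, integer(1)) != nrow(tw))) {
    abort("All embeddings must share the same objects.")
  }
  if (ncol(tw) == 0) return(numeric(0))
  clip <- 1 - 1e-7

  zero_var_seen <- FALSE
  best_r <- function(col, other) {
    if (var(col) == 0 || ncol(other) == 0) {
      zero_var_seen <<- TRUE
      return(0)
    }
    sds <- apply(other, 2, var)
    if (all(sds == 0)) {
      zero_var_seen <<- TRUE
      return(0)
    }
    r <- suppressWarnings(cor(col, other))
    max(r[, sds > 0], na.rm = TRUE)
  }

  scores <- vapply(seq_len(ncol(tw)), function(d) {
    rs <- vapply(ows, function(o) best_r(tw[, d], o), numeric(1))
    rs <- pmin(pmax(rs, -clip), clip)
    tanh(mean(atanh(rs)))
  }, numeric(1))
  if (zero_var_seen) {
    warn("Zero-variance dimension(s): those comparisons contribute r = 0.")
  }
  scores
}

#' Pick the most reproducible embedding among random restarts
#'
#' Scores every embedding by the mean of its per-dimension reproducibility
#' against all the others (see [dimension_reproducibility()]) and returns
#' the one with the highest mean; ties go to the lowest index.
#'
#' @param embeddings List of at least two embeddings over the same objects.
#' @return A list of class `reproducibility_report`: `selected_index`,
#'   `embedding` (the winner), `per_embedding_mean`, and `per_dim_scores`
#'   (list of per-dimension score vectors).
#' @seealso [train_spose_restarts()]
#' @export
select_most_reproducible <- function(embeddings) {
  if (length(embeddings) < 2) abort("Need at least two embeddings.")
  per_dim <- lapply(seq_along(embeddings), function(i) {
    dimension_reproducibility(embeddings[[i]], embeddings[-i])
  })
  means <- vapply(per_dim, function(s) if (length(s)) mean(s) else -Inf,
                  numeric(1))
  sel <- which.max(means)  # which.max already breaks ties toward lowest index
  structure(
    list(selected_index = sel, embedding = embeddings[[sel]],
         per_embedding_mean = means, per_dim_scores = per_dim),
    class = "reproducibility_report"
  )
}

#' @export
print.reproducibility_report <- function(x, ...) {
  cat(sprintf(
    "<reproducibility_report> %d embeddings; selected #%d (mean r = %.3f)\n",
    length(x$per_embedding_mean), x$selected_index,
    x$per_embedding_mean[x$selected_index]))
  invisible(x)
}

#' Train many restarts and keep the most reproducible embedding
#'
#' Runs the full training procedure `n_restarts` times with consecutive
#' seeds and selects the embedding with the best reproducibility index.
#' Large-scale applications of this model family use 72 restarts; reduce
#' for exploratory work.
#'
#' @param data Triplet table.
#' @param config Base [spose_config()]; restart `i` uses seed
#'   `config$seed + i - 1`.
#' @param n_restarts Number of random restarts (default 72).
#' @return A `reproducibility_report` (see [select_most_reproducible()])
#'   with the extra field `embeddings` (all restarts).
#' @export
train_spose_restarts <- function(data, config = spose_config(),
                                 n_restarts = 72L) {
  assert_count(n_restarts, "n_restarts", min = 2L)
  data <- as_triplet_df(data)
  fits <- purrr::map(seq_len(n_restarts), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i - 1L
    train_spose(data, cfg, n_objects = attr(data, "n_objects"))
  })
  report <- select_most_reproducible(fits)
  report$embeddings <- fits
  report
}
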