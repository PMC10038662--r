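#' Representational similarity analysis by Pearson correlation
#'
#' Correlates the strictly-lower-triangular parts of two representational
#' dissimilarity matrices over the same objects in the same order.
#'
#' @param rdm_a,rdm_b Square symmetric dissimilarity matrices of equal
#'   dimension.
#' @return Pearson's r of the two lower-triangular vectors.
#' @export
rsa_pearson <- function(rdm_a, rdm_b) {
  va <- lower_tri(rdm_a)
  vb <- lower_tri(rdm_b)
  if (length(va) != length(vb)) abort("RDMs must have matching dimensions.")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    abort("Correlation undefined: an RDM has zero variance off-diagonal.")
  }
  cor(va, vb)
}

#' Object-level bootstrap of an RSA correlation
#'
#' Resamples *objects* (not matrix cells) with replacement and recomputes
#' the RDM correlation on the induced submatrices, which respects the
#' dependence among cells sharing an object.  When several matrix rows
#' refer to the same underlying object (duplicate concepts in a dataset),
#' supply `unique_object_ids` so duplicates are resampled as one unit;
#' exact self-pairs created by sampling the same row twice are excluded,
#' while pairs between distinct rows of one unit are retained.  Draws with
#' fewer than 3 distinct rows are redrawn.
#'
#' @param rdm_a,rdm_b Matched dissimilarity matrices.
#' @param unique_object_ids Vector mapping matrix rows to underlying object
#'   identities; defaults to one unit per row.
#' @param n_boot Number of bootstrap draws (default 100,000, the scale used
#'   for fine-grained similarity evaluation; minimum 100).
#' @param seed Integer seed.
#' @return A list of class `rsa_boot`: `r_obs` (full-sample correlation),
#'   `boot_r` (draws), `ci_low`, `ci_high` (95% percentile interval).
#' @export
bootstrap_object_rsa <- function(rdm_a, rdm_b, unique_object_ids = NULL,
                                 n_boot = 1e5, seed = 1L) {
  assert_count(n_boot, "n_boot", min = 100L)
  n <- nrow(rdm_a)
  stopifnot(is.matrix(rdm_a), is.matrix(rdm_b), ncol(rdm_a) == n,
            nrow(rdm_b) == n, ncol(rdm_b) == n)
  if (is.null(unique_object_ids)) unique_object_ids <- seq_len(n)
  stopifnot(length(unique_object_ids) == n)
  units <- split(seq_len(n), unique_object_ids)
  r_obs <- rsa_pearson(rdm_a, rdm_b)

  boot_r <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      repeat {
        drawn <- unlist(units[sample.int(length(units), replace = TRUE)],
                        use.names = FALSE)
        if (length(unique(drawn)) >= 3) break
      }
      k <- length(drawn)
      # all index pairs p < q over the drawn rows
      p <- rep(seq_len(k - 1), times = (k - 1):1)
      q <- sequence((k - 1):1, from = 2:k)
      keep <- drawn[p] != drawn[q]  # drop exact self-pairs
      ia <- cbind(drawn[p][keep], drawn[q][keep])
      va <- rdm_a[ia]
      vb <- rdm_b[ia]
      if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else cor(va, vb)
    }, numeric(1))
  })
  ci <- quantile(boot_r, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(r_obs = r_obs, boot_r = boot_r,
                 ci_low = ci[1], ci_high = ci[2]),
            class = "rsa_boot")
}

#' @export
print.rsa_boot <- function(x, ...) {
  cat(sprintf("<rsa_boot> r = %.3f (95%% CI %.3f-%.3f, %d draws)\n",
              x$r_obs, x$ci_low, x$ci_high, length(x$boot_r)))
  invisible(x)
}

#' Majority-vote improvement test across datasets
#'
#' Tests whether a new model predicts measured similarity better than an
#' old one across several datasets, using aligned bootstrap draws: for each
#' draw, the datasets in which the new model's correlation exceeds the old
#' one's are counted, and the draw counts as an overall improvement only if
#' more than half the datasets improved (ties are non-improvements).  The
#' p-value is the fraction of draws without an overall improvement.
#'
#' @param boot_new,boot_old Matrices of bootstrap correlations,
#'   `n_draws x n_datasets`, aligned so row `i` of both comes from the same
#'   draw.
#' @return A list of class `improvement_test`: `p_value`,
#'   `mean_improvement` (mean of `new - old` over all draws and datasets),
#'   `frac_improved_draws`, `n_draws`, `n_datasets`.
#' @examples
#' new <- matrix(0.6, 100, 8); old <- matrix(0.5, 100, 8)
#' improvement_test(new, old)$p_value  # 0
#' @export
improvement_test <- function(boot_new, boot_old) {
  boot_new <- as.matrix(boot_new)
  boot_old <- as.matrix(boot_old)
  if (!all(dim(boot_new) == dim(boot_old))) {
    abort("`boot_new` and `boot_old` must have identical dimensions.")
  }
  if (ncol(boot_new) < 2) abort("Need at least 2 datasets.")
  improved <- rowSums(boot_new > boot_old) > ncol(boot_new) / 2
  structure(
    list(p_value = mean(!improved),
         mean_improvement = mean(boot_new - boot_old),
         frac_improved_draws = mean(improved),
         n_draws = nrow(boot_new), n_datasets = ncol(boot_new)),
    class = "improvement_test"
  )
}

#' @export
print.improvement_test <- function(x, ...) {
  cat(sprintf(
    "<improvement_test> mean improvement %+.4f, p = %.4g (%d draws, %d datasets)\n",
    x$mean_improvement, x$p_value, x$n_draws, x$n_datasets))
  invisible(x)
}
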