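#' Choice-probability similarity matrix from an embedding
#'
#' The similarity of objects `i` and `j` is defined behaviorally: the
#' probability, under the softmax choice model, that a third object `k` is
#' picked as the odd-one-out of the triple `{i, j, k}` (so that `i` and `j`
#' survive as the most similar pair), averaged over all other objects `k`
#' in the context.  Restricting `context` to a subset of objects (e.g. all
#' members of one superordinate category) yields context-constrained
#' similarities, which differ from simply subsetting the full-context
#' matrix -- the third objects defining each judgment change with the
#' context.
#'
#' @param weights Embedding matrix, `gt_embedding` or `spose_embedding`.
#' @param context Optional vector of at least 3 object indices (1-based)
#'   restricting both the object set and the averaged-over third objects.
#' @return A symmetric matrix over the context objects with entries in
#'   `[0, 1]`; the diagonal is stored as 1 by convention and carries no
#'   information (self-similarity is undefined in the triplet task).
#'   Row/column names are object ids when available.
#' @examples
#' gt <- make_ground_truth_embedding(8, 3, seed = 1)
#' choice_prob_similarity(gt)
#' @export
choice_prob_similarity <- function(weights, context = NULL) {
  w <- embedding_weights(weights)
  n_all <- nrow(w)
  if (is.null(context)) context <- seq_len(n_all)
  context <- as.integer(context)
  if (length(context) < 3) abort("`context` must contain at least 3 objects.")
  if (any(context < 1 | context > n_all) || anyDuplicated(context)) {
    abort("`context` must be distinct valid object indices.")
  }
  wc <- w[context, , drop = FALSE]
  n <- length(context)
  s <- tcrossprod(wc)  # all pairwise dot products within the context
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- setdiff(seq_len(n), c(i, j))
      s_ij <- s[i, j]
      m <- pmax(s_ij, s[i, k], s[j, k])
      p <- exp(s_ij - m) / (exp(s_ij - m) + exp(s[i, k] - m) + exp(s[j, k] - m))
      sim[i, j] <- sim[j, i] <- mean(p)
    }
  }
  ids <- rownames(w)[context] %||% as.character(context)
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Convert a similarity matrix to a dissimilarity matrix
#'
#' Choice-probability similarities are probabilities in `[0, 1]`, so the
#' dissimilarity is `1 - similarity` off the diagonal; the diagonal is set
#' to 0.  Applying the conversion twice returns the original off-diagonal
#' values.
#'
#' @param S Symmetric similarity matrix with entries in `[0, 1]`.
#' @return The representational dissimilarity matrix (RDM).
#' @export
similarity_to_rdm <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  d <- 1 - S
  diag(d) <- 0
  d
}

#' Strictly-lower-triangular vectorization
#'
#' Extracts the strictly-lower-triangular entries in row-major order (row
#' 2 column 1, row 3 columns 1-2, ...), the fixed order used for all RDM
#' correlations in this package so results are bit-reproducible.  The
#' result has length `n_pairs(n) = choose(n, 2)`.
#'
#' @param M Square matrix.
#' @return Numeric vector of length `choose(nrow(M), 2)`.
#' @export
lower_tri <- function(M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) abort("`M` must be square.")
  n <- nrow(M)
  if (n < 2) return(numeric(0))
  rows <- rep(2:n, times = 1:(n - 1))
  cols <- unlist(lapply(2:n, function(i) seq_len(i - 1)))
  M[cbind(rows, cols)]
}

#' @rdname count_triplets
#' @export
n_pairs <- function(n_objects) count_pairs(n_objects)

#' Brute-force choice-probability similarity (reference implementation)
#'
#' Direct enumeration over every triple `(i, j, k)`; cubic in the context
#' size and intended as an independent check of
#' [choice_prob_similarity()] on small object sets.
#'
#' @inheritParams choice_prob_similarity
#' @return A similarity matrix identical (up to floating-point roundoff) to
#'   [choice_prob_similarity()].
#' @export
choice_prob_similarity_bruteforce <- function(weights, context = NULL) {
  w <- embedding_weights(weights)
  if (is.null(context)) context <- seq_len(nrow(w))
  wc <- w[context, , drop = FALSE]
  n <- nrow(wc)
  sim <- matrix(1, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ps <- c()
      for (k in seq_len(n)) {
        if (k == i || k == j) next
        p <- triplet_probabilities(wc, c(i, j, k))
        ps <- c(ps, p[1, "p_ab"])  # P(k is the odd-one-out)
      }
      sim[i, j] <- sim[j, i] <- mean(ps)
    }
  }
  ids <- rownames(wc) %||% as.character(context)
  dimnames(sim) <- list(ids, ids)
  sim
}
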