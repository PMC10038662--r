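#' Sample triplet odd-one-out task designs
#'
#' Draws triples of distinct object indices for the odd-one-out task.  With
#' `balanced = TRUE` the design aims at uniform pair coverage, mirroring
#' large-scale crowdsourcing designs in which every cell of the object-pair
#' similarity matrix is sampled roughly equally often: all `choose(n, 3)`
#' triples are enumerated in a shuffled order and consumed cyclically, so
#' whenever `n_trials` is a multiple of `choose(n_objects, 3)` every pair is
#' sampled exactly `3 * n_trials / choose(n_objects, 2)` times.
#'
#' @param n_objects Number of objects, at least 3.
#' @param n_trials Number of triplet trials to draw.
#' @param seed Integer seed.
#' @param balanced If `TRUE` (default), use shuffled enumeration with cyclic
#'   refill; if `FALSE`, draw each triple independently and uniformly.
#' @param max_enumerate Safety cap on `choose(n_objects, 3)` for the balanced
#'   design (enumeration is explicit); above it an error suggests
#'   `balanced = FALSE`.
#'
#' @return A tibble with integer columns `a`, `b`, `c` (1-based object
#'   indices, `a < b < c` within each row) and attribute `n_objects`.
#' @examples
#' sample_triplet_tasks(6, 10, seed = 1)
#' @export
sample_triplet_tasks <- function(n_objects, n_trials, seed = 1,
                                 balanced = TRUE, max_enumerate = 5e6) {
  n_objects <- assert_count(n_objects, "n_objects", min = 3L)
  n_trials <- assert_count(n_trials, "n_trials", min = 1L)

  trips <- with_seed(seed, {
    if (balanced) {
      n_triples <- choose(n_objects, 3)
      if (n_triples > max_enumerate) {
        abort(paste0("choose(n_objects, 3) exceeds `max_enumerate`; ",
                     "use balanced = FALSE for very large object sets."))
      }
      all_trips <- t(utils::combn(n_objects, 3L))
      idx <- integer(0)
      while (length(idx) < n_trials) {
        idx <- c(idx, sample.int(n_triples))
      }
      all_trips[idx[seq_len(n_trials)], , drop = FALSE]
    } else {
      m <- matrix(0L, n_trials, 3L)
      for (i in seq_len(n_trials)) {
        m[i, ] <- sort(sample.int(n_objects, 3L))
      }
      m
    }
  })
  out <- tibble::tibble(a = as.integer(trips[, 1]), b = as.integer(trips[, 2]),
                        c = as.integer(trips[, 3]))
  attr(out, "n_objects") <- n_objects
  out
}

#' Simulate odd-one-out choices from a ground-truth embedding
#'
#' Runs the softmax choice model forward: for a triple `{i, j, k}` with
#' pairwise dot products `s_ij`, `s_ik`, `s_jk` of the embedding vectors,
#' object `k` is picked as the odd-one-out with probability
#' `exp(s_ij) / (exp(s_ij) + exp(s_ik) + exp(s_jk))` (and cyclically for the
#' other two objects) -- the most similar pair "survives" and the remaining
#' object is the odd one out.  No temperature parameter is used.
#'
#' @param gt A `gt_embedding`, `spose_embedding`, or plain non-negative
#'   weight matrix.
#' @param triples Data frame with columns `a`, `b`, `c` (1-based indices),
#'   e.g. from [sample_triplet_tasks()].
#' @param seed Integer seed (ignored when `deterministic = TRUE`).
#' @param deterministic If `TRUE`, pick the argmax-probability odd-one-out,
#'   breaking ties toward the lowest object index.
#'
#' @return A tibble with columns `a`, `b`, `c`, `choice` (the chosen
#'   odd-one-out, one of `a`, `b`, `c`) and attribute `n_objects`.
#' @examples
#' gt <- make_ground_truth_embedding(10, 3, sparsity = 0.2, seed = 1)
#' trips <- sample_triplet_tasks(10, 100, seed = 2)
#' simulate_choices(gt, trips, seed = 3)
#' @export
simulate_choices <- function(gt, triples, seed = 1, deterministic = FALSE) {
  w <- embedding_weights(gt)
  triples <- as_triplet_df(triples, n_objects = nrow(w), need_choice = FALSE)
  p <- triplet_probabilities(w, triples)
  # p columns: P(c odd), P(b odd), P(a odd) -- see triplet_probabilities().
  odd_prob <- cbind(p[, "p_bc"], p[, "p_ac"], p[, "p_ab"])  # P(a), P(b), P(c)
  obj <- cbind(triples$a, triples$b, triples$c)

  pick <- if (deterministic) {
    # argmax probability; ties -> lowest object index among the tied
    apply_pick <- function(i) {
      pr <- odd_prob[i, ]
      cand <- which(pr >= max(pr) - 1e-12)
      cand[which.min(obj[i, cand])]
    }
    vapply(seq_len(nrow(obj)), apply_pick, integer(1))
  } else {
    with_seed(seed, {
      u <- runif(nrow(obj))
      cum1 <- odd_prob[, 1]
      cum2 <- cum1 + odd_prob[, 2]
      1L + (u >= cum1) + (u >= cum2)
    })
  }
  out <- tibble::tibble(a = triples$a, b = triples$b, c = triples$c,
                        choice = obj[cbind(seq_len(nrow(obj)), pick)])
  attr(out, "n_objects") <- nrow(w)
  out
}

#' Pair-coverage summary for a triplet design
#'
#' Each triplet trial samples three object pairs.  The mean pair-sampling
#' count is `3 * n_trials / choose(n_objects, 2)`; when the triples
#' themselves are supplied, the minimum and maximum counts are computed by
#' exact tallying over all `choose(n_objects, 2)` pairs.
#'
#' @param triples_or_count A data frame of triples (columns `a`, `b`, `c`)
#'   or a single trial count.
#' @param n_objects Number of objects, at least 2.
#'
#' @return A one-row tibble with columns `n_trials`, `n_pairs`, `mean_count`,
#'   `min_count`, `max_count` (the latter two `NA` when only a count is
#'   given).
#' @examples
#' pair_coverage_stats(4574059, n_objects = 1854)$mean_count  # ~7.99
#' @export
pair_coverage_stats <- function(triples_or_count, n_objects) {
  n_objects <- assert_count(n_objects, "n_objects", min = 2L)
  np <- count_pairs(n_objects)
  if (is.numeric(triples_or_count) && length(triples_or_count) == 1) {
    n_trials <- assert_count(triples_or_count, "triples_or_count")
    return(tibble::tibble(n_trials = n_trials, n_pairs = np,
                          mean_count = 3 * n_trials / np,
                          min_count = NA_real_, max_count = NA_real_))
  }
  trips <- as_triplet_df(triples_or_count, n_objects = n_objects,
                         need_choice = FALSE)
  n_trials <- nrow(trips)
  # pair id for i<j (1-based, row-major over the strict lower triangle)
  pair_id <- function(i, j) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    (hi - 1) * (hi - 2) / 2 + lo
  }
  ids <- c(pair_id(trips$a, trips$b), pair_id(trips$a, trips$c),
           pair_id(trips$b, trips$c))
  counts <- tabulate(ids, nbins = np)
  tibble::tibble(n_trials = n_trials, n_pairs = np,
                 mean_count = 3 * n_trials / np,
                 min_count = min(counts), max_count = max(counts))
}

#' Exact triplet and pair counts
#'
#' `count_triplets(n)` is `choose(n, 3)` and `count_pairs(n)` is
#' `choose(n, 2)`, computed exactly (these counts stay below 2^53 for any
#' realistic object set, so double arithmetic is exact).  For the 1854-object
#' set used in large-scale odd-one-out studies these are 1,060,412,604
#' triplets and 1,717,731 pairs.
#'
#' @param n_objects Number of objects.
#' @return The exact count as a (whole) double.
#' @examples
#' count_triplets(1854)
#' count_pairs(720)
#' @export
count_triplets <- function(n_objects) {
  n_objects <- assert_count(n_objects, "n_objects", min = 3L)
  n <- as.numeric(n_objects)
  round(n * (n - 1) * (n - 2) / 6)
}

#' @rdname count_triplets
#' @export
count_pairs <- function(n_objects) {
  n_objects <- assert_count(n_objects, "n_objects", min = 2L)
  n <- as.numeric(n_objects)
  round(n * (n - 1) / 2)
}

#' Tally repeated-triplet choices
#'
#' Groups trials by their (unordered) triple and counts how often each of
#' the three objects was chosen as the odd-one-out.  The result feeds
#' [behavioral_noise_ceiling()].
#'
#' @param trials Triplet table with columns `a`, `b`, `c`, `choice`.
#' @return A tibble with one row per unique triple: `a`, `b`, `c`,
#'   `n_a`, `n_b`, `n_c` (choice counts) and `n_repeats`.
#' @export
consistency_counts <- function(trials) {
  trials <- as_triplet_df(trials)
  trials %>%
    group_by(.data$a, .data$b, .data$c) %>%
    summarise(n_a = sum(.data$choice == .data$a),
              n_b = sum(.data$choice == .data$b),
              n_c = sum(.data$choice == .data$c),
              n_repeats = n(), .groups = "drop")
}
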