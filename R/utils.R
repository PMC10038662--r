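# Internal validation and RNG helpers.

# Run `code` under a fixed seed without clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < min ||
      x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x >= lo &&
    (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf("`%s` must be a number in [%g, %g%s.", name, lo, hi,
                  if (open_hi) ")" else "]"))
  }
  invisible(as.numeric(x))
}

assert_positive <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    abort(sprintf("`%s` must be a %s number.", name,
                  if (strict) "positive" else "non-negative"))
  }
  invisible(as.numeric(x))
}

# Extract the weight matrix from any accepted embedding representation.
embedding_weights <- function(x) {
  w <- if (inherits(x, "spose_embedding") || inherits(x, "gt_embedding")) {
    x$weights
  } else if (is.matrix(x)) {
    x
  } else {
    abort("Expected a weight matrix, `gt_embedding` or `spose_embedding`.")
  }
  if (!is.numeric(w)) abort("Embedding weights must be numeric.")
  w
}

# Validate a triplet table: columns a, b, c, choice with 1-based indices.
as_triplet_df <- function(trials, n_objects = NULL, need_choice = TRUE) {
  if (is.matrix(trials)) trials <- as.data.frame(trials)
  if (!is.data.frame(trials)) abort("`trials` must be a data frame or matrix.")
  cols <- c("a", "b", "c", if (need_choice) "choice")
  if (!all(cols %in% names(trials))) {
    if (ncol(trials) >= length(cols)) {
      names(trials)[seq_along(cols)] <- cols
    } else {
      abort(sprintf("`trials` needs columns %s.", toString(cols)))
    }
  }
  trials <- tibble::as_tibble(trials[, cols, drop = FALSE])
  if (is.null(n_objects)) {
    n_objects <- attr(trials, "n_objects", exact = TRUE) %||%
      max(trials$a, trials$b, trials$c)
  }
  abc <- cbind(trials$a, trials$b, trials$c)
  if (any(abc < 1L) || any(abc > n_objects)) {
    abort("Object indices must lie in [1, n_objects].")
  }
  if (any(trials$a == trials$b | trials$a == trials$c | trials$b == trials$c)) {
    abort("Each triplet must contain three distinct objects.")
  }
  if (need_choice &&
      any(trials$choice != trials$a & trials$choice != trials$b &
          trials$choice != trials$c)) {
    abort("`choice` must be one of the trial's three objects.")
  }
  attr(trials, "n_objects") <- as.integer(n_objects)
  trials
}

`%||%` <- function(a, b) if (is.null(a)) b else a
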