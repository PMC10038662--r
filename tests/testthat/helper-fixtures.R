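# Shared fixtures, built in code.

# small ground-truth embedding + simulated choices for quick training tests
tiny_recovery_data <- function(n_objects = 20, n_dims = 3, n_trials = 8000,
                               seed = 42) {
  gt <- make_ground_truth_embedding(n_objects, n_dims, sparsity = 0.5,
                                    scale = 1, seed = seed)
  trips <- sample_triplet_tasks(n_objects, n_trials, seed = seed + 1)
  choices <- simulate_choices(gt, trips, seed = seed + 2)
  list(gt = gt, choices = choices)
}

# hand-built embedding whose columns are easy to reason about
stacked_embedding <- function(cols) {
  w <- do.call(cbind, cols)
  rownames(w) <- sprintf("obj%03d", seq_len(nrow(w)))
  w
}

expect_symmetric <- function(m, tol = 1e-12) {
  expect_lt(max(abs(m - t(m))), tol)
}

# temp file/dir cleaned up when the test finishes
withr_local_file <- function(name, env = parent.frame()) {
  path <- file.path(tempdir(), paste0(name, "-", as.integer(runif(1, 0, 1e8))))
  withr::defer(unlink(path, recursive = TRUE), envir = env)
  path
}
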