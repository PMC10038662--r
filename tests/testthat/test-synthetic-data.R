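test_that("ground-truth embeddings are non-negative, sparse and reproducible", {
  gt <- make_ground_truth_embedding(10, 3, sparsity = 0, scale = 1, seed = 1)
  expect_equal(dim(gt$weights), c(10, 3))
  expect_true(all(gt$weights >= 0))
  expect_identical(sum(gt$weights == 0), 0L)

  gt1 <- make_ground_truth_embedding(30, 4, sparsity = 0.4, seed = 7)
  gt2 <- make_ground_truth_embedding(30, 4, sparsity = 0.4, seed = 7)
  expect_identical(gt1$weights, gt2$weights)

  # empirical zero fraction concentrates around the target (binomial bound)
  big <- make_ground_truth_embedding(2000, 10, sparsity = 0.6, seed = 3)
  expect_lt(abs(mean(big$weights == 0) - 0.6), 0.02)

  expect_error(make_ground_truth_embedding(2, 3), "n_objects")
  expect_error(make_ground_truth_embedding(10, 3, sparsity = 1), "sparsity")
})

test_that("triplet designs have distinct members and balanced pair coverage", {
  # only one triple exists over 3 objects
  t3 <- sample_triplet_tasks(3, 5, seed = 1)
  expect_true(all(t3$a == 1 & t3$b == 2 & t3$c == 3))

  # full enumeration over 4 objects: each of the 6 pairs appears exactly twice
  t4 <- sample_triplet_tasks(4, 4, seed = 2, balanced = TRUE)
  cov4 <- pair_coverage_stats(t4, 4)
  expect_equal(cov4$min_count, 2)
  expect_equal(cov4$max_count, 2)

  # distinctness invariant on a larger random draw
  tr <- sample_triplet_tasks(15, 500, seed = 3, balanced = FALSE)
  expect_true(all(tr$a < tr$b & tr$b < tr$c))
  expect_true(all(tr$a >= 1 & tr$c <= 15))

  # exact uniformity whenever n_trials is a multiple of choose(n, 3)
  for (n in c(5, 6, 8)) {
    nt <- 2 * choose(n, 3)
    cov <- pair_coverage_stats(sample_triplet_tasks(n, nt, seed = n), n)
    expect_equal(cov$min_count, cov$max_count)
    expect_equal(cov$mean_count, 3 * nt / choose(n, 2))
  }

  expect_error(sample_triplet_tasks(2, 5), "n_objects")
})

test_that("simulated choices follow the softmax model", {
  # all-zero embedding: every position chosen 1/3 of the time
  w0 <- matrix(0, 6, 2)
  trips <- sample_triplet_tasks(6, 30000, seed = 1)
  ch <- simulate_choices(w0, trips, seed = 2)
  freq <- c(mean(ch$choice == ch$a), mean(ch$choice == ch$b),
            mean(ch$choice == ch$c))
  expect_true(all(abs(freq - 1 / 3) < 0.01))

  # dominant pair forces the remaining object out deterministically
  w <- rbind(c(10, 0), c(10, 0), c(0, 0))
  det <- simulate_choices(w, tibble::tibble(a = 1, b = 2, c = 3),
                          deterministic = TRUE)
  expect_equal(det$choice, 3L)

  # same seed, same choices
  c1 <- simulate_choices(w0, trips, seed = 9)
  c2 <- simulate_choices(w0, trips, seed = 9)
  expect_identical(c1, c2)
})

test_that("empirical choice frequencies converge to the analytic softmax", {
  w <- rbind(c(1.2, 0.3), c(0.4, 0.9), c(0.8, 0.1), c(0, 0))
  triple <- tibble::tibble(a = 1, b = 2, c = 3)
  p <- triplet_probabilities(w, triple)
  expected <- c(p[1, "p_bc"], p[1, "p_ac"], p[1, "p_ab"])  # P(a), P(b), P(c)

  n <- 1e5
  reps <- triple[rep(1, n), ]
  ch <- simulate_choices(w, reps, seed = 4)
  emp <- c(mean(ch$choice == 1), mean(ch$choice == 2), mean(ch$choice == 3))
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(emp - expected) < 3 * se))
})

test_that("repeated-measures simulation matches its signal-plus-noise model", {
  # zero noise: all repeats identical
  rm0 <- simulate_repeated_measures(3, 10, 4, signal_sd = 1, noise_sd = 0,
                                    seed = 1)
  expect_equal(rm0$responses[, , 1], rm0$responses[, , 4])

  # zero signal: variance of image means is noise_sd^2 / n_repeats
  rmn <- simulate_repeated_measures(2, 5000, 8, signal_sd = 0, noise_sd = 1,
                                    seed = 2)
  means <- apply(rmn$responses, c(1, 2), mean)
  expect_lt(abs(var(means[1, ]) - 1 / 8), 0.02)

  expect_identical(
    simulate_repeated_measures(2, 4, 3, seed = 5)$responses,
    simulate_repeated_measures(2, 4, 3, seed = 5)$responses
  )
  expect_error(simulate_repeated_measures(2, 4, 1), "n_repeats")
  expect_error(simulate_repeated_measures(2, 4, 3, noise_sd = -1), "noise_sd")
})

test_that("fusion simulation injects information only after each onset", {
  tm <- seq(-100, 400, by = 20)
  fd <- simulate_fusion_data(200, 10, tm, n_sessions = 4,
                             roi_onsets = c(V1 = 100, FFA = 200),
                             snr = 2, seed = 1)
  expect_s3_class(fd, "fusion_data")
  expect_equal(dim(fd$sensor_data), c(200, 10, length(tm)))
  expect_true(all(table(fd$session_labels) >= 2))

  # before all onsets, sensors are pure noise w.r.t. the region responses
  pre <- which(tm < 100)
  rs <- sapply(pre, function(t) {
    max(abs(cor(fd$sensor_data[, , t], fd$roi_responses$V1)))
  })
  expect_true(all(rs < 3 / sqrt(200)))

  # noiseless limit: region feature exactly linearly decodable post-onset
  fdi <- simulate_fusion_data(60, 6, tm, n_sessions = 3,
                              roi_onsets = c(V1 = 100), snr = Inf, seed = 2)
  t_post <- which(tm >= 100)[1]
  fit <- lm.fit(cbind(1, fdi$sensor_data[, , t_post]), fdi$roi_responses$V1)
  expect_lt(max(abs(fit$residuals)), 1e-8)

  expect_identical(
    simulate_fusion_data(40, 4, tm, 2, c(A = 0), seed = 3)$sensor_data,
    simulate_fusion_data(40, 4, tm, 2, c(A = 0), seed = 3)$sensor_data
  )
  expect_error(
    simulate_fusion_data(40, 4, tm, 2, c(A = 900), seed = 3),
    "onset"
  )
})

test_that("pair coverage and combinatorial counts are exact", {
  # single triple over 3 objects
  cov1 <- pair_coverage_stats(tibble::tibble(a = 1, b = 2, c = 3), 3)
  expect_equal(cov1$mean_count, 1)
  expect_equal(cov1$min_count, 1)
  expect_equal(cov1$max_count, 1)

  # mean from a trial count alone equals 3 t / C(n,2)
  trips <- sample_triplet_tasks(20, 1000, seed = 1, balanced = FALSE)
  cov <- pair_coverage_stats(trips, 20)
  # brute-force tally over all 190 pairs
  tally <- matrix(0, 20, 20)
  for (i in seq_len(nrow(trips))) {
    pr <- combn(c(trips$a[i], trips$b[i], trips$c[i]), 2)
    for (j in 1:3) {
      tally[pr[1, j], pr[2, j]] <- tally[pr[1, j], pr[2, j]] + 1
    }
  }
  counts <- tally[upper.tri(tally)]
  expect_equal(cov$mean_count, sum(counts) / 190)
  expect_equal(cov$min_count, min(counts))
  expect_equal(cov$max_count, max(counts))

  expect_equal(count_triplets(3), 1)
  expect_equal(count_pairs(2), 1)
  # identity linking the two counts
  for (n in c(3, 7, 50, 1854)) {
    expect_equal(count_pairs(n) * (n - 2) / 3, count_triplets(n))
  }
})

test_that("repeated-triplet tallies sum to the repeat counts", {
  gt <- make_ground_truth_embedding(9, 2, seed = 1)
  base <- sample_triplet_tasks(9, 50, seed = 2)
  reps <- base[rep(seq_len(50), each = 6), ]
  ch <- simulate_choices(gt, reps, seed = 3)
  counts <- consistency_counts(ch)
  expect_equal(nrow(counts), 50)
  expect_true(all(counts$n_a + counts$n_b + counts$n_c == counts$n_repeats))
  expect_true(all(counts$n_repeats == 6))
})
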