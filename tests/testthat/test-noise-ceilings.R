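test_that("the ceiling formula behaves at its analytic landmarks", {
  # direct formula: signal 1, noise 1 -> 0.5 at single trial, 12/13 at 12
  arr <- simulate_repeated_measures(1, 5000, 12, signal_sd = 1, noise_sd = 1,
                                    seed = 1)
  nc1 <- neuro_noise_ceiling(arr, n_average = 1, bias_correct = TRUE)
  nc12 <- neuro_noise_ceiling(arr, n_average = 12, bias_correct = TRUE)
  expect_lt(abs(nc1$ceiling - 0.5), 0.03)
  expect_lt(abs(nc12$ceiling - 12 / 13), 0.02)
  # estimated variances track the generating ones
  expect_lt(abs(nc1$signal_var - 1), 0.1)
  expect_lt(abs(nc1$noise_var - 1), 0.05)

  # zero noise: ceiling exactly 1 for every channel
  noiseless <- simulate_repeated_measures(3, 50, 5, signal_sd = 1,
                                          noise_sd = 0, seed = 2)
  expect_equal(neuro_noise_ceiling(noiseless, 1)$ceiling, rep(1, 3))
})

test_that("bias correction removes the noise leak into the signal variance", {
  rm <- simulate_repeated_measures(2, 5000, 4, signal_sd = 1, noise_sd = 2,
                                   seed = 3)
  truth <- 1 / (1 + 4 / 4)  # signal 1, noise 4, n_average 4
  nc_bc <- neuro_noise_ceiling(rm, n_average = 4, bias_correct = TRUE)
  expect_true(all(abs(nc_bc$ceiling - truth) < 0.02))
  # without correction the ceiling is systematically above the analytic value
  nc_raw <- neuro_noise_ceiling(rm, n_average = 4, bias_correct = FALSE)
  expect_true(all(nc_raw$ceiling > nc_bc$ceiling))

  expect_true(all(nc_raw$ceiling >= 0 & nc_raw$ceiling <= 1))
  expect_error(neuro_noise_ceiling(array(0, c(2, 3, 1)), 1), "repeats")
})

test_that("behavioral consistency ceilings match hand-computed values", {
  expect_equal(as.numeric(behavioral_noise_ceiling(rbind(c(12, 0, 0)))), 100)
  expect_equal(as.numeric(behavioral_noise_ceiling(rbind(c(4, 4, 4)))),
               100 / 3, tolerance = 1e-12)
  # mean over triplets: (100 + 50) / 2
  expect_equal(
    as.numeric(behavioral_noise_ceiling(rbind(c(6, 0, 0), c(3, 3, 0)))), 75)

  expect_error(behavioral_noise_ceiling(rbind(c(1, 0, 0))), "twice")
  expect_error(behavioral_noise_ceiling(matrix(0, 0, 3)), "non-empty")
})

test_that("the modal-count lower bound holds for simulated repeats", {
  gt <- make_ground_truth_embedding(10, 2, seed = 4)
  base <- sample_triplet_tasks(10, 40, seed = 5)
  for (R in c(2, 3, 12)) {
    reps <- base[rep(seq_len(40), each = R), ]
    ch <- simulate_choices(gt, reps, seed = R)
    nc <- behavioral_noise_ceiling(consistency_counts(ch))
    expect_gte(as.numeric(nc), 100 * ceiling(R / 3) / R)
    expect_lte(as.numeric(nc), 100)
  }
})

test_that("the sample modal fraction converges to its exact multinomial expectation", {
  # exact E[max count]/R by enumeration over the trinomial distribution
  exact_modal_mean <- function(p, R) {
    tot <- 0
    for (i in 0:R) for (j in 0:(R - i)) {
      k <- R - i - j
      pr <- exp(lchoose(R, i) + lchoose(R - i, j) +
                  i * log(p[1]) + j * log(p[2]) + k * log(p[3]))
      tot <- tot + pr * max(i, j, k) / R
    }
    100 * tot
  }
  w <- rbind(c(1.0, 0.2), c(0.3, 0.8), c(0.6, 0.1))
  p <- triplet_probabilities(w, c(1, 2, 3))
  pv <- c(p[1, "p_bc"], p[1, "p_ac"], p[1, "p_ab"])
  R <- 12
  n_triplets <- 4000
  reps <- tibble::tibble(a = 1, b = 2, c = 3)[rep(1, n_triplets * R), ]
  ch <- simulate_choices(w, reps, seed = 6)
  grp <- rep(seq_len(n_triplets), each = R)
  counts <- cbind(tapply(ch$choice == 1, grp, sum),
                  tapply(ch$choice == 2, grp, sum),
                  tapply(ch$choice == 3, grp, sum))
  mc <- as.numeric(behavioral_noise_ceiling(counts))
  expect_lt(abs(mc - exact_modal_mean(pv, R)), 0.5)
})
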