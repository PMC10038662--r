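test_that("choice-probability similarity equals exhaustive enumeration", {
  # random embeddings up to n = 12: exhaustive oracle over every (i, j, k)
  for (n in c(5, 10, 12)) {
    set.seed(n)
    w <- matrix(rexp(n * 3), n, 3)
    fast <- choice_prob_similarity(w)
    slow <- choice_prob_similarity_bruteforce(w)
    expect_lt(max(abs(fast - slow)), 1e-10)
    expect_symmetric(fast)
    expect_true(all(fast >= 0 & fast <= 1))
  }
})

test_that("identical objects give similarity 1/3 and dissimilarity 2/3", {
  w <- matrix(1, 6, 2)  # all objects identical -> all probabilities uniform
  s <- choice_prob_similarity(w)
  expect_equal(unname(s[lower.tri(s)]), rep(1 / 3, 15), tolerance = 1e-12)
  d <- similarity_to_rdm(s)
  expect_equal(unname(d[lower.tri(d)]), rep(2 / 3, 15), tolerance = 1e-12)
  expect_equal(unname(diag(d)), rep(0, 6))
  # conversion is an involution off the diagonal
  back <- similarity_to_rdm(d)
  expect_equal(back[lower.tri(back)], s[lower.tri(s)])
})

test_that("context-constrained similarity differs from subsetting the full matrix", {
  set.seed(7)
  w <- matrix(rexp(30), 10, 3)
  ctx <- c(1, 3, 5, 7)
  full <- choice_prob_similarity(w)
  constrained <- choice_prob_similarity(w, context = ctx)
  expect_gt(max(abs(full[ctx, ctx] - constrained)), 1e-3)
  expect_error(choice_prob_similarity(w, context = c(1, 2)), "at least 3")
})

test_that("lower-triangular vectorization has the exact pairwise length", {
  expect_equal(length(lower_tri(matrix(0, 720, 720))), 258840)
  expect_equal(n_pairs(1854), 1717731)
  m <- matrix(1:4, 2, 2)
  expect_equal(lower_tri(m), m[2, 1])
  # row-major order: row 3 of a 3x3 contributes entries (3,1), (3,2) last
  m3 <- matrix(1:9, 3, 3)
  expect_equal(lower_tri(m3), c(m3[2, 1], m3[3, 1], m3[3, 2]))
  expect_error(lower_tri(matrix(0, 2, 3)), "square")
})

test_that("RSA correlation matches a hand-computed fixture and affine invariance", {
  expect_equal(rsa_pearson(diag(4) * 0 + outer(1:4, 1:4),
                           outer(1:4, 1:4)), 1)

  set.seed(8)
  w <- matrix(rexp(24), 8, 3)
  rdm <- similarity_to_rdm(choice_prob_similarity(w))
  expect_equal(rsa_pearson(rdm, rdm), 1)
  expect_equal(rsa_pearson(rdm, max(rdm) + 1 - rdm), -1)
  # invariant to positive affine transforms of one RDM
  expect_equal(rsa_pearson(rdm, 3 * rdm + 0.2), 1, tolerance = 1e-12)

  # 4-object worked fixture against cor() on the 6 lower-tri entries
  ra <- matrix(0, 4, 4); rb <- matrix(0, 4, 4)
  va <- c(0.1, 0.5, 0.3, 0.9, 0.2, 0.6); vb <- c(0.2, 0.4, 0.1, 0.8, 0.5, 0.3)
  ra[lower.tri(ra)] <- va; ra <- ra + t(ra)
  rb[lower.tri(rb)] <- vb; rb <- rb + t(rb)
  expect_equal(rsa_pearson(ra, rb), cor(va, vb), tolerance = 1e-12)

  expect_error(rsa_pearson(matrix(1, 3, 3), rdm[1:3, 1:3]), "zero variance")
})

test_that("object-level bootstrap respects identity and duplicates", {
  set.seed(9)
  w <- matrix(rexp(45), 15, 3)
  rdm <- similarity_to_rdm(choice_prob_similarity(w))
  bs <- bootstrap_object_rsa(rdm, rdm, n_boot = 200, seed = 1)
  expect_true(all(abs(bs$boot_r - 1) < 1e-9))
  expect_equal(bs$r_obs, 1)

  # independent random RDMs: the CI straddles 0
  set.seed(10)
  n <- 100
  m1 <- matrix(rnorm(n^2), n); m1 <- (m1 + t(m1)) / 2; diag(m1) <- 0
  m2 <- matrix(rnorm(n^2), n); m2 <- (m2 + t(m2)) / 2; diag(m2) <- 0
  bs0 <- bootstrap_object_rsa(m1, m2, n_boot = 300, seed = 2)
  expect_lt(bs0$ci_low, 0)
  expect_gt(bs0$ci_high, 0)

  # duplicate units resampled together are reproducible under a seed
  ids <- c(1, 1, 2, 3, 4, 5, 6, 7, 7, 8, 9, 10, 11, 12, 13)
  b1 <- bootstrap_object_rsa(rdm, m1[1:15, 1:15], unique_object_ids = ids,
                             n_boot = 150, seed = 3)
  b2 <- bootstrap_object_rsa(rdm, m1[1:15, 1:15], unique_object_ids = ids,
                             n_boot = 150, seed = 3)
  expect_identical(b1$boot_r, b2$boot_r)
})

test_that("the improvement test applies the majority rule exactly", {
  old <- matrix(runif(800), 100, 8)
  expect_equal(improvement_test(old + 0.1, old)$p_value, 0)
  # ties are non-improvements
  expect_equal(improvement_test(old, old)$p_value, 1)

  # 7 of 8 datasets improved in every draw -> improvement (> 50% rule), p = 0
  new <- old + 0.1
  new[, 8] <- old[, 8] - 0.1
  it <- improvement_test(new, old)
  expect_equal(it$p_value, 0)
  expect_equal(it$frac_improved_draws, 1)

  # exactly half improved does not count (> 50%, not >=)
  new2 <- old
  new2[, 1:4] <- old[, 1:4] + 0.1
  new2[, 5:8] <- old[, 5:8] - 0.1
  expect_equal(improvement_test(new2, old)$p_value, 1)

  expect_error(improvement_test(old[, 1:3], old), "identical dimensions")
})
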