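test_that("identical constant preference gives p = 1", {
  tr <- dplyr::bind_rows(
    make_trials(c(5, 5, 5), c(5, 5, 5), "a"),
    make_trials(c(5, 5, 5), c(5, 5, 5), "b")
  )
  rt <- pi_randomization_test(tr, n_permutations = 199, exact = "never", seed = 1)
  expect_equal(rt$statistic, 0)
  expect_equal(rt$p_value, 1)

  tr3 <- dplyr::bind_rows(tr, make_trials(c(5, 5), c(5, 5), "c"))
  ra <- pi_randomization_anova(tr3, n_permutations = 199, seed = 1)
  expect_equal(ra$statistic, 0)
  expect_equal(ra$p_value, 1)
})

test_that("exhaustive enumeration matches an independent oracle exactly", {
  tr <- dplyr::bind_rows(
    make_trials(c(14, 12, 15), c(4, 6, 5), "a"),
    make_trials(c(8, 9, 6), c(10, 8, 11), "b")
  )
  rt <- pi_randomization_test(tr, n_permutations = 1000, exact = "always")
  expect_true(rt$exhaustive)
  expect_equal(rt$n_permutations, choose(6, 3))
  p_oracle <- oracle_exact_p(
    preference_index(c(14, 12, 15), c(4, 6, 5)), c(18, 18, 20),
    preference_index(c(8, 9, 6), c(10, 8, 11)), c(18, 17, 17)
  )
  expect_equal(rt$p_value, p_oracle)
})

test_that("Monte-Carlo p agrees with exhaustive enumeration within 3 MC SEs", {
  set.seed(31)
  tr <- dplyr::bind_rows(
    make_trials(rbinom(5, 14, 0.65), rbinom(5, 6, 0.5), "a"),
    make_trials(rbinom(5, 14, 0.45), rbinom(5, 6, 0.5), "b")
  )
  exact <- pi_randomization_test(tr, exact = "always")
  mc <- pi_randomization_test(tr, n_permutations = 4000, exact = "never", seed = 5)
  se <- sqrt(exact$p_value * (1 - exact$p_value) / 4000)
  expect_lt(abs(mc$p_value - exact$p_value), 3 * se + 1 / 4000)
})

test_that("auto mode switches to enumeration for small instances", {
  tr <- dplyr::bind_rows(
    make_trials(c(14, 12, 15), c(4, 6, 5), "a"),
    make_trials(c(8, 9, 6), c(10, 8, 11), "b")
  )
  rt <- pi_randomization_test(tr, n_permutations = 1000) # choose(6,3) = 20 <= 1000
  expect_true(rt$exhaustive)
  rt2 <- pi_randomization_test(tr, n_permutations = 10, seed = 1)
  expect_false(rt2$exhaustive)
})

test_that("Monte-Carlo p-values are uniform under the null", {
  pvals <- numeric(400)
  for (i in seq_along(pvals)) {
    tr <- dplyr::bind_rows(
      simulate_choice_trials(6, treatment = "a", seed = 20000 + i),
      simulate_choice_trials(6, treatment = "b", seed = 40000 + i)
    )
    pvals[i] <- pi_randomization_test(tr, n_permutations = 199, exact = "never",
                                      seed = 60000 + i)$p_value
  }
  # p-values are discrete on multiples of 1/200, so KS ties are expected
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("randomization ANOVA detects a shifted group", {
  rejections <- logical(200)
  for (i in seq_along(rejections)) {
    tr <- dplyr::bind_rows(
      simulate_choice_trials(6, p_exposed_arm = 0.5, treatment = "a", seed = 3 * i),
      simulate_choice_trials(6, p_exposed_arm = 0.5, treatment = "b", seed = 3 * i + 1),
      simulate_choice_trials(6, p_exposed_arm = 0.9, treatment = "c", seed = 3 * i + 2)
    )
    # group c shifted by ~0.8 in expected PI
    p <- pi_randomization_anova(tr, n_permutations = 299, seed = 5 * i)$p_value
    rejections[i] <- p < 0.05
  }
  expect_gte(mean(rejections), 0.8)
})

test_that("blocked permutation validates block structure", {
  tr <- dplyr::bind_rows(
    make_trials(c(10, 9), c(5, 6), "a", block = c("b1", "b2")),
    make_trials(c(7, 6), c(8, 9), "b", block = c("b1", "b2"))
  )
  rt <- pi_randomization_test(tr, n_permutations = 99, seed = 1)
  expect_false(rt$exhaustive) # blocks force Monte Carlo
  expect_true(rt$p_value > 0 && rt$p_value <= 1)

  bad <- dplyr::bind_rows(
    make_trials(c(10, 9), c(5, 6), "a", block = "b1"),
    make_trials(c(7, 6), c(8, 9), "b", block = "b2")
  )
  expect_error(pi_randomization_test(bad, n_permutations = 99, seed = 1),
               class = "deathcue_block_error")
  mixed <- tr
  mixed$block[2] <- NA
  expect_error(pi_randomization_test(mixed, n_permutations = 99, seed = 1),
               class = "deathcue_block_error")
})

test_that("group-size and group-count preconditions are enforced", {
  tr <- dplyr::bind_rows(
    make_trials(10, 5, "a"),
    make_trials(c(7, 6), c(8, 9), "b")
  )
  expect_error(pi_randomization_test(tr, seed = 1), class = "deathcue_insufficient_data")
  two <- dplyr::bind_rows(make_trials(c(10, 9), c(5, 6), "a"),
                          make_trials(c(7, 6), c(8, 9), "b"))
  expect_error(pi_randomization_anova(two, seed = 1), class = "deathcue_bad_param")
})

test_that("one-sided p-values from the two tails sum to at least 1", {
  tr <- dplyr::bind_rows(
    make_trials(c(14, 12, 15, 13), c(4, 6, 5, 7), "a"),
    make_trials(c(8, 9, 6, 7), c(10, 8, 11, 12), "b")
  )
  lo <- pi_randomization_test(tr, sidedness = "one_sided_less", exact = "always")
  hi <- pi_randomization_test(tr, sidedness = "one_sided_greater", exact = "always")
  expect_gte(lo$p_value + hi$p_value, 1) # ties counted in both tails
})
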