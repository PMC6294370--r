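trial_row <- function(log_r_att, log_r_unatt = 0, task = "number") {
  tibble::tibble(task = task, log_r_att = log_r_att, log_r_unatt = log_r_unatt)
}

test_that("choice probability follows the additive cumulative-Gaussian model", {
  # symmetric point
  p0 <- observer_params(beta_num = 0, lapse = 0, mu0_num = 0)
  expect_equal(choice_probability(trial_row(0), p0)$p_test, 0.5)

  # standard-normal CDF oracle at r_att = 1.2, sigma = 0.16
  p1 <- observer_params(sigma_num = 0.16, beta_num = 0, lapse = 0)
  expect_equal(choice_probability(trial_row(log(1.2)), p1)$p_test,
               pnorm(log(1.2) / 0.16), tolerance = 1e-12)
  expect_equal(choice_probability(trial_row(log(1.2)), p1)$p_test,
               0.8727, tolerance = 1e-4)

  # lapse bounds the asymptotes at lapse/2 and 1 - lapse/2
  p2 <- observer_params(lapse = 0.1)
  expect_equal(choice_probability(trial_row(50), p2)$p_test, 0.95)
  expect_equal(choice_probability(trial_row(-50), p2)$p_test, 0.05)

  # the unattended dimension shifts the decision variable by beta * log ratio
  p3 <- observer_params(sigma_num = 0.2, beta_num = 0.5, lapse = 0)
  expect_equal(choice_probability(trial_row(0.1, log(2)), p3)$p_test,
               pnorm((0.1 + 0.5 * log(2)) / 0.2))

  expect_error(choice_probability(trial_row(Inf), p0), "ratio")
})

test_that("choice probability is monotone in the attended log-ratio", {
  params <- observer_params(sigma_num = 0.18, beta_num = 0.3, lapse = 0.05)
  for (unatt in c(-log(2), log(2))) {
    p <- choice_probability(trial_row(seq(-1, 1, 0.05), unatt), params)$p_test
    expect_true(all(diff(p) > 0))
  }
})

test_that("simulation is seed-reproducible and respects the noiseless limit", {
  des <- enumerate_design("number")
  params <- observer_params()
  t1 <- simulate_responses(des, params, seed = 11)
  t2 <- simulate_responses(des, params, seed = 11)
  expect_identical(t1, t2)
  t3 <- simulate_responses(des, params, seed = 12)
  expect_false(identical(t1$choice, t3$choice))

  # near-zero noise, zero lapse: choices are the sign of the decision variable
  det <- observer_params(sigma_num = 1e-9, sigma_size = 1e-9,
                         beta_num = 0.2, beta_size = 0.2, lapse = 0)
  tab <- simulate_responses(des, det, seed = 1)
  expect_equal(tab$choice,
               as.integer(tab$log_r_att + 0.2 * tab$log_r_unatt > 0))
})

test_that("empirical choice proportions match the generating probability", {
  # 432 draws at p = pnorm(log(1.2)/0.16) = 0.8727: 99% binomial band
  trials <- trial_row(rep(log(1.2), 432))
  params <- observer_params(sigma_num = 0.16, beta_num = 0, lapse = 0)
  p <- pnorm(log(1.2) / 0.16)
  band <- qbinom(c(0.005, 0.995), 432, p) / 432
  hits <- vapply(1:20, function(i) {
    mean(simulate_responses(trials, params, seed = 100 + i)$choice)
  }, numeric(1))
  expect_true(mean(hits >= band[1] & hits <= band[2]) >= 0.9)
})

test_that("beta = 0 makes choices independent of the unattended level", {
  des <- enumerate_design("number")
  params <- observer_params(beta_num = 0, lapse = 0.02)
  # chi-square on choice x unattended level within each ratio, pooled trials
  rejections <- vapply(1:10, function(i) {
    big <- dplyr::bind_rows(replicate(23, des, simplify = FALSE))  # ~10k trials
    tab <- simulate_responses(big, params, seed = 500 + i)
    pvals <- vapply(split(tab, tab$n_test), function(cell) {
      suppressWarnings(
        chisq.test(table(cell$choice, cell$unattended_level))$p.value
      )
    }, numeric(1))
    any(pvals < 0.01 / 6)  # Bonferroni across the 6 ratios
  }, logical(1))
  expect_lte(mean(rejections), 0.05)
})

test_that("positive beta produces a congruency effect that shrinks with ratio distance", {
  # expected error rates computed analytically from the choice probabilities
  des <- enumerate_design("size")
  params <- observer_params(sigma_size = 0.24, beta_size = 0.3, lapse = 0.02)
  probs <- choice_probability(des, params)
  probs$expected_error <- ifelse(probs$log_r_att > 0, 1 - probs$p_test,
                                 probs$p_test)
  cell <- tapply(probs$expected_error,
                 list(probs$ratio_bin, probs$congruency), mean)
  effect <- cell[, "incongruent"] - cell[, "congruent"]
  expect_true(all(effect > 0))
  expect_gt(effect[["close"]], effect[["far"]])
})

test_that("cohort simulation reproduces the group structure", {
  des <- enumerate_design("number")
  ctrl <- cohort_spec(4, "control")
  sim <- simulate_cohort(ctrl, list(number = des), seed = 3)
  expect_equal(nrow(sim$params), 4)
  expect_equal(nrow(sim$responses), 4 * 432)
  expect_equal(as.vector(table(sim$responses$subject_id)), rep(432, 4))

  # dyscalculic beta_num mixture produces both signs for large cohorts
  dys <- cohort_spec(40, "dyscalculic")
  simd <- simulate_cohort(dys, list(number = des[1:12, ]), seed = 4)
  expect_true(any(simd$params$beta_num > 0) && any(simd$params$beta_num < 0))
  # mixture centered away from zero
  expect_gt(mean(abs(simd$params$beta_num)), 0.2)

  # degenerate cohort: zero spread, all subjects identical
  deg <- cohort_spec(3, "control", sigma_num_sd = 0, sigma_size_sd = 0,
                     beta_num_sd = 0, beta_size_sd = 0, lapse_sd = 0)
  simdeg <- simulate_cohort(deg, list(number = des[1:12, ]), seed = 5)
  expect_equal(length(unique(simdeg$params$sigma_num)), 1L)
  expect_equal(length(unique(simdeg$params$beta_size)), 1L)

  # same master seed reproduces everything
  sim2 <- simulate_cohort(ctrl, list(number = des), seed = 3)
  expect_identical(sim$responses, sim2$responses)
})
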