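step_data <- function(levels = c(-0.69, -0.51, -0.18, 0.18, 0.51, 0.69),
                      n_per = 20) {
  tibble::tibble(
    log_r_att = rep(levels, each = n_per),
    choice = as.integer(rep(levels, each = n_per) > 0)
  )
}

test_that("noiseless step data recover a step at zero", {
  fit <- fit_psychometric(step_data())
  grid <- grid_config()
  # likelihood is flat between the innermost levels, so the MAP is only
  # determined up to that interval; the (symmetric) posterior mean pins zero
  expect_lte(abs(fit$pse), 0.18 + 1e-12)
  post_mean <- sum(fit$pse_marginal$pse * fit$pse_marginal$prob)
  expect_lte(abs(post_mean), diff(grid$pse[1:2]) + 1e-12)
  expect_equal(fit$sigma, min(grid$sigma))                 # scale at the floor
  expect_equal(fit$lapse, 0)
})

test_that("the JND is sigma times the 75% normal quantile on every fit", {
  des <- enumerate_design("number")
  for (i in 1:5) {
    resp <- simulate_responses(des, observer_params(sigma_num = 0.1 + 0.04 * i),
                               seed = 40 + i)
    fit <- fit_psychometric(resp)
    expect_equal(fit$jnd, fit$sigma * qnorm(0.75), tolerance = 1e-12)
    expect_equal(weber_fraction(fit), fit$jnd)
    expect_equal(weber_fraction(fit, "proportional"), expm1(fit$jnd))
  }
})

test_that("the posterior is a proper distribution with a sensible MAP", {
  des <- enumerate_design("number")
  resp <- simulate_responses(des, observer_params(sigma_num = 0.2), seed = 77)
  fit <- fit_psychometric(resp)
  expect_equal(sum(fit$pse_marginal$prob), 1, tolerance = 1e-9)
  # MAP pse within one grid cell of the marginal argmax (unimodal posterior)
  marg_map <- fit$pse_marginal$pse[which.max(fit$pse_marginal$prob)]
  expect_lte(abs(fit$pse - marg_map), diff(fit$grid$pse[1:2]) + 1e-12)
  expect_equal(fit$n_trials, 432)
})

test_that("sigma recovery is accurate at the 432-trial design (scaled-down check)", {
  des <- enumerate_design("number")
  set.seed(13)
  sig <- runif(30, 0.1, 0.3)
  err <- vapply(seq_along(sig), function(i) {
    p <- observer_params(sigma_num = sig[i], beta_num = 0, lapse = 0.02)
    fit_psychometric(simulate_responses(des, p, seed = 2000 + i))$sigma - sig[i]
  }, numeric(1))
  expect_lte(median(abs(err)), 0.03)
})

test_that("degenerate and underdetermined inputs raise errors", {
  one_level <- tibble::tibble(log_r_att = rep(0.2, 10), choice = rep(1L, 10))
  expect_error(fit_psychometric(one_level), "degenerate|levels")
  mixed_one_level <- tibble::tibble(log_r_att = rep(0.2, 10),
                                    choice = rep(c(0L, 1L), 5))
  expect_error(fit_psychometric(mixed_one_level), "levels")
})

test_that("split fits isolate the unattended magnitudes", {
  des <- enumerate_design("size")
  resp <- simulate_responses(des, observer_params(beta_size = 0.25), seed = 9)
  fs <- split_fit_by_unattended(resp, "small")
  fb <- split_fit_by_unattended(resp, "big")
  expect_equal(fs$n_trials, 216)
  expect_equal(fb$n_trials, 216)
  expect_error(split_fit_by_unattended(resp[resp$unattended_level == "big", ],
                                       "small"), "empty")
})

test_that("the additive model induces a PSE difference of 2 beta log 2", {
  # size task: unattended numerosities 5 vs 20 are log-ratios -/+ log 2
  des <- enumerate_design("size")
  beta <- 0.25
  target <- 2 * beta * log(2)
  covered <- 0; n_runs <- 10
  for (i in 1:n_runs) {
    resp <- simulate_responses(
      des, observer_params(sigma_size = 0.2, beta_size = beta, lapse = 0.02),
      seed = 300 + i
    )
    bias <- bias_estimate(resp)
    expect_gt(bias$signed_bias, 0)  # underestimation with few dots
    if (bias$ci95[1] <= target && target <= bias$ci95[2]) covered <- covered + 1
  }
  expect_gte(covered, n_runs - 2)  # 95% credible intervals
})

test_that("beta = 0 yields small PSE differences that are rarely 'reliable'", {
  des <- enumerate_design("number")
  reliable <- vapply(1:15, function(i) {
    resp <- simulate_responses(
      des, observer_params(sigma_num = 0.2, beta_num = 0, lapse = 0.02),
      seed = 700 + i
    )
    bias_estimate(resp)$reliable
  }, logical(1))
  expect_lte(mean(reliable), 0.2)
})

test_that("PSE-difference posteriors behave like convolutions", {
  # identical marginals: symmetric difference, CI covers 0, not reliable
  m <- discrete_gaussian_marginal(0.05, 0.03)
  d0 <- pse_difference(m, m)
  expect_equal(d0$posterior_mean_diff, 0, tolerance = 1e-10)
  expect_lte(d0$ci95[1], 0); expect_gte(d0$ci95[2], 0)
  expect_false(d0$reliable)
  # symmetry of the difference posterior about zero
  post <- d0$posterior
  expect_equal(post$prob, rev(post$prob), tolerance = 1e-12)

  # point masses at +0.05 and -0.05: difference 0.10, zero-width CI
  pm1 <- tibble::tibble(pse = 0.05, prob = 1)
  pm2 <- tibble::tibble(pse = -0.05, prob = 1)
  dp <- pse_difference(pm1, pm2)
  expect_equal(dp$signed_bias, 0.10)
  expect_equal(unname(dp$ci95), c(0.10, 0.10))
  expect_true(dp$reliable)

  # Gaussian closed form: N(0.08, .02^2) - N(0, .02^2) ~ N(0.08, .0283^2)
  g1 <- discrete_gaussian_marginal(0.08, 0.02)
  g2 <- discrete_gaussian_marginal(0.00, 0.02)
  dg <- pse_difference(g1, g2)
  mu <- sum(dg$posterior$diff * dg$posterior$prob)
  v <- sum(dg$posterior$diff^2 * dg$posterior$prob) - mu^2
  expect_equal(mu, 0.08, tolerance = 0.08 * 0.01)
  expect_equal(sqrt(v), 0.02 * sqrt(2), tolerance = 0.02 * sqrt(2) * 0.01)
  gauss_ci <- 0.08 + c(-1, 1) * qnorm(0.975) * 0.02 * sqrt(2)
  expect_lt(max(abs(unname(dg$ci95) - gauss_ci)), 0.011)  # one grid step
})

test_that("incommensurate grids are rejected", {
  g1 <- discrete_gaussian_marginal(0, 0.02, grid = seq(-0.6, 0.6, length.out = 121))
  g2 <- discrete_gaussian_marginal(0, 0.02, grid = seq(-0.5, 0.5, length.out = 90))
  expect_error(pse_difference(g1, g2), "commensurate")
})

test_that("tidy and glance expose the fitted quantities", {
  resp <- simulate_responses(enumerate_design("number"),
                             observer_params(), seed = 1)
  fit <- fit_psychometric(resp)
  td <- tidy(fit)
  expect_equal(td$term, c("pse", "sigma", "lapse", "jnd"))
  gl <- glance(fit)
  expect_equal(gl$sigma, fit$sigma)
  expect_s3_class(autoplot(fit), "ggplot")
})
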