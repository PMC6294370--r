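make_mini_responses <- function() {
  # 12 hand-built trials: 2 per ratio_bin x congruency cell;
  # errors only in the incongruent-close cell (both trials -> rate 0.5 each? no:
  # one error of two trials -> 0.5)
  tibble::tibble(
    log_r_att  = rep(c(0.69, -0.69, 0.51, -0.51, 0.18, -0.18), 2),
    ratio_bin  = rep(rep(c("far", "medium", "close"), each = 2), 2),
    congruency = rep(c("congruent", "incongruent"), each = 6),
    # correct everywhere except one of the two incongruent-close trials
    choice = c(1L, 0L, 1L, 0L, 1L, 0L,   # congruent: all correct
               1L, 0L, 1L, 0L, 0L, 0L)   # incongruent: error at +0.18
  )
}

test_that("congruency table counts errors by direct arithmetic", {
  tab <- congruency_table(make_mini_responses())
  expect_equal(nrow(tab), 3)
  expect_equal(tab$congruent, c(0, 0, 0))
  expect_equal(tab$congruency_effect[tab$ratio_bin == "close"], 0.5)
  expect_equal(tab$congruency_effect[tab$ratio_bin == "far"], 0)

  # noiseless unbiased observer: no errors anywhere
  des <- enumerate_design("number")
  det <- observer_params(sigma_num = 1e-9, beta_num = 0, lapse = 0)
  resp <- simulate_responses(des, det, seed = 1)
  tab0 <- congruency_table(resp)
  expect_equal(tab0$congruent, c(0, 0, 0))
  expect_equal(tab0$incongruent, c(0, 0, 0))

  expect_error(congruency_table(make_mini_responses()[1:6, ]), "empty")
})

test_that("a size-interfered observer shows graded congruency effects", {
  des <- enumerate_design("size")
  big <- dplyr::bind_rows(replicate(5, des, simplify = FALSE))
  resp <- simulate_responses(
    big, observer_params(sigma_size = 0.24, beta_size = 0.3, lapse = 0.02),
    seed = 15
  )
  tab <- congruency_table(resp)
  expect_true(all(tab$congruency_effect > 0))
  expect_gt(tab$congruency_effect[tab$ratio_bin == "close"],
            tab$congruency_effect[tab$ratio_bin == "far"])
})

test_that("cohort bias summaries match hand arithmetic", {
  b <- c(0.05, -0.03, 0.08, 0.02, -0.01)
  s <- cohort_bias_summary(tibble::tibble(signed_bias = b, unsigned_bias = abs(b)))
  expect_equal(s$t_statistic, mean(b) / (sd(b) / sqrt(5)), tolerance = 1e-12)
  expect_equal(s$df, 4)
  expect_false(s$degenerate)

  z <- cohort_bias_summary(tibble::tibble(signed_bias = rep(0, 4),
                                          unsigned_bias = rep(0, 4)))
  expect_true(z$degenerate)
  expect_equal(z$t_statistic, 0)
  expect_equal(z$n_reliable, NA_integer_)

  d <- cohort_bias_summary(tibble::tibble(signed_bias = rep(0.1, 4),
                                          unsigned_bias = rep(0.1, 4),
                                          reliable = rep(TRUE, 4)))
  expect_true(d$degenerate)
  expect_equal(d$t_statistic, Inf)
  expect_equal(d$n_reliable, 4L)
})

test_that("group mean unsigned bias dominates the absolute signed mean", {
  set.seed(31)
  for (i in 1:20) {
    b <- rnorm(10, sd = 0.3)
    s <- cohort_bias_summary(tibble::tibble(signed_bias = b,
                                            unsigned_bias = abs(b)))
    expect_gte(s$mean_unsigned, abs(s$mean_signed) - 1e-12)
  }
})

test_that("the dip statistic matches the LP brute force", {
  # n = 2: the lower bound 1/(2n) is attained
  expect_equal(dip_statistic(c(0, 1)), 0.25)
  expect_equal(dip_lp_oracle(c(0, 1)), 0.25, tolerance = 1e-9)

  # equally spaced samples attain 1/(2n) for any n
  for (n in c(4, 9, 16)) {
    expect_lt(abs(dip_statistic((1:n) / n) - 1 / (2 * n)), 1e-8)
  }

  # randomized cross-validation against the independent LP oracle
  set.seed(41)
  for (rep in 1:25) {
    x <- round(runif(sample(4:10, 1)), 2)
    if (length(unique(x)) < 2) next
    expect_equal(dip_statistic(x), dip_lp_oracle(x), tolerance = 1e-7)
  }
})

test_that("dip statistic respects its bounds", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(4:30, 1)
    x <- rnorm(n)
    d <- dip_statistic(x)
    expect_gte(d, 1 / (2 * n) - 1e-9)
    expect_lte(d, 0.25 + 1e-9)
  }
})

test_that("dip test separates unimodal from well-separated bimodal samples", {
  # unimodal Gaussian, n = 10: non-significant in nearly all runs
  # (shared Monte-Carlo null: the uniform null for fixed n is one distribution)
  set.seed(55)
  null10 <- replicate(2000, dip_statistic(runif(10)))
  p_uni <- vapply(1:100, function(i) {
    mean(null10 >= dip_statistic(rnorm(10)))
  }, numeric(1))
  expect_gte(mean(p_uni > 0.05), 0.95)

  # well-separated mixture (+/- 3 sd), n = 50: strongly significant
  set.seed(56)
  x <- c(rnorm(25, -3), rnorm(25, 3))
  res <- dip_test(x, n_replicates = 2000)
  expect_lt(res$p_value, 0.01)
  expect_equal(res$n_replicates, 2000)

  expect_error(dip_test(c(1, 2, 3)), "n >= 4")
  expect_error(dip_test(rep(1, 10)), "identical")
})

test_that("the task-by-group contrast recovers hand-built cell means", {
  biases <- tibble::tibble(
    subject_id = rep(sprintf("s%02d", 1:8), each = 2),
    group = rep(c("a", "b"), each = 8),
    task = rep(c("number", "size"), 8),
    unsigned_bias = c(rep(c(1, 1), 4),      # group a: number 1, size 1
                      rep(c(2, 1), 4))      # group b: number 2, size 1
  )
  set.seed(61)
  res <- group_contrast_unsigned(biases, n_permutations = 500,
                                 group_order = c("a", "b"))
  expect_equal(res$interaction_contrast, 1)
  expect_equal(nrow(res$cells), 4)

  # identical groups: contrast 0 and an unremarkable permutation p
  same <- dplyr::mutate(biases, unsigned_bias = rep(c(1.5, 1), 8))
  set.seed(62)
  res0 <- group_contrast_unsigned(same, n_permutations = 200,
                                  group_order = c("a", "b"))
  expect_equal(res0$interaction_contrast, 0)
  expect_equal(res0$p_value, 1)  # every permuted contrast is also 0

  lone <- biases[biases$subject_id %in% c("s01", "s05", "s06", "s07", "s08"), ]
  expect_error(group_contrast_unsigned(lone, group_order = c("a", "b")),
               ">= 2 subjects")
})
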