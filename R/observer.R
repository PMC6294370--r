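#' Synthetic-observer parameters
#'
#' A parametric stand-in for a human observer in the two comparison tasks.
#' On each trial the observer forms a noisy decision variable
#' `log r_att + beta * log r_unatt - mu0` (natural-log ratios of test to
#' reference on the attended and unattended dimensions, the size dimension
#' always expressed as mean item *area*) and chooses the test stimulus when
#' it exceeds zero, with Gaussian internal noise of scale `sigma` and a
#' small symmetric lapse rate.
#'
#' The additive-in-log interference weight `beta` is the minimal generative
#' model whose induced shift of the point of subjective equality is
#' analytically `-beta * log r_unatt`, so a design with unattended levels at
#' ratios 0.5 and 2 yields a signed bias (PSE_small - PSE_big) of exactly
#' `2 * beta * log 2` — a closed form used throughout the recovery tests.
#'
#' @param sigma_num,sigma_size Internal noise SD in log units per task
#'   (> 0).  The Weber fraction in log units is `0.6745 * sigma`, so
#'   sigma of 0.22-0.34 corresponds to Weber fractions of ~0.15-0.23.
#' @param beta_num Interference weight of the log size(area)-ratio on
#'   number decisions (signed; ~0 in typical adults).
#' @param beta_size Interference weight of the log number-ratio on size
#'   decisions (positive: more dots look bigger).
#' @param lapse Stimulus-independent response probability in `[0, 0.1]`,
#'   split equally between the two asymptotes.
#' @param mu0_num,mu0_size Constant criterion offsets (log units).
#' @return An object of class `observer_params`.
#' @examples
#' observer_params(sigma_num = 0.24, beta_size = 0.2)
#' @export
observer_params <- function(sigma_num = 0.24, sigma_size = 0.24,
                            beta_num = 0, beta_size = 0.2,
                            lapse = 0.02, mu0_num = 0, mu0_size = 0) {
  stopifnot(sigma_num > 0, sigma_size > 0, lapse >= 0, lapse <= 0.1)
  structure(
    list(sigma_num = sigma_num, sigma_size = sigma_size,
         beta_num = beta_num, beta_size = beta_size,
         lapse = lapse, mu0_num = mu0_num, mu0_size = mu0_size),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  cat("<observer_params>\n")
  cat(sprintf("  number: sigma = %.3f, beta = %+.3f, mu0 = %+.3f\n",
              x$sigma_num, x$beta_num, x$mu0_num))
  cat(sprintf("  size:   sigma = %.3f, beta = %+.3f, mu0 = %+.3f\n",
              x$sigma_size, x$beta_size, x$mu0_size))
  cat(sprintf("  lapse = %.3f\n", x$lapse))
  invisible(x)
}

#' Probability of choosing the test stimulus
#'
#' For each trial, `P(choose test) = lapse/2 + (1 - lapse) *
#' Phi((log r_att + beta * log r_unatt - mu0) / sigma)`, with `beta`,
#' `sigma` and `mu0` taken for the trial's task.  Probabilities are bounded
#' in `[lapse/2, 1 - lapse/2]`.
#'
#' @param trials A design tibble from [enumerate_design()] (needs columns
#'   `task`, `log_r_att`, `log_r_unatt`).
#' @param params An [observer_params()].
#' @return The input tibble with a `p_test` column appended.
#' @examples
#' des <- enumerate_design("number")
#' head(choice_probability(des, observer_params())$p_test)
#' @export
choice_probability <- function(trials, params) {
  stopifnot(inherits(params, "observer_params"))
  if (any(!is.finite(trials$log_r_att)) || any(!is.finite(trials$log_r_unatt))) {
    stop("non-positive stimulus ratios", call. = FALSE)
  }
  is_num <- trials$task == "number"
  sigma <- ifelse(is_num, params$sigma_num, params$sigma_size)
  beta <- ifelse(is_num, params$beta_num, params$beta_size)
  mu0 <- ifelse(is_num, params$mu0_num, params$mu0_size)
  z <- (trials$log_r_att + beta * trials$log_r_unatt - mu0) / sigma
  p <- params$lapse / 2 + (1 - params$lapse) * stats::pnorm(z)
  dplyr::mutate(trials, p_test = p)
}

#' Simulate binary choices for a trial design
#'
#' One Bernoulli draw per trial at the [choice_probability()].  Uses the R
#' random number stream; set a seed (or pass `seed`) for reproducibility.
#'
#' @param design A design tibble from [enumerate_design()].
#' @param params An [observer_params()].
#' @param seed Optional integer seed applied locally (the global RNG state
#'   is restored afterwards).
#' @return A response table: the design plus `p_test` and `choice`
#'   (1 = chose test, i.e. judged the test "greater").
#' @export
simulate_responses <- function(design, params, seed = NULL) {
  probs <- choice_probability(design, params)
  draw <- function() stats::rbinom(nrow(probs), 1L, probs$p_test)
  choice <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  dplyr::mutate(probs, choice = choice)
}

# evaluate expr under a temporary RNG state
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Cohort specification for the synthetic observer
#'
#' Describes the distribution of observer parameters across a simulated
#' group.  Control-like cohorts draw the number-task interference weight
#' tightly around zero and a positive size-task weight (numerosity inflates
#' perceived mean size).  Dyscalculic-like cohorts draw the number-task
#' weight from a two-component mixture with opposite-sign means, emulating
#' subjects who strongly over- or under-estimate numerosity depending on
#' item size, and have coarser number acuity.
#'
#' Default magnitudes: noise SDs give Weber fractions around 0.16 (controls)
#' and 0.2 (dyscalculics, number task); the size-task weight 0.2 induces a
#' signed size bias of `2 * 0.2 * log 2 ~ 0.28` log units; the mixture at
#' `+/-0.35` induces unsigned number biases near 0.49 log units with signs
#' cancelling on average.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param group `"control"` or `"dyscalculic"`.
#' @param sigma_num_mean,sigma_num_sd,sigma_size_mean,sigma_size_sd Normal
#'   distribution of internal noise per task (truncated at 0.05).
#' @param beta_num_mean,beta_num_sd Number-task interference weight:
#'   Normal for controls; for dyscalculics these give the component SD and
#'   the mixture is `0.5 N(-beta_num_mix, sd) + 0.5 N(+beta_num_mix, sd)`.
#' @param beta_num_mix Absolute mixture-component mean (dyscalculic only).
#' @param mix_weight Share of subjects in the positive mixture component.
#'   Membership is stratified (`round(n * mix_weight)` subjects positive,
#'   shuffled), so both modes are populated even in small cohorts.
#' @param beta_size_mean,beta_size_sd Size-task interference weight.
#' @param lapse_mean,lapse_sd Lapse distribution (truncated to `[0, 0.1]`).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects,
                        group = c("control", "dyscalculic"),
                        sigma_num_mean = if (group == "control") 0.24 else 0.30,
                        sigma_num_sd = 0.04,
                        sigma_size_mean = 0.24,
                        sigma_size_sd = 0.04,
                        beta_num_mean = 0,
                        beta_num_sd = if (group == "control") 0.03 else 0.08,
                        beta_num_mix = 0.35,
                        mix_weight = 0.5,
                        beta_size_mean = 0.2,
                        beta_size_sd = 0.06,
                        lapse_mean = 0.02,
                        lapse_sd = 0.015) {
  group <- match.arg(group)
  stopifnot(n_subjects >= 1, mix_weight >= 0, mix_weight <= 1)
  structure(
    list(n_subjects = as.integer(n_subjects), group = group,
         sigma_num_mean = sigma_num_mean, sigma_num_sd = sigma_num_sd,
         sigma_size_mean = sigma_size_mean, sigma_size_sd = sigma_size_sd,
         beta_num_mean = beta_num_mean, beta_num_sd = beta_num_sd,
         beta_num_mix = beta_num_mix, mix_weight = mix_weight,
         beta_size_mean = beta_size_mean, beta_size_sd = beta_size_sd,
         lapse_mean = lapse_mean, lapse_sd = lapse_sd),
    class = "cohort_spec"
  )
}

#' Draw observer parameters for one cohort
#'
#' @param cohort A [cohort_spec()].
#' @return A tibble with one row per subject (`subject_id`, `group`, the
#'   drawn parameters, and a `params` list-column of [observer_params()]).
#' @keywords internal
draw_cohort_params <- function(cohort) {
  n <- cohort$n_subjects
  trunc_norm <- function(n, mean, sd, lo, hi) {
    pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
  }
  sigma_num <- trunc_norm(n, cohort$sigma_num_mean, cohort$sigma_num_sd, 0.05, Inf)
  sigma_size <- trunc_norm(n, cohort$sigma_size_mean, cohort$sigma_size_sd, 0.05, Inf)
  if (cohort$group == "dyscalculic") {
    # stratified mixture membership: round(n * w) subjects in the positive
    # component, the rest negative, in shuffled order.  With i.i.d. draws a
    # small cohort often lands 7/3 or worse, and a 3-subject minor mode is
    # undetectable by a dip test at n = 10 however well separated; the
    # cohorts this emulates show both modes populated.
    n_pos <- round(n * cohort$mix_weight)
    comp <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    beta_num <- stats::rnorm(n, ifelse(comp == 1, cohort$beta_num_mix,
                                       -cohort$beta_num_mix), cohort$beta_num_sd)
  } else {
    beta_num <- stats::rnorm(n, cohort$beta_num_mean, cohort$beta_num_sd)
  }
  beta_size <- stats::rnorm(n, cohort$beta_size_mean, cohort$beta_size_sd)
  lapse <- trunc_norm(n, cohort$lapse_mean, cohort$lapse_sd, 0, 0.1)
  tibble::tibble(
    subject_id = sprintf("%s_%02d", substr(cohort$group, 1, 4), seq_len(n)),
    group = cohort$group,
    sigma_num = sigma_num, sigma_size = sigma_size,
    beta_num = beta_num, beta_size = beta_size, lapse = lapse,
    params = purrr::pmap(
      list(sigma_num, sigma_size, beta_num, beta_size, lapse),
      function(sn, ss, bn, bs, l) {
        observer_params(sigma_num = sn, sigma_size = ss, beta_num = bn,
                        beta_size = bs, lapse = l)
      }
    )
  )
}

#' Simulate a cohort of synthetic observers
#'
#' Draws per-subject parameters from the cohort distributions, then
#' simulates one response table per subject and task.  Per-subject seeds
#' are derived deterministically from the master seed, the subject index
#' and the task, so individual subjects are reproducible even when the
#' cohort is resized.
#'
#' @param cohort A [cohort_spec()].
#' @param designs A named list of design tibbles (e.g.
#'   `list(number = enumerate_design("number"), size =
#'   enumerate_design("size"))`), or a single design tibble.
#' @param seed Master integer seed.
#' @return A list with `params` (tibble, one row per subject) and
#'   `responses` (one tibble binding all subjects and tasks, with
#'   `subject_id` and `group` columns).
#' @export
simulate_cohort <- function(cohort, designs, seed = 1) {
  stopifnot(inherits(cohort, "cohort_spec"))
  if (is.data.frame(designs)) {
    designs <- stats::setNames(list(designs), designs$task[1])
  }
  params <- with_local_seed(derive_seed(seed, 0L, 0L), draw_cohort_params(cohort))
  responses <- purrr::imap(designs, function(des, task_name) {
    task_idx <- match(task_name, c("number", "size"))
    purrr::map2_dfr(seq_len(nrow(params)), params$params, function(i, p) {
      tab <- simulate_responses(des, p, seed = derive_seed(seed, i, task_idx))
      dplyr::mutate(tab,
                    subject_id = params$subject_id[i],
                    group = params$group[i],
                    .before = 1)
    })
  })
  list(params = params, responses = dplyr::bind_rows(responses))
}

# deterministic per-subject, per-task seed below 2^31
derive_seed <- function(master, subject_index, task_index) {
  as.integer((as.numeric(master) * 7919 + subject_index * 131 +
                task_index * 17 + 1) %% 2147483647)
}
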