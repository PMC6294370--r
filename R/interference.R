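#' Error rates by ratio bin and congruency
#'
#' An error is a choice inconsistent with the true sign of the attended
#' log-ratio (e.g. calling the 5-dot test "more numerous" than the 10-dot
#' reference).  Responses are split by ratio bin (far/medium/close) and
#' congruency; the congruency effect is the incongruent-minus-congruent
#' error-rate difference per bin.
#'
#' @param responses A response table with `log_r_att`, `choice`,
#'   `congruency` and `ratio_bin` columns.
#' @return A tibble with one row per ratio bin: error rates for congruent
#'   and incongruent trials and their difference `congruency_effect`.
#' @export
congruency_table <- function(responses) {
  stopifnot(all(c("log_r_att", "choice", "congruency", "ratio_bin") %in%
                  names(responses)))
  if (any(responses$log_r_att == 0)) {
    stop("attended ratio equal to 1: error undefined", call. = FALSE)
  }
  tab <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(responses,
                    error = (.data$choice == 1) != (.data$log_r_att > 0)),
      .data$ratio_bin, .data$congruency
    ),
    n_trials = dplyr::n(), error_rate = mean(.data$error), .groups = "drop"
  )
  full <- tidyr::expand_grid(ratio_bin = c("far", "medium", "close"),
                             congruency = c("congruent", "incongruent"))
  if (nrow(dplyr::anti_join(full, tab, by = c("ratio_bin", "congruency"))) > 0) {
    stop("empty ratio-bin x congruency cell", call. = FALSE)
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(tab, -"n_trials"),
    names_from = "congruency", values_from = "error_rate"
  )
  out <- dplyr::mutate(wide,
    congruency_effect = .data$incongruent - .data$congruent,
    ratio_bin = factor(.data$ratio_bin, levels = c("far", "medium", "close"))
  )
  dplyr::arrange(out, .data$ratio_bin)
}

#' Group summary of signed and unsigned biases
#'
#' One-sample t-test of the signed biases against zero, plus the count of
#' subjects whose individual bias was flagged reliable (95% credible
#' interval excluding zero).
#'
#' @param per_subject A tibble with columns `signed_bias`, `unsigned_bias`
#'   and optionally `reliable` (e.g. row-bound [tidy.bias_estimate()]
#'   outputs), or a list of `bias_estimate` objects.
#' @return One-row tibble: `n`, `mean_signed`, `mean_unsigned`,
#'   `t_statistic`, `df`, `p_value`, `n_reliable`, `degenerate` (TRUE when
#'   the signed biases have zero variance, making t undefined/infinite).
#' @export
cohort_bias_summary <- function(per_subject) {
  if (is.list(per_subject) && !is.data.frame(per_subject)) {
    per_subject <- dplyr::bind_rows(lapply(per_subject, tidy))
  }
  stopifnot(nrow(per_subject) >= 2)
  sb <- per_subject$signed_bias
  n <- length(sb)
  sdv <- stats::sd(sb)
  degenerate <- sdv == 0
  if (degenerate) {
    tstat <- if (mean(sb) == 0) 0 else Inf * sign(mean(sb))
    pval <- if (mean(sb) == 0) 1 else 0
  } else {
    tt <- stats::t.test(sb)
    tstat <- unname(tt$statistic)
    pval <- tt$p.value
  }
  tibble::tibble(
    n = n,
    mean_signed = mean(sb),
    mean_unsigned = mean(per_subject$unsigned_bias),
    t_statistic = tstat,
    df = n - 1,
    p_value = pval,
    n_reliable = if ("reliable" %in% names(per_subject))
      sum(per_subject$reliable) else NA_integer_,
    degenerate = degenerate
  )
}

#' Hartigan's dip statistic
#'
#' The dip is the smallest sup-norm distance between the empirical CDF and
#' any unimodal CDF (convex below its mode, concave above).  It lies in
#' `[1/(2n), 0.25]` for samples with at least two distinct values and
#' grows with bimodality.  Computed by bisection on the band half-width,
#' deciding feasibility with greatest-convex-minorant /
#' least-concave-majorant scans (compiled code; validated against a
#' linear-programming oracle).
#'
#' @param x Numeric vector (n >= 2 after removing non-finite values).
#' @return The dip statistic (a single number).
#' @examples
#' dip_statistic(c(0, 1))            # 0.25
#' dip_statistic(seq(0, 1, 0.1))     # 1/(2n)
#' @export
dip_statistic <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least 2 finite values", call. = FALSE)
  .dip_stat_cpp(as.numeric(x))
}

#' Dip test of unimodality with a Monte-Carlo uniform null
#'
#' Tests whether a sample (here typically per-subject signed biases) is
#' consistent with a unimodal distribution.  The p-value is the fraction
#' of uniform(0, 1) samples of the same size whose dip is at least as
#' large as the observed dip (the uniform is the least favourable unimodal
#' null).  Uses the R random number stream; set a seed for
#' reproducibility.
#'
#' @param x Numeric vector, n >= 4, not all values identical.
#' @param n_replicates Monte-Carlo replicates (default 2000).
#' @return A `dip_result`: one-row tibble with `dip_statistic`, `p_value`,
#'   `n`, `n_replicates`.
#' @examples
#' set.seed(1)
#' dip_test(rnorm(20))$p_value             # unimodal: large p
#' dip_test(c(rnorm(25, -3), rnorm(25, 3)))$p_value  # bimodal: small p
#' @export
dip_test <- function(x, n_replicates = 2000) {
  x <- x[is.finite(x)]
  if (length(x) < 4) stop("dip test needs n >= 4 finite values", call. = FALSE)
  if (length(unique(x)) == 1) stop("all values identical", call. = FALSE)
  obs <- .dip_stat_cpp(as.numeric(x))
  null_dips <- .dip_null_cpp(length(x), n_replicates)
  out <- tibble::tibble(
    dip_statistic = obs,
    p_value = mean(null_dips >= obs),
    n = length(x),
    n_replicates = n_replicates
  )
  class(out) <- c("dip_result", class(out))
  out
}

#' Task-by-group interaction on unsigned biases
#'
#' Compares the interference magnitude (unsigned bias) across two groups
#' and the two tasks with the targeted difference-of-differences contrast
#' `(groupB - groupA on the number task) - (groupB - groupA on the size
#' task)`, and a permutation p-value obtained by shuffling group labels at
#' the subject level.  A positive contrast means group B's excess
#' interference is specific to the number task — the headline signature
#' distinguishing dyscalculic-like from control-like cohorts.
#'
#' @param biases Tibble with columns `subject_id`, `group` (two levels),
#'   `task` (`"number"`, `"size"`), `unsigned_bias` — one row per subject
#'   and task.
#' @param n_permutations Label permutations for the p-value.
#' @param group_order Optional character vector of length 2 giving
#'   (groupA, groupB); defaults to sorted unique levels.
#' @return A list with `cells` (mean +/- sem per group x task),
#'   `interaction_contrast`, `p_value`, `n_permutations`.
#' @export
group_contrast_unsigned <- function(biases, n_permutations = 10000,
                                    group_order = NULL) {
  stopifnot(all(c("subject_id", "group", "task", "unsigned_bias") %in%
                  names(biases)))
  groups <- group_order %||% sort(unique(biases$group))
  stopifnot(length(groups) == 2)
  counts <- dplyr::count(dplyr::distinct(biases, .data$subject_id, .data$group),
                         .data$group)
  if (any(counts$n < 2)) stop("each group needs >= 2 subjects", call. = FALSE)

  cells <- dplyr::summarise(
    dplyr::group_by(biases, .data$group, .data$task),
    n = dplyr::n(),
    mean_unsigned = mean(.data$unsigned_bias),
    sem = stats::sd(.data$unsigned_bias) / sqrt(dplyr::n()),
    .groups = "drop"
  )

  wide <- tidyr::pivot_wider(
    dplyr::select(biases, "subject_id", "group", "task", "unsigned_bias"),
    names_from = "task", values_from = "unsigned_bias"
  )
  contrast_fun <- function(labels) {
    a <- labels == groups[1]
    (mean(wide$number[!a]) - mean(wide$number[a])) -
      (mean(wide$size[!a]) - mean(wide$size[a]))
  }
  obs <- contrast_fun(wide$group)
  perm <- vapply(seq_len(n_permutations), function(i) {
    contrast_fun(sample(wide$group))
  }, numeric(1))
  list(
    cells = cells,
    interaction_contrast = obs,
    p_value = mean(abs(perm) >= abs(obs) - 1e-12),
    n_permutations = n_permutations,
    groups = groups
  )
}
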