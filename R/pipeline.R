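#' Fit one subject's response tables and estimate interference biases
#'
#' For each task present in the responses: a full-data psychometric fit
#' (precision: sigma, JND/Weber fraction) and the unattended-split fits
#' convolved into a [pse_difference()] bias estimate.
#'
#' @param responses Response table for one subject (may contain both
#'   tasks).
#' @param grid A [grid_config()].
#' @return A tibble with one row per task: fit parameters plus signed and
#'   unsigned bias, credible interval, reliability flag.
#' @export
subject_summary <- function(responses, grid = grid_config()) {
  purrr::map_dfr(split(responses, responses$task), function(tab) {
    full <- fit_psychometric(tab, grid = grid)
    bias <- bias_estimate(tab, grid = grid)
    dplyr::bind_cols(
      tibble::tibble(task = tab$task[1]),
      glance(full),
      tidy(bias)
    )
  })
}

#' Run the full simulated experiment
#'
#' Orchestrates design enumeration, cohort simulation (a control-like and
#' a dyscalculic-like group, both tasks, 432 trials per task), per-subject
#' psychometric fits and bias estimates, congruency tables, group bias
#' summaries, dip tests on the signed-bias distributions, the
#' task-by-group interaction contrast on unsigned biases, and (optionally)
#' correlations with a synthetic calculation-ability score.  The master
#' seed drives every stage; a rerun with the same seed reproduces the
#' report exactly.
#'
#' The optional synthetic ability score is a stand-in for an external
#' calculation measure: an inverse-efficiency-like score generated as a
#' monotone function of the subject's true number-task interference weight
#' plus noise.  It exists so the correlation stage is exercisable without
#' human data; it is not an empirical claim.
#'
#' @param n_control,n_dyscalculic Cohort sizes (defaults 14 and 10).
#' @param seed Master integer seed.
#' @param config A [design_config()].
#' @param grid A [grid_config()].
#' @param control,dyscalculic Optional [cohort_spec()] overrides.
#' @param synthetic_scores Generate the synthetic ability score and the
#'   correlation report (default TRUE).
#' @param out_dir Optional directory: writes tidy CSVs and a summary JSON.
#' @return A `run_report` list: `subjects`, `fits`, `congruency`,
#'   `group_summaries`, `dip_tests`, `interaction`, `correlations`,
#'   `summary` (plain list, JSON-serialisable), `seed`.
#' @export
run_experiment <- function(n_control = 14, n_dyscalculic = 10, seed = 1,
                           config = design_config(), grid = grid_config(),
                           control = NULL, dyscalculic = NULL,
                           synthetic_scores = TRUE, out_dir = NULL) {
  control <- control %||% cohort_spec(n_control, "control")
  dyscalculic <- dyscalculic %||% cohort_spec(n_dyscalculic, "dyscalculic")
  stopifnot(inherits(control, "cohort_spec"), inherits(dyscalculic, "cohort_spec"))

  designs <- list(number = enumerate_design("number", config),
                  size = enumerate_design("size", config))

  sim_ctrl <- simulate_cohort(control, designs, seed = derive_seed(seed, 1L, 1L))
  sim_dys <- simulate_cohort(dyscalculic, designs, seed = derive_seed(seed, 2L, 1L))
  params <- dplyr::bind_rows(sim_ctrl$params, sim_dys$params)
  responses <- dplyr::bind_rows(sim_ctrl$responses, sim_dys$responses)

  fits <- purrr::map_dfr(split(responses, responses$subject_id), function(tab) {
    dplyr::mutate(subject_summary(tab, grid = grid),
                  subject_id = tab$subject_id[1], group = tab$group[1],
                  .before = 1)
  })

  congruency <- purrr::map_dfr(
    split(responses, list(responses$group, responses$task)),
    function(tab) {
      dplyr::mutate(congruency_table(tab),
                    group = tab$group[1], task = tab$task[1], .before = 1)
    }
  )

  group_summaries <- purrr::map_dfr(
    split(fits, list(fits$group, fits$task)),
    function(tab) {
      dplyr::mutate(cohort_bias_summary(tab),
                    group = tab$group[1], task = tab$task[1], .before = 1)
    }
  )

  dip_tests <- purrr::map_dfr(
    split(fits, list(fits$group, fits$task)),
    function(tab) {
      res <- with_local_seed(
        derive_seed(seed, 3L, match(tab$task[1], c("number", "size"))),
        dip_test(tab$signed_bias)
      )
      dplyr::mutate(res, group = tab$group[1], task = tab$task[1], .before = 1)
    }
  )

  interaction <- with_local_seed(
    derive_seed(seed, 4L, 1L),
    group_contrast_unsigned(
      dplyr::select(fits, "subject_id", "group", "task", "unsigned_bias"),
      group_order = c("control", "dyscalculic")
    )
  )

  correlations <- NULL
  scores <- NULL
  if (synthetic_scores) {
    scores <- with_local_seed(derive_seed(seed, 5L, 1L), {
      wide <- tidyr::pivot_wider(
        dplyr::select(fits, "subject_id", "group", "task",
                      "unsigned_bias", "jnd"),
        names_from = "task", values_from = c("unsigned_bias", "jnd"),
        names_glue = "{.value}_{substr(task, 1, 4)}"
      )
      wide <- dplyr::rename(wide,
        unsigned_bias_num = "unsigned_bias_numb",
        jnd_num = "jnd_numb"
      )
      # synthetic calculation IE score: worse (larger) with stronger
      # number-task interference weight, plus noise
      beta_mag <- abs(params$beta_num[match(wide$subject_id, params$subject_id)])
      dplyr::mutate(wide,
        score = 600 + 900 * beta_mag + stats::rnorm(dplyr::n(), 0, 60),
        group_num = as.integer(.data$group == "dyscalculic")
      )
    })
    correlations <- correlation_report(
      scores,
      measures = c("unsigned_bias_num", "unsigned_bias_size",
                   "jnd_num", "jnd_size"),
      covariate_cols = "group_num"
    )
  }

  summary <- list(
    schema_version = "1.0",
    seed = seed,
    n_control = control$n_subjects,
    n_dyscalculic = dyscalculic$n_subjects,
    n_trials_per_task = nrow(designs$number),
    group_summaries = as.data.frame(group_summaries),
    dip_tests = as.data.frame(dip_tests),
    interaction_contrast = interaction$interaction_contrast,
    interaction_p = interaction$p_value
  )

  report <- structure(
    list(subjects = params, fits = fits, congruency = congruency,
         group_summaries = group_summaries, dip_tests = dip_tests,
         interaction = interaction, correlations = correlations,
         scores = scores, summary = summary, seed = seed),
    class = "run_report"
  )

  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "\n")
  cat(sprintf("  %d control + %d dyscalculic subjects, %d trials/task\n",
              x$summary$n_control, x$summary$n_dyscalculic,
              x$summary$n_trials_per_task))
  cat("  group bias summaries:\n")
  print(x$group_summaries)
  cat(sprintf("  task x group interaction on unsigned bias: %+.4f (p = %.4f)\n",
              x$interaction$interaction_contrast, x$interaction$p_value))
  invisible(x)
}

#' Write a run report to disk
#'
#' Tidy CSVs for the per-subject fits, congruency tables, group summaries
#' and correlations, plus a machine-readable `summary.json`.
#'
#' @param report A `run_report` from [run_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(dplyr::select(report$subjects, -"params"),
                   file.path(out_dir, "subjects.csv"))
  readr::write_csv(report$fits, file.path(out_dir, "subject_fits.csv"))
  readr::write_csv(report$congruency, file.path(out_dir, "congruency.csv"))
  readr::write_csv(report$group_summaries, file.path(out_dir, "group_summaries.csv"))
  readr::write_csv(report$dip_tests, file.path(out_dir, "dip_tests.csv"))
  if (!is.null(report$correlations)) {
    readr::write_csv(report$correlations, file.path(out_dir, "correlations.csv"))
  }
  jsonlite::write_json(report$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Write a response table to CSV
#'
#' @param responses A response table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path)
  invisible(path)
}

response_schema <- c(
  "task", "trial", "n_test", "d_test", "n_ref", "d_ref", "attended_ratio",
  "log_r_att", "log_r_unatt", "unattended_level", "congruency", "ratio_bin",
  "field_diameter", "position_factor", "session", "repetition", "choice"
)

#' Read and validate a response-table CSV
#'
#' Checks the documented schema, recomputes the congruency and ratio-bin
#' labels from the log ratios and cross-checks them against the file
#' (rejecting inconsistent rows with their indices).  Unknown extra
#' columns are preserved with a warning.
#'
#' @param path CSV file written by [write_responses()] (or conforming to
#'   the same schema).
#' @return A validated response tibble.
#' @export
ingest_responses <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(response_schema, names(tab))
  if (length(missing)) {
    stop("missing required columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(tab), c(response_schema, "subject_id", "group", "p_test"))
  if (length(extra)) {
    warning("unknown columns preserved: ", paste(extra, collapse = ", "),
            call. = FALSE)
  }
  if (!all(tab$choice %in% c(0, 1))) {
    stop("choice must be 0/1", call. = FALSE)
  }
  if (any(!is.finite(tab$log_r_att)) || any(tab$log_r_att == 0)) {
    stop("invalid attended log-ratio", call. = FALSE)
  }
  expected_congruency <- ifelse(
    sign(tab$log_r_att) == sign(tab$log_r_unatt), "congruent", "incongruent"
  )
  bad <- which(tab$congruency != expected_congruency)
  if (length(bad)) {
    stop("inconsistent congruency labels at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  expected_bin <- unsplit(
    lapply(split(tab$log_r_att, tab$task), bin_ratios), tab$task
  )
  bad <- which(tab$ratio_bin != expected_bin)
  if (length(bad)) {
    stop("inconsistent ratio_bin labels at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tab
}
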