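#' Enumerate the full factorial trial design for one task
#'
#' Crosses the 6 attended-dimension ratios with 2 unattended magnitudes,
#' 2 total field areas, 2 spatial positions/presentation orders, 3
#' repetitions and 3 sessions, giving 432 trials per task (each ratio
#' presented 72 times).  Every record carries its congruency label
#' (congruent when the attended and unattended dimensions deviate from the
#' reference in the same direction) and its ratio bin (far/medium/close,
#' pairing symmetric ratios around 1).
#'
#' The attended stimulus axis is the natural log of the test/reference
#' ratio.  Numerosity ratios are exact (e.g. 5/10); size ratios are
#' expressed as mean item *area* ratios, i.e. `2 * log(d_test / d_ref)`,
#' so that the two tasks share a comparable log scale.
#'
#' @param task `"number"` or `"size"`.
#' @param config A [design_config()].
#' @return A tibble with one row per trial: `task`, `trial`, `n_test`,
#'   `d_test`, `n_ref`, `d_ref`, `attended_ratio`, `log_r_att`,
#'   `log_r_unatt`, `unattended_level`, `congruency`, `ratio_bin`,
#'   `field_diameter`, `position_factor`, `session`, `repetition`.
#' @examples
#' des <- enumerate_design("number")
#' nrow(des)              # 432
#' table(des$n_test)      # 72 per ratio
#' @export
enumerate_design <- function(task = c("number", "size"), config = design_config()) {
  task <- match.arg(task)
  validate_design_config(config)

  if (task == "number") {
    levels_att <- tibble::tibble(
      n_test = config$number_task_counts,
      d_test_small = unname(config$number_task_sizes["small"]),
      d_test_big = unname(config$number_task_sizes["big"])
    )
    cells <- tidyr::expand_grid(
      n_test = config$number_task_counts,
      unattended_level = c("small", "big"),
      field_diameter = config$field_diameters,
      position_factor = c("first_left", "second_right"),
      session = seq_len(config$sessions),
      repetition = seq_len(config$repetitions_per_session)
    )
    cells <- dplyr::mutate(cells,
      d_test = unname(config$number_task_sizes[.data$unattended_level]),
      log_r_att = log(.data$n_test / config$reference_n),
      log_r_unatt = 2 * log(.data$d_test / config$reference_diameter)
    )
  } else {
    cells <- tidyr::expand_grid(
      d_test = config$size_task_diameters,
      unattended_level = c("small", "big"),
      field_diameter = config$field_diameters,
      position_factor = c("first_left", "second_right"),
      session = seq_len(config$sessions),
      repetition = seq_len(config$repetitions_per_session)
    )
    cells <- dplyr::mutate(cells,
      n_test = unname(config$size_task_counts[.data$unattended_level]),
      log_r_att = 2 * log(.data$d_test / config$reference_diameter),
      log_r_unatt = log(.data$n_test / config$reference_n)
    )
  }

  out <- dplyr::mutate(cells,
    task = task,
    n_ref = config$reference_n,
    d_ref = config$reference_diameter,
    attended_ratio = exp(.data$log_r_att),
    congruency = dplyr::if_else(
      sign(.data$log_r_att) == sign(.data$log_r_unatt),
      "congruent", "incongruent"
    ),
    ratio_bin = bin_ratios(.data$log_r_att)
  )
  if (any(out$log_r_att == 0)) {
    stop("test and reference must never be equal on the attended dimension",
         call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$session, .data$repetition)
  out <- dplyr::mutate(out, trial = dplyr::row_number())
  dplyr::select(
    out, "task", "trial", "n_test", "d_test", "n_ref", "d_ref",
    "attended_ratio", "log_r_att", "log_r_unatt", "unattended_level",
    "congruency", "ratio_bin", "field_diameter", "position_factor",
    "session", "repetition"
  )
}

# Pair symmetric ratios into far/medium/close by |log ratio|: the two most
# extreme ratios are "far", the middle two "medium", the two nearest the
# reference "close".  Robust to size-task area ratios that are only
# approximately symmetric (e.g. 0.51 vs 2.04).
bin_ratios <- function(log_r) {
  lv <- sort(unique(log_r))
  if (length(lv) != 6) {
    stop("expected 6 distinct ratios, got ", length(lv), call. = FALSE)
  }
  bins_by_value <- character(6)
  bins_by_value[order(-abs(lv))] <- rep(c("far", "medium", "close"), each = 2)
  bins_by_value[match(log_r, lv)]
}

#' Sample individual dot diameters around a mean
#'
#' Individual dot diameters are the centers of the `n` equal-width bins of
#' the symmetric interval `[mean - half_width, mean + half_width]`, so the
#' arithmetic mean of the returned diameters equals `mean_diameter`
#' exactly and the spread of sizes scales with the mean.
#'
#' @param n Number of dots (>= 1).
#' @param mean_diameter Mean diameter in degrees.
#' @param half_width Interval half-width in degrees; must be smaller than
#'   `mean_diameter` so no diameter is non-positive.
#' @return Numeric vector of `n` diameters (degrees), increasing.
#' @examples
#' sample_dot_diameters(5, 0.25, 0.09)
#' @export
sample_dot_diameters <- function(n, mean_diameter, half_width) {
  stopifnot(n >= 1, mean_diameter > 0)
  if (half_width >= mean_diameter) {
    stop("half_width must be < mean_diameter (diameters must stay positive)",
         call. = FALSE)
  }
  width <- 2 * half_width / n
  mean_diameter - half_width + width * (seq_len(n) - 0.5)
}

#' Place dots inside a virtual circle by rejection sampling
#'
#' Draws dot centers uniformly within the field, subject to: every dot lies
#' entirely inside the virtual circle, dots keep a minimum edge-to-edge gap
#' from each other, and no dot overlaps the central fixation exclusion
#' disk.  Dots are placed largest-first (easier constraint satisfaction);
#' if a dot cannot be placed within the attempt budget the whole array is
#' restarted, and an error is raised once the total budget is exhausted
#' (an infeasible configuration).  Polarities are half black / half white;
#' for odd counts the majority colour is drawn at random.
#'
#' Uses the R random number stream: set a seed for reproducible arrays.
#'
#' @param diameters Dot diameters in degrees.
#' @param field_diameter Virtual-circle diameter in degrees.
#' @param config A [design_config()] supplying the separation, fixation and
#'   density constraints.
#' @return A `dot_array`: a tibble with columns `x`, `y`, `diameter`,
#'   `polarity` and attribute `field_diameter`.
#' @examples
#' set.seed(1)
#' arr <- place_dots(sample_dot_diameters(10, 0.35, 0.135), 7.6)
#' array_metrics(arr)
#' @export
place_dots <- function(diameters, field_diameter, config = design_config()) {
  stopifnot(length(diameters) >= 1, all(diameters > 0), field_diameter > 0)
  n <- length(diameters)
  R <- field_diameter / 2
  density <- n / (pi * R^2)
  if (density > config$density_cap) {
    stop(sprintf("array density %.3f exceeds cap %.3f dots/deg^2",
                 density, config$density_cap), call. = FALSE)
  }
  ord <- order(diameters, decreasing = TRUE)
  d_sorted <- diameters[ord]
  fix_r <- config$fixation_exclusion_radius
  sep <- config$min_separation

  budget <- config$max_attempts
  attempts_used <- 0L
  repeat {
    xs <- numeric(n); ys <- numeric(n)
    placed <- 0L
    failed <- FALSE
    for (i in seq_len(n)) {
      di <- d_sorted[i]
      r_max <- R - di / 2
      if (r_max < 0) stop("dot larger than field: placement infeasible", call. = FALSE)
      ok <- FALSE
      while (attempts_used < budget) {
        attempts_used <- attempts_used + 1L
        # uniform over the disk of admissible centers
        rr <- r_max * sqrt(stats::runif(1))
        th <- stats::runif(1, 0, 2 * pi)
        cx <- rr * cos(th); cy <- rr * sin(th)
        if (sqrt(cx^2 + cy^2) < fix_r + di / 2) next
        if (placed > 0L) {
          gaps <- sqrt((xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2) -
            (d_sorted[seq_len(placed)] + di) / 2
          if (any(gaps < sep)) next
        }
        ok <- TRUE
        break
      }
      if (!ok) { failed <- TRUE; break }
      placed <- placed + 1L
      xs[placed] <- cx; ys[placed] <- cy
    }
    if (!failed) break
    if (attempts_used >= budget) {
      stop(sprintf(
        "could not place %d dots in a %.2f deg field after %d attempts: infeasible configuration",
        n, field_diameter, budget), call. = FALSE)
    }
  }

  # undo the largest-first ordering so diameters match the input
  xs_out <- numeric(n); ys_out <- numeric(n)
  xs_out[ord] <- xs; ys_out[ord] <- ys

  n_black <- if (n %% 2 == 0) n %/% 2 else n %/% 2 + stats::rbinom(1, 1, 0.5)
  polarity <- sample(rep(c("black", "white"), c(n_black, n - n_black)))

  new_dot_array(
    tibble::tibble(x = xs_out, y = ys_out, diameter = diameters,
                   polarity = polarity),
    field_diameter = field_diameter
  )
}

new_dot_array <- function(df, field_diameter) {
  out <- tibble::new_tibble(df, field_diameter = field_diameter,
                            class = "dot_array")
  out
}

#' @export
print.dot_array <- function(x, ...) {
  cat(sprintf("<dot_array> %d dots in a %.2f deg field\n",
              nrow(x), attr(x, "field_diameter")))
  NextMethod()
}

#' Check the geometric invariants of a dot array
#'
#' Verifies containment in the virtual circle, the minimum edge-to-edge
#' separation, the fixation exclusion zone, the black/white balance and the
#' density cap.  Returns `TRUE` invisibly or raises an informative error.
#'
#' @param spec A `dot_array` from [place_dots()].
#' @param config A [design_config()].
#' @return `TRUE`, invisibly.
#' @export
validate_dot_array <- function(spec, config = design_config()) {
  R <- attr(spec, "field_diameter") / 2
  tol <- 1e-9
  if (any(sqrt(spec$x^2 + spec$y^2) + spec$diameter / 2 > R + tol)) {
    stop("dot extends outside the virtual circle", call. = FALSE)
  }
  if (any(sqrt(spec$x^2 + spec$y^2) - spec$diameter / 2 <
          config$fixation_exclusion_radius - tol)) {
    stop("dot overlaps the fixation exclusion zone", call. = FALSE)
  }
  n <- nrow(spec)
  if (n > 1) {
    dmat <- as.matrix(stats::dist(cbind(spec$x, spec$y)))
    rad <- spec$diameter / 2
    gaps <- dmat - outer(rad, rad, `+`)
    diag(gaps) <- Inf
    if (any(gaps < config$min_separation - tol)) {
      stop("dots closer than the minimum separation", call. = FALSE)
    }
  }
  pol <- table(factor(spec$polarity, levels = c("black", "white")))
  if (abs(pol[["black"]] - pol[["white"]]) > 1) {
    stop("black/white counts differ by more than 1", call. = FALSE)
  }
  if (n / (pi * R^2) > config$density_cap + tol) {
    stop("density exceeds the cap", call. = FALSE)
  }
  invisible(TRUE)
}

#' Summary metrics of a dot array
#'
#' @param spec A `dot_array`, or a plain data frame with `diameter` plus a
#'   `field_diameter` attribute or argument.
#' @param field_diameter Field diameter in degrees (taken from the
#'   attribute when `NULL`).
#' @return A one-row tibble: `numerosity`, `mean_item_diameter`,
#'   `mean_item_area` (deg^2), `total_surface_area` (deg^2) and `density`
#'   (dots/deg^2).
#' @examples
#' metrics_for(20, 0.25, 5.8)$density  # ~0.75 dots/deg^2
#' @export
array_metrics <- function(spec, field_diameter = NULL) {
  fd <- field_diameter %||% attr(spec, "field_diameter")
  stopifnot(!is.null(fd), fd > 0, nrow(spec) >= 1)
  areas <- pi * (spec$diameter / 2)^2
  tibble::tibble(
    numerosity = nrow(spec),
    mean_item_diameter = mean(spec$diameter),
    mean_item_area = mean(areas),
    total_surface_area = sum(areas),
    density = nrow(spec) / (pi * (fd / 2)^2)
  )
}

#' Design-cell metrics without placing dots
#'
#' Convenience wrapper: computes [array_metrics()] for a design cell
#' described by numerosity, mean diameter and field diameter, using the
#' configured bin-center diameter sampling.
#'
#' @param n Numerosity.
#' @param mean_diameter Mean dot diameter (deg).
#' @param field_diameter Virtual-circle diameter (deg).
#' @param config A [design_config()].
#' @return A one-row tibble as in [array_metrics()].
#' @export
metrics_for <- function(n, mean_diameter, field_diameter,
                        config = design_config()) {
  d <- sample_dot_diameters(n, mean_diameter,
                            half_width_for(mean_diameter, config))
  array_metrics(tibble::tibble(diameter = d), field_diameter = field_diameter)
}
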