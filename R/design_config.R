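#' Experimental design configuration
#'
#' Bundles every constant that defines the stimulus set and the factorial
#' trial design: the two virtual field diameters, the dot-separation and
#' fixation constraints, the test levels of each task, the reference array,
#' and the diameter-interval half-widths used when sampling heterogeneous
#' dot sizes.
#'
#' Defaults reproduce the published stimulus set: test numerosities
#' 5, 6, 8, 12, 17 and 20 dots against a 10-dot reference (ratios 0.5-2),
#' test mean diameters 0.25-0.5 deg against a 0.35 deg reference, virtual
#' circles of 7.6 and 5.8 deg, dots at least 0.25 deg apart, and
#' size-sampling intervals of +/-0.09, 0.11, 0.12, 0.15, 0.17 and 0.19 deg
#' that scale with the mean diameter.  The densest design cell (20 dots in
#' the 5.8 deg field) reaches ~0.75 dots/deg^2, just under the default
#' density cap, keeping all arrays in the sparse "number regime".
#'
#' @param field_diameters Numeric vector of virtual-circle diameters (deg).
#' @param min_separation Minimum edge-to-edge gap between dots (deg).
#' @param fixation_exclusion_radius Radius of the central disk no dot may
#'   overlap (deg).  The source display does not fix this value; 0.3 deg is
#'   a conservative default.
#' @param number_task_counts Test numerosities for the number task.
#' @param number_task_sizes Mean diameters (deg) of the unattended size
#'   levels in the number task (small, big).
#' @param size_task_diameters Test mean diameters (deg) for the size task.
#' @param size_task_counts Numerosities (small, big) of the unattended
#'   number levels in the size task.
#' @param reference_n,reference_diameter Reference array: 10 dots of
#'   0.35 deg mean diameter (0.1 deg^2 mean item area).
#' @param interval_half_widths Named numeric vector mapping each mean
#'   diameter (as character) to the half-width (deg) of the symmetric
#'   interval from which individual dot diameters are drawn.
#' @param reference_half_width Half-width for the 0.35 deg reference mean
#'   (not part of the published table; linearly interpolated).
#' @param repetitions_per_session,sessions Repetition structure.
#' @param density_cap Maximum allowed dot density (dots/deg^2).
#' @param max_attempts Rejection-sampling budget per array in
#'   [place_dots()].
#'
#' @return An object of class `design_config` (a named list).
#' @examples
#' cfg <- design_config()
#' cfg$number_task_counts
#' @export
design_config <- function(field_diameters = c(7.6, 5.8),
                          min_separation = 0.25,
                          fixation_exclusion_radius = 0.3,
                          number_task_counts = c(5, 6, 8, 12, 17, 20),
                          number_task_sizes = c(small = 0.25, big = 0.5),
                          size_task_diameters = c(0.25, 0.27, 0.30, 0.40, 0.46, 0.50),
                          size_task_counts = c(small = 5, big = 20),
                          reference_n = 10,
                          reference_diameter = 0.35,
                          interval_half_widths = c(
                            "0.25" = 0.09, "0.27" = 0.11, "0.3" = 0.12,
                            "0.4" = 0.15, "0.46" = 0.17, "0.5" = 0.19
                          ),
                          reference_half_width = 0.135,
                          repetitions_per_session = 3,
                          sessions = 3,
                          density_cap = 0.76,
                          max_attempts = 10000) {
  cfg <- list(
    field_diameters = as.numeric(field_diameters),
    min_separation = min_separation,
    fixation_exclusion_radius = fixation_exclusion_radius,
    number_task_counts = as.numeric(number_task_counts),
    number_task_sizes = number_task_sizes,
    size_task_diameters = as.numeric(size_task_diameters),
    size_task_counts = size_task_counts,
    reference_n = reference_n,
    reference_diameter = reference_diameter,
    interval_half_widths = interval_half_widths,
    reference_half_width = reference_half_width,
    repetitions_per_session = repetitions_per_session,
    sessions = sessions,
    density_cap = density_cap,
    max_attempts = max_attempts
  )
  class(cfg) <- "design_config"
  validate_design_config(cfg)
  cfg
}

validate_design_config <- function(cfg) {
  stopifnot(
    length(cfg$field_diameters) >= 1, all(cfg$field_diameters > 0),
    cfg$min_separation >= 0,
    cfg$fixation_exclusion_radius >= 0,
    all(cfg$number_task_counts >= 1),
    all(cfg$number_task_sizes > 0),
    all(cfg$size_task_diameters > 0),
    all(cfg$size_task_counts >= 1),
    cfg$reference_n >= 1, cfg$reference_diameter > 0,
    cfg$repetitions_per_session >= 1, cfg$sessions >= 1,
    cfg$density_cap > 0, cfg$max_attempts >= 1
  )
  # interval half-widths must leave every dot diameter positive
  means <- as.numeric(names(cfg$interval_half_widths))
  if (any(cfg$interval_half_widths >= means)) {
    stop("interval half-width must be smaller than its mean diameter", call. = FALSE)
  }
  if (cfg$reference_half_width >= cfg$reference_diameter) {
    stop("reference half-width must be smaller than the reference diameter", call. = FALSE)
  }
  invisible(cfg)
}

#' Look up the diameter-interval half-width for a mean diameter
#'
#' Returns the configured half-width for a tabulated mean, or a linear
#' interpolation/extrapolation of the configured (mean, half-width) pairs
#' for non-tabulated means such as the 0.35 deg reference.
#'
#' @param mean_diameter Mean dot diameter in degrees.
#' @param config A [design_config()].
#' @return Half-width in degrees.
#' @export
half_width_for <- function(mean_diameter, config = design_config()) {
  tab_means <- as.numeric(names(config$interval_half_widths))
  hw <- unname(config$interval_half_widths)
  out <- vapply(mean_diameter, function(m) {
    hit <- which(abs(tab_means - m) < 1e-9)
    if (length(hit) == 1L) return(hw[hit])
    if (abs(m - config$reference_diameter) < 1e-9) return(config$reference_half_width)
    stats::approx(tab_means, hw, xout = m, rule = 2)$y
  }, numeric(1))
  out
}

#' @export
print.design_config <- function(x, ...) {
  cat("<design_config>\n")
  cat("  field diameters:", paste(x$field_diameters, collapse = ", "), "deg\n")
  cat("  number task: n =", paste(x$number_task_counts, collapse = ", "),
      "| unattended d =", paste(x$number_task_sizes, collapse = ", "), "deg\n")
  cat("  size task: d =", paste(x$size_task_diameters, collapse = ", "),
      "| unattended n =", paste(x$size_task_counts, collapse = ", "), "\n")
  cat("  reference:", x$reference_n, "dots,", x$reference_diameter, "deg\n")
  cat("  min separation:", x$min_separation, "deg; density cap:",
      x$density_cap, "dots/deg^2\n")
  invisible(x)
}
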