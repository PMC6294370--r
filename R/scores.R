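#' Inverse-efficiency score
#'
#' Mean reaction time divided by the proportion of correct responses, a
#' composite that penalises fast-but-inaccurate performance.  Units follow
#' the reaction time (typically ms).
#'
#' @param mean_rt Mean reaction time (> 0).
#' @param prop_correct Proportion correct in `(0, 1]`.
#' @return `mean_rt / prop_correct` (vectorised).
#' @examples
#' ie_score(598, 46 / 48)  # 623.9
#' @export
ie_score <- function(mean_rt, prop_correct) {
  if (any(prop_correct <= 0)) {
    stop("prop_correct must be > 0 (IE undefined at zero accuracy)", call. = FALSE)
  }
  stopifnot(all(prop_correct <= 1), all(mean_rt > 0))
  mean_rt / prop_correct
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite, non-zero
#'   variance).
#' @return One-row tibble: `r`, `t_statistic`, `df`, `p_value`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3,
            all(is.finite(x)), all(is.finite(y)))
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y)
  tibble::tibble(
    r = unname(ct$estimate),
    t_statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = ct$p.value,
    n = length(x)
  )
}

#' Partial correlation controlling for covariates
#'
#' Correlates the least-squares residuals of `x` and `y` after regressing
#' each on the covariates; the p-value uses `n - k - 2` degrees of freedom
#' for `k` covariates.  With no covariates this reduces exactly to
#' [pearson_r()].
#'
#' @param x,y Numeric vectors.
#' @param covariates A data frame (or vector/matrix) of covariates; may be
#'   empty or `NULL`.
#' @return One-row tibble: `r`, `t_statistic`, `df`, `p_value`, `n`,
#'   `n_covariates`.
#' @export
partial_r <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0 ||
      (is.data.frame(covariates) && ncol(covariates) == 0)) {
    out <- pearson_r(x, y)
    return(dplyr::mutate(out, n_covariates = 0L))
  }
  Z <- as.data.frame(covariates)
  k <- ncol(Z)
  n <- length(x)
  stopifnot(length(y) == n, nrow(Z) == n)
  if (n <= k + 2) stop("need n > k + 2 observations", call. = FALSE)
  mm <- stats::model.matrix(~ ., data = Z)
  if (qr(mm)$rank < ncol(mm)) stop("collinear covariates", call. = FALSE)
  rx <- stats::lm.fit(mm, x)$residuals
  ry <- stats::lm.fit(mm, y)$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("zero residual variance", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tstat <- r * sqrt(df / (1 - r^2))
  tibble::tibble(
    r = r,
    t_statistic = tstat,
    df = df,
    p_value = 2 * stats::pt(-abs(tstat), df),
    n = n,
    n_covariates = k
  )
}

#' Correlation report linking interference to an ability score
#'
#' Pearson and partial correlations (controlling for the supplied
#' covariates) between each bias/precision measure and a per-subject
#' ability score such as the calculation inverse-efficiency score.
#'
#' @param scores Tibble with one row per subject, containing `score` (the
#'   ability measure) and the measure columns in `measures`.
#' @param measures Character vector of column names to correlate with
#'   `score`.
#' @param covariate_cols Character vector of covariate column names for
#'   the partial correlations (e.g. group and an inhibition index).
#' @return Tibble with one row per measure and correlation type.
#' @export
correlation_report <- function(scores,
                               measures = c("unsigned_bias_num",
                                            "unsigned_bias_size",
                                            "jnd_num", "jnd_size"),
                               covariate_cols = character()) {
  stopifnot("score" %in% names(scores), all(measures %in% names(scores)))
  purrr::map_dfr(measures, function(mcol) {
    simple <- dplyr::mutate(pearson_r(scores[[mcol]], scores$score),
                            n_covariates = 0L)
    rows <- dplyr::mutate(simple, measure = mcol, type = "pearson", .before = 1)
    if (length(covariate_cols)) {
      part <- partial_r(scores[[mcol]], scores$score,
                        scores[covariate_cols])
      rows <- dplyr::bind_rows(
        rows, dplyr::mutate(part, measure = mcol, type = "partial", .before = 1)
      )
    }
    rows
  })
}
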