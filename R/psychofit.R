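#' Posterior grid configuration for psychometric fitting
#'
#' The cumulative-Gaussian psychometric function is fitted by evaluating
#' the posterior on a fixed 3-D grid (uniform priors): point of subjective
#' equality (PSE) on a linear grid, the Gaussian scale `sigma` on a
#' log-spaced grid, and the lapse rate on a coarse linear grid.  A grid
#' posterior (rather than MCMC) keeps fits deterministic and fast.
#'
#' @param pse Grid of PSE values (log units); default 121 points on
#'   `[-0.6, 0.6]`.
#' @param sigma Grid of scale values; default 61 log-spaced points on
#'   `[0.02, 1]`.
#' @param lapse Grid of lapse rates; default `0, 0.01, ..., 0.1`.  Use
#'   `lapse = 0` to fit without a lapse parameter.
#' @return An object of class `grid_config`.
#' @export
grid_config <- function(pse = seq(-0.6, 0.6, length.out = 121),
                        sigma = exp(seq(log(0.02), log(1), length.out = 61)),
                        lapse = seq(0, 0.1, by = 0.01)) {
  stopifnot(length(pse) >= 2, all(is.finite(pse)),
            all(sigma > 0), length(sigma) >= 2,
            all(lapse >= 0), all(lapse <= 0.5))
  structure(list(pse = sort(pse), sigma = sort(sigma), lapse = sort(lapse)),
            class = "grid_config")
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' The proportion of "test greater" choices is modelled as
#' `p(x) = lapse/2 + (1 - lapse) * Phi((x - pse) / sigma)` on the
#' log-ratio axis `x = log(test / reference)` of the attended dimension
#' (item *area* for the size task).  The Bernoulli likelihood is evaluated
#' on the [grid_config()] grid with uniform priors; the reported fit is
#' the maximum a posteriori point, and the normalized marginal posterior
#' of the PSE is retained for credible-interval arithmetic
#' ([pse_difference()]).
#'
#' The 50% point of the fitted curve is the PSE; the difference between
#' the 75% and 50% points is the just-noticeable difference,
#' `jnd = sigma * qnorm(0.75)`, reported also as the Weber fraction (log
#' units).
#'
#' @param responses A response table ([simulate_responses()] or
#'   [ingest_responses()]): needs `log_r_att` and `choice`.
#' @param grid A [grid_config()].
#' @return An object of class `psychometric_fit`: MAP `pse`, `sigma`,
#'   `lapse`, derived `jnd` and `weber_fraction`, `n_trials`, `loglik`,
#'   the aggregated `data` (level, n, k) and the `pse_marginal` tibble.
#' @examples
#' des <- enumerate_design("number")
#' resp <- simulate_responses(des, observer_params(), seed = 42)
#' fit <- fit_psychometric(resp)
#' glance(fit)
#' @export
fit_psychometric <- function(responses, grid = grid_config()) {
  stopifnot(inherits(grid, "grid_config"),
            all(c("log_r_att", "choice") %in% names(responses)))
  counts <- rowsum(cbind(n = rep(1, nrow(responses)), k = responses$choice),
                   group = responses$log_r_att)
  agg <- tibble::tibble(level = as.numeric(rownames(counts)),
                        n = counts[, "n"], k = counts[, "k"])
  agg <- agg[order(agg$level), ]
  if (nrow(agg) < 2) {
    if (sum(agg$k) == 0 || sum(agg$k) == sum(agg$n)) {
      stop("degenerate fit: single stimulus level with identical responses",
           call. = FALSE)
    }
    stop("need responses at >= 2 distinct stimulus levels", call. = FALSE)
  }

  # log-likelihood over the (pse, sigma, lapse) grid (compiled kernel)
  ll <- .psychofit_ll_cpp(grid$pse, grid$sigma, grid$lapse,
                          agg$level, agg$n, agg$k)

  post <- exp(ll - max(ll))
  post <- post / sum(post)
  map_idx <- arrayInd(which.max(post), dim(post))
  pse <- grid$pse[map_idx[1]]
  sigma <- grid$sigma[map_idx[2]]
  lapse <- grid$lapse[map_idx[3]]
  pse_marg <- rowSums(matrix(post, nrow = dim(post)[1]))

  structure(
    list(
      pse = pse, sigma = sigma, lapse = lapse,
      jnd = sigma * stats::qnorm(0.75),
      weber_fraction = sigma * stats::qnorm(0.75),
      n_trials = sum(agg$n),
      loglik = max(ll),
      data = agg,
      pse_marginal = tibble::tibble(pse = grid$pse, prob = pse_marg),
      grid = grid
    ),
    class = "psychometric_fit"
  )
}

#' Weber fraction of a fit under a chosen convention
#'
#' @param fit A `psychometric_fit`.
#' @param convention `"log"` (default): the JND in natural-log units,
#'   `sigma * qnorm(0.75)`; `"proportional"`: `exp(jnd) - 1`, the
#'   equivalent proportional stimulus change.  The two differ by < 10% for
#'   typical acuities.
#' @return A single number.
#' @export
weber_fraction <- function(fit, convention = c("log", "proportional")) {
  convention <- match.arg(convention)
  if (convention == "log") fit$jnd else expm1(fit$jnd)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat("<psychometric_fit>", x$n_trials, "trials,",
      nrow(x$data), "stimulus levels\n")
  cat(sprintf("  PSE = %+.4f  sigma = %.4f  lapse = %.3f  (MAP)\n",
              x$pse, x$sigma, x$lapse))
  cat(sprintf("  JND = %.4f log units (Weber fraction, log convention)\n", x$jnd))
  invisible(x)
}

#' @rdname fit_psychometric
#' @param x A `psychometric_fit`.
#' @param ... Unused.
#' @export
tidy.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    term = c("pse", "sigma", "lapse", "jnd"),
    estimate = c(x$pse, x$sigma, x$lapse, x$jnd)
  )
}

#' @rdname fit_psychometric
#' @export
glance.psychometric_fit <- function(x, ...) {
  tibble::tibble(
    pse = x$pse, sigma = x$sigma, lapse = x$lapse, jnd = x$jnd,
    weber_fraction = x$weber_fraction, n_trials = x$n_trials,
    loglik = x$loglik
  )
}

#' @rdname fit_psychometric
#' @param object A `psychometric_fit`.
#' @export
autoplot.psychometric_fit <- function(object, ...) {
  xs <- seq(min(object$data$level), max(object$data$level), length.out = 200)
  curve <- tibble::tibble(
    x = xs,
    p = object$lapse / 2 +
      (1 - object$lapse) * stats::pnorm((xs - object$pse) / object$sigma)
  )
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$level, y = .data$k / .data$n)) +
    ggplot2::geom_line(data = curve, ggplot2::aes(x = .data$x, y = .data$p),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(size = .data$n), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$pse, linetype = "dotted") +
    ggplot2::scale_size_area(max_size = 4, guide = "none") +
    ggplot2::labs(x = "log (test / reference)", y = "P(chose test)") +
    ggplot2::theme_minimal()
}

#' Fit the psychometric function on one unattended-magnitude subset
#'
#' Splits the response table by the magnitude (small or big) of the
#' unattended dimension and fits the selected subset only.  For a full
#' 432-trial design each subset holds 216 trials.
#'
#' @param responses A response table with an `unattended_level` column.
#' @param level `"small"` or `"big"`.
#' @param grid A [grid_config()].
#' @return A `psychometric_fit`.
#' @export
split_fit_by_unattended <- function(responses, level = c("small", "big"),
                                    grid = grid_config()) {
  level <- match.arg(level)
  sub <- dplyr::filter(responses, .data$unattended_level == level)
  if (nrow(sub) == 0) stop("empty subset for unattended level ", level, call. = FALSE)
  fit_psychometric(sub, grid = grid)
}

#' Posterior distribution of a PSE difference, and the bias it implies
#'
#' Convolves the marginal PSE posterior of the "unattended small" fit with
#' the reflection of the "unattended big" marginal to obtain the posterior
#' of their difference (small - big).  From it: the 95% equal-tailed
#' credible interval, and `p_reliable = 1 -` the largest coverage level
#' whose equal-tailed interval still excludes zero (computed as
#' `2 * min(P(D <= 0), P(D >= 0))`, capped at 1).  A subject's bias is
#' flagged `reliable` when `p_reliable < 0.05`, equivalently when the 95%
#' interval excludes zero.
#'
#' @param fit_small,fit_big `psychometric_fit` objects (or tibbles with
#'   `pse`/`prob` columns) for the unattended-small and unattended-big
#'   subsets.  Their PSE grids must share a common spacing.
#' @return An object of class `bias_estimate`: `signed_bias` (difference
#'   of MAP PSEs), `unsigned_bias`, posterior mean `posterior_mean_diff`,
#'   `ci95`, `p_reliable`, `reliable`, and the difference posterior tibble.
#' @export
pse_difference <- function(fit_small, fit_big) {
  m_small <- marginal_of(fit_small)
  m_big <- marginal_of(fit_big)
  steps <- c(diff(m_small$pse), diff(m_big$pse))
  if (length(steps) && max(steps) - min(steps) > 1e-8) {
    stop("PSE grids are not commensurate (unequal spacing)", call. = FALSE)
  }

  # discrete convolution: all pairwise differences D = A - B, masses
  # aggregated on the (regular) difference lattice
  dvals <- round(as.vector(outer(m_small$pse, m_big$pse, `-`)), 9)
  pvals <- as.vector(outer(m_small$prob, m_big$prob))
  agg <- rowsum(pvals, group = dvals)
  dgrid <- as.numeric(rownames(agg))
  ord <- order(dgrid)
  dgrid <- dgrid[ord]
  dm <- as.vector(agg)[ord]
  dm <- dm / sum(dm)

  cdf <- cumsum(dm)
  ql <- dgrid[which(cdf >= 0.025)[1]]
  qu <- dgrid[which(cdf >= 0.975)[1]]
  p_le0 <- sum(dm[dgrid <= 0])
  p_ge0 <- sum(dm[dgrid >= 0])
  p_rel <- min(1, 2 * min(p_le0, p_ge0))

  map_s <- m_small$pse[which.max(m_small$prob)]
  map_b <- m_big$pse[which.max(m_big$prob)]
  signed <- map_s - map_b

  structure(
    list(
      signed_bias = signed,
      unsigned_bias = abs(signed),
      posterior_mean_diff = sum(dgrid * dm),
      ci95 = c(lower = ql, upper = qu),
      p_reliable = p_rel,
      reliable = p_rel < 0.05,
      posterior = tibble::tibble(diff = dgrid, prob = dm)
    ),
    class = "bias_estimate"
  )
}

marginal_of <- function(x) {
  if (inherits(x, "psychometric_fit")) return(x$pse_marginal)
  stopifnot(is.data.frame(x), all(c("pse", "prob") %in% names(x)))
  tibble::tibble(pse = x$pse, prob = x$prob / sum(x$prob))
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat("<bias_estimate>\n")
  cat(sprintf("  signed bias (small - big) = %+.4f log units\n", x$signed_bias))
  cat(sprintf("  95%% CI [%.4f, %.4f]  p = %.4f  reliable: %s\n",
              x$ci95[1], x$ci95[2], x$p_reliable, x$reliable))
  invisible(x)
}

#' @rdname pse_difference
#' @param x A `bias_estimate`.
#' @param ... Unused.
#' @export
tidy.bias_estimate <- function(x, ...) {
  tibble::tibble(
    signed_bias = x$signed_bias,
    unsigned_bias = x$unsigned_bias,
    posterior_mean_diff = x$posterior_mean_diff,
    ci_lower = unname(x$ci95["lower"]),
    ci_upper = unname(x$ci95["upper"]),
    p_reliable = x$p_reliable,
    reliable = x$reliable
  )
}

#' Signed/unsigned interference bias of one response table
#'
#' Convenience wrapper: split-fit by unattended magnitude and convolve the
#' PSE posteriors.
#'
#' @param responses A response table for one subject and task.
#' @param grid A [grid_config()].
#' @return A `bias_estimate`.
#' @export
bias_estimate <- function(responses, grid = grid_config()) {
  pse_difference(
    split_fit_by_unattended(responses, "small", grid = grid),
    split_fit_by_unattended(responses, "big", grid = grid)
  )
}
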