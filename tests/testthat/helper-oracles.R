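# Independent oracles used across tests.

# ---- Hartigan dip by linear programming (boot::simplex) ----
# Minimises the band half-width d over unimodal chains with the mode at
# each data point in turn (the optimal unimodal CDF may jump at its mode).
# Completely independent of the package's bisection/hull implementation.

dip_prep_oracle <- function(x) {
  x <- sort(x)
  n <- length(x)
  u <- unique(x)
  cnt <- as.vector(table(match(x, u)))
  a <- cumsum(cnt) / n
  b <- c(0, a[-length(a)])
  list(u = u, a = a, b = b, m = length(u), n = n)
}

dip_lp_mode_k <- function(pp, k) {
  m <- pp$m; u <- pp$u; a <- pp$a; b <- pp$b
  nv <- k; nw <- m - k + 1
  nvar <- 1 + nv + nw
  iv <- function(j) 1 + j
  iw <- function(j) 1 + nv + (j - k + 1)
  A1 <- NULL; b1 <- NULL; A2 <- NULL; b2 <- NULL
  add_le <- function(coefs, rhs) {
    row <- numeric(nvar); row[coefs[, 1]] <- coefs[, 2]
    A1 <<- rbind(A1, row); b1 <<- c(b1, rhs)
  }
  add_ge <- function(coefs, rhs) {
    row <- numeric(nvar); row[coefs[, 1]] <- coefs[, 2]
    A2 <<- rbind(A2, row); b2 <<- c(b2, rhs)
  }
  for (j in 1:k) {
    lo_j <- if (j < k) a[j] else b[j]   # jump at the mode relaxes the gate
    if (lo_j > 0) add_ge(cbind(c(iv(j), 1), c(1, 1)), lo_j)
    add_le(cbind(c(iv(j), 1), c(1, -1)), b[j])
  }
  for (j in k:m) {
    hi_j <- if (j > k) b[j] else a[j]
    add_ge(cbind(c(iw(j), 1), c(1, 1)), a[j])
    add_le(cbind(c(iw(j), 1), c(1, -1)), hi_j)
  }
  if (k >= 2) for (j in 1:(k - 1)) add_ge(cbind(c(iv(j + 1), iv(j)), c(1, -1)), 0)
  add_ge(cbind(c(iw(k), iv(k)), c(1, -1)), 0)
  if (k <= m - 1) for (j in k:(m - 1)) add_ge(cbind(c(iw(j + 1), iw(j)), c(1, -1)), 0)
  if (k >= 3) for (j in 1:(k - 2)) {
    d1 <- u[j + 1] - u[j]; d2 <- u[j + 2] - u[j + 1]
    add_ge(cbind(c(iv(j + 2), iv(j + 1), iv(j)),
                 c(1 / d2, -1 / d2 - 1 / d1, 1 / d1)), 0)
  }
  if (m - k >= 2) for (j in k:(m - 2)) {
    d1 <- u[j + 1] - u[j]; d2 <- u[j + 2] - u[j + 1]
    add_ge(cbind(c(iw(j + 2), iw(j + 1), iw(j)),
                 c(-1 / d2, 1 / d2 + 1 / d1, -1 / d1)), 0)
  }
  obj <- numeric(nvar); obj[1] <- 1
  res <- try(boot::simplex(a = obj, A1 = A1, b1 = b1, A2 = A2, b2 = b2,
                           maxi = FALSE, n.iter = 3000), silent = TRUE)
  if (inherits(res, "try-error") || res$solved != 1) return(NA_real_)
  res$value
}

dip_lp_oracle <- function(x) {
  pp <- dip_prep_oracle(x)
  if (pp$m == 1) return(0)
  min(vapply(seq_len(pp$m), function(k) dip_lp_mode_k(pp, k), numeric(1)),
      na.rm = TRUE)
}

# ---- discrete Gaussian marginal on a PSE grid ----
discrete_gaussian_marginal <- function(mean, sd, grid = seq(-0.6, 0.6, length.out = 121)) {
  p <- stats::dnorm(grid, mean, sd)
  tibble::tibble(pse = grid, prob = p / sum(p))
}

# quick coarse grid for tests that only need rough fits
coarse_grid <- function() {
  grid_config(
    pse = seq(-0.6, 0.6, length.out = 61),
    sigma = exp(seq(log(0.02), log(1), length.out = 31)),
    lapse = c(0, 0.02, 0.05)
  )
}
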