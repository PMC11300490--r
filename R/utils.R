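# Internal numeric helpers shared across the simulator and the analysis layer.

#' Derive a reproducible sub-stream seed
#'
#' Folds a master seed together with an arbitrary sequence of labels
#' (strings or integers) into a deterministic 32-bit seed, so that each
#' simulation stage and each participant gets an independent, stable random
#' stream. Reordering unrelated stages does not perturb a stage's stream.
#'
#' @param master Integer master seed.
#' @param ... Stage labels: character strings and/or integers.
#' @return A single integer suitable for [set.seed()].
#' @examples
#' derive_seed(1, "cohort")
#' derive_seed(1, "staircase", "A01", 3L)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  m <- 2147483647 # 2^31 - 1; all arithmetic stays exact in doubles
  h <- abs(as.double(master)) %% m
  for (p in list(...)) {
    xs <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\x1f")) else as.double(p)
    for (x in xs) h <- (h * 69069 + (abs(x) %% m) + 1) %% m
  }
  as.integer(h)
}

#' Geometric mean
#'
#' @param x Positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (any(!is.finite(x)) || any(x <= 0)) stop("geometric mean requires finite positive values")
  exp(mean(log(x)))
}

# Mean and sd of a normal(mu, sigma) truncated to [lo, hi].
tnorm_moments <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  Z <- stats::pnorm(b) - stats::pnorm(a)
  if (Z <= 0) return(c(mean = NA_real_, sd = NA_real_))
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mu + sigma * (da - db) / Z
  v <- sigma^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Solve for the parent (mu, sigma) of a truncated normal whose *truncated*
# mean/sd match the targets. Needed because plugging printed sample moments
# straight into the parent distribution would bias the simulated moments
# whenever the truncation bounds bite.
match_truncnorm <- function(mean, sd, lo, hi, tol = 1e-6) {
  stopifnot(lo < hi, sd > 0, mean > lo, mean < hi)
  obj <- function(p) {
    mm <- tnorm_moments(p[1], exp(p[2]), lo, hi)
    if (any(is.na(mm))) return(1e10)
    (mm[1] - mean)^2 + (mm[2] - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  if (fit$value > tol) {
    stop(sprintf(
      "cannot match truncated-normal moments (mean=%.3g, sd=%.3g on [%.3g, %.3g]); residual %.3g",
      mean, sd, lo, hi, fit$value))
  }
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

#' Sample a moment-matched truncated normal
#'
#' Draws from a normal distribution truncated to `[lo, hi]` whose parent
#' parameters are solved so that the mean and standard deviation of the
#' *truncated* distribution equal `mean` and `sd`. Sampling uses the inverse
#' CDF, so draws consume exactly `n` uniforms from the current RNG stream.
#'
#' @param n Number of draws.
#' @param mean,sd Target mean and standard deviation of the truncated
#'   distribution.
#' @param lo,hi Truncation bounds (`lo < mean < hi`).
#' @return Numeric vector of length `n`, all values in `[lo, hi]`.
#' @export
rtruncnorm_matched <- function(n, mean, sd, lo, hi) {
  par <- match_truncnorm(mean, sd, lo, hi)
  p_lo <- stats::pnorm(lo, par$mu, par$sigma)
  p_hi <- stats::pnorm(hi, par$mu, par$sigma)
  u <- stats::runif(n, p_lo, p_hi)
  x <- stats::qnorm(u, par$mu, par$sigma)
  pmin(pmax(x, lo), hi)
}

# Noncentral-t inversion: CI for the noncentrality parameter of an observed
# t statistic. Returns c(lower, upper). The search range is capped (the
# noncentral CDFs are impractically slow at astronomical noncentrality, and
# effects that large are beyond any reporting precision).
ncp_t_ci <- function(t, df, level = 0.95) {
  alpha <- (1 - level) / 2
  lim <- min(max(abs(t), 1) + 50, 5e3)
  # pt() warns about its final-digit precision at large ncp; harmless here
  f_lo <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - (1 - alpha)
  f_hi <- function(ncp) suppressWarnings(stats::pt(t, df, ncp)) - alpha
  lo <- tryCatch(stats::uniroot(f_lo, c(-lim, lim), tol = 1e-10)$root,
                 error = function(e) -lim)
  hi <- tryCatch(stats::uniroot(f_hi, c(-lim, lim), tol = 1e-10)$root,
                 error = function(e) lim)
  c(lo, hi)
}

# Noncentral-F inversion: CI for the noncentrality parameter of an observed
# F statistic (lower bound floored at 0).
ncp_f_ci <- function(f, df1, df2, level = 0.95) {
  alpha <- (1 - level) / 2
  hi_cap <- min(max(f * df1, 1) * 10 + 1000, 1e4)
  g <- function(ncp, target) stats::pf(f, df1, df2, ncp) - target
  root <- function(target) {
    if (g(0, target) < 0) return(0)
    if (g(hi_cap, target) > 0) return(hi_cap) # off-scale effect: capped
    stats::uniroot(g, c(0, hi_cap), target = target, tol = 1e-9)$root
  }
  lo <- root(1 - alpha)
  hi <- root(alpha)
  c(lo, max(lo, hi))
}
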