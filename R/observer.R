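# Psychometric observer: maps latent capacity to stochastic all-targets-
# correct trial outcomes as a function of object speed and attentional load.

#' Construct a psychometric observer
#'
#' An observer is described by a capacity `C` (the speed threshold at load
#' 1, cm/s), an allocation exponent `alpha` (per-load threshold
#' `C * load^(-alpha)`, so `alpha = 1` is exact 1/i resource sharing), a
#' psychometric width `sigma` in log10-speed units, and a lapse rate. The
#' response model is a lapse-and-guess logistic in log10 speed: the task
#' scores a trial correct only when all `load` targets are identified among
#' `n_objects`, so the chance floor is `1 / choose(n_objects, load)`.
#'
#' @param capacity Speed threshold at load 1 (cm/s, > 0).
#' @param alpha Allocation exponent (>= 0).
#' @param sigma Psychometric width, log10 units (> 0).
#' @param lapse Lapse probability in `[0, 0.5)`.
#' @param n_objects Total objects on screen (default 8).
#' @return A list of class `"psychometric_observer"`.
#' @examples
#' obs <- psychometric_observer(200)
#' threshold(obs, 1:4)
#' p_correct(obs, speed = 100, load = 2)
#' @export
psychometric_observer <- function(capacity, alpha = 1, sigma = 0.04,
                                  lapse = 0, n_objects = 8) {
  stopifnot(capacity > 0, alpha >= 0, sigma > 0, lapse >= 0, lapse < 0.5,
            n_objects >= 1)
  structure(list(capacity = capacity, alpha = alpha, sigma = sigma,
                 lapse = lapse, n_objects = as.integer(n_objects)),
            class = "psychometric_observer")
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat(sprintf(
    "Psychometric observer: C = %.4g cm/s, alpha = %.3g, sigma = %.3g log10, lapse = %.3g, %d objects\n",
    x$capacity, x$alpha, x$sigma, x$lapse, x$n_objects))
  invisible(x)
}

as_observer <- function(x) {
  if (inherits(x, "psychometric_observer")) return(x)
  # one row of a cohort table
  psychometric_observer(x$capacity, x$alpha, x$sigma, x$lapse)
}

#' Per-load speed threshold
#'
#' `threshold(obs, i)` returns `C * i^(-alpha)`: under the allocation model
#' the trackable speed is shared as the inverse of the number of targets.
#'
#' @param observer A [psychometric_observer()].
#' @param load Number of targets (integer-valued, >= 1); vectorized.
#' @return Threshold speed(s), cm/s.
#' @export
threshold <- function(observer, load) {
  observer <- as_observer(observer)
  if (any(load < 1)) stop("load must be >= 1")
  observer$capacity * load^(-observer$alpha)
}

#' All-correct guessing floor
#'
#' Probability of identifying all `load` targets by guessing a uniformly
#' random `load`-subset of `n_objects`: `1 / choose(n_objects, load)`.
#'
#' @param load Number of targets.
#' @param n_objects Total objects.
#' @return Guessing probability.
#' @export
guess_rate <- function(load, n_objects = 8) {
  if (any(load < 1) || any(load > n_objects)) stop("load must be in 1..n_objects")
  1 / choose(n_objects, load)
}

#' Probability of an all-targets-correct response
#'
#' `p = gamma + (1 - gamma - lapse) * S((log10 theta - log10 v) / sigma)`
#' with `S` the standard logistic, `theta` the per-load threshold and
#' `gamma` the guessing floor. Monotonically non-increasing in `v`; at
#' `v = theta` (with `lapse = 0` and the floor removed) it is exactly 0.5.
#'
#' @param observer A [psychometric_observer()].
#' @param speed Object speed, cm/s (> 0); vectorized.
#' @param load Number of targets.
#' @param guess Optional override of the guessing floor (e.g. 0 to inspect
#'   the bare sigmoid); default `guess_rate(load, n_objects)`.
#' @return Probability in `[0, 1]`.
#' @export
p_correct <- function(observer, speed, load, guess = NULL) {
  observer <- as_observer(observer)
  if (any(speed <= 0)) stop("speed must be positive")
  if (any(load < 1)) stop("load must be >= 1")
  gam <- if (is.null(guess)) guess_rate(load, observer$n_objects) else guess
  th <- threshold(observer, load)
  gam + (1 - gam - observer$lapse) *
    stats::plogis((log10(th) - log10(speed)) / observer$sigma)
}

#' Simulate one trial outcome
#'
#' Bernoulli draw at [p_correct()], consuming one uniform from the current
#' RNG stream (seed with [set.seed()] or via [derive_seed()] for
#' reproducibility).
#'
#' @inheritParams p_correct
#' @return Logical: all targets identified correctly.
#' @export
simulate_response <- function(observer, speed, load) {
  stats::runif(length(speed)) < p_correct(observer, speed, load)
}

#' Speed at the 50% point of the full response curve
#'
#' Solves `p_correct(v) = 0.5` in closed form; with a non-zero guessing
#' floor or lapse this sits slightly off the threshold `theta`. The
#' one-up/one-down staircase converges around this point.
#'
#' @inheritParams p_correct
#' @return Speed (cm/s) where the probability of an all-correct response is
#'   0.5, or `NA` if the curve never reaches 0.5.
#' @export
midpoint_speed <- function(observer, load) {
  observer <- as_observer(observer)
  gam <- guess_rate(load, observer$n_objects)
  s_target <- (0.5 - gam) / (1 - gam - observer$lapse)
  if (any(s_target <= 0 | s_target >= 1)) return(NA_real_)
  u <- stats::qlogis(s_target) # (log10 theta - log10 v)/sigma
  10^(log10(threshold(observer, load)) - u * observer$sigma)
}
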