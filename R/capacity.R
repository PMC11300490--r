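# Capacity models: the decreasing logarithmic curve of speed score against
# attentional load, and the log10-log10 linear allocation model whose slope
# of -1 is exact 1/i resource sharing.

new_capacity_fit <- function(model, slope, intercept, r.squared, data, fit,
                             group = NA_character_) {
  structure(list(model = model, slope = slope, intercept = intercept,
                 r.squared = r.squared, data = data, lm = fit, group = group),
            class = "capacity_fit")
}

fit_capacity_ls <- function(x, y, transform_x, transform_y, model, group) {
  stopifnot(length(x) == length(y))
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("non-finite inputs")
  if (any(x <= 0)) stop("loads must be positive")
  if (model == "loglog10" && any(y <= 0))
    stop("log-log fit requires positive speed scores")
  tx <- transform_x(x)
  ty <- transform_y(y)
  min_pts <- if (model == "log_natural") 3L else 2L
  if (length(unique(x)) < min_pts)
    stop("degenerate fit: need at least ", min_pts, " distinct loads")
  fit <- stats::lm(ty ~ tx)
  co <- stats::coef(fit)
  r2 <- if (stats::var(ty) == 0) {
    warning("zero-variance response: R^2 reported as 0 by convention")
    0
  } else {
    # computed directly so exact fits do not trip summary.lm warnings
    1 - sum(stats::residuals(fit)^2) / sum((ty - mean(ty))^2)
  }
  new_capacity_fit(model, unname(co[2]), unname(co[1]), r2,
                   data.frame(load = x, score = y), fit, group)
}

#' Fit the logarithmic capacity curve
#'
#' Ordinary least squares of the speed score on the natural log of the
#' attentional load: `y = a * ln(x) + b`. Fitted on group means of the
#' condition speed scores in the replication analysis (use per-participant
#' points for individual-differences work).
#'
#' @param load Attentional loads (>= 3 distinct values).
#' @param score Speed scores, cm/s.
#' @param group Optional group label carried into the fit object.
#' @return A `"capacity_fit"` with `slope` (a), `intercept` (b) and
#'   `r.squared`.
#' @examples
#' f <- fit_log_capacity(1:4, -125.4 * log(1:4) + 228.48)
#' coef(f) # recovers a = -125.4, b = 228.48 exactly
#' @export
fit_log_capacity <- function(load, score, group = NA_character_) {
  fit_capacity_ls(load, score, log, identity, "log_natural", group)
}

#' Fit the log-log allocation line
#'
#' Ordinary least squares of `log10(score)` on `log10(load)`:
#' `log10(y) = m * log10(x) + c`. Under the allocation model
#' `y = capacity / load`, the slope is exactly -1.
#'
#' @inheritParams fit_log_capacity
#' @return A `"capacity_fit"` with `slope` (m), `intercept` (c) and
#'   `r.squared`.
#' @examples
#' f <- fit_loglog(1:4, 320 / (1:4))
#' coef(f)["slope"] # -1
#' @export
fit_loglog <- function(load, score, group = NA_character_) {
  fit_capacity_ls(load, score, log10, log10, "loglog10", group)
}

#' Departure from exact 1/i resource allocation
#'
#' Difference between the fitted log-log slope and -1. Zero means resources
#' are shared exactly as the inverse of the number of targets; negative
#' values mean performance falls off faster than 1/i.
#'
#' @param fit A `"capacity_fit"` from [fit_loglog()].
#' @return Unitless slope deviation `m - (-1)`.
#' @export
allocation_departure <- function(fit) {
  stopifnot(inherits(fit, "capacity_fit"))
  if (fit$model != "loglog10")
    stop("allocation_departure is defined for log-log fits")
  fit$slope - (-1)
}

#' @export
coef.capacity_fit <- function(object, ...) {
  c(slope = object$slope, intercept = object$intercept)
}

#' @export
predict.capacity_fit <- function(object, load = object$data$load, ...) {
  if (any(load <= 0)) stop("loads must be positive")
  if (object$model == "log_natural") {
    object$slope * log(load) + object$intercept
  } else {
    10^(object$slope * log10(load) + object$intercept)
  }
}

#' @export
fitted.capacity_fit <- function(object, ...) predict(object)

#' @export
residuals.capacity_fit <- function(object, ...) {
  object$data$score - predict(object)
}

#' @export
print.capacity_fit <- function(x, digits = 4, ...) {
  eq <- if (x$model == "log_natural") {
    sprintf("y = %s*ln(x) + %s", format(x$slope, digits = digits),
            format(x$intercept, digits = digits))
  } else {
    sprintf("log10(y) = %s*log10(x) + %s", format(x$slope, digits = digits),
            format(x$intercept, digits = digits))
  }
  cat(sprintf("Capacity fit (%s%s): %s,  R^2 = %s\n",
              x$model,
              if (!is.na(x$group)) paste0(", ", x$group) else "",
              eq, format(x$r.squared, digits = digits)))
  invisible(x)
}

#' @export
summary.capacity_fit <- function(object, ...) {
  print(object)
  cat("\nPoints:\n")
  print(cbind(object$data, fitted = fitted(object),
              residual = residuals(object)), digits = 4)
  if (object$model == "loglog10") {
    cat(sprintf("\nAllocation departure (slope + 1): %.4f\n",
                allocation_departure(object)))
  }
  invisible(object)
}

#' @export
plot.capacity_fit <- function(x, ..., main = NULL) {
  d <- x$data
  if (x$model == "log_natural") {
    xx <- seq(min(d$load), max(d$load), length.out = 100)
    graphics::plot(d$load, d$score, pch = 19,
                   xlab = "attentional load (targets)",
                   ylab = "speed score (cm/s)",
                   main = main %||% "Capacity curve", ...)
    graphics::lines(xx, predict(x, xx))
  } else {
    graphics::plot(log10(d$load), log10(d$score), pch = 19,
                   xlab = "log10 load", ylab = "log10 speed score",
                   main = main %||% "Allocation (log-log)", ...)
    graphics::abline(x$intercept, x$slope)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group-level capacity fits
#'
#' Averages condition speed scores within group x load and fits both
#' capacity models per group, as in the replication analysis.
#'
#' @param scores Long score table (`group`, `load`, `speed_score`), e.g.
#'   `simulate_experiment(...)$scores`.
#' @return Named list per group, each with elements `means` (load, mean,
#'   se), `log_fit` and `loglog_fit`.
#' @export
group_capacity_fits <- function(scores) {
  stopifnot(all(c("group", "load", "speed_score") %in% names(scores)))
  out <- list()
  for (g in levels(factor(scores$group))) {
    d <- scores[scores$group == g, ]
    m <- stats::aggregate(speed_score ~ load, data = d, mean)
    s <- stats::aggregate(speed_score ~ load, data = d,
                          function(v) stats::sd(v) / sqrt(length(v)))
    means <- data.frame(load = m$load, mean = m$speed_score, se = s$speed_score)
    out[[g]] <- list(
      means = means,
      log_fit = fit_log_capacity(means$load, means$mean, group = g),
      loglog_fit = fit_loglog(means$load, means$mean, group = g)
    )
  }
  out
}
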