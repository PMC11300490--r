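test_that("refitting exact logarithmic data recovers the coefficients", {
  # points evaluated from published group curves, refit from scratch
  cases <- list(c(a = -125.4, b = 228.48), c(a = -130.4, b = 249.93),
                c(a = 40, b = 3), c(a = -2.5, b = 0.1))
  for (cf in cases) {
    y <- cf["a"] * log(1:4) + cf["b"]
    fit <- fit_log_capacity(1:4, y)
    expect_equal(fit$slope, unname(cf["a"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(cf["b"]), tolerance = 1e-10)
    expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  }
})

test_that("refitting exact power-law data recovers the log-log line", {
  cases <- list(c(m = -1.10, c = 2.37), c(m = -0.89, c = 2.41),
                c(m = -1, c = log10(320)))
  for (cf in cases) {
    y <- 10^(cf["c"]) * (1:4)^(cf["m"])
    fit <- fit_loglog(1:4, y)
    expect_equal(fit$slope, unname(cf["m"]), tolerance = 1e-10)
    expect_equal(fit$intercept, unname(cf["c"]), tolerance = 1e-10)
    expect_equal(fit$r.squared, 1, tolerance = 1e-10)
  }
  # y = k/x for any positive k is slope -1, intercept log10 k
  fit <- fit_loglog(1:4, 57 / (1:4))
  expect_equal(unname(coef(fit)), c(-1, log10(57)), tolerance = 1e-12)
})

test_that("least squares matches a grid-refined brute-force minimum", {
  set.seed(14)
  for (rep in 1:5) {
    y <- runif(4, 50, 250)
    fit <- fit_log_capacity(1:4, y)
    oracle <- grid_ls(log(1:4), y)
    expect_equal(fit$slope, oracle[1], tolerance = 1e-4)
    expect_equal(fit$intercept, oracle[2], tolerance = 1e-4)
  }
})

test_that("degenerate inputs are rejected or handled by convention", {
  expect_error(fit_log_capacity(c(1, 2), c(10, 20)), "degenerate")
  expect_error(fit_log_capacity(c(2, 2, 2), c(1, 2, 3)), "degenerate")
  expect_error(fit_loglog(2, 10), "degenerate")
  expect_error(fit_loglog(1:4, c(-1, 2, 3, 4)), "positive")
  expect_error(fit_log_capacity(0:3, c(1, 2, 3, 4)), "positive")
  # flat response: zero slope, R^2 reported as 0 with a warning
  expect_warning(flat <- fit_log_capacity(1:4, rep(100, 4)), "zero-variance")
  expect_equal(flat$slope, 0)
  expect_identical(flat$r.squared, 0)
})

test_that("allocation departure measures deviation from 1/i sharing", {
  mk <- function(m) fit_loglog(1:4, 10^(2 + m * log10(1:4)))
  expect_equal(allocation_departure(mk(-1)), 0, tolerance = 1e-12)
  expect_equal(allocation_departure(mk(-1.10)), -0.10, tolerance = 1e-10)
  expect_equal(allocation_departure(mk(-0.89)), 0.11, tolerance = 1e-10)
  expect_error(allocation_departure(fit_log_capacity(1:4, 1:4)), "log-log")
})

test_that("log-log slope is invariant to rescaling the response", {
  set.seed(15)
  y <- runif(4, 50, 250)
  f1 <- fit_loglog(1:4, y)
  f2 <- fit_loglog(1:4, 7.3 * y)
  expect_equal(f2$slope, f1$slope, tolerance = 1e-12)
  expect_equal(f2$intercept, f1$intercept + log10(7.3), tolerance = 1e-12)
})

test_that("capacity_fit methods are mutually consistent", {
  y <- c(228, 150, 95, 60)
  fit <- fit_log_capacity(1:4, y)
  expect_named(coef(fit), c("slope", "intercept"))
  expect_equal(predict(fit, 1), fit$intercept)
  expect_equal(fitted(fit) + residuals(fit), y, tolerance = 1e-12)
  ll <- fit_loglog(1:4, y)
  expect_equal(predict(ll, 1), 10^ll$intercept, tolerance = 1e-12)
  expect_output(print(fit), "ln\\(x\\)")
  expect_output(summary(ll), "Allocation departure")
})

test_that("group fits aggregate condition scores per group", {
  co <- generate_cohort(cohort_config(n_per_group = 6, seed = 4))
  ex <- simulate_experiment(co, seed = 4)
  fits <- group_capacity_fits(ex$scores)
  expect_setequal(names(fits), c("autism", "neurotypical"))
  for (g in fits) {
    expect_equal(nrow(g$means), 4)
    expect_s3_class(g$log_fit, "capacity_fit")
    expect_s3_class(g$loglog_fit, "capacity_fit")
    # group means decrease with load
    expect_true(all(diff(g$means$mean) < 0))
  }
})
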