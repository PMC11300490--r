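test_that("step coefficients match the normal-equations oracle", {
  d <- make_reg_data(n = 10, seed = 17) # 40-row seeded design
  h <- hierarchical_regression(d)
  X1 <- cbind(1, d$load, d$asd, d$load * d$asd)
  expect_equal(h$step1$table$b, ne_coef(X1, d$speed_score), tolerance = 1e-8)
  X2 <- cbind(1, d$load, d$asd, d$cpt3_d, d$pri, d$vci, d$load * d$asd)
  ord <- match(c("(Intercept)", "load", "asd", "cpt3_d", "pri", "vci",
                 "load:asd"), h$step2$table$term)
  expect_equal(h$step2$table$b[ord], ne_coef(X2, d$speed_score),
               tolerance = 1e-8)
  expect_equal(h$step1$r.squared, ne_r2(X1, d$speed_score), tolerance = 1e-10)
  expect_equal(h$step2$r.squared, ne_r2(X2, d$speed_score), tolerance = 1e-10)
})

test_that("sr^2 is the unique R^2 each term adds, bounded by model R^2", {
  d <- make_reg_data(n = 12, seed = 19, noise = 20)
  h <- hierarchical_regression(d)
  tab <- h$step2$table
  y <- d$speed_score
  cols <- list("(Intercept)" = rep(1, nrow(d)), load = d$load, asd = d$asd,
               cpt3_d = d$cpt3_d, pri = d$pri, vci = d$vci,
               "load:asd" = d$load * d$asd)
  Xf <- do.call(cbind, cols)
  r2_full <- ne_r2(Xf, y)
  for (tm in c("load", "asd", "cpt3_d", "pri", "vci", "load:asd")) {
    Xr <- do.call(cbind, cols[setdiff(names(cols), tm)])
    sr2_oracle <- r2_full - ne_r2(Xr, y)
    got <- tab$sr2[tab$term == tm]
    expect_equal(got, max(sr2_oracle, 0), tolerance = 1e-8)
    expect_lte(got, h$step2$r.squared + 1e-12)
  }
  # model R^2 equals 1 - SSE/SST to high precision
  fit <- h$step2$fit
  sse <- sum(residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  expect_equal(h$step2$r.squared, 1 - sse / sst, tolerance = 1e-10)
})

test_that("nested-model Delta F follows the closed form", {
  cmp <- delta_f(0.676, 0.724, q = 3, df_den = 429)
  # value implied by the published step R^2 pair (printed as 24.99 from
  # unrounded inputs)
  expect_equal(cmp$delta_f, 24.87, tolerance = 0.01)
  expect_equal(cmp$delta_r2, 0.048, tolerance = 1e-12)
  expect_lt(cmp$p, 0.001)
  # agreement with anova() on an actual nested pair
  d <- make_reg_data(n = 10, seed = 23, noise = 15)
  h <- hierarchical_regression(d)
  ref <- anova(h$step1$fit, h$step2$fit)
  expect_equal(h$comparison$delta_f, ref$F[2], tolerance = 1e-8)
  expect_equal(h$comparison$p, ref$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("noise-free data gives a saturated fit and collinearity errors name terms", {
  d <- make_reg_data(n = 8, seed = 29, noise = 0)
  h <- hierarchical_regression(d)
  expect_equal(h$step2$r.squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(residuals(h$step2$fit))), 1e-8)
  # aliased predictor
  d$dup <- d$pri
  expect_error(
    hierarchical_regression(d, step2_terms = c("cpt3_d", "pri", "vci", "dup")),
    "collinear")
})

test_that("load coding options change the design as documented", {
  d <- make_reg_data(n = 10, seed = 31, noise = 5)
  hn <- hierarchical_regression(d)
  expect_true("load" %in% hn$step1$table$term) # single numeric slope
  hf <- hierarchical_regression(d, load_coding = "factor")
  expect_true(any(grepl("load[234]", hf$step1$table$term)))
})

test_that("capacity-link recovery rescales the marginal PRI slope", {
  co <- generate_cohort(cohort_config(n_per_group = 40, seed = 41))
  ex <- simulate_experiment(co, seed = 41)
  tab <- analysis_table(ex, co)
  link <- estimate_capacity_link(tab, alpha = 1)
  expect_equal(link$scale, mean(1 / (1:4)))
  expect_equal(link$estimate, link$marginal / link$scale, tolerance = 1e-12)
  # estimate in the right region of the generative value
  expect_lt(abs(link$estimate - 0.94), 0.75)
  expect_lt(link$ci[1], link$estimate)
  expect_gt(link$ci[2], link$estimate)
})
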