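test_that("mixed ANOVA matches the explicit sums-of-squares oracle", {
  d <- make_mixed_data(a = 2, b = 2, w = 2, n = 4, seed = 51)
  res <- mixed_anova(d, dv = "y", id = "id", within = "W",
                     between = c("A", "B"))
  oracle <- ss_oracle(d)
  key <- function(x) gsub(" ", "", x)
  for (i in seq_len(nrow(oracle))) {
    row <- res$table[key(res$table$effect) == key(oracle$effect[i]), ]
    expect_equal(nrow(row), 1)
    expect_equal(row$ss, oracle$ss[i], tolerance = 1e-8)
    expect_equal(row$ss_err, oracle$ss_err[i], tolerance = 1e-8)
    expect_equal(row$F, oracle$F[i], tolerance = 1e-8)
    expect_equal(row$df_num, oracle$df_num[i])
    expect_equal(row$df_den, oracle$df_den[i])
  }
  # partial eta^2 is SS_effect / (SS_effect + SS_error) in its own stratum
  expect_equal(res$table$pes,
               res$table$ss / (res$table$ss + res$table$ss_err),
               tolerance = 1e-12)
  expect_true(all(res$table$pes >= 0 & res$table$pes <= 1))
})

test_that("a four-level within factor decomposes against the oracle too", {
  d <- make_mixed_data(a = 2, b = 2, w = 4, n = 3, seed = 53)
  res <- mixed_anova(d, dv = "y", id = "id", within = "W",
                     between = c("A", "B"))
  oracle <- ss_oracle(d)
  got <- res$table[match(gsub("W", "W", oracle$effect),
                         gsub(" ", "", res$table$effect)), ]
  expect_equal(got$ss, oracle$ss, tolerance = 1e-8)
  expect_equal(got$F, oracle$F, tolerance = 1e-8)
})

test_that("F statistics are invariant to adding a constant", {
  d <- make_mixed_data(a = 2, b = 2, w = 3, n = 4, seed = 55)
  r1 <- mixed_anova(d, dv = "y", id = "id", within = "W",
                    between = c("A", "B"))
  d$y <- d$y + 1234.5
  r2 <- mixed_anova(d, dv = "y", id = "id", within = "W",
                    between = c("A", "B"))
  expect_equal(r2$table$F, r1$table$F, tolerance = 1e-8)
  expect_equal(r2$table$pes, r1$table$pes, tolerance = 1e-8)
})

test_that("exactly equal between-cell means give zero between F", {
  d <- make_mixed_data(a = 2, b = 2, w = 2, n = 6, seed = 57,
                       effects = c(A = 0, B = 0, W = 5, AB = 0, AW = 0,
                                   BW = 0, ABW = 0))
  # center participant means within each between cell so the cell means are
  # *identical*, leaving only subject-level and within-load variation
  cellmean <- tapply(d$y, list(d$A, d$B), mean)
  d$y <- d$y - cellmean[cbind(d$A, d$B)] + mean(d$y)
  res <- mixed_anova(d, dv = "y", id = "id", within = "W",
                     between = c("A", "B"))
  btw <- res$table[res$table$effect %in% c("A", "B", "A:B"), ]
  expect_true(all(btw$F < 1e-12))
  expect_true(all(btw$pes < 1e-12))
  w <- res$table[res$table$effect == "W", ]
  expect_gt(w$F, 10)
})

test_that("incomplete designs are rejected with diagnostics", {
  d <- make_mixed_data(a = 2, b = 2, w = 2, n = 3, seed = 59)
  expect_error(mixed_anova(d[-1, ], dv = "y", id = "id", within = "W",
                           between = c("A", "B")), "incomplete")
  # a between cell with a single participant
  drop_ids <- unique(d$id[d$A == 1 & d$B == 1])[-1]
  d2 <- d[!d$id %in% drop_ids, ]
  expect_error(mixed_anova(d2, dv = "y", id = "id", within = "W",
                           between = c("A", "B")), "cell")
})

test_that("trend coding reports single-df load effects on subject df", {
  d <- make_mixed_data(a = 2, b = 2, w = 4, n = 14, seed = 61,
                       effects = c(A = 3, B = 6, W = 10, AB = 0, AW = 0,
                                   BW = 0, ABW = 0))
  res <- mixed_anova(d, dv = "y", id = "id", within = "W",
                     between = c("A", "B"), trend = TRUE)
  wrow <- res$table[res$table$effect == "W", ]
  expect_equal(wrow$df_num, 1)
  expect_equal(wrow$df_den, 4 * 14 - 4) # F(1, 52) with 14 per cell
  expect_lt(wrow$p, 0.001)
  # linear trend oracle: one-sample t on per-subject contrast scores
  wts <- scale(1:4, scale = FALSE)[, 1]
  wts <- wts / sqrt(sum(wts^2))
  wide <- unique(d[, c("id", "A", "B")])
  cs <- tapply(seq_len(nrow(d)), d$id, function(i) {
    di <- d[i, ]; sum(di$y[order(di$W)] * wts)
  })
  fit <- lm(cs[as.character(wide$id)] ~ A * B, data = wide,
            contrasts = list(A = "contr.sum", B = "contr.sum"))
  t_int <- summary(fit)$coefficients["(Intercept)", "t value"]
  expect_equal(wrow$F, t_int^2, tolerance = 1e-8)
})
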