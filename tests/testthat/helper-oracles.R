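# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain normal equations, explicit sums of
# squares, grid search, and enumeration.

# Least-squares coefficients by the normal equations.
ne_coef <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

ne_r2 <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  res <- y - X %*% b
  1 - sum(res^2) / sum((y - mean(y))^2)
}

# Grid-refined least-squares minimum for y ~ slope * f(x) + intercept.
grid_ls <- function(fx, y, rounds = 6, span = NULL, center = NULL) {
  if (is.null(center)) center <- c(0, mean(y))
  if (is.null(span)) span <- c(max(abs(y)) + 1, max(abs(y)) + 1)
  best <- center
  for (r in seq_len(rounds)) {
    sl <- seq(best[1] - span[1], best[1] + span[1], length.out = 41)
    ic <- seq(best[2] - span[2], best[2] + span[2], length.out = 41)
    sse <- outer(sl, ic, function(a, b)
      vapply(seq_along(a), function(k)
        sum((y - (a[k] * fx + b[k]))^2), numeric(1)))
    ij <- which(sse == min(sse), arr.ind = TRUE)[1, ]
    best <- c(sl[ij[1]], ic[ij[2]])
    span <- span / 10
  }
  best # (slope, intercept)
}

# Explicit sums-of-squares decomposition for a balanced two-between
# (A, B) x one-within (W) mixed design with subjects nested in A x B.
# Returns the same effects as mixed_anova(trend = FALSE).
ss_oracle <- function(d, dv = "y", A = "A", B = "B", W = "W", id = "id") {
  y <- d[[dv]]
  fA <- factor(d[[A]]); fB <- factor(d[[B]])
  fW <- factor(d[[W]]); fS <- factor(d[[id]])
  a <- nlevels(fA); b <- nlevels(fB); w <- nlevels(fW)
  n <- length(unique(fS)) / (a * b) # subjects per cell
  gm <- mean(y)
  m_a <- tapply(y, fA, mean); m_b <- tapply(y, fB, mean)
  m_w <- tapply(y, fW, mean)
  m_ab <- tapply(y, list(fA, fB), mean)
  m_aw <- tapply(y, list(fA, fW), mean)
  m_bw <- tapply(y, list(fB, fW), mean)
  m_abw <- tapply(y, list(fA, fB, fW), mean)
  m_s <- tapply(y, fS, mean)
  s_cell <- tapply(y, fS, function(i) NA) # placeholder
  # subject cell means: each subject sits in one AxB cell
  sub_ab <- unique(data.frame(s = fS, a = fA, b = fB))
  ss_A <- n * b * w * sum((m_a - gm)^2)
  ss_B <- n * a * w * sum((m_b - gm)^2)
  ss_AB <- n * w * sum((m_ab - outer(m_a - gm, m_b - gm, "+") - gm)^2)
  ss_W <- n * a * b * sum((m_w - gm)^2)
  ss_AW <- n * b * sum((m_aw - outer(m_a, m_w, "+") + gm)^2)
  ss_BW <- n * a * sum((m_bw - outer(m_b, m_w, "+") + gm)^2)
  dev_abw <- m_abw
  for (i in 1:a) for (j in 1:b) for (k in 1:w) {
    dev_abw[i, j, k] <- m_abw[i, j, k] - m_ab[i, j] - m_aw[i, k] - m_bw[j, k] +
      m_a[i] + m_b[j] + m_w[k] - gm
  }
  ss_ABW <- n * sum(dev_abw^2)
  cellmean_of_sub <- m_ab[cbind(as.integer(sub_ab$a), as.integer(sub_ab$b))]
  ss_subj <- w * sum((m_s[as.character(sub_ab$s)] - cellmean_of_sub)^2)
  ss_tot <- sum((y - gm)^2)
  ss_err_w <- ss_tot - ss_A - ss_B - ss_AB - ss_subj - ss_W - ss_AW -
    ss_BW - ss_ABW
  df_subj <- a * b * (n - 1)
  df_err_w <- a * b * (n - 1) * (w - 1)
  eff <- function(name, ss, df1, ss_err, df_err) {
    data.frame(effect = name, ss = ss, df_num = df1, ss_err = ss_err,
               df_den = df_err, F = (ss / df1) / (ss_err / df_err))
  }
  rbind(
    eff("A", ss_A, a - 1, ss_subj, df_subj),
    eff("B", ss_B, b - 1, ss_subj, df_subj),
    eff("A:B", ss_AB, (a - 1) * (b - 1), ss_subj, df_subj),
    eff("W", ss_W, w - 1, ss_err_w, df_err_w),
    eff("A:W", ss_AW, (a - 1) * (w - 1), ss_err_w, df_err_w),
    eff("B:W", ss_BW, (b - 1) * (w - 1), ss_err_w, df_err_w),
    eff("A:B:W", ss_ABW, (a - 1) * (b - 1) * (w - 1), ss_err_w, df_err_w)
  )
}

# Balanced toy mixed-design dataset builder.
make_mixed_data <- function(a = 2, b = 2, w = 2, n = 4, seed = 1,
                            effects = c(A = 3, B = 2, W = 5, AB = 1,
                                        AW = 0.5, BW = 0, ABW = 0.2),
                            sd_subj = 1, sd_err = 1) {
  set.seed(seed)
  grid <- expand.grid(A = factor(seq_len(a)), B = factor(seq_len(b)),
                      s = seq_len(n))
  grid$id <- factor(paste0(grid$A, grid$B, grid$s))
  subj_int <- stats::rnorm(nrow(grid), 0, sd_subj)
  out <- do.call(rbind, lapply(seq_len(w), function(k) {
    d <- grid
    d$W <- factor(k, levels = seq_len(w))
    zA <- as.integer(d$A) - mean(seq_len(a))
    zB <- as.integer(d$B) - mean(seq_len(b))
    zW <- k - mean(seq_len(w))
    d$y <- effects["A"] * zA + effects["B"] * zB + effects["W"] * zW +
      effects["AB"] * zA * zB + effects["AW"] * zA * zW +
      effects["BW"] * zB * zW + effects["ABW"] * zA * zB * zW +
      subj_int + stats::rnorm(nrow(d), 0, sd_err)
    d
  }))
  out
}

# A practically deterministic step observer: all-correct below the load-4
# threshold, all-incorrect above (guessing floor 1/choose(16, 4), width ~0).
step_observer <- function(threshold_speed) {
  psychometric_observer(capacity = threshold_speed * 4, alpha = 1,
                        sigma = 1e-9, lapse = 0, n_objects = 16)
}

# Seeded participant-by-load toy design for regression tests.
make_reg_data <- function(n = 10, seed = 17, noise = 1) {
  set.seed(seed)
  d <- expand.grid(id = seq_len(n), load = 1:4)
  d$id <- sprintf("P%02d", d$id)
  per <- data.frame(id = sprintf("P%02d", seq_len(n)),
                    group = rep(c("autism", "neurotypical"), length.out = n),
                    pri = rnorm(n, 100, 15), vci = rnorm(n, 100, 15),
                    cpt3_d = rnorm(n, 50, 10))
  d <- merge(d, per, by = "id")
  d$group <- factor(d$group, levels = c("neurotypical", "autism"))
  d$asd <- as.integer(d$group == "autism")
  d$speed_score <- 250 - 55 * d$load - 15 * d$asd + 0.8 * (d$pri - 100) +
    rnorm(nrow(d), 0, noise)
  d
}
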