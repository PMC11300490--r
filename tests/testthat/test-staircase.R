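test_that("speed updates follow the 0.05-log step rule with clamping", {
  cfg <- staircase_config()
  st <- staircase_init(cfg)
  expect_equal(st$speed, 68)
  down <- staircase_step(st, FALSE, cfg)
  expect_equal(down$speed, 68 * 10^(-0.05)) # ~60.61
  up <- staircase_step(st, TRUE, cfg)
  expect_equal(up$speed, 68 * 10^(0.05))
  # multiplicative symmetry: up then down returns exactly to the start
  back <- staircase_step(up, FALSE, cfg)
  expect_equal(back$speed, 68)
  # clamping at both bounds
  hi <- st; hi$speed <- 544
  expect_equal(staircase_step(hi, TRUE, cfg)$speed, 544)
  lo <- st; lo$speed <- 0.68
  expect_equal(staircase_step(lo, FALSE, cfg)$speed, 0.68)
})

test_that("inversions are recorded at the speed of the reversing trial", {
  cfg <- staircase_config()
  st <- staircase_init(cfg)
  st <- staircase_step(st, TRUE, cfg)   # trial 1 at 68, no direction yet
  expect_length(st$inversion_speeds, 0)
  v2 <- st$speed                        # 68 * 10^0.05
  st <- staircase_step(st, FALSE, cfg)  # correct -> incorrect: inversion
  expect_equal(st$inversion_speeds, v2)
  st <- staircase_step(st, FALSE, cfg)  # same direction: no new inversion
  expect_length(st$inversion_speeds, 1)
  v4 <- st$speed
  st <- staircase_step(st, TRUE, cfg)   # incorrect -> correct: inversion
  expect_equal(st$inversion_speeds, c(v2, v4))
})

test_that("a step observer's block score lands within one log step of threshold", {
  obs <- step_observer(100) # all-correct below 100 cm/s, all-incorrect above
  set.seed(5)
  blk <- run_block(obs, load = 4)
  expect_length(blk$inversion_speeds, 6)
  expect_gt(blk$block_score, 100 * 10^(-0.05))
  expect_lt(blk$block_score, 100 * 10^(0.05))
  # exhaustive trace oracle: from 68 the staircase climbs while correct,
  # then alternates between the first speed above threshold (v_hi) and the
  # one just below; the six inversions are three of each, so the geometric
  # mean is exactly v_hi * 10^(-0.025)
  v_hi <- 68
  while (v_hi <= 100) v_hi <- v_hi * 10^0.05
  expect_equal(blk$block_score, v_hi * 10^(-0.025), tolerance = 1e-9)
})

test_that("blocks score the geometric mean of six inversions", {
  x <- c(68, 60.61, 68, 60.61, 68, 60.61)
  expect_equal(geometric_mean(x), 64.19, tolerance = 1e-3)
  set.seed(8)
  blk <- run_block(psychometric_observer(150), load = 2)
  expect_equal(blk$block_score, geometric_mean(blk$inversion_speeds))
  expect_true(blk$block_score >= min(blk$inversion_speeds))
  expect_true(blk$block_score <= max(blk$inversion_speeds))
  # the trial log flags exactly the six inversion trials
  expect_equal(sum(blk$trials$inversion_flag), 6)
  expect_equal(blk$trials$speed_cms[blk$trials$inversion_flag],
               blk$inversion_speeds)
  expect_true(all(blk$trials$speed_cms >= 0.68 &
                    blk$trials$speed_cms <= 544))
})

test_that("a floor-level observer oscillates at the clamp yet terminates", {
  # capacity far below the staircase floor: correct responses happen only
  # by guessing (p = 1/70), mostly while pinned at speed_min, and those
  # direction changes still count as inversions so the block terminates
  obs <- psychometric_observer(0.001, sigma = 1e-6, lapse = 0)
  cfg <- staircase_config(max_trials = 2000)
  set.seed(21)
  blk <- run_block(obs, load = 4, config = cfg)
  expect_length(blk$inversion_speeds, 6)
  expect_equal(min(blk$trials$speed_cms), 0.68) # reached the clamp
  expect_true(all(blk$inversion_speeds >= 0.68))
  expect_lt(blk$block_score, 68) # far below the starting speed
  # a zero-probability observer cannot invert: the trial cap fires
  never <- psychometric_observer(1e-6, sigma = 1e-9, lapse = 0,
                                 n_objects = 100)
  set.seed(22)
  expect_error(run_block(never, load = 4), "inversions")
})

test_that("the fast block loop agrees with the exported response model", {
  # run_block inlines p_correct for speed; verify the two never diverge
  obs <- psychometric_observer(216, sigma = 0.04, lapse = 0.05)
  for (ld in 1:4) {
    gam <- guess_rate(ld, obs$n_objects)
    lt <- log10(threshold(obs, ld))
    v <- 10^seq(log10(0.68), log10(544), length.out = 41)
    inline_p <- gam + (1 - gam - obs$lapse) /
      (1 + exp(-(lt - log10(v)) / obs$sigma))
    expect_equal(inline_p, p_correct(obs, v, ld), tolerance = 1e-12)
  }
})

test_that("condition scores average two independent blocks", {
  obs <- psychometric_observer(150)
  set.seed(10)
  cond <- run_condition(obs, load = 2)
  expect_length(cond$block_scores, 2)
  expect_equal(cond$speed_score, mean(cond$block_scores))
  expect_false(cond$block_scores[1] == cond$block_scores[2])
  # geometric aggregation option
  set.seed(10)
  cond_g <- run_condition(obs, 2, staircase_config(block_average = "geometric"))
  expect_equal(cond_g$speed_score, geometric_mean(cond_g$block_scores))
})

test_that("staircase estimator converges near the psychometric midpoint", {
  # one-up/one-down targets the 50% point; over many seeded blocks the
  # mean log error stays within one 0.05-log step
  obs <- psychometric_observer(150, sigma = 0.04, lapse = 0)
  mid <- midpoint_speed(obs, 2)
  err <- vapply(1:200, function(b) {
    set.seed(1000 + b)
    log10(run_block(obs, 2)$block_score) - log10(mid)
  }, numeric(1))
  expect_lt(abs(mean(err)), 0.05)
})

test_that("qualification implements the two-round comprehension rule", {
  expect_identical(as.character(qualification(c(TRUE, TRUE))), "qualified")
  expect_identical(attr(qualification(c(TRUE, TRUE)), "trials_used"), 2L)
  expect_identical(as.character(qualification(c(TRUE, FALSE, TRUE))),
                   "qualified")
  r2 <- qualification(c(FALSE, FALSE, FALSE, TRUE, TRUE))
  expect_identical(as.character(r2), "requalified")
  expect_identical(attr(r2, "round"), 2L)
  expect_identical(
    as.character(qualification(c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))),
    "failed")
  expect_error(qualification(c(TRUE, FALSE)), "incomplete")
  expect_error(qualification(logical(0)), "incomplete")
})

test_that("experiment runner is seed-stable, order-invariant and complete", {
  co <- generate_cohort(cohort_config(n_per_group = 4, seed = 2))
  e1 <- simulate_experiment(co, seed = 5)
  e2 <- simulate_experiment(co, seed = 5)
  expect_identical(e1$scores, e2$scores)
  expect_equal(nrow(e1$scores), nrow(co) * 4)
  expect_setequal(unique(e1$scores$load), 1:4)
  # per-participant streams: reversing the cohort order leaves scores intact
  e3 <- simulate_experiment(co[rev(seq_len(nrow(co))), ], seed = 5)
  m1 <- e1$scores[order(e1$scores$id, e1$scores$load), ]
  m3 <- e3$scores[order(e3$scores$id, e3$scores$load), ]
  rownames(m1) <- rownames(m3) <- NULL
  expect_equal(m1, m3)
  # a different seed moves the scores
  e4 <- simulate_experiment(co, seed = 6)
  expect_false(all(e4$scores$speed_score == e1$scores$speed_score))
  # trial log carries participant, load, block and inversion bookkeeping
  e5 <- simulate_experiment(co[1:2, ], seed = 5, trial_log = TRUE)
  expect_true(all(c("participant_id", "load", "block", "speed_cms",
                    "correct", "inversion_flag") %in% names(e5$trials)))
  expect_equal(sum(e5$trials$inversion_flag), 2 * 4 * 2 * 6)
})
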