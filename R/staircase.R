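# Adaptive one-up/one-down speed staircase: trial-to-trial speed updates,
# inversion bookkeeping, geometric-mean block scores, and two-block
# condition speed scores (the study design's primary outcome).

#' Staircase configuration
#'
#' Protocol constants of the adaptive speed staircase: speed starts at 68
#' cm/s, moves up after a correct response and down after an incorrect one
#' by 0.05 log10 units, is clamped to \[0.68, 544\] cm/s, and a block ends at
#' the sixth inversion (a correct answer followed by an incorrect one, or
#' vice versa). The block score is the geometric mean of the six inversion
#' speeds; the condition speed score averages two blocks.
#'
#' @param initial_speed Starting speed, cm/s.
#' @param log_step Step size in log10 units.
#' @param speed_min,speed_max Clamp bounds, cm/s.
#' @param inversions_to_stop Inversions ending a block (default 6).
#' @param blocks_per_condition Blocks averaged into a condition score.
#' @param max_trials Non-convergence guard: a block aborts with an error
#'   after this many trials.
#' @param block_average `"arithmetic"` (default: the mean of the two block
#'   scores) or `"geometric"`.
#' @return A list of class `"staircase_config"`.
#' @export
staircase_config <- function(initial_speed = 68, log_step = 0.05,
                             speed_min = 0.68, speed_max = 544,
                             inversions_to_stop = 6L,
                             blocks_per_condition = 2L,
                             max_trials = 500L,
                             block_average = c("arithmetic", "geometric")) {
  block_average <- match.arg(block_average)
  stopifnot(speed_min > 0, speed_min < initial_speed,
            initial_speed < speed_max, log_step > 0,
            inversions_to_stop >= 2, blocks_per_condition >= 1,
            max_trials > inversions_to_stop)
  structure(list(initial_speed = initial_speed, log_step = log_step,
                 speed_min = speed_min, speed_max = speed_max,
                 inversions_to_stop = as.integer(inversions_to_stop),
                 blocks_per_condition = as.integer(blocks_per_condition),
                 max_trials = as.integer(max_trials),
                 block_average = block_average),
            class = "staircase_config")
}

#' Initialize a staircase state
#'
#' @param config A [staircase_config()].
#' @return A list of class `"staircase_state"`: `speed` (the speed the next
#'   trial is presented at), `speeds`/`correct` (trial history),
#'   `inversion_speeds`, and `last_correct` (NA before the first trial; the
#'   first trial has no direction, so the earliest possible inversion is at
#'   trial 2).
#' @export
staircase_init <- function(config = staircase_config()) {
  structure(list(speed = config$initial_speed,
                 speeds = numeric(0), correct = logical(0),
                 inversion_speeds = numeric(0), last_correct = NA),
            class = "staircase_state")
}

#' Record a response and compute the next speed
#'
#' The trial is presented at `state$speed`; `correct` is its outcome. When
#' the response direction reverses (correct after incorrect or vice versa)
#' an inversion is recorded at the presented speed of the reversing trial.
#' The next speed is `speed * 10^(+log_step)` after a correct response and
#' `speed * 10^(-log_step)` after an incorrect one, clamped to
#' `[speed_min, speed_max]`. Direction changes still count as inversions
#' while the speed is pinned at a clamp, so degenerate observers cannot
#' deadlock a block.
#'
#' @param state A `"staircase_state"`.
#' @param correct Logical outcome of the trial at `state$speed`.
#' @param config A [staircase_config()].
#' @return The updated state.
#' @export
staircase_step <- function(state, correct, config = staircase_config()) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1, !is.na(correct))
  v <- state$speed
  state$speeds <- c(state$speeds, v)
  state$correct <- c(state$correct, correct)
  if (!is.na(state$last_correct) && correct != state$last_correct) {
    state$inversion_speeds <- c(state$inversion_speeds, v)
  }
  state$last_correct <- correct
  vnew <- v * 10^(if (correct) config$log_step else -config$log_step)
  state$speed <- min(max(vnew, config$speed_min), config$speed_max)
  state
}

#' Run one staircase block against an observer
#'
#' Iterates [simulate_response()] and [staircase_step()] until
#' `inversions_to_stop` inversions have occurred, then scores the block as
#' the geometric mean of the inversion speeds. Uses the current RNG stream;
#' seed before calling for reproducibility.
#'
#' @param observer A [psychometric_observer()] (or a cohort row).
#' @param load Number of targets (1--4).
#' @param config A [staircase_config()].
#' @return A list of class `"block_result"`: `block_score` (cm/s),
#'   `inversion_speeds`, `n_trials`, and a `trials` data.frame
#'   (`trial_index`, `speed_cms`, `correct`, `inversion_flag`).
#' @examples
#' set.seed(11)
#' blk <- run_block(psychometric_observer(150), load = 2)
#' blk$block_score
#' @export
run_block <- function(observer, load, config = staircase_config()) {
  observer <- as_observer(observer)
  if (load < 1) stop("load must be >= 1")
  # flat, validated-once inner loop: the staircase is the hot path of every
  # simulated experiment
  gam <- guess_rate(load, observer$n_objects)
  lt <- log10(threshold(observer, load))
  one_minus <- 1 - gam - observer$lapse
  sig <- observer$sigma
  up <- 10^config$log_step
  dn <- 10^(-config$log_step)
  vmin <- config$speed_min
  vmax <- config$speed_max
  n_stop <- config$inversions_to_stop
  maxt <- config$max_trials
  u <- stats::runif(maxt)

  speeds <- numeric(maxt)
  corr <- logical(maxt)
  invf <- logical(maxt)
  inv_speeds <- numeric(n_stop)
  v <- config$initial_speed
  last <- NA
  n_inv <- 0L
  t <- 0L
  while (n_inv < n_stop) {
    t <- t + 1L
    if (t > maxt) {
      stop(sprintf(
        "staircase did not reach %d inversions within %d trials (load %d, C = %.3g)",
        n_stop, maxt, load, observer$capacity))
    }
    p <- gam + one_minus / (1 + exp(-(lt - log10(v)) / sig))
    c_t <- u[t] < p
    speeds[t] <- v
    corr[t] <- c_t
    if (!is.na(last) && c_t != last) {
      n_inv <- n_inv + 1L
      inv_speeds[n_inv] <- v
      invf[t] <- TRUE
    }
    last <- c_t
    v <- v * (if (c_t) up else dn)
    v <- min(max(v, vmin), vmax)
  }
  structure(list(
    block_score = geometric_mean(inv_speeds),
    inversion_speeds = inv_speeds,
    n_trials = t,
    trials = data.frame(trial_index = seq_len(t), speed_cms = speeds[seq_len(t)],
                        correct = corr[seq_len(t)], inversion_flag = invf[seq_len(t)])
  ), class = "block_result")
}

#' Run one condition (two blocks at one attentional load)
#'
#' @inheritParams run_block
#' @return A list of class `"condition_score"`: `load`, `block_scores`, and
#'   `speed_score` (their arithmetic mean by default; the outcome measure at
#'   this load).
#' @export
run_condition <- function(observer, load, config = staircase_config()) {
  blocks <- lapply(seq_len(config$blocks_per_condition), function(b)
    run_block(observer, load, config))
  scores <- vapply(blocks, `[[`, numeric(1), "block_score")
  y <- if (config$block_average == "arithmetic") mean(scores)
       else geometric_mean(scores)
  structure(list(load = load, block_scores = scores, speed_score = y,
                 blocks = blocks),
            class = "condition_score")
}

#' Qualification rule for task comprehension
#'
#' Participants qualify by tracking one of eight objects in the first two of
#' three trials (two correct responses among the first three, short-circuiting
#' when the first two are both correct). If they fail, instructions are
#' re-explained and a second round of three trials requires two correct
#' responses.
#'
#' @param responses Ordered logical vector of 1-target practice outcomes.
#' @return `"qualified"` (round 1), `"requalified"` (round 2) or `"failed"`.
#'   Attributes `round` and `trials_used` record how the decision was made.
#' @examples
#' qualification(c(TRUE, TRUE))
#' qualification(c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
#' @export
qualification <- function(responses) {
  stopifnot(is.logical(responses))
  need <- function(k) if (length(responses) < k)
    stop("incomplete input: need at least ", k, " responses")
  round_pass <- function(offset) {
    # pass with >=2 correct of 3; short-circuit when the first two are correct
    need(offset + 2L)
    r <- responses[(offset + 1L):(offset + 2L)]
    if (all(r)) return(list(pass = TRUE, used = offset + 2L))
    need(offset + 3L)
    r3 <- responses[(offset + 1L):(offset + 3L)]
    list(pass = sum(r3) >= 2, used = offset + 3L)
  }
  r1 <- round_pass(0L)
  if (r1$pass)
    return(structure("qualified", round = 1L, trials_used = r1$used))
  r2 <- round_pass(r1$used)
  if (r2$pass)
    return(structure("requalified", round = 2L, trials_used = r2$used))
  structure("failed", round = 2L, trials_used = r2$used)
}

#' Simulate the full MOT protocol for a cohort
#'
#' For every participant, runs two staircase blocks at each attentional load
#' 1--4 (block order randomized per participant, as in the task protocol)
#' and records block scores and condition speed scores. Per-participant
#' random streams are derived from `seed` and the participant id, so results
#' are invariant to cohort ordering and fully reproducible.
#'
#' @param cohort A `mot_cohort` (or data.frame with `id`, `group`,
#'   `capacity`, `alpha`, `sigma`, `lapse`).
#' @param config A [staircase_config()].
#' @param loads Attentional loads to test (default 1:4).
#' @param seed Integer seed for the measurement stage.
#' @param trial_log Keep the per-trial staircase log? (modestly slower,
#'   larger output)
#' @return A list of class `"mot_experiment"`: `scores` (one row per
#'   participant x load: `id`, `group`, `load`, block scores,
#'   `speed_score`), `trials` (the trial log or NULL), plus the config.
#' @export
simulate_experiment <- function(cohort, config = staircase_config(),
                                loads = 1:4, seed = 1L, trial_log = FALSE) {
  stopifnot(all(c("id", "group", "capacity", "alpha", "sigma", "lapse")
                %in% names(cohort)))
  n_b <- config$blocks_per_condition
  rows <- vector("list", nrow(cohort))
  logs <- if (trial_log) vector("list", nrow(cohort)) else NULL
  for (pi in seq_len(nrow(cohort))) {
    p <- cohort[pi, ]
    obs <- psychometric_observer(p$capacity, p$alpha, p$sigma, p$lapse)
    set.seed(derive_seed(seed, "staircase", p$id))
    units <- expand.grid(block = seq_len(n_b), load = loads)
    units <- units[sample.int(nrow(units)), ] # randomized block order
    bscore <- matrix(NA_real_, length(loads), n_b,
                     dimnames = list(loads, NULL))
    plog <- if (trial_log) vector("list", nrow(units)) else NULL
    for (ui in seq_len(nrow(units))) {
      ld <- units$load[ui]
      bk <- units$block[ui]
      blk <- run_block(obs, ld, config)
      bscore[as.character(ld), bk] <- blk$block_score
      if (trial_log) {
        tl <- blk$trials
        tl$participant_id <- p$id
        tl$load <- ld
        tl$block <- bk
        plog[[ui]] <- tl
      }
    }
    y <- if (config$block_average == "arithmetic") rowMeans(bscore)
         else apply(bscore, 1, geometric_mean)
    rows[[pi]] <- data.frame(
      id = p$id, group = as.character(p$group), load = loads,
      block1_score = bscore[, 1],
      block2_score = if (n_b >= 2) bscore[, 2] else NA_real_,
      speed_score = y, stringsAsFactors = FALSE)
    if (trial_log) logs[[pi]] <- do.call(rbind, plog)
  }
  scores <- do.call(rbind, rows)
  scores$group <- factor(scores$group, levels = c("neurotypical", "autism"))
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 trials = if (trial_log) do.call(rbind, logs) else NULL,
                 config = config, loads = loads, seed = seed),
            class = "mot_experiment")
}

#' @export
print.mot_experiment <- function(x, ...) {
  cat("MOT staircase experiment:",
      length(unique(x$scores$id)), "participants x",
      length(x$loads), "loads\n")
  agg <- stats::aggregate(speed_score ~ group + load, data = x$scores, mean)
  agg$speed_score <- round(agg$speed_score, 1)
  print(stats::reshape(agg, idvar = "group", timevar = "load",
                       direction = "wide"), row.names = FALSE)
  invisible(x)
}

#' Write condition scores to CSV
#'
#' @param experiment A `mot_experiment` (or its `scores` data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(experiment, path) {
  scores <- if (inherits(experiment, "mot_experiment")) experiment$scores
            else experiment
  utils::write.csv(scores, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read condition scores from CSV
#'
#' @param path CSV with columns `id`, `group`, `load`, `speed_score` (block
#'   score columns optional).
#' @return A data.frame with `group` releveled to (neurotypical, autism).
#' @export
read_scores_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(c("id", "group", "load", "speed_score"), names(x))
  if (length(miss))
    stop("score table is missing columns: ", paste(miss, collapse = ", "))
  x$group <- factor(x$group, levels = c("neurotypical", "autism"))
  x
}
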