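# End-to-end orchestration: cohort -> staircase measurement -> capacity
# fits, planned t-tests, hierarchical regression, style classification and
# mixed ANOVA, with optional CSV/JSON/figure output.

#' Run the full synthetic replication
#'
#' Generates a cohort, measures every participant with the adaptive speed
#' staircase (two blocks at each attentional load 1--4), and runs the whole
#' analysis battery: per-group logarithmic and log-log capacity fits on the
#' group mean speed scores, planned group comparisons at each load, the
#' two-step hierarchical regression, intellectual-style classification, and
#' the mixed-design ANOVA on the style-labelled subsample. Everything is
#' derived from `seed`, so a repeated call reproduces the output bitwise.
#'
#' @param n_per_group Participants per group (default 55).
#' @param seed Master seed; all stage seeds derive from it.
#' @param cohort Optional pre-built `mot_cohort` (overrides `n_per_group`).
#' @param cohort_cfg Optional [cohort_config()]; its seed is replaced by a
#'   stage seed derived from `seed`.
#' @param staircase A [staircase_config()].
#' @param style_ties Tie policy for [classify_styles()]; the default
#'   `"truncate"` gives equal style cells as in the published design.
#' @param anova_trend Use the single-df load-trend coding in the ANOVA?
#' @param out_dir If non-NULL, write tables, results JSON and figures here
#'   via [write_results()].
#' @param trial_log Keep the per-trial staircase log.
#' @return A list of class `"mot_replication"`: `cohort`, `experiment`,
#'   `table` (long analysis table), `fits` (per-group capacity fits),
#'   `ttests`, `regression`, `anova`, `style_counts`, `seed`.
#' @examples
#' rep <- mot_replicate(n_per_group = 4, seed = 42)
#' rep$fits$autism$loglog_fit
#' @export
mot_replicate <- function(n_per_group = 55, seed = 1L, cohort = NULL,
                          cohort_cfg = NULL,
                          staircase = staircase_config(),
                          style_ties = "truncate",
                          anova_trend = FALSE,
                          out_dir = NULL, trial_log = FALSE) {
  if (is.null(cohort)) {
    if (is.null(cohort_cfg)) cohort_cfg <- cohort_config(n_per_group = n_per_group)
    cohort_cfg$seed <- derive_seed(seed, "cohort-stage")
    cohort <- generate_cohort(cohort_cfg)
  }
  if (min(table(cohort$group)) >= 4) {
    cohort <- add_style(cohort, ties = style_ties)
  } else {
    # too few participants to form quartiles: record scores, label nobody
    cohort$discrepancy <- discrepancy_score(cohort$pri, cohort$vci,
                                            cohort$fsiq)
    cohort$style <- factor("unclassified",
                           levels = c("verbal", "unclassified",
                                      "fluid_reasoning"))
  }
  experiment <- simulate_experiment(cohort, config = staircase,
                                    seed = derive_seed(seed, "measurement"),
                                    trial_log = trial_log)
  tab <- analysis_table(experiment, cohort)
  fits <- group_capacity_fits(experiment$scores)
  tt <- planned_load_ttests(experiment$scores)
  # fewer than ~5 participants cannot support the Step-2 covariate set
  hreg <- tryCatch(hierarchical_regression(tab), error = function(e) {
    warning("hierarchical regression skipped: ", conditionMessage(e))
    NULL
  })
  styled <- merge(experiment$scores,
                  as.data.frame(cohort)[, c("id", "style")], by = "id")
  styled <- styled[styled$style != "unclassified", ]
  styled$style <- droplevels(styled$style)
  anova_res <- if (nrow(styled) > 0 &&
                   all(table(unique(styled[, c("id", "group", "style")])[
                     , c("group", "style")]) >= 2)) {
    mixed_anova(styled, trend = anova_trend)
  } else NULL
  res <- structure(list(
    cohort = cohort, experiment = experiment, table = tab, fits = fits,
    ttests = tt, regression = hreg, anova = anova_res,
    style_counts = table(cohort$group, cohort$style), seed = seed
  ), class = "mot_replication")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' @export
print.mot_replication <- function(x, ...) {
  cat("MOT synthetic replication (seed", x$seed, ")\n\n")
  print(x$experiment)
  cat("\nGroup capacity fits (on group mean speed scores):\n")
  for (g in names(x$fits)) {
    print(x$fits[[g]]$log_fit)
    print(x$fits[[g]]$loglog_fit)
  }
  cat("\nPlanned group comparisons by load:\n")
  tt <- x$ttests
  tt[-1] <- lapply(tt[-1], round, 3)
  print(tt, row.names = FALSE)
  cat("\n")
  if (!is.null(x$regression)) print(x$regression)
  else cat("Hierarchical regression unavailable for this cohort size\n")
  if (!is.null(x$anova)) {
    cat("\n")
    print(x$anova)
  }
  invisible(x)
}

#' @export
summary.mot_replication <- function(object, ...) print(object)

#' Write replication outputs to a directory
#'
#' Writes `participants.csv`, `condition_scores.csv`, optionally
#' `trial_log.csv`, a versioned `results.json` (fits, t-tests, regression,
#' ANOVA, style counts), and the three summary figures (`fig_bars.pdf`,
#' `fig_logfit.pdf`, `fig_loglog.pdf`).
#'
#' @param x A `mot_replication`.
#' @param out_dir Output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(x, out_dir) {
  stopifnot(inherits(x, "mot_replication"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_participants_csv(x$cohort, file.path(out_dir, "participants.csv"))
  write_scores_csv(x$experiment, file.path(out_dir, "condition_scores.csv"))
  if (!is.null(x$experiment$trials)) {
    utils::write.csv(x$experiment$trials, file.path(out_dir, "trial_log.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  fit_json <- function(f) list(model = f$model, slope = f$slope,
                               intercept = f$intercept,
                               r_squared = f$r.squared,
                               n_points = nrow(f$data), group = f$group)
  step_json <- function(s) list(r_squared = s$r.squared,
                                adj_r_squared = s$adj.r.squared,
                                f = s$fstatistic, df = s$df,
                                coefficients = s$table)
  res <- list(
    schema_version = "1.0",
    seed = x$seed,
    fits = lapply(x$fits, function(g)
      list(log = fit_json(g$log_fit), loglog = fit_json(g$loglog_fit),
           means = g$means)),
    planned_ttests = x$ttests,
    regression = if (!is.null(x$regression)) {
      list(step1 = step_json(x$regression$step1),
           step2 = step_json(x$regression$step2),
           comparison = x$regression$comparison)
    },
    anova = if (!is.null(x$anova)) x$anova$table,
    style_counts = as.data.frame(x$style_counts)
  )
  jsonlite::write_json(res, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  plot_replication(x, out_dir)
  invisible(out_dir)
}

# Fig-2-style panels: group bars with SE, log fit curves, log-log lines.
plot_replication <- function(x, out_dir) {
  groups <- names(x$fits)
  cols <- c("grey35", "grey70")

  grDevices::pdf(file.path(out_dir, "fig_bars.pdf"), width = 6, height = 4.5)
  m <- do.call(rbind, lapply(x$fits, function(g) g$means$mean))
  se <- do.call(rbind, lapply(x$fits, function(g) g$means$se))
  bp <- graphics::barplot(m, beside = TRUE, names.arg = x$fits[[1]]$means$load,
                          col = cols, ylim = c(0, max(m + 2 * se) * 1.1),
                          xlab = "attentional load (targets)",
                          ylab = "mean speed score (cm/s)")
  graphics::arrows(bp, m - se, bp, m + se, angle = 90, code = 3, length = 0.03)
  graphics::legend("topright", legend = groups, fill = cols, bty = "n")
  grDevices::dev.off()

  grDevices::pdf(file.path(out_dir, "fig_logfit.pdf"), width = 6, height = 4.5)
  xx <- seq(1, 4, length.out = 100)
  ylim <- range(unlist(lapply(x$fits, function(g) g$means$mean)))
  graphics::plot(NA, xlim = c(1, 4), ylim = ylim * c(0.8, 1.1),
                 xlab = "attentional load (targets)",
                 ylab = "mean speed score (cm/s)")
  for (i in seq_along(groups)) {
    g <- x$fits[[groups[i]]]
    graphics::points(g$means$load, g$means$mean, pch = 19, col = cols[i])
    graphics::lines(xx, predict(g$log_fit, xx), col = cols[i])
  }
  graphics::legend("topright", legend = groups, col = cols, pch = 19, bty = "n")
  grDevices::dev.off()

  grDevices::pdf(file.path(out_dir, "fig_loglog.pdf"), width = 6, height = 4.5)
  graphics::plot(NA, xlim = c(0, log10(4)),
                 ylim = range(unlist(lapply(x$fits, function(g)
                   log10(g$means$mean)))) + c(-0.1, 0.1),
                 xlab = "log10 load", ylab = "log10 mean speed score")
  for (i in seq_along(groups)) {
    g <- x$fits[[groups[i]]]
    graphics::points(log10(g$means$load), log10(g$means$mean), pch = 19,
                     col = cols[i])
    graphics::abline(g$loglog_fit$intercept, g$loglog_fit$slope, col = cols[i])
  }
  graphics::legend("bottomleft", legend = groups, col = cols, pch = 19, bty = "n")
  grDevices::dev.off()
  invisible(NULL)
}
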