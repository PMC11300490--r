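# Three-way mixed-design ANOVA: two between-subject factors (group,
# intellectual style) and one within-subject factor (attentional load),
# with partial eta squared and noncentral-F confidence intervals.

#' Mixed-design ANOVA with partial eta squared
#'
#' Fits the classical univariate mixed-model ANOVA via [stats::aov()] with
#' subject-within-group error strata (`Error(id/within)`): between-subject
#' effects are tested against the subject stratum, within-subject effects
#' against the subject-by-load stratum. Partial eta squared is
#' `SS_effect / (SS_effect + SS_error)` with the error of the effect's own
#' stratum; its 95% CI inverts the noncentral F distribution.
#'
#' With `trend = TRUE` the within factor instead enters as a single-df
#' linear contrast computed per participant (so every load-related effect is
#' reported with 1 numerator df and the between-subject residual df, e.g.
#' F(1, 52) for 56 participants in 4 between cells), and between-subject
#' effects are computed on participant means. This is the collapsed
#' single-df reading of a four-level within factor; both codings are
#' available and neither is asserted as "the" published one.
#'
#' @param data Long table with one row per participant x load.
#' @param dv Outcome column (default `"speed_score"`).
#' @param id Participant id column.
#' @param within Within-subject factor column (default `"load"`).
#' @param between Character vector of between-subject factor columns.
#' @param trend Use the single-df linear-trend coding of the within factor?
#' @return A list of class `"mot_anova"` with a `table` data.frame: one row
#'   per effect (`effect`, `df_num`, `df_den`, `ss`, `ss_err`, `F`, `p`,
#'   `pes`, `pes_lo`, `pes_hi`) and the fitted `aov` object (`NULL` when
#'   `trend = TRUE`).
#' @export
mixed_anova <- function(data, dv = "speed_score", id = "id",
                        within = "load", between = c("group", "style"),
                        trend = FALSE) {
  stopifnot(all(c(dv, id, within, between) %in% names(data)))
  d <- as.data.frame(data)
  d$.id <- factor(d[[id]])
  d$.w <- factor(d[[within]])
  for (b in between) d[[b]] <- factor(as.character(d[[b]]))
  d$.y <- d[[dv]]

  tab_w <- table(d$.id, d$.w)
  if (any(tab_w != 1))
    stop("incomplete design: every participant needs exactly one row per ",
         within, " level")
  cell <- unique(d[, c(".id", between)])
  cc <- table(cell[, between])
  if (any(cc < 2))
    stop("incomplete design: every between-subject cell needs >= 2 participants")
  if (length(unique(as.vector(cc))) > 1)
    warning("unbalanced between-subject cells: sequential sums of squares")

  pes_row <- function(effect, ss, ss_err, df1, df2, f, p) {
    ci <- ncp_f_ci(f, df1, df2)
    pes <- ss / (ss + ss_err)
    data.frame(effect = effect, df_num = df1, df_den = df2, ss = ss,
               ss_err = ss_err, F = f, p = p, pes = pes,
               pes_lo = ci[1] / (ci[1] + df1 + df2 + 1),
               pes_hi = ci[2] / (ci[2] + df1 + df2 + 1),
               stringsAsFactors = FALSE)
  }

  if (!trend) {
    rhs <- paste(c(between, ".w"), collapse = " * ")
    form <- stats::as.formula(paste(".y ~", rhs, "+ Error(.id/.w)"))
    fit <- stats::aov(form, data = d)
    rows <- list()
    for (stratum in summary(fit)) {
      st <- stratum[[1]]
      eff <- trimws(rownames(st))
      res <- which(eff == "Residuals")
      if (!length(res)) next
      ss_err <- st[res, "Sum Sq"]
      df_err <- st[res, "Df"]
      for (r in setdiff(seq_len(nrow(st)), res)) {
        rows[[length(rows) + 1]] <- pes_row(
          gsub("\\.w", within, eff[r]), st[r, "Sum Sq"], ss_err,
          st[r, "Df"], df_err, st[r, "F value"], st[r, "Pr(>F)"])
      }
    }
    out <- do.call(rbind, rows)
    return(structure(list(table = out, aov = fit, trend = FALSE,
                          within = within, between = between),
                     class = "mot_anova"))
  }

  # single-df linear-trend coding of the within factor
  lv <- suppressWarnings(as.numeric(levels(d$.w)))
  if (any(is.na(lv))) lv <- seq_along(levels(d$.w))
  wts <- (lv - mean(lv)) / sqrt(sum((lv - mean(lv))^2))
  wide <- stats::reshape(d[, c(".id", between, ".w", ".y")],
                         idvar = c(".id", between), timevar = ".w",
                         direction = "wide")
  ymat <- as.matrix(wide[, paste0(".y.", levels(d$.w))])
  wide$.contrast <- as.vector(ymat %*% wts)
  wide$.mean <- rowMeans(ymat)
  rhs_b <- paste(between, collapse = " * ")
  ctr <- stats::setNames(as.list(rep("contr.sum", length(between))), between)
  # sum-to-zero coding so the intercept is the unweighted grand contrast mean
  fit_c <- stats::lm(stats::as.formula(paste(".contrast ~", rhs_b)),
                     data = wide, contrasts = ctr)
  fit_m <- stats::lm(stats::as.formula(paste(".mean ~", rhs_b)), data = wide,
                     contrasts = ctr)
  df2 <- fit_c$df.residual
  rows <- list()
  # between-subject effects from participant means
  an_m <- stats::anova(fit_m)
  ss_err_m <- an_m["Residuals", "Sum Sq"]
  for (r in setdiff(rownames(an_m), "Residuals")) {
    rows[[length(rows) + 1]] <- pes_row(
      r, an_m[r, "Sum Sq"], ss_err_m, an_m[r, "Df"],
      an_m["Residuals", "Df"], an_m[r, "F value"], an_m[r, "Pr(>F)"])
  }
  # load effects: intercept of the contrast model is the load main effect;
  # factor terms are load-by-between interactions
  an_c <- stats::anova(fit_c)
  ss_err_c <- an_c["Residuals", "Sum Sq"]
  sm <- summary(fit_c)$coefficients
  t_int <- sm["(Intercept)", "t value"]
  n_tot <- nrow(wide)
  ss_int <- t_int^2 * ss_err_c / df2
  rows[[length(rows) + 1]] <- pes_row(
    within, ss_int, ss_err_c, 1, df2, t_int^2,
    2 * stats::pt(-abs(t_int), df2))
  for (r in setdiff(rownames(an_c), "Residuals")) {
    rows[[length(rows) + 1]] <- pes_row(
      paste0(r, ":", within), an_c[r, "Sum Sq"], ss_err_c, an_c[r, "Df"],
      an_c["Residuals", "Df"], an_c[r, "F value"], an_c[r, "Pr(>F)"])
  }
  structure(list(table = do.call(rbind, rows), aov = NULL, trend = TRUE,
                 within = within, between = between),
            class = "mot_anova")
}

#' @export
print.mot_anova <- function(x, digits = 3, ...) {
  cat(sprintf("Mixed-design ANOVA (%s coding of %s)\n",
              if (x$trend) "linear-trend" else "full factorial", x$within))
  tab <- x$table
  tab$ss <- round(tab$ss, 2)
  tab$ss_err <- round(tab$ss_err, 2)
  tab$F <- round(tab$F, 2)
  tab$p <- signif(tab$p, 3)
  for (v in c("pes", "pes_lo", "pes_hi")) tab[[v]] <- round(tab[[v]], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
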