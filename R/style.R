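# Intellectual-style classification: the fluid-vs-verbal discrepancy score
# and within-group quartile labels.

#' Fluid-vs-verbal discrepancy score
#'
#' `D = (PRI - VCI) / FSIQ`: positive when perceptual (fluid) reasoning
#' exceeds verbal comprehension, scaled by overall ability.
#'
#' @param pri,vci,fsiq Wechsler index standard scores (FSIQ > 0);
#'   vectorized.
#' @return Unitless discrepancy score(s).
#' @examples
#' discrepancy_score(115, 92, 103) # 23/103
#' @export
discrepancy_score <- function(pri, vci, fsiq) {
  if (any(fsiq <= 0)) stop("FSIQ must be positive")
  (pri - vci) / fsiq
}

#' Classify intellectual styles by within-group quartiles
#'
#' Ranks discrepancy scores within each group and labels scores at or above
#' the 75th percentile "fluid_reasoning" and at or below the 25th percentile
#' "verbal"; the middle half is "unclassified". Percentile rank is computed
#' as `100 * (rank - 1) / (n - 1)` with average ranks for ties (inclusive at
#' both cutoffs), which yields 14 + 14 labelled participants per group of
#' 55 with distinct scores. With `ties = "truncate"`, cutoff ties are broken
#' deterministically by input order so cells have exactly the tie-free
#' counts.
#'
#' @param d Discrepancy scores ([discrepancy_score()]).
#' @param group Group membership, same length as `d`.
#' @param ties `"inclusive"` (default: all cutoff ties get the label) or
#'   `"truncate"`.
#' @return Factor with levels `verbal`, `unclassified`, `fluid_reasoning`,
#'   in the input order.
#' @export
classify_styles <- function(d, group, ties = c("inclusive", "truncate")) {
  ties <- match.arg(ties)
  stopifnot(length(d) == length(group), all(is.finite(d)))
  group <- as.character(group)
  style <- rep("unclassified", length(d))
  for (g in unique(group)) {
    idx <- which(group == g)
    n <- length(idx)
    if (n < 4) stop("need >= 4 participants per group to form quartiles")
    x <- d[idx]
    if (length(unique(x)) == 1) {
      warning("all discrepancy scores equal in group '", g,
              "': everyone unclassified")
      next
    }
    if (ties == "inclusive") {
      pr <- 100 * (rank(x, ties.method = "average") - 1) / (n - 1)
      style[idx[pr >= 75]] <- "fluid_reasoning"
      style[idx[pr <= 25]] <- "verbal"
    } else {
      # tie-free label counts, ties broken by position
      pr_first <- 100 * (seq_len(n) - 1) / (n - 1)
      k_hi <- sum(pr_first >= 75)
      k_lo <- sum(pr_first <= 25)
      ord <- order(x, idx) # ascending, stable in input order
      style[idx[ord[seq_len(k_lo)]]] <- "verbal"
      style[idx[ord[seq.int(n - k_hi + 1, n)]]] <- "fluid_reasoning"
    }
  }
  factor(style, levels = c("verbal", "unclassified", "fluid_reasoning"))
}

#' Add discrepancy and style columns to a participant table
#'
#' @param cohort A `mot_cohort` (needs `pri`, `vci`, `fsiq`, `group`).
#' @param ties Tie policy passed to [classify_styles()].
#' @return The cohort with extra columns `discrepancy` and `style`.
#' @export
add_style <- function(cohort, ties = c("inclusive", "truncate")) {
  stopifnot(all(c("pri", "vci", "fsiq", "group") %in% names(cohort)))
  cohort$discrepancy <- discrepancy_score(cohort$pri, cohort$vci, cohort$fsiq)
  cohort$style <- classify_styles(cohort$discrepancy, cohort$group,
                                  ties = match.arg(ties))
  cohort
}
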