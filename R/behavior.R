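#' Relative subjective utility of 20 points
#'
#' `40 * (u20 - u0) / (u40 - u0)`, where the `u` are a subject's mean
#' satisfaction ratings after 0-, 20-, and 40-point outcomes. Equals 20
#' (i.e. 50% of 40) for a linear utility curve and exceeds 20 for a concave
#' one; invariant to affine rescaling of the rating scale.
#'
#' @param mean_u0,mean_u20,mean_u40 mean ratings per outcome (vectorized).
#' @return value on the 0-40 points scale.
#' @export
relative_utility_20 <- function(mean_u0, mean_u20, mean_u40) {
  if (any(mean_u40 == mean_u0)) stop("u40 equals u0; relative utility undefined")
  40 * (mean_u20 - mean_u0) / (mean_u40 - mean_u0)
}

is_mixed_risk_pair <- function(pair) {
  stim <- derive_stimulus_distributions()
  risk <- setNames(stim$risk_level, stim$stimulus_id)
  ps <- split_pair(pair)
  risk[ps$stim1] != risk[ps$stim2]
}

#' Risk seeking: percentage of mixed-risk trials choosing the risky gamble
#'
#' Restricted to trials pairing one high-risk with one low-risk gamble
#' (4 of the 6 pairs; 64 trials of a full 96-trial run).
#'
#' @param trials one subject's trial table.
#' @return percentage in `[0, 100]`.
#' @export
risk_seeking <- function(trials) {
  mixed <- is_mixed_risk_pair(trials$pair)
  if (!any(mixed)) stop("no mixed-risk trials")
  stim <- derive_stimulus_distributions()
  risk <- setNames(stim$risk_level, stim$stimulus_id)
  100 * mean(risk[trials$choice[mixed]] == "high")
}

#' Counterfactual sensitivity
#'
#' Difference in mean satisfaction with a 20-point outcome when the foregone
#' outcome was 0 versus 40 points (counterfactual blocks only). Positive
#' values mean relief/regret modulation in the expected direction.
#'
#' @param trials one subject's trial table.
#' @return VAS-units difference, or `NA` (with a message) when either cell
#'   has no trials — possible by chance in a 96-trial run.
#' @export
counterfactual_sensitivity <- function(trials) {
  cf <- trials[trials$block_type == "counterfactual" & trials$outcome == 20 &
                 !is.na(trials$counterfactual), , drop = FALSE]
  lo <- cf$satisfaction[cf$counterfactual == 0]
  hi <- cf$satisfaction[cf$counterfactual == 40]
  if (length(lo) == 0L || length(hi) == 0L) {
    message("empty outcome-20 counterfactual cell; sensitivity is NA")
    return(NA_real_)
  }
  mean(lo) - mean(hi)
}

#' Pearson association between two per-subject measures
#'
#' Two-sided Pearson correlation test; subjects with a missing value in
#' either measure are dropped pairwise (with a message).
#'
#' @param x,y numeric vectors of equal length (one entry per subject).
#' @return list `r`, `p`, `n`.
#' @export
pearson_association <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  if (sum(!keep) > 0) message("dropping ", sum(!keep), " subject(s) with missing values")
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete subjects")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector; correlation undefined")
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-subject behavioral summary
#'
#' Mean satisfaction by outcome (all blocks), relative utility of 20, risk
#' seeking, and counterfactual sensitivity, joined with the trait-anxiety
#' score when a subjects table is supplied.
#'
#' @param trials cohort trial table.
#' @param subjects optional subjects table with `subject_id`, `stai_t`.
#' @return data.frame, one row per subject.
#' @export
behavior_summary <- function(trials, subjects = NULL) {
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    tt <- trials[trials$subject_id == id, , drop = FALSE]
    mu <- tapply(tt$satisfaction, factor(tt$outcome, levels = c(0, 20, 40)), mean)
    ru <- if (any(is.na(mu))) NA_real_ else
      relative_utility_20(mu[["0"]], mu[["20"]], mu[["40"]])
    data.frame(
      subject_id = id,
      mean_u0 = mu[["0"]], mean_u20 = mu[["20"]], mean_u40 = mu[["40"]],
      relative_utility_20 = ru,
      risk_seeking = risk_seeking(tt),
      counterfactual_sensitivity = suppressMessages(counterfactual_sensitivity(tt)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(subjects)) {
    out <- merge(out, subjects[, c("subject_id", "stai_t")], by = "subject_id",
                 all.x = TRUE, sort = FALSE)
  }
  out
}

#' Behavioral association table
#'
#' The three tested associations: concavity vs. risk seeking, trait anxiety
#' vs. risk seeking, trait anxiety vs. counterfactual sensitivity.
#'
#' @param summary output of [behavior_summary()] including `stai_t`.
#' @return data.frame `measure_x`, `measure_y`, `r`, `p`, `n`.
#' @export
behavior_associations <- function(summary) {
  pairs <- list(
    c("relative_utility_20", "risk_seeking"),
    c("stai_t", "risk_seeking"),
    c("stai_t", "counterfactual_sensitivity")
  )
  rows <- lapply(pairs, function(pp) {
    pa <- suppressMessages(pearson_association(summary[[pp[1]]], summary[[pp[2]]]))
    data.frame(measure_x = pp[1], measure_y = pp[2],
               r = pa$r, p = pa$p, n = pa$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
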