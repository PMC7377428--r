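#' Quantile-probability table for data and/or fitted models
#'
#' For each stimulus, pooled across subjects: the response probability (the
#' fraction of its appearances on which it was chosen) and the quantiles of
#' its choice-conditional RTs. The model rows recompute the same statistics
#' on a large seeded simulation from each subject's fitted parameters over
#' the six pairs (equally weighted, matching the task design).
#'
#' @param trials cohort trial table.
#' @param fits optional named list of `lba_fit` (adds a model source named by
#'   the fits' variant).
#' @param quantile_levels strictly increasing levels in (0, 1).
#' @param n_sim simulated trials per subject for the model source.
#' @param seed integer seed for the model simulation.
#' @return long data.frame: `source`, `stimulus`, `resp_prob`, `level`,
#'   `rt_q`. Never-chosen stimuli get `NA` quantiles (flagged with a message).
#' @export
quantile_probability_data <- function(trials, fits = NULL,
                                      quantile_levels = c(.1, .3, .5, .7, .9),
                                      n_sim = 10000L, seed = 1L) {
  stopifnot(all(diff(quantile_levels) > 0),
            all(quantile_levels > 0 & quantile_levels < 1))
  out <- qp_one_source(trials, "data", quantile_levels)
  if (!is.null(fits)) {
    variant <- fits[[1]]$variant
    sim <- lapply(seq_along(fits), function(i) {
      simulate_from_params(fits[[i]]$params, n_sim,
                           seed = derive_seed(seed, 1010L, i),
                           subject_id = names(fits)[i])
    })
    out <- rbind(out, qp_one_source(do.call(rbind, sim), variant, quantile_levels))
  }
  rownames(out) <- NULL
  out
}

# Simulate n trials from one parameter set, pairs equally weighted.
simulate_from_params <- function(params, n, seed, subject_id = "sim") {
  pr <- stimulus_pairs()
  per <- diff(round(seq(0, n, length.out = nrow(pr) + 1)))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  rows <- lapply(seq_len(nrow(pr)), function(i) {
    race <- simulate_race(c(pr$stim1[i], pr$stim2[i]), params, n = per[i])
    data.frame(subject_id = subject_id, pair = pr$pair[i],
               choice = race$choice, rt_s = race$rt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

qp_one_source <- function(trials, source, levels) {
  ps <- split_pair(trials$pair)
  rows <- lapply(STIMULI, function(st) {
    appear <- ps$stim1 == st | ps$stim2 == st
    chosen <- trials$choice == st
    p <- sum(chosen) / sum(appear)
    if (!any(chosen)) {
      message("stimulus ", st, " never chosen in source '", source,
              "'; quantiles marked missing")
      q <- rep(NA_real_, length(levels))
    } else {
      q <- unname(quantile(trials$rt_s[chosen], probs = levels, type = 7))
    }
    data.frame(source = source, stimulus = st, resp_prob = p,
               level = levels, rt_q = q, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Quantile-probability plot
#'
#' Response probability on the x axis, RT quantiles on the y axis, one point
#' column per stimulus and source.
#'
#' @param qp output of [quantile_probability_data()].
#' @param ... passed to [plot()].
#' @export
plot_qp <- function(qp, ...) {
  src <- unique(qp$source)
  cols <- seq_along(src)
  plot(range(qp$resp_prob, na.rm = TRUE), range(qp$rt_q, na.rm = TRUE),
       type = "n", xlab = "response probability", ylab = "RT quantile (s)", ...)
  for (i in seq_along(src)) {
    d <- qp[qp$source == src[i], ]
    points(d$resp_prob, d$rt_q, col = cols[i], pch = i)
  }
  legend("topright", legend = src, col = cols, pch = seq_along(src), bty = "n")
  invisible(qp)
}

#' Pearson chi-square goodness of fit for choice counts
#'
#' `X^2 = sum (O - E)^2 / E` over the four stimulus categories, df = 3.
#' Observed counts exceeding expected at the extremes indicate behavior less
#' random than the model predicts.
#'
#' @param observed,expected per-stimulus chosen counts (length 4, equal
#'   totals; expected counts all positive).
#' @return list `statistic`, `df`, `p`.
#' @export
chisq_choice_gof <- function(observed, expected) {
  stopifnot(length(observed) == 4L, length(expected) == 4L)
  if (any(expected <= 0)) stop("expected counts must be positive")
  if (abs(sum(observed) - sum(expected)) > 1e-6) {
    stop("observed and expected totals differ")
  }
  x2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  list(statistic = x2, df = df, p = pchisq(x2, df, lower.tail = FALSE))
}

#' Model-expected per-stimulus choice counts
#'
#' Sums each subject's predicted per-pair choice probabilities over every
#' trial of the cohort, giving the expected number of times each stimulus is
#' chosen under the fitted model.
#'
#' @param fits named list of `lba_fit`.
#' @param trials cohort trial table.
#' @return list `observed`, `expected` (named length-4 vectors) ready for
#'   [chisq_choice_gof()].
#' @export
expected_choice_counts <- function(fits, trials) {
  expected <- setNames(numeric(4), STIMULI)
  for (id in names(fits)) {
    pred <- pair_predictions(fits[[id]]$params)
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    cnt <- table(factor(sub$pair, levels = pred$pair))
    pp <- split_pair(pred$pair)
    for (i in seq_len(nrow(pred))) {
      n <- as.numeric(cnt[pred$pair[i]])
      expected[pp$stim1[i]] <- expected[pp$stim1[i]] + n * pred$p_first[i]
      expected[pp$stim2[i]] <- expected[pp$stim2[i]] + n * (1 - pred$p_first[i])
    }
  }
  observed <- table(factor(trials$choice, levels = STIMULI))
  list(observed = as.numeric(observed), expected = as.numeric(expected))
}

#' Kolmogorov-Smirnov goodness of fit for RT distributions
#'
#' Per stimulus, a two-sample KS test between the pooled choice-conditional
#' empirical RTs and a pooled model RT sample simulated per subject from its
#' fitted parameters at `sim_multiplier` times the subject's trial count.
#'
#' @param trials cohort trial table.
#' @param fits named list of `lba_fit`.
#' @param sim_multiplier model sample size per subject, as a multiple of the
#'   subject's trial count.
#' @param seed integer seed.
#' @return data.frame `stimulus`, `D`, `p`, `n_data`, `n_model`.
#' @export
ks_rt_gof <- function(trials, fits, sim_multiplier = 100L, seed = 1L) {
  sims <- lapply(seq_along(fits), function(i) {
    id <- names(fits)[i]
    n <- sum(trials$subject_id == id) * sim_multiplier
    simulate_from_params(fits[[i]]$params, n,
                         seed = derive_seed(seed, 1111L, i), subject_id = id)
  })
  sim <- do.call(rbind, sims)
  rows <- lapply(STIMULI, function(st) {
    emp <- trials$rt_s[trials$choice == st]
    mod <- sim$rt_s[sim$choice == st]
    if (length(emp) == 0L || length(mod) == 0L) {
      stop("empty RT sample for stimulus ", st)
    }
    kt <- suppressWarnings(ks.test(emp, mod))
    data.frame(stimulus = st, D = unname(kt$statistic), p = kt$p.value,
               n_data = length(emp), n_model = length(mod),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-way within-subject ANOVA on normalized drift rates
#'
#' Classic repeated-measures decomposition of the subject x risk x EV table
#' (one value per cell): each effect is tested against its effect-by-subject
#' interaction; partial eta^2 = SS_effect / (SS_effect + SS_error).
#'
#' @param drifts data.frame with columns `subject_id`, `risk`
#'   (`"high"`/`"low"`), `ev` (`"high"`/`"low"`), `value` — one row per
#'   subject per cell (complete 2x2 per subject, >= 3 subjects).
#' @return data.frame: `effect` (`risk`, `ev`, `risk:ev`), `F`, `df1`, `df2`,
#'   `p`, `peta2`; attribute `ss` holds the full decomposition.
#' @export
rm_anova_drift <- function(drifts) {
  need <- c("subject_id", "risk", "ev", "value")
  if (!all(need %in% names(drifts))) stop("drifts needs columns ",
                                          paste(need, collapse = ", "))
  tab <- table(drifts$subject_id, drifts$risk, drifts$ev)
  if (any(tab != 1L)) stop("each subject needs exactly one value per risk x EV cell")
  n <- length(unique(drifts$subject_id))
  if (n < 3L) stop("need at least 3 subjects")

  y <- drifts$value
  grand <- mean(y)
  m_s <- tapply(y, drifts$subject_id, mean)
  m_r <- tapply(y, drifts$risk, mean)
  m_e <- tapply(y, drifts$ev, mean)
  m_sr <- tapply(y, list(drifts$subject_id, drifts$risk), mean)
  m_se <- tapply(y, list(drifts$subject_id, drifts$ev), mean)
  m_re <- tapply(y, list(drifts$risk, drifts$ev), mean)

  ss_total <- sum((y - grand)^2)
  ss_subj <- 4 * sum((m_s - grand)^2)
  ss_risk <- 2 * n * sum((m_r - grand)^2)
  ss_ev <- 2 * n * sum((m_e - grand)^2)
  ss_re <- n * sum((m_re - outer(m_r - grand, m_e - grand, `+`) - grand)^2)
  ss_rs <- 2 * sum((m_sr - outer(m_s - grand, m_r - grand, `+`) - grand)^2)
  ss_es <- 2 * sum((m_se - outer(m_s - grand, m_e - grand, `+`) - grand)^2)
  ss_res <- ss_total - ss_subj - ss_risk - ss_ev - ss_re - ss_rs - ss_es

  eff <- function(name, ss_eff, ss_err) {
    df1 <- 1L; df2 <- n - 1L
    tol <- 1e-12 * max(ss_total, 1)
    # a numerically null effect is reported as F = 0 even when its error
    # stratum is also empty (noise-free constructed data)
    if (ss_eff <= tol) {
      Fv <- 0; pv <- 1; peta <- 0
    } else if (ss_err <= tol) {
      Fv <- Inf; pv <- 0; peta <- 1
    } else {
      Fv <- (ss_eff / df1) / (ss_err / df2)
      pv <- pf_upper(Fv, df1, df2)
      peta <- ss_eff / (ss_eff + ss_err)
    }
    data.frame(effect = name, F = Fv, df1 = df1, df2 = df2,
               p = pv, peta2 = peta, stringsAsFactors = FALSE)
  }
  out <- rbind(eff("risk", ss_risk, ss_rs),
               eff("ev", ss_ev, ss_es),
               eff("risk:ev", ss_re, ss_res))
  attr(out, "ss") <- c(total = ss_total, subject = ss_subj, risk = ss_risk,
                       ev = ss_ev, `risk:ev` = ss_re, `risk:subject` = ss_rs,
                       `ev:subject` = ss_es, residual = ss_res)
  out
}

pf_upper <- function(f, df1, df2) stats::pf(f, df1, df2, lower.tail = FALSE)

#' Normalized-drift table for the risk-by-EV ANOVA
#'
#' @param fits named list of drift-variant `lba_fit`.
#' @return data.frame `subject_id`, `risk`, `ev`, `value` (normalized drift).
#' @export
normalized_drift_table <- function(fits) {
  stim <- derive_stimulus_distributions()
  rows <- lapply(names(fits), function(id) {
    nd <- normalized_drift_rates(fits[[id]])
    data.frame(subject_id = id, risk = stim$risk_level, ev = stim$ev_level,
               value = unname(nd[stim$stimulus_id]), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
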