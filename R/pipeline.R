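#' Pipeline run configuration
#'
#' @param seed master integer seed (required; every stochastic stage derives
#'   a substream from it).
#' @param n_subjects cohort size to simulate (ignored when `trials_path`
#'   points at existing data).
#' @param population [population_config()].
#' @param fit [fit_config()].
#' @param n_sim_qp simulated trials per subject for the model side of the
#'   quantile-probability table.
#' @param ks_multiplier model RT sample size multiplier for the KS tests.
#' @param out_dir output directory (created if absent).
#' @param trials_path,subjects_path optional existing input tables; when
#'   `NULL`, a synthetic cohort is simulated.
#' @param units RT units of an input trials file.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, n_subjects = 44L, population = population_config(),
                       fit = fit_config(), n_sim_qp = 10000L,
                       ks_multiplier = 100L, out_dir = "lbachoice_out",
                       trials_path = NULL, subjects_path = NULL,
                       units = "s") {
  stopifnot(!missing(seed), length(seed) == 1L, is.finite(seed),
            n_subjects >= 1L, n_sim_qp >= 1L, ks_multiplier >= 1L)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 population = population, fit = fit,
                 n_sim_qp = as.integer(n_sim_qp),
                 ks_multiplier = as.integer(ks_multiplier),
                 out_dir = out_dir, trials_path = trials_path,
                 subjects_path = subjects_path, units = units),
            class = c("run_config", "list"))
}

#' Run the full analysis pipeline
#'
#' Simulate (or read) a cohort, fit both LBA variants per subject, assess
#' them (quantile-probability table, chi-square choice GOF, KS RT GOF,
#' risk-by-EV ANOVA on normalized drifts), predict per-pair choice
#' probabilities (whole-data and held-out), and compute the behavioral
#' summary and associations. All tables are written as CSV under
#' `config$out_dir`, along with a structured log and a plain-text summary.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with every intermediate product.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  log_lines <- c(sprintf("seed: %d", config$seed),
                 sprintf("R: %s", R.version.string),
                 sprintf("started: %s", format(t_start)))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log_lines <<- c(log_lines, sprintf("stage %s: %.1f s", name,
                                       as.numeric(Sys.time() - t0, units = "secs")))
    res
  }

  cohort <- stage("simulate", {
    if (is.null(config$trials_path)) {
      simulate_cohort(config$n_subjects, config$population, config$seed)
    } else {
      list(trials = read_trials(config$trials_path, config$units),
           subjects = if (!is.null(config$subjects_path))
             read_subjects(config$subjects_path) else NULL)
    }
  })
  write_trials(cohort$trials, file.path(config$out_dir, "trials.csv"))
  if (!is.null(cohort$subjects))
    write_subjects(cohort$subjects, file.path(config$out_dir, "subjects.csv"))

  fits_drift <- stage("fit_drift",
    fit_cohort(cohort$trials, "drift_model", config$fit,
               seed = derive_seed(config$seed, 1L)))
  fits_bound <- stage("fit_boundary",
    fit_cohort(cohort$trials, "boundary_model", config$fit,
               seed = derive_seed(config$seed, 2L)))
  write.csv(fits_table(fits_drift),
            file.path(config$out_dir, "fits_drift.csv"), row.names = FALSE)
  write.csv(fits_table(fits_bound),
            file.path(config$out_dir, "fits_boundary.csv"), row.names = FALSE)

  nll_drift <- sum(vapply(fits_drift, `[[`, 0, "nll"))
  nll_bound <- sum(vapply(fits_bound, `[[`, 0, "nll"))
  best_fits <- if (nll_drift <= nll_bound) fits_drift else fits_bound

  assessment <- stage("assess", {
    qp <- quantile_probability_data(cohort$trials, fits_drift,
                                    n_sim = config$n_sim_qp,
                                    seed = derive_seed(config$seed, 3L))
    qp_b <- quantile_probability_data(cohort$trials, fits_bound,
                                      n_sim = config$n_sim_qp,
                                      seed = derive_seed(config$seed, 4L))
    qp <- rbind(qp, qp_b[qp_b$source != "data", ])
    cc <- expected_choice_counts(best_fits, cohort$trials)
    chisq <- chisq_choice_gof(cc$observed, cc$expected)
    ks <- ks_rt_gof(cohort$trials, best_fits,
                    sim_multiplier = config$ks_multiplier,
                    seed = derive_seed(config$seed, 5L))
    anova <- rm_anova_drift(normalized_drift_table(fits_drift))
    list(qp = qp, chisq = chisq, ks = ks, anova = anova,
         choice_counts = cc)
  })
  write.csv(assessment$qp, file.path(config$out_dir, "qp_table.csv"),
            row.names = FALSE)
  write.csv(assessment$ks, file.path(config$out_dir, "ks_gof.csv"),
            row.names = FALSE)
  write.csv(assessment$anova, file.path(config$out_dir, "anova_drift.csv"),
            row.names = FALSE)

  whole <- stage("predict", predicted_vs_actual(best_fits, cohort$trials))
  write.csv(whole, file.path(config$out_dir, "correlations_whole.csv"),
            row.names = FALSE)
  write.csv(attr(whole, "predictions"),
            file.path(config$out_dir, "predictions_whole.csv"), row.names = FALSE)

  held <- stage("holdout",
    holdout_evaluation(cohort$trials, "drift_model", config$fit,
                       seed = derive_seed(config$seed, 6L)))
  write.csv(held$correlations,
            file.path(config$out_dir, "correlations_holdout.csv"),
            row.names = FALSE)

  behav <- stage("behavior", {
    bs <- behavior_summary(cohort$trials, cohort$subjects)
    assoc <- if ("stai_t" %in% names(bs)) behavior_associations(bs) else NULL
    list(summary = bs, associations = assoc)
  })
  write.csv(behav$summary, file.path(config$out_dir, "behavior_summary.csv"),
            row.names = FALSE)
  if (!is.null(behav$associations))
    write.csv(behav$associations,
              file.path(config$out_dir, "behavior_associations.csv"),
              row.names = FALSE)

  summary_txt <- c(
    "LBA risky-choice pipeline summary",
    sprintf("subjects: %d, trials: %d", length(unique(cohort$trials$subject_id)),
            nrow(cohort$trials)),
    sprintf("total NLL: drift-rate %.1f, response-boundary %.1f (%s preferred)",
            nll_drift, nll_bound,
            ifelse(nll_drift <= nll_bound, "drift-rate", "response-boundary")),
    sprintf("choice chi-square: X2(%d) = %.2f, p = %.4g",
            assessment$chisq$df, assessment$chisq$statistic, assessment$chisq$p),
    "KS RT goodness of fit:",
    sprintf("  %s: D = %.3f, p = %.3g", assessment$ks$stimulus,
            assessment$ks$D, assessment$ks$p),
    "risk x EV ANOVA on normalized drifts:",
    sprintf("  %s: F(%d,%d) = %.2f, p = %.4g, partial eta2 = %.3f",
            assessment$anova$effect, assessment$anova$df1, assessment$anova$df2,
            assessment$anova$F, assessment$anova$p, assessment$anova$peta2),
    "predicted vs actual choice rates (whole data):",
    sprintf("  %s: r = %.3f, p = %.3g", whole$pair, whole$r, whole$p),
    "predicted vs actual choice rates (held out):",
    sprintf("  %s: r = %.3f, p = %.3g", held$correlations$pair,
            held$correlations$r, held$correlations$p)
  )
  if (!is.null(behav$associations)) {
    summary_txt <- c(summary_txt, "behavioral associations:",
                     sprintf("  %s vs %s: r = %.3f, p = %.3g",
                             behav$associations$measure_x,
                             behav$associations$measure_y,
                             behav$associations$r, behav$associations$p))
  }
  writeLines(summary_txt, file.path(config$out_dir, "summary.txt"))
  log_lines <- c(log_lines, sprintf("finished: %s", format(Sys.time())))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(cohort = cohort, fits_drift = fits_drift,
                 fits_boundary = fits_bound, assessment = assessment,
                 correlations_whole = whole, holdout = held,
                 behavior = behav, summary = summary_txt))
}
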