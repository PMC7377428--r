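#' Default synthetic-population configuration
#'
#' Parameters of the generative cohort. Drift structure per subject:
#' `v(stimulus) = v0 + beta_risk * [low risk] + beta_ev * [high EV] +
#' stimulus-level noise`, all in evidence units/s with drift SD `s = 1`.
#' The low-risk drift advantage `beta_risk` is coupled to the subject's
#' utility curvature `rho` (`beta_risk = beta_risk_base +
#' risk_utility_gain * (0.5^rho - 0.5^rho_mean) + noise`), so that more
#' concave subjects prefer the safe gambles more strongly — the behavioral
#' association between concavity and risk aversion exists as ground truth.
#' The trait-anxiety score is drawn independently of every choice parameter,
#' encoding the null associations as recoverable structure.
#'
#' Time-scale defaults (`t0` mean 0.12 s) follow the reported mean
#' non-decision time of 120 ms; evidence units are set by `s = 1`.
#'
#' @param ... overrides of any default (name = value).
#' @return a list of class `population_config`.
#' @export
population_config <- function(...) {
  cfg <- list(
    v0_mean = 2.0, v0_sd = 0.4,            # baseline drift
    beta_ev_mean = 0.3, beta_ev_sd = 0.35, # high-EV drift bonus
    beta_risk_base = 0.5,                  # low-risk drift bonus at mean rho
    risk_utility_gain = 3.5,               # coupling of beta_risk to concavity
    beta_risk_sd = 0.4,                    # residual beta_risk noise
    drift_stim_noise_sd = 0.25,            # idiosyncratic per-stimulus noise
    A_mean = 0.7, A_sd = 0.2, A_min = 0.1, # start-point range
    bmA_mean = 0.35, bmA_sd = 0.1, bmA_min = 0.05, # threshold minus A
    t0_mean = 0.12, t0_sd = 0.05, t0_min = 0.02,   # non-decision time (s)
    drift_sd = 1.0,                        # fixed scale convention
    rho_mean = 0.7, rho_sd = 0.2, rho_min = 0.2, rho_max = 1.5,
    kappa_mean = 0.2, kappa_sd = 0.1,      # counterfactual weight, >= 0
    rating_noise_sd = 8,                   # VAS units
    stai_mean = 40, stai_sd = 10           # truncated to [20, 80]
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown population_config keys: ",
                            paste(unknown, collapse = ", "))
  cfg <- modifyList(cfg, over)
  sds <- grep("_sd$", names(cfg), value = TRUE)
  if (any(unlist(cfg[sds]) < 0)) stop("SDs must be non-negative")
  if (cfg$drift_sd <= 0) stop("drift_sd must be positive")
  structure(cfg, class = c("population_config", "list"))
}

#' Read/write a population configuration as JSON
#'
#' The shipped defaults live at
#' `system.file("extdata", "population_config.json", package = "lbachoice")`.
#'
#' @param path file path.
#' @param config a `population_config`.
#' @return `read_population_config` returns a `population_config`.
#' @export
read_population_config <- function(path) {
  do.call(population_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' @rdname read_population_config
#' @export
write_population_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

rtrunc_norm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  x <- rnorm(n, mean, sd)
  bad <- x < lo | x > hi
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < lo | x > hi
  }
  x
}

#' Draw a synthetic subject population
#'
#' Generates ground-truth subject profiles: per-stimulus LBA drift rates with
#' the risk/EV structure of [population_config()], shared `A`, `b`, `t0`,
#' utility exponent `rho`, counterfactual weight `kappa`, rating noise, and
#' an independent trait-anxiety score (STAI-T, 20-80).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return data.frame, one row per subject: `subject_id`, true drift columns
#'   `v_HR_HEV` ... `v_LR_LEV`, `A`, `b`, `t0`, `s`, `rho`, `kappa`,
#'   `rating_noise_sd`, `stai_t`, plus the generative `beta_risk`, `beta_ev`.
#' @export
sample_population <- function(n_subjects, config = population_config(), seed = 1L) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  cfg <- config
  old <- .Random.seed_guard(derive_seed(seed, 101L))
  on.exit(old(), add = TRUE)
  n <- n_subjects
  rho <- rtrunc_norm(n, cfg$rho_mean, cfg$rho_sd, cfg$rho_min, cfg$rho_max)
  beta_risk <- cfg$beta_risk_base +
    cfg$risk_utility_gain * (0.5^rho - 0.5^cfg$rho_mean) +
    rnorm(n, 0, cfg$beta_risk_sd)
  beta_ev <- rnorm(n, cfg$beta_ev_mean, cfg$beta_ev_sd)
  v0 <- rnorm(n, cfg$v0_mean, cfg$v0_sd)
  stim <- derive_stimulus_distributions()
  vmat <- sapply(seq_len(nrow(stim)), function(i) {
    v0 + beta_risk * (stim$risk_level[i] == "low") +
      beta_ev * (stim$ev_level[i] == "high") +
      rnorm(n, 0, cfg$drift_stim_noise_sd)
  })
  vmat <- matrix(vmat, nrow = n)
  colnames(vmat) <- paste0("v_", stim$stimulus_id)
  A <- rtrunc_norm(n, cfg$A_mean, cfg$A_sd, lo = cfg$A_min)
  bmA <- rtrunc_norm(n, cfg$bmA_mean, cfg$bmA_sd, lo = cfg$bmA_min)
  t0 <- rtrunc_norm(n, cfg$t0_mean, cfg$t0_sd, lo = cfg$t0_min)
  kappa <- rtrunc_norm(n, cfg$kappa_mean, cfg$kappa_sd, lo = 0)
  stai <- round(rtrunc_norm(n, cfg$stai_mean, cfg$stai_sd, 20, 80))
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    vmat,
    A = A, b = A + bmA, t0 = t0, s = cfg$drift_sd,
    rho = rho, kappa = kappa, rating_noise_sd = cfg$rating_noise_sd,
    stai_t = as.integer(stai),
    beta_risk = beta_risk, beta_ev = beta_ev,
    stringsAsFactors = FALSE
  )
  out
}

profile_params <- function(profile) {
  v <- unlist(profile[paste0("v_", STIMULI)])
  names(v) <- STIMULI
  lba_params(v, profile$A, profile$b, profile$t0, profile$s)
}

#' Satisfaction rating on the 0-100 visual analog scale
#'
#' Generative model of the post-feedback rating: utility
#' `u(x) = 100 * (x/40)^rho`; with a counterfactual outcome shown, a linear
#' regret/relief adjustment `-kappa * (u(cf) - u(outcome))`; Gaussian rating
#' noise; result clipped to `[0, 100]`.
#'
#' @param outcome obtained points (0, 20, or 40); vectorized.
#' @param counterfactual foregone points, or `NA` when not shown.
#' @param rho utility exponent (> 0).
#' @param kappa counterfactual weight (>= 0).
#' @param noise_sd rating noise SD in VAS units.
#' @return ratings in `[0, 100]`. Uses the session RNG.
#' @export
satisfaction_rating <- function(outcome, counterfactual = NA, rho, kappa,
                                noise_sd = 0) {
  stopifnot(all(outcome %in% c(0, 20, 40)), rho > 0, kappa >= 0, noise_sd >= 0)
  u <- function(x) 100 * (x / 40)^rho
  base <- u(outcome)
  adj <- ifelse(is.na(counterfactual), 0, -kappa * (u(counterfactual) - base))
  r <- base + adj + if (noise_sd > 0) rnorm(length(base), 0, noise_sd) else 0
  pmin(pmax(r, 0), 100)
}

#' Simulate one subject's run through a task schedule
#'
#' Per trial, (choice, rt) come from [simulate_race()] under the subject's
#' true LBA parameters; the obtained outcome is drawn from the chosen
#' gamble's chip distribution; in counterfactual blocks a foregone outcome is
#' drawn from the unchosen gamble; the satisfaction rating follows
#' [satisfaction_rating()].
#'
#' @param profile one row of [sample_population()].
#' @param schedule output of [build_task_schedule()].
#' @param seed integer seed.
#' @return data.frame of trials: schedule columns plus `subject_id`,
#'   `choice`, `rt_s`, `outcome`, `counterfactual` (NA outside counterfactual
#'   blocks), `satisfaction`.
#' @export
simulate_subject <- function(profile, schedule, seed = 1L) {
  params <- profile_params(profile)
  stim <- derive_stimulus_distributions()
  rownames(stim) <- stim$stimulus_id
  old <- .Random.seed_guard(derive_seed(seed, 202L))
  on.exit(old(), add = TRUE)
  n <- nrow(schedule)
  ps <- split_pair(schedule$pair)
  choice <- character(n); rt <- numeric(n)
  for (p in unique(schedule$pair)) {
    idx <- which(schedule$pair == p)
    pr <- split_pair(p)
    race <- simulate_race(c(pr$stim1, pr$stim2), params, n = length(idx))
    choice[idx] <- race$choice
    rt[idx] <- race$rt
  }
  draw_outcome <- function(stim_id) {
    counts <- as.numeric(stim[stim_id, c("n0", "n20", "n40")])
    sample(c(0, 20, 40), 1L, prob = counts / 100)
  }
  outcome <- vapply(choice, draw_outcome, numeric(1))
  unchosen <- ifelse(choice == ps$stim1, ps$stim2, ps$stim1)
  is_cf <- schedule$block_type == "counterfactual"
  counterfactual <- rep(NA_real_, n)
  counterfactual[is_cf] <- vapply(unchosen[is_cf], draw_outcome, numeric(1))
  satisfaction <- satisfaction_rating(outcome, counterfactual,
                                      rho = profile$rho, kappa = profile$kappa,
                                      noise_sd = profile$rating_noise_sd)
  data.frame(
    subject_id = profile$subject_id,
    schedule,
    choice = choice, rt_s = rt,
    outcome = outcome, counterfactual = counterfactual,
    satisfaction = satisfaction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws a population, builds one seeded schedule per subject (alternating
#' counterbalance arms), and simulates every subject's trials.
#'
#' @inheritParams sample_population
#' @return list with `subjects` (the population table) and `trials` (all
#'   trials, stacked).
#' @export
simulate_cohort <- function(n_subjects, config = population_config(), seed = 1L) {
  subjects <- sample_population(n_subjects, config, seed)
  arms <- rep(c("cf_first", "nocf_first"), length.out = n_subjects)
  trials <- lapply(seq_len(n_subjects), function(i) {
    sched <- build_task_schedule(derive_seed(seed, 303L, i), arms[i])
    simulate_subject(subjects[i, ], sched, seed = derive_seed(seed, 404L, i))
  })
  list(subjects = subjects, trials = do.call(rbind, trials))
}
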