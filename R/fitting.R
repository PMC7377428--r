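#' Fitting configuration
#'
#' @param n_restarts number of jittered restarts of the simplex optimizer.
#' @param maxit maximum simplex iterations per restart (2000 lets the
#'   7-parameter simplex reach `reltol` on 96-trial subjects).
#' @param reltol relative convergence tolerance passed to [optim()].
#' @param drift_sd fixed trial-to-trial drift SD (scale convention, not a
#'   free parameter).
#' @return list of class `fit_config`.
#' @export
fit_config <- function(n_restarts = 10L, maxit = 2000L, reltol = 1e-7,
                       drift_sd = 1.0) {
  stopifnot(n_restarts >= 1L, maxit >= 1L, reltol > 0, drift_sd > 0)
  structure(list(n_restarts = as.integer(n_restarts), maxit = as.integer(maxit),
                 reltol = reltol, drift_sd = drift_sd),
            class = c("fit_config", "list"))
}

# Free parameters live in a transformed space that enforces the constraints:
#   drifts (or shared drift)    unconstrained
#   log A                       A > 0
#   log(b - A) (per threshold)  b > A
#   qlogis(t0 / min rt)         0 < t0 < min observed rt
theta_to_params <- function(theta, variant, rt_min, drift_sd) {
  # clamp the transformed coordinates so exp()/plogis() cannot under/overflow
  theta <- unname(theta)
  clamp <- function(x) pmin(pmax(x, -30), 30)
  if (variant == "drift_model") {
    v <- theta[1:4]; names(v) <- STIMULI
    A <- max(exp(clamp(theta[5])), 1e-6)
    b <- A + exp(clamp(theta[6]))
    t0 <- rt_min * plogis(clamp(theta[7]))
    lba_params(v, A, b, t0, drift_sd)
  } else {
    v <- theta[1]
    A <- max(exp(clamp(theta[2])), 1e-6)
    b <- A + exp(clamp(theta[3:6])); names(b) <- STIMULI
    t0 <- rt_min * plogis(clamp(theta[7]))
    boundary_params(v, b, A, t0, drift_sd)
  }
}

empirical_choice_fraction <- function(trials) {
  ps <- split_pair(trials$pair)
  shown <- c(ps$stim1, ps$stim2)
  chosen <- table(factor(trials$choice, levels = STIMULI))
  appear <- table(factor(shown, levels = STIMULI))
  rate <- as.numeric(chosen) / pmax(as.numeric(appear), 1L)
  names(rate) <- STIMULI
  list(rate = rate, appearances = as.numeric(appear))
}

#' Heuristic starting parameters for maximum-likelihood fitting
#'
#' Initialization rules: `t0` starts at 0.9 x the minimum observed RT; the
#' threshold starts at 2 x the SD of the RTs (read as evidence units under a
#' unit evidence rate) with `A = b/2`; drift starts are centered at 1 and
#' ordered by each stimulus's empirical choice fraction. When `jitter_sd > 0`
#' the start is perturbed in the transformed space (used for restarts).
#'
#' @param trials subject trial table (`pair`, `choice`, `rt_s`).
#' @param variant `"drift_model"` or `"boundary_model"`.
#' @param jitter_sd SD of Gaussian jitter in transformed space (session RNG).
#' @param drift_sd fixed drift SD.
#' @return parameter object of the requested variant.
#' @export
initialize_params <- function(trials, variant = c("drift_model", "boundary_model"),
                              jitter_sd = 0, drift_sd = 1.0) {
  variant <- match.arg(variant)
  ecf <- empirical_choice_fraction(trials)
  if (any(ecf$appearances == 0)) stop("every stimulus needs at least one trial")
  rt_min <- min(trials$rt_s)
  rt_sd <- max(sd(trials$rt_s), 0.05)
  b0 <- max(2 * rt_sd, 0.2)
  A0 <- b0 / 2
  t0_0 <- 0.9 * rt_min
  centered <- ecf$rate - mean(ecf$rate)
  theta <- if (variant == "drift_model") {
    c(1 + 2 * centered, log(A0), log(b0 - A0), qlogis(0.9))
  } else {
    # faster-chosen stimuli get lower starting thresholds
    c(1, log(A0), log(b0 - A0) - centered, qlogis(0.9))
  }
  if (jitter_sd > 0) theta <- theta + rnorm(length(theta), 0, jitter_sd)
  theta_to_params(theta, variant, rt_min, drift_sd)
}

params_to_theta <- function(params, rt_min) {
  if (inherits(params, "lba_params")) {
    c(unname(params$drift_means[STIMULI]),
      log(params$start_max),
      log(params$threshold - params$start_max),
      qlogis(min(params$nondecision / rt_min, 1 - 1e-8)))
  } else {
    c(params$drift_mean,
      log(params$start_max),
      log(unname(params$thresholds[STIMULI]) - params$start_max),
      qlogis(min(params$nondecision / rt_min, 1 - 1e-8)))
  }
}

#' Maximum-likelihood LBA fit for one subject
#'
#' Minimizes the race negative log-likelihood with Nelder-Mead simplex in the
#' transformed parameter space, best of `n_restarts` jittered restarts. The
#' drift-rate variant frees 4 drifts plus shared `A`, `b`, `t0`; the
#' response-boundary variant frees 4 thresholds plus shared `v`, `A`, `t0`
#' (both 7 free parameters; drift SD fixed).
#'
#' @param trials one subject's trial table.
#' @param variant `"drift_model"` or `"boundary_model"`.
#' @param config [fit_config()].
#' @param seed integer seed (controls restart jitter only).
#' @return object of class `lba_fit`: `variant`, `params`, `nll`,
#'   `n_restarts_used`, `converged`, `seed`, `restart_nlls`.
#' @export
fit_subject <- function(trials, variant = c("drift_model", "boundary_model"),
                        config = fit_config(), seed = 1L) {
  variant <- match.arg(variant)
  if (nrow(trials) < 1L) stop("empty trial set")
  rt_min <- min(trials$rt_s)
  drift_sd <- config$drift_sd

  ps <- split_pair(trials$pair)
  other <- ifelse(trials$choice == ps$stim1, ps$stim2, ps$stim1)
  ci <- match(trials$choice, STIMULI)
  oi <- match(other, STIMULI)
  if (any(is.na(ci)) || any(is.na(oi))) stop("unknown stimulus ids in trials")
  rt <- trials$rt_s

  drift_idx <- if (variant == "drift_model") 1:4 else 1L
  trans_idx <- setdiff(1:7, drift_idx)
  objective <- function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta[trans_idx]) > 30) ||
        any(abs(theta[drift_idx]) > 1e3)) return(1e12)
    if (variant == "drift_model") {
      v <- theta[1:4]
      A <- max(exp(theta[5]), 1e-6); b <- A + exp(theta[6])
      t0 <- rt_min * plogis(theta[7])
      lba_race_nll_cpp(rt, v[ci], v[oi], rep(b, length(rt)), rep(b, length(rt)),
                       A, t0, drift_sd)
    } else {
      v <- rep(theta[1], length(rt))
      A <- max(exp(theta[2]), 1e-6); bst <- A + exp(theta[3:6])
      t0 <- rt_min * plogis(theta[7])
      lba_race_nll_cpp(rt, v, v, bst[ci], bst[oi], A, t0, drift_sd)
    }
  }

  old <- .Random.seed_guard(derive_seed(seed, 505L))
  on.exit(old(), add = TRUE)
  best <- NULL
  restart_nlls <- numeric(config$n_restarts)
  for (r in seq_len(config$n_restarts)) {
    init <- initialize_params(trials, variant,
                              jitter_sd = if (r == 1L) 0 else 0.3,
                              drift_sd = drift_sd)
    theta0 <- params_to_theta(init, rt_min)
    opt <- optim(theta0, objective, method = "Nelder-Mead",
                 control = list(maxit = config$maxit, reltol = config$reltol))
    restart_nlls[r] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (!is.finite(best$value)) stop("no restart converged to a finite NLL")
  n_best <- sum(restart_nlls <= best$value + 1e-6)
  if (n_best == 1L && config$n_restarts > 1L) {
    message("best NLL reached by a single restart; consider more restarts")
  }
  structure(list(
    variant = variant,
    params = theta_to_params(best$par, variant, rt_min, drift_sd),
    nll = best$value,
    n_restarts_used = config$n_restarts,
    converged = best$convergence == 0L,
    seed = seed,
    restart_nlls = restart_nlls
  ), class = "lba_fit")
}

#' @export
print.lba_fit <- function(x, ...) {
  cat("LBA fit (", x$variant, "), NLL = ", format(x$nll, digits = 6),
      ", converged = ", x$converged, "\n", sep = "")
  if (x$variant == "drift_model") {
    cat("  drifts:", paste(sprintf("%s=%.3f", STIMULI,
                                   x$params$drift_means[STIMULI]), collapse = " "), "\n")
    cat(sprintf("  A=%.3f b=%.3f t0=%.3f s=%.2f\n", x$params$start_max,
                x$params$threshold, x$params$nondecision, x$params$drift_sd))
  } else {
    cat("  thresholds:", paste(sprintf("%s=%.3f", STIMULI,
                                       x$params$thresholds[STIMULI]), collapse = " "), "\n")
    cat(sprintf("  v=%.3f A=%.3f t0=%.3f s=%.2f\n", x$params$drift_mean,
                x$params$start_max, x$params$nondecision, x$params$drift_sd))
  }
  invisible(x)
}

#' Normalized drift rates
#'
#' Each fitted drift divided by the subject's mean drift across the four
#' stimuli, so the four ratios average to exactly 1. Removes between-subject
#' scale differences before the risk-by-EV ANOVA.
#'
#' @param fit an `lba_fit` of the drift-rate variant.
#' @return named numeric vector of four ratios (mean 1).
#' @export
normalized_drift_rates <- function(fit) {
  stopifnot(inherits(fit, "lba_fit"))
  if (fit$variant != "drift_model") stop("normalized drifts require the drift-rate variant")
  v <- fit$params$drift_means[STIMULI]
  m <- mean(v)
  if (m <= 0) stop("mean drift rate is non-positive; normalization undefined")
  v / m
}

#' Fit every subject in a cohort
#'
#' @param trials cohort trial table (column `subject_id`).
#' @param variant model variant.
#' @param config [fit_config()].
#' @param seed master seed; each subject gets a derived substream.
#' @return named list of `lba_fit` objects, one per subject.
#' @export
fit_cohort <- function(trials, variant = c("drift_model", "boundary_model"),
                       config = fit_config(), seed = 1L) {
  variant <- match.arg(variant)
  ids <- unique(trials$subject_id)
  fits <- lapply(seq_along(ids), function(i) {
    fit_subject(trials[trials$subject_id == ids[i], , drop = FALSE],
                variant, config, seed = derive_seed(seed, 606L, i))
  })
  names(fits) <- ids
  fits
}

#' Tabulate a list of fits as a flat data.frame
#'
#' @param fits named list of `lba_fit` (from [fit_cohort()]).
#' @return data.frame with one row per subject: parameters, `nll`,
#'   `converged`, `n_restarts_used`, `seed`.
#' @export
fits_table <- function(fits) {
  rows <- lapply(names(fits), function(id) {
    f <- fits[[id]]
    base <- data.frame(subject_id = id, variant = f$variant, nll = f$nll,
                       converged = f$converged,
                       n_restarts_used = f$n_restarts_used, seed = f$seed,
                       stringsAsFactors = FALSE)
    if (f$variant == "drift_model") {
      v <- as.list(f$params$drift_means[STIMULI])
      names(v) <- paste0("v_", STIMULI)
      cbind(base, as.data.frame(v),
            data.frame(A = f$params$start_max, b = f$params$threshold,
                       t0 = f$params$nondecision, s = f$params$drift_sd))
    } else {
      b <- as.list(f$params$thresholds[STIMULI])
      names(b) <- paste0("b_", STIMULI)
      cbind(base, as.data.frame(b),
            data.frame(v = f$params$drift_mean, A = f$params$start_max,
                       t0 = f$params$nondecision, s = f$params$drift_sd))
    }
  })
  do.call(rbind, rows)
}
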