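#' Linear ballistic accumulator parameters
#'
#' Constructors for the two model variants. In the drift-rate variant each
#' stimulus has its own mean drift `v` and all share one threshold `b`; in
#' the response-boundary variant each stimulus has its own threshold and all
#' share one drift. Both share the start-point range `A` (starting evidence
#' is Uniform(0, A)), the non-decision time `t0` (seconds), and the
#' trial-to-trial drift SD `s`, which is fixed to 1 by convention for scale
#' identifiability.
#'
#' @param drift_means named numeric vector (one per stimulus) of mean drift
#'   rates, evidence units per second.
#' @param start_max `A >= 0`, upper end of the uniform start-point range.
#' @param threshold `b > A`, response threshold (scalar for the drift
#'   variant).
#' @param nondecision `t0 >= 0`, seconds.
#' @param drift_sd `s > 0`, SD of the trial-sampled drift.
#' @return an object of class `lba_params` (drift variant) or
#'   `lba_boundary_params`.
#' @export
lba_params <- function(drift_means, start_max, threshold, nondecision, drift_sd = 1) {
  start_max <- max(start_max, 1e-6)  # guarded lower bound on A
  stopifnot(
    is.numeric(drift_means), !is.null(names(drift_means)),
    all(is.finite(drift_means)),
    length(start_max) == 1L,
    length(threshold) == 1L, threshold > start_max,
    length(nondecision) == 1L, nondecision >= 0,
    length(drift_sd) == 1L, drift_sd > 0
  )
  structure(
    list(drift_means = drift_means, start_max = start_max,
         threshold = threshold, nondecision = nondecision, drift_sd = drift_sd),
    class = "lba_params"
  )
}

#' @param thresholds named numeric vector (one per stimulus) of thresholds,
#'   each `> start_max`.
#' @param drift_mean shared scalar mean drift.
#' @rdname lba_params
#' @export
boundary_params <- function(drift_mean, thresholds, start_max, nondecision, drift_sd = 1) {
  start_max <- max(start_max, 1e-6)
  stopifnot(
    is.numeric(thresholds), !is.null(names(thresholds)),
    all(thresholds > start_max),
    length(drift_mean) == 1L, is.finite(drift_mean),
    nondecision >= 0, drift_sd > 0
  )
  structure(
    list(drift_mean = drift_mean, thresholds = thresholds,
         start_max = start_max,
         nondecision = nondecision, drift_sd = drift_sd),
    class = "lba_boundary_params"
  )
}

# (v, b) for one accumulator under either variant
acc_vb <- function(params, stim) {
  if (inherits(params, "lba_params")) {
    v <- params$drift_means[stim]
    if (any(is.na(v))) stop("unknown stimulus id: ", paste(stim, collapse = ", "))
    list(v = unname(v), b = rep(params$threshold, length(stim)))
  } else if (inherits(params, "lba_boundary_params")) {
    b <- params$thresholds[stim]
    if (any(is.na(b))) stop("unknown stimulus id: ", paste(stim, collapse = ", "))
    list(v = rep(params$drift_mean, length(stim)), b = unname(b))
  } else {
    stop("params must be lba_params or lba_boundary_params")
  }
}

#' Defective first-passage CDF of a single linear ballistic accumulator
#'
#' Probability that an accumulator with threshold `b`, start range `A`,
#' trial-sampled drift `Normal(v, s^2)` and start `Uniform(0, A)` has reached
#' threshold by decision time `t`. The distribution is defective: its limit
#' as `t` grows is `1 - pnorm(-v/s)`, the probability of a positive sampled
#' drift.
#'
#' @param t decision time(s) in seconds, strictly positive (vectorized).
#' @param b,A,v,s scalar accumulator parameters; `b > A >= 1e-6`, `s > 0`.
#' @return defective probabilities in `[0, 1]`.
#' @export
lba_cdf <- function(t, b, A, v, s) {
  check_acc(t, b, A, s)
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  F <- 1 + ((b - A - t * v) / A) * pnorm(z1) -
    ((b - t * v) / A) * pnorm(z2) +
    (ts / A) * dnorm(z1) - (ts / A) * dnorm(z2)
  pmin(pmax(F, 0), 1)
}

#' Defective first-passage density of a single linear ballistic accumulator
#'
#' Density (1/s) of first-passage at decision time `t`; integrates over
#' `(0, Inf)` to `1 - pnorm(-v/s)`.
#'
#' @inheritParams lba_cdf
#' @return non-negative densities.
#' @export
lba_pdf <- function(t, b, A, v, s) {
  check_acc(t, b, A, s)
  ts <- t * s
  z1 <- (b - A - t * v) / ts
  z2 <- (b - t * v) / ts
  f <- (v * pnorm(z2) - v * pnorm(z1) + s * dnorm(z1) - s * dnorm(z2)) / A
  pmax(f, 0)
}

check_acc <- function(t, b, A, s) {
  if (any(t <= 0)) stop("decision time t must be > 0")
  stopifnot(length(b) == 1L, length(A) == 1L, length(s) == 1L)
  if (!(b > A)) stop("threshold b must exceed start range A")
  if (A < 1e-6) stop("A must be >= 1e-6 (guarded lower bound)")
  if (s <= 0) stop("drift SD s must be > 0")
  invisible(TRUE)
}

#' Race likelihood of one observed (choice, rt)
#'
#' Likelihood density of choosing `choice` at time `rt` in a two-accumulator
#' race between the members of `pair`: with decision time
#' `tau = rt - t0`, the winner's defective density times the loser's survival,
#' normalized by the probability that at least one sampled drift is positive,
#' `1 - pnorm(-v_c/s) * pnorm(-v_o/s)`. Returns 0 for `rt <= t0`.
#'
#' @param choice chosen stimulus id, one member of `pair`.
#' @param rt observed response time(s), seconds (vectorized).
#' @param pair character vector of the two competing stimulus ids.
#' @param params `lba_params` or `lba_boundary_params`.
#' @return likelihood density value(s).
#' @export
race_likelihood <- function(choice, rt, pair, params) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  if (!(choice %in% pair)) stop("choice must be a member of pair")
  other <- setdiff(pair, choice)
  s <- params$drift_sd
  pc <- acc_vb(params, choice)
  po <- acc_vb(params, other)
  tau <- rt - params$nondecision
  out <- numeric(length(rt))
  ok <- tau > 0
  if (any(ok)) {
    norm <- 1 - pnorm(-pc$v / s) * pnorm(-po$v / s)
    A <- params$start_max
    out[ok] <- lba_pdf(tau[ok], pc$b, A, pc$v, s) *
      (1 - lba_cdf(tau[ok], po$b, A, po$v, s)) / norm
  }
  out
}

#' Negative log-likelihood of a trial set under an LBA variant
#'
#' Sum over trials of `-log(race_likelihood)`. Trials whose likelihood
#' underflows to zero (or whose `rt <= t0`) contribute a large finite penalty
#' `-log(1e-300)` each, keeping derivative-free optimization stable.
#'
#' @param trials data.frame with columns `pair` (label `"stim1:stim2"`),
#'   `choice`, `rt_s`.
#' @param params `lba_params` or `lba_boundary_params`.
#' @return scalar negative log-likelihood.
#' @export
negative_log_likelihood <- function(trials, params) {
  if (nrow(trials) == 0L) stop("empty trial set")
  ps <- split_pair(trials$pair)
  other <- ifelse(trials$choice == ps$stim1, ps$stim2, ps$stim1)
  if (any(trials$choice != ps$stim1 & trials$choice != ps$stim2)) {
    stop("some trials have choice outside their pair")
  }
  vc <- acc_vb(params, trials$choice)
  vo <- acc_vb(params, other)
  lba_race_nll_cpp(trials$rt_s, vc$v, vo$v, vc$b, vo$b,
                   params$start_max, params$nondecision, params$drift_sd)
}

#' Simulate two-accumulator LBA races
#'
#' For each race, both accumulators draw a start `Uniform(0, A)` and a drift
#' `Normal(v, s^2)`; an accumulator with non-positive drift never finishes.
#' Whole races in which both drifts are non-positive are redrawn (matching
#' the likelihood normalization). The first accumulator to reach its
#' threshold wins; ties (measure zero) go to the first pair member.
#'
#' @param pair character vector of the two competing stimulus ids.
#' @param params `lba_params` or `lba_boundary_params`.
#' @param n number of races.
#' @param max_redraws cap on whole-set redraw passes for all-negative drifts.
#' @return data.frame with `choice` and `rt` (seconds), `n` rows. Uses the
#'   session RNG; seed with [set.seed()] or [derive_seed()] upstream.
#' @export
simulate_race <- function(pair, params, n = 1L, max_redraws = 1000L) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2], n >= 1L)
  s <- params$drift_sd
  A <- params$start_max
  a1 <- acc_vb(params, pair[1])
  a2 <- acc_vb(params, pair[2])
  d1 <- rnorm(n, a1$v, s); d2 <- rnorm(n, a2$v, s)
  bad <- d1 <= 0 & d2 <= 0
  tries <- 0L
  while (any(bad)) {
    tries <- tries + 1L
    if (tries > max_redraws) stop("drift resampling cap exceeded (pathological params)")
    m <- sum(bad)
    d1[bad] <- rnorm(m, a1$v, s)
    d2[bad] <- rnorm(m, a2$v, s)
    bad <- d1 <= 0 & d2 <= 0
  }
  k1 <- runif(n, 0, A); k2 <- runif(n, 0, A)
  t1 <- ifelse(d1 > 0, (a1$b - k1) / d1, Inf)
  t2 <- ifelse(d2 > 0, (a2$b - k2) / d2, Inf)
  first_wins <- t1 <= t2
  data.frame(
    choice = ifelse(first_wins, pair[1], pair[2]),
    rt = params$nondecision + pmin(t1, t2),
    stringsAsFactors = FALSE
  )
}
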