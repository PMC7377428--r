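# Gauss-Legendre nodes/weights on [-1, 1] by Golub-Welsch; cached per order.
.gl_cache <- new.env(parent = emptyenv())
gauss_legendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.gl_cache[[key]])) return(.gl_cache[[key]])
  k <- seq_len(n - 1)
  off <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  res <- list(x = e$values[ord], w = 2 * e$vectors[1, ord]^2)
  .gl_cache[[key]] <- res
  res
}

#' Predicted probability of choosing the first member of a pair
#'
#' Integrates the race identity
#' `p_i = Int f_i(tau) (1 - F_j(tau)) dtau / (1 - pnorm(-v_i/s) pnorm(-v_j/s))`
#' by adaptive quadrature over `(0, Inf)`. The two members' probabilities sum
#' to 1 within 1e-6.
#'
#' @param params `lba_params` or `lba_boundary_params`.
#' @param pair two stimulus ids; the probability refers to `pair[1]`.
#' @return probability in `[0, 1]`.
#' @export
predict_choice_prob <- function(params, pair) {
  stopifnot(length(pair) == 2L, pair[1] != pair[2])
  s <- params$drift_sd
  A <- params$start_max
  a1 <- acc_vb(params, pair[1])
  a2 <- acc_vb(params, pair[2])
  norm <- 1 - pnorm(-a1$v / s) * pnorm(-a2$v / s)
  integrand <- function(tau) {
    lba_pdf(tau, a1$b, A, a1$v, s) * (1 - lba_cdf(tau, a2$b, A, a2$v, s))
  }
  # upper truncation: past T_up both accumulators' remaining finishing mass
  # is below 1e-12, so the integrand's tail contributes nothing at tolerance
  lim1 <- 1 - pnorm(-a1$v / s); lim2 <- 1 - pnorm(-a2$v / s)
  T_up <- 1
  while (T_up < 1e8 &&
         (lim1 - lba_cdf(T_up, a1$b, A, a1$v, s) > 1e-12 ||
          lim2 - lba_cdf(T_up, a2$b, A, a2$v, s) > 1e-12)) {
    T_up <- T_up * 2
  }
  # split the domain at quantiles of the winning accumulator's finish-time
  # distribution (bisection on its monotone CDF), so near-delta densities
  # from extreme fitted parameter sets cannot slip between quadrature nodes;
  # each segment is handled by fixed-order Gauss-Legendre quadrature, which
  # has no data-dependent failure modes
  fracs <- c(1e-9, 1e-6, 1e-4, 1e-3, 0.01, seq(0.05, 0.95, by = 0.1),
             0.99, 0.999, 1 - 1e-4, 1 - 1e-6, 1 - 1e-9)
  targets <- fracs * lim1
  lo <- rep(1e-12, length(fracs)); hi <- rep(T_up, length(fracs))
  for (k in 1:45) {  # vectorized bisection; knots only bracket mass
    mid <- (lo + hi) / 2
    below <- lba_cdf(mid, a1$b, A, a1$v, s) < targets
    lo[below] <- mid[below]; hi[!below] <- mid[!below]
  }
  knots <- unique(c(hi, T_up))
  knots <- sort(knots[is.finite(knots) & knots > 0])
  gl <- gauss_legendre(41L)
  total <- 0
  for (i in seq_len(length(knots) - 1L)) {
    h <- (knots[i + 1] - knots[i]) / 2
    if (h < 1e-15) next
    mid <- (knots[i + 1] + knots[i]) / 2
    total <- total + h * sum(gl$w * integrand(mid + h * gl$x))
  }
  p <- total / norm
  min(max(p, 0), 1)
}

#' Per-pair predicted probabilities for one fitted subject
#'
#' @param params fitted parameter object.
#' @return data.frame `pair`, `p_first` (probability of the lexicographically
#'   first member).
#' @export
pair_predictions <- function(params) {
  pr <- stimulus_pairs()
  pr$p_first <- vapply(seq_len(nrow(pr)), function(i) {
    predict_choice_prob(params, c(pr$stim1[i], pr$stim2[i]))
  }, numeric(1))
  pr[, c("pair", "p_first")]
}

#' Empirical per-pair choice rates
#'
#' Fraction of each pair's trials on which the lexicographically first member
#' was chosen.
#'
#' @param trials trial table for one subject (or any trial subset).
#' @param require_all_pairs raise if one of the 6 pairs has no trials
#'   (otherwise that pair is returned with `NA`).
#' @return data.frame `pair`, `rate_first`, `n`.
#' @export
empirical_choice_rates <- function(trials, require_all_pairs = TRUE) {
  pr <- stimulus_pairs()
  ps <- split_pair(trials$pair)
  pr$n <- vapply(pr$pair, function(p) sum(trials$pair == p), numeric(1))
  if (require_all_pairs && any(pr$n == 0)) {
    stop("pairs with zero trials: ",
         paste(pr$pair[pr$n == 0], collapse = ", "))
  }
  pr$rate_first <- vapply(seq_len(nrow(pr)), function(i) {
    idx <- trials$pair == pr$pair[i]
    if (!any(idx)) return(NA_real_)
    mean(trials$choice[idx] == pr$stim1[i])
  }, numeric(1))
  pr[, c("pair", "rate_first", "n")]
}

#' Predicted vs. actual choice rates across subjects
#'
#' For each of the 6 pairs, the Pearson correlation (two-sided test) across
#' subjects between model-predicted choice probabilities and empirical choice
#' rates.
#'
#' @param fits named list of `lba_fit` keyed by subject id.
#' @param trials cohort trial table (used for the empirical rates; pass the
#'   held-out half for out-of-sample evaluation).
#' @return data.frame `pair`, `r`, `p`, `n`, plus a `predictions` attribute
#'   holding the per-subject table.
#' @export
predicted_vs_actual <- function(fits, trials) {
  ids <- names(fits)
  if (length(ids) < 3L) stop("need at least 3 subjects")
  per_subj <- lapply(ids, function(id) {
    pred <- pair_predictions(fits[[id]]$params)
    emp <- empirical_choice_rates(trials[trials$subject_id == id, , drop = FALSE])
    data.frame(subject_id = id, pair = pred$pair,
               predicted = pred$p_first, empirical = emp$rate_first,
               n = emp$n, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per_subj)
  pr <- stimulus_pairs()
  res <- lapply(pr$pair, function(p) {
    d <- tab[tab$pair == p, ]
    if (sd(d$predicted) == 0 || sd(d$empirical) == 0) {
      stop("constant predicted or empirical vector for pair ", p,
           "; correlation undefined")
    }
    ct <- cor.test(d$predicted, d$empirical)
    data.frame(pair = p, r = unname(ct$estimate), p = ct$p.value,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  attr(out, "predictions") <- tab
  out
}

#' Stratified half split of one subject's trials
#'
#' Per pair, exactly half of its trials (8 of 16 at full task scale) are
#' assigned to the test half uniformly at random; the rest train. Train and
#' test are disjoint and exhaust the input.
#'
#' @param trials one subject's trials; every pair must have an even count.
#' @param seed integer seed.
#' @return list `train`, `test` (data.frames).
#' @export
holdout_split <- function(trials, seed = 1L) {
  counts <- table(trials$pair)
  if (any(counts %% 2 != 0)) {
    stop("odd per-pair trial counts; stratified half split undefined")
  }
  old <- .Random.seed_guard(derive_seed(seed, 707L))
  on.exit(old(), add = TRUE)
  test_idx <- unlist(lapply(names(counts), function(p) {
    idx <- which(trials$pair == p)
    sample(idx, length(idx) / 2)
  }))
  test_idx <- sort(test_idx)
  list(train = trials[-test_idx, , drop = FALSE],
       test = trials[test_idx, , drop = FALSE])
}

#' Held-out prediction analysis for a cohort
#'
#' Each subject's trials are half-split stratified by pair; the model is fit
#' on the training half only and its per-pair predicted probabilities are
#' correlated across subjects with the empirical rates of the test half.
#'
#' @param trials cohort trial table.
#' @param variant model variant for fitting.
#' @param config [fit_config()].
#' @param seed master seed (drives both the splits and the fits).
#' @return list: `correlations` (pair, r, p, n), `fits`, `splits`.
#' @export
holdout_evaluation <- function(trials, variant = "drift_model",
                               config = fit_config(), seed = 1L) {
  ids <- unique(trials$subject_id)
  if (length(ids) < 3L) stop("need at least 3 subjects")
  splits <- list(); fits <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    sp <- holdout_split(trials[trials$subject_id == id, , drop = FALSE],
                        seed = derive_seed(seed, 808L, i))
    fit <- tryCatch(
      fit_subject(sp$train, variant, config, seed = derive_seed(seed, 909L, i)),
      error = function(e) {
        warning("subject ", id, " failed to fit on the training half: ",
                conditionMessage(e))
        NULL
      })
    if (!is.null(fit)) {
      splits[[id]] <- sp
      fits[[id]] <- fit
    }
  }
  test <- do.call(rbind, lapply(splits, `[[`, "test"))
  list(correlations = predicted_vs_actual(fits, test),
       fits = fits, splits = splits)
}
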