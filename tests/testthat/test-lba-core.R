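test_that("lba_cdf behaves at the boundaries and at infinity", {
  expect_equal(lba_cdf(1e-9, 1, 0.5, 1.5, 1), 0)
  # limit t -> Inf is the probability of a positive sampled drift
  expect_equal(lba_cdf(1e7, 1, 0.5, 1, 1), 1 - pnorm(-1), tolerance = 1e-6)
  expect_equal(lba_cdf(1e7, 2, 0.3, 2, 1), 1 - pnorm(-2), tolerance = 1e-6)
  # monotone non-decreasing
  ts <- seq(0.05, 8, length.out = 200)
  expect_true(all(diff(lba_cdf(ts, 1.2, 0.6, 1.8, 1)) >= -1e-12))
  expect_error(lba_cdf(-1, 1, 0.5, 1, 1), "must be > 0")
  expect_error(lba_cdf(1, 0.4, 0.5, 1, 1), "exceed")
})

test_that("lba_pdf is the derivative of lba_cdf (numerical oracle)", {
  sets <- random_valid_params(101, n = 10)
  h <- 1e-6
  for (p in sets) {
    b <- p$threshold; A <- p$start_max; v <- p$drift_means[[1]]
    for (t in c(0.15, 0.4, 0.9, 2.1)) {
      num <- (lba_cdf(t + h, b, A, v, 1) - lba_cdf(t - h, b, A, v, 1)) / (2 * h)
      f <- lba_pdf(t, b, A, v, 1)
      if (f > 1e-8) expect_equal(num, f, tolerance = 1e-5)
    }
  }
})

test_that("lba_pdf integrates to the defective mass and is non-negative", {
  # split at t = 5 so the adaptive rule cannot overlook the peak in (0, 1);
  # the integral over (0, T) must equal F(T), and the defective limit is
  # analytic (slow near-zero drifts leave ~2.5e-4 of mass beyond t = 200)
  mass <- integrate(function(t) lba_pdf(t, 1, 0.5, 2, 1), 0, 5,
                    rel.tol = 1e-10)$value +
    integrate(function(t) lba_pdf(t, 1, 0.5, 2, 1), 5, 200,
              rel.tol = 1e-10)$value
  expect_equal(mass, lba_cdf(200, 1, 0.5, 2, 1), tolerance = 1e-7)
  expect_equal(mass, 1 - pnorm(-2), tolerance = 1e-3)
  expect_equal(lba_cdf(1e7, 1, 0.5, 2, 1), 1 - pnorm(-2), tolerance = 1e-6)
  for (p in random_valid_params(202, n = 5)) {
    ts <- seq(1e-3, 10, length.out = 400)
    expect_true(all(lba_pdf(ts, p$threshold, p$start_max,
                            p$drift_means[[2]], 1) >= 0))
  }
})

test_that("lba_cdf matches a simulation oracle", {
  set.seed(404)
  n <- 2e5
  b <- 1; A <- 0.5; v <- 1.5; s <- 1; t <- 1
  d <- rnorm(n, v, s); k <- runif(n, 0, A)
  prop <- mean(d > 0 & (b - k) / d <= t)
  se <- sqrt(prop * (1 - prop) / n)
  expect_lt(abs(lba_cdf(t, b, A, v, s) - prop), 3 * se)
})

test_that("race likelihood: edge cases and exchangeability", {
  p <- ref_params()
  pair <- c("HR_HEV", "LR_LEV")
  expect_equal(race_likelihood("HR_HEV", p$nondecision, pair, p), 0)
  expect_equal(race_likelihood("HR_HEV", 0.05, pair, p), 0)
  expect_error(race_likelihood("LR_HEV", 0.5, pair, p), "member of pair")
  # symmetric accumulators give identical likelihoods for either choice
  sym <- lba_params(c(HR_HEV = 2, HR_LEV = 2, LR_HEV = 2, LR_LEV = 2),
                    0.5, 1, 0.1, 1)
  expect_equal(race_likelihood("HR_HEV", 0.6, pair, sym),
               race_likelihood("LR_LEV", 0.6, pair, sym))
})

test_that("race likelihood integrals for the two choices sum to 1", {
  for (p in c(list(ref_params(), ref_boundary_params()),
              random_valid_params(303, n = 3))) {
    pair <- c("HR_LEV", "LR_HEV")
    tot <- sum(vapply(pair, function(ch) {
      integrate(function(rt) race_likelihood(ch, rt, pair, p),
                p$nondecision, p$nondecision + 60, rel.tol = 1e-8,
                subdivisions = 400L)$value
    }, numeric(1)))
    expect_equal(tot, 1, tolerance = 1e-4)
  }
})

test_that("negative_log_likelihood equals the brute-force product oracle", {
  p <- ref_params()
  set.seed(11)
  trials <- do.call(rbind, lapply(1:5, function(i) {
    pr <- stimulus_pairs()[sample(6, 1), ]
    r <- simulate_race(c(pr$stim1, pr$stim2), p, 1)
    data.frame(pair = pr$pair, choice = r$choice, rt_s = r$rt)
  }))
  brute <- -sum(log(vapply(1:5, function(i) {
    ps <- strsplit(trials$pair[i], ":", fixed = TRUE)[[1]]
    race_likelihood(trials$choice[i], trials$rt_s[i], ps, p)
  }, numeric(1))))
  expect_equal(negative_log_likelihood(trials, p), brute, tolerance = 1e-10)
  # additivity under duplication
  expect_equal(negative_log_likelihood(rbind(trials, trials), p),
               2 * negative_log_likelihood(trials, p), tolerance = 1e-10)
  expect_error(negative_log_likelihood(trials[0, ], p), "empty")
  # a pre-t0 trial draws the finite penalty, not Inf
  bad <- trials; bad$rt_s[1] <- p$nondecision / 2
  val <- negative_log_likelihood(bad, p)
  expect_true(is.finite(val))
  expect_gt(val, -log(1e-300) - 1)
})

test_that("simulate_race: symmetry, determinism limit, and distribution", {
  sym <- lba_params(c(HR_HEV = 2, HR_LEV = 2, LR_HEV = 2, LR_LEV = 2),
                    0.5, 1, 0.1, 1)
  set.seed(42)
  r <- simulate_race(c("HR_HEV", "LR_LEV"), sym, n = 1e5)
  se <- sqrt(0.25 / 1e5)
  expect_lt(abs(mean(r$choice == "HR_HEV") - 0.5), 3 * se)
  expect_true(all(r$rt > sym$nondecision))

  # s -> 0, A -> 0: deterministic finish at t0 + b/v
  det <- lba_params(c(HR_HEV = 2, HR_LEV = 2, LR_HEV = 2, LR_LEV = 2),
                    1e-6, 1, 0.1, 1e-9)
  set.seed(1)
  rd <- simulate_race(c("HR_HEV", "HR_LEV"), det, n = 100)
  expect_equal(rd$rt, rep(0.1 + 1 / 2, 100), tolerance = 1e-4)

  # simulated choice proportion matches the closed-form race probability
  p <- ref_params()
  set.seed(7)
  rr <- simulate_race(c("HR_LEV", "LR_HEV"), p, n = 1e5)
  pq <- predict_choice_prob(p, c("HR_LEV", "LR_HEV"))
  expect_lt(abs(mean(rr$choice == "HR_LEV") - pq), 3 * sqrt(pq * (1 - pq) / 1e5))

  # simulated RT deciles match the closed-form conditional RT distribution
  dec <- quantile(rr$rt, probs = seq(0.1, 0.9, 0.2))
  cond_cdf <- function(t) {
    integrate(function(u) race_likelihood("HR_LEV", u, c("HR_LEV", "LR_HEV"), p),
              p$nondecision, t, rel.tol = 1e-9)$value +
      integrate(function(u) race_likelihood("LR_HEV", u, c("HR_LEV", "LR_HEV"), p),
                p$nondecision, t, rel.tol = 1e-9)$value
  }
  for (i in seq_along(dec)) {
    lev <- seq(0.1, 0.9, 0.2)[i]
    expect_lt(abs(cond_cdf(dec[[i]]) - lev), 0.01)
  }
})

test_that("increasing a drift increases that option's win probability", {
  base <- c(HR_HEV = 2, HR_LEV = 2, LR_HEV = 2, LR_LEV = 2)
  probs <- vapply(c(1.5, 2, 2.5, 3), function(v) {
    dm <- base; dm["HR_HEV"] <- v
    predict_choice_prob(lba_params(dm, 0.5, 1, 0.1, 1), c("HR_HEV", "HR_LEV"))
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("parameter validation rejects degenerate inputs", {
  expect_error(lba_params(c(a = 1), 0.5, 0.4, 0.1), "threshold")
  expect_error(lba_params(c(a = 1), 0.5, 1, -0.1))
  expect_error(lba_params(c(a = 1), 0.5, 1, 0.1, drift_sd = 0))
  expect_error(boundary_params(1, c(a = 0.4), 0.5, 0.1))
  expect_error(simulate_race(c("HR_HEV", "HR_HEV"), ref_params(), 1))
  # pathological params exhaust the redraw cap
  hopeless <- lba_params(c(HR_HEV = -50, HR_LEV = -50, LR_HEV = 0, LR_LEV = 0),
                         0.5, 1, 0.1, 0.01)
  set.seed(2)
  expect_error(simulate_race(c("HR_HEV", "HR_LEV"), hopeless, n = 10,
                             max_redraws = 5), "cap")
})
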