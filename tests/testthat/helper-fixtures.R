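# Shared fixtures: small synthetic cohort and a reference parameter set.
# Everything is generated in code at load time; no files on disk.

STIM4 <- c("HR_HEV", "HR_LEV", "LR_HEV", "LR_LEV")

ref_params <- function() {
  lba_params(
    drift_means = c(HR_HEV = 2.3, HR_LEV = 2.0, LR_HEV = 2.8, LR_LEV = 2.5),
    start_max = 0.7, threshold = 1.05, nondecision = 0.12, drift_sd = 1
  )
}

ref_boundary_params <- function() {
  boundary_params(
    drift_mean = 2.2,
    thresholds = c(HR_HEV = 1.0, HR_LEV = 1.2, LR_HEV = 0.9, LR_LEV = 1.1),
    start_max = 0.6, nondecision = 0.15, drift_sd = 1
  )
}

# one small cohort reused across files (6 subjects x 96 trials)
fixture_cohort <- simulate_cohort(6, seed = 301)

# fast fitting configuration for unit tests (acceptance uses defaults)
quick_fit <- fit_config(n_restarts = 3, maxit = 800)

random_valid_params <- function(rng_seed, n = 1) {
  set.seed(rng_seed)
  lapply(seq_len(n), function(i) {
    A <- runif(1, 0.2, 1.2)
    b <- A + runif(1, 0.08, 1)
    v <- runif(4, 0.3, 3.2)
    names(v) <- STIM4
    lba_params(v, A, b, runif(1, 0.05, 0.3), 1)
  })
}
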