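#' The four task gambles, derived from their moment constraints
#'
#' Each gamble is a drawing of one chip from a pool of 100 chips worth 0, 20,
#' or 40 points. The task design fixes the first two moments of each gamble:
#' expected value 24 (high EV) or 20 (low EV) points, and variance 384 (high
#' risk) or 96 (low risk) points^2. Writing p20 and p40 for the chip
#' proportions of the 20- and 40-point chips, the constraints
#' `20 p20 + 40 p40 = EV` and `400 p20 + 1600 p40 = Var + EV^2` form a 2x2
#' linear system with a unique solution for every risk-by-EV cell; the
#' 0-point count is the remainder out of 100.
#'
#' @return a data.frame with one row per stimulus: `stimulus_id`
#'   (`HR_HEV`, `HR_LEV`, `LR_HEV`, `LR_LEV`), chip counts `n0`, `n20`,
#'   `n40`, `risk_level`, `ev_level`, and the recomputed `ev` and `variance`.
#' @examples
#' derive_stimulus_distributions()
#' @export
derive_stimulus_distributions <- function() {
  cells <- data.frame(
    stimulus_id = STIMULI,
    risk_level  = c("high", "high", "low", "low"),
    ev_level    = c("high", "low", "high", "low"),
    ev          = c(24, 20, 24, 20),
    variance    = c(384, 384, 96, 96),
    stringsAsFactors = FALSE
  )
  outcomes <- c(0, 20, 40)
  chips <- t(vapply(seq_len(nrow(cells)), function(i) {
    ev <- cells$ev[i]
    m2 <- cells$variance[i] + ev^2
    # moments in chip-proportion space: [20 40; 400 1600] %*% c(p20, p40)
    sol <- solve(matrix(c(20, 400, 40, 1600), 2, 2), c(ev, m2))
    p <- c(1 - sum(sol), sol)
    n <- p * 100
    if (any(n < -1e-9) || any(abs(n - round(n)) > 1e-9)) {
      stop("moment constraints do not yield non-negative integer chip counts",
           call. = FALSE)
    }
    round(n)
  }, numeric(3)))
  cells$n0 <- chips[, 1]
  cells$n20 <- chips[, 2]
  cells$n40 <- chips[, 3]
  stopifnot(rowSums(chips) == 100)
  cells[, c("stimulus_id", "n0", "n20", "n40", "risk_level", "ev_level",
            "ev", "variance")]
}

#' The six unordered stimulus pairs
#'
#' Pairs are canonically oriented: `stim1 < stim2` lexicographically, and the
#' pair label is `"stim1:stim2"`. All per-pair bookkeeping (choice rates,
#' predicted probabilities) refers to the first member of this orientation.
#'
#' @return data.frame with columns `pair`, `stim1`, `stim2` (6 rows).
#' @export
stimulus_pairs <- function() {
  cmb <- combn(STIMULI, 2)
  data.frame(
    pair = paste(cmb[1, ], cmb[2, ], sep = ":"),
    stim1 = cmb[1, ],
    stim2 = cmb[2, ],
    stringsAsFactors = FALSE
  )
}

split_pair <- function(pair) {
  parts <- strsplit(pair, ":", fixed = TRUE)
  list(stim1 = vapply(parts, `[`, "", 1L),
       stim2 = vapply(parts, `[`, "", 2L))
}

#' Build the 4-block x 24-trial task schedule
#'
#' Each of the 6 stimulus pairs occurs exactly 4 times per block (16 times in
#' total), so each stimulus appears on 48 of the 96 trials. Within-block trial
#' order and the left/right display assignment are randomized by `seed`.
#' Half the blocks give counterfactual feedback (the foregone outcome is
#' shown) and half do not; `counterbalance_arm` selects which type comes
#' first, alternating thereafter.
#'
#' @param seed integer seed for the shuffle.
#' @param counterbalance_arm `"cf_first"` or `"nocf_first"`.
#' @return data.frame of 96 trial slots: `block`, `block_type`, `trial`,
#'   `pair`, `left_stim`.
#' @export
build_task_schedule <- function(seed, counterbalance_arm = c("cf_first", "nocf_first")) {
  counterbalance_arm <- match.arg(counterbalance_arm)
  pairs <- stimulus_pairs()
  block_types <- if (counterbalance_arm == "cf_first") {
    c("counterfactual", "no_counterfactual", "counterfactual", "no_counterfactual")
  } else {
    c("no_counterfactual", "counterfactual", "no_counterfactual", "counterfactual")
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  blocks <- lapply(1:4, function(b) {
    idx <- sample(rep(seq_len(6), each = 4))
    side <- runif(24) < 0.5
    data.frame(
      block = b,
      block_type = block_types[b],
      trial = 1:24,
      pair = pairs$pair[idx],
      left_stim = ifelse(side, pairs$stim1[idx], pairs$stim2[idx]),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, blocks)
}

# Seed the session RNG, returning a restore closure (keeps user RNG state
# untouched by package internals).
.Random.seed_guard <- function(seed) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  }
}
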