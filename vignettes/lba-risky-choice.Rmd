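---
title: "Decisional randomness in explicit risky choice: the LBA pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decisional randomness in explicit risky choice: the LBA pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

People choosing between explicitly described gambles do not choose
deterministically: given identical information they sometimes pick the option
they generally prefer less, even when it is strictly inferior (same risk,
lower expected value). `lbachoice` implements a complete pipeline for testing
whether a *linear ballistic accumulator* (LBA) — a sequential sampling model
in which each option has an independent, linearly rising evidence accumulator
and the first to reach threshold wins — accounts for this decisional
randomness, jointly with the reaction-time (RT) distributions it implies.

The task it models is a four-gamble design. Each gamble draws one chip from a
pool of 100 chips worth 0, 20, or 40 points, and the chip counts fix the
first two moments exactly: expected value 24 ("high EV") or 20 ("low EV"),
variance 384 ("high risk") or 96 ("low risk"). The four risk-by-EV cells give
six unordered stimulus pairs; a session is 4 blocks of 24 trials in which
every pair appears 16 times, so every gamble is on screen in 48 trials. Half
the blocks reveal the foregone outcome ("counterfactual feedback"); after
every outcome the subject rates satisfaction on a 0–100 visual analog scale
(VAS).

## The model

For one accumulator with threshold $b$, start point $k \sim U(0, A)$, and
drift $d \sim N(v, s^2)$ drawn per trial, the time to threshold is
$(b-k)/d$ for $d > 0$. Its first-passage distribution has the closed forms

$$F(t) = 1 + \tfrac{b-A-tv}{A}\Phi\!\big(\tfrac{b-A-tv}{ts}\big)
           - \tfrac{b-tv}{A}\Phi\!\big(\tfrac{b-tv}{ts}\big)
           + \tfrac{ts}{A}\phi\!\big(\tfrac{b-A-tv}{ts}\big)
           - \tfrac{ts}{A}\phi\!\big(\tfrac{b-tv}{ts}\big)$$

$$f(t) = \tfrac{1}{A}\Big[v\Phi\!\big(\tfrac{b-tv}{ts}\big)
         - v\Phi\!\big(\tfrac{b-A-tv}{ts}\big)
         + s\phi\!\big(\tfrac{b-A-tv}{ts}\big)
         - s\phi\!\big(\tfrac{b-tv}{ts}\big)\Big].$$

Both are *defective*: their total mass is $1 - \Phi(-v/s)$, because a
negative sampled drift never finishes. For an observed choice $c$ at time
$\mathrm{rt}$ racing against alternative $o$, with decision time
$\tau = \mathrm{rt} - t_0$,

$$L(c, \mathrm{rt}) \;=\;
  \frac{f_c(\tau)\,\big(1 - F_o(\tau)\big)}
       {1 - \Phi(-v_c/s)\,\Phi(-v_o/s)},$$

the denominator conditioning on at least one accumulator finishing. The
simulator applies the same convention (whole trials with two non-positive
drifts are redrawn), so the generative and inferential models match. The
source report is silent on this normalization; we follow the model's source
literature and document it here as an assumption.

Two seven-parameter variants are compared:

* **drift-rate variant** — one drift per gamble ($v_1..v_4$), shared
  $A$, $b$, $t_0$: value modulates evidence accumulation speed;
* **response-boundary variant** — one threshold per gamble ($b_1..b_4$),
  shared $v$, $A$, $t_0$: value modulates response caution.

The drift SD $s$ is fixed at 1 in both, the standard LBA scale convention;
it is configurable (`fit_config(drift_sd = ...)`) but never free.

## Fitting

Each subject is fitted independently by maximum likelihood (no hierarchy).
The optimizer is Nelder–Mead simplex in a transformed space that makes every
constraint structural rather than penalized:

| free parameter | transform | guarantees |
|---|---|---|
| drifts (or shared drift) | identity | — |
| $A$ | $\log A$ | $A > 0$ (floored at $10^{-6}$) |
| $b$ | $\log(b - A)$ | $b > A$, per threshold |
| $t_0$ | $\mathrm{logit}(t_0 / \min \mathrm{rt})$ | $0 < t_0 < \min \mathrm{rt}$ |

The logistic transform for $t_0$ deviates from a plain $\log t_0$: it
implements, in one stroke, the upper bound at the minimum observed RT that
prevents the zero-likelihood collapse a free $t_0$ invites. Trials whose
likelihood underflows contribute a finite penalty $-\log(10^{-300})$ so the
simplex always sees a gradient.

Starting values use common LBA-tutorial heuristics (the source report cites
but does not reprint its own): $t_0 = 0.9 \times \min \mathrm{rt}$;
$b = 2\,\mathrm{SD}(\mathrm{rt})$ read as evidence units under a unit
evidence rate, with $A = b/2$; drift starts centered at 1 and ordered by each
stimulus's empirical choice fraction. The default is the best of 10 restarts
(first from the raw heuristic, the rest jittered with SD 0.3 in transformed
space, maxit 2000, reltol $10^{-7}$): a single simplex start on 7 parameters
is not reliable. All of this is configurable via `fit_config()`.

## Prediction and assessment

Per-pair choice probabilities come from the race identity
$p_i = \int_0^\infty f_i (1 - F_j)\,d\tau$ (normalized as above). The
integral is evaluated by fixed-order Gauss–Legendre quadrature on segments
delimited by quantiles of the winner's finish-time distribution (found by
bisection on the monotone CDF), truncated where both accumulators' remaining
mass is below $10^{-12}$. We abandoned R's adaptive `integrate()` on
$(0,\infty)$ here: fitted parameter sets routinely produce near-delta
densities that trigger its divergence heuristics, while the segmented rule is
deterministic and conserves $p_i + p_j = 1$ to well below $10^{-6}$.

Model assessment mirrors the report surface of the original analysis:

* **quantile-probability table** — per stimulus, pooled across subjects:
  response probability (fraction of its 48·n appearances chosen) and
  choice-conditional RT quantiles at .1/.3/.5/.7/.9, for the data and for a
  large seeded simulation from the fitted parameters (default $10^4$
  trials/subject). The model side is simulated rather than computed from an
  analytic mixture CDF; the pooled-over-subjects model distribution has no
  closed form and simulation error is controlled by the simulation count.
* **chi-square choice GOF** — observed per-stimulus choice counts against
  expected counts obtained by summing the fitted model's per-pair
  probabilities over every trial, $df = 3$. Observed counts more extreme
  than expected indicate behavior *less random* than the model.
* **KS RT GOF** — per stimulus, a two-sample Kolmogorov–Smirnov test of the
  pooled empirical RTs against a pooled model sample (100× each subject's
  trial count, seeded). Two-sample rather than one-sample for the same
  no-closed-form reason.
* **risk × EV ANOVA** — normalized drifts (each subject's four drifts
  divided by their mean, so ratios average to 1) enter a classic two-way
  within-subject decomposition; each effect is tested against its
  effect-by-subject stratum and reported with partial $\eta^2$. A
  numerically null effect in noise-free constructed data is reported as
  $F = 0$, $p = 1$ rather than 0/0.

The held-out analysis splits each subject's trials in half stratified by
pair (8 of 16 per pair, seeded), fits on the training half only, and
correlates predicted probabilities with empirical rates computed on the test
half across subjects, two-sided Pearson, no multiplicity correction — one
split per seed, with repetition left to the caller.

## The synthetic cohort: what it emulates and what it does not

No raw trial data accompany the original study, so the pipeline is validated
on a generative stand-in, and every downstream claim is a *structural
analogue*, not a reproduction of the published point estimates. A subject
profile holds true LBA parameters, a utility exponent $\rho$, a
counterfactual weight $\kappa$, rating noise, and a trait-anxiety score
(STAI-T):

* **drift structure** — $v(\text{stim}) = v_0 + \beta_\text{risk}\,
  [\text{low risk}] + \beta_\text{EV}\,[\text{high EV}] + \varepsilon$,
  giving preference for safer, richer gambles on average while noise in
  accumulation produces the decisional randomness under study.
* **utility and ratings** — $u(x) = 100 (x/40)^\rho$ on the VAS, the minimal
  concave family consistent with expected-utility framing; with a shown
  counterfactual the rating is $u(\text{out}) - \kappa\,(u(\text{cf}) -
  u(\text{out}))$ — a symmetric linear regret/relief term — plus Gaussian
  noise, clipped to $[0, 100]$. The original report does not state the VAS
  range; 0–100 with clipping is our stand-in.
* **concavity–risk coupling** — $\beta_\text{risk} = 0.5 +
  3.5\,(0.5^\rho - 0.5^{0.7}) + \varepsilon$: more concave subjects (smaller
  $\rho$) carry a larger low-risk drift advantage, so the negative
  association between the relative utility of 20 and risk seeking exists as
  recoverable ground truth.
* **trait anxiety** — truncated normal on 20–80, drawn independently of
  every choice parameter: the published null associations encoded as
  calibration targets (false-positive rate ≈ 5% at $\alpha = .05$).

Time defaults follow the published parameter scale where one exists
($t_0$: mean 0.12 s ± 0.05, matching the reported mean non-decision time of
120 ms; RTs are seconds everywhere, with `read_trials(units = "ms")` for
millisecond files). Evidence-scale defaults ($v_0 = 2.0$, $A = 0.7 \pm 0.2$,
$b - A = 0.35 \pm 0.1$ under $s = 1$) give realistic 0.4–0.8 s RTs and
dominant-pair choice rates around .75.

The between-subject SDs (0.4 for $v_0$, 0.35 for $\beta_\text{EV}$, 0.4
residual for $\beta_\text{risk}$, 0.25 per-stimulus) were calibrated to the
*observable* population signature the original cohort displays — per-pair
choice rates spreading widely across subjects, whole-data predicted-vs-actual
correlations above .5 for all six pairs, positive held-out correlations. Our
first, narrower choice produced a cohort whose held-out correlations hovered
near zero: the prediction analyses are powered by between-subject
heterogeneity, and a homogeneous cohort makes them uninformative regardless
of how well the model fits. The calibration was done once, against those
published signatures, before the acceptance suite was frozen.

The generator does **not** emulate: learning or satisfaction dynamics across
trials, fatigue, position effects (left/right is randomized and ignored,
as reported), real-money incentives, or any anxiety-behavior coupling. A
green test therefore establishes that the pipeline recovers the structure it
was given at the stated scale — not that the original subjects obeyed the
LBA.

## Numerical choices and degenerate inputs

* $A$ is floored at $10^{-6}$; the $A \to 0$ limit needs no special casing
  because the logarithmic transform keeps fits away from it.
* Simulated finish-time ties (measure zero) go to the first pair member, so
  seeded runs are bit-reproducible.
* Subjects whose test half lacks variation are retained; a fully constant
  predicted or empirical vector raises an error rather than a silent NA.
* An outcome-20 cell with no counterfactual-0 or counterfactual-40 trials
  (possible by chance in 96 trials) yields a flagged `NA` sensitivity, and
  association tests drop missing subjects pairwise with a message.
* Every stochastic stage derives its stream from one master seed via
  `derive_seed()` (a small multiplicative mix kept below $2^{31}$), so any
  stage can be re-run in isolation.

## Model-comparison power at paper scale: a known limitation

With 96 trials per subject, the two seven-parameter variants mimic each
other in-sample: on drift-generated cohorts the drift variant achieves the
lower NLL for only ~40–45% of subjects, and deeper restarts do not change
this. The discrimination is informational, not numerical — at 960
trials/subject the drift variant wins 90% of subjects, and data generated
from the boundary variant always prefer the boundary variant. What *does*
separate the variants at paper scale is the pooled quantile-probability
discrepancy (the comparison the original figure actually displays): boundary
fits reproduce the pooled QP table visibly worse on the large majority of
seeded cohorts. The acceptance criterion formulated as a per-subject NLL win
rate is therefore expected to stay red, and is left red deliberately; the
QP-based property is tested and passes.

## Running the pipeline

```{r}
library(lbachoice)
cfg <- run_config(seed = 1, n_subjects = 44, out_dir = "out")
res <- run_pipeline(cfg)
readLines(file.path("out", "summary.txt"))
```

Subcommand-style use (`simulate`, `fit`, `predict`, `holdout`, `assess`,
`behavior`, `run-all`) is available through the CLI script installed at
`system.file("cli", "lbachoice-cli.R", package = "lbachoice")`.
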