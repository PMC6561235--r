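---
title: "Models and design of the riskforage pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design of the riskforage pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(riskforage)
```

## The task and what the package models

In the risk variant of the Web-Surf foraging paradigm, a subject has 40
minutes to cycle — in a fixed order — through four video galleries. Each
encounter offers a delay the subject can either wait out (*stay*) to earn
a short video, rated 1–4 afterwards, or decline (*skip*). Delays span
3–30 s. Offers are *non-risky* (one known delay) or *risky*: three
possible delays (low/mid/high, integer, equally spaced), of which only
the range is shown; the realization appears only after a stay. Receiving
the high delay after accepting a risky deal is a *loss* ("bad" outcome),
the low delay a win ("good"), framed purely by outcome *type* relative to
the offer, never by its economic value. After every trial a five-click
travel task imposes a switching cost.

The package provides both halves of a closed loop:

1. a **generative model** (`session_config()`, `population_config()`,
   `simulate_study()`) producing trial-level logs with known ground
   truth, and
2. the **analysis pipeline** (thresholds → framing datasets →
   mixed-effects model suite → individual differences → discounting)
   whose claims can therefore be verified by parameter recovery.

## Revealed-preference thresholds

A subject's price for a gallery is the delay at which staying flips to
skipping. `fit_heaviside_threshold()` fits the step predictor
$1 - H(d - T)$, with $H(0) = \tfrac12$, by least squares over candidate
thresholds (the range bounds plus midpoints between adjacent distinct
delays). The step fit — unlike a logistic — returns the maximal/minimal
offered delay for all-stay/all-skip galleries instead of diverging.
Numerical choices: the loss is SSE over 0/1 choices (equivalent to
misclassification count away from the half-point, and trivially
oracle-checkable); ties across candidates return the midpoint of the
tied range, unbiased between the last stay and the first skip.

Per-trial thresholds are leave-one-out: the threshold attached to risky
trial $i$ is fit on the gallery's other risky trials (represented by
their mid delay), so a trial never shapes its own covariate. Non-risky
trials receive the gallery mean of that vector; fits use risky trials
only (a config switch could admit non-risky trials, but the default
follows the revealed-preference logic of pricing uncertain offers).
Expected value is linear, $EV = T - \mathrm{mean}(low, mid, high)$,
assuming equal outcome likelihoods — the subject is never told the true
probabilities, and the simulator's default is uniform thirds, exposed in
`session_config(outcome_probs=)` for sensitivity analyses.

## The synthetic population

Each agent carries, per gallery, a true threshold $\tau_g$; choices are
logistic with inverse temperature $\beta$ (default 0.5 per second):
$P(\text{stay}) = \mathrm{logit}^{-1}\big(\beta(\tau_g - d) +
\mathbf{1}[\text{prev risky loss}](\gamma_i + \eta V_{t-1})\big)$, where
$V_{t-1}$ is the previous trial's actual value under the agent's own
thresholds. The framing coefficient is
$\gamma_i = \gamma_0 + \gamma_E E_i$ with latent externalizing
$E_i \sim N(0,1)$: $\gamma_0 = -0.6$ produces group-level risk aversion
after losses, and $\gamma_E = 1.2$ attenuates or reverses it for
high-externalizing agents. By default $E$ enters *only* the choice
pathway — ratings carry no externalizing link — so reward pursuit and
reward valuation dissociate at the trait level by construction.

Ratings are ordered-latent: gallery mean (coupled to the subject's own
threshold deviations, which is what drives the threshold-vs-rating
validity correlations), a value slope, a bad-outcome offset (default
+0.3, so losses are rated *higher* at matched value), Gaussian noise, and
three cutpoints onto 1–4. Reaction times are log-normal with a post-loss
slowing of 0.1 log-seconds. Discounting rates are log-normal
($\ln k_{delay} \sim N(-5.26, 2.05^2)$ per day;
$\ln h \sim N(0.28, 0.84^2)$ per unit odds-against). The externalizing
inventory is a 2-parameter logistic item-response model over 100 items in
three subfactors; problem-subscale items have high difficulty, so most
agents endorse none — reproducing the zero inflation the retention rule
(keep subjects endorsing ≥ 1 item) is designed for.

Two generator choices deserve emphasis:

* **Gallery preferences are idiosyncratic and hierarchical.** Thresholds
  are a subject-level mean (population mean 16 s, between-subject SD
  2.5 s) plus per-gallery deviations (SD 2 s). Two sequential-design
  artifacts motivate this. First, population-*aligned* gallery means
  would make the previous trial's value covariate systematically predict
  the upcoming gallery's attractiveness through the fixed cycle,
  manufacturing a spurious outcome-type effect in perfectly null data.
  Second, even idiosyncratic but iid per-gallery thresholds carry a
  mechanically negative circular lag-1 autocovariance ($-\sigma^2/4$
  with four galleries) that a subject intercept cannot absorb, biasing
  the null by about one standard error. With the hierarchical structure
  the sequential models are calibrated — the acceptance suite checks the
  null rejection rate directly.
* **Effect sizes are design defaults, not truth claims.** The defaults
  (risky fraction 0.8, $\gamma_E = 1.2$, rating offset 0.3, RT slowing
  0.1) are set so that the group and trait effects are detectable with
  roughly 100 subjects and 40-minute sessions, the scale at which such
  studies are run; every one of them is a `population_config()` or
  `session_config()` argument.

What the generator does *not* emulate: real item wording or psychometric
norms, drift-diffusion RT dynamics, satiety or fatigue drifts (global
consumption trends in real data have no generative counterpart here), or
correlated demographics — age, sex and ethnicity are drawn independently
of behavior, so passing recovery tests show the pipeline's statistics
work, not that covariate confounding in real samples is harmless.

## The model suite

All group models are mixed-effects fits (`lme4`; `lmerTest` for
Satterthwaite p-values on linear models; Wald intervals and z-tests for
logistic ones), with subject random intercepts, and — in the matched
follow-ups, where each subject contributes a narrow value range —
correlated random intercept + value slope, the standard reading of a
`(value | subject)` grouping term. The estimation backend is maximum
likelihood rather than posterior sampling; the contract is on
estimates/intervals, not the sampler. 95% intervals, two-sided p-values,
Benjamini–Hochberg adjustment within each model's fixed effects (the
per-table layout of such analyses suggests within-model adjustment; a
joint adjustment would only rescale the same ranking).

Row filters: the primary choice model keeps risky stays followed by a
risky offer; ratings are modeled against the *current* trial's outcome
and value (the video just earned; a `rating_lag` switch restores the
lag-1 variant); the RT model keeps trials preceded by a risky stay; the
global models keep all trials (choice) or all stays (ratings, which only
exist there); the integrated model uses three-level framing-and-risk
coding (good/bad/non-risk, reference bad). Matched follow-up subsets
pair bad-outcome trials with comparison trials of the same subject whose
previous actual value lies within ±0.5 s, nearest first; the tolerance
and the greedy rule are package choices (only "matched by actual value"
is inherent to the design), and matched pairs are value-balanced by
construction. "Mid" outcomes do not enter the matched contrasts, which
compare only loss vs win and loss vs certainty.

Degenerate inputs are contractual: empty model datasets are skipped with
a recorded reason; single-subject data fall back to fixed effects with a
flag; non-convergence and likely separation are flagged on the result,
never silently dropped.

## Individual differences and robust correlations

Per-subject analogues of the primary models are plain `glm`/`lm` fits;
the extracted quantity is the unstandardized bad-vs-good coefficient.
These estimates are intrinsically noisy: with a single 40-minute session
a subject contributes a few dozen usable sequential trials, and the
previous-value and outcome-class predictors are partly collinear (a bad
outcome *is* a long realized delay, hence a low value), so per-subject
coefficients rank-correlate with the generative truth at roughly
0.3–0.45; the correlation climbs with additional sessions. The
trait-level tests are nevertheless well powered because they aggregate
100 such estimates.

Trait correlations are percentage-bend partial correlations (bend 0.2 —
the standard robust-correlation default; the implementation agrees with
independent references to numerical precision), after least-squares
residualization on age, sex and dummy-coded ethnicity. The primary pair
(choice and rating coefficients vs log total score, `ln(total + 1)` so a
zero total is defined) is two-tailed; the six follow-ups (three
subfactors, three retained-subject problem subscales) are one-tailed in
the direction of more risk seeking after losses, BH-adjusted as a family
of six. Follow-up correlations with fewer than 8 retained subjects are
skipped, not computed.

## Discounting

Titration menus span \$0.50–\$10 against a \$10 later/risky amount. The
menu uses an arithmetic \$0.50 grid (a geometric grid was considered;
the arithmetic grid keeps the indifference-point quantization uniform at
±\$0.25 across the range). Indifference points take the midpoint between
the largest smaller-sooner amount rejected and the smallest accepted;
censored or non-monotone runs are flagged and bracketed. Hyperbolic fits
minimize SSE on the indifference points over $\ln k$ (positivity by
parameterization; boundary fits flagged), with $R^2 = 1 - SSE/SST$ on
the points — fitting on points rather than raw choices matches how such
$R^2$ values are conventionally reported. The probability task's
published rate statistic is treated as $\ln h$; on that reading a \$10
reward is worth \$9.51 after a 10-day delay at the median delay rate and
\$8.72 at a 90% chance at the median probability rate, matching the
conventional worked values to rounding.

## Problem sizes and determinism

Everything is seeded: identical (agent, config, seed) triples give
byte-identical logs, and the CSV round trip is exact (reaction times are
written at 4 decimals). The recovery suites used by the tests and the
acceptance script run 20 replicates of 100-subject, 40-minute studies
for the framing-sign and dissociation checks (40 replicates for the null
calibration, where the quantity of interest is a rejection *rate*), 100
subjects for threshold recovery, 1000 random datasets for the
step-fit-vs-oracle equivalence, and 1000 random vectors for the BH
step-up oracle; these sizes make the Monte-Carlo margins comfortably
smaller than the acceptance bands while keeping a full run in the
minutes range.

## Known limitations

* The Heaviside fit is consistent for the *crossing point* of any
  monotone choice rule but is not an efficiency-optimal estimator under
  logistic noise; its virtue is boundedness in extreme galleries.
* Marginal (population-averaged) logistic coefficients are attenuated
  relative to the generative conditional ones when covariates are
  omitted (non-collapsibility) — sign and significance recover, exact
  magnitudes need not.
* The travel task and rating input are charged to the clock as fixed
  draws (5 clicks × log-normal latency; 1 s per rating); no published
  timing distributions exist for them, so session trial counts are
  approximate.
* With only four galleries, validity correlations per subject rest on
  n = 4 points and are accordingly coarse; they are reported per subject
  and summarized by medians.
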