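# riskforage

Simulation and analysis of risky stay/skip foraging behavior — the risk
variant of the Web-Surf task family, in which subjects forage for video
rewards under a 40-minute clock, deciding serially whether to *stay*
through a delay for a reward or *skip* to the next of four galleries.
Risky offers present three possible delays (low/mid/high) whose
realization is hidden until the subject commits; receiving the high delay
is a *risky loss*. The package is aimed at decision scientists and
computational-psychiatry researchers who want to prototype, power, and
validate analyses of such tasks by parameter recovery on synthetic
populations with known ground truth.

## What it computes

* **Revealed-preference delay thresholds.** Stay/skip choices in a
  gallery are fit with a Heaviside step predictor `1 − H(d − T)`
  (H(0) = ½), choosing the threshold `T` that minimizes the squared
  choice residuals; thresholds are computed per trial by leave-one-out so
  a trial never influences its own covariate. Expected value of an offer
  is `EV = T − mean(low, mid, high)` (linear, equal outcome likelihoods),
  spanning −27 … 27 s on the 3–30 s delay grid.
* **Outcome framing.** Realized delays on risky stays are classed by
  *type*, not value: low = good, high = bad (a loss), middle = mid.
* **Sequential mixed-effects models.** The seven model families of the
  analysis — primary choice `Choice_t ~ value_{t−1} + outcome_{t−1} +
  (1|subject)`, primary rating, reaction time, value-matched follow-up
  contrasts with random value slopes, global consumption-by-risk trends,
  a control model, and an integrated rating-by-outcome model — with
  Benjamini–Hochberg FDR adjustment within each model.
* **Individual differences.** Per-subject choice/rating outcome-type
  coefficients, a synthetic 100-item externalizing inventory (total,
  three subfactors, three zero-inflated problem subscales with an
  endorse-at-least-one retention rule), and robust (percentage-bend)
  partial correlations controlling age, sex and ethnicity.
* **Discounting.** Hyperbolic fits `V = A/(1 + kD)` for delay and
  `V = A/(1 + hθ)`, `θ = (1−p)/p`, for probability discounting, with
  titration indifference points, R², and Johnson–Bickel nonsystematic-data
  flags.
* **Exact power for correlations** under the bivariate-normal sampling
  distribution of r (`power_corr_n(0.3, 0.8)` gives 84).

## Worked example

```r
library(riskforage)
library(dplyr)

study <- simulate_study(population_config(n_subjects = 20, seed = 2),
                        session_config(), seed = 2)
thr   <- assign_trial_thresholds(study$trials)

# threshold recovery against ground truth
left_join(subject_thresholds(thr), true_thresholds_long(study$agents),
          by = c("subject_id", "gallery")) |>
  summarise(median_abs_error = median(abs(threshold - tau), na.rm = TRUE))
#> # A tibble: 1 × 1
#>   median_abs_error
#>              <dbl>
#> 1            0.851

suite <- run_model_suite(study$trials, thr)
tidy(suite$models$rt_framing)
#> # A tibble: 4 × 6
#>   term           estimate    ci_lo   ci_hi         p   p_adj
#>   <chr>             <dbl>    <dbl>   <dbl>     <dbl>   <dbl>
#> 1 (Intercept)    0.200     0.118   0.282   0.0000157 NA
#> 2 value_prev    -0.000736 -0.00478 0.00330 0.721     0.729
#> 3 class_prevbad  0.0813    0.0148  0.148   0.0166    0.0499
#> 4 class_prevmid  0.00903  -0.0421  0.0601  0.729     0.729
```

Gallery thresholds come back within ~0.85 s of the generative truth at
n = 20, and the reaction-time model recovers the generator's post-loss
slowing of 0.1 log-seconds (`class_prevbad` = 0.081, FDR-adjusted
p = 0.0499): subjects are slower to decide after a risky loss.

`autoplot()` methods exist for psychophysics curves, fitted models and
discounting fits; `plot_subject_thresholds()` shows a subject's
stay/skip pattern. A command-line driver chains the stages:

```sh
Rscript -e 'riskforage::run_cli()' simulate --seed 7 --out sim/
Rscript -e 'riskforage::run_cli()' analyze  --in sim/ --out results/
Rscript -e 'riskforage::run_cli()' recover  --in sim/ --truth sim/ground_truth.csv --out rec/
Rscript -e 'riskforage::run_cli()' report   --in results/
```

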