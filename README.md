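# vhsl

Analysis toolkit for visuo-haptic statistical-learning experiments in which
"objects" carry no boundary cues and are defined solely by co-occurrence
statistics: each object is a **true pair** of abstract shapes that always
appear together in a fixed horizontal or vertical arrangement, while chimeric
**pseudo pairs** match them visually but behave haptically as two separate
things. After exposure to the statistics in one modality (watching composite
scenes, or pulling them apart with a robotic interface), participants are
tested in both modalities — a haptic pulling test and a two-alternative
visual familiarity test — so that *zero-shot* cross-modal generalisation can
be measured.

The package is for researchers building, simulating or analyzing this family
of paradigms. It provides, end to end:

* **Designs** — exhaustive enumeration of the 3×3-grid exposure scene set
  (444 unique scenes under the adjacency/centre/translation constraints) and
  exact block designs for haptic exposure, pulling tests, familiarity tests
  and training;
* **Physics** — the bond model of breakage forces (11.25 N within-object,
  3.75 N between-object contacts, summed over the split line, giving the
  7.5 / 15 / 22.5 N levels);
* **Simulation** — behavioral cohorts from a latent learning-strength model
  with known ground truth, including participants who internalize a *wrong*
  (pair-swapped) inventory;
* **Analysis** — per-participant measures (fraction correct `f_c`, pulling
  correlation `ρ`, training-based exclusion), the **rectified
  exponential-binomial model**

  `P(ρ) = β₀` for ρ ≤ 0, `P(ρ) = β₁ + (β₀ − β₁)·e^(−ρ/λ)` for ρ > 0,
  `T_c ~ Binomial(P(ρ), T)`

  with maximum-likelihood fitting, a χ²(2) likelihood-ratio test, a sampled
  profile-likelihood confidence band, a Laplace-approximation Bayes factor
  and the range-coverage summary `(P(1) − P(0))/0.5`; the within-participant
  object-consistency statistic; the explicitness partial-correlation
  analysis; and scaled JZS Bayes factors (Cauchy prior scale √2/2) for
  t-tests and regression.

Everything takes and returns tibbles, so the pipeline composes with dplyr;
fitted models support `tidy()`, `glance()` and `autoplot()`.

## Worked example

Simulate both experiments (20 participants each), pool them, and run the full
analysis:

```r
library(vhsl)
library(dplyr)

vis <- simulate_experiment(
  cohort_config(n_participants = 20, experiment = "visual_exposure", seed = 7),
  phases = c("haptic_training", "haptic_pulling_test", "familiarity_test"))
hap <- simulate_experiment(
  cohort_config(n_participants = 20, experiment = "haptic_exposure", seed = 8),
  phases = c("haptic_pulling_test", "familiarity_test"))
hap$trials$participant_id <- hap$trials$participant_id + 20L
trials <- bind_rows(vis$trials, hap$trials)

debrief <- tibble::tibble(
  participant_id = c(vis$cohort$participant_id, hap$cohort$participant_id + 20L),
  noticed = c(vis$cohort$explicit_n_correct, hap$cohort$explicit_n_correct) > 0,
  n_correct_pairs = c(vis$cohort$explicit_n_correct, hap$cohort$explicit_n_correct),
  n_true_pairs = rep(c(6L, 4L), each = 20))

report <- vhsl_analyze(trials, debrief = debrief, seed = 1)
report
#> <vhsl_report>
#>   participants: 40 (0 excluded)
#>   refb fit: beta0 0.522 beta1 1.000 lambda 0.491 | chi2(2) 115.2, p 9.6e-26 | log10 BF 22.9 | coverage 83%
#>   consistency: 0.115 +/- 0.069, t(35) = 1.67, p = 0.104, BF = 0.6
#>   explicitness: R_full 0.71, R_partial 0.64, implicit share 81%

generics::tidy(report$refb$fit)
#> # A tibble: 3 × 3
#>   term   estimate std_error
#>   <chr>     <dbl>     <dbl>
#> 1 beta0     0.522    0.0490
#> 2 beta1     1.000    0.0647
#> 3 lambda    0.491    0.168
```

Reading the output: the fitted curve rises from a baseline familiarity
accuracy of 0.52 (participants whose pulling was at or below chance) to an
asymptote of 1.00 with rate constant λ = 0.49; the likelihood-ratio test
against a flat curve is χ²(2) = 115.2 and the Laplace Bayes factor favours
the rising curve by ~23 orders of magnitude; moving from chance pulling
(ρ = 0) to perfect pulling (ρ = 1) traverses 83% of the attainable
familiarity range. The object-consistency correlation averages 0.115 across
the 36 participants for whom it is defined (ceiling performers are excluded
as undefined, hence t(35)); this simulated cohort used the realistic default
swap rate of 0.1, so the within-participant signal is weak. Controlling for
explicit pair knowledge leaves most of the visual–haptic relation intact
(0.64²/0.71² ≈ 81% of the shared variance is implicit here).

`autoplot(report$refb$fit, band = report$refb$band)` draws the familiar
fraction-correct-vs-ρ figure with the 95% profile-likelihood band.

Individual stages are plain functions: `build_inventory()`,
`enumerate_exposure_scenes()`, `breakage_force()`,
`generate_haptic_exposure_design()`, `simulate_from_refb()`, `fit_refb()`,
`lr_test()`, `profile_ci_band()`, `laplace_log10_bf()`, `scene_scores()`,
`object_consistency()`, `jzs_bf_one_sample()` and friends. See the methods
vignette (`vignettes/methods.Rmd`) for the models, their assumptions and all
numerical choices.

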