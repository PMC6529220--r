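---
title: "Models and methods behind vhsl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vhsl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vhsl)
```

## The scientific setting

`vhsl` implements the computational machinery of a visuo-haptic
statistical-learning paradigm. Participants are exposed to "objects" that have
no boundary cues at all: each object is a *true pair* of abstract shapes that
always co-occur in a fixed horizontal or vertical arrangement, either across a
stream of visual scenes or through the forces experienced when pulling
composite scenes apart with a bimanual robot. Chimeric *pseudo pairs* —
built from shapes of two different true pairs — have matched visual
statistics but behave haptically as two separate objects. After exposure in
one modality, participants are tested in **both**: a haptic pulling test (pull
with the force you believe will break the scene) and a two-alternative visual
familiarity test (true pair vs pseudo pair). The interesting quantity is
*zero-shot* cross-modal generalisation: whether pulling behaviour can be
predicted from purely visual statistics and vice versa.

Everything in the package is organized around tabular trial logs (tibbles,
one row per trial) so the whole pipeline composes with dplyr verbs.

## Stimulus combinatorics

The visual-exposure stimulus set is the complete collection of placements of
three distinct pairs on a 3×3 grid subject to three constraints: every pair
must have a cell edge-adjacent (4-neighborhood: the shapes are displayed with
no gaps, so corner contact does not count) to another pair's cell; the centre
cell must be occupied; and translation-equivalent configurations count once.
`enumerate_exposure_scenes()` performs this search exhaustively over a few
thousand candidate placements and deduplicates by a canonical translation
(bounding box anchored at the origin). With three horizontal and three
vertical true pairs this produces 444 unique scenes — 42 all-horizontal, 108
with two column-aligned horizontal pairs plus a vertical one, 72 with the two
horizontal pairs offset, and the mirror counts for the vertical family — and
every pair appears in exactly 222 scenes. The test suite checks the
enumerator against the closed-form case counts; deduplication is by
translation only (no rotations or reflections, which would merge scenes the
design treats as distinct).

The 2×2 designs (haptic exposure and both pulling tests) are generated
exhaustively per block: every same-orientation combination of pairs, in both
arrangement orders and both pulling directions. "Pseudorandomization" is a
seeded uniform shuffle within each block; the design prescribes no other
constraint. Stimulus timing (700 ms displays, 1 s pauses, 3 s holds) plays no
role in any analysis and is not simulated.

## The bond model of breakage forces

Forces are static thresholds, not time-resolved spring simulations: the only
behaviourally relevant quantity is the threshold at which a scene separates.
Edge-sharing pieces of the same object attach with 11.25 N and pieces of
different objects with 3.75 N; the breakage force of a pull is the sum of
bond strengths crossing the mid-line split. On a 2×2 scene the split always
crosses two contacts, which yields the three canonical levels: 22.5 N
(breaking two true pairs), 15 N (breaking a true and a pseudo pair), 7.5 N
(any pull that merely separates objects). Training scenes made of coloured
rectangles and squares (configurations C2, C3, C4) obey the same rule. The
40 N robot force cap and the 5 N pull-onset threshold are carried in
`bond_config()` and applied by the simulator and the performance measures,
not by the force rule itself.

## The synthetic cohort

The deposited behavioral data are not bundled; instead `simulate_experiment()`
generates cohorts from an explicit latent-variable model so that every
analysis stage can be tested against known ground truth. The model is the
package's own construction — the study it emulates posits no generative model
of behaviour, only that performance on both tasks shares a common underlying
cause. Each participant carries:

* `theta` ∈ [0, 1], learning strength, drawn from Beta(1.5, 1.5) by default —
  broad, covering poor to near-ceiling learners, matching the wide spread of
  empirical performance;
* `sigma_pull` (default 4 N), motor noise on pulling forces — chosen so that
  simulated force separations between levels (a few newtons of spread around
  7.5/15/22.5 N targets) resemble published force traces;
* `transfer_gain` (default 0.8), a single multiplicative attenuation applied
  to `theta` whenever a task probes the modality *not* experienced during
  exposure — the cue-conflict account of weaker cross-modal expression;
* with probability `swap_probability`, an *internal inventory* in which two
  same-orientation true pairs have exchanged a shape. Such participants
  behave consistently with the wrong objects in both tasks.

Pulling forces are a learning-weighted mixture,
`(1 − θ_eff)·7.5 + θ_eff·B_int + N(0, σ)` clipped to [0, 40], where `B_int`
is the breakage force computed from the participant's internal inventory.
Familiarity choices select the internally-true pair with probability
`0.5 + (p_max − 0.5)(1 − exp(−θ_eff/λ_gen))` (defaults `p_max = 0.95`,
`λ_gen = 0.3`, chosen so fitted curves on simulated cohorts have the shape of
the published ones); when neither displayed pair is internally true the
choice is uniform. Explicitness is generated as
`Binomial(n_true_pairs, θ·explicit_rate)/n_true_pairs`, reproducing the
0–1 debriefing grid. There is no trial-order learning during tests, matching
the empirical absence of block trends.

What this generator does *not* emulate: reaction times, force-trace dynamics,
attention lapses, per-pair heterogeneity of learning within a participant
(other than the discrete inventory swap), and any drift of learning across
test trials. Passing tests therefore certify the analysis machinery, not the
psychological fidelity of the generative model.

A consequence of the swap mechanism worth knowing: a swapped participant is
at chance on the two swapped pairs in the familiarity test (their internal
objects never coincide with a displayed pseudo pair), so overall accuracy is
reduced but not driven below chance. Within-participant object consistency,
on the other hand, is positive only insofar as a participant's internal
inventory differs from the true one or noise intervenes — with a veridical
internal inventory all two-true-pair scenes are internally identical and the
scene scores carry no signal. The consistency property tests therefore use
cohorts in which every participant internalizes a swapped inventory.

## The rectified exponential-binomial model

Familiarity accuracy is linked to pulling correlation ρ by
`P(ρ) = β0` for ρ ≤ 0 and `P(ρ) = β1 + (β0 − β1)·exp(−ρ/λ)` for ρ > 0, with
`T_c ~ Binomial(P(ρ), T)` per participant. β0 is the baseline accuracy of
chance-or-worse pullers, β1 the asymptote, λ the rate of rise. Numerical
choices:

* **Fitting** (`fit_refb()`): bounded L-BFGS-B with an analytic gradient over
  the box β ∈ [1e−4, 1−1e−4], λ ∈ [1e−3, 10]; 20 starts by default — one
  moment-based (β0 from the pooled rate of ρ ≤ 0 participants, β1 from the
  upper half of ρ) plus a seeded Latin hypercube (log-spaced in λ). Ties are
  broken by log-likelihood, then smaller λ. Probabilities are clamped to
  [1e−9, 1−1e−9] before logging; participants at ceiling are retained (the
  binomial handles them). When no ρ is positive, λ is unidentified and the
  fit is flagged (`boundary = TRUE`) rather than silently returned.
* **Curvature**: central finite differences (step 1e−4, relative above 1) of
  the negative log-likelihood at the optimum.
* **Likelihood-ratio test**: 2·(ℓ_full − ℓ_null) against χ²(2). Under the
  null λ is unidentified, so the χ²(2) reference is an approximation; in
  simulation at cohort scale (N = 20, T = 72) the test runs slightly
  conservative (rejection ≈ 0.04 at α = 0.05), which the calibration test
  documents.
* **Profile-likelihood band** (`profile_ci_band()`): 100,000 draws from the
  Laplace approximation at the optimum, retaining draws whose log-likelihood
  is within `q/2` of the maximum with `q` the 95th percentile of χ²(3) (3 =
  number of estimated parameters); the band is the pointwise extrema of the
  retained curves, intersected with [0, 1]. The ML curve is always retained,
  and draws are prefix-stable in the sample count so the band can only widen
  as samples grow. A non-positive-definite Hessian is diagonally regularized
  with a warning.
* **Laplace Bayes factor** (`laplace_log10_bf()`): each marginal likelihood
  is approximated by the standard Laplace form, likelihood at the optimum
  times |H|^(−1/2), with constant 2π factors dropped (they cancel or do not
  scale with the data). The package implements the standard Laplace
  correction — the ½·log-determinant — rather than any literal reading of a
  "square root of the log-determinant", which is not a meaningful marginal
  likelihood approximation.
* **Range coverage**: `(P(1) − P(0))/0.5`, the share of the attainable
  familiarity range (0.5–1) traversed between chance and perfect pulling.

## Bayes factors

All frequentist tests carry scaled JZS Bayes factors: a Cauchy prior of scale
`r = √2/2` on the standardized effect (the conventional default; the scale is
configurable and logged in every result), integrated numerically over the
variance-mixing parameter `g` after mapping onto the unit interval (adaptive
quadrature, absolute tolerance 1e−8, evaluated in log space for stability at
extreme `t`). Two-sample tests use effective sample size `n₁n₂/(n₁+n₂)`; the
regression Bayes factor uses the standard mixture-of-g prior with an
inverse-gamma(1/2, n/2) mixing density and depends on the data only through
R². The tests validate all three forms against an independent fixed-grid
Simpson oracle to 1e−6 relative error.

## Consistency and explicitness analyses

For every unique ordered two-true-pair scene of the pulling test (12 in the
visual-exposure design, 4 in the haptic-exposure design) a haptic score
(mean break-direction force minus mean separate-direction force across
repetitions) and a familiarity score (mean over the scene's two pairs of the
fraction of familiarity trials in which that pair was chosen; the
denominator is the number of trials in which the pair appeared, which the
design balances) are computed; a participant's object consistency is the
Pearson correlation of the two scores across scenes. Zero-variance cases
(e.g. ceiling performers) are flagged undefined and excluded from the group
test, never zeroed. The group test is a two-sided one-sample t-test across
participants, pooled over experiments — pooling changes only the degrees of
freedom, never an individual's value.

The explicitness analysis regresses visual performance on haptic performance
plus an experiment indicator (common slope, experiment-specific intercepts)
and reports the indicator-adjusted correlation; the partial version first
residualizes both performances on explicitness *within each experiment*. The
ratio of squared correlations measures the share of the generalisation effect
attributable to implicit transfer. With constant explicitness the
residualization is mere centering and the partial correlation equals the raw
one — a fixed point the tests assert.

Exclusion follows the training-based rule: a participant enters the analysis
only with a significantly positive Pearson correlation between clamp-catch
training forces and breakage forces. The source text does not state the
test's sidedness; the package uses the conservative reading, two-sided
p < 0.05 *and* r > 0, and records the per-participant reason. Correlation is
Pearson throughout (the t²–ρ² equivalence only holds for Pearson); Spearman
is available as an option but never the default.

## Simulation scales used by the tests

The test suite exercises the pipeline at the study's own scale — cohorts of
N = 20 participants with T = 72 familiarity trials — with replicate counts
chosen to keep the whole suite to a few minutes of CPU: 200 replicates for
parameter recovery (median sup-norm error of the fitted curve ≤ 0.05,
absolute median bias of β0/β1 ≤ 0.03 at truth (0.55, 0.95, 0.3)), 2,000 null
cohorts for LRT calibration, 200 all-swapped cohorts plus 50 spliced-null
cohorts for the consistency property, and 100 replicates for band coverage.
The spliced null crosses the familiarity phase of one cohort with the pulling
phase of an independently seeded one, severing the common latent cause while
preserving all marginal distributions.

## Known limitations

* The generative behavioral model is deliberately minimal; estimates of the
  rectified exponential-binomial on simulated cohorts should not be read as
  predictions about real populations.
* The LRT's χ²(2) reference is approximate under the null (λ unidentified);
  the Bayes factor comparison does not share this issue.
* The Laplace Bayes factor requires a positive-definite Hessian; flat
  likelihoods (e.g. all-ρ ≤ 0 data) yield a curvature error instead of a
  number, by design.
* Imported real trial logs must follow the package's documented CSV schema;
  no importer for any external deposit layout is provided.
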