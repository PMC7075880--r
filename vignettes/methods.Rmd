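---
title: "Models and methods: composite memory scoring, guessing chance, and reinstatement decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reinstater)
library(dplyr)
```

`reinstater` analyzes AB–AC memory-integration experiments: behaviorally,
via a composite 0–9 memory score with an analytic guessing chance level and
condition statistics; neurally, via a scene-vs-face pattern decoder whose
per-trial scene probability indexes scene reinstatement during A–C
learning. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic-data generator does and does not
emulate.

## The composite memory score

Each tested object passes through three phases, each worth 0–3 points:

* **Item recognition** — 6-point confidence, 1 = "very sure seen" … 6 =
  "very sure not seen". A correct "old" response earns 3/2/1 points for
  confidence 1/2/3; "new" responses (4–6) and timeouts earn 0. The
  direction of the mapping (most-confident = 3 points, monotonically
  decreasing) is fixed by the design of the scale.
* **Associative recall** — two raters score the typed scene description as
  0 / 0.5 / 1; the rater mean is multiplied by 3 so the phase carries the
  same weight as the recognition phases. Disagreement is resolved by
  averaging; a single-rater table can duplicate its one rater.
* **Associative recognition** — 2AFC with a 6-point left/right confidence
  scale: 1–3 express high-to-low confidence in the left scene, 4–6
  low-to-high confidence in the right. A correct side earns 3/2/1 points
  for the outer/middle/inner confidence band ({1,6} / {2,5} / {3,4}); the
  wrong side or a timeout earns 0. We read the scale's middle levels as
  {2,5} forming the intermediate band — the only reading consistent with a
  six-level symmetric scale in which {3,4} are the low-confidence levels.

Item recognition gates the trial: the later phases only take place after a
correct "old" response, so `item_points = 0` forces the total to 0. A
timeout in a later phase zeroes only that phase. Lures can never earn
memory points; an endorsed lure is a *false alarm* and is recorded with
the pseudo-points (3/2/1 by confidence) it would have earned, which feed
the chance-level estimate.

The test suite checks the two canonical worked examples
(3 + 1 + 0 = 4; 2 + 2 + 3 = 7) and compares `score_trials()` against an
independently written scalar oracle over the exhaustive grid of all
admissible response combinations (7 item confidences × 3 × 3 rater scores
× 7 associative confidences × 2 sides).

## The guessing chance level

A responder with no memory earns points only by a false alarm at item
recognition followed by a lucky associative-recognition guess; recall is
assumed to contribute nothing. Writing $x \in \{1,2,3\}$ for the item
points implied by the false-alarm confidence and $y \in \{0,\dots,3\}$ for
the associative points obtained on a chance response,

$$
C \;=\; p(\mathrm{FA}) \sum_x p(x \mid \mathrm{FA})
\Bigl( x + \tfrac12 \sum_y p(y \mid \mathrm{FA},\, x)\, y \Bigr),
$$

the $\tfrac12$ being the probability of guessing the correct side of the
2AFC. Ingredients are estimated per participant:
$p(\mathrm{FA})$ is the endorsed-lure fraction; $p(x \mid \mathrm{FA})$
the distribution of false-alarm pseudo-points; and
$p(y \mid \mathrm{FA}, x)$ is taken from the participant's *studied*
trials as the row-normalized contingency of associative points against
item points. False alarms have no associative phase of their own, so the
studied-trial contingency is the only available estimate of "points given
a chance response"; this is an inference about the intended procedure, and
the package documents it as such.

Three policies keep $C$ defined on degenerate data:

* zero false alarms → a degenerate profile with $C = 0$ (the formula's
  limit); a pooled alternative (`group_chance_level(method = "pooled")`)
  exists for users who prefer group conditionals;
* an item-point level the participant never produced → fall back to their
  marginal associative-point distribution, rather than inventing zeros;
* group level = unweighted mean of per-participant $C$ values by default
  (the pooled computation is exposed as an option, since printed group
  statistics can be read either way).

`monte_carlo_guessing_chance()` simulates the memory-free responder
directly and serves as the independent oracle: the acceptance suite sweeps
100 random profiles at $10^5$ trials and requires agreement within 3
standard errors.

## Condition statistics

Congruency ratings are binned 1–2 → incongruent, 3 → excluded (the rating
expresses indifference), 4–5 → congruent. Crossing with the 3-level
reactivation report gives the per-participant 2 × 3 cell table
(`condition_summary()`), from which:

* `one_sample_test()` computes the two-tailed one-sample t against the
  chance level, with two effect sizes: the standard one-sample
  $d = (M - C)/SD$ and $d_{0} = M/SD$ (both are reported because published
  one-sample d values are frequently computed as $M/SD$);
* `rm_anova_2x3()` fits the within-subject ANOVA with per-effect error
  strata (subject × effect), partial
  $\eta^2 = SS_\text{eff} / (SS_\text{eff} + SS_\text{err})$, and listwise
  deletion of participants missing any of the six cells — the behavior
  implied by published degrees of freedom that fall short of the sample
  size. No sphericity correction is applied by default;
  Greenhouse–Geisser is available by flag. Trials with a missing
  reactivation report are excluded from condition analyses (no level can
  be assigned to them).

Effect-SS values that vanish to rounding error (constant input) are
reported as $F = 0$, $p = 1$ rather than 0/0. `apply_exclusions()`
implements the low-trial rule: a participant with any analyzed cell below
`min_trials = 10` is flagged for exclusion.

## The reinstatement decoder

* **Temporal preprocessing.** Per run: a discrete-cosine drift basis
  (periods > 128 s; the conventional high-pass default, configurable) is
  regressed out, then every voxel is z-scored within the run. Constant
  voxels are zeroed and flagged. Standardization is per run for encoding
  data too — the alternative (session-wide) is not implemented because the
  decoder only ever sees run-filtered data.
* **Training-scan selection.** For every scene/face localizer block, the
  volumes 3 TRs and 6 TRs after onset (the 4th and 7th scans of a 12 s
  block at TR = 2 s) are taken, riding the hemodynamic plateau: 40 scans
  (20 per class) for the 10+10 block design.
* **Feature selection.** The `k = 250` voxels with the largest two-class
  ANOVA-F, computed on training folds only; exact ties break by ascending
  voxel index for determinism.
* **Classifier.** L2-regularized linear logistic regression (glmnet,
  `alpha = 0`, fixed penalty `lambda = 1/n_train` — the unit-strength
  convention — convergence threshold 1e-6, deterministic).
* **Cross-validation.** 20 chunks of 2 scans; each chunk pairs one scene
  and one face scan from different blocks, assigned deterministically from
  the seed, so every held-out fold is class-balanced and chunks never
  straddle a block. The published description ("chunks contain scans from
  different localizer blocks") admits several constructions; the balanced
  pairing is the one that satisfies the constraint while keeping fold
  accuracies well-defined at 0/0.5/1.
* **Permutation inference.** Labels are shuffled at chunk level (each
  chunk's scene/face assignment is re-drawn), the *entire* CV — feature
  selection included — is re-run per permutation, and
  $p = \#\{\text{null} \ge \text{observed}\}/B$, the literal proportion
  definition; a `plus_one` variant gives the $(\cdot+1)/(B+1)$ estimator.
* **Event decoding.** The final model is refit on all 40 scans (standard
  practice; a fold-ensemble alternative was considered and rejected as
  needlessly path-dependent) and applied to the volume 3 TRs after each
  AC-encoding onset, yielding a per-trial scene probability that is then
  analyzed with the same 2 × 3 ANOVA machinery as the memory score.

No-leakage is enforced structurally (per-fold feature selection) and
tested behaviorally: on pure noise, a deliberately leaky variant (features
chosen once on all scans) inflates accuracy while the package's route
stays at chance.

## The synthetic generator

`synthetic_config()` encodes the study-shaped design: 120 triads (half
congruent by assignment), 60 lures, a 17.1% lure false-alarm rate with
pseudo-point split proportional to 8.8/4.8/3.5, 10 localizer blocks per
category over 2 runs, 12 s blocks at TR = 2 s, 500 in-mask voxels of which
250 carry class signal.

Behavior follows a latent ordered-threshold model: association strength
$s = \mu + u_p + \beta_c\,[\text{congruent}] + \varepsilon_s$; the
reactivation report is a noisy 3-level threshold readout of $s$; memory
strength $m = s + \beta_r r + \beta_{cr} r\,[\text{congruent}] +
\varepsilon_m$; and every observed response (confidences, rater scores,
2AFC side) is a thresholded or logistic readout of $m$. Because the report
$r$ and the memory strength share the latent $s$, binning by the report
induces a *true* association even with $\beta_r = 0$ — a deliberate
property (self-reports are readouts, not randomized treatments). Generator
null-calibration tests therefore shrink the shared trial-level variance
when a pure null is needed.

Effect-size defaults were calibrated once so the six cell means
qualitatively reproduce the canonical congruency × reactivation ordering —
congruent above incongruent at every level, means rising with reactivation,
the rise concentrated in the congruent bin — and then frozen; no attempt is
made to match published cell means numerically.

Patterns use a fixed random spatial pattern per category on the signal
voxels, a block boxcar shifted by 2 volumes standing in for the
hemodynamic delay (the analysis reads fixed-offset volumes, so a shift is
sufficient and keeps the generator analytically transparent), low-frequency
drift, and unit white noise; `snr` scales the pattern amplitude. One
design deviation: the inter-block interval defaults to 8 s rather than the
acquisition's 7 s so that block onsets stay TR-aligned, which the
selection arithmetic assumes. AC-encoding trials embed the *scene* pattern
at amplitude $\gamma (r-1)/2$ plus trial noise at the read-out volumes, so
$\gamma = 0$ is an exact null and recovery of the graded amplitude is the
pipeline-level figure of merit.

Not emulated: physiological/motion noise, spatial autocorrelation,
anatomical mask structure, HRF shape variability. Passing tests therefore
demonstrate the correctness and calibration of the *analysis*, not claims
about real scanner data.

## Problem sizes used by the test suite

Stochastic calibration claims are asserted at sizes chosen to keep the
suite deterministic-fast while retaining statistical force: decoder chance
behavior at the full study scale over 200 seeded replicates;
permutation-p uniformity at a reduced scale (60 voxels, 60 permutations,
40 replicates; Kolmogorov–Smirnov at α = 0.01); behavioral effect recovery
over 100 study-scale replicates; reinstatement monotonicity over 3 seeded
pipeline runs and its γ = 0 null over 20. The generator's own defaults are
never changed by tests.

## Known limitations

* The chance-level conditionals borrow the studied-trial contingency for
  false alarms; if genuine guessing behaves differently after a false
  alarm, $C$ is an approximation.
* The permutation p-value at $B$ permutations has resolution $1/B$ and the
  plain proportion estimator can return exactly 0; use `plus_one` when a
  strictly positive p is required.
* The decoder assumes TR-aligned onsets and a fixed read-out offset; no
  HRF deconvolution or beta-series estimation is performed.
* `rm_anova_2x3()` is specialized to the 2 × 3 within-subject design; it
  is not a general ANOVA engine.
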