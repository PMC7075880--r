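# reinstater

Behavioral scoring and scene-reinstatement decoding for AB–AC
memory-integration experiments.

## The problem

In the associative-inference (AB–AC) paradigm, participants learn a
pseudoword–scene pair (A–B) and later a pseudoword–object pair (A–C), so the
scene and object are linked only indirectly through the shared cue. Studies
of memory integration then ask two questions:

1. **Behavior.** How well is the indirect B–C association remembered, and
   how does that depend on the rated *congruency* of the scene–object pair
   and on the participant's reported *reactivation* of the scene while
   learning A–C?
2. **Brain.** Does scene-selective cortex actually reinstate the scene
   during A–C learning — and does a pattern classifier's scene probability
   track the behavioral reactivation report?

`reinstater` implements the full analysis path for both questions as an R
package, together with a synthetic-data generator that emulates the study
design, so every stage can be exercised and tested without access to
scanner data.

## What's inside

**Composite memory score (0–9).** A three-part memory test — 6-point
confidence-rated object recognition, free associative recall scored by two
raters, and a confidence-rated 2AFC associative recognition — is collapsed
into a single score:

    score = item points (0–3) + 3 × mean(rater1, rater2) + associative points (0–3)

with item recognition gating the rest (a missed object scores 0 overall).
`score_trials()` implements the rules; an exhaustive enumeration in the
test suite pins every response combination against an independent oracle.

**Analytic guessing chance level.** A memory-free responder only earns
points via a false alarm (FA) at item recognition followed by a lucky 2AFC
guess. Its expected score is

    C = p(FA) · Σₓ p(x | FA) · ( x + ½ · Σ_y p(y | FA, x) · y )

where x ∈ {1,2,3} are item points implied by the FA confidence and
y ∈ {0..3} the associative points given a chance response (recall is
assumed to contribute nothing). `chance_level_eq1()` evaluates the formula,
`estimate_guessing_profile()` estimates its ingredients from lure
responses, and `monte_carlo_guessing_chance()` is an independent simulation
oracle.

**Condition statistics.** Congruency ratings (1–5) are binned
(1–2 incongruent / 3 excluded / 4–5 congruent), crossed with the 3-level
reactivation report, and analyzed with one-sample t-tests against the
chance level plus a 2×3 repeated-measures ANOVA with partial η²
(`condition_summary()`, `one_sample_test()`, `rm_anova_2x3()`).

**Scene-vs-face decoder.** Localizer runs are high-pass filtered
(discrete-cosine basis) and voxelwise z-scored per run; training volumes
are read 3 TRs and 6 TRs after each block onset (40 scans for the
study-shaped 10+10 block design); the 250 voxels with the largest
between-class ANOVA-F are selected *within each cross-validation fold*; an
L2-regularized linear logistic model is evaluated by leave-one-chunk-out
CV over 20 class-balanced chunks and tested against a chunk-level label
permutation null; the refit model then yields a per-trial scene
probability for AC-encoding events read 3 TRs after onset
(`train_reinstatement_decoder()`, `decode_events()`).

**Synthetic study generator.** `synthetic_config()` +
`simulate_behavior()` / `simulate_localizer()` / `simulate_ac_encoding()`
generate behavioral tables and NIfTI-compatible voxel patterns with known
ground truth (latent memory strength, signal voxels, reinstatement
amplitudes), at the study's design sizes by default.

## Worked example

```r
library(reinstater)
library(dplyr)

cfg <- synthetic_config(seed = 42)       # study-shaped defaults
beh <- simulate_behavior(cfg)

scored <- beh$test |>
  filter(!is_lure) |>
  score_trials() |>
  attach_conditions(beh$ratings, beh$encoding)

# per-participant guessing chance level from the lure responses
profiles <- estimate_guessing_profiles(beh$test, scored)
group_chance_level(profiles)
#> [1] 0.4556411

cells <- condition_summary(scored)
congruent_means <- cells |>
  filter(congruency_bin == "congruent") |>
  group_by(participant_id) |> summarise(m = mean(mean, na.rm = TRUE))
one_sample_test(congruent_means$m, null = group_chance_level(profiles))
#> # A tibble: 1 × 8
#>       n  mean    sd     t    df  p_value cohens_d d_vs_zero
#>   <int> <dbl> <dbl> <dbl> <int>    <dbl>    <dbl>     <dbl>
#> 1    25  4.61  1.03  20.2    24 1.38e-16     4.05      4.49

rm_anova_2x3(cells)
#> 2x3 repeated-measures ANOVA (25 complete cases)
#>   congruency   F(1, 24) = 966.88, p = 6.645e-21, partial eta^2 = 0.98
#>   reactivation F(2, 48) = 237.41, p = 1.287e-25, partial eta^2 = 0.91
#>   interaction  F(2, 48) =  34.50, p = 5.169e-10, partial eta^2 = 0.59
```

The tibble reports the one-sample t-test of the per-participant congruent
cell means against the estimated guessing chance level (two effect sizes:
`cohens_d` = (M − C)/SD and `d_vs_zero` = M/SD). The ANOVA block shows
that the generator's injected congruency and reactivation effects — and
their interaction — are recovered from the scored synthetic data.

Decoding side:

```r
loc <- simulate_localizer(cfg)
pre <- temporal_preprocess(loc$dataset)
dec <- train_reinstatement_decoder(pre, decoder_spec(n_permutations = 1000, seed = 42))
glance(dec)
#> # A tibble: 1 × 5
#>   cv_accuracy permutation_p n_permutations n_scans k_features
#>         <dbl>         <dbl>          <int>   <int>      <int>
#> 1           1             0           1000      40        250

truth1 <- filter(beh$truth, participant_id == "p01")
ac <- temporal_preprocess(simulate_ac_encoding(cfg, truth1, loc$truth))
decode_events(dec, ac) |>
  left_join(truth1, by = "triad_id") |>
  group_by(r) |> summarise(scene_prob = mean(scene_prob))
#> # A tibble: 3 × 2
#>       r scene_prob
#>   <int>      <dbl>
#> 1     1      0.394
#> 2     2      0.888
#> 3     3      0.995
```

Decoded scene probability rises with the latent reactivation level `r`,
the pattern-level analog of the behavioral reactivation effect.

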