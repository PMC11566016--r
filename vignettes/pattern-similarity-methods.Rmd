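---
title: "Measuring sleep-dependent neural differentiation with pattern similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sleep-dependent neural differentiation with pattern similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a learned association (scene A predicts scene B) is violated — A is
suddenly followed by novel faces X and Y instead of B — the hippocampus can
adapt by *differentiating* the representations of A and B: B relinquishes
the features it shared with A and acquires new ones, reducing future
interference. `remdiff` implements the complete measurement pipeline for
this phenomenon, including the hypothesis that the representational change
is consummated during REM sleep rather than wake or NREM sleep alone.

The pipeline has five stages, each a package module:

1. **Design** (`generate_design`, `generate_post_session`,
   `validate_design`): a statistical-learning stream of 96 A–B scene pairs
   over six runs (16 per run, half *violation*, half *nonviolation*). Each
   run opens with a snapshot phase (every A and B shown once, a pair's B
   never directly after its own A) and continues with the learning phase in
   which each violation pair follows the event template
   AB‑AB‑AB‑AX‑B‑AY‑B and each nonviolation pair AB‑AB‑AB‑B‑B, interleaved
   so that successive events of the same pair are separated by 2–20 other
   pair events. Trials last 1 s with a 2 s inter-stimulus interval. A
   second session re-presents all B scenes, then all X/Y faces, once each.
2. **Snapshots** (`preprocess_run`, `extract_pattern`,
   `build_snapshot_matrices`): after discarding 9 leading and 5 trailing
   volumes, each voxel is high-pass filtered (discrete-cosine regression,
   1/128 Hz cutoff) and z-scored; an item's *snapshot* is the single masked
   volume nearest the hemodynamic peak, 4.5 s after stimulus onset (exactly
   3 volumes at TR = 1.5 s).
3. **Pattern similarity** (`pair_similarity`, `differentiation_score`,
   `item_specificity_z`, `b_prediction_scores`, `coupling_correlation`,
   `bxy_integration_scores`): pairmate similarity is the Pearson
   correlation between the pre-learning snapshot of A and the post-learning
   snapshot of B, Fisher z-transformed. The *neural differentiation score*
   is the violation-minus-nonviolation difference of condition means
   (negative = more violation-related differentiation). Item specificity is
   assessed by re-pairing B items within condition 1,000 times and
   z-scoring the observed score against that null. *B prediction* is the
   mean Fisher-z correlation of the pre-learning B snapshot with the
   activity evoked by that pair's X and Y violation events; its across-pair
   correlation with pairmate similarity quantifies prediction–
   differentiation coupling. The B–X–Y control correlates post-learning B
   with post-learning face snapshots to rule out face-noise explanations.
4. **Group statistics** (`planned_contrast`, `one_sample_test`,
   `two_group_compare`, `bonferroni_alpha`, `correlate`): the primary test
   is a pooled-variance planned contrast with weights REM −1, NREM 0.5,
   Wake 0.5 and error df `N − k`; follow-ups are directional one-sample t
   tests; two-group sleep comparisons dispatch between Student, Welch and
   Wilcoxon tests on assumption checks; families are Bonferroni-corrected.
5. **Sleep metrics** (`score_architecture`, `classify_nap`,
   `spindle_density`): 30-s-epoch hypnograms yield TIB, TST, efficiency,
   per-stage minutes and percentages, WASO, nap classification, and
   spindle densities per stage.

Because the real fMRI/EEG data are not bundled, a first-class synthetic
generator (`simulate_subject`, `simulate_cohort`, `render_bold`,
`simulate_hypnogram`) produces subjects with *planted, known* effects so
every stage is testable end to end.

## The generative model

For each pair the generator draws an orthonormal latent basis and splits it
into mutually orthogonal blocks: shared features (size $k_s$), A-unique and
B-unique features ($k_u$ each), novel features ($k_n$), and X/Y face
features ($k_u$ each, violation pairs only). Each block contributes a random
direction in its subspace with fixed norm $a\sqrt{k}$ (amplitude $a$ =
`signal_amp`). Patterns are sums of components plus white measurement noise
of sd `noise_sd`:

- pre-learning A: shared + A-unique
- pre-learning B: shared + B-unique
- post-learning B, violation: $(1-d_p)\,$shared + B-unique + $d_p\,$novel
- post-learning B, nonviolation: $(1+\delta_{int})\,$shared + B-unique
- violation-evoked: face + $\pi_p\,$(shared + B-unique)
- post-learning face: face

Here $\pi_p \in [0,1]$ is the pair's B-reactivation weight, drawn from a
truncated normal (`pred_mean`, `pred_sd`), and the realized differentiation
shift is $d_p = \mathrm{clip}(\delta_{diff} + \kappa(\pi_p -
\overline{\pi}), 0, 1)$. The linear $\kappa$ channel is the simplest
monotone stand-in for the weakening arm of the nonmonotonic plasticity
hypothesis: the more strongly B is reactivated during a violation, the more
its representation subsequently sheds shared features.

**Why fixed-norm feature weights?** With i.i.d. Gaussian weights the
component norms are chi-distributed and vary by ~50% across pairs at the
default block sizes. That heterogeneity both inflates pair-level similarity
variance and — because the shared-feature norm enters B-reactivation and
pairmate similarity with the same sign — induces a *positive* across-pair
correlation that partially masks the planted negative coupling, making
planted effect sizes uninterpretable. Drawing each component as a random
direction with fixed norm keeps the planted shifts homogeneous and the
coupling channel identifiable.

**Default study conditions.** Cohorts default to 23 subjects per group
(Wake, NREM, REM; 69 total). Wake and NREM plant no representational
change; REM plants $\delta_{diff} = 0.5$, $\delta_{int} = 0.2$ (the
integration channel reflects the observation that group differences can be
carried by *higher* nonviolation similarity with REM sleep) and $\kappa =
1$. All groups share `pred_mean = 0.35`, `pred_sd = 0.2`, since
reactivation occurs during learning, before the offline manipulation.
Defaults `n_vox = 500`, $k_s = 8$, $k_u = k_n = 6$, `signal_amp = 3`,
`noise_sd = 1` put pairmate correlations near 0.1 — the weak-signal regime
typical of hippocampal pattern-similarity measurements. The magnitudes of
$\delta_{diff}$, $\delta_{int}$ and $\kappa$ are package choices: the
phenomenon has no published effect size in similarity units.

One design realization is shared across a simulated cohort: the similarity
analyses are invariant to the per-participant re-randomization of item
assignments, so sharing the design does not couple subjects, while keeping
cohort simulation fast and exactly reproducible from the master seed. Every
random quantity flows from named integer seeds; subject seeds are derived
from the master seed by a fixed splitting rule.

## Numerical and procedural choices

- **Sequence interleaving** is a greedy randomized construction with
  deadlines: at each position a pair is eligible if its previous event lies
  at least `min_gap + 1` positions back, and a pair whose next event would
  otherwise overshoot `max_gap` (or run out of room before the end of the
  run) is placed immediately; dead ends trigger a fresh attempt, bounded at
  10,000 attempts per run (the error reports the bound). Observed attempt
  counts at the default geometry average ~1.4. "Distance between
  repetitions" is counted in pair events, not trials, because a pair event
  (AB) spans two trials.
- **Snapshot timing**: a single volume, no multi-TR averaging or GLM betas;
  the 0-based index is `round((onset + 4.5 − time_offset)/TR)` with
  *half-up* rounding, documented and tested. Onsets stay on the original
  acquisition timeline; the preprocessing discard is carried explicitly as
  `time_offset` so misalignment cannot happen silently. Violation-evoked
  patterns use the same 4.5-s rule as snapshots.
- **High-pass filtering** regresses each voxel on a discrete-cosine basis
  with frequencies below the cutoff, the standard drift model in
  neuroimaging software, since only the cutoff (1/128 Hz) is specified.
- **Degenerate correlations**: |r| = 1 can arise on noise-free toys; such
  values are clamped to ±(1 − 1e−12) with a warning before the Fisher
  transform. `fisher_z` itself rejects |r| ≥ 1. Zero-variance patterns
  raise errors naming the offending item; `preprocess_run` has a tolerant
  mode that zeroes constant voxels instead of failing.
- **Randomization null**: shuffles are uniform permutations of the B-to-
  pair assignment within each condition, identity permutation allowed; the
  null SD is the sample SD (n−1) of the 1,000 shuffled scores.
- **Effect sizes**: the d conventions are inferred from the full set of
  reported (t, d) pairs — contrasts use $d = 2t/\sqrt{df}$ and one-sample
  tests $d = t/\sqrt{n}$ — and reproduce every reported pair to within the
  rounding of the published t values.
- **Assumption checks** for the two-group dispatch are Shapiro–Wilk per
  group and median-centered Levene, both at α = 0.05; the source analyses
  name only the fallback tests, so the diagnostics are package choices. A
  zero-variance group is routed to the rank-sum branch.
- **Sleep scoring**: epochs are fixed at 30 s; sleep onset is the first
  non-wake epoch; WASO counts all wake from sleep onset to lights-on,
  including terminal wake; artifact epochs are excluded from
  spindle-density denominators. The wake-reassignment rule ("only short,
  fragmented sleep") is qualitative in the source, so it is operationalized
  as a consolidated-sleep bout shorter than `min_consolidated_sleep_min`
  (default 10 min) within the first 30 min — the threshold is an exposed
  parameter, not a reconstruction.

## What the validation suite shows — and what it cannot

The test suite validates the pipeline against its own ground truth at
specific problem sizes, chosen to keep the default run in minutes: null
calibration uses 500 zero-effect subjects at the full 96-pair design with
1,000 shuffles (item-specificity z: mean ≈ 0, sd ≈ 0.94); contrast size
uses 1,000 scaled-down cohorts (8 subjects per group, 8 pairs, 60 voxels;
empirical type-I ≈ 0.045 at nominal 0.05); parameter recovery uses 200 REM
subjects at the default conditions (sign recovery ≥ 99% for the
differentiation score and the prediction-differentiation coupling).

The generator emulates the *structure* of the study — pair templates,
snapshot phases, group sizes, planted differentiation/integration/coupling
channels, NREM-vs-REM hypnograms with spindles — but not everything about
real data: no spatial autocorrelation between voxels, no physiological or
motion artifacts, no inter-subject variability in effect magnitude, no
hemispheric or subfield structure, and Gaussian noise only. Passing tests
therefore demonstrate that the *estimators and inference procedures* are
correct and calibrated, not that real hippocampal data would show these
effects.

A structural note on the rendering round trip: after per-voxel z-scoring, a
run dominated by a single trial reduces each voxel to its sign, capping the
correlation between an extracted single-trial pattern and its ground truth
at $\sqrt{2/\pi} \approx 0.80$ regardless of noise. Faithful recovery
(r > 0.99) requires a run with many heterogeneous trials, whose variety
homogenizes per-voxel temporal variance; the round-trip check accordingly
renders the 96-item post-learning snapshot run at a widened 30-s stimulus
asynchrony so trials are isolated *and* numerous. Exact alignment of the
renderer and extractor (r = 1) is verified separately on the un-normalized
time series.

## Known limitations

- The snapshot is the single nearest volume; whether peak averaging or
  interpolation would be preferable is untested here.
- No voxel selection is applied within an ROI before correlation.
- The integration channel acts only on the nonviolation condition and the
  differentiation channel only on the violation condition; real
  representational change is unlikely to be so cleanly separable.
- `analyze_cohort` assumes one subject per row of the design; longitudinal
  or repeated-cohort structures are out of scope.

## A minimal end-to-end run

```{r, eval = FALSE}
library(remdiff)

cohort <- simulate_cohort(n_per_group = 4, seed = 7,
                          n_vox = 120, k_s = 6, k_u = 4, k_n = 4)
metrics <- analyze_cohort(cohort, n_shuffles = 500, seed = 8)
report <- cohort_report(metrics)
report[report$test == "contrast_REM_vs_noREM" &
         report$measure == "diff_score", ]
```
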