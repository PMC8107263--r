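---
title: "Evaluating continuous tumor-cellularity estimates: concordance, agreement, and a gameable metric"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating continuous tumor-cellularity estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkeval)
```

## The evaluation problem

Tumor cellularity (TC) is the fraction of a tumor-bed region occupied by
invasive or in-situ tumor cells. After neoadjuvant treatment, TC is a key
input to residual cancer burden assessment, and pathologists estimate it
visually on H&E-stained slides — a task with substantial inter-reader
variability. Image-analysis challenges for automated TC estimation score
algorithms that emit one continuous TC estimate per image patch against
pathologist reference scores, per patch, across hundreds of patches drawn
from a much smaller number of patients.

Three properties make this evaluation statistically interesting:

1. **Calibration cannot be assumed.** Two pathologists can rank patches
   almost identically while disagreeing systematically on the absolute
   percentages. A fair primary endpoint must compare *rankings*, not
   values.
2. **Scores are heavily tied.** Pathologists report TC on a coarse
   percentage grid and assign exact 0 to tumor-free patches, so a large
   share of patch pairs is tied in the reference. Tie handling is not a
   corner case here; it decides the metric.
3. **Patches are clustered.** All patches from one patient are correlated;
   resampling patches as if independent would understate uncertainty.

`pkeval` implements the complete evaluation stack for this setting: pair
counting, the PK concordance metric, Kendall's tau-b, ICC(2,1),
patient-clustered bootstrap intervals, a submission-validation and
leaderboard harness, and a synthetic challenge generator that makes every
component testable without any image data.

## Pair counts: the common currency

For score vectors $r$ (reference) and $a$ (algorithm) over $n$ patches,
every unordered pair falls into exactly one of five classes:

* $C$ — concordant: $r$ and $a$ order the pair the same way, strictly;
* $D$ — discordant: strictly opposite orders;
* $T_A$ — tied in the algorithm only;
* $T_R$ — tied in the reference only;
* $T_B$ — tied in both.

`count_pairs()` computes all five in $O(n \log n)$ (merge-sort inversion
counting, the same scheme compiled Kendall-tau implementations use) and is
tested to agree *exactly* with exhaustive enumeration. Two conventions are
worth making explicit because published formulas rarely do:

* **Pairs tied in both vectors are their own class.** $T_B$ is excluded
  from $T_A$ and $T_R$. With this convention tau-b computed from the five
  counts is algebraically the textbook tie-corrected tau-b, and a constant
  submission gets PK exactly 0.5 (below) — both of which fail if $T_B$ is
  double-counted into the one-sided tallies.
* **Ties are exact floating-point equality.** Submissions arrive as
  decimal text; an epsilon would silently reclassify pairs and would itself
  be a surface for gaming (an algorithm could engineer near-ties).

## The prediction probability PK

$$P_K \;=\; \frac{C + \tfrac{1}{2}T_A}{C + D + T_A}$$

PK is the probability that the algorithm orders a randomly chosen
*reference-distinguished* pair correctly, with half credit for algorithm
ties. Pairs the reference cannot order ($T_R$, $T_B$) carry no information
about ranking skill and are excluded. Useful identities, all tested
exactly:

* a constant submission scores exactly $0.5$ ($C = D = 0$);
* negating the algorithm swaps $C \leftrightarrow D$, mapping
  $P_K \mapsto 1 - P_K$;
* any strictly increasing transform of either vector leaves $P_K$
  unchanged — this is why miscalibration is invisible to it;
* for a binary reference, $P_K$ *is* the trapezoidal (Mann–Whitney) AUC;
  `trapezoidal_auc()` computes the AUC independently from mid-ranks and the
  two agree to $10^{-12}$.

With a multi-rater reference the convention is to compute PK against each
rater separately and average (`average_metric_over_raters()`,
`metric_avg_pk()`).

## Why not Kendall's tau-b: the binning exploit

$$\tau_B \;=\; \frac{C - D}{\sqrt{(C+D+T_A)(C+D+T_R)}}$$

tau-b looks like the obvious concordance endpoint, but it rewards a
specific manipulation: **bin your continuous outputs**. Binning converts
hard-to-order pairs (nearby scores) into ties; those pairs are
disproportionately discordant, so $D$ collapses much faster than $C$. The
numerator $C - D$ grows while the $T_A$ term only enters under a square
root, so tau-b *increases*. PK charges the same maneuver differently: the
lost pairs leave its denominator $C + D + T_A$ almost unchanged (ties stay
in it at half credit), so PK *decreases*.

`run_gaming_experiment()` reproduces this directly: at the package's
default generator settings with algorithm noise SD 0.1, binning to 10
equal-width bins raises mean tau-b (about $0.82 \to 0.85$) while lowering
mean PK (about $0.93 \to 0.92$), with the discordant count shrinking by
roughly $1.8\times$ against $1.06\times$ for the concordant count. The
direction holds in essentially every seeded repetition; the acceptance
suite demands 19 of 20.

```{r gaming, eval = FALSE}
run_gaming_experiment(synthetic_config(),
                      algorithm_profile("cont", noise_sd = 0.1),
                      bin_grid = 10, n_reps = 200, seed = 1)
```

## ICC(2,1): the calibration-sensitive counterpoint

Mean squared error is the loss most TC regressors train on, so the harness
also reports the two-way random-effects, absolute-agreement, single-rater
intraclass correlation (Shrout–Fleiss ICC(2,1)):

$$ICC(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

computed from the subjects-by-raters two-way ANOVA mean squares
(`anova_mean_squares()`, `icc_2_1()`). Where PK ignores calibration
entirely, ICC(2,1) charges it: adding a constant offset to one column
strictly lowers ICC while PK stays at 1. Negative values are returned as
computed — real leaderboards do print them for degenerate submissions.
Algorithm-vs-reference ICC uses a two-column (algorithm, rater) matrix per
rater, averaged over raters, mirroring the PK averaging. Missing cells are
rejected, never imputed: the harness guarantees complete score tables, and
silent imputation would change the mean squares.

## Uncertainty: the patient-clustered percentile bootstrap

All confidence intervals come from one mechanism
(`cluster_bootstrap()`): resample *patients* with replacement (same number
of patients; a patient drawn twice contributes all patches twice),
re-evaluate the metric per replicate — for averaged metrics, the per-rater
values are recomputed and re-averaged inside each replicate — and take
percentile quantiles of the replicate distribution. The point estimate is
always computed on the full, unresampled data. Defaults: 1000 replicates,
95% intervals.

Design choices made where the design was genuinely open:

* **Resampling unit.** Patients, not slides or patches: patches within a
  patient are correlated, and a patient can contribute several slides. The
  slide-level alternative would be defensible when each patient has one
  slide; the containers carry both ids so either is computable.
* **Undefined replicates.** A resample can make the metric undefined
  (e.g. every drawn patient has constant reference scores). Such replicates
  are dropped, counted in `n_dropped`, and warned about rather than
  aborting a 1000-replicate run; the count keeps the decision auditable.
  Only if *every* replicate is undefined does the call error.
* **Seeding.** Replicate $r$ uses a stream derived deterministically from
  `(root seed, r)`, so the full replicate vector is reproducible and
  independent of evaluation order.
* **Significance between algorithms.** `paired_difference()` applies the
  *same* resampled patient set to both algorithms and takes the percentile
  CI of the difference; the difference is significant iff the CI excludes
  zero. The leaderboard's `significance_frontier()` walks each entry down
  the ranking to the first significantly different competitor. A paired
  percentile bootstrap is used because it is the only resampling machinery
  the evaluation otherwise needs — no separate test family, no extra
  assumptions. No multiplicity correction is applied across the board;
  frontiers are reported as pairwise statements.

The acceptance suite checks calibration empirically: over 200 seeded
synthetic trials at the default configuration, the 95% intervals cover the
generator's true interrater PK (obtained by large-sample Monte Carlo) at an
observed rate around 0.91–0.94, within the loose [0.90, 0.99] band
appropriate for a percentile interval on ~18 clusters.

## The synthetic challenge generator

`generate_reference()` emulates the statistical shape of pathologist TC
reference data, not its imagery:

* **Hierarchy.** Default 18 patients × 2 slides × 31 patches ≈ 1100
  patches — the scale of a real challenge test set — so the clustered
  bootstrap has realistic cluster counts.
* **Zero inflation.** A patch is tumor-free (latent TC exactly 0) with
  probability 0.25, mirroring the prominent spike at 0% in real reference
  histograms.
* **Continuous spread.** Non-zero latent TC is drawn from a two-mode beta
  mixture (weight 0.45 on Beta(1.2, 3.5), rest Beta(5, 1.8)): broad
  low-cellularity mass plus a concentrated high-cellularity mode. This
  targets the qualitative shape of real score histograms; it is a chosen
  default, not a fit.
* **Rater discretization.** Raters report on a 0.05 grid (pathologists
  score in coarse percentage steps). The grid is a visible knob
  (`grid_step`) because real reporting granularity varies.
* **Second rater.** Additive Gaussian noise (`rater_noise_sd`, default
  0.12) before clamping and re-gridding, with exact zeros preserved with
  probability 0.9 (`zero_fidelity`) — a second reader usually, but not
  always, also calls a tumor-free patch 0. The 0.12 default was set by
  Monte-Carlo calibration so the two simulated raters' average interrater
  PK is ≈ 0.926, matching the operating range of experienced pathologists
  on this task; the calibration sweep is itself a test.
* **Algorithms.** `algorithm_profile()` composes a strictly increasing
  miscalibration (identity, power, or affine), additive noise, clamping to
  [0, 1], and optional equal-width binning to midpoints. Midpoints are an
  arbitrary-but-sensible within-bin representative: any constant gives
  identical rank metrics, midpoints keep MSE and ICC meaningful.
* **Latent truth** rides alongside the generated reference for
  parameter-recovery tests and simulated algorithms; it is never written
  into the reference CSV.

What the generator does **not** emulate: image content and
histology-specific failure modes (adenosis mistaken for tumor, lobular
carcinoma underestimation), reader drift over time, and any dependence of
rater noise on the latent value other than clamping at the boundaries.
Passing tests therefore demonstrate that the *evaluation machinery* is
correct and calibrated on data with realistic tie structure, clustering,
and noise — not that any algorithm performs well on real slides.

## Patch-level error analysis

`patch_mse()` aggregates, per patch, the squared difference between each
rater and each algorithm: mean over algorithms, then mean over raters,
alongside the mean and SD of the algorithm scores. "Mean over algorithms"
is the operative choice: with ~100 algorithms a *sum* of squared errors
would be orders of magnitude above the values real error tables print,
while the mean reproduces them. When both raters give the same score $s$,
the patch MSE decomposes exactly as
$(\bar{a} - s)^2 + \operatorname{Var}_{pop}(a)$ — squared consensus bias
plus algorithm spread — which the tests verify to $10^{-12}$, and which is
consistent (within caption rounding) with published worst-patch examples
such as a zero-TC patch with mean algorithm score $0.53 \pm 0.28$ and
MSE 0.364.

## Numerical conventions and degenerate inputs

* Scores are fractions in [0, 1] internally; percent is handled only at
  the CSV boundary (`parse_reference(unit = "percent")` or
  `<rater>.percent` columns). Out-of-range submission scores are
  validation failures, never clamped: TC is a fraction by definition.
* Undefined metrics (constant reference: $C+D+T_A = 0$; zero ICC
  denominator) raise a dedicated `pkeval_undefined_metric` condition,
  distinct from input-validation errors, so the bootstrap can drop exactly
  those replicates and nothing else.
* Leaderboard ties share the smaller (competition) rank with the next rank
  skipped; display order among ties falls back to `entry_id` so output is
  deterministic.
* Pair-count fields are returned as doubles holding exact integers: counts
  grow as $n^2/2$ and would overflow 32-bit integers near $n = 93{,}000$.

## Problem sizes used by the shipped tests

The test suite exercises every component at sizes chosen to make the
statistical assertions sharp while keeping a full run around two to three
minutes: pair-count oracle equivalence on 1000 random vectors up to
$n = 200$; ICC against an independent ANOVA oracle on 100 random matrices;
bootstrap coverage over 200 seeded trials of the default 1116-patch
configuration at 300 replicates each; the binning experiment as 20
repetitions of 200 simulated challenges; and leaderboard rank recovery
over 50 simulated four-algorithm challenges. `scripts/acceptance.R` re-runs
the same computations from scratch and writes the headline numbers as
JSON.

## Known limitations

* The percentile bootstrap slightly undercovers with few clusters; with
  ~18 patients, observed coverage sits near 0.91–0.94 rather than 0.95.
  BCa or studentized intervals are deliberately out of scope.
* The significance frontier makes no multiplicity adjustment.
* The generator's rater-noise model is homoscedastic apart from clamping;
  real reader disagreement is larger mid-range than at 0 or 100% TC for
  reasons beyond clamping.
* ICC confidence intervals use the same patient bootstrap as PK rather
  than F-distribution theory; the two approaches need not coincide on
  small samples.
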