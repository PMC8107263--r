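# pkeval — concordance-based evaluation of continuous tumor-cellularity estimates

Tumor cellularity (TC) — the fraction of a tumor bed occupied by invasive
or in-situ tumor cells — is scored by pathologists on breast-cancer
resection slides after neoadjuvant treatment, and a growing family of
image-analysis algorithms tries to score it automatically, one continuous
estimate per 512×512 image patch. Evaluating those algorithms fairly is
harder than it looks: pathologists are not calibrated to each other, their
scores are heavily tied (coarse percentage grids, exact zeros for
tumor-free patches), and patches cluster within patients.

`pkeval` is the complete evaluation stack for this setting, aimed at
challenge organizers and method developers who need to score, rank, and
compare continuous-estimate algorithms against a multi-rater reference:

* **Tie-aware pair counting** (`count_pairs`): every pair of patches is
  concordant (C), discordant (D), tied only in the algorithm (TA), tied
  only in the reference (TR), or tied in both (TB); O(n log n), exactly
  equal to exhaustive enumeration.
* **Prediction probability** (`prediction_probability`), the primary
  ranking endpoint:

  ```
  PK = (C + TA/2) / (C + D + TA)
  ```

  the probability of ordering a random reference-distinguished pair
  correctly; calibration-free, equal to the trapezoidal AUC for binary
  references, and — unlike Kendall's tau-b — not gameable by binning
  outputs.
* **Kendall's tau-b** (`kendall_tau_b`), `(C − D)/√((C+D+TA)(C+D+TR))`,
  with `run_gaming_experiment()` demonstrating the tie-inflation exploit
  that disqualifies it as a challenge endpoint.
* **ICC(2,1)** (`icc_2_1`), the two-way random-effects absolute-agreement
  intraclass correlation — the calibration-sensitive secondary endpoint.
* **Patient-clustered percentile bootstrap** (`cluster_bootstrap`,
  `paired_difference`): resamples patients, not patches; powers all CIs
  and the leaderboard significance frontier.
* **Challenge harness**: reference/submission CSV I/O, non-destructive
  submission validation (`validate_submission`), scoring
  (`score_submission`), competition-ranked leaderboards
  (`build_leaderboard`, `significance_frontier`), and patch-level MSE
  analysis (`patch_mse`).
* **Synthetic challenge generator** (`synthetic_config`,
  `generate_reference`, `generate_algorithm`,
  `run_challenge_simulation`): seeded, zero-inflated, grid-discretized
  two-rater references plus configurable algorithm profiles (noise,
  monotone miscalibration, deliberate binning), so the whole stack is
  testable with no external data.

## Worked example: a simulated three-algorithm challenge

```r
library(pkeval)

cfg <- synthetic_config(n_patients = 12, slides_per_patient = 1,
                        patches_per_slide = 30)
roster <- list(algorithm_profile("deepcell", noise_sd = 0.05),
               algorithm_profile("quicknet", noise_sd = 0.12),
               algorithm_profile("binny",    noise_sd = 0.12, n_bins = 10))
sim <- run_challenge_simulation(cfg, roster, n_boot = 1000, seed = 7)
sim$leaderboard
```

```
Leaderboard (sorted by average PK)
 rank     team entry_id avg_pk pk_ci_low pk_ci_high avg_icc icc_ci_low
    1 deepcell deepcell  0.941     0.936      0.947   0.967      0.963
    2 quicknet quicknet  0.894     0.880      0.908   0.928      0.911
    3    binny    binny  0.885     0.872      0.897   0.923      0.910
 icc_ci_high pk_path1 pk_path2
       0.971    0.970    0.912
       0.943    0.912    0.875
       0.935    0.902    0.868
```

Each row is one algorithm: `avg_pk` is its prediction probability against
each of the two simulated pathologists, averaged (per-rater values in
`pk_path1`/`pk_path2`), with a 95% patient-clustered percentile bootstrap
CI; `avg_icc` is the analogous averaged ICC(2,1). The low-noise algorithm
wins; note `binny` — the same algorithm as `quicknet` but with its outputs
binned to 10 levels — *loses* PK relative to its continuous twin, exactly
the property that makes PK the right endpoint.

```r
sim$frontier
#>   deepcell   quicknet      binny
#> "quicknet"         NA         NA
```

The frontier says the rank-1 entry is statistically separated (paired
bootstrap difference, α = 0.05) from `quicknet` and everything below it;
the bottom two entries are not separable from anything below them.

```r
head(as.data.frame(sim$patch_errors), 3)
#>     patch_id        mse avg_score   sd_score path1 path2
#> 1 patch00036 0.08036018 0.3269429 0.06931277  0.45   0.7
#> 2 patch00038 0.07201003 0.5304744 0.07004757  0.50   0.9
#> 3 patch00115 0.07118623 0.7630573 0.08828079  0.75   0.4
```

The patch-error table ranks patches by how badly the whole algorithm field
missed them (mean squared error against each rater, averaged over raters)
— the top rows here are patches where the two raters themselves disagree.

The same operations are available from a shell via the thin CLI at
`inst/cli/pkeval` (subcommands `validate`, `score`, `leaderboard`,
`patch-errors`, `simulate`, `gaming`).

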