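# vergeflow

Activity-flow mapping of binocular convergence fMRI at the cortical-parcel
level, with a fully synthetic, ground-truth-known test bed.

## The problem

Convergent eye movements (rotating both eyes inward to fixate near targets)
engage a small, well-replicated set of cortical regions — bilateral primary
visual cortex (V1), frontal eye field (FEF), supplementary/cingulate eye
field (SCEF), and anterior intraparietal area (AIP) — here called the
*cortical circuitry of convergence* (CCC). `vergeflow` asks how much of the
CCC's task-evoked activation is explainable as *distributed* processing:
activity propagating in from the rest of cortex over resting-state
functional connections, rather than computed locally.

The core model generates a held-out region's activation as the
connectivity-weighted sum of all source regions' actual activations,

```
FlowAct_j = Σ_{i≠j} Act_i · FC_ij
```

with `Act_i` the GLM beta of source parcel *i*, and `FC_ij` the regularized
partial correlation (cross-validated graphical lasso) between parcels *i*
and *j* estimated from resting-state data. All eight CCC parcels are
excluded from every source set to avoid circularity. Downstream the package
quantifies:

- **accuracy** of generated vs. actual activations (Pearson r, R², MAE;
  per subject, then group-averaged),
- **vergence specificity** — after per-parcel min–max normalization, the
  ratio of mean VM-condition to mean VS-condition activation (null value 1),
- **distributed contribution** — 100 · generated/actual specificity, tested
  against a 50% null with max-T sign-flip permutation tests,
- **network contributions** — per-network means of the flow terms entering
  the CCC, with pairwise max-T ranking ("wins out of 11"), VM>VS flow
  contrasts, and general dominance analysis over all 4,095 subset
  regressions,
- **condensed submodels** — VIS-CON-DAN, VIS-CON, VIS-DAN, VIS-Only,
  DAN-Only, a V1-initiated model, and matched-size random subnetworks,
- **repeated-session reliability** — session-2 connectivity generating
  session-1 activations.

Because the analysis is designed for data that are not publicly deposited,
the package ships a first-class synthetic cohort generator: resting BOLD
drawn from a sparse ground-truth precision matrix (12 networks, planted
CCC↔VIS2/DAN pathways), block-design task runs with the study's exact
timing, 24 motion + 20 aCompCor confounds with displacement spikes, and CCC
activations planted as a calibrated mixture of distributed flow and local
signal — so the distributed mixing weight λ and the specificity ratio ρ are
known and recoverable.

## Worked example

Simulate a small cohort (60 parcels, 8 subjects, λ = 0.75, ρ = 1.5), run the
full experiment, and render the report:

```r
library(vergeflow)
cfg    <- sim_config_small(n_subjects = 8, seed = 3)
cohort <- simulate_cohort(cfg)
report <- run_experiment(cohort, n_perm = 1000, progress = TRUE)
writeLines(report_render(report))
```

which prints (elided):

```
# Activity-flow experiment report

- config hash: 3fd87857 | seed: 3 | n = 8 subjects | P = 60 | 1000 permutations

## Model accuracy (per subject, then group mean)
- whole model: r = 0.657, R^2 = -0.043, MAE = 0.241
- L CCC response profile: r = 0.860, R^2 = -0.030, MAE = 0.356
- R CCC response profile: r = 0.861, R^2 = 0.143, MAE = 0.305

## Vergence specificity (null value 1)
- L hemisphere (df = 6 after outlier removal): actual 1.421 (t = 12.50,
  p = 0.000999, significant), generated 1.055 (t = 2.60, p = 0.02597, significant)

## Distributed contribution (reference line: 50%)
- L hemisphere: 74.27% vs 50% (t(6) = 41.13, p = 0.008991, significant)
- R hemisphere: 75.42% vs 50% (t(6) = 36.76, p = 0.000999, significant)

## Network contributions (VM conditions)
- L hemisphere ranking: VIS2 (11/11 wins) > DAN (4/11 wins) > CON (0/11 wins)
...
## Condensed submodels (response-profile R^2)
- R: full 0.14; VIS-CON-DAN 0.12; VIS-CON -0.07; VIS-DAN 0.08; VIS-Only -0.13;
  DAN-Only -1.43; V1-initiated -1.69
```

Reading it: the actual specificity recovers the planted ρ = 1.5 (pulled
slightly toward 1 by GLM noise entering the min–max normalization); the
distributed contribution recovers the planted λ = 0.75 as ≈74–75% and is
significantly above the 50% null; the planted VIS2 > DAN pathway ordering is
recovered; and restricted submodels lose response-profile R² monotonically
down to the V1-initiated model, whose strongly negative R² means it is far
worse than predicting the mean — the expected signature of a misspecified
local model on distributed-truth data. Generated activations correlate
highly with the actual ones (profile r ≈ 0.86) while their R² is near zero
because graphical-lasso shrinkage scales the generated values down at a
150-frame resting scan — r is scale-free, R² is not.

Lower-level entry points: `make_parcellation()`, `make_ground_truth_fc()`,
`simulate_rest()`, `make_designs()`, `simulate_task_runs()` (generator);
`denoise()`, `canonical_hrf()`, `estimate_betas()`, `subject_activations()`
(preprocessing/GLM); `fc_glasso()`, `fc_pearson()`, `seed_fc_map()`
(connectivity); `actflow_generate()`, `network_partitioned_generate()`,
`secondary_circulation()`, `v1_initiated()` (flow engine); `accuracy()`,
`vergence_specificity()`, `mad_outliers()` (evaluation); `maxt_one_sample()`,
`maxt_paired()` (inference); `rank_networks()`, `dominance()`,
`compare_submodels()` (network statistics).

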