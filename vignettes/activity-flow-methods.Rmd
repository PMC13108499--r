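---
title: "Activity flow mapping of binocular convergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity flow mapping of binocular convergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vergeflow)
```

## The scientific question

Binocular convergence — the inward rotation of both eyes for near fixation —
is classically attributed to a small set of cortical regions: primary visual
cortex (V1), the frontal eye field (FEF), the supplementary and cingulate eye
field (SCEF), and the anterior intraparietal area (AIP), bilaterally. We call
these eight parcels the *cortical circuitry of convergence* (CCC). The
question this package operationalizes is whether the task-evoked activations
of the CCC arise primarily from local computation within those regions, or
from *distributed* processing: activity arriving from the rest of cortex
along resting-state functional connections.

## The model

### Activity flow

The core generative model says that a held-out region's task activation can
be reconstructed as the connectivity-weighted sum of every other region's
actual activation:

$$\mathrm{FlowAct}_j \;=\; \sum_{i \neq j} \mathrm{Act}_i \cdot \mathrm{FC}_{ij}$$

where $\mathrm{Act}_i$ is region $i$'s GLM beta for a condition and
$\mathrm{FC}_{ij}$ is the resting-state connectivity between $i$ and $j$.
`actflow_generate()` implements this sum and retains the individual *flow
terms* $\mathrm{Act}_i \cdot \mathrm{FC}_{ij}$, which by construction add up
exactly to the generated value — the basis for all network-level
decompositions. To avoid circularity, every result in the pipeline excludes
*all eight* CCC parcels from the source set (policy `exclude_ccc`), not just
the target; `target_only` is retained as a comparison variant, and
`exclude_ccc_radius` additionally masks all parcels within 10 mm of the
target to guard against spatial signal leakage from haemodynamic smoothness.

### Connectivity: regularized partial correlation

FC is estimated per subject with the graphical lasso: sparse inverse
covariance under an L1 penalty, converted to partial correlations
$-\Theta_{ij}/\sqrt{\Theta_{ii}\Theta_{jj}}$. Partial correlations remove
indirect (shared-source) dependence, which matters for a model that
interprets $\mathrm{FC}_{ij}$ as a direct propagation weight. The penalty is
chosen by cross-validation: parcel series are standardized (so the penalty is
scale-free), timepoints are split into *contiguous* blocks (shuffled folds
would leak autocorrelated samples between train and test), and the penalty
maximizing held-out Gaussian log-likelihood on a 20-point log-spaced grid is
refit on all frames. Five folds are the default; neither the fold count nor
the selection criterion is prescribed by the underlying method, so both are
configurable and recorded on the result. The solver is a block coordinate
descent written for this package (no graphical-lasso implementation is part
of the package's R dependency set), warm-started along the penalty path; a
test verifies its KKT stationarity conditions and that the fitted precision
maximizes the penalized likelihood against random perturbations.

### Activation estimation

Task betas come from a two-step procedure. First, each run is denoised:
per-parcel regression on an intercept, a linear trend, and 44 nuisance
columns (6 motion parameters with derivatives and quadratics = 24; 5
aCompCor components with derivatives and quadratics = 20). Resting runs
additionally drop their first five frames and receive one indicator
regressor per spike frame (frame-wise displacement strictly greater than
0.25 mm, computed as the root-sum-of-squares of the six motion-parameter
increments with rotations scaled to a 50-mm sphere). Task runs are denoised
with the 44 confounds only — spike regressors are a resting-state step here.
Second, a GLM with one canonical-HRF-convolved boxcar per condition (double
gamma: 6-s response, 16-s undershoot at 1/6 amplitude, 32-s support) plus
per-run intercept and drift is fit to the denoised series; the two VM runs
are concatenated with shared condition columns. The two-step procedure is
less efficient than a joint model, but it is the procedure the analysis is
defined around, and the accompanying tests confirm exact recovery of planted
betas in the noiseless limit and unbiasedness under noise. Because denoising
applies the same temporal projection to every parcel, it acts as a common
linear distortion of all betas — which is why the generative identity (below)
survives it exactly.

### Vergence specificity and distributed contribution

For each subject and hemisphere, the four CCC parcels' 8-condition profiles
are min–max normalized: the actual profile by its own minimum and maximum,
the generated profile by the *actual* minimum and maximum (values outside
[0, 1] are retained, not clamped — clamping would bias the generated index
toward the null). The vergence specificity index is
$\overline{VM}/\overline{VS}$, the ratio of the mean normalized activation
over the two vergence-motor conditions to the mean over the two
vergence-sensory conditions; 1 is the null value. The distributed
contribution is $100 \cdot \mathrm{spec}_{generated}/\mathrm{spec}_{actual}$,
tested against a 50% null. Subjects are screened with a median-absolute-
deviation rule at the conservative ±5 threshold, using the 1.4826
consistency constant (the cited rule's standard form; the threshold source
states only "±5 deviations"). A subject flagged in either the actual or the
generated index is removed from both, per hemisphere independently — which
is why the two hemispheres can end with different degrees of freedom.
Degenerate normalizations (constant actual profile) and non-positive
$\overline{VS}$ are excluded with a warning, never imputed.

### Inference: max-T sign-flip permutation

All group tests are upper-tailed one-sample (or paired) t tests with
family-wise correction by the maximum-statistic permutation method: the null
is built by randomly sign-flipping the centered subject rows and recording
the maximum t across the family on each permutation. The corrected p-value
uses the validity convention $(b+1)/(n_{perm}+1)$; the classic $b/n_{perm}$
is reported alongside. The family is explicit per analysis: {actual,
generated} specificity per hemisphere, 132 ordered network pairs for the
ranking (ordered pairs because each network's score is its significant wins
out of 11), 12 networks or all non-CCC parcels for the VM-versus-VS flow
contrasts. The reference analyses use 100,000 permutations (the package
default); simulation suites use 1,000, which bounds attainable p-values at
1/1001 but leaves the 0.05 decision threshold well resolved.

### Network contributions and dominance

Flow terms into the CCC are aggregated per source network by the *mean* over
the network's parcels (a sum would reward network size), then averaged over
the hemisphere's CCC targets and the scoped conditions. Dominance analysis
regresses, per subject, the 32 pooled observations (4 CCC parcels × 8
conditions per hemisphere) of actual activation on the 12
network-partitioned generated activations, enumerating all $2^{12}-1 = 4095$
nonempty predictor subsets with an intercept in every fit. *General*
dominance — averaging each predictor's incremental $R^2$ first within, then
across subset sizes — is used because it is the variant whose partial values
sum exactly to the full-model $R^2$; a plain average over all subsets would
not. Pooling the 4 parcels with the 8 conditions keeps the observation count
(32) above the predictor count (12); this pooling is a design choice the
method description leaves open.

## The synthetic cohort generator

No human data ship with the package; every stage is exercised on synthetic
cohorts whose ground truth is known. The generator is first-class, tested
code, and its defaults are the study conditions: 360 parcels (12 networks, 8
CCC parcels, four per hemisphere as V1/FEF/SCEF/AIP), 48 subjects, two
150-frame resting sessions at TR = 2 s, and the printed task designs — VM
runs with five 19-s and five 18-s blocks in 208 frames (two runs), VS with
five 22-s and five 18-s blocks, SM with ten 24-s blocks, FT with six 20-s
blocks in 92 frames, giving eight conditions across four tasks. Gap
placement between blocks is not specified by the designs' sources, so gaps
are spread evenly — a reproducibility choice that preserves the printed task
seconds and frame counts.

### Ground truth connectivity

Resting series are drawn from a sparse ground-truth precision matrix:
within-network edges (probability 0.20, magnitude 1.0), rare cross-network
edges (0.01, 0.40), and planted CCC pathways — every CCC parcel connects to
all VIS2 parcels bilaterally (magnitude 0.7; early visual cortex is strongly
callosally connected) and to all same-hemisphere DAN parcels (magnitude
0.5), with only the edge weights randomized (uniform on 0.75-1 of the
magnitude). Deterministic pathway membership keeps the planted network
ordering stable across cohorts — with Bernoulli pathway edges at small P,
the realized ordering would vary from draw to draw and the recovery
properties would test the draw, not the pipeline. Random background edges
incident to a CCC parcel are damped (by
0.4) so the circuit's connectivity fingerprint is dominated by the
controlled pathways rather than by the high realization variance of a few
Bernoulli edge draws — at small P a single random full-strength edge into
the circuit could otherwise overturn the planted network ordering in some
cohorts. All off-diagonal precision entries are negative, so every true
partial correlation is positive and flow weights cannot cancel in sign.
Positive definiteness is enforced by diagonal dominance (diagonal = 1 +
absolute row sum). Edge magnitudes were chosen so the planted structure is
actually recoverable at resting-scan lengths — true partial correlations of
roughly 0.08–0.3, dense and homogeneous (≈0.1) on the planted CCC pathways
— because a generator whose truth is undetectable at the
study's own scan length would make every downstream property vacuous. The
latent signal is AR(1) with coefficient 0.3 and innovations scaled so the
marginal covariance equals the precision inverse exactly; observation noise
(sd 0.2) is white, so the observed covariance is $\Sigma + \sigma^2 I$ — the
quantity the long-run covariance test checks against.

### Planted activations and the meaning of lambda

Source (non-CCC) parcels share a common 8-condition profile shape, scaled by
a per-network gain (VIS2 1.8 > DAN 1.0 > VIS1 0.8 > others 0.4–0.5) plus
i.i.d. subject noise (sd 0.10). The shared shape has VM mean
$\lambda\rho$, VS mean 1, SM mean 0.5, and FT exactly 0, where $\lambda$ is
the distributed mixing weight and $\rho$ the planted specificity ratio. Each
CCC parcel's beta vector is the mixture

$$\beta_j \;=\; \lambda \cdot \mathrm{flow}_j \;+\; (1-\lambda) \cdot \mathrm{local}_j \;+\; \varepsilon_j$$

where $\mathrm{flow}_j$ is the *exact* activity-flow sum of the realized
source betas through the true partial correlations (all CCC excluded), and
$\mathrm{local}_j$ is the parcel's expected flow gain times a local profile
with VM mean $\rho(1+\lambda)$, plus i.i.d. noise orthogonalized against the
realized flow profile. This calibration has three consequences, verified by
tests: the expected actual VM/VS ratio is exactly $\rho$ for every
$\lambda$; the noiseless distributed contribution is exactly
$100\lambda$; and at $\rho = 1$ the expected VM and VS betas are equal (a
clean null). The local component deliberately carries *extra* vergence
specificity beyond the flow component — if the local term were pure
zero-mean noise, generated and actual specificity would coincide in
expectation and the contribution statistic could not distinguish any
$\lambda$ from 1; a monotone mapping from $\lambda$ to the measured
contribution requires a structured local term. Because all sources share one
profile shape, the *shape* of a generated CCC profile is invariant to how FC
estimation reweights the sources (only the gain changes), which makes the
specificity of generated activations robust to graphical-lasso shrinkage —
a deliberate identifiability property of the generator.

### What the generator does not emulate

Gaussian parcel series with AR(1) temporal structure, linear confound
coupling, and level-shift motion spikes are a deliberately minimal stand-in:
no haemodynamic nonlinearity, no spatial smoothness between parcels (the
distance matrix comes from a random 3-D embedding and is metadata for the
radius-exclusion policy, not a smoothness model), no physiological rhythms,
no inter-subject variation in the connectome (all subjects share one
ground-truth precision; only noise realizations and betas vary), and no
vascular or susceptibility artifacts. Passing tests therefore show that the
*pipeline recovers what the model family assumes*, not that real BOLD data
satisfy those assumptions.

## Numerical choices and degenerate inputs

- Graphical lasso: convergence tolerance 1e-4 on the covariance update,
  inner coordinate-descent tolerance 1e-6; non-convergence at every penalty
  is an error carrying the penalty trace; constant parcel series are
  rejected by name. Estimated partial correlations are clipped to [-1, 1].
- HRF convolution happens on a 0.1-s microtime grid and is sampled at frame
  times, so block onsets need not align to the TR grid.
- The boundary case FD = 0.25 mm is *not* a spike (strict inequality);
  distances exactly at the exclusion radius are *not* excluded (strict
  less-than).
- Rank-deficient nuisance matrices abort with the collinear columns named;
  rank-deficient dominance subsets fall back to a least-norm fit with a
  warning.
- A network emptied by the source policy contributes exact zeros to the
  partition (keeping the 12-way sum identity), and a subject whose
  normalization degenerates is excluded, never imputed.
- Seeds: one master seed expands through a deterministic multiplicative
  hash (`derive_seed`) into per-stage, per-subject, per-session streams; all
  derived seeds stay below 2^31.

## Problem sizes

The test suite and the acceptance script run at the reduced scale the
package adopts for simulation work: P = 60 parcels (retaining all 12
networks and the 8 CCC parcels), cohorts of 8–24 subjects, 1,000
permutations, and 20-seed replication for parameter-recovery and ranking
properties. These sizes were chosen so the full suite completes on a single
CPU while keeping every statistical property testable; the generator runs
unchanged at the full 360-parcel, 48-subject scale.

## Known limitations

- At the study's resting-scan length (150 frames) the cross-validated lasso
  penalty shrinks partial correlations substantially, so generated
  activations are systematically scaled down relative to actual ones:
  Pearson r of generated versus actual stays high (it is scale-free) while
  R² can sit near or below zero (it is not). Specificity and contribution
  are ratio statistics computed after normalization with the actual range
  and are robust to this shrinkage; absolute R² values are not, and longer
  resting scans raise them.
- The pipeline is linear end to end; multi-step or nonlinear propagation is
  out of scope (the secondary within-CCC circulation implements exactly one
  extra step, as a control).
- Whole-cortex accuracy is computed on condition-level betas (8 columns);
  run-level variants are not implemented.
- The max-T engine implements upper-tailed tests only, matching every test
  in the analysis; two-sided families would need the symmetric extension.
- Dominance analysis is limited to 20 predictors by subset enumeration; the
  reference use is 12.
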