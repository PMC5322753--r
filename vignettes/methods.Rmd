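---
title: "Methods: a two-stage RBF cascade for ILD risk from routine indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a two-stage RBF cascade for ILD risk from routine indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ildcascade)
```

## The problem and the model

Rheumatoid arthritis (RA) patients who develop interstitial lung disease
(ILD), and in particular its fibrotic form (pulmonary fibrosis, PF), face
sharply worse prognoses, yet the reference diagnostic — high-resolution CT —
is not a screening instrument. `ildcascade` implements a screening pipeline
that estimates ILD/PF risk from routine clinical examination indicators
(CEIs): demographic items and routine blood and urine measurements that
every hospitalized patient already has.

The pipeline has five stages.

1. **Single-indicator screening.** Each CEI is evaluated as a univariate
   marker separating ILD from healthy-lung patients by empirical ROC
   analysis. A CEI is *ILD-associated* when its AUC is significantly
   larger than 0.5 (two-sided z test on the DeLong standard error,
   $\alpha = 0.05$). Indicators are ranked by the Youden index
   $J = SE + SP - 1$ at the ROC-optimal cutoff. PF patients are excluded
   from every model-building step and reserved for evaluation.
2. **First-stage network (ANN I).** The associated CEIs enter a greedy
   forward selection: at each step the candidate whose addition maximizes
   the Youden index of a freshly trained radial-basis-function (RBF)
   network is kept, and the final input set is the prefix of the trace
   with maximal $J$. ANN I is an RBF network with 12 Gaussian hidden
   units and a linear output (a "4-12-1" architecture when four inputs
   are chosen), trained on 0–1 normalized inputs.
3. **Patient similarity.** With the selected inputs as coordinates, every
   pair of patients gets a Euclidean distance; retaining the smallest
   $k$ distances as edges yields a patient–patient similarity network
   (PPSN) that can be exported as an edge list or GraphML for Cytoscape.
4. **Derivative information (the core idea).** For patient $i$, the other
   reference patients are sorted by distance to $i$ and divided into $m$
   mutually exclusive, nearly equal divisions; division 1 holds the most
   similar patients. A chosen division $d$ yields four features: $f_1$
   the patient's own ANN I score, $f_2$ the mean ANN I score in the
   division, $f_3$ the mean distance to it, and $f_4$ the observed ILD
   proportion among its members. $f_4$ is a nonparametric local estimate
   of disease probability that a small parametric network cannot express
   on its own.
5. **Second-stage network (ANN II).** For every $m \in \{5, 10, 15, 20\}$
   and every $d \le m$ — 50 candidates — a second 4-12-1 RBF network is
   trained on $(f_1, \dots, f_4)$; the candidate with the highest Youden
   index becomes ANN II ("5D1" denotes division 1 of the 5-division
   scheme). The ROC-optimal cutoff of its output is the frozen decision
   threshold for all later cohorts.

## The RBF trainer

The original study used a proprietary neural-network toolbox whose
training algorithm is unpublished. The trainer here is a documented,
classical construction chosen for reproducibility, not a re-implementation
of that tool:

* **Centers** by seeded k-means on the training inputs ($K = 12$ by
  default, exposed as a parameter).
* **Widths**: each unit's width is its distance to the nearest other
  center times a global multiplier.
* **Output layer** by ridge-regularized least squares (ridge $10^{-6}$ on
  the hidden weights, bias unpenalized). With $K = n$ and vanishing
  ridge this reduces to classical RBF interpolation, which the test
  suite verifies.
* **Output normalization**: raw outputs are min–max rescaled by the
  bounds observed on the training set and clipped to $[0, 1]$.
* **Holdout protocol**: patients are split 2:1:1 into training,
  verification and testing sets (largest-remainder rounding, so 533
  patients split 267/133/133). The width multiplier is the only tuned
  hyperparameter, picked from $\{0.5, 1, 2, 4\}$ by verification-set
  Youden index. Pearson correlations between output and status on the
  training and testing sets ($R_{Tr}$, $R_{Te}$) are reported; similar
  values indicate good generalization.

Exact replication of the original tool's weights is explicitly not a
goal; behavioral equivalence at the level of the reported metrics is.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | significance level of the AUC-vs-0.5 screen |
| `k_centers` | 12 | hidden units per network (the "-12-" in 4-12-1) |
| `ridge` | 1e-6 | output-layer regularization |
| `width_grid` | 0.5, 1, 2, 4 | candidate width multipliers |
| `m_values` | 5, 10, 15, 20 | division counts explored for ANN II |
| `n_edges` | 1500–3000 | PPSN edge budgets |
| `cutoff` | trained | decision threshold, ROC-optimal on ANN II output |

Normalization bounds are fitted on the model-building cohort and frozen:
an external cohort must be mapped through the training normalizer, and
out-of-range values are clipped to $[0, 1]$ rather than extrapolated so
network inputs stay in the trained domain. When more than half of an
external cohort's values clip, the evaluation report raises a scale
warning instead of failing.

## Numerical and procedural choices

* **ROC conventions.** Operating points are computed at every distinct
  score threshold (positive call at score ≥ threshold); AUC is the
  Mann–Whitney concordance with ties counted one half; each screening
  CEI's curve is taken in the direction giving AUC ≥ 0.5 and the
  direction is recorded. Cutoff ties break toward the higher
  specificity; sensitivity at fixed specificity 0.8 uses the
  step-function (no interpolation) convention. The AUC-vs-0.5 test is
  two-sided (the sidedness of the original screen is unstated; two-sided
  is the conservative choice and its type-I error is verified by
  simulation).
* **Degenerate inputs.** Constant scores give AUC 0.5 with p = 1 (never
  a division-by-zero); a sensitivity or specificity of exactly 1 makes
  the diagnostic odds ratio infinite and is signalled as a typed error;
  constant CEIs fail normalization by name.
* **Ties and determinism.** Distance ties at the PPSN edge boundary and
  at division boundaries break by patient ID; greedy-selection ties
  break toward the higher single-CEI AUC; every randomized step (k-means
  seeding, holdout splits, fold draws) is seeded, derived from one
  pipeline seed by fixed offsets, and restores the caller's RNG state.
  Retraining with the same seed is bit-identical.
* **Division remainders.** Dividing $n$ others into $m$ divisions of
  nearly equal size gives the first $n \bmod m$ divisions one extra
  member, i.e. the extras go to the *nearest* divisions (532 others at
  $m = 5$ → 107, 107, 106, 106, 106).
* **Leakage discipline.** A reference patient is always scored
  leave-self-out; an external patient sees the full reference cohort. In
  cross-validation the entire cascade — normalizer, ANN I, reference
  cohort, division scheme, ANN II — is rebuilt per fold and the held-out
  fold is scored as external; any other choice leaks labels through
  $f_4$. Folds are stratified by lung status so no training set loses a
  class at desk scale.
* **Candidate evaluation.** Candidate metrics are computed on the full
  model-building cohort scored by the trained candidate (pooled
  evaluation, matching the granularity of a single summary row per
  candidate); a strict holdout mode (`evaluation = "holdout"`) is
  provided for sensitivity analyses. Which convention the original study
  used is unstated; both are implemented and the default documented.
* **No multiple-testing correction** in the screen, by design fidelity:
  the original protocol applied none, and the forward selection
  re-evaluates candidates jointly afterwards.

## What the synthetic generator emulates — and what it does not

`default_study_spec()` emulates the study conditions: 169 healthy + 364
ILD + 87 PF patients; 32 CEIs in three classes (2 basic, 22 blood,
8 urine); age planted at a single-CEI AUC of 0.71 and the eosinophil,
platelet and white-cell counts at AUCs 0.56–0.59 (the platelet shift
negative, exercising the inverse ROC direction); four further indicators
near-null (AUC ≈ 0.53) and the rest null. Gaussian indicators make the
calibration exact through the binormal identity
$AUC = \Phi(\delta/\sqrt{2})$, which the suite checks by simulation.
PF patients are "more extreme ILD": their informative shifts are
multiplied by 1.3, giving the severity ordering under which positive-only
TPR exceeds ILD sensitivity.

The *clustered* mode adds latent patient subpopulations: cluster centers
in the informative-CEI space and cluster-specific ILD prevalences spread
around the cohort rate. This is the minimal mechanism that makes
division-1 derivative features informative beyond the patient's own
score. Its defaults (30 clusters, center spread 2.5 SD, enrichment 1.2)
are a length-scale choice: the latent subpopulation (~18 patients) must
sit below the coarsest division block (~27 members at $m = 20$) and below
what 12 RBF centers can resolve, because when the clusters are coarse the
first-stage network absorbs the neighborhood signal itself and the
cascade has nothing left to add.

Limitations to keep in mind when reading passing tests: the generator
draws CEIs independently within groups (no attempt at the real joint
covariance between, say, the white-cell count and its differential), has
no longitudinal structure, and its missingness is completely at random.
Passing tests therefore demonstrate that the pipeline recovers the
structures it assumes, not that those structures exhaust real cohorts.
The headline metrics of the original study (its exact AUCs, TPRs and the
0.622 cutoff) depend on an unpublished trainer and the original patient
data, and are treated as qualitative references throughout.

A deliberate consequence of emulating the published effect sizes: the
three weak blood indicators sit at AUCs where a DeLong screen at
$\alpha = 0.05$ with 169-vs-364 patients has only moderate power
(standard error of a null AUC ≈ 0.027, so an AUC of 0.562 is about 2.3
null SEs from 0.5). Joint recovery of all four planted indicators in
nearly every replicate is therefore not statistically achievable at this
sample size, and the acceptance suite records that fact rather than
inflating the planted effects.

## Problem sizes used by the test suite

Unit and property tests run on cohorts of 100–533 patients (the
screening, calibration and mechanism checks use the full 533-patient
study composition; structural and round-trip checks use 120–320 patients
and a reduced division grid, which exercises identical code paths at
smaller n). Monte-Carlo calibration uses 1,000–2,000 replicates; seed
counts per stochastic property are 10–40. These sizes were chosen so the
full suite exercises every claim at meaningful scale while remaining
comfortable to run on a laptop.

## Known limitations

* The RBF trainer is a documented stand-in; numerical equality with the
  original study's weights is out of reach by construction.
* The screen tests each CEI marginally; correlated indicators can be
  jointly informative yet individually missed (or vice versa).
* Derivative features freeze the reference cohort at training time;
  population drift between reference and deployment cohorts surfaces
  only as the clipping warning.
* `evaluate_positive_only` cannot compute an AUC (single class) — it
  reports the TPR at the frozen cutoff only.
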