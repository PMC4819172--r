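---
title: "Feature-error probability densities for single-model quality assessment"
author: "qprob authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature-error probability densities for single-model quality assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qprob)
```

## The problem

Protein structure prediction produces pools of alternative 3-D models
(decoys) for a target sequence; model quality assessment (QA) must rank them
without the native structure. Consensus QA methods compare models to each
other and fail when the pool is dominated by similar low-quality models —
precisely the hard, template-free regime. `qprob` implements a *single-model*
method: it scores one model at a time from that model's own features and
predicts its GDT-TS (the mean, over 1/2/4/8 Å thresholds, of the largest
fraction of CA atoms superposable within the threshold; range [0, 1]).

## The model

Eleven features are computed per model, each oriented so that larger is
better and scaled into [0, 1] (canonical order from `qprob_features()`):

1. a length-normalized RF_CB_SRS_OD statistical-potential score,
2. secondary-structure similarity (sequence-predicted vs model 3-state),
3. a secondary-structure penalty score (F_H + F_S)/N counting predicted
   helix/strand residues realized in the model,
4. a Euclidean compactness score (mean pairwise CA distance over a
   length-dependent reference),
5. fraction of exposed surface belonging to nonpolar residues,
6. fraction of residue mass in exposed residues,
7. fraction of total reference area exposed,
8. solvent-accessibility similarity (predicted vs model 2-state),
9. a length-normalized RWplus score,
10. the ModelEvaluator SVM score (already in [0, 1]),
11. a length-normalized Dope score.

Each feature `i` is treated as a noisy, biased estimator of the true GDT-TS.
On a training set with known GDT-TS `R_j`, the per-feature errors
`FE_ij = F_ij − R_j` are fitted with a normal distribution: mean `M_i`
(the feature's bias) and population standard deviation `SD_i` (its
reliability). At prediction time, the feature's bias-adjusted score
`Adjust_i = clip(pre_i − M_i, 0, 1)` centers a Gaussian density which is
divided by its own peak value,

    f_i(X) = exp( −(X − Adjust_i)² / (2·SD_i²) ),

so every feature's density tops out at exactly 1 regardless of its spread.
The combined score is the weighted sum over present features,

    P_combine(X) = Σ_i W_i · f_i(X),

and the predicted quality is the `X` on the grid {0, 0.001, …, 1}
maximizing `P_combine` (ties go to the smallest `X`). A *sum* rather than a
product is essential: the fitted weight vector contains a negative entry
(Dope), which a product of densities could not express. Narrow-SD features
act as needles that pin the argmax near their adjusted score; broad-SD
features contribute gentle preferences.

## Normalization of raw energies

Statistical potentials grow in magnitude with protein length, so raw scores
are mapped onto [0, 1] with length-dependent linear ranges fitted on a
non-redundant structure set: DFIRE2 from [−1.971·L, 0], RWplus from
[−232.6·L, 0], RF_CB_SRS_OD from [0.4823·L − 300, 700]. The best (lowest)
energy maps to 1 so that every feature is positively oriented with GDT-TS —
the orientation under which the fitted error means are small. Scores
outside the range clip. Dope has no published range constants; the package
default maps from [−1.0·L, 0] and is exposed in
`qprob_config()$normalization$dope_slope` as an artifact choice. DFIRE2
normalization is provided for baseline comparisons but DFIRE2 is not one of
the 11 combined features. The normalization length is the target sequence
length `N` when a sequence is supplied (models with unresolved residues are
otherwise penalized twice), the model length when not.

## Weight training

Weights are fitted by grid coordinate descent against the per-target
average GDT-TS loss: for each target, predict every model, take the
top-ranked one, and charge the gap between the pool's best true GDT-TS and
the picked model's. Weights live on the grid −0.8 to 0.8 in steps of 0.01
and Min-Loss starts at 1. The features are swept in canonical order; each coordinate scans all 161 grid values
with the others fixed and accepts the minimizer when it strictly lowers the
loss — or when it matches the current loss while moving the weight strictly
toward zero. The second clause is this package's design choice: the
closest-to-zero tie-break is only able to keep weights sparse if loss-
neutral shrinkage is actually accepted, and draining uninformative weights
is what lets a single dominant feature take over. Termination is still
guaranteed because every accepted move strictly decreases the pair
(loss, Σ|W_i|) lexicographically over a finite grid; a sweep cap (100)
guards degenerate inputs. The Min-Loss trajectory is non-increasing by
construction.

The loss is non-convex and plateau-ridden, so the descent is
initialization-sensitive: on a constructed instance with one perfect
feature and ten pure-noise features, a substantial fraction of random
starts stalls in local minima well above the optimum. `train_weights`
therefore runs `n_restarts = 5` starts — the first from the all-zero
vector, the rest seeded random — and stops early when a run reaches loss
0, the global lower bound. The zero start is the null model: greedy
forward selection from it adds only strictly-improving weights, which
empirically lands in sparse, well-generalizing optima, while the random
restarts cover instances where that greedy path stalls. With at least 8
targets, a seeded 25% target-level validation slice is withheld from the
descent and restarts are compared by validation loss (ties keep the
earlier, sparser run): selecting by training loss alone systematically
favors restarts that memorized the training ranking with noise-feature
weights and generalize worse. The published 11-weight vector
(`qprob_default_weights()`, summing to 0.53) ships as the default for
scoring without retraining.

## Ground truth and evaluation

`gdt_ts()` computes GDT-TS with Kabsch superpositions. Chains with at most
`exact_n = 10` common residues are solved exactly by enumerating every
superposition subset of size ≥ 3 — feasible because the cost is 2^n — while
larger chains use a search heuristic seeded from every contiguous fragment
of length 3/5/7 plus the full set, refined by iterative inclusion of
in-threshold residues and iterative exclusion of the worst-fitting residue.
The heuristic can only undershoot the optimum; the test suite bounds its
gap on small instances (≤ 0.1 GDT-TS units observed, usually one residue at
one threshold). Fractions use the native residue count, so missing model
residues cost score.

Evaluation mirrors CASP practice: per-target Pearson/Spearman/Kendall
(tau-b) correlations between predicted and true scores, the per-target
GDT-TS loss, two-sided Wilcoxon signed-rank tests between paired per-target
metric lists (zeros dropped; exact null for ≤ 25 tie-free differences, else
normal approximation with continuity correction), and summed top-1 Z-scores
across methods with the conventional floor at −2
(`qprob_config()$evaluation$zscore_floor`).

## Internal structure assigners

To run without external binaries, the package includes:

* **Shrake–Rupley SASA** (`compute_sasa`): per-atom accessible area from a
  fixed golden-spiral lattice (960 points by default, probe 1.4 Å); a point
  on the probe-expanded sphere is buried when it lies on or inside a
  neighbour's expanded sphere. The fixed lattice makes results exactly
  reproducible; the cost is a small orientation dependence (total-area
  changes under rotation < 0.5%). Relative accessibility uses Gly-X-Gly
  reference areas; residues above 0.25 relative accessibility count as
  exposed (a common convention; the threshold is configurable).
* **Dihedral-window secondary structure** (`assign_secondary_structure`):
  helix for φ ∈ [−100°, −30°], ψ ∈ [−80°, −5°] over ≥ 4 consecutive
  residues; strand for φ ∈ [−180°, −40°], ψ ∈ [50°, 180°] ∪ [−180°, −170°]
  over ≥ 3; else coil. Chains too short for the run-length minima come out
  all coil. A DSSP output file, when available, overrides both assigners
  via `read_dssp()` (8-state codes collapsed H/G/I→H, E/B→E, else C).

These stand-ins are deliberately simple; they are not DSSP
reimplementations and make no hydrogen-bond assignments.

## The synthetic generator

`make_feature_dataset()` emulates a reduced CASP-like training pool: by
default 20 targets × 30 models with true quality uniform on [0.2, 0.8], and
per-feature errors `Normal(μ_i, σ_i)` added to the truth and clipped to
[0, 1] — exactly the error model's assumption, with an error profile in
which the ModelEvaluator feature is the least biased (μ = −0.0219) and
tightest and the compactness score carries the largest bias (μ = 0.4119);
the remaining profile entries are plausible one-time choices. The default
pool size keeps a full training run in tens of seconds on one CPU while
leaving enough targets for the validation split. `make_helix()` /
`make_decoy()` build ideal α-helical backbones (NeRF construction from
ideal bond geometry, φ = −57°, ψ = −47°) and Gaussian-perturbed decoys
whose expected CA RMSD equals the requested magnitude.

What the generator does **not** emulate: feature–feature noise correlation
(real energy scores are strongly correlated), target-difficulty structure
(real pools have per-target quality distributions far from uniform),
non-Gaussian and truncated error shapes, and physically plausible decoy
geometry. Passing the synthetic tests therefore demonstrates the
correctness of the machinery — normalization, error fitting, density
combination, training, evaluation — not the real-data accuracy of the
method, which depends on feature quality on actual CASP pools.

## Numerical choices and degenerate inputs

* Scoring grid step 0.001; argmax ties to the smallest X; adjusted centers
  clipped to [0, 1] (switchable via `scoring$clip_adjusted`) so predictions
  stay in the valid GDT-TS range.
* Error SDs floored at 0.01 (`error_model$sd_floor`): a zero-variance
  feature would otherwise become a delta function and override all others.
  Errors are modeled as untruncated Gaussians even though they live in
  [−1, 1]; the mismatch is accepted as part of the model.
* Missing features: densities of absent features are dropped and the
  remaining weights rescaled to the full-set weight mass (a scale factor,
  so the argmax is unchanged); fewer than 4 computable features is an
  error.
* Population (÷n) rather than sample SD; negligible at training scale.
* PDB dialect: first MODEL block, altlocs by highest occupancy then first
  seen, residues ordered by (number, insertion code), residues without CA
  dropped with a warning, single chain enforced.
* Models are matched to the target sequence positionally by residue number;
  unresolved residues count in N but drop out of similarity numerators and
  denominators.

## Problem sizes used by the test suite

Training properties run on 20 targets × 30 models (the generator default);
the end-to-end loop trains on that scale and evaluates 10 held-out targets;
GDT-TS oracle comparisons use 8–10-residue chains where exhaustive subset
enumeration is feasible; density-combination checks use 1000 random
contexts against a 100×-finer grid scan; error-model recovery uses 1000
samples per feature.

## Known limitations

* The seven structural features need externally predicted secondary
  structure and solvent accessibility to be fully populated; without them a
  model is scored from 4 features only.
* The four external energy/ML scores must be computed by their own
  programs and supplied as a TSV; the package only normalizes and combines
  them.
* The GDT-TS heuristic is not LGA; for chains above `exact_n` it can
  undershoot slightly.
* No local (per-residue) quality estimates, no consensus mode, no
  multi-chain support.
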