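# qprob — single-model protein quality assessment from feature error densities

Protein structure prediction yields pools of candidate 3-D models; quality
assessment (QA) must rank them without the native structure. Consensus QA
compares models to each other and collapses on hard targets whose pools are
full of similar bad models. `qprob` is a *single-model* method for people
building or benchmarking structure-prediction pipelines: it predicts a
model's GDT-TS from that model's own features.

## The method

Eleven features — seven structural/physicochemical scores computed from
the model (secondary-structure and solvent-accessibility agreement with
sequence-based predictions, compactness, surface composition) plus four
externally computed scores (length-normalized RF_CB_SRS_OD, RWplus and
Dope statistical potentials, and the ModelEvaluator SVM score) — are each
treated as a noisy, biased estimator of GDT-TS. On training data with known
GDT-TS `R_j`, the per-feature errors `FE_ij = F_ij − R_j` are fitted with a
normal distribution, giving a bias `M_i` and spread `SD_i` per feature. For
a new model, each present feature contributes a peak-normalized Gaussian
centered on its bias-adjusted score:

    f_i(X) = exp( −(X − (pre_i − M_i))² / (2·SD_i²) ),   X ∈ [0,1]

and the predicted quality is the argmax over a 0.001 grid of the weighted
combination

    P_combine(X) = Σ_i  W_i · f_i(X).

The 11 weights (shipped: `[0.03, 0.09, 0.04, 0.08, 0.08, 0.01, 0.03, 0.10,
0.00, 0.09, −0.02]`, in canonical feature order) are fitted by grid
coordinate descent against the per-target GDT-TS loss — the gap between a
pool's best model and the model the predictor ranks first. The package also
implements the surrounding machinery: PDB/FASTA/DSSP/TSV readers, an
internal Shrake–Rupley surface and dihedral-window secondary-structure
assigner, GDT-TS (exact for small chains, fragment-seeded heuristic above),
CASP-style evaluation (per-target Pearson/Spearman/Kendall, GDT-TS loss,
Wilcoxon signed-rank, summed top-1 Z-scores), and synthetic fixture
generators so the whole pipeline runs without external data. See the
methods vignette (`vignettes/qprob-methods.Rmd`) for assumptions, tunables
and limitations.

## Worked example

Structural side — build a native, perturb it, measure true quality and
compute the model-derived features:

```r
library(qprob)
native <- make_helix(40, model_id = "native")
decoy  <- make_decoy(native, rms_target = 4, seed = 2, model_id = "decoy")
gdt_ts(decoy, native)
#> [1] 0.49375
round(assemble_feature_vector(decoy), 3)
#>      rf_cb_srs_od     ss_similarity        ss_penalty euclidean_compact
#>                NA                NA                NA             0.616
#>  surface_nonpolar      exposed_mass   exposed_surface     sa_similarity
#>             0.481             0.904             0.571                NA
#>            rwplus         modeleval              dope
#>                NA                NA                NA
```

A 4 Å-perturbed helix has true GDT-TS 0.494; without sequence-based
predictions or external energies, 4 of the 11 features are computable.

Statistical side — the full train/score/evaluate loop on a synthetic pool
(20 training targets × 30 models; one feature generated with error SD 0.02,
the rest 0.3):

```r
sds <- setNames(rep(0.3, 11), qprob_features()); sds["modeleval"] <- 0.02
train   <- make_feature_dataset(synthetic_spec(seed = 101, feature_sds = sds))
heldout <- make_feature_dataset(synthetic_spec(seed = 102, n_targets = 10,
                                               feature_sds = sds))
stats <- train_error_stats(train$features, train$truths)
round(stats[stats$feature == "modeleval", c("M", "SD")], 4)
#>         M     SD
#> 10 -0.0222 0.0197          # the generating bias/spread were -0.0219/0.02
ws <- train_weights(train$features, train$truths, stats, seed = 42)
ws
#> weight_set: Min-Loss = 0.004988 after 4 sweep(s)
#> ... euclidean_compact 0.11, modeleval 0.06, all others 0.00
```

Scoring the held-out targets with the trained weights and evaluating:

```r
preds <- do.call(rbind, lapply(seq_len(nrow(heldout$features)), function(i) {
  data.frame(target_id = heldout$features$target_id[i],
             model_id  = heldout$features$model_id[i],
             score = predict_quality(unlist(heldout$features[i, qprob_features()]),
                                     stats, ws$weights))
}))
evaluate_dataset(preds, heldout$truths)$summary
#>   ave_corr ave_spearman ave_kendall ave_loss n_targets
#> 1   0.5471       0.5681      0.5203   0.0109        10
```

The per-target loss of 0.011 means the model picked first was on average
within 0.011 GDT-TS of each pool's true best — the training isolated the
dominant feature. (Correlations are moderate because the nine noisy
features still blur mid-ranking order; model *selection*, the loss metric,
is what the weights are trained for.)

Command-line wrappers for the same steps live in `inst/cli/qprob.R`
(`synth`, `features`, `train-errors`, `train-weights`, `score`).

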