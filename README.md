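# micmap — mapping informative clusters in fMRI multivariate analysis

`micmap` is an R package for localizing condition-related information in
fMRI data with a hierarchical multivariate approach. Instead of ranking
individual voxels by the weights of a whole-brain classifier — a procedure
whose selected voxel sets are notoriously unstable across cross-validation
folds — it parcellates the brain into *local homogeneous clusters*
(spatially connected voxels with similar raw time courses, grown by
competitive region growing on mean pairwise Pearson correlation), collapses
each cluster's multi-voxel pattern to a single value, and ranks whole
clusters by the absolute discriminative weights `|w_j|` of a second-level
linear SVM.

Methods implemented, all behind one cross-validated harness:

| method | features | summary |
|---|---|---|
| `MIV`   | voxels          | none (whole-brain SVM weights) |
| `MIVs`  | voxels          | as MIV, on 6-mm-smoothed data |
| `uMIC`  | homogeneous clusters | spatial mean |
| `mMIC`  | homogeneous clusters | Gaussian naive Bayes log-odds discriminant |
| `mMICc` | cubic clusters  | GNB discriminant (non-functional parcels) |

The cluster partition keeps merging mutual-nearest-neighbor cluster pairs
(similarity: mean pairwise correlation of raw time series) and retires a
cluster once it reaches a preset size `Ts`, so cluster sizes lie in
`[Ts, 2(Ts-1)]`. The GNB discriminant of a cluster `H` for pattern `x` is

    f_H(x) = log P(c1)/P(c2) + sum_{v in H} [ log N(x_v; mu_v1, s2_v) - log N(x_v; mu_v2, s2_v) ]

with per-voxel means and pooled ML variances fitted on training samples
only. Mapping quality is evaluated by predictive accuracy and selection
robustness (mean pairwise intersection-over-union of the voxel sets chosen
across folds) at ten geometric feature levels (100, 150, 225, ..., 3844
voxels), and — on simulated data — by ROC/AUC of the weight map against the
preset informative voxels.

The package includes the matching block-design BOLD simulator: a
32 x 32 x 5 grid, two conditions, eight runs of three 32-s blocks per
condition separated by 16-s fixations (TR 2 s), irregular connected
informative regions, spatially smoothed white noise, and exact calibration
of the contrast-to-noise ratio (CNR = spatial mean of the temporal maximum
absolute signal in the informative regions / temporal SD of the
post-smoothing noise).

## Worked example

```r
library(micmap)

cfg <- sim_config(cnr = 0.2, region_size_voxels = 60, seed = 1)
sim <- simulate_dataset(cfg)
measure_cnr(sim$truth)
#> [1] 0.2

res <- mic_cv(sim$dataset, sim$design, methods = c("mMIC", "MIV"),
              folds = make_folds(sim$design$run, 4, seed = 1),
              Ts = 15, truth = sim$truth)
res$mMIC
#> Mapping result: max accuracy 1.000, mean robustness 0.513, mean AUC 0.867
res$MIV
#> Mapping result: max accuracy 1.000, mean robustness 0.333, mean AUC 0.740
```

Here both methods decode the two conditions perfectly at the best feature
level (`max accuracy`), but the cluster method's selected voxel sets
overlap far more across folds (`mean robustness`, intersection-over-union)
and rank the truly informative voxels higher (`mean AUC` against the
simulated ground truth) — the motivating result: cluster-level mapping is
more reliable without sacrificing decoding performance.

A thin command-line interface covers the same pipeline
(`exec/micmap simulate|partition|evaluate`), writing NIfTI volumes, a
design TSV and JSON metrics; see `?mic_cli`.

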