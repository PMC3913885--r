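# capkit

Co-activation pattern (CAP) analysis of resting-state fMRI in R.

Conventional resting-state methods (seed correlation, ICA) average
connectivity over whole scans and so assume stationary interactions
between regions. CAP analysis drops that assumption: every acquired
volume (time frame) is treated as an observation, and the n frames —
flattened to m-dimensional in-brain vectors t_1, ..., t_n — are
partitioned into k clusters R_1, ..., R_k by k-means minimizing the sum
of within-cluster distances

    J = Σᵢ Σ_{tⱼ ∈ Rᵢ} d(tⱼ, μᵢ),    d(x, y) = 1 − r(x, y),

with r Pearson's spatial correlation and μᵢ the cluster mean. Averaging
each cluster's (unmasked) frames yields k CAP maps, summarized by
per-voxel Z-statistic maps, occurrence rates, within-cluster similarity
and polarity; per-subject occurrence rates are compared between groups
by permutation testing. The package is aimed at researchers studying
dynamic functional connectivity who want the frame-clustering pipeline,
its comparison machinery (seed maps, sliding windows, spatial map
pairing), and a ground-truth synthetic generator in one tested place.

## What's inside

| stage | functions |
|---|---|
| volumes ↔ frame vectors | `load_4d`, `save_4d`, `frames_from_4d`, `volume_from_vector`, `brain_mask`, `mni_to_voxel` |
| signal conditioning | `preprocess_session`, `temporal_normalize`, `detrend_and_bandpass`, `regress_nuisance`, `smooth_gaussian` |
| supra-threshold masking | `supra_threshold_mask`, `filter_small_components`, `mask_frames` |
| clustering | `kmeans_frames`, `correlation_distance` |
| CAP summaries | `compute_caps`, `cap_metrics`, `write_caps` |
| group statistics | `session_occurrence_matrix`, `permutation_test`, `motion_summary` |
| comparison | `seed_correlation_map`, `sliding_window_map`, `spatial_corr_matrix`, `best_match_pairs`, `map_distribution_stats`, `precedence_matrix` |
| synthetic data | `generate_patterns`, `latent_state_model`, `simulate_dataset`, `recovery_score` |
| orchestration | `run_config`, `run_extract`, `run_group_test`, `inst/cli/capkit.R` |

## Worked example

Simulate a small multi-subject scan with 8 known co-activation states,
run the standard pipeline (4 mm smoothing, temporal normalization,
10%/5% supra-threshold masking with 6-voxel component filtering,
correlation-distance k-means with k = 8), and score recovery:

```r
library(capkit)

grid <- volume_grid(c(10, 10, 8), voxel_size = c(3, 3, 3))
mask <- brain_mask(grid, array(TRUE, c(10, 10, 8)))

patterns <- generate_patterns(8, mask, support_voxels = 100, seed = 2)
model <- latent_state_model(patterns, matrix(1/8, 1, 8),
                            amplitude = 1, noise_sd = 1)  # peak SNR 1
sim <- simulate_dataset(model, n_subjects = 10, frames_per_subject = 200,
                        tr = 3, mask = mask, seed = 3, as_volumes = TRUE)

pre <- lapply(sim$volumes, function(v)
  preprocess_session(v, mask, tr = 3, fwhm = 4,
                     low = NULL, high = NULL, gsr = FALSE)$values)
frames <- frame_matrix(do.call(rbind, pre), mask, sim$sessions)

res <- run_extract(frames, run_config(k = 8, seed = 1))
res$assignment
#> cap_clustering: k = 8  n = 2000  J = 1210.22  ( 11 iterations )

recovery_score(sim$labels, res$assignment$labels)[c("ari", "accuracy")]
#> $ari
#> [1] 0.90614
#>
#> $accuracy
#> [1] 0.9575

round(res$caps$occurrence, 3)
#> [1] 0.115 0.136 0.130 0.132 0.112 0.136 0.116 0.123
```

The adjusted Rand index of 0.91 says the clustering recovered the
planted frame labels almost perfectly despite voxel noise as large as
the peak signal; the occurrence rates sit near the design value of
1/8 = 0.125. `res$caps` also holds the mean maps, Z maps, similarity
and polarity per CAP, and `run_group_test()` compares per-subject
occurrence rates between groups with a permutation test.

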