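---
title: "Co-activation pattern analysis: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-activation pattern analysis: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capkit)
```

## The model

Conventional resting-state analyses (seed correlation, ICA) summarize
minutes of fMRI signal into one stationary connectivity pattern per
network. Co-activation pattern (CAP) analysis instead treats every
acquired volume as an observation in its own right: the n time frames,
flattened to m-dimensional in-brain vectors t_1, ..., t_n, are
partitioned into k clusters R_1, ..., R_k by k-means so as to minimize
the sum of within-cluster distances

J = sum_i sum_{t_j in R_i} d(t_j, mu_i),

where mu_i is the mean of the frames in R_i and d(x, y) = 1 - r(x, y)
is one minus Pearson's spatial correlation. Frames assigned to a
cluster are then simply averaged (without any masking) to give the k
CAP maps. The correlation distance makes clustering sensitive only to
the spatial *shape* of activation, not its amplitude or offset — the
appropriate invariance for normalized BOLD data.

Each CAP is summarized by a per-voxel Z-statistic map (cluster mean
divided by its standard error across member frames), an occurrence rate
(fraction of frames in the cluster, overall and per subject), a
within-cluster similarity (mean correlation of member frames to their
mean, used to rank CAPs), and a polarity (mean of strictly positive map
values plus mean of strictly negative values, whose sign says whether
activation or de-activation dominates).

## Signal conditioning

`preprocess_session()` applies, in order: spatial Gaussian smoothing
(FWHM 4 mm by default), removal of linear and quadratic trends with an
ideal zero-phase band-pass of 0.005–0.1 Hz, nuisance regression
(white-matter and CSF means, 6 rigid-motion parameters, and optionally
the in-mask global signal), and per-voxel temporal normalization to
mean 0 / SD 1 within each session. Stages can be disabled
individually; registration to MNI space is assumed done upstream.

Numerical choices worth knowing:

* **SD convention.** Temporal normalization divides by the population
  SD. Because the correlation distance is scale-invariant, the choice
  (population vs unbiased) cannot change any clustering result; it is
  fixed purely for reproducibility of stored values.
* **Band-pass realization.** A frequency-domain brick-wall filter:
  Fourier coefficients with frequency in [low, high] are kept, all
  others zeroed. It is exactly zero-phase, has unit passband gain, and
  introduces no ringing parameters. No equivalence with any particular
  AFNI/FSL filter is claimed beyond the stated passband.
* **Smoothing.** Separable truncated Gaussian (4 sigma), with the
  kernel renormalized at volume boundaries so constants are preserved.
* **Global signal regression** defaults on; it makes the in-mask
  spatial mean of every residual frame exactly zero (regression
  commutes with spatial averaging). The no-GSR variant is one flag.

## Supra-threshold masking

To suppress measurement noise in the clustering distances, each frame
is reduced to its extremes: exactly `floor(0.10 m)` highest and
`floor(0.05 m)` lowest values are kept (ties broken by the fixed voxel
order), and 3D connected components smaller than 6 voxels are
discarded, separately within the positive and negative tiers.
Sub-threshold voxels are set to zero and distances are computed over
the full-length vector, keeping all frames in one common vector space;
whether the original procedure used zero-filled vectors or pairwise
mask unions is not determinable, so the zero-filled convention is fixed
and documented here. Masking affects *only* the clustering; CAP
averaging always uses unmasked frames.

Connectivity defaults to 6 (face adjacency), the most conservative
reading of "inter-connected in 3D"; 18 and 26 are available. If
filtering would empty a frame's mask entirely — which happens in very
noisy data where no extreme value forms a 6-voxel cluster — the
unfiltered supra-threshold mask is kept for that frame and the event is
logged, so no frame ever drops out of the analysis.

## The clustering algorithm

Frames are row-standardized (spatial mean 0, unit norm), under which
1 - r(x, y) = |x - y|^2 / 2 and the normalized mean of a cluster's
standardized members is the exact minimizer of its within-cluster
distance sum. Lloyd iterations therefore decrease J monotonically, and
the objective has the closed form J = sum_i (n_i - |s_i|), with s_i
the vector sum of standardized members.

Initialization is k-means++-style seeding adapted to the correlation
distance, from a private seeded RNG stream (so results do not depend
on, nor disturb, the caller's RNG state). Ties in assignment go to the
lowest cluster index; an emptied cluster is re-seeded with the frame
farthest from its centroid. After Lloyd convergence each run is
polished by single-frame relocation in the style of Hartigan–Wong,
using the closed form above to evaluate every candidate move exactly
from one dot-product matrix; this escapes assignments that are stable
under batch updates but not under single-point moves (small instances
where plain Lloyd demonstrably misses the exhaustive-enumeration
optimum are covered in the test suite). The best of `n_restarts = 5`
restarts by J is returned; defaults `max_iter = 300`, label-fixpoint
convergence. Restart count, initialization, and convergence criteria
are this package's choices — the published method specifies none of
them.

`k = 30` is the default cluster count, kept from the original
whole-brain analysis; no automatic k selection is attempted.

## Group statistics

Per-subject occurrence rates feed a permutation test: the statistic is
the difference of group means per CAP; the null is built by randomly
re-assigning subjects to groups of the observed sizes (default 50,000
draws); p-values are two-sided with the add-one estimator
(1 + #{|null| >= |obs|}) / (n_perm + 1), then Bonferroni-corrected by
min(1, k p). The add-one estimator never returns zero and is slightly
conservative; with occurrence rates on a discrete grid (multiples of
one over the per-subject frame count), ties at the observed value make
the realized type-I error fall a little below the nominal level, which
the calibration test's binomial bounds accommodate.

Head-motion summaries follow the per-pair convention: displacement
between consecutive volumes is the Euclidean norm of the change in the
3 translation parameters, averaged over pairs (rotations analogously).
The text this mirrors could also be read as sqrt-of-mean-square per
pair; both are implemented (`rms = "euclidean"` default,
`"mean_square"` switch) since the wording does not settle it.

## Comparison machinery

Seed correlation maps use 6 x 6 x 6 mm cubes (2 x 2 x 2 voxels at 3 mm)
whose member voxels are those with centers within half a side of the
seed coordinate; default seeds are the standard PCC, mPFC, IPS and
motor locations. Sliding-window variants never cross session
boundaries. Cross-set map pairing is greedy without replacement on
|r| (ICA signs are arbitrary; signed matching is a switch), ties by
index order. Temporal precedence of CAPs is operationalized — the
original supplementary procedure being unspecified — as a
transition-count asymmetry test: within-session transitions are
counted, and each unordered pair (i, j) gets an exact two-sided
binomial test of count(i->j) against count(j->i) at p = 1/2,
Bonferroni-corrected over the k(k-1)/2 pairs.

## The synthetic-data generator

`generate_patterns()` + `simulate_dataset()` emulate concatenated
multi-subject resting scans in which every frame is one of K latent
co-activation states plus i.i.d. Gaussian voxel noise:

t = amplitude * pattern[z] + noise,   z ~ per-subject state probabilities.

Patterns are unions of Gaussian blobs on compact supports placed by
farthest-point sampling; supports are disjoint by default, and a
requested support-overlap (Jaccard) between adjacent patterns is
realized by pulling their centres together with a bisection on the
measured overlap. Patterns are normalized to unit peak so `amplitude /
noise_sd` is the peak voxel-wise SNR. States are i.i.d. across frames
by default, matching the frame-exchangeable treatment of the method; a
Markov persistence option exists for precedence-test power studies, and
optional temporal Gaussian smoothing stands in for hemodynamic
blurring (no balloon-model realism is attempted, and no HRF
convolution is applied by default since the method operates on frames
directly).

What the generator does *not* emulate: spatially correlated scanner
noise, motion artifacts coupled to the signal, physiological
confounds, inter-subject anatomical variability, and graded (rather
than discrete) state mixtures. Passing recovery tests therefore shows
the estimator is correct under its own generative assumptions, not
that real data satisfy them.

## Validation design and problem sizes

The test suite validates each stage against independent oracles:
masking against exact counting, component filtering against planted
component sizes, the clustering objective against exhaustive
enumeration on 6-frame instances and against `stats::kmeans` on
standardized data, Z maps against per-voxel `t.test`, and the
permutation test against binomial calibration bounds.

The end-to-end recovery condition uses K = 8 disjoint 100-voxel states
on a 10 x 10 x 8 grid of 3 mm voxels, 10 subjects x 200 frames (2,000
frames), peak SNR 1, the standard conditioning (4 mm smoothing,
temporal normalization) and default masking, k = 8; adjusted Rand
index >= 0.9 is required, and the noiseless limit must be recovered
exactly. Statistical calibration uses 200 null replicates and a
planted 0.2 occurrence-rate gap (against within-group SD of about
0.02) at 1,000 permutations. These sizes were chosen as the smallest
at which the claimed behaviours are clearly separated from their
failure modes; `scripts/acceptance.R` re-runs the same computations
from scratch at any seed.

## Known limitations

* The correlation distance is undefined for constant frames; such
  frames must be excluded (the zero-variance check lists offenders).
* k-means with restarts is a local optimizer; the relocation polish
  reduces but does not eliminate dependence on initialization for
  large, weakly separated problems.
* The ideal band-pass assumes the session is long enough that
  frequency resolution (1 / (n TR)) is finer than the passband edges.
* Voxel ordering inside flattened frame vectors is the column-major
  order of in-mask voxels (x fastest), the native NIfTI serialization;
  any fixed order would do, and this one avoids a re-sort on every
  volume round-trip.
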