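Package: capkit
Title: Co-Activation Pattern Analysis of Resting-State fMRI Time Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Decomposes resting-state fMRI time series into spatial
    co-activation patterns (CAPs) by clustering individual time frames
    under a correlation distance. Implements per-voxel signal
    conditioning (detrending, band-pass filtering, nuisance regression,
    spatial smoothing, temporal normalization), supra-threshold frame
    masking with 3D connected-component filtering, frame-wise k-means
    minimizing the sum of within-cluster correlation distances, CAP
    summary maps (mean and Z-statistic maps, occurrence rates,
    within-cluster similarity, polarity), permutation tests on
    per-subject occurrence rates, and comparison utilities (seed
    correlation maps, sliding windows, spatial cross-correlation and
    map pairing, transition-asymmetry tests). Includes a synthetic-data
    generator with known latent states for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    mclust,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
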