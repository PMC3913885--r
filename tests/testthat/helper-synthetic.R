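# shared fixtures, all generated in code

make_grid <- function(dims = c(6L, 6L, 6L), vox = c(3, 3, 3)) {
  volume_grid(dims, voxel_size = vox)
}

full_mask <- function(dims = c(6L, 6L, 6L), vox = c(3, 3, 3)) {
  brain_mask(make_grid(dims, vox), array(TRUE, dims))
}

# a small planted-state dataset run through the conditioning pipeline
# (4 mm smoothing + temporal normalization), mirroring the study design
planted_study <- function(K = 8L, n_subjects = 10L,
                          frames_per_subject = 200L,
                          dims = c(10L, 10L, 8L), support = 100L,
                          amplitude = 1, noise_sd = 1, seed = 1L,
                          state_prob = NULL, groups = NULL) {
  mask <- full_mask(dims)
  pat <- generate_patterns(K, mask, support_voxels = support,
                           seed = seed)
  if (is.null(state_prob)) state_prob <- matrix(1 / K, 1, K)
  model <- latent_state_model(pat, state_prob, amplitude = amplitude,
                              noise_sd = noise_sd)
  sim <- simulate_dataset(model, n_subjects, frames_per_subject,
                          tr = 3, mask = mask, groups = groups,
                          seed = seed + 1L, as_volumes = TRUE)
  pre <- lapply(sim$volumes, function(v)
    preprocess_session(v, mask, tr = 3, fwhm = 4, low = NULL,
                       high = NULL, gsr = FALSE)$values)
  sim$frames_pre <- frame_matrix(do.call(rbind, pre), mask,
                                 sim$sessions)
  sim$mask <- mask
  sim$patterns <- pat
  sim
}

# definitional correlation-distance objective for a fixed assignment,
# with centroids refit as means of row-standardized members
oracle_J <- function(x, labels, k) {
  xs <- x - rowMeans(x)
  xs <- xs / sqrt(rowSums(xs^2))
  J <- 0
  for (i in seq_len(k)) {
    memb <- which(labels == i)
    if (length(memb) == 0L) next
    mu <- colMeans(xs[memb, , drop = FALSE])
    for (j in memb) J <- J + (1 - cor(x[j, ], mu))
  }
  J
}
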