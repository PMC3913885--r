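test_that("disjoint patterns have disjoint supports and near-zero correlation", {
  mask <- full_mask(c(10L, 10L, 8L))
  pat <- generate_patterns(8, mask, support_voxels = 100, seed = 2)
  expect_equal(dim(pat), c(8L, mask$m))
  expect_equal(unname(apply(pat, 1, max)), rep(1, 8))  # unit peak
  sup <- apply(pat, 1, function(v) which(v > 0))
  for (i in 1:7) for (j in (i + 1):8)
    expect_length(intersect(sup[, i], sup[, j]), 0)
  offdiag <- cor(t(pat)) - diag(8)
  expect_lt(max(abs(offdiag)), 0.15)
  # K = 1: a single normalized map
  p1 <- generate_patterns(1, mask, seed = 1)
  expect_equal(dim(p1), c(1L, mask$m))
  expect_equal(max(p1), 1)
})

test_that("requested support overlap is realized within tolerance", {
  mask <- full_mask(c(10L, 10L, 8L))
  for (f in c(0.2, 0.5)) {
    pat <- generate_patterns(4, mask, support_voxels = 100,
                             overlap_fraction = f, seed = 2)
    sup <- lapply(1:4, function(i) which(pat[i, ] > 0))
    jac <- vapply(1:3, function(i)
      length(intersect(sup[[i]], sup[[i + 1]])) /
        length(union(sup[[i]], sup[[i + 1]])), numeric(1))
    expect_true(all(abs(jac - f) < 0.1))
  }
  expect_error(generate_patterns(4, mask, overlap_fraction = 1), "overlap")
  expect_error(generate_patterns(20, full_mask(c(4L, 4L, 4L)),
                                 support_voxels = 60), "do not fit")
})

test_that("the noiseless limit reproduces patterns exactly and clusters perfectly", {
  mask <- full_mask(c(8L, 8L, 6L))
  pat <- generate_patterns(4, mask, support_voxels = 60, seed = 4)
  model <- latent_state_model(pat, matrix(0.25, 1, 4), noise_sd = 0)
  sim <- simulate_dataset(model, n_subjects = 2, frames_per_subject = 30,
                          mask = mask, seed = 5)
  for (j in seq_along(sim$labels))
    expect_equal(sim$frames$values[j, ], pat[sim$labels[j], ])
  fit <- kmeans_frames(sim$frames, k = 4, seed = 1)
  expect_equal(recovery_score(sim$labels, fit$labels)$accuracy, 1)
})

test_that("empirical state frequencies converge to the design probabilities", {
  prob <- c(0.5, 0.3, 0.2)
  model <- latent_state_model(matrix(rnorm(3 * 20), 3, 20),
                              matrix(prob, 1, 3), noise_sd = 0.5)
  sim <- simulate_dataset(model, n_subjects = 1,
                          frames_per_subject = 10000, seed = 6)
  emp <- tabulate(sim$labels, 3) / 10000
  expect_lt(max(abs(emp - prob)), 3 / sqrt(10000) + 0.015)
})

test_that("fixed seeds give bit-identical datasets", {
  mask <- full_mask(c(6L, 6L, 6L))
  pat <- generate_patterns(3, mask, seed = 7)
  model <- latent_state_model(pat, matrix(1 / 3, 1, 3))
  s1 <- simulate_dataset(model, 3, 20, mask = mask, seed = 9)
  s2 <- simulate_dataset(model, 3, 20, mask = mask, seed = 9)
  expect_identical(s1$frames$values, s2$frames$values)
  expect_identical(s1$labels, s2$labels)
  s3 <- simulate_dataset(model, 3, 20, mask = mask, seed = 10)
  expect_false(identical(s1$labels, s3$labels))
})

test_that("state sequences honour Markov persistence", {
  model <- latent_state_model(matrix(rnorm(2 * 10), 2, 10),
                              matrix(0.5, 1, 2), noise_sd = 0,
                              markov_persistence = 0.9)
  sim <- simulate_dataset(model, 1, 2000, seed = 11)
  stay <- mean(sim$labels[-1] == sim$labels[-2000])
  expect_gt(stay, 0.85)
})

test_that("invalid model specifications are rejected", {
  expect_error(latent_state_model(matrix(1, 2, 5), matrix(c(0.7, 0.7), 1, 2)),
               "sum to 1")
  expect_error(latent_state_model(matrix(1, 2, 5), matrix(0.5, 1, 2),
                                  noise_sd = -1), "noise_sd")
})

test_that("recovery scores are 1 for identity, ~0 for chance, 0.9 for 10% noise", {
  set.seed(71)
  z <- sample(1:5, 5000, replace = TRUE)
  expect_equal(recovery_score(z, z)$accuracy, 1)
  expect_equal(recovery_score(z, z)$ari, 1)
  z_rand <- sample(1:5, 5000, replace = TRUE)
  expect_lt(abs(recovery_score(z, z_rand)$ari), 0.05)
  z_corrupt <- z
  flip <- sample(5000, 500)
  z_corrupt[flip] <- sample(1:5, 500, replace = TRUE)
  acc <- recovery_score(z, z_corrupt)$accuracy
  expect_gt(acc, 0.88); expect_lt(acc, 0.95)
  # accuracy is invariant to relabeling the estimate
  perm <- c(3L, 1L, 2L, 5L, 4L)
  expect_equal(recovery_score(z, perm[z])$accuracy, 1)
  expect_error(recovery_score(1:3, 1:4), "length")
})

test_that("simulated occurrence matrices are valid rates", {
  occ <- simulate_occurrence(matrix(0.2, 6, 5), 100, seed = 3)
  expect_equal(unname(rowSums(occ)), rep(1, 6))
  expect_true(all(occ >= 0))
  expect_identical(occ, simulate_occurrence(matrix(0.2, 6, 5), 100,
                                            seed = 3))
})
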