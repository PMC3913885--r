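test_that("seed correlation maps hit the definitional extremes", {
  mask <- full_mask(c(6L, 6L, 6L))
  set.seed(61)
  n <- 50
  x <- matrix(rnorm(n * mask$m), n, mask$m)
  center <- voxel_to_mni(c(3L, 3L, 3L), mask$grid)
  seed_tc <- rowMeans(x[, capkit:::cube_voxels(center, mask, 6), drop = FALSE])
  x[, 1] <- seed_tc          # a voxel equal to the seed mean
  x[, 2] <- -seed_tc         # and its negation
  fm <- frame_matrix(x, mask)
  cmap <- seed_correlation_map(fm, center, cube_mm = 6)
  expect_equal(cmap[1], 1)
  expect_equal(cmap[2], -1)
  # matches a direct per-voxel correlation oracle
  seed_tc2 <- rowMeans(x[, capkit:::cube_voxels(center, mask, 6), drop = FALSE])
  oracle <- apply(x, 2L, function(v) cor(seed_tc2, v))
  expect_equal(cmap, oracle, tolerance = 1e-12)
  expect_error(seed_correlation_map(fm, c(1e4, 0, 0)), "no in-mask")
})

test_that("a 6 mm cube at 3 mm resolution holds 8 voxels", {
  mask <- full_mask(c(6L, 6L, 6L))
  center <- voxel_to_mni(c(3L, 3L, 3L), mask$grid) + c(1.5, 1.5, 1.5)
  expect_equal(length(capkit:::cube_voxels(center, mask, 6)), 8L)
})

test_that("seed maps recover a planted network", {
  # one planted state whose support is about a decile of the mask
  sim <- planted_study(K = 4, n_subjects = 2, frames_per_subject = 200,
                       dims = c(8L, 8L, 8L), support = 50, seed = 3)
  # seed at the peak voxel of pattern 1
  peak <- sim$mask$idx[which.max(sim$patterns[1, ])]
  center <- voxel_to_mni(arrayInd(peak, sim$mask$grid$dims)[1, ],
                         sim$mask$grid)
  cmap <- seed_correlation_map(sim$frames_pre, center, cube_mm = 6)
  top <- order(cmap, decreasing = TRUE)[seq_len(floor(sim$mask$m / 10))]
  support <- which(sim$patterns[1, ] > 0)
  jacc <- length(intersect(top, support)) / length(union(top, support))
  expect_gte(jacc, 0.5)
})

test_that("sliding windows reduce to the full seed map and expose transients", {
  mask <- full_mask(c(6L, 6L, 6L))
  set.seed(62)
  n <- 40
  x <- matrix(rnorm(n * mask$m), n, mask$m)
  st <- session_table("s1", "p1", "A", 1, n, 2)
  fm <- frame_matrix(x, mask, st)
  center <- voxel_to_mni(c(3L, 3L, 3L), mask$grid)
  sw <- sliding_window_map(fm, center, window_frames = n)
  expect_equal(nrow(sw$maps), 1L)
  expect_equal(sw$maps[1, ], seed_correlation_map(fm, center),
               tolerance = 1e-12)
  expect_error(sliding_window_map(fm, center, window_frames = n + 1),
               "longer than session")
  expect_error(sliding_window_map(fm, center, window_frames = 2), ">= 3")

  # a state active only in frames 10-16 (with frame-varying amplitude
  # shared by the seed region) dominates the covering window
  pattern <- rnorm(mask$m)
  xs <- matrix(rnorm(n * mask$m, sd = 0.3), n, mask$m)
  seed_vox <- capkit:::cube_voxels(center, mask, 6)
  amp <- c(1.5, 0.5, 2, 1, 2.5, 0.8, 1.8)
  xs[10:16, ] <- xs[10:16, ] + amp %o% pattern
  xs[10:16, seed_vox] <- xs[10:16, seed_vox] + amp
  w_in <- seed_correlation_map(frame_matrix(xs[10:16, ], mask), center)
  w_out <- seed_correlation_map(frame_matrix(xs[25:31, ], mask), center)
  r_in <- cor(w_in, pattern)
  r_out <- cor(w_out, pattern)
  expect_gt(r_in - r_out, 0.3)

  # stationarity: longer windows drift less from the full-session map
  full <- seed_correlation_map(fm, center)
  mad_for <- function(w) {
    sw <- sliding_window_map(fm, center, window_frames = w, step = 5)
    mean(abs(sweep(sw$maps, 2L, full)))
  }
  expect_lt(mad_for(30), mad_for(5))
})

test_that("spatial cross-correlation matches a per-pair oracle", {
  set.seed(63)
  A <- matrix(rnorm(4 * 100), 4, 100)
  B <- matrix(rnorm(3 * 100), 3, 100)
  cc <- spatial_corr_matrix(A, B)
  for (i in 1:4) for (j in 1:3)
    expect_equal(cc[i, j], cor(A[i, ], B[j, ]), tolerance = 1e-12)
  self <- spatial_corr_matrix(A, A)
  expect_equal(diag(self), rep(1, 4))
  expect_error(spatial_corr_matrix(rbind(A, 0), B), "zero-variance")
  expect_error(spatial_corr_matrix(A, B[, 1:50]), "voxel counts")
})

test_that("greedy pairing recovers permutations and reports leftovers", {
  corr <- matrix(0.05, 3, 3)
  corr[1, 2] <- 0.9; corr[2, 3] <- -0.8; corr[3, 1] <- 0.7
  res <- best_match_pairs(corr)
  expect_equal(res$pairs$j[order(res$pairs$i)], c(2L, 3L, 1L))
  expect_equal(res$pairs$r[res$pairs$i == 2], -0.8)  # |r| matching
  expect_length(res$unmatched_A, 0)

  res32 <- best_match_pairs(matrix(runif(6), 3, 2))
  expect_equal(nrow(res32$pairs), 2L)
  expect_length(res32$unmatched_A, 1L)

  # signed matching can differ
  signed <- best_match_pairs(corr, absolute = FALSE)
  expect_true(all(signed$pairs$r >= -1))
})

test_that("greedy pairing usually equals the optimal assignment", {
  # exhaustive max-weight matching oracle on 4 x 4 instances
  perms <- capkit:::permutations_of(4L)
  optimal <- function(w) {
    max(vapply(perms, function(p) sum(w[cbind(1:4, p)]), numeric(1)))
  }
  # instances structured like real cross-correlation matrices: one
  # strong partner per map over a weak background
  set.seed(64)
  agree <- 0L
  for (rep in 1:40) {
    perm <- sample(4)
    corr <- matrix(runif(16, -0.25, 0.25), 4, 4)
    corr[cbind(1:4, perm)] <- runif(4, 0.5, 0.95) *
      sample(c(-1, 1), 4, replace = TRUE)
    g <- best_match_pairs(corr)
    if (abs(sum(abs(g$pairs$r)) - optimal(abs(corr))) < 1e-12)
      agree <- agree + 1L
  }
  expect_gte(agree / 40, 0.9)
})

test_that("map distribution statistics flag asymmetric tails", {
  set.seed(65)
  sym <- rnorm(20000)
  expo <- rexp(20000) - 1        # heavy upper tail
  stats <- map_distribution_stats(rbind(sym, expo, -expo))
  expect_lt(abs(stats$skewness[1]), 0.1)
  expect_gt(stats$skewness[2], 1)
  expect_equal(stats$skewness[3], -stats$skewness[2], tolerance = 1e-12)
  expect_gt(stats$tail_asymmetry[2], 0)
  expect_lt(stats$tail_asymmetry[3], 0)
})

test_that("transition counts and asymmetry tests behave correctly", {
  st <- session_table("s1", "p1", "A", 1, 4, 2)
  pm <- precedence_matrix(c(1L, 2L, 1L, 2L), st, k = 2)
  expect_equal(pm$counts[1, 2], 2L)
  expect_equal(pm$counts[2, 1], 1L)
  # reversing the session's time axis transposes the count matrix
  pm_rev <- precedence_matrix(rev(c(1L, 2L, 1L, 2L)), st, k = 2)
  expect_equal(pm_rev$counts, t(pm$counts))
  # transitions never cross session boundaries
  st2 <- session_table(c("s1", "s2"), c("p1", "p2"), c("A", "A"),
                       c(1, 3), c(2, 4), 2)
  pm2 <- precedence_matrix(c(1L, 2L, 2L, 1L), st2, k = 2)
  expect_equal(sum(pm2$counts), 2L)
})

test_that("the asymmetry test is conservative under exchangeable labels", {
  set.seed(66)
  st <- session_table("s1", "p1", "A", 1, 300, 2)
  rejections <- 0L
  n_rep <- 100
  for (rep in seq_len(n_rep)) {
    labels <- sample(1:4, 300, replace = TRUE)
    pm <- precedence_matrix(labels, st, k = 4)
    if (any(pm$tests$p_bonferroni <= 0.05)) rejections <- rejections + 1L
  }
  # per-replicate family-wise rate is at most ~5%; allow the binomial
  # 99.5% upper bound for p = 0.05, n = 100
  expect_lte(rejections, qbinom(0.995, n_rep, 0.05))
})
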