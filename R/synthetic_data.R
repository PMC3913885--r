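# Evaluate `code` under a fixed RNG seed, restoring the caller's
# .Random.seed afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate latent co-activation patterns
#'
#' Builds K spatial patterns over the in-mask voxels, each a union of
#' Gaussian blobs on a spatially compact support. Pattern centres are
#' placed by farthest-point sampling so supports are well separated;
#' each support is grown as the `support_voxels` unused voxels nearest
#' its centre, so `overlap_fraction = 0` guarantees disjoint supports.
#' With `overlap_fraction > 0`, supports become the `support_voxels`
#' voxels nearest each centre and adjacent centres are pulled together
#' by bisection until the measured support Jaccard of each adjacent
#' pair matches the requested fraction.
#'
#' Patterns are normalized to unit peak (maximum value 1), so the
#' simulator's `amplitude` is the per-voxel peak signal change and
#' `amplitude / noise_sd` is the peak voxel-wise SNR.
#'
#' @param K number of patterns (>= 1).
#' @param mask a [brain_mask()].
#' @param support_voxels voxels per pattern support; default
#'   `floor(mask$m / K)`.
#' @param overlap_fraction target support Jaccard between adjacent
#'   patterns, in \[0, 1).
#' @param n_blobs Gaussian bumps per pattern (default 3).
#' @param seed RNG seed for blob placement.
#' @return K x m matrix of unit-peak patterns.
#' @export
generate_patterns <- function(K, mask, support_voxels = NULL,
                              overlap_fraction = 0, n_blobs = 3,
                              seed = 1L) {
  stopifnot(inherits(mask, "brain_mask"), K >= 1)
  if (overlap_fraction < 0 || overlap_fraction >= 1)
    stop("`overlap_fraction` must be in [0, 1)")
  m <- mask$m
  if (is.null(support_voxels)) support_voxels <- max(1L, floor(m / K))
  s <- as.integer(support_voxels)
  if (overlap_fraction == 0 && K * s > m)
    stop("patterns do not fit: need ", K * s, " voxels, mask has ", m)
  if (overlap_fraction > 0 && s > m)
    stop("support larger than mask")
  coords <- arrayInd(mask$idx, mask$grid$dims)
  mm <- t(mask$grid$affine %*% rbind(t(coords) - 1, 1))[, 1:3, drop = FALSE]
  # farthest-point seeding of pattern centres
  centres <- integer(K)
  centres[1] <- which.min(rowSums(sweep(mm, 2L, colMeans(mm))^2))
  d_near <- sqrt(rowSums(sweep(mm, 2L, mm[centres[1], ])^2))
  if (K > 1) for (i in 2:K) {
    centres[i] <- which.max(d_near)
    d_near <- pmin(d_near, sqrt(rowSums(sweep(mm, 2L, mm[centres[i], ])^2)))
  }
  supports <- vector("list", K)
  if (overlap_fraction == 0) {
    used <- rep(FALSE, m)
    for (i in seq_len(K)) {
      d <- rowSums(sweep(mm, 2L, mm[centres[i], ])^2)
      d[used] <- Inf
      sel <- order(d)[seq_len(s)]
      used[sel] <- TRUE
      supports[[i]] <- sel
    }
  } else {
    nearest_s <- function(point) {
      order(rowSums(sweep(mm, 2L, point)^2))[seq_len(s)]
    }
    jacc <- function(a, b)
      length(intersect(a, b)) / length(union(a, b))
    pos <- mm[centres[1], ]
    supports[[1]] <- nearest_s(pos)
    prev_pos <- pos
    for (i in seq_len(K)[-1]) {
      orig <- mm[centres[i], ]
      lo <- 0; hi <- 1
      for (it in 1:20) {
        t <- (lo + hi) / 2
        cand <- nearest_s((1 - t) * orig + t * prev_pos)
        if (jacc(supports[[i - 1L]], cand) < overlap_fraction)
          lo <- t else hi <- t
      }
      t <- (lo + hi) / 2
      supports[[i]] <- nearest_s((1 - t) * orig + t * prev_pos)
      prev_pos <- (1 - t) * orig + t * prev_pos
    }
  }
  pat <- matrix(0, K, m)
  with_seed(seed, {
    for (i in seq_len(K)) {
      sup <- supports[[i]]
      blob_centres <- sup[sample.int(length(sup),
                                     min(n_blobs, length(sup)))]
      # kernel width scaled to the support's spatial extent
      sigma <- max(mean(mask$grid$voxel_size),
                   max(stats::dist(mm[c(blob_centres, centres[i]), ,
                                      drop = FALSE])) / 3)
      val <- numeric(length(sup))
      for (cc in blob_centres) {
        d2 <- rowSums(sweep(mm[sup, , drop = FALSE], 2L, mm[cc, ])^2)
        val <- val + exp(-d2 / (2 * sigma^2))
      }
      pat[i, sup] <- val
      pat[i, ] <- pat[i, ] / max(pat[i, ])
    }
  })
  pat
}

#' Latent-state model of concatenated resting scans
#'
#' The generative model behind the synthetic datasets: each time frame
#' of each subject is drawn from one of K latent spatial co-activation
#' states; frame t of subject s equals
#' `amplitude * pattern[z_st] + N(0, noise_sd)` voxel-wise, with the
#' state `z_st` drawn i.i.d. (or with Markov persistence) from subject
#' s's state-probability row.
#'
#' @param patterns K x m matrix of state patterns (rows unit-norm, e.g.
#'   from [generate_patterns()]).
#' @param state_prob n_subjects x K matrix of per-subject state
#'   probabilities; rows must sum to 1. A single row is recycled.
#' @param amplitude signal scale (default 1).
#' @param noise_sd Gaussian noise SD per voxel (default 1); with
#'   unit-norm patterns, `amplitude / noise_sd` sets the per-frame SNR.
#' @param hrf_fwhm_s optional temporal Gaussian smoothing FWHM in
#'   seconds (0 = none), a stand-in for hemodynamic blurring.
#' @param markov_persistence probability of staying in the current state
#'   (0 = i.i.d. states, the default frame-exchangeable regime).
#' @return An object of class `latent_state_model`.
#' @export
latent_state_model <- function(patterns, state_prob, amplitude = 1,
                               noise_sd = 1, hrf_fwhm_s = 0,
                               markov_persistence = 0) {
  patterns <- as.matrix(patterns)
  state_prob <- matrix(as.numeric(state_prob), ncol = nrow(patterns))
  if (any(abs(rowSums(state_prob) - 1) > 1e-8))
    stop("state_prob rows must sum to 1")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(patterns = patterns, state_prob = state_prob,
                 K = nrow(patterns), amplitude = amplitude,
                 noise_sd = noise_sd, hrf_fwhm_s = hrf_fwhm_s,
                 markov_persistence = markov_persistence),
            class = "latent_state_model")
}

# one subject's state sequence
simulate_state_sequence <- function(prob, n, persistence = 0) {
  K <- length(prob)
  if (persistence <= 0) return(sample.int(K, n, replace = TRUE, prob = prob))
  z <- integer(n)
  z[1] <- sample.int(K, 1, prob = prob)
  for (t in seq_len(n - 1L)) {
    z[t + 1L] <- if (runif(1) < persistence) z[t] else
      sample.int(K, 1, prob = prob)
  }
  z
}

#' Simulate a concatenated multi-subject dataset
#'
#' @param model a [latent_state_model()].
#' @param n_subjects number of subjects (one session each).
#' @param frames_per_subject frames per session.
#' @param tr repetition time in seconds (default 3).
#' @param mask optional [brain_mask()]; when given, the returned frames
#'   are a full `frame_matrix` on it and `volumes` can be reconstructed.
#' @param groups optional per-subject group labels (default all "A").
#' @param seed RNG seed; fixed seed gives bit-identical datasets.
#' @param as_volumes also return per-subject 4D arrays (requires
#'   `mask`; off by default to save memory).
#' @return list with `frames` (n x m matrix, or `frame_matrix` when a
#'   mask is given), `labels` (ground-truth states), `sessions`
#'   ([session_table()]), `motion` (list of per-session n x 6 stub
#'   traces), `occurrence_true` (subjects x K empirical state
#'   frequencies), and optionally `volumes`.
#' @export
simulate_dataset <- function(model, n_subjects, frames_per_subject,
                             tr = 3, mask = NULL, groups = NULL,
                             seed = 1L, as_volumes = FALSE) {
  stopifnot(inherits(model, "latent_state_model"))
  if (as_volumes && is.null(mask))
    stop("`as_volumes` requires a mask")
  m <- ncol(model$patterns)
  if (!is.null(mask) && mask$m != m)
    stop("mask voxel count != pattern length")
  prob <- model$state_prob
  if (nrow(prob) == 1L) prob <- prob[rep(1L, n_subjects), , drop = FALSE]
  if (nrow(prob) != n_subjects)
    stop("state_prob rows != n_subjects")
  if (is.null(groups)) groups <- rep("A", n_subjects)
  n <- n_subjects * frames_per_subject
  labels <- integer(n)
  x <- matrix(0, n, m)
  motion <- vector("list", n_subjects)
  with_seed(seed, {
    for (s in seq_len(n_subjects)) {
      rows <- (s - 1L) * frames_per_subject + seq_len(frames_per_subject)
      z <- simulate_state_sequence(prob[s, ], frames_per_subject,
                                   model$markov_persistence)
      labels[rows] <- z
      sig <- model$amplitude * model$patterns[z, , drop = FALSE]
      if (model$noise_sd > 0)
        sig <- sig + matrix(rnorm(length(rows) * m, sd = model$noise_sd),
                            length(rows), m)
      if (model$hrf_fwhm_s > 0)
        sig <- temporal_gaussian_smooth(sig, model$hrf_fwhm_s / tr)
      x[rows, ] <- sig
      motion[[s]] <- matrix(rnorm(frames_per_subject * 6, sd = 0.02),
                            frames_per_subject, 6)
    }
  })
  sessions <- session_table(
    session_id = sprintf("ses%03d", seq_len(n_subjects)),
    subject_id = sprintf("sub%03d", seq_len(n_subjects)),
    group_label = groups,
    frame_start = (seq_len(n_subjects) - 1L) * frames_per_subject + 1L,
    frame_stop = seq_len(n_subjects) * frames_per_subject,
    tr = tr)
  occurrence_true <- t(vapply(seq_len(n_subjects), function(s) {
    rows <- (s - 1L) * frames_per_subject + seq_len(frames_per_subject)
    tabulate(labels[rows], nbins = model$K) / frames_per_subject
  }, numeric(model$K)))
  frames <- if (is.null(mask)) x else frame_matrix(x, mask, sessions)
  out <- list(frames = frames, labels = labels, sessions = sessions,
              motion = motion, occurrence_true = occurrence_true)
  if (as_volumes) {
    out$volumes <- lapply(seq_len(n_subjects), function(s) {
      rows <- (s - 1L) * frames_per_subject + seq_len(frames_per_subject)
      arr <- array(0, c(mask$grid$dims, frames_per_subject))
      for (j in seq_along(rows))
        arr[, , , j] <- volume_from_vector(x[rows[j], ], mask)
      arr
    })
  }
  out
}

# FWHM given in frames; truncated normalized kernel per column
temporal_gaussian_smooth <- function(x, fwhm_frames) {
  s <- fwhm_frames / (2 * sqrt(2 * log(2)))
  if (s <= 0) return(x)
  half <- max(1L, ceiling(4 * s))
  kern <- exp(-(seq(-half, half))^2 / (2 * s^2))
  n <- nrow(x)
  acc <- matrix(0, n, ncol(x)); wsum <- numeric(n)
  for (o in seq(-half, half)) {
    w <- kern[o + half + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + w * x[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  acc / wsum
}

#' Simulate per-subject occurrence matrices only
#'
#' Multinomial sampling of frame counts per state, without generating
#' voxel data; used for calibrating the occurrence-rate permutation
#' test.
#'
#' @param state_prob n_subjects x K probability matrix (rows sum to 1).
#' @param frames_per_subject frames per session.
#' @param seed RNG seed.
#' @return subjects x K occurrence matrix (rows sum to 1).
#' @export
simulate_occurrence <- function(state_prob, frames_per_subject, seed = 1L) {
  state_prob <- as.matrix(state_prob)
  with_seed(seed, {
    t(apply(state_prob, 1L, function(p)
      as.numeric(stats::rmultinom(1, frames_per_subject, p)) /
        frames_per_subject))
  })
}

#' Score recovery of ground-truth frame labels
#'
#' Accuracy under the best one-to-one label matching (optimal over all
#' permutations for K <= 8, greedy on the confusion matrix beyond), and
#' the adjusted Rand index as a chance-corrected agreement measure.
#'
#' @param true_labels,labels integer label vectors of equal length.
#' @return list(accuracy, ari, permutation) where `permutation[i]` is
#'   the estimated cluster matched to true state i.
#' @export
recovery_score <- function(true_labels, labels) {
  if (length(true_labels) != length(labels))
    stop("label vectors differ in length")
  kt <- max(true_labels); ke <- max(labels)
  K <- max(kt, ke)
  conf <- matrix(0L, K, K)
  for (t in seq_along(true_labels))
    conf[true_labels[t], labels[t]] <- conf[true_labels[t], labels[t]] + 1L
  perm <- best_assignment(conf)
  acc <- sum(conf[cbind(seq_len(K), perm)]) / length(true_labels)
  list(accuracy = acc,
       ari = mclust::adjustedRandIndex(true_labels, labels),
       permutation = perm)
}

# maximize trace of conf[, perm]: exhaustive for small K, greedy beyond
best_assignment <- function(conf) {
  K <- nrow(conf)
  if (K <= 8L) {
    perms <- permutations_of(K)
    scores <- vapply(perms, function(p)
      sum(conf[cbind(seq_len(K), p)]), numeric(1))
    perms[[which.max(scores)]]
  } else {
    perm <- integer(K)
    free <- rep(TRUE, K)
    for (step in seq_len(K)) {
      sub <- conf
      sub[perm > 0, ] <- -1L
      sub[, !free] <- -1L
      best <- which(sub == max(sub), arr.ind = TRUE)[1, ]
      perm[best[1]] <- best[2]
      free[best[2]] <- FALSE
    }
    perm
  }
}

permutations_of <- function(K) {
  if (K == 1L) return(list(1L))
  sub <- permutations_of(K - 1L)
  out <- vector("list", K * length(sub))
  i <- 0L
  for (p in sub) for (pos in seq_len(K)) {
    i <- i + 1L
    out[[i]] <- append(p, K, after = pos - 1L)
  }
  out
}
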