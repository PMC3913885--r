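#' A named set of spatial maps on a shared brain mask
#'
#' @param name label for the set (e.g. "CAPs", "ICs", "TFMs").
#' @param maps q x m numeric matrix, one map per row, in the mask's
#'   fixed voxel order.
#' @param mask the shared [brain_mask()] (optional but recommended).
#' @return An object of class `map_set`.
#' @export
map_set <- function(name, maps, mask = NULL) {
  maps <- as.matrix(maps)
  if (nrow(maps) < 1L) stop("need at least one map")
  if (!is.null(mask) && ncol(maps) != mask$m)
    stop("maps have ", ncol(maps), " voxels but mask has ", mask$m)
  structure(list(name = name, maps = maps, mask = mask),
            class = "map_set")
}

#' Read a map set from a 4D NIfTI file
#'
#' @param path 4D NIfTI file, one volume per map.
#' @param mask [brain_mask()] used to flatten each volume.
#' @param name set label (defaults to the file name).
#' @return A `map_set`.
#' @export
read_map_set <- function(path, mask, name = basename(path)) {
  loaded <- load_4d(path)
  fm <- frames_from_4d(loaded$data, mask)
  map_set(name, fm$values, mask)
}

# voxels whose centers lie within +/- cube_mm/2 of `center` on every axis
cube_voxels <- function(center, mask, cube_mm = 6) {
  g <- mask$grid
  dims <- g$dims
  coords <- arrayInd(mask$idx, dims)
  mm <- t(g$affine %*% rbind(t(coords) - 1, 1))[, 1:3, drop = FALSE]
  inside <- abs(mm[, 1] - center[1]) <= cube_mm / 2 &
            abs(mm[, 2] - center[2]) <= cube_mm / 2 &
            abs(mm[, 3] - center[3]) <= cube_mm / 2
  which(inside)
}

#' Seed-based correlation map
#'
#' The seed time course is the mean over in-mask voxels inside an
#' axis-aligned cube (default 6 x 6 x 6 mm, i.e. 2 x 2 x 2 voxels at
#' 3 mm resolution) centred at an MNI coordinate; the map is the Pearson
#' correlation of every in-mask voxel's time course with the seed.
#'
#' @param frames a `frame_matrix`.
#' @param center MNI mm triple, e.g. the PCC seed `c(0, -53, 26)`.
#' @param cube_mm cube side length in mm (default 6).
#' @return Numeric vector of length m (one r per in-mask voxel).
#' @export
seed_correlation_map <- function(frames, center, cube_mm = 6) {
  stopifnot(inherits(frames, "frame_matrix"))
  sel <- cube_voxels(center, frames$mask, cube_mm)
  if (length(sel) == 0L)
    stop("seed cube at (", paste(center, collapse = ", "),
         ") contains no in-mask voxels")
  seed <- rowMeans(frames$values[, sel, drop = FALSE])
  drop(stats::cor(seed, frames$values))
}

#' Default seed coordinates (MNI mm)
#'
#' Standard resting-state seeds: posterior cingulate cortex, medial
#' prefrontal cortex, left intraparietal sulcus, and left motor cortex.
#'
#' @return Named list of MNI mm triples.
#' @export
default_seeds <- function() {
  list(PCC = c(0, -53, 26), mPFC = c(0, 52, -6),
       IPS = c(-24, -58, 52), motor = c(-36, -25, 57))
}

#' Sliding-window seed correlation maps
#'
#' Computes [seed_correlation_map()] on each contiguous window of
#' `window_frames` frames; windows never cross session boundaries. Short
#' windows expose the dependence of seed maps on analysis-window
#' position that single-frame clustering avoids.
#'
#' @param frames a `frame_matrix` (sessions taken from its
#'   `session_table`; a single session is assumed if absent).
#' @param center MNI mm seed centre.
#' @param window_frames window length in frames (>= 3).
#' @param step window step (default 1).
#' @param cube_mm cube side length in mm.
#' @return data.frame-like list: `maps` (windows x m matrix), `start`
#'   (first frame of each window), `session_id`.
#' @export
sliding_window_map <- function(frames, center, window_frames, step = 1L,
                               cube_mm = 6) {
  stopifnot(inherits(frames, "frame_matrix"))
  if (window_frames < 3L) stop("`window_frames` must be >= 3")
  sess <- session_of_frames(frames)
  out_maps <- list(); out_start <- integer(0); out_sess <- character(0)
  for (sid in unique(sess)) {
    fr <- which(sess == sid)
    if (window_frames > length(fr))
      stop("window (", window_frames, ") longer than session ", sid,
           " (", length(fr), " frames)")
    starts <- seq(1L, length(fr) - window_frames + 1L, by = step)
    for (s0 in starts) {
      win <- fr[s0:(s0 + window_frames - 1L)]
      sub <- frame_matrix(frames$values[win, , drop = FALSE], frames$mask)
      out_maps[[length(out_maps) + 1L]] <-
        seed_correlation_map(sub, center, cube_mm)
      out_start <- c(out_start, fr[s0])
      out_sess <- c(out_sess, sid)
    }
  }
  list(maps = do.call(rbind, out_maps), start = out_start,
       session_id = out_sess)
}

#' Spatial cross-correlation matrix between two map sets
#'
#' Entry (i, j) is the Pearson correlation of map i of `A` with map j of
#' `B` over the shared in-mask voxels.
#'
#' @param A,B `map_set` objects (or plain q x m matrices) on the same
#'   mask.
#' @return q_A x q_B numeric matrix.
#' @export
spatial_corr_matrix <- function(A, B) {
  a <- if (inherits(A, "map_set")) A$maps else as.matrix(A)
  b <- if (inherits(B, "map_set")) B$maps else as.matrix(B)
  if (ncol(a) != ncol(b)) stop("map sets have different voxel counts")
  if (any(apply(a, 1, stats::sd) == 0) || any(apply(b, 1, stats::sd) == 0))
    stop("zero-variance map")
  stats::cor(t(a), t(b))
}

#' Pair maps across two sets by highest spatial correlation
#'
#' Greedy matching without replacement on the cross-correlation matrix:
#' repeatedly take the unmatched (i, j) pair with the largest |r|
#' (or signed r with `absolute = FALSE`), ties broken by (i, j) order.
#' Absolute correlation is the default because ICA map signs are
#' arbitrary.
#'
#' @param corr q_A x q_B cross-correlation matrix from
#'   [spatial_corr_matrix()].
#' @param absolute match on |r| (default TRUE).
#' @return list with `pairs` (data.frame i, j, r, in matching order) and
#'   `unmatched_A`, `unmatched_B` (indices left unpaired).
#' @export
best_match_pairs <- function(corr, absolute = TRUE) {
  corr <- as.matrix(corr)
  score <- if (absolute) abs(corr) else corr
  qa <- nrow(corr); qb <- ncol(corr)
  free_a <- rep(TRUE, qa); free_b <- rep(TRUE, qb)
  pairs <- data.frame(i = integer(0), j = integer(0), r = numeric(0))
  for (step in seq_len(min(qa, qb))) {
    sub <- score
    sub[!free_a, ] <- -Inf
    sub[, !free_b] <- -Inf
    best <- which(sub == max(sub), arr.ind = TRUE)
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
    pairs <- rbind(pairs, data.frame(i = best[1], j = best[2],
                                     r = corr[best[1], best[2]]))
    free_a[best[1]] <- FALSE
    free_b[best[2]] <- FALSE
  }
  rownames(pairs) <- NULL
  list(pairs = pairs, unmatched_A = which(free_a),
       unmatched_B = which(free_b))
}

#' Distribution diagnostics of map statistics
#'
#' Per map: the sample skewness (third standardized moment) and a tail
#' asymmetry index, the sum of the 99th and 1st percentiles (positive
#' when the upper tail is heavier — the signature that distinguishes ICA
#' z-statistic maps, which lack significantly negative values, from
#' CAPs).
#'
#' @param maps a `map_set` or q x m matrix.
#' @return data.frame (map_id, skewness, tail_asymmetry).
#' @export
map_distribution_stats <- function(maps) {
  x <- if (inherits(maps, "map_set")) maps$maps else as.matrix(maps)
  skew <- apply(x, 1L, function(v) {
    v <- v - mean(v)
    m2 <- mean(v^2)
    if (m2 == 0) return(0)
    mean(v^3) / m2^1.5
  })
  tails <- apply(x, 1L, function(v) {
    q <- quantile(v, c(0.01, 0.99), names = FALSE)
    q[1] + q[2]
  })
  data.frame(map_id = seq_len(nrow(x)), skewness = skew,
             tail_asymmetry = tails)
}

#' CAP transition counts and temporal-precedence test
#'
#' Counts label transitions between consecutive frames within each
#' session, then tests each unordered CAP pair (i, j) for asymmetry —
#' whether i tends to precede j more often than the reverse — with a
#' two-sided exact binomial test of count(i -> j) against
#' count(j -> i) under p = 1/2, Bonferroni-corrected over the
#' k(k-1)/2 pairs. Self-transitions are counted but not tested.
#'
#' @param assignment a `cap_clustering` or integer label vector.
#' @param sessions a [session_table()]; transitions never cross session
#'   boundaries.
#' @param k number of CAPs.
#' @return list with `counts` (k x k matrix, entry (i, j) =
#'   count(i -> j)) and `tests` (data.frame i, j, n_ij, n_ji, p_raw,
#'   p_bonferroni).
#' @export
precedence_matrix <- function(assignment, sessions, k = NULL) {
  labels <- if (inherits(assignment, "cap_clustering")) assignment$labels else as.integer(assignment)
  if (is.null(k))
    k <- if (inherits(assignment, "cap_clustering")) assignment$k else max(labels)
  validate_sessions(sessions, length(labels))
  counts <- matrix(0L, k, k)
  for (r in seq_len(nrow(sessions))) {
    fr <- sessions$frame_start[r]:sessions$frame_stop[r]
    if (length(fr) < 2L) next
    from <- labels[fr[-length(fr)]]
    to <- labels[fr[-1L]]
    for (t in seq_along(from))
      counts[from[t], to[t]] <- counts[from[t], to[t]] + 1L
  }
  n_tests <- k * (k - 1) / 2
  tests <- do.call(rbind, lapply(seq_len(k - 1L), function(i) {
    do.call(rbind, lapply(seq((i + 1L), k), function(j) {
      nij <- counts[i, j]; nji <- counts[j, i]
      p <- if (nij + nji == 0) 1 else
        stats::binom.test(nij, nij + nji, p = 0.5)$p.value
      data.frame(i = i, j = j, n_ij = nij, n_ji = nji, p_raw = p,
                 p_bonferroni = min(1, n_tests * p))
    }))
  }))
  rownames(tests) <- NULL
  list(counts = counts, tests = tests)
}
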