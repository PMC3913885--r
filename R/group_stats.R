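#' Session bookkeeping table
#'
#' One row per scanning session (one session per subject in the default
#' design): subject id, group label, the 1-based frame range the session
#' occupies in the concatenated frame matrix, and the repetition time.
#' Frame ranges must be disjoint, contiguous, and cover 1..n exactly.
#'
#' @param session_id,subject_id,group_label character vectors.
#' @param frame_start,frame_stop 1-based inclusive frame ranges.
#' @param tr repetition time(s) in seconds (> 0).
#' @return A data.frame of class `session_table`.
#' @export
session_table <- function(session_id, subject_id, group_label,
                          frame_start, frame_stop, tr) {
  st <- data.frame(session_id = as.character(session_id),
                   subject_id = as.character(subject_id),
                   group_label = as.character(group_label),
                   frame_start = as.integer(frame_start),
                   frame_stop = as.integer(frame_stop),
                   tr = as.numeric(tr))
  class(st) <- c("session_table", "data.frame")
  validate_sessions(st)
  st
}

validate_sessions <- function(st, n_frames = NULL) {
  if (any(st$tr <= 0)) stop("TR must be positive")
  if (any(st$frame_stop < st$frame_start)) stop("empty frame range")
  o <- order(st$frame_start)
  starts <- st$frame_start[o]; stops <- st$frame_stop[o]
  if (starts[1] != 1L || any(starts[-1] != stops[-length(stops)] + 1L))
    stop("session frame ranges must be contiguous and start at 1")
  if (!is.null(n_frames) && stops[length(stops)] != n_frames)
    stop("session frame ranges cover 1..", stops[length(stops)],
         " but there are ", n_frames, " frames")
  invisible(st)
}

#' Read / write session tables as TSV
#'
#' @param path TSV file with a header row and columns session_id,
#'   subject_id, group_label, frame_start, frame_stop, tr.
#' @return A `session_table`.
#' @export
read_session_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  do.call(session_table, df[c("session_id", "subject_id", "group_label",
                              "frame_start", "frame_stop", "tr")])
}

#' @rdname read_session_table
#' @param st a `session_table`.
#' @export
write_session_table <- function(st, path) {
  write.table(st, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-subject CAP occurrence matrix
#'
#' Entry (s, i) is the fraction of subject s's frames assigned to CAP i:
#' the per-session occurrence rate. Rows sum to 1; weighting rows by
#' frame counts recovers the global occurrence rates.
#'
#' @param assignment a `cap_clustering` or integer label vector.
#' @param sessions a [session_table()].
#' @param k number of CAPs (defaults from the assignment).
#' @return subjects x k matrix with subject ids as row names.
#' @export
session_occurrence_matrix <- function(assignment, sessions, k = NULL) {
  labels <- if (inherits(assignment, "cap_clustering")) assignment$labels else as.integer(assignment)
  if (is.null(k))
    k <- if (inherits(assignment, "cap_clustering")) assignment$k else max(labels)
  validate_sessions(sessions, length(labels))
  subjects <- unique(sessions$subject_id)
  occ <- matrix(0, length(subjects), k,
                dimnames = list(subjects, NULL))
  for (s in seq_along(subjects)) {
    rows <- sessions[sessions$subject_id == subjects[s], , drop = FALSE]
    fr <- unlist(mapply(seq, rows$frame_start, rows$frame_stop,
                        SIMPLIFY = FALSE))
    if (length(fr) == 0L) stop("subject ", subjects[s], " has no frames")
    occ[s, ] <- tabulate(labels[fr], nbins = k) / length(fr)
  }
  occ
}

#' Permutation test on per-subject occurrence rates
#'
#' Tests, per CAP, whether mean occurrence differs between two groups.
#' The statistic is the difference of group means; the null distribution
#' is built by randomly re-assigning subjects to two groups of the
#' observed sizes. Two-sided p-values use the add-one estimator
#' `p = (1 + #\{|null| >= |obs|\}) / (n_perm + 1)` (never exactly zero)
#' and a Bonferroni correction `min(1, k p)` is applied over the k CAPs.
#'
#' @param occurrence subjects x k matrix from
#'   [session_occurrence_matrix()].
#' @param groups two-level factor/character vector, one entry per
#'   subject (row).
#' @param n_perm number of permutations (default 50000).
#' @param seed RNG seed for the permutations.
#' @return data.frame (cap_id, mean_groupA, mean_groupB, diff, p_raw,
#'   p_bonferroni), with attribute `groups` naming the two levels in
#'   (A, B) order.
#' @export
permutation_test <- function(occurrence, groups, n_perm = 50000L,
                             seed = 1L) {
  occurrence <- as.matrix(occurrence)
  if (n_perm < 1L) stop("`n_perm` must be >= 1")
  lev <- unique(as.character(groups))
  if (length(lev) != 2L) stop("exactly two group levels required, got ",
                              length(lev))
  gA <- which(groups == lev[1]); gB <- which(groups == lev[2])
  n <- nrow(occurrence); k <- ncol(occurrence)
  if (length(gA) == 0L || length(gB) == 0L) stop("a group is empty")
  mA <- colMeans(occurrence[gA, , drop = FALSE])
  mB <- colMeans(occurrence[gB, , drop = FALSE])
  obs <- mA - mB
  rng <- make_rng(seed)
  nA <- length(gA)
  # indicator matrix of permuted group-A memberships, then one matrix
  # product gives all null statistics at once
  perm_idx <- rng(function()
    vapply(seq_len(n_perm), function(i) sample.int(n, nA), integer(nA)))
  ind <- matrix(0, n_perm, n)
  ind[cbind(rep(seq_len(n_perm), each = nA), as.vector(perm_idx))] <- 1
  sumA <- ind %*% occurrence
  total <- matrix(colSums(occurrence), n_perm, k, byrow = TRUE)
  null_diff <- sumA / nA - (total - sumA) / (n - nA)
  exceed <- colSums(abs(null_diff) >= matrix(abs(obs), n_perm, k,
                                             byrow = TRUE))
  p_raw <- (1 + exceed) / (n_perm + 1)
  res <- data.frame(cap_id = seq_len(k),
                    mean_groupA = mA, mean_groupB = mB, diff = obs,
                    p_raw = p_raw,
                    p_bonferroni = pmin(1, k * p_raw))
  attr(res, "groups") <- lev
  res
}

#' Head-motion summary of a session
#'
#' For each pair of consecutive frames, the displacement is the
#' Euclidean norm of the difference of the 3 translation parameters
#' (the Van Dijk convention); `mean_translation` averages these over
#' pairs, and `mean_rotation` is computed analogously on the rotation
#' columns. `rms = "mean_square"` switches to the square root of the
#' mean squared component difference.
#'
#' @param trace n x 6 matrix: translations (mm) in columns 1-3,
#'   rotations in columns 4-6 (radians; set `degrees = TRUE` to convert).
#' @param rms "euclidean" (default) or "mean_square".
#' @param degrees rotations are in degrees and should be converted to
#'   radians first.
#' @return list(mean_translation, mean_rotation).
#' @export
motion_summary <- function(trace, rms = c("euclidean", "mean_square"),
                           degrees = FALSE) {
  rms <- match.arg(rms)
  trace <- as.matrix(trace)
  if (nrow(trace) < 2L) stop("need at least 2 frames")
  if (ncol(trace) != 6L) stop("motion trace must have 6 columns")
  if (degrees) trace[, 4:6] <- trace[, 4:6] * pi / 180
  dd <- diff(trace)
  per_pair <- function(cols) {
    sq <- rowSums(dd[, cols, drop = FALSE]^2)
    if (rms == "euclidean") mean(sqrt(sq)) else mean(sqrt(sq / 3))
  }
  list(mean_translation = per_pair(1:3), mean_rotation = per_pair(4:6))
}

#' Read motion parameters from whitespace-delimited text
#'
#' One row per frame, six columns: 3 translations in mm, then 3
#' rotations.
#'
#' @param path text file path.
#' @return n x 6 numeric matrix.
#' @export
read_motion <- function(path) {
  m <- as.matrix(read.table(path, header = FALSE))
  if (ncol(m) != 6L) stop("expected 6 motion columns, got ", ncol(m))
  unname(m)
}
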