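#' Compute CAP maps and per-CAP metrics from a clustering
#'
#' Frames assigned to the same cluster are simply averaged to form the k
#' co-activation patterns (CAPs); averaging always uses the unmasked
#' frames, regardless of any supra-threshold masking applied for the
#' clustering distances. Each mean map is also normalized per voxel by
#' the standard error across member frames to give a Z-statistic map,
#' and three per-CAP summaries are computed:
#'
#' * occurrence: fraction of all frames in the cluster;
#' * similarity: mean spatial correlation of member frames to their mean;
#' * polarity: mean of the strictly positive map values plus the mean of
#'   the strictly negative values (sign says whether activation or
#'   de-activation dominates).
#'
#' CAPs are ranked by similarity, descending (ties by cluster id). The
#' standard error uses the unbiased (n-1) SD; single-member clusters and
#' zero-SD voxels get Z = 0, with a warning for the former. The
#' "Z-statistic" label follows field convention although the quantity is
#' a per-voxel one-sample t statistic; no normal-quantile conversion is
#' applied.
#'
#' @param frames a `frame_matrix` of unmasked (conditioned) frames, or a
#'   plain n x m matrix.
#' @param assignment a `cap_clustering` (or plain integer label vector in
#'   1..k) with one label per frame.
#' @param k number of CAPs; defaults to `assignment$k` or `max(labels)`.
#' @return An object of class `cap_set`: list with `mean_maps` (k x m),
#'   `z_maps` (k x m), `n_members`, `occurrence`, `similarity`,
#'   `polarity`, `rank`, `k`.
#' @export
compute_caps <- function(frames, assignment, k = NULL) {
  x <- if (inherits(frames, "frame_matrix")) frames$values else as.matrix(frames)
  labels <- if (inherits(assignment, "cap_clustering")) assignment$labels else as.integer(assignment)
  if (length(labels) != nrow(x))
    stop("assignment length != frame count")
  if (is.null(k))
    k <- if (inherits(assignment, "cap_clustering")) assignment$k else max(labels)
  n <- nrow(x); m <- ncol(x)
  mean_maps <- matrix(0, k, m)
  z_maps <- matrix(0, k, m)
  n_members <- integer(k)
  similarity <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    memb <- which(labels == i)
    n_i <- length(memb)
    n_members[i] <- n_i
    if (n_i == 0L) {
      warning("cluster ", i, " is empty; maps set to zero")
      similarity[i] <- NA_real_
      next
    }
    xi <- x[memb, , drop = FALSE]
    mu <- colMeans(xi)
    mean_maps[i, ] <- mu
    if (n_i == 1L) {
      warning("cluster ", i, " has a single member; Z map set to zero")
    } else {
      s <- sqrt(colSums(sweep(xi, 2L, mu)^2) / (n_i - 1))
      se <- s / sqrt(n_i)
      z <- ifelse(se > 0, mu / se, 0)
      z_maps[i, ] <- z
    }
    similarity[i] <- mean(apply(xi, 1L, function(t_j) stats::cor(t_j, mu)))
  }
  occurrence <- n_members / n
  polarity <- apply(mean_maps, 1L, map_polarity)
  rank <- order(-similarity, seq_len(k))
  structure(list(mean_maps = mean_maps, z_maps = z_maps,
                 n_members = n_members, occurrence = occurrence,
                 similarity = similarity, polarity = polarity,
                 rank = rank, k = k),
            class = "cap_set")
}

# mean of strictly positive values + mean of strictly negative values;
# a map lacking one sign contributes only the other term
map_polarity <- function(map) {
  pos <- map[map > 0]; neg <- map[map < 0]
  (if (length(pos)) mean(pos) else 0) + (if (length(neg)) mean(neg) else 0)
}

#' @export
print.cap_set <- function(x, ...) {
  cat("cap_set:", x$k, "CAPs;",
      "occurrence", paste(signif(x$occurrence, 3), collapse = " "), "\n")
  invisible(x)
}

#' Per-CAP metrics table
#'
#' @param caps a `cap_set` from [compute_caps()].
#' @return data.frame (cap_id, n_members, occurrence, similarity,
#'   polarity, rank) where `rank` is each CAP's position in the
#'   similarity-descending ordering.
#' @export
cap_metrics <- function(caps) {
  stopifnot(inherits(caps, "cap_set"))
  pos <- integer(caps$k)
  pos[caps$rank] <- seq_len(caps$k)
  data.frame(cap_id = seq_len(caps$k),
             n_members = caps$n_members,
             occurrence = caps$occurrence,
             similarity = caps$similarity,
             polarity = caps$polarity,
             rank = pos)
}

#' Write a CAP set as NIfTI maps plus a metrics TSV
#'
#' @param caps a `cap_set`.
#' @param mask the [brain_mask()] whose voxel order the maps use.
#' @param dir output directory.
#' @return The directory, invisibly. Writes `cap_mean.nii.gz` and
#'   `cap_z.nii.gz` (4D, one volume per CAP) and `cap_metrics.tsv`.
#' @export
write_caps <- function(caps, mask, dir) {
  stopifnot(inherits(caps, "cap_set"), inherits(mask, "brain_mask"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  to_4d <- function(maps) {
    arr <- array(0, c(mask$grid$dims, caps$k))
    for (i in seq_len(caps$k))
      arr[, , , i] <- volume_from_vector(maps[i, ], mask)
    arr
  }
  save_4d(to_4d(caps$mean_maps), mask$grid, file.path(dir, "cap_mean.nii.gz"))
  save_4d(to_4d(caps$z_maps), mask$grid, file.path(dir, "cap_z.nii.gz"))
  write.table(cap_metrics(caps), file.path(dir, "cap_metrics.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
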