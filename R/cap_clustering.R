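#' Correlation distance between two vectors
#'
#' The clustering distance: 1 minus the Pearson correlation coefficient,
#' so values lie in \[0, 2\]. Symmetric and invariant to positive affine
#' transforms of either argument. Both vectors must have nonzero
#' variance; frames emptied by the supra-threshold mask must be excluded
#' upstream.
#'
#' @param x,y numeric vectors of equal length (>= 2) with nonzero
#'   variance.
#' @return `1 - cor(x, y)`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation distance undefined for zero-variance input")
  1 - stats::cor(x, y)
}

# Row-standardize to spatial mean 0 and unit L2 norm: correlation of two
# rows is then their dot product, and the correlation distance becomes
# (squared Euclidean distance) / 2.
standardize_rows <- function(x) {
  x <- x - rowMeans(x)
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) stop("zero-variance frame(s): ",
                          paste(head(which(nrm == 0)), collapse = ", "))
  x / nrm
}

#' k-means clustering of fMRI time frames under correlation distance
#'
#' Partitions the n frames into k clusters minimizing the sum of
#' within-cluster distances
#' \deqn{J = \sum_{i=1}^{k} \sum_{t_j \in R_i} d(t_j, \mu_i),}
#' where `d` is [correlation_distance()] and each centroid is the mean
#' of its members' (row-standardized) vectors — for vectors of equal
#' norm this normalized mean is the exact minimizer of the within-cluster
#' sum, so J is non-increasing over Lloyd iterations.
#'
#' Initialization is k-means++-style seeding adapted to the correlation
#' distance; ties in the assignment step go to the lowest cluster index;
#' a cluster emptied during iteration is re-seeded with the frame
#' currently farthest from its centroid. The best of `n_restarts` runs
#' by J is returned.
#'
#' @param frames a `frame_matrix` (typically the masked variant from
#'   [mask_frames()]) or a plain n x m matrix.
#' @param k number of clusters (default 30).
#' @param seed RNG seed for initialization.
#' @param max_iter iteration cap per restart (default 300).
#' @param n_restarts independent restarts (default 5).
#' @return An object of class `cap_clustering`: list with `labels`
#'   (length n, values 1..k), `centroids` (k x m, means of standardized
#'   members), `J`, `J_trace` (J after each update of the winning
#'   restart), `n_iter`, `seed`, `k`.
#' @export
kmeans_frames <- function(frames, k = 30, seed = 1L, max_iter = 300L,
                          n_restarts = 5L) {
  x <- if (inherits(frames, "frame_matrix")) frames$values else as.matrix(frames)
  n <- nrow(x)
  if (n < k) stop("need at least k = ", k, " frames, got ", n)
  xs <- standardize_rows(x)
  best <- NULL
  rng <- make_rng(seed)
  for (r in seq_len(n_restarts)) {
    fit <- kmeans_once(xs, k, rng, max_iter)
    if (is.null(best) || fit$J < best$J) best <- fit
  }
  structure(list(labels = best$labels, centroids = best$centroids,
                 J = best$J, J_trace = best$J_trace,
                 n_iter = best$n_iter, seed = seed, k = k),
            class = "cap_clustering")
}

#' @export
print.cap_clustering <- function(x, ...) {
  cat("cap_clustering: k =", x$k, " n =", length(x$labels),
      " J =", signif(x$J, 6), " (", x$n_iter, "iterations )\n")
  invisible(x)
}

# A private RNG stream so clustering seeds never disturb (or depend on)
# the caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    st <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
    st
  })
  function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, envir = globalenv())
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    expr()
  }
}

# For unit-norm zero-mean rows the objective has the closed form
# J = sum_i (n_i - ||s_i||), s_i = sum of member vectors: each cluster's
# refit centroid is s_i / ||s_i|| and its within-cluster distance sum is
# n_i - ||s_i||. Single-frame relocation (Hartigan-Wong style) uses this
# to escape Lloyd-stable local minima: moving frame j from cluster a to
# b changes J by ||s_a|| + ||s_b|| - ||s_a - x_j|| - ||s_b + x_j||
# (negated), evaluated exactly from one n x k dot-product matrix.
hartigan_refine <- function(xs, labels, k, max_moves = 200L) {
  n <- nrow(xs)
  S <- matrix(0, k, ncol(xs))
  for (i in seq_len(k)) {
    memb <- which(labels == i)
    if (length(memb)) S[i, ] <- colSums(xs[memb, , drop = FALSE])
  }
  norms <- sqrt(rowSums(S^2))
  sizes <- tabulate(labels, k)
  for (move in seq_len(max_moves)) {
    D <- tcrossprod(xs, S)                    # x_j . s_i
    a <- labels
    na <- norms[a]
    new_a <- sqrt(pmax(na^2 - 2 * D[cbind(seq_len(n), a)] + 1, 0))
    # ΔJ(j: a -> b) = ||s_a|| + ||s_b|| - ||s_a - x_j|| - ||s_b + x_j||,
    # negative = improvement
    new_b <- sqrt(sweep(2 * D, 2L, norms^2 + 1, "+"))
    delta <- sweep(-new_b, 2L, norms, "+") + (na - new_a)
    delta[cbind(seq_len(n), a)] <- 0
    delta[sizes[a] == 1L, ] <- 0               # never empty a cluster
    best <- which.min(delta)
    if (delta[best] >= -1e-12) break
    j <- (best - 1L) %% n + 1L
    b <- (best - 1L) %/% n + 1L
    from <- labels[j]
    S[from, ] <- S[from, ] - xs[j, ]
    S[b, ] <- S[b, ] + xs[j, ]
    norms[c(from, b)] <- sqrt(rowSums(S[c(from, b), , drop = FALSE]^2))
    sizes[from] <- sizes[from] - 1L
    sizes[b] <- sizes[b] + 1L
    labels[j] <- b
  }
  labels
}

# One Lloyd run on row-standardized data (unit-norm, zero-mean rows),
# followed by single-frame relocation refinement.
kmeans_once <- function(xs, k, rng, max_iter) {
  n <- nrow(xs)
  centers <- kmeanspp_init(xs, k, rng)
  cs <- standardize_rows(xs[centers, , drop = FALSE])
  labels <- integer(n)
  J_trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    sim <- tcrossprod(xs, cs)            # Pearson r(frame, centroid)
    new_labels <- max.col(sim, ties.method = "first")
    # recompute centroids as member means, re-seeding emptied clusters
    for (i in seq_len(k)) {
      memb <- which(new_labels == i)
      if (length(memb) == 0L) {
        worst <- which.max(1 - sim[cbind(seq_len(n), new_labels)])
        new_labels[worst] <- i
        memb <- worst
        message("cluster ", i, " emptied; re-seeded with frame ", worst)
      }
      mu <- colMeans(xs[memb, , drop = FALSE])
      cs[i, ] <- mu / sqrt(sum(mu^2))
    }
    J <- sum(1 - tcrossprod(xs, cs)[cbind(seq_len(n), new_labels)])
    J_trace <- c(J_trace, J)
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  # single-frame relocation polish; J can only decrease
  labels <- hartigan_refine(xs, labels, k)
  cs <- t(vapply(seq_len(k), function(i) {
    memb <- which(labels == i)
    mu <- colMeans(xs[memb, , drop = FALSE])
    mu / sqrt(sum(mu^2))
  }, numeric(ncol(xs))))
  J <- sum(1 - tcrossprod(xs, cs)[cbind(seq_len(n), labels)])
  if (J < J_trace[length(J_trace)] - 1e-12) J_trace <- c(J_trace, J)
  # report centroids on the mean-of-standardized-members scale
  centroids <- t(vapply(seq_len(k), function(i) {
    memb <- which(labels == i)
    colMeans(xs[memb, , drop = FALSE])
  }, numeric(ncol(xs))))
  list(labels = labels, centroids = centroids, J = min(J_trace),
       J_trace = J_trace, n_iter = length(J_trace))
}

# k-means++ seeding under correlation distance: first centre uniform,
# subsequent centres sampled with probability proportional to the
# distance to the nearest centre chosen so far.
kmeanspp_init <- function(xs, k, rng) {
  n <- nrow(xs)
  centers <- integer(k)
  centers[1] <- rng(function() sample.int(n, 1))
  d_near <- 1 - tcrossprod(xs, xs[centers[1], , drop = FALSE])[, 1]
  for (i in seq_len(k - 1L)) {
    d_pos <- pmax(d_near, 0)
    d_pos[centers[seq_len(i)]] <- 0
    if (sum(d_pos) == 0) {
      cand <- setdiff(seq_len(n), centers[seq_len(i)])
      centers[i + 1L] <- cand[rng(function() sample.int(length(cand), 1))]
    } else {
      centers[i + 1L] <- rng(function() sample.int(n, 1, prob = d_pos))
    }
    d_new <- 1 - tcrossprod(xs, xs[centers[i + 1L], , drop = FALSE])[, 1]
    d_near <- pmin(d_near, d_new)
  }
  centers
}

#' Write clustering results as TSV + JSON metadata
#'
#' @param assignment a `cap_clustering`.
#' @param frames the `frame_matrix` that was clustered (for session ids).
#' @param dir output directory (created if needed).
#' @return The directory, invisibly. Writes `labels.tsv` (frame_index,
#'   session_id, label, distance) and `clustering.json` (seed, J,
#'   iterations, k).
#' @export
write_clustering <- function(assignment, frames, dir) {
  stopifnot(inherits(assignment, "cap_clustering"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- if (inherits(frames, "frame_matrix")) frames$values else as.matrix(frames)
  xs <- standardize_rows(x)
  cs <- standardize_rows(assignment$centroids)
  d <- 1 - tcrossprod(xs, cs)[cbind(seq_len(nrow(xs)), assignment$labels)]
  sess <- session_of_frames(frames)
  tab <- data.frame(frame_index = seq_len(nrow(xs)),
                    session_id = sess,
                    label = assignment$labels,
                    distance = d)
  write.table(tab, file.path(dir, "labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(seed = assignment$seed, J = assignment$J,
               iterations = assignment$n_iter, k = assignment$k)
  jsonlite::write_json(meta, file.path(dir, "clustering.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

session_of_frames <- function(frames) {
  if (inherits(frames, "frame_matrix") && !is.null(frames$sessions)) {
    st <- frames$sessions
    sess <- rep(NA_character_, nrow(frames$values))
    for (r in seq_len(nrow(st)))
      sess[st$frame_start[r]:st$frame_stop[r]] <- st$session_id[r]
    sess
  } else {
    n <- if (inherits(frames, "frame_matrix")) nrow(frames$values) else nrow(frames)
    rep("s1", n)
  }
}
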