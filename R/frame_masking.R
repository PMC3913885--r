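#' Supra-threshold frame mask
#'
#' Selects, per frame, the most extreme signal values used when computing
#' clustering distances: the `p_high` fraction of highest values is
#' marked +1 and the `p_low` fraction of lowest values -1 (defaults 10%
#' and 5%); everything else is 0. Exactly `floor(p_high * m)` positive
#' and `floor(p_low * m)` negative voxels are selected, with boundary
#' ties broken by the fixed voxel order. A constant frame yields an
#' all-zero mask with a warning. Being percentile-based, the mask is
#' invariant to positive affine rescaling of the frame.
#'
#' @param frame numeric vector of length m (one frame's in-mask values).
#' @param p_high,p_low fractions with `p_low + p_high < 1`.
#' @return Integer vector in \{-1, 0, +1\} of length m.
#' @export
supra_threshold_mask <- function(frame, p_high = 0.10, p_low = 0.05) {
  if (p_high < 0 || p_low < 0 || p_high + p_low >= 1)
    stop("need p_high, p_low >= 0 and p_high + p_low < 1")
  m <- length(frame)
  sgn <- integer(m)
  if (max(frame) == min(frame)) {
    warning("constant frame: supra-threshold mask is empty")
    return(sgn)
  }
  n_hi <- floor(p_high * m)
  n_lo <- floor(p_low * m)
  ord <- order(frame, seq_len(m))  # ties broken by voxel order
  if (n_lo > 0) sgn[ord[seq_len(n_lo)]] <- -1L
  if (n_hi > 0) sgn[ord[seq(m - n_hi + 1L, m)]] <- 1L
  sgn
}

#' Remove small connected components from a signed mask
#'
#' Labels 3D connected components separately within the +1 and the -1
#' voxel sets of a supra-threshold mask and zeroes any component with
#' fewer than `min_component` voxels. Connectivity defaults to 6
#' (face-adjacent), the most conservative reading of 3D
#' inter-connectedness; 18 and 26 are available.
#'
#' @param sgn integer vector in \{-1, 0, +1\} over the mask's voxels.
#' @param mask a [brain_mask()] giving the voxels' 3D positions.
#' @param min_component minimum surviving component size (default 6).
#' @param connectivity 6, 18 or 26.
#' @return The filtered signed vector. Idempotent; never increases the
#'   number of nonzero voxels.
#' @export
filter_small_components <- function(sgn, mask, min_component = 6,
                                    connectivity = 6) {
  stopifnot(inherits(mask, "brain_mask"), length(sgn) == mask$m)
  out <- as.integer(sgn)
  for (s in c(1L, -1L)) {
    sel <- which(out == s)
    if (length(sel) == 0L) next
    sizes_by_voxel <- component_sizes(mask$idx[sel], mask$grid$dims,
                                      connectivity)
    out[sel[sizes_by_voxel < min_component]] <- 0L
  }
  out
}

# Sizes of the 3D connected components containing each active voxel.
# `lin` holds linear (column-major) indices into a dims-shaped array.
component_sizes <- function(lin, dims, connectivity = 6) {
  offs <- connectivity_offsets(connectivity)
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  ix <- ((lin - 1L) %% nx) + 1L
  iy <- (((lin - 1L) %/% nx) %% ny) + 1L
  iz <- ((lin - 1L) %/% (nx * ny)) + 1L
  nmemb <- length(lin)
  edges_from <- integer(0); edges_to <- integer(0)
  for (r in seq_len(nrow(offs))) {
    jx <- ix + offs[r, 1]; jy <- iy + offs[r, 2]; jz <- iz + offs[r, 3]
    ok <- jx >= 1L & jx <= nx & jy >= 1L & jy <= ny & jz >= 1L & jz <= nz
    nb <- (jz[ok] - 1L) * nx * ny + (jy[ok] - 1L) * nx + jx[ok]
    hit <- match(nb, lin)
    found <- !is.na(hit)
    edges_from <- c(edges_from, which(ok)[found])
    edges_to <- c(edges_to, hit[found])
  }
  g <- igraph::make_graph(as.vector(rbind(edges_from, edges_to)),
                          n = nmemb, directed = FALSE)
  comp <- igraph::components(g)
  comp$csize[comp$membership]
}

# Half-space neighbour offsets (each undirected adjacency counted once)
connectivity_offsets <- function(connectivity) {
  all_offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  all_offs <- all_offs[rowSums(abs(all_offs)) > 0, , drop = FALSE]
  ord <- rowSums(abs(all_offs))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  offs <- all_offs[keep, , drop = FALSE]
  # keep one of each +/- pair
  key <- offs %*% c(1, 10, 100)
  offs[key > 0, , drop = FALSE]
}

#' Apply a signed mask to a frame
#'
#' Retains frame values where the mask sign is nonzero and zeroes the
#' rest; the zero-filled full-length vector keeps all frames in a common
#' vector space for the clustering distance.
#'
#' @param frame numeric vector of length m.
#' @param sgn integer vector in \{-1, 0, +1\}, same length.
#' @return Masked frame, same length.
#' @export
apply_mask <- function(frame, sgn) {
  stopifnot(length(frame) == length(sgn))
  frame * (sgn != 0)
}

#' Supra-threshold masking of every frame in a frame matrix
#'
#' Runs [supra_threshold_mask()], [filter_small_components()] and
#' [apply_mask()] on each row. The result feeds the clustering only; CAP
#' averaging always uses the unmasked frames.
#'
#' If component filtering removes every supra-threshold voxel of a frame
#' (possible in very noisy data where no extreme values form a large
#' enough cluster), the pre-filter supra-threshold mask is kept for that
#' frame so it stays clusterable; the affected frame indices are
#' reported in a message.
#'
#' @param frames a `frame_matrix`.
#' @param p_high,p_low percentile fractions (defaults 0.10 and 0.05).
#' @param min_component minimum connected-component size (default 6).
#' @param connectivity 6, 18 or 26.
#' @return A `frame_matrix` of masked values.
#' @export
mask_frames <- function(frames, p_high = 0.10, p_low = 0.05,
                        min_component = 6, connectivity = 6) {
  stopifnot(inherits(frames, "frame_matrix"))
  x <- frames$values
  out <- x
  fallback <- integer(0)
  for (j in seq_len(nrow(x))) {
    sgn0 <- supra_threshold_mask(x[j, ], p_high, p_low)
    sgn <- filter_small_components(sgn0, frames$mask, min_component,
                                   connectivity)
    if (all(sgn == 0L) && any(sgn0 != 0L)) {
      sgn <- sgn0
      fallback <- c(fallback, j)
    }
    out[j, ] <- apply_mask(x[j, ], sgn)
  }
  if (length(fallback))
    message("component filter emptied ", length(fallback),
            " frame(s); kept their unfiltered supra-threshold masks (",
            paste(head(fallback, 5), collapse = ", "),
            if (length(fallback) > 5) ", ..." else "", ")")
  frame_matrix(out, frames$mask, frames$sessions)
}
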