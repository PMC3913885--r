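#' Temporal normalization of voxel time series
#'
#' Each voxel's time course is centred to mean 0 and scaled to standard
#' deviation 1 within each session. The population SD (divide by n) is
#' used; the downstream correlation distance is scale-invariant, so the
#' choice only fixes the stored scale. Zero-variance voxels map to zeros.
#'
#' @param x numeric matrix, frames in rows, voxels in columns (a single
#'   session), or a plain vector for one voxel.
#' @return The normalized matrix (or vector), same shape.
#' @export
temporal_normalize <- function(x) {
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("temporal normalization needs >= 2 frames")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu)
  s <- sqrt(colMeans(xc^2))
  s[s == 0] <- Inf   # constant voxels -> all zeros
  out <- sweep(xc, 2L, s, "/")
  if (vec) drop(out) else out
}

#' Detrend and band-pass filter voxel time series
#'
#' Removes linear and quadratic trends by least squares, then applies an
#' ideal (brick-wall) frequency-domain band-pass with zero phase: Fourier
#' coefficients whose frequency lies in `[low, high]` are kept, all
#' others (including DC unless `low == 0`) are zeroed.
#'
#' @param x numeric matrix (frames x voxels, one session) or vector.
#' @param tr repetition time in seconds (> 0).
#' @param low,high passband edges in Hz; requires
#'   `0 <= low < high < 1/(2*tr)`.
#' @param detrend remove linear + quadratic trends first (default TRUE).
#' @return Filtered series, same shape; output length equals input length.
#' @export
detrend_and_bandpass <- function(x, tr, low = 0.005, high = 0.1,
                                 detrend = TRUE) {
  if (tr <= 0) stop("`tr` must be positive")
  nyq <- 1 / (2 * tr)
  if (low < 0 || low >= high) stop("need 0 <= low < high")
  if (high >= nyq) stop("`high` must be below the Nyquist frequency ", nyq)
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  n <- nrow(x)
  if (detrend) {
    tt <- seq_len(n)
    basis <- cbind(1, tt, tt^2)
    x <- stats::lm.fit(basis, x)$residuals
    x <- as.matrix(x)
  }
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low & freqs <= high
  xf <- stats::mvfft(x)
  xf[!keep, ] <- 0
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (vec) drop(out) else out
}

#' Build a nuisance regressor set
#'
#' Collects the per-session nuisance time courses regressed out of the
#' data: white-matter mean, CSF mean, the 6 rigid-motion parameters, and
#' optionally the brain-averaged (global) signal.
#'
#' @param motion n x 6 matrix of rigid-motion parameters (3 translations
#'   in mm, then 3 rotations), or NULL.
#' @param wm,csf optional length-n mean time courses.
#' @param global_signal optional length-n brain-averaged time course
#'   (global signal regression).
#' @return A `nuisance_set`: list with `regressors` (n x q matrix) and
#'   `labels`.
#' @export
nuisance_set <- function(motion = NULL, wm = NULL, csf = NULL,
                         global_signal = NULL) {
  cols <- list()
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (ncol(motion) != 6L) stop("motion must have 6 columns")
    colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                          "rot_x", "rot_y", "rot_z")
    cols <- c(cols, as.data.frame(motion))
  }
  if (!is.null(wm)) cols$wm <- wm
  if (!is.null(csf)) cols$csf <- csf
  if (!is.null(global_signal)) cols$global <- global_signal
  if (length(cols) == 0L) stop("no nuisance regressors supplied")
  reg <- do.call(cbind, cols)
  ns <- nrow(reg)
  bad <- apply(reg, 2L, function(v) all(v == 0))
  if (any(bad)) stop("constant-zero nuisance column(s): ",
                     paste(colnames(reg)[bad], collapse = ", "))
  structure(list(regressors = reg, labels = colnames(reg)),
            class = "nuisance_set")
}

#' Regress nuisance signals out of voxel time series
#'
#' Projects each voxel time course onto the orthogonal complement of the
#' nuisance columns plus an intercept, returning least-squares residuals.
#' A rank-deficient design triggers a warning and a pseudo-inverse fit.
#'
#' @param x numeric matrix (frames x voxels, one session) or vector.
#' @param nuisance a [nuisance_set()] with matching frame count.
#' @return Residual series, same shape as `x`.
#' @export
regress_nuisance <- function(x, nuisance) {
  stopifnot(inherits(nuisance, "nuisance_set"))
  vec <- is.null(dim(x))
  x <- as.matrix(x)
  reg <- cbind(intercept = 1, nuisance$regressors)
  if (nrow(reg) != nrow(x))
    stop("nuisance rows (", nrow(reg), ") != frame count (", nrow(x), ")")
  qr_reg <- qr(reg)
  if (qr_reg$rank < ncol(reg)) {
    warning("rank-deficient nuisance design; using pseudo-inverse")
    beta <- MASS_ginv(reg) %*% x
    out <- x - reg %*% beta
  } else {
    out <- stats::lm.fit(reg, x)$residuals
    out <- as.matrix(out)
  }
  if (vec) drop(out) else out
}

# Moore-Penrose pseudo-inverse via SVD (small designs only)
MASS_ginv <- function(a, tol = sqrt(.Machine$double.eps)) {
  s <- svd(a)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Spatial Gaussian smoothing of a volume
#'
#' Separable Gaussian kernel with `sigma = fwhm / (2 sqrt(2 log 2))` per
#' axis, converted to voxel units by the grid's voxel size. The kernel is
#' truncated at 4 sigma and renormalized at the boundary so constants are
#' preserved. `fwhm = 0` is the identity.
#'
#' @param volume 3D numeric array.
#' @param grid a [volume_grid()] giving voxel sizes in mm.
#' @param fwhm full width at half maximum of the kernel, in mm (>= 0).
#' @return Smoothed 3D array.
#' @export
smooth_gaussian <- function(volume, grid, fwhm = 4) {
  stopifnot(inherits(grid, "volume_grid"))
  if (fwhm < 0) stop("`fwhm` must be non-negative")
  if (fwhm == 0) return(volume)
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  sigma_vox <- (fwhm / (2 * sqrt(2 * log(2)))) / grid$voxel_size
  out <- volume
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    half <- max(1L, ceiling(4 * s))
    kern <- exp(-(seq(-half, half))^2 / (2 * s^2))
    out <- convolve_axis(out, kern, axis)
  }
  out
}

# 1D convolution along one axis of a 3D array, kernel renormalized per
# position so that in-bounds weights sum to 1 (constant-preserving).
convolve_axis <- function(vol, kern, axis) {
  d <- dim(vol)
  n <- d[axis]
  half <- (length(kern) - 1L) / 2L
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  v <- aperm(vol, perm)
  mat <- matrix(v, nrow = n)
  acc <- matrix(0, nrow = n, ncol = ncol(mat))
  wsum <- numeric(n)
  for (o in seq(-half, half)) {
    w <- kern[o + half + 1L]
    src <- seq_len(n) + o
    ok <- src >= 1L & src <= n
    acc[ok, ] <- acc[ok, ] + w * mat[src[ok], , drop = FALSE]
    wsum[ok] <- wsum[ok] + w
  }
  res <- acc / wsum
  dim(res) <- d[perm]
  aperm(res, order(perm))
}

#' Run the full per-session preprocessing pipeline
#'
#' Applies, in order: spatial smoothing, detrending + band-pass
#' filtering, nuisance regression (optionally including the global
#' signal), and temporal normalization. Stages can be disabled
#' individually.
#'
#' @param data 4D array for one session.
#' @param mask a [brain_mask()].
#' @param tr repetition time in seconds.
#' @param fwhm smoothing kernel FWHM in mm (0 disables).
#' @param low,high band-pass edges in Hz (NULL disables filtering).
#' @param motion optional n x 6 motion-parameter matrix.
#' @param wm,csf optional nuisance time courses.
#' @param gsr include the global (in-mask spatial mean) signal as a
#'   nuisance regressor (default TRUE).
#' @param normalize apply temporal normalization last (default TRUE).
#' @return A `frame_matrix` of conditioned in-mask values.
#' @export
preprocess_session <- function(data, mask, tr, fwhm = 4,
                               low = 0.005, high = 0.1,
                               motion = NULL, wm = NULL, csf = NULL,
                               gsr = TRUE, normalize = TRUE) {
  stopifnot(inherits(mask, "brain_mask"))
  if (fwhm > 0) {
    for (j in seq_len(dim(data)[4]))
      data[, , , j] <- smooth_gaussian(data[, , , j], mask$grid, fwhm)
  }
  fm <- frames_from_4d(data, mask)
  x <- fm$values
  if (!is.null(low) && !is.null(high))
    x <- detrend_and_bandpass(x, tr, low, high)
  gs <- if (gsr) rowMeans(x) else NULL
  if (!is.null(motion) || !is.null(wm) || !is.null(csf) || !is.null(gs)) {
    ns <- nuisance_set(motion = motion, wm = wm, csf = csf,
                       global_signal = gs)
    x <- regress_nuisance(x, ns)
  }
  if (normalize) x <- temporal_normalize(x)
  frame_matrix(x, mask, fm$sessions)
}
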