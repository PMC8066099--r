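#' @title Planar filtering and resampling of MRI volumes
#' @description Image operations applied before feature extraction: in-plane
#'   resampling to a common spatial resolution, the Laplacian-of-Gaussian
#'   (LoG) filter bank, and the intensity-based (IB) filter: ROI percentile
#'   normalisation followed by threshold-pair subpopulation masks. All
#'   filtering is planar (per axial slice); the slice axis is left untouched
#'   because slice thickness varies across acquisition protocols.
#' @name imaging
NULL

# 2D linear convolution with edge-replicated boundary, computed by FFT on
# zero-padded copies. Kernels used in this package are symmetric, so
# convolution and correlation coincide.
conv2d_replicate <- function(img, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kc <- (ncol(kernel) - 1L) %/% 2L
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(rep(1L, kr), seq_len(nr), rep(nr, kr))
  ci <- c(rep(1L, kc), seq_len(nc), rep(nc, kc))
  p <- img[ri, ci, drop = FALSE]
  pr <- nrow(p) + nrow(kernel) - 1L
  pc <- ncol(p) + ncol(kernel) - 1L
  A <- matrix(0, pr, pc); A[seq_len(nrow(p)), seq_len(ncol(p))] <- p
  B <- matrix(0, pr, pc); B[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- Re(stats::fft(stats::fft(A) * stats::fft(B), inverse = TRUE)) / (pr * pc)
  full[(2L * kr + 1L):(2L * kr + nr), (2L * kc + 1L):(2L * kc + nc), drop = FALSE]
}

# Isotropic 2D Gaussian smoothing kernel sampled on the pixel grid,
# normalised to unit sum. sigma_px per axis (row, col).
gaussian_kernel_2d <- function(sigma_px, radius_factor = 4) {
  r1 <- max(1L, ceiling(radius_factor * sigma_px[1]))
  r2 <- max(1L, ceiling(radius_factor * sigma_px[2]))
  x <- (-r1):r1; y <- (-r2):r2
  k <- exp(-outer(x^2 / (2 * sigma_px[1]^2), y^2 / (2 * sigma_px[2]^2), "+"))
  k / sum(k)
}

#' Discrete Laplacian-of-Gaussian convolution kernel
#'
#' Samples the analytic 2D LoG
#' \deqn{-\frac{1}{\pi\sigma^4}\Big(1-\frac{x^2+y^2}{2\sigma^2}\Big)
#'       e^{-(x^2+y^2)/(2\sigma^2)}}
#' at physical pixel-centre offsets (so \eqn{\sigma} is in millimetres and the
#' grid step is the voxel spacing), then recentres the kernel to zero sum so a
#' constant image maps exactly to zero.
#'
#' @param sigma_mm Filter width in millimetres (> 0).
#' @param spacing_mm Length-2 planar pixel spacing (row, col) in millimetres.
#' @param radius_factor Kernel half-width in units of `sigma_mm` (default 4).
#' @return A numeric matrix of odd dimensions summing to zero.
#' @export
log_kernel <- function(sigma_mm, spacing_mm, radius_factor = 4) {
  stopifnot(sigma_mm > 0, length(spacing_mm) == 2, all(spacing_mm > 0))
  r1 <- max(1L, ceiling(radius_factor * sigma_mm / spacing_mm[1]))
  r2 <- max(1L, ceiling(radius_factor * sigma_mm / spacing_mm[2]))
  x <- ((-r1):r1) * spacing_mm[1]
  y <- ((-r2):r2) * spacing_mm[2]
  r2g <- outer(x^2, y^2, "+")
  k <- -(1 / (pi * sigma_mm^4)) * (1 - r2g / (2 * sigma_mm^2)) * exp(-r2g / (2 * sigma_mm^2))
  k - mean(k)
}

#' Laplacian-of-Gaussian filter applied per axial slice
#'
#' Band-pass response at scale `sigma_mm`. The convention `sigma_mm = 0`
#' returns the raw image unchanged, so the unfiltered image is the first
#' member of the filter bank (the study's importance ranking includes kurtosis
#' on the raw images).
#'
#' @param v A [volume_with_mask()].
#' @param sigma_mm Filter width in millimetres (>= 0).
#' @return A `volume_with_mask` with filtered intensities; mask and spacing
#'   unchanged.
#' @export
log_filter <- function(v, sigma_mm) {
  stopifnot(inherits(v, "volume_with_mask"))
  if (!is.numeric(sigma_mm) || length(sigma_mm) != 1L || is.na(sigma_mm) || sigma_mm < 0)
    stop("`sigma_mm` must be a single nonnegative number", call. = FALSE)
  if (sigma_mm == 0) return(v)
  k <- log_kernel(sigma_mm, v$spacing_mm[1:2])
  out <- v$intensities
  for (s in seq_len(dim(out)[3]))
    out[, , s] <- conv2d_replicate(v$intensities[, , s], k)
  v$intensities <- out
  v
}

#' The default LoG scale grid
#'
#' Arithmetic grid of filter widths from 0 to 4.2 mm in steps of 0.35 mm
#' (13 scales in total), 0 meaning the unfiltered image.
#'
#' @param max_mm Largest scale (default 4.2).
#' @param step_mm Grid step (default 0.35).
#' @return Numeric vector of sigma values in millimetres.
#' @export
sigma_grid <- function(max_mm = 4.2, step_mm = 0.35) {
  round(seq(0, max_mm, by = step_mm), 10)
}

#' Resample a volume in-plane to a target pixel spacing
#'
#' Bilinear interpolation of each axial slice onto a grid with the requested
#' planar spacing (default 0.548 mm, the resolution all study images were
#' homogenised to); the slice axis is untouched. The mask is interpolated
#' linearly and re-binarised at 0.5.
#'
#' @param v A [volume_with_mask()].
#' @param target_mm Target in-plane spacing in millimetres (default 0.548).
#' @return A `volume_with_mask` with planar spacing `target_mm`.
#' @export
resample_planar <- function(v, target_mm = 0.548) {
  stopifnot(inherits(v, "volume_with_mask"))
  if (!is.numeric(target_mm) || length(target_mm) != 1L || target_mm <= 0)
    stop("`target_mm` must be a single positive number", call. = FALSE)
  sp <- v$spacing_mm
  if (isTRUE(all.equal(sp[1], target_mm)) && isTRUE(all.equal(sp[2], target_mm)))
    return(v)
  d <- dim(v$intensities)
  if (d[1] < 2L || d[2] < 2L)
    stop("cannot resample a degenerate (single-voxel) plane", call. = FALSE)
  n1 <- max(2L, as.integer(round(d[1] * sp[1] / target_mm)))
  n2 <- max(2L, as.integer(round(d[2] * sp[2] / target_mm)))
  # target pixel centre -> fractional source index (pixel-centre alignment)
  xi <- pmin(pmax(((seq_len(n1) - 0.5) * target_mm) / sp[1] + 0.5, 1), d[1])
  yj <- pmin(pmax(((seq_len(n2) - 0.5) * target_mm) / sp[2] + 0.5, 1), d[2])
  i0 <- pmin(floor(xi), d[1] - 1L); fx <- xi - i0
  j0 <- pmin(floor(yj), d[2] - 1L); fy <- yj - j0
  interp_slice <- function(m) {
    a <- m[i0, j0, drop = FALSE]; b <- m[i0 + 1L, j0, drop = FALSE]
    c_ <- m[i0, j0 + 1L, drop = FALSE]; e <- m[i0 + 1L, j0 + 1L, drop = FALSE]
    wx <- matrix(fx, n1, n2); wy <- matrix(fy, n1, n2, byrow = TRUE)
    # nested lerp keeps constant regions bit-exact
    top <- a + wy * (c_ - a)
    bot <- b + wy * (e - b)
    top + wx * (bot - top)
  }
  ints <- array(0, c(n1, n2, d[3]))
  msk <- array(FALSE, c(n1, n2, d[3]))
  for (s in seq_len(d[3])) {
    ints[, , s] <- interp_slice(v$intensities[, , s])
    msk[, , s] <- interp_slice(v$mask[, , s] * 1) >= 0.5
  }
  if (!any(msk))
    stop("ROI vanished during resampling; target spacing too coarse", call. = FALSE)
  volume_with_mask(ints, c(target_mm, target_mm, sp[3]), msk)
}

#' Intensity-based normalisation of ROI grey levels
#'
#' Linearly rescales ROI intensities so that the 1st percentile of the ROI
#' histogram maps to 0 and the 99th percentile maps to 1, then clips to
#' \[0, 1\]. Voxels outside the ROI are left unchanged (they are never read
#' downstream).
#'
#' @param v A [volume_with_mask()] whose ROI holds at least two distinct
#'   values.
#' @return A `volume_with_mask` with ROI intensities in \[0, 1\].
#' @export
ib_normalize <- function(v) {
  stopifnot(inherits(v, "volume_with_mask"))
  vals <- roi_values(v)
  q <- stats::quantile(vals, c(0.01, 0.99), names = FALSE, type = 7)
  if (q[2] <= q[1])
    stop("degenerate ROI: 1st and 99th percentile coincide; cannot normalise",
         call. = FALSE)
  scaled <- pmin(pmax((vals - q[1]) / (q[2] - q[1]), 0), 1)
  v$intensities[v$mask] <- scaled
  v
}

#' Enumerate the intensity-threshold pairs of the IB filter
#'
#' All (lower, upper) percentage pairs with lower < upper drawn from the
#' levels 0, `step_pct`, ..., 100. With the default 10% step this yields the
#' 55 combinations of the study's filter bank.
#'
#' @param step_pct Level step in percent (default 10; must divide 100).
#' @return A data frame with integer columns `lower_pct` and `upper_pct`.
#' @export
ib_threshold_pairs <- function(step_pct = 10) {
  stopifnot(step_pct > 0, 100 %% step_pct == 0)
  lv <- seq(0L, 100L, by = as.integer(step_pct))
  g <- expand.grid(lower_pct = lv, upper_pct = lv)
  g <- g[g$lower_pct < g$upper_pct, , drop = FALSE]
  g <- g[order(g$lower_pct, g$upper_pct), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Subpopulation mask for one threshold pair
#'
#' Selects the ROI voxels whose normalised intensity lies in the closed
#' interval \[lower/100, upper/100\]. Boundary voxels therefore belong to both
#' adjacent pairs; an empty subpopulation is a legal result (features computed
#' on it return the missing sentinel).
#'
#' @param normed A volume produced by [ib_normalize()].
#' @param lower_pct,upper_pct Integer percentages with `lower_pct < upper_pct`.
#' @return A 3D logical array, subset of the ROI mask.
#' @export
subpopulation_mask <- function(normed, lower_pct, upper_pct) {
  stopifnot(inherits(normed, "volume_with_mask"), lower_pct < upper_pct)
  normed$mask & normed$intensities >= lower_pct / 100 &
    normed$intensities <= upper_pct / 100
}
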