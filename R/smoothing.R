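# Separable Gaussian smoothing on a voxel grid, with masked-kernel
# renormalization.  Shared by the synthetic generator (background noise
# smoothness), ReHo map smoothing, and the Monte-Carlo null fields, so all
# three see exactly the same operator.

#' Convert a Gaussian FWHM to its standard deviation
#'
#' FWHM = 2 * sqrt(2 * log(2)) * sigma.
#'
#' @param fwhm full width at half maximum (any length unit).
#' @return sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Truncated, normalized 1D Gaussian kernel sampled at integer offsets.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# n x n band matrix applying 1D convolution (zero padding) along one axis.
conv_band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  for (d in -r:r) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    M[cbind(i[ok], j[ok])] <- kernel[d + r + 1L]
  }
  M
}

# Separable 3D convolution of `vol` with per-axis kernels (zero padding).
conv3_separable <- function(vol, kernels) {
  d <- dim(vol)
  # axis 1
  if (length(kernels[[1]]) > 1L)
    vol <- array(conv_band_matrix(d[1], kernels[[1]]) %*%
                   matrix(vol, d[1]), d)
  # axis 2
  if (length(kernels[[2]]) > 1L) {
    vol <- aperm(vol, c(2, 1, 3))
    vol <- array(conv_band_matrix(d[2], kernels[[2]]) %*%
                   matrix(vol, d[2]), d[c(2, 1, 3)])
    vol <- aperm(vol, c(2, 1, 3))
  }
  # axis 3
  if (length(kernels[[3]]) > 1L) {
    vol <- aperm(vol, c(3, 2, 1))
    vol <- array(conv_band_matrix(d[3], kernels[[3]]) %*%
                   matrix(vol, d[3]), d[c(3, 2, 1)])
    vol <- aperm(vol, c(3, 2, 1))
  }
  vol
}

#' Masked Gaussian smoothing of a 3D volume
#'
#' Isotropic Gaussian smoothing with the kernel restricted to the mask:
#' out = conv(x * m) / conv(m) inside the mask, 0 outside, so a constant
#' in-mask field is left unchanged and no out-of-mask value leaks in.
#' With `mask = NULL` the full grid acts as the mask (plain smoothing with
#' edge renormalization).
#'
#' @param vol numeric 3D array.
#' @param fwhm_mm isotropic kernel FWHM in mm (0 = identity).
#' @param voxel_size_mm length-3 voxel dimensions in mm.
#' @param mask logical 3D array or NULL.
#' @return smoothed 3D array.
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_size_mm, mask = NULL) {
  stopifnot(length(dim(vol)) == 3L, fwhm_mm >= 0, length(voxel_size_mm) == 3L)
  if (fwhm_mm == 0) {
    if (!is.null(mask)) vol[!mask] <- 0
    return(vol)
  }
  sig <- fwhm_to_sigma(fwhm_mm) / voxel_size_mm
  ks <- lapply(sig, gaussian_kernel_1d)
  if (is.null(mask)) {
    num <- conv3_separable(vol, ks)
    den <- conv3_separable(array(1, dim(vol)), ks)
    return(num / den)
  }
  m <- array(as.numeric(mask), dim(vol))
  num <- conv3_separable(vol * m, ks)
  den <- conv3_separable(m, ks)
  out <- array(0, dim(vol))
  inm <- mask & den > 0
  out[inm] <- num[inm] / den[inm]
  out
}
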