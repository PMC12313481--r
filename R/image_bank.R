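# Derived-image bank for texture analysis: the original volume, four
# Laplacian-of-Gaussian filtered volumes (fine -> coarse sigma), and the
# eight sub-bands of a single-level undecimated 3-D Haar wavelet transform.
# 13 image types in total; with 86 (or 88) intensity features per type plus
# 14 shape features this yields the 1132 / 1158 feature inventories.

# 1-D convolution along one axis of a 3-D array, mirror boundary.
conv_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dp <- dim(v)
  S <- matrix(v, dp[1L], dp[2L] * dp[3L])
  n <- nrow(S)
  half <- (length(kernel) - 1L) %/% 2L
  out <- matrix(0, n, ncol(S))
  base <- seq_len(n)
  for (k in seq_along(kernel)) {
    off <- k - 1L - half
    out <- out + kernel[k] * S[mirror_index(base + off, n), , drop = FALSE]
  }
  aperm(array(out, dp), order(perm))
}

# sampled Gaussian and its second derivative, truncated at 4 sigma,
# sigma in voxel units; g normalized to unit sum
gaussian_kernels <- function(sigma_vox) {
  half <- max(1L, ceiling(4 * sigma_vox))
  x <- seq(-half, half)
  g <- exp(-x^2 / (2 * sigma_vox^2))
  g <- g / sum(g)
  d2 <- g * (x^2 - sigma_vox^2) / sigma_vox^4
  list(g = g, d2 = d2)
}

#' Laplacian-of-Gaussian filtered volume
#'
#' Computes \eqn{\sigma^2 \nabla^2 (G_\sigma * I)} by separable
#' convolution: for each axis, the 1-D second-derivative-of-Gaussian kernel
#' along that axis and plain Gaussians along the others, summed over axes.
#' The \eqn{\sigma^2} factor gives the usual scale normalization so
#' responses are comparable across sigmas.
#'
#' @param vol 3-D array.
#' @param sigma filter scale in mm.
#' @param spacing voxel spacing in mm (length 3).
#' @return filtered 3-D array of the same shape.
#' @export
log_filter <- function(vol, sigma, spacing = c(1, 1, 1)) {
  spacing <- as.numeric(spacing)
  ks <- lapply(1:3, function(a) gaussian_kernels(sigma / spacing[a]))
  out <- array(0, dim(vol))
  for (a in 1:3) {
    tmp <- vol
    for (b in 1:3) {
      kern <- if (b == a) ks[[b]]$d2 else ks[[b]]$g
      tmp <- conv_axis(tmp, kern, b)
    }
    out <- out + tmp
  }
  sigma^2 * out
}

# undecimated single-level Haar analysis along one axis:
# L[i] = (x[i] + x[i+1])/sqrt(2), H[i] = (x[i] - x[i+1])/sqrt(2)
haar_axis <- function(vol, axis) {
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dp <- dim(v)
  S <- matrix(v, dp[1L], dp[2L] * dp[3L])
  nxt <- mirror_index(seq_len(dp[1L]) + 1L, dp[1L])
  L <- (S + S[nxt, , drop = FALSE]) / sqrt(2)
  H <- (S - S[nxt, , drop = FALSE]) / sqrt(2)
  list(L = aperm(array(L, dp), order(perm)),
       H = aperm(array(H, dp), order(perm)))
}

#' Single-level undecimated 3-D Haar wavelet decomposition
#'
#' All eight low/high-pass combinations over the three axes, on the original
#' grid (no decimation, so voxel-wise ROI masking carries over directly).
#' Sub-band names follow the `LLL` ... `HHH` convention with letters in
#' axis order. A constant input has all detail (any-H) sub-bands identically
#' zero.
#'
#' @param vol 3-D array.
#' @return named list of 8 arrays (`LLL`, `HLL`, `LHL`, ..., `HHH`).
#' @export
wavelet_bank <- function(vol) {
  ax1 <- haar_axis(vol, 1L)
  out <- list()
  for (c1 in c("L", "H")) {
    ax2 <- haar_axis(ax1[[c1]], 2L)
    for (c2 in c("L", "H")) {
      ax3 <- haar_axis(ax2[[c2]], 3L)
      for (c3 in c("L", "H"))
        out[[paste0(c1, c2, c3)]] <- ax3[[c3]]
    }
  }
  out
}

#' Build the 13-image derived bank
#'
#' Original volume, LoG at each configured sigma, and the 8 Haar sub-bands.
#' Requires isotropic spacing (the pipeline resamples first) so the LoG
#' scales and texture offsets are physically meaningful.
#'
#' @param vol 3-D array (typically the normalized first post-contrast phase).
#' @param spacing voxel spacing in mm (length 3, must be isotropic).
#' @param config a [feature_config()].
#' @return named list of 13 arrays:
#'   `original`, `log_sigma_<s>`, `wavelet_<band>`.
#' @export
build_image_bank <- function(vol, spacing = c(1, 1, 1),
                             config = feature_config()) {
  spacing <- as.numeric(spacing)
  if (max(spacing) - min(spacing) > 1e-6)
    stop("image bank requires isotropically resampled input", call. = FALSE)
  bank <- list(original = vol)
  for (s in config$log_sigmas)
    bank[[sprintf("log_sigma_%g", s)]] <- log_filter(vol, s, spacing)
  wb <- wavelet_bank(vol)
  for (nm in names(wb)) bank[[paste0("wavelet_", nm)]] <- wb[[nm]]
  bank
}
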