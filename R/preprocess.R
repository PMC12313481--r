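# Geometry and intensity standardization ahead of feature extraction:
# resampling to isotropic voxels with cubic B-spline interpolation (nearest
# neighbour for label maps) and z-score intensity normalization against a
# reference region (pectoralis muscle in the clinical setting), rescaled by
# 100 so the downstream fixed bin width of 25 is meaningful.
#
# Kinetic voxel classification deliberately runs on raw intensities: the
# 50% / 10% rules are ratios, and the z-score shift would corrupt them.
# Normalization applies only to the volumes that feed feature extraction.

#' Preprocessing configuration
#'
#' @param target_spacing isotropic voxel size in mm (default 1.0).
#' @param scale affine rescale applied after the z-score transform
#'   (default 100, so reference-region SD maps to 100 intensity units).
#' @param bin_width fixed discretization bin width on the normalized scale
#'   (default 25, i.e. a quarter of a reference SD).
#' @return object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_spacing = 1.0, scale = 100,
                              bin_width = 25) {
  if (target_spacing <= 0) stop("target_spacing must be > 0", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  structure(list(target_spacing = target_spacing, scale = scale,
                 bin_width = bin_width),
            class = "preprocess_config")
}

# --- cubic B-spline machinery (separable, per axis) ----------------------
# Direct cubic B-spline interpolation needs the spline coefficients, not the
# samples: a causal/anti-causal recursive prefilter with pole z = sqrt(3)-2
# (Unser's algorithm), mirror boundary. Operates along rows of a matrix so
# whole volumes are filtered with two short loops.
bspline_prefilter <- function(S) {
  z <- sqrt(3) - 2
  n <- nrow(S)
  if (n < 2L) return(S)
  S <- 6 * S
  cp <- matrix(0, n, ncol(S))
  horizon <- min(n, ceiling(log(1e-12) / log(abs(z))))
  zk <- z^(seq_len(horizon) - 1L)
  cp[1L, ] <- colSums(S[seq_len(horizon), , drop = FALSE] * zk)
  for (k in 2:n) cp[k, ] <- S[k, ] + z * cp[k - 1L, ]
  cm <- matrix(0, n, ncol(S))
  cm[n, ] <- (z / (z * z - 1)) * (cp[n, ] + z * cp[n - 1L, ])
  for (k in (n - 1L):1L) cm[k, ] <- z * (cm[k + 1L, ] - cp[k, ])
  cm
}

# mirror (reflect-without-repeat) index into 1..n
mirror_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

# interpolate along the first axis of matrix S at continuous 1-based
# coordinates x (vector); method "bspline" or "nearest"
interp_axis <- function(S, x, method) {
  n <- nrow(S)
  if (method == "nearest") {
    idx <- pmin(pmax(as.integer(round(x)), 1L), n)
    return(S[idx, , drop = FALSE])
  }
  C <- bspline_prefilter(S)
  i <- floor(x); t <- x - i
  t2 <- t * t; t3 <- t2 * t
  w0 <- (1 - 3 * t + 3 * t2 - t3) / 6
  w1 <- (4 - 6 * t2 + 3 * t3) / 6
  w2 <- (1 + 3 * t + 3 * t2 - 3 * t3) / 6
  w3 <- t3 / 6
  r0 <- mirror_index(i - 1L, n); r1 <- mirror_index(i, n)
  r2 <- mirror_index(i + 1L, n); r3 <- mirror_index(i + 2L, n)
  w0 * C[r0, , drop = FALSE] + w1 * C[r1, , drop = FALSE] +
    w2 * C[r2, , drop = FALSE] + w3 * C[r3, , drop = FALSE]
}

# resample one axis of a 3-D array to new continuous coordinates
resample_one_axis <- function(vol, axis, x, method) {
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  d <- dim(v)
  out <- interp_axis(matrix(v, d[1L], d[2L] * d[3L]), x, method)
  out <- array(out, c(length(x), d[2L], d[3L]))
  aperm(out, order(perm))
}

# new grid size + input-index coordinates for one axis (voxel-center
# convention, origin at the first voxel center; size rule matches the
# standard round(old_size * old_spacing / new_spacing))
resample_coords <- function(n_old, sp_old, sp_new) {
  n_new <- max(1L, as.integer(round(n_old * sp_old / sp_new)))
  list(n = n_new, x = 1 + (seq_len(n_new) - 1L) * sp_new / sp_old)
}

#' Resample a volume to a new isotropic spacing
#'
#' Cubic B-spline interpolation for images, nearest neighbour for masks and
#' label maps (which therefore keep their exact label set). Output size per
#' axis is `round(n * spacing / target_spacing)`, preserving physical extent
#' to within one voxel.
#'
#' @param vol 3-D array.
#' @param spacing current voxel spacing in mm (length 3).
#' @param config a [preprocess_config()] (uses `target_spacing`).
#' @param method `"bspline"` (images) or `"nearest"` (masks/labels).
#' @return resampled 3-D array with attribute `spacing`.
#' @export
resample_volume <- function(vol, spacing, config = preprocess_config(),
                            method = c("bspline", "nearest")) {
  method <- match.arg(method)
  spacing <- as.numeric(spacing)
  tgt <- config$target_spacing
  out <- vol
  for (a in 1:3) {
    rc <- resample_coords(dim(out)[a], spacing[a], tgt)
    if (rc$n == dim(out)[a] && isTRUE(all.equal(spacing[a], tgt))) next
    out <- resample_one_axis(out, a, rc$x, method)
  }
  if (method == "nearest") out <- array(as.integer(out), dim(out))
  attr(out, "spacing") <- rep(tgt, 3L)
  out
}

#' Resample a DCE series and its mask to isotropic voxels
#'
#' All phases are resampled with cubic B-spline interpolation; the mask with
#' nearest neighbour on the same target grid.
#'
#' @param series a [dce_series()].
#' @param mask aligned integer/logical 3-D array.
#' @param config a [preprocess_config()].
#' @return list with resampled `series` and `mask`.
#' @export
resample_isotropic <- function(series, mask, config = preprocess_config()) {
  stopifnot_mask(mask, series$phases[[1L]])
  phases <- lapply(series$phases, resample_volume,
                   spacing = series$spacing, config = config,
                   method = "bspline")
  phases <- lapply(phases, function(v) { attributes(v) <- list(dim = dim(v)); v })
  m <- resample_volume(mask, series$spacing, config, method = "nearest")
  list(series = dce_series(phases, rep(config$target_spacing, 3L)),
       mask = m)
}

#' Z-score normalization map from a reference region
#'
#' Computes the shared affine map `x -> (x - mean_ref)/sd_ref * scale` from
#' a reference-region mask (pectoralis muscle in the clinical pipeline) on
#' one volume — conventionally the first post-contrast phase — so the same
#' map can be applied to every phase of a patient.
#'
#' @param vol 3-D volume the reference statistics are read from.
#' @param reference_mask 0/1 array marking the reference region.
#' @param scale affine rescale (default 100).
#' @return list with `center`, `sd`, `scale` and closure `apply`.
#' @export
zscore_map <- function(vol, reference_mask, scale = 100) {
  idx <- which(reference_mask > 0)
  if (length(idx) == 0L)
    stop("reference region is empty", call. = FALSE)
  vals <- vol[idx]
  m <- mean(vals); s <- stats::sd(vals)
  if (!is.finite(s) || s <= 0)
    stop("reference region has zero intensity SD", call. = FALSE)
  list(center = m, sd = s, scale = scale,
       apply = function(x) (x - m) / s * scale)
}

#' Apply z-score normalization to a volume
#'
#' `(vol - mean_ref)/sd_ref * scale`; over the reference region itself the
#' result has mean 0 and SD `scale`. Being affine and increasing, the map
#' preserves the rank order of voxel intensities exactly.
#'
#' @param vol 3-D volume.
#' @param reference_mask 0/1 reference-region mask (ignored when `map` is
#'   given).
#' @param map optional precomputed [zscore_map()] shared across phases.
#' @param scale affine rescale (default 100).
#' @return normalized 3-D array.
#' @export
normalize_zscore <- function(vol, reference_mask = NULL, map = NULL,
                             scale = 100) {
  if (is.null(map)) {
    if (is.null(reference_mask))
      stop("either reference_mask or map is required", call. = FALSE)
    map <- zscore_map(vol, reference_mask, scale)
  }
  map$apply(vol)
}
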