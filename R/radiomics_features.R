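# Radiomic feature extraction from the first post-contrast phase over the
# whole-tumor or washout-region ROI. The inventory is pinned to the study
# design: 14 shape features on the original geometry plus, per image type
# (original + 4 LoG + 8 wavelet = 13), 18 first-order, 22 or 24 GLCM, 14
# GLDM, 16 GLRLM and 16 GLSZM features:
#   14 + 13 * (18 + 22 + 14 + 16 + 16) = 1132   (whole-tumor run)
#   14 + 13 * (18 + 24 + 14 + 16 + 16) = 1158   (washout-region run)

# the 2 GLCM features absent from the 22-feature set: SumAverage duplicates
# 2*JointAverage under symmetric matrices, and MCC is the costliest
glcm_dropped_at_22 <- c("SumAverage", "MCC")

#' Radiomic feature configuration
#'
#' @param glcm_count 22 or 24 GLCM features per image type: 22 gives the
#'   1132-feature whole-tumor inventory, 24 the 1158-feature washout one.
#' @param log_sigmas LoG filter scales in mm (4 values for the 13-type bank).
#' @param bin_width fixed discretization bin width (normalized intensity
#'   units; default 25 after z-score normalization scaled by 100).
#' @param min_roi_voxels ROIs smaller than this raise a degenerate-ROI error
#'   (default 10), mirroring the exclusion of cases whose kinetic maps are
#'   insufficient for analysis.
#' @return object of class `feature_config`.
#' @export
feature_config <- function(glcm_count = 22L, log_sigmas = c(1, 2, 3, 4),
                           bin_width = 25, min_roi_voxels = 10L) {
  glcm_count <- as.integer(glcm_count)
  if (!glcm_count %in% c(22L, 24L))
    stop("glcm_count must be 22 or 24", call. = FALSE)
  if (length(log_sigmas) != 4L || any(log_sigmas <= 0))
    stop("log_sigmas must be 4 positive scales (mm)", call. = FALSE)
  if (bin_width <= 0) stop("bin_width must be > 0", call. = FALSE)
  structure(list(glcm_count = glcm_count, log_sigmas = log_sigmas,
                 bin_width = bin_width,
                 min_roi_voxels = as.integer(min_roi_voxels)),
            class = "feature_config")
}

#' Per-class feature counts for a configuration
#'
#' Closed form: `total = 14 + 13 * (18 + glcm_count + 14 + 16 + 16)`.
#' The default whole-tumor configuration gives shape 14, first-order 234,
#' GLCM 286, GLDM 182, GLRLM 208, GLSZM 208, total 1132; the washout
#' configuration (`glcm_count = 24`) gives GLCM 312, total 1158.
#'
#' @param config a [feature_config()].
#' @return named list of per-class counts, `n_image_types` and `total`.
#' @export
feature_inventory <- function(config = feature_config()) {
  n_img <- 1L + length(config$log_sigmas) + 8L
  counts <- list(shape = 14L,
                 firstorder = 18L * n_img,
                 glcm = config$glcm_count * n_img,
                 gldm = 14L * n_img,
                 glrlm = 16L * n_img,
                 glszm = 16L * n_img)
  counts$n_image_types <- n_img
  counts$total <- counts$shape + counts$firstorder + counts$glcm +
    counts$gldm + counts$glrlm + counts$glszm
  counts
}

# ---- first-order features (18) ------------------------------------------

firstorder_features <- function(vals, gray_levels, voxvol) {
  n <- length(vals)
  mu <- mean(vals)
  qs <- stats::quantile(vals, c(0.10, 0.25, 0.50, 0.75, 0.90),
                        names = FALSE, type = 7)
  varp <- sum((vals - mu)^2) / n
  sdev <- sqrt(varp)
  mid <- vals[vals >= qs[1] & vals <= qs[5]]
  p <- tabulate(gray_levels) / n
  skew <- if (sdev > 0) (sum((vals - mu)^3) / n) / sdev^3 else 0
  kurt <- if (sdev > 0) (sum((vals - mu)^4) / n) / varp^2 else 0
  c(Energy = sum(vals^2),
    TotalEnergy = voxvol * sum(vals^2),
    Entropy = -sum(p[p > 0] * log2(p[p > 0])),
    Minimum = min(vals),
    Percentile10 = qs[1],
    Percentile90 = qs[5],
    Maximum = max(vals),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = skew,
    Kurtosis = kurt,
    Variance = varp,
    Uniformity = sum(p^2))
}

# ---- shape features (14), voxel-based ------------------------------------

# boundary voxels: ROI voxels with at least one 6-neighbour outside the ROI
boundary_voxels <- function(mask) {
  d <- dim(mask)
  m <- mask > 0
  offs <- connectivity_offsets(6L, half = FALSE)
  pos <- arrayInd(which(m), d)
  onb <- rep(FALSE, nrow(pos))
  for (k in seq_len(nrow(offs))) {
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    nb_in_mask <- rep(FALSE, nrow(pos))
    nb_lin <- nb[!outside, 1] + d[1] * (nb[!outside, 2] - 1L) +
      d[1] * d[2] * (nb[!outside, 3] - 1L)
    nb_in_mask[!outside] <- m[nb_lin]
    onb <- onb | !nb_in_mask
  }
  pos[onb, , drop = FALSE]
}

# voxel-face surface area: exposed 6-neighbour faces times face area
voxel_surface_area <- function(mask, spacing) {
  d <- dim(mask)
  m <- mask > 0
  areas <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
             spacing[1] * spacing[2])
  total <- 0
  offs <- connectivity_offsets(6L, half = FALSE)
  pos <- arrayInd(which(m), d)
  for (k in seq_len(nrow(offs))) {
    ax <- which(offs[k, ] != 0)
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    outside <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    nb_lin <- nb[!outside, 1] + d[1] * (nb[!outside, 2] - 1L) +
      d[1] * d[2] * (nb[!outside, 3] - 1L)
    exposed <- sum(outside) + sum(!m[nb_lin])
    total <- total + exposed * areas[ax]
  }
  total
}

max_pairwise_diameter <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  if (nrow(coords) > 4000L) {  # keep dist() bounded; hull-ish subsample
    keep <- unique(c(apply(coords, 2, which.min), apply(coords, 2, which.max),
                     seq(1L, nrow(coords), length.out = 4000L)))
    coords <- coords[keep, , drop = FALSE]
  }
  max(stats::dist(coords))
}

shape_features <- function(mask, spacing) {
  d <- dim(mask)
  idx <- which(mask > 0)
  n <- length(idx)
  voxvol <- voxel_volume(spacing)
  vol <- n * voxvol
  area <- voxel_surface_area(mask, spacing)
  pos <- arrayInd(idx, d)
  phys <- sweep(pos, 2, spacing, `*`)
  bnd <- boundary_voxels(mask)
  bphys <- sweep(bnd, 2, spacing, `*`)
  if (nrow(bphys) == 0L) bphys <- phys
  d3 <- max_pairwise_diameter(bphys)
  d2 <- function(cols) {
    best <- 0
    split_ax <- setdiff(1:3, cols)
    for (s in unique(bnd[, split_ax])) {
      cc <- bphys[bnd[, split_ax] == s, cols, drop = FALSE]
      if (nrow(cc) >= 2L) best <- max(best, max_pairwise_diameter(cc))
    }
    best
  }
  # principal axis lengths from the physical-coordinate covariance
  if (n > 1L) {
    ev <- sort(eigen(stats::cov(phys), only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  axes <- 4 * sqrt(ev)
  sph <- (36 * pi * vol^2)^(1 / 3) / area
  c(MeshVolume = vol,
    VoxelVolume = vol,
    SurfaceArea = area,
    SurfaceVolumeRatio = area / vol,
    Sphericity = sph,
    Maximum3DDiameter = d3,
    Maximum2DDiameterSlice = d2(c(1, 2)),
    Maximum2DDiameterColumn = d2(c(1, 3)),
    Maximum2DDiameterRow = d2(c(2, 3)),
    MajorAxisLength = axes[1],
    MinorAxisLength = axes[2],
    LeastAxisLength = axes[3],
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1)
}

# ---- extraction ----------------------------------------------------------

#' Extract the full radiomic feature vector from one volume + ROI
#'
#' Shape features are computed once on the ROI geometry; intensity and
#' texture features are computed per image type of the 13-image bank, with
#' fixed-bin-width discretization anchored at each derived image's ROI
#' minimum. Feature names follow `<imagetype>_<class>_<feature>`.
#'
#' @param vol 3-D volume (normalized first post-contrast phase), isotropic.
#' @param roi_mask 0/1 array; fewer than `min_roi_voxels` foreground voxels
#'   raises a degenerate-ROI error.
#' @param spacing voxel spacing in mm.
#' @param config a [feature_config()].
#' @return named numeric vector of length `feature_inventory(config)$total`.
#' @export
extract_features <- function(vol, roi_mask, spacing = c(1, 1, 1),
                             config = feature_config()) {
  stopifnot_mask(roi_mask, vol)
  idx <- which(roi_mask > 0)
  if (length(idx) < config$min_roi_voxels)
    stop(sprintf("degenerate ROI: %d voxels < minimum %d",
                 length(idx), config$min_roi_voxels), call. = FALSE)
  voxvol <- voxel_volume(spacing)
  out <- shape_features(roi_mask, spacing)
  names(out) <- paste0("original_shape_", names(out))
  bank <- build_image_bank(vol, spacing, config)
  glcm_keep <- if (config$glcm_count == 22L) {
    setdiff(c("Autocorrelation", "ClusterProminence", "ClusterShade",
              "ClusterTendency", "Contrast", "Correlation",
              "DifferenceAverage", "DifferenceEntropy", "DifferenceVariance",
              "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2", "InverseVariance",
              "JointAverage", "JointEnergy", "JointEntropy", "MCC",
              "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"),
            glcm_dropped_at_22)
  } else NULL
  for (nm in names(bank)) {
    v <- bank[[nm]]
    vals <- v[idx]
    gl <- discretize_fixed_width(vals, config$bin_width)
    Ng <- attr(gl, "Ng")
    G <- array(NA_integer_, dim(v)); G[idx] <- gl
    fo <- firstorder_features(vals, gl, voxvol)
    glcm <- glcm_features(glcm_matrix(G, Ng))
    if (!is.null(glcm_keep)) glcm <- glcm[glcm_keep]
    gldm <- gldm_features(gldm_matrix(G, Ng))
    glrlm <- glrlm_features(glrlm_matrix(G, Ng))
    glszm <- glszm_features(glszm_matrix(G, Ng))
    blk <- c(stats::setNames(fo, paste0(nm, "_firstorder_", names(fo))),
             stats::setNames(glcm, paste0(nm, "_glcm_", names(glcm))),
             stats::setNames(gldm, paste0(nm, "_gldm_", names(gldm))),
             stats::setNames(glrlm, paste0(nm, "_glrlm_", names(glrlm))),
             stats::setNames(glszm, paste0(nm, "_glszm_", names(glszm))))
    out <- c(out, blk)
  }
  stopifnot(!anyDuplicated(names(out)))
  out
}

#' Extract features from a DCE series for a given ROI
#'
#' Reads the first post-contrast phase of the series (the phase the study
#' design pins for feature extraction) and delegates to [extract_features()].
#'
#' @param series a [dce_series()].
#' @param roi_mask 0/1 ROI array (whole tumor or washout subregion).
#' @param config a [feature_config()].
#' @return named numeric feature vector.
#' @export
extract_feature_vector <- function(series, roi_mask,
                                   config = feature_config()) {
  extract_features(phase_first(series), roi_mask, series$spacing, config)
}
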