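# Synthetic DCE phantoms and feature cohorts with known ground truth.
#
# The patient cohort behind this analysis is not publicly deposited, so the
# pipeline is driven end-to-end by phantoms: every in-mask voxel follows one
# of three kinetic archetypes (persistent / washout / plateau), background
# voxels follow a non-enhancing curve, and the archetype assignment is kept
# as a ground-truth subregion map against which the segmentation can be
# scored exactly.

#' Kinetic curve archetype
#'
#' Parameterizes a voxel time-intensity curve by its pre-contrast baseline,
#' the relative rise from pre-contrast to the first post-contrast phase
#' (`uptake_fraction`, which must exceed the 50% enhancement gate for an
#' enhancing voxel) and the relative change from first to last post phase
#' (`late_slope_fraction`: > +0.10 persistent, < -0.10 washout, within
#' +/-0.10 plateau).
#'
#' @param name one of `"persistent"`, `"washout"`, `"plateau"`.
#' @param baseline pre-contrast signal intensity (> 0, arbitrary units).
#' @param uptake_fraction relative S0 -> S1 rise (unitless).
#' @param late_slope_fraction relative S1 -> Slast change (unitless). If
#'   `NULL`, a class-typical default is used: +0.30 persistent, -0.30
#'   washout, 0 plateau.
#' @return object of class `curve_archetype`.
#' @export
curve_archetype <- function(name = c("persistent", "washout", "plateau"),
                            baseline = 100,
                            uptake_fraction = 1.0,
                            late_slope_fraction = NULL) {
  name <- match.arg(name)
  if (!is.finite(baseline) || baseline <= 0)
    stop("baseline must be positive", call. = FALSE)
  if (is.null(late_slope_fraction)) {
    late_slope_fraction <- switch(name, persistent = 0.30,
                                  washout = -0.30, plateau = 0)
  }
  ok <- switch(name,
    persistent = late_slope_fraction > 0.10,
    washout    = late_slope_fraction < -0.10,
    plateau    = abs(late_slope_fraction) <= 0.10)
  if (!ok)
    stop(sprintf("late_slope_fraction %.3f inconsistent with archetype '%s'",
                 late_slope_fraction, name), call. = FALSE)
  structure(list(name = name, baseline = baseline,
                 uptake_fraction = uptake_fraction,
                 late_slope_fraction = late_slope_fraction),
            class = "curve_archetype")
}

#' Simulate one voxel time-intensity curve
#'
#' Element 1 is the pre-contrast value; element 2 the first post-contrast
#' value `baseline * (1 + uptake_fraction)`; the final element the last
#' post-contrast value `first_post * (1 + late_slope_fraction)`. Intermediate
#' post phases interpolate linearly in phase index between the first and
#' last post values (the voxel classification only ever reads pre, first and
#' last, so the intermediate shape is deliberately simple). Gaussian noise
#' with SD `noise_sd` is added independently per phase.
#'
#' @param archetype a [curve_archetype()].
#' @param n_post_phases number of post-contrast phases (>= 2; the clinical
#'   protocol this emulates acquires 8).
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param seed optional integer seed for reproducibility.
#' @return numeric vector of length `1 + n_post_phases`.
#' @export
#' @examples
#' wa <- curve_archetype("washout", baseline = 100, uptake_fraction = 0.6,
#'                       late_slope_fraction = -0.125)
#' simulate_voxel_curve(wa, n_post_phases = 8, noise_sd = 0)
simulate_voxel_curve <- function(archetype, n_post_phases = 8L,
                                 noise_sd = 0, seed = NULL) {
  stopifnot(inherits(archetype, "curve_archetype"))
  n_post_phases <- as.integer(n_post_phases)
  if (n_post_phases < 2L)
    stop("n_post_phases must be >= 2", call. = FALSE)
  if (archetype$baseline <= 0)
    stop("baseline must be positive", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  s0 <- archetype$baseline
  s1 <- s0 * (1 + archetype$uptake_fraction)
  slast <- s1 * (1 + archetype$late_slope_fraction)
  post <- s1 + (slast - s1) * (seq_len(n_post_phases) - 1L) / (n_post_phases - 1L)
  curve <- c(s0, post)
  if (noise_sd > 0)
    curve <- curve + stats::rnorm(length(curve), sd = noise_sd)
  curve
}

#' Phantom specification
#'
#' @param grid_shape integer length-3, voxels per axis.
#' @param voxel_spacing mm per axis (length 3).
#' @param semi_axes ellipsoid tumor semi-axes in mm (length 3).
#' @param lobulation amplitude (fraction of radius, in `[0, 0.5)`) of a
#'   low-order spherical-harmonic perturbation of the ellipsoid surface,
#'   giving the lobulated margins typical of these tumors; 0 = smooth
#'   ellipsoid. Masks remain connected by construction.
#' @param class_proportions length-3 nonnegative vector
#'   (washout, plateau, persistent) summing to 1 — the mixture from which
#'   each in-mask voxel's archetype is drawn.
#' @param noise_sd additive Gaussian noise SD in signal units.
#' @param n_post_phases post-contrast phase count (default 8).
#' @param baseline pre-contrast signal level for tumor voxels.
#' @param seed integer seed.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         voxel_spacing = c(1, 1, 1),
                         semi_axes = c(12, 10, 9),
                         lobulation = 0,
                         class_proportions = c(0.25, 0.34, 0.41),
                         noise_sd = 0,
                         n_post_phases = 8L,
                         baseline = 100,
                         seed = 1L) {
  p <- as.numeric(class_proportions)
  if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("class_proportions must be 3 nonnegative numbers summing to 1",
         call. = FALSE)
  if (n_post_phases < 2L) stop("n_post_phases must be >= 2", call. = FALSE)
  if (lobulation < 0 || lobulation >= 0.5)
    stop("lobulation must be in [0, 0.5)", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_spacing = as.numeric(voxel_spacing),
                 semi_axes = as.numeric(semi_axes),
                 lobulation = lobulation,
                 class_proportions = p,
                 noise_sd = noise_sd,
                 n_post_phases = as.integer(n_post_phases),
                 baseline = baseline,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Default archetypes used by simulate_phantom, keyed by subregion code
# (1 washout, 2 plateau, 3 persistent). Uptake 1.0 = 100% rise, comfortably
# above the 50% gate; slopes +/-0.30 sit well outside the +/-10% band so
# moderate noise does not flip classes.
phantom_archetypes <- function(baseline = 100) {
  list(curve_archetype("washout",    baseline, 1.0, -0.30),
       curve_archetype("plateau",    baseline, 1.0,  0.00),
       curve_archetype("persistent", baseline, 1.0, +0.30))
}

# Ellipsoidal (optionally lobulated) tumor mask centered in the grid.
# Lobulation scales the local radius by 1 + a*Y(theta,phi) with a real
# low-order harmonic, so radius stays within (1-a, 1+a) of the ellipsoid
# and the mask stays star-shaped (hence connected).
make_tumor_mask <- function(grid_shape, voxel_spacing, semi_axes,
                            lobulation = 0) {
  ctr <- (grid_shape + 1) / 2
  x <- (seq_len(grid_shape[1]) - ctr[1]) * voxel_spacing[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) * voxel_spacing[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) * voxel_spacing[3]
  if (any(semi_axes * (1 + lobulation) >
          (grid_shape * voxel_spacing) / 2))
    stop("tumor geometry exceeds the grid", call. = FALSE)
  X <- array(x, grid_shape)
  Y <- array(rep(y, each = grid_shape[1]), grid_shape)
  Z <- array(rep(z, each = grid_shape[1] * grid_shape[2]), grid_shape)
  u <- X / semi_axes[1]; v <- Y / semi_axes[2]; w <- Z / semi_axes[3]
  r <- sqrt(u^2 + v^2 + w^2)
  if (lobulation > 0) {
    # real sectoral l=3 harmonic (up to normalization): cos(3*phi) sin^3(theta)
    rho <- pmax(sqrt(u^2 + v^2 + w^2), .Machine$double.eps)
    sin_theta3 <- (sqrt(u^2 + v^2) / rho)^3
    phi <- atan2(v, u)
    pert <- 1 + lobulation * cos(3 * phi) * sin_theta3
    r <- r / pert
  }
  r <= 1
}

#' Simulate a DCE phantom with ground-truth kinetic subregions
#'
#' Builds an ellipsoidal (optionally lobulated) tumor inside the grid,
#' assigns each in-mask voxel a kinetic archetype drawn from
#' `class_proportions`, synthesizes the full 1 + `n_post_phases` series per
#' voxel via [simulate_voxel_curve()]'s curve model, and keeps the archetype
#' assignment as the ground-truth subregion map (codes 1 washout, 2 plateau,
#' 3 persistent; 0 outside). Background voxels enhance by only 10%
#' (below the 50% gate) so they are excluded from every ground-truth label.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `series` ([dce_series()]), `mask` (0/1 array),
#'   `truth` (integer label array), `class_counts` (named realized counts)
#'   and `spec`.
#' @export
simulate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  gs <- spec$grid_shape
  mask <- make_tumor_mask(gs, spec$voxel_spacing, spec$semi_axes,
                          spec$lobulation)
  idx <- which(mask)
  n_in <- length(idx)
  if (n_in == 0L) stop("tumor mask is empty", call. = FALSE)

  labels <- sample.int(3L, n_in, replace = TRUE, prob = spec$class_proportions)
  truth <- array(0L, gs)
  truth[idx] <- labels

  arch <- phantom_archetypes(spec$baseline)
  np <- spec$n_post_phases
  n_phases <- np + 1L

  # noiseless curve per archetype, plus the non-enhancing background curve
  curves <- vapply(arch, simulate_voxel_curve, numeric(n_phases),
                   n_post_phases = np, noise_sd = 0)
  bg_arch <- structure(list(name = "background", baseline = spec$baseline,
                            uptake_fraction = 0.10,
                            late_slope_fraction = 0),
                       class = "curve_archetype")
  bg_curve <- simulate_voxel_curve(bg_arch, n_post_phases = np, noise_sd = 0)

  phases <- vector("list", n_phases)
  for (ph in seq_len(n_phases)) {
    vol <- array(bg_curve[ph], gs)
    vol[idx] <- curves[ph, labels]
    if (spec$noise_sd > 0)
      vol <- vol + array(stats::rnorm(prod(gs), sd = spec$noise_sd), gs)
    phases[[ph]] <- vol
  }

  list(series = dce_series(phases, spec$voxel_spacing),
       mask = array(as.integer(mask), gs),
       truth = truth,
       class_counts = c(washout = sum(labels == 1L),
                        plateau = sum(labels == 2L),
                        persistent = sum(labels == 3L)),
       spec = spec)
}

#' Cohort specification for the feature-table generator
#'
#' Stands in for the 124-patient feature matrices: `n_informative` columns
#' carry a standardized mean difference `feature_effect` between the two
#' outcome classes, the rest are pure noise.
#'
#' @param n_patients cohort size.
#' @param prevalence fraction of positive-class patients, in (0, 1).
#' @param feature_effect standardized mean difference on informative columns.
#' @param n_features total feature count.
#' @param n_informative number of informative columns (<= `n_features`).
#' @param seed integer seed.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 124L, prevalence = 0.5,
                        feature_effect = 1.0, n_features = 100L,
                        n_informative = 5L, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)", call. = FALSE)
  if (n_informative > n_features)
    stop("n_informative must not exceed n_features", call. = FALSE)
  structure(list(n_patients = as.integer(n_patients), prevalence = prevalence,
                 feature_effect = feature_effect,
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a patients-by-features cohort with binary labels
#'
#' Features are iid standard normal; for positive-class patients the first
#' `n_informative` columns are shifted by `feature_effect` (a standardized
#' mean difference, since the noise SD is 1). Labels are Bernoulli at the
#' stated prevalence.
#'
#' @param spec a [cohort_spec()].
#' @return list with `features` (matrix with unique column names
#'   `feat_0001`...), `labels` (0/1 integer vector) and
#'   `informative` (column names of the informative set).
#' @export
simulate_feature_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients; p <- spec$n_features
  labels <- stats::rbinom(n, 1L, spec$prevalence)
  x <- matrix(stats::rnorm(n * p), n, p)
  cn <- sprintf("feat_%04d", seq_len(p))
  colnames(x) <- cn
  if (spec$n_informative > 0L)
    x[labels == 1L, seq_len(spec$n_informative)] <-
      x[labels == 1L, seq_len(spec$n_informative), drop = FALSE] +
      spec$feature_effect
  rownames(x) <- sprintf("pt_%04d", seq_len(n))
  list(features = x, labels = labels,
       informative = cn[seq_len(spec$n_informative)])
}

#' Simulate paired washout-region and whole-tumor feature tables
#'
#' Emulates the two-ROI design on one cohort: the same patients get a
#' washout-region table whose informative columns carry
#' `spec$feature_effect`, and a whole-tumor table with effect
#' `tumor_effect` (default 0, i.e. only the washout ROI carries signal —
#' the regime under which the subregion model should outperform the
#' whole-tumor model).
#'
#' @param spec a [cohort_spec()]; drives the washout table and the labels.
#' @param tumor_effect standardized mean difference in the whole-tumor
#'   table (default 0).
#' @return list with `washout`, `tumor` (feature matrices sharing rows),
#'   `labels` and `informative`.
#' @export
simulate_paired_roi_cohort <- function(spec, tumor_effect = 0) {
  wa <- simulate_feature_cohort(spec)
  tu_spec <- spec
  tu_spec$feature_effect <- tumor_effect
  tu_spec$seed <- spec$seed + 10000L
  tu <- simulate_feature_cohort(tu_spec)
  # same patients: reuse the washout cohort's labels, regenerate the tumor
  # features' class shift (if any) against those labels
  x <- tu$features
  if (tumor_effect != 0) {
    x[, seq_len(spec$n_informative)] <-
      x[, seq_len(spec$n_informative), drop = FALSE] -
      tumor_effect * tu$labels + tumor_effect * wa$labels
  }
  list(washout = wa$features, tumor = x, labels = wa$labels,
       informative = wa$informative)
}
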