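# Per-tumor kinetic-heterogeneity statistics computed from a subregion map
# and the DCE phases: component proportions, the KH entropy, peak
# enhancement, enhanced volume, and the predominant / worst curve types.

#' Proportions of the three kinetic components
#'
#' `P_i = count(label i) / count(labels 1-3)` over the enhanced voxels of a
#' subregion map, in the order (washout, plateau, persistent).
#'
#' @param map integer subregion label array (codes 0-3).
#' @return named numeric length-3 vector summing to 1.
#' @export
component_proportions <- function(map) {
  counts <- c(sum(map == 1L), sum(map == 2L), sum(map == 3L))
  total <- sum(counts)
  if (total == 0L)
    stop("no enhanced voxels: kinetic profile is undefined", call. = FALSE)
  stats::setNames(counts / total, c("washout", "plateau", "persistent"))
}

#' Kinetic heterogeneity (normalized Shannon entropy)
#'
#' \deqn{KH = -\sum_{i=1}^{k} P_i \log_k P_i}
#' with the convention \eqn{0 \log 0 = 0} and \eqn{k = 3} kinetic
#' categories. KH ranges over \eqn{[0, 1]}: 0 when the enhanced region
#' contains a single component (homogeneous), 1 at equal thirds (maximal
#' heterogeneity).
#'
#' @param P nonnegative proportions summing to 1 (tolerance 1e-6).
#' @param k number of kinetic categories (fixed at 3 for the
#'   washout/plateau/persistent partition; kept as an argument so the
#'   normalization is explicit).
#' @return KH value in `[0, 1]`.
#' @export
#' @examples
#' kinetic_heterogeneity(c(1/3, 1/3, 1/3))  # 1
#' kinetic_heterogeneity(c(1, 0, 0))        # 0
kinetic_heterogeneity <- function(P, k = 3L) {
  P <- as.numeric(P)
  if (any(P < 0) || abs(sum(P) - 1) > 1e-6)
    stop("P must be nonnegative proportions summing to 1", call. = FALSE)
  nz <- P > 0
  -sum(P[nz] * log(P[nz]) / log(k)) + 0  # "+ 0" normalizes IEEE -0 to 0
}

#' Peak enhancement over the enhanced region
#'
#' The maximum relative rise `(S1 - S0)/S0` over enhanced voxels — a
#' scale-free measure of the strongest first-pass enhancement in the tumor.
#'
#' @param S0 pre-contrast volume.
#' @param S1 first post-contrast volume.
#' @param enh_mask logical/0-1 enhancement mask.
#' @return unitless maximum relative enhancement.
#' @export
peak_enhancement <- function(S0, S1, enh_mask) {
  idx <- which(enh_mask > 0)
  if (length(idx) == 0L)
    stop("empty enhancement mask: peak enhancement undefined", call. = FALSE)
  max((S1[idx] - S0[idx]) / S0[idx])
}

#' Enhanced volume in mm^3
#'
#' Foreground voxel count times the physical voxel volume. An empty mask is
#' a valid zero-volume result.
#'
#' @param enh_mask logical/0-1 enhancement mask.
#' @param spacing voxel spacing in mm (length 3, positive).
#' @return volume in mm^3.
#' @export
enhanced_volume <- function(enh_mask, spacing) {
  spacing <- as.numeric(spacing)
  if (any(spacing <= 0)) stop("spacing must be positive", call. = FALSE)
  sum(enh_mask > 0) * voxel_volume(spacing)
}

#' Predominant curve type
#'
#' The code (1 washout, 2 plateau, 3 persistent) of the largest component
#' proportion; ties break toward the more suspicious type (washout first).
#'
#' @param P proportions in (washout, plateau, persistent) order.
#' @return integer code in 1..3.
#' @export
predominant_type <- function(P) {
  unname(which.max(P))  # first maximum = smallest code = most suspicious on ties
}

#' Worst (most suspicious) curve type present
#'
#' The smallest code with nonzero proportion under the suspiciousness
#' ordering washout(1) < plateau(2) < persistent(3): any washout at all
#' makes washout the worst type.
#'
#' @param P proportions in (washout, plateau, persistent) order.
#' @return integer code in 1..3.
#' @export
worst_type <- function(P) {
  unname(which(P > 0)[1L])
}

#' Full kinetic profile of one tumor
#'
#' Computes every per-tumor kinetic parameter from the phases and a
#' subregion map: the three component proportions (as percentages in the
#' output row), KH, peak enhancement, enhanced volume and the
#' predominant/worst types. Tumors without enhancing voxels yield a profile
#' of `NA`s flagged `insufficient = TRUE` (mirroring the exclusion of cases
#' whose CAD output is insufficient for analysis) rather than zeros.
#'
#' @param series a [dce_series()].
#' @param map integer subregion map from [segment_kinetics()].
#' @return one-row data.frame with columns `peak_enhancement`,
#'   `enhanced_volume`, `washout_pct`, `plateau_pct`, `persistent_pct`,
#'   `kinetic_heterogeneity`, `predominant_type`, `worst_type`,
#'   `insufficient`.
#' @export
kinetic_profile <- function(series, map) {
  enh <- map > 0L
  if (!any(enh)) {
    return(data.frame(peak_enhancement = NA_real_, enhanced_volume = NA_real_,
                      washout_pct = NA_real_, plateau_pct = NA_real_,
                      persistent_pct = NA_real_,
                      kinetic_heterogeneity = NA_real_,
                      predominant_type = NA_integer_, worst_type = NA_integer_,
                      insufficient = TRUE))
  }
  P <- component_proportions(map)
  data.frame(row.names = NULL,
             peak_enhancement = peak_enhancement(phase_pre(series),
                                                 phase_first(series), enh),
             enhanced_volume = enhanced_volume(enh, series$spacing),
             washout_pct = 100 * P[["washout"]],
             plateau_pct = 100 * P[["plateau"]],
             persistent_pct = 100 * P[["persistent"]],
             kinetic_heterogeneity = kinetic_heterogeneity(P),
             predominant_type = predominant_type(P),
             worst_type = worst_type(P),
             insufficient = FALSE)
}
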