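# Voxel-wise kinetic classification of the enhancing tumor.
#
# Two ratio rules drive the partition, both computed on raw (pre-
# normalization) intensities because they are relative changes:
#   gate:  a voxel enhances if (S1 - S0)/S0 > enhancement_gate  (default 50%)
#   type:  r = (Slast - S1)/S1; r > +late_delta -> persistent,
#          r < -late_delta -> washout, |r| <= late_delta -> plateau.
# Boundary conventions are strict for the gate and for persistent/washout;
# plateau takes the closed band — mirroring "over 50%", "more than 10%",
# "within a 10% range".

#' Kinetic classification thresholds
#'
#' @param enhancement_gate relative S0 -> S1 rise required for a voxel to
#'   count as enhancing (strict `>`; default 0.50).
#' @param late_delta half-width of the plateau band on the relative
#'   S1 -> Slast change (default 0.10). Plateau is the closed interval
#'   `[-late_delta, +late_delta]`; persistent/washout are strict.
#' @return object of class `kinetic_thresholds`.
#' @export
kinetic_thresholds <- function(enhancement_gate = 0.50, late_delta = 0.10) {
  if (!(late_delta > 0 && late_delta < enhancement_gate))
    stop("need 0 < late_delta < enhancement_gate", call. = FALSE)
  structure(list(enhancement_gate = enhancement_gate, late_delta = late_delta),
            class = "kinetic_thresholds")
}

#' Subregion label codes
#'
#' Codes follow the suspiciousness ordering used in clinical reporting:
#' 1 = washout (most suspicious), 2 = plateau, 3 = persistent;
#' 0 = non-enhancing / outside the tumor.
#' @format named integer vector.
#' @export
SUBREGION_CODES <- c(none = 0L, washout = 1L, plateau = 2L, persistent = 3L)

#' Enhancement mask: voxels rising more than the gate
#'
#' A voxel is included iff it lies inside the tumor mask, has `S0 > 0`, and
#' `(S1 - S0)/S0 > enhancement_gate` (strict). Voxels with non-positive or
#' non-finite `S0` are excluded and counted in the attached quality report,
#' never classified.
#'
#' @param S0 pre-contrast volume.
#' @param S1 first post-contrast volume.
#' @param tumor_mask 3-D 0/1 (or logical) array.
#' @param thresholds a [kinetic_thresholds()].
#' @return logical 3-D array with attribute `quality` (list with
#'   `n_tumor`, `n_enhanced`, `n_bad_baseline`).
#' @export
enhancement_mask <- function(S0, S1, tumor_mask,
                             thresholds = kinetic_thresholds()) {
  stopifnot_mask(tumor_mask, S0)
  if (!identical(dim(S0), dim(S1)))
    stop("S0 and S1 must share a grid", call. = FALSE)
  inside <- tumor_mask > 0
  if (!any(inside)) stop("tumor mask is empty", call. = FALSE)
  bad <- inside & (!is.finite(S0) | S0 <= 0)
  ok <- inside & !bad
  m <- array(FALSE, dim(S0))
  m[ok] <- (S1[ok] - S0[ok]) / S0[ok] > thresholds$enhancement_gate
  attr(m, "quality") <- list(n_tumor = sum(inside),
                             n_enhanced = sum(m),
                             n_bad_baseline = sum(bad))
  m
}

#' Classify enhanced voxels into washout / plateau / persistent
#'
#' For each voxel in the enhancement mask, the relative late change
#' `r = (Slast - S1)/S1` is compared against the plateau band:
#' `r > +late_delta` is persistent (3), `r < -late_delta` washout (1),
#' otherwise plateau (2). Non-enhanced voxels get 0.
#'
#' @param S1 first post-contrast volume.
#' @param Slast last post-contrast volume.
#' @param enh_mask logical array from [enhancement_mask()].
#' @param thresholds a [kinetic_thresholds()].
#' @return integer label array (a subregion map) with attribute
#'   `spacing` copied from `attr(enh_mask, "spacing")` when present.
#' @export
classify_enhancement_voxels <- function(S1, Slast, enh_mask,
                                        thresholds = kinetic_thresholds()) {
  if (!any(enh_mask)) stop("enhancement mask is empty", call. = FALSE)
  idx <- which(enh_mask)
  s1 <- S1[idx]
  stopifnot(all(is.finite(s1)), all(s1 > 0))  # guaranteed by the gate
  r <- (Slast[idx] - s1) / s1
  lab <- rep(SUBREGION_CODES[["plateau"]], length(idx))
  lab[r > thresholds$late_delta]  <- SUBREGION_CODES[["persistent"]]
  lab[r < -thresholds$late_delta] <- SUBREGION_CODES[["washout"]]
  out <- array(0L, dim(S1))
  out[idx] <- lab
  if (!is.null(attr(enh_mask, "spacing")))
    attr(out, "spacing") <- attr(enh_mask, "spacing")
  out
}

#' Segment a DCE series into kinetic subregions
#'
#' Convenience wrapper: computes the enhancement mask from pre and first
#' post-contrast phases, then classifies enhanced voxels from first and last
#' post-contrast phases.
#'
#' @param series a [dce_series()].
#' @param tumor_mask 3-D 0/1 array aligned with the series.
#' @param thresholds a [kinetic_thresholds()].
#' @return integer subregion map (codes 0-3) with attributes `spacing` and
#'   `quality`.
#' @export
segment_kinetics <- function(series, tumor_mask,
                             thresholds = kinetic_thresholds()) {
  m <- enhancement_mask(phase_pre(series), phase_first(series),
                        tumor_mask, thresholds)
  if (!any(m)) {
    # nothing rose above the gate: an empty (all-zero) subregion map, the
    # downstream kinetic_profile marks such tumors insufficient
    sub <- array(0L, dim(m))
  } else {
    sub <- classify_enhancement_voxels(phase_first(series),
                                       phase_last(series), m, thresholds)
  }
  attr(sub, "spacing") <- series$spacing
  attr(sub, "quality") <- attr(m, "quality")
  sub
}

# neighbor offsets for 6- or 26-connectivity; only the 3 / 13 "positive"
# half is needed for undirected adjacency
connectivity_offsets <- function(connectivity = 26L, half = TRUE) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0L, , drop = FALSE]
  if (connectivity == 6L) g <- g[rowSums(abs(g)) == 1L, , drop = FALSE]
  else if (connectivity != 26L)
    stop("connectivity must be 6 or 26", call. = FALSE)
  if (half) {
    keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
      (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
    g <- g[keep, , drop = FALSE]
  }
  g
}

# Connected-component labelling of the foreground of a 3-D array under 6- or
# 26-connectivity. Returns integer array of component ids (0 = background).
# Edges are assembled vectorized per offset; igraph does the union-find.
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  fg <- which(mask > 0)
  out <- array(0L, d)
  if (length(fg) == 0L) return(out)
  pos <- arrayInd(fg, d)
  key <- array(0L, d)
  key[fg] <- seq_along(fg)
  offs <- connectivity_offsets(connectivity, half = TRUE)
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- pos + matrix(offs[k, ], nrow(pos), 3, byrow = TRUE)
    okv <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
           nb[, 2] >= 1 & nb[, 2] <= d[2] &
           nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(okv)) next
    nb_lin <- nb[okv, 1] + d[1] * (nb[okv, 2] - 1L) + d[1] * d[2] * (nb[okv, 3] - 1L)
    nb_key <- key[nb_lin]
    hit <- nb_key > 0L
    from <- c(from, which(okv)[hit])
    to <- c(to, nb_key[hit])
  }
  g <- igraph::make_graph(rbind(from, to), n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  out[fg] <- as.integer(comp)
  out
}

#' Keep only the largest connected cluster of a binary mask
#'
#' With multiple lesions, only the largest cluster enters the kinetic
#' analysis. Ties on voxel count are broken toward the component with the
#' lexicographically smallest centroid (a warning is emitted).
#'
#' @param mask 3-D 0/1 (or logical) array with at least one foreground voxel.
#' @param connectivity 26 (default, the 3-D CAD convention) or 6.
#' @return integer 0/1 array containing only the winning component.
#' @export
largest_component <- function(mask, connectivity = 26L) {
  if (!any(mask > 0)) stop("mask is empty", call. = FALSE)
  comp <- label_components(mask, connectivity)
  sizes <- tabulate(comp[comp > 0L])
  winners <- which(sizes == max(sizes))
  if (length(winners) > 1L) {
    cents <- t(vapply(winners, function(ci)
      colMeans(arrayInd(which(comp == ci), dim(mask))), numeric(3)))
    ord <- do.call(order, as.data.frame(cents))
    winners <- winners[ord[1L]]
    warning("tie on largest-component size; keeping the component with the ",
            "smallest centroid", call. = FALSE)
  }
  array(as.integer(comp == winners), dim(mask))
}
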