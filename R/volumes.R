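#' DCE series container
#'
#' An ordered stack of co-registered 3-D volumes sharing one voxel grid:
#' index 1 is the pre-contrast volume (S0), index 2 the first post-contrast
#' volume (S1) and the last index the final post-contrast volume (Slast).
#'
#' @param phases list of 3-D numeric arrays, all with identical dim.
#' @param spacing numeric length-3, voxel spacing in mm per axis.
#' @return object of class `dce_series`.
#' @export
dce_series <- function(phases, spacing = c(1, 1, 1)) {
  if (!is.list(phases) || length(phases) < 3L)
    stop("a DCE series needs at least 3 phases (pre, first post, last post)",
         call. = FALSE)
  d <- dim(phases[[1L]])
  if (is.null(d) || length(d) != 3L)
    stop("phases must be 3-D arrays", call. = FALSE)
  for (p in phases) {
    if (!identical(dim(p), d))
      stop("all phases must share the same grid", call. = FALSE)
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)", call. = FALSE)
  structure(list(phases = phases, spacing = spacing),
            class = "dce_series")
}

#' @export
print.dce_series <- function(x, ...) {
  d <- dim(x$phases[[1L]])
  cat(sprintf("<dce_series> %d phases (1 pre + %d post), grid %dx%dx%d, spacing %s mm\n",
              length(x$phases), length(x$phases) - 1L, d[1], d[2], d[3],
              paste(format(x$spacing), collapse = "x")))
  invisible(x)
}

#' Number of post-contrast phases
#' @param series a `dce_series`.
#' @return integer count of post-contrast volumes.
#' @export
n_post_phases <- function(series) length(series$phases) - 1L

#' Phase accessors
#'
#' Convenience accessors for the three phases the kinetic analysis reads:
#' pre-contrast (S0), first post-contrast (S1) and last post-contrast
#' (Slast).
#'
#' @param series a [dce_series()].
#' @return a 3-D array.
#' @name phase-accessors
NULL

#' @rdname phase-accessors
#' @export
phase_pre   <- function(series) series$phases[[1L]]

#' @rdname phase-accessors
#' @export
phase_first <- function(series) series$phases[[2L]]

#' @rdname phase-accessors
#' @export
phase_last  <- function(series) series$phases[[length(series$phases)]]

#' Voxel volume in mm^3
#' @param spacing numeric length-3 spacing in mm.
#' @return scalar voxel volume.
#' @export
voxel_volume <- function(spacing) prod(as.numeric(spacing))

stopifnot_mask <- function(mask, template = NULL) {
  if (is.null(dim(mask)) || length(dim(mask)) != 3L)
    stop("mask must be a 3-D array", call. = FALSE)
  if (!is.null(template) && !identical(dim(mask), dim(template)))
    stop("mask geometry does not match the image volume", call. = FALSE)
  invisible(TRUE)
}
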