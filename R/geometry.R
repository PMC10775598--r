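#' Signed Euclidean distance map of a binary mask
#'
#' Per-voxel signed distance (mm) to the mask surface, negative inside and
#' positive outside, computed with a separable anisotropic Euclidean distance
#' transform on voxel centres: outside voxels carry the distance to the
#' nearest set voxel centre, inside voxels minus the distance to the nearest
#' unset voxel centre. The zero level therefore sits within one voxel of the
#' digital boundary.
#'
#' @param mask a [mask3d()], neither empty nor full.
#' @param spacing voxel spacing in mm, `(z, y, x)` order.
#' @return numeric 3D array of signed distances (mm).
#' @export
signed_distance <- function(mask, spacing = mask$spacing) {
  m <- mask$flags
  if (!any(m)) stop("mask is empty")
  if (all(m)) stop("mask is full")
  dims <- dim(m)
  d_out <- sqrt(.edt_sq(as.logical(m), dims, as.numeric(spacing)))
  d_in <- sqrt(.edt_sq(!m, dims, as.numeric(spacing)))
  d_out - d_in
}

#' Expand a mask by an outer margin
#'
#' Margin realized by thresholding the Euclidean distance map rather than by
#' iterating a structuring element, so anisotropic spacing is handled exactly
#' and margins compose (up to digitization at the boundary). A voxel belongs
#' to the expanded mask when its centre lies within `margin_mm` of a set
#' voxel centre; `expand(m, 0)` is the identity.
#'
#' @param mask a non-empty [mask3d()].
#' @param margin_mm non-negative margin in mm.
#' @param spacing voxel spacing override.
#' @return a [mask3d()] with role `"DERIVED"`.
#' @export
expand <- function(mask, margin_mm, spacing = mask$spacing) {
  if (margin_mm < 0) stop("margin must be non-negative")
  if (!any(mask$flags)) stop("mask is empty")
  if (margin_mm == 0) return(mask)
  d2 <- .edt_sq(as.logical(mask$flags), dim(mask$flags), as.numeric(spacing))
  mask3d(array(d2 <= margin_mm^2, dim(mask$flags)),
         name = mask$name, role = "DERIVED", spacing = spacing)
}

#' Shrink a mask by an inner margin
#'
#' Keeps voxels whose centre lies at least `margin_mm` from every unset voxel
#' centre (erosion through the distance map). The result may be empty; that
#' is flagged via `empty_warned` and a warning, not an error, because the
#' stepwise CTV-erosion analysis must tolerate vanished volumes.
#'
#' @inheritParams expand
#' @return a [mask3d()], possibly empty.
#' @export
shrink <- function(mask, margin_mm, spacing = mask$spacing) {
  if (margin_mm < 0) stop("margin must be non-negative")
  if (margin_mm == 0) return(mask)
  if (!any(mask$flags)) stop("mask is empty")
  if (all(mask$flags)) stop("mask is full")
  d2 <- .edt_sq(!mask$flags, dim(mask$flags), as.numeric(spacing))
  flags <- array(d2 >= margin_mm^2 & mask$flags, dim(mask$flags))
  empty <- !any(flags)
  if (empty)
    warning(sprintf("mask '%s' empty after %.1f mm inner margin",
                    mask$name, margin_mm))
  mask3d(flags, name = mask$name, role = "DERIVED", spacing = spacing,
         empty_warned = empty)
}

#' Stepwise synthetic CTV series by PTV erosion
#'
#' Builds the nested family `CTV_m = shrink(PTV, m)` for each margin,
#' the construction behind the minimum-adequate-margin analysis: eroding the
#' PTV by the candidate margin recovers the CTV that margin would have
#' protected. Margins must be ascending so the family is ordered
#' `CTV_m1 >= CTV_m2` for `m1 < m2`.
#'
#' @param ptv a non-empty [mask3d()] (the planning target volume).
#' @param margins_mm ascending non-negative margins in mm (default 1..10).
#' @return named list of [mask3d()] `"CTV_{m}mm"`; empty members carry
#'   `empty_warned = TRUE`.
#' @export
ctv_series_from_ptv <- function(ptv, margins_mm = 1:10) {
  if (is.unsorted(margins_mm)) stop("margins must be ascending")
  out <- lapply(margins_mm, function(m) {
    mk <- withCallingHandlers(
      shrink(ptv, m),
      warning = function(w) invokeRestart("muffleWarning"))
    mk$name <- sprintf("CTV_%gmm", m)
    mk
  })
  names(out) <- sprintf("CTV_%gmm", margins_mm)
  n_empty <- sum(vapply(out, function(m) m$empty_warned, logical(1)))
  if (n_empty > 0)
    warning(sprintf("%d of %d eroded CTV volumes are empty", n_empty,
                    length(out)))
  out
}
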