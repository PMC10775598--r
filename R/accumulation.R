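#' Accumulate per-fraction dose onto the reference anatomy
#'
#' Each fraction's dose grid of the requested plan type is pulled back to the
#' reference frame through its ground-truth displacement field (trilinear
#' interpolation; samples that land outside the grid contribute zero and are
#' counted) and voxel-wise summed. With the per-fraction prescription times
#' the number of fractions as the phase prescription, a perfectly delivered
#' course scores 100%.
#'
#' The field for a fraction is taken from `fraction$field` (a 4D array as
#' produced by [displacement_field()]) when present — the hook for an
#' externally supplied deformable registration — otherwise it is materialized
#' from `fraction$field_shift` and the phantom. A fraction with neither is an
#' error.
#'
#' @param fractions list of fraction records; each carries `scheduled_dose`,
#'   `adaptive_dose`, `delivered`, and `field` or `field_shift`.
#' @param plan_type `"scheduled"`, `"adaptive"`, or `"delivered"`
#'   (as-delivered course following each fraction's delivered flag).
#' @param phantom the [build_phantom()] anatomy (needed to materialize
#'   fields from stored shifts).
#' @return a [grid3d()] of summed dose with attributes `n_fractions` and
#'   `n_outside` (out-of-grid pullback samples).
#' @export
accumulate_phase <- function(fractions,
                             plan_type = c("scheduled", "adaptive",
                                           "delivered"),
                             phantom = NULL) {
  plan_type <- match.arg(plan_type)
  if (length(fractions) == 0L) stop("no fractions to accumulate")
  dims <- dim(fractions[[1]]$scheduled_dose$values)
  spacing <- fractions[[1]]$scheduled_dose$spacing
  for (f in fractions) {
    for (g in list(f$scheduled_dose, f$adaptive_dose)) {
      if (!identical(dim(g$values), dims) ||
          !isTRUE(all.equal(g$spacing, spacing)))
        stop("fractions have mixed grid geometries")
    }
  }
  # sum in a canonical order (by fraction id) so that permuting the input
  # list reproduces the result bit-identically despite float addition
  ids <- vapply(fractions, function(f) as.character(f$fraction_id %||% ""),
                character(1))
  fractions <- fractions[order(ids)]
  # continuous 0-based sample indices of every reference voxel
  base <- lapply(1:3, function(ax)
    as.numeric(slice.index(array(0, dims), ax) - 1))
  acc <- array(0, dims)
  n_outside <- 0L
  for (f in fractions) {
    pt <- if (plan_type == "delivered") f$delivered else plan_type
    vol <- switch(pt, scheduled = f$scheduled_dose, adaptive = f$adaptive_dose)
    field <- f[["field"]]  # exact: f$field would partial-match field_shift
    if (is.null(field)) {
      if (is.null(f[["field_shift"]]))
        stop("fraction has no displacement field")
      if (is.null(phantom))
        stop("phantom needed to materialize displacement fields")
      field <- displacement_field(phantom, f$field_shift)
    }
    if (!identical(dim(field)[1:3], dims))
      stop("displacement field geometry does not match the dose grids")
    iz <- base[[1]] + as.numeric(field[, , , 1]) / spacing[1]
    iy <- base[[2]] + as.numeric(field[, , , 2]) / spacing[2]
    ix <- base[[3]] + as.numeric(field[, , , 3]) / spacing[3]
    s <- .trilinear_sample(as.numeric(vol$values), dims, iz, iy, ix, 0)
    acc <- acc + array(s$values, dims)
    n_outside <- n_outside + s$n_outside
  }
  out <- grid3d(acc, spacing = spacing,
                origin = fractions[[1]]$scheduled_dose$origin)
  attr(out, "n_fractions") <- length(fractions)
  attr(out, "n_outside") <- n_outside
  out
}

#' Accumulated EUD per erosion margin (margin table)
#'
#' Erodes the PTV stepwise ([ctv_series_from_ptv()]) and computes the
#' normalized accumulated EUD of each resulting synthetic CTV under the
#' accumulated dose. Phase prescription is `params$prescription *
#' n_fractions`.
#'
#' @param accumulated result of [accumulate_phase()].
#' @param ptv the reference PTV [mask3d()].
#' @param params an [eud_params()] with the per-fraction prescription.
#' @param margins_mm ascending erosion margins (default 1..10 mm).
#' @param n_fractions number of fractions summed into `accumulated`
#'   (defaults to its attribute).
#' @return data.frame with columns `margin_mm`, `eud_pct`, `empty`.
#' @export
margin_table <- function(accumulated, ptv, params, margins_mm = 1:10,
                         n_fractions = attr(accumulated, "n_fractions")) {
  if (is.null(n_fractions)) stop("n_fractions not given")
  series <- withCallingHandlers(
    ctv_series_from_ptv(ptv, margins_mm),
    warning = function(w) invokeRestart("muffleWarning"))
  phase_params <- eud_params(params$a, params$prescription * n_fractions)
  if (all(vapply(series, function(m) m$empty_warned, logical(1))))
    stop("every eroded CTV is empty")
  eud <- vapply(seq_along(series), function(i) {
    if (series[[i]]$empty_warned) return(NA_real_)
    as.numeric(normalized_eud(accumulated, series[[i]], phase_params))
  }, numeric(1))
  data.frame(margin_mm = margins_mm, eud_pct = eud,
             empty = vapply(series, function(m) m$empty_warned, logical(1)),
             row.names = NULL)
}

#' Minimum adequate erosion margin
#'
#' Smallest margin whose accumulated EUD strictly exceeds the threshold,
#' scanned in ascending order. Returns `NA` (sentinel "none within the
#' scanned margins") when no margin qualifies.
#'
#' @param eud_by_margin a [margin_table()] result.
#' @param threshold_pct EUD threshold in percent (default 95).
#' @return margin in mm, or `NA_real_`.
#' @export
min_adequate_margin <- function(eud_by_margin, threshold_pct = 95) {
  ok <- !eud_by_margin$empty & !is.na(eud_by_margin$eud_pct) &
    eud_by_margin$eud_pct > threshold_pct
  if (!any(ok)) return(NA_real_)
  min(eud_by_margin$margin_mm[ok])
}
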