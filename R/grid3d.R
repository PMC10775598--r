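#' 3D scalar dose grid
#'
#' A `grid3d` is an axis-aligned 3D scalar field (dose in Gy) stored as a
#' numeric array in `(z, y, x)` axis order, together with per-axis voxel
#' spacing and the world position of the centre of voxel `(1,1,1)`.
#' World coordinates of a voxel centre are `origin + (index - 1) * spacing`.
#'
#' @param values numeric 3D array, finite and non-negative (dose in Gy).
#' @param spacing numeric length-3, strictly positive voxel size in mm,
#'   `(z, y, x)` order.
#' @param origin numeric length-3, world position (mm) of the first voxel
#'   centre.
#' @return an object of class `grid3d`.
#' @export
grid3d <- function(values, spacing = c(2, 2, 2), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(is.finite(values)))
    stop("dose values must be finite")
  if (any(values < 0))
    stop("dose values must be non-negative")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  if (length(origin) != 3L)
    stop("origin must have three components")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "grid3d")
}

#' Binary structure mask on a dose lattice
#'
#' A `mask3d` shares the lattice of a companion [grid3d()]: same array shape,
#' same spacing. `role` records the clinical role of the structure.
#'
#' @param flags logical 3D array of voxel membership.
#' @param name structure label (e.g. `"CTV"`, `"parotid_l"`).
#' @param role one of `"CTV"`, `"PTV"`, `"OAR"`, `"BODY"`, `"DERIVED"`.
#' @param spacing voxel spacing in mm, `(z, y, x)` order.
#' @param empty_warned internal flag set when a derived mask came out empty.
#' @return an object of class `mask3d`.
#' @export
mask3d <- function(flags, name = "structure", role = "DERIVED",
                   spacing = c(2, 2, 2), empty_warned = FALSE) {
  if (!is.array(flags) || length(dim(flags)) != 3L)
    stop("flags must be a 3D array")
  storage.mode(flags) <- "logical"
  role <- match.arg(role, c("CTV", "PTV", "OAR", "BODY", "DERIVED"))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three strictly positive values")
  structure(list(flags = flags, name = name, role = role, spacing = spacing,
                 empty_warned = isTRUE(empty_warned)),
            class = "mask3d")
}

#' @export
print.grid3d <- function(x, ...) {
  cat(sprintf("<grid3d> %s voxels, spacing %s mm, dose %.3f-%.3f Gy\n",
              paste(dim(x$values), collapse = "x"),
              paste(format(x$spacing), collapse = "x"),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  cat(sprintf("<mask3d> '%s' (%s), %s voxels, %d set\n",
              x$name, x$role, paste(dim(x$flags), collapse = "x"),
              sum(x$flags)))
  invisible(x)
}

n_voxels <- function(mask) sum(mask$flags)

check_lattice <- function(dose, mask) {
  if (!identical(dim(dose$values), dim(mask$flags)))
    stop("dose grid and mask have different shapes")
  invisible(TRUE)
}

masked_doses <- function(dose, mask) {
  check_lattice(dose, mask)
  if (!any(mask$flags)) stop("empty structure")
  dose$values[mask$flags]
}

#' Structure volume in cubic centimetres
#'
#' Voxel count times voxel volume; no partial-volume correction.
#'
#' @param mask a [mask3d()].
#' @param spacing optional spacing override (mm, `(z, y, x)`).
#' @return volume in cc.
#' @export
volume_cc <- function(mask, spacing = mask$spacing) {
  sum(mask$flags) * prod(spacing) / 1000
}
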