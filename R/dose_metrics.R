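#' gEUD tissue-exponent registry and prescription
#'
#' Parameters of the power-law generalized equivalent uniform dose. The
#' registry ships the exponents used throughout the analysis: tumour
#' `a = -20` (cold-spot sensitive), parotid gland `a = 1.43` (close to mean
#' dose), larynx `a = 9.1` (serial-type). Exponents for further organs at
#' risk (e.g. spinal cord) have no default and must be supplied explicitly.
#'
#' @param a unitless tissue exponent, non-zero.
#' @param prescription prescribed dose in Gy, positive.
#' @return an `eud_params` list.
#' @export
eud_params <- function(a, prescription) {
  if (length(a) != 1L || !is.finite(a) || a == 0) stop("invalid exponent")
  if (length(prescription) != 1L || !is.finite(prescription) ||
      prescription <= 0) stop("prescription must be positive")
  structure(list(a = a, prescription = prescription), class = "eud_params")
}

#' @rdname eud_params
#' @export
eud_exponents <- function() c(tumor = -20, parotid = 1.43, larynx = 9.1)

#' Generalized equivalent uniform dose
#'
#' Power-law gEUD over the voxel doses inside a structure,
#' \eqn{(\sum_i v_i d_i^a)^{1/a}} with equal per-voxel volume weights
#' \eqn{v_i = 1/n}. Computed on the raw voxel list (not a binned DVH) in
#' log space, so extreme exponents such as \eqn{a = \pm 100} are stable.
#'
#' For negative exponents, zero dose makes \eqn{d^a} diverge; voxel doses can
#' be floored at `floor_gy` before the power sum (the pipeline uses
#' `1e-3 * prescription`). Floored voxels are counted in the
#' `"n_floored"` attribute of the result. Without a floor, a non-positive
#' masked dose under `a < 0` is an error.
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()] on the same lattice.
#' @param a tissue exponent, non-zero.
#' @param floor_gy optional guard floor (Gy) applied to voxel doses when
#'   `a < 0`; `NULL` disables the guard.
#' @return gEUD in Gy, with attribute `n_floored`.
#' @export
geud <- function(dose, mask, a, floor_gy = NULL) {
  if (length(a) != 1L || !is.finite(a) || a == 0) stop("invalid exponent")
  d <- masked_doses(dose, mask)
  n_floored <- 0L
  if (a < 0) {
    if (!is.null(floor_gy)) {
      n_floored <- sum(d < floor_gy)
      d <- pmax(d, floor_gy)
    }
    if (any(d <= 0))
      stop("non-positive dose in structure with negative exponent")
  }
  # log-sum-exp of a*log(d); voxels at exactly 0 are fine for a > 0
  if (a > 0 && any(d == 0)) {
    lx <- a * log(d[d > 0])
    if (length(lx) == 0L) return(structure(0, n_floored = n_floored))
    m <- max(lx)
    lmean <- m + log(sum(exp(lx - m))) - log(length(d))
  } else {
    lx <- a * log(d)
    m <- max(lx)
    lmean <- m + log(sum(exp(lx - m))) - log(length(d))
  }
  structure(exp(lmean / a), n_floored = n_floored)
}

#' gEUD as a percentage of the prescribed dose
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()].
#' @param params an [eud_params()].
#' @return EUD normalized to prescription, in percent.
#' @export
normalized_eud <- function(dose, mask, params) {
  g <- geud(dose, mask, params$a,
            floor_gy = if (params$a < 0) 1e-3 * params$prescription else NULL)
  structure(100 * as.numeric(g) / params$prescription,
            n_floored = attr(g, "n_floored"))
}

#' Cumulative dose-volume histogram
#'
#' Volume fraction of the structure receiving at least each bin-edge dose.
#' The curve starts at 1 for edge 0 and is non-increasing; the last edge
#' exceeds the maximum masked dose.
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()].
#' @param bin_width histogram bin width in Gy, positive.
#' @return data.frame with columns `dose_gy` (bin edges) and `volume_fraction`.
#' @export
dvh <- function(dose, mask, bin_width = 0.05) {
  if (bin_width <= 0) stop("bin_width must be positive")
  d <- masked_doses(dose, mask)
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  frac <- vapply(edges, function(e) mean(d >= e), numeric(1))
  data.frame(dose_gy = edges, volume_fraction = frac)
}

#' Dose received by at least a given volume fraction (D_q)
#'
#' The largest dose `d` such that at least fraction `q` of the masked voxels
#' receive `>= d`. Evaluated as an order statistic of the sorted voxel doses
#' without interpolation: the `ceiling(q * n)`-th largest dose. `q = 1` is the
#' minimum dose, the `q -> 0` limit the maximum.
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()].
#' @param q volume fraction in (0, 1].
#' @return dose in Gy.
#' @export
d_at_volume <- function(dose, mask, q) {
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q > 1)
    stop("q must lie in (0, 1]")
  d <- sort(masked_doses(dose, mask), decreasing = TRUE)
  d[ceiling(q * length(d))]
}

#' Volume receiving at least a dose threshold (V_d)
#'
#' Percentage of the structure receiving at least `threshold_pct`% of the
#' prescription (V100 is `threshold_pct = 100`).
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()].
#' @param params an [eud_params()] carrying the prescription.
#' @param threshold_pct threshold as percent of prescription.
#' @return percent of structure volume.
#' @export
v_at_dose <- function(dose, mask, params, threshold_pct = 100) {
  d <- masked_doses(dose, mask)
  100 * mean(d >= threshold_pct / 100 * params$prescription)
}

#' Per-fraction dose metric panel for one structure
#'
#' Bundles the endpoint metrics for a (fraction, structure, plan) triple:
#' normalized EUD, V100, D99/D95/D90, exact voxel Dmin/Dmax, and the
#' homogeneity measure `Dmax - D99` (all as percent of prescription).
#'
#' @param dose a [grid3d()].
#' @param mask a non-empty [mask3d()].
#' @param params an [eud_params()].
#' @param fraction_id,plan_type identifiers stored in the row; `plan_type`
#'   is one of `"reference"`, `"scheduled"`, `"adaptive"`.
#' @return one-row data.frame (a `MetricRow`).
#' @export
metric_row <- function(dose, mask, params, fraction_id = NA_character_,
                       plan_type = c("reference", "scheduled", "adaptive")) {
  plan_type <- match.arg(plan_type)
  d <- masked_doses(dose, mask)
  pct <- function(x) 100 * x / params$prescription
  row <- data.frame(
    fraction_id = fraction_id,
    structure = mask$name,
    plan_type = plan_type,
    eud_pct = as.numeric(normalized_eud(dose, mask, params)),
    v100_pct = v_at_dose(dose, mask, params, 100),
    d99_pct = pct(d_at_volume(dose, mask, 0.99)),
    d95_pct = pct(d_at_volume(dose, mask, 0.95)),
    d90_pct = pct(d_at_volume(dose, mask, 0.90)),
    dmin_pct = pct(min(d)),
    dmax_pct = pct(max(d)),
    stringsAsFactors = FALSE
  )
  row$homogeneity_pct <- row$dmax_pct - row$d99_pct
  row
}

#' gEUD from a differential DVH (cross-check path)
#'
#' Bins the masked voxel doses at `bin_width` and evaluates the power sum on
#' bin centres. Exists only to cross-check the voxel-list path; binning
#' biases the cold-spot-sensitive exponents, which is why the voxel list is
#' the primary route.
#'
#' @inheritParams geud
#' @param bin_width bin width in Gy.
#' @return gEUD in Gy.
#' @export
geud_from_dvh <- function(dose, mask, a, bin_width = 0.01) {
  if (length(a) != 1L || !is.finite(a) || a == 0) stop("invalid exponent")
  d <- masked_doses(dose, mask)
  if (a < 0 && any(d <= 0))
    stop("non-positive dose in structure with negative exponent")
  br <- seq(0, max(d) + bin_width, by = bin_width)
  h <- graphics::hist(d, breaks = br, plot = FALSE)
  w <- h$counts / length(d)
  keep <- w > 0
  (sum(w[keep] * h$mids[keep]^a))^(1 / a)
}
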