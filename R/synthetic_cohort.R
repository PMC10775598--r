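#' Default phantom and plan configuration
#'
#' The phantom is a desk-scale stand-in for a head-and-neck planning CT:
#' a large BODY ellipsoid, a mobile tongue-compartment CTV ellipsoid, a PTV
#' obtained by isotropic expansion, and four static organs at risk (left and
#' right parotid, larynx, spinal cord), all rasterized on one lattice.
#' All lengths are mm, in `(z, y, x)` world order (z = craniocaudal,
#' y = anterior-posterior, x = lateral).
#'
#' @param shape grid size per axis (voxels), `(z, y, x)`.
#' @param spacing voxel spacing (mm).
#' @param prescription per-fraction prescribed dose (Gy).
#' @param planning_margin_mm CTV-to-PTV margin of the reference plan.
#' @param adaptive_margin_mm margin applied around the anatomy-of-the-day CTV
#'   when the adaptive plan is shaped.
#' @param sigma_penumbra_mm Gaussian penumbra width of the idealized dose
#'   shaper.
#' @param hot_max cap on the dose plateau as a multiple of prescription
#'   (clinical hotspot constraint; must be <= 1.15).
#' @return a config list understood by [build_phantom()] and the dose makers.
#' @export
phantom_config <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                           prescription = 2, planning_margin_mm = 5,
                           adaptive_margin_mm = 3, sigma_penumbra_mm = 3,
                           hot_max = 1.04) {
  if (any(shape < 48) || any(spacing > 3))
    stop("grid must be at least 48^3 at <= 3 mm spacing")
  if (hot_max > 1.15) stop("hot_max exceeds the 1.15 x prescription bound")
  centre <- (shape - 1) * spacing / 2
  list(
    shape = as.integer(shape), spacing = spacing,
    prescription = prescription,
    planning_margin_mm = planning_margin_mm,
    adaptive_margin_mm = adaptive_margin_mm,
    sigma_penumbra_mm = sigma_penumbra_mm,
    hot_max = hot_max,
    body = list(centre = centre, semi = c(60, 58, 58)),
    ctv = list(centre = centre + c(0, -8, 0), semi = c(15, 12, 12)),
    oars = list(
      parotid_l = list(centre = centre + c(0, -4, 30), semi = c(12, 8, 8)),
      parotid_r = list(centre = centre + c(0, -4, -30), semi = c(12, 8, 8)),
      larynx    = list(centre = centre + c(-40, -4, 0), semi = c(10, 9, 9)),
      cord      = list(centre = centre + c(0, 32, 0),  semi = c(40, 5, 5))
    ),
    taper_mm = 10
  )
}

ellipsoid_mask <- function(shape, spacing, centre, semi, name = "structure",
                           role = "DERIVED") {
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - 1) * spacing[i] -
                                   centre[i]) / semi[i])
  z2 <- ax[[1]]^2
  y2 <- ax[[2]]^2
  x2 <- ax[[3]]^2
  flags <- outer(outer(z2, y2, `+`), x2, `+`) <= 1
  mask3d(flags, name = name, role = role, spacing = spacing)
}

#' Build the anatomy phantom
#'
#' Deterministic given the configuration (the seed is recorded for
#' provenance but the anatomy itself is parametric, not sampled).
#' Containment is enforced: CTV inside PTV inside BODY, OARs inside BODY and
#' disjoint from the CTV.
#'
#' @param config a [phantom_config()].
#' @param seed integer recorded in the phantom.
#' @return an `anatomy_phantom` list with masks `body`, `ctv`, `ptv`, `oars`.
#' @export
build_phantom <- function(config = phantom_config(), seed = 1L) {
  sp <- config$spacing
  body <- ellipsoid_mask(config$shape, sp, config$body$centre,
                         config$body$semi, "BODY", "BODY")
  ctv <- ellipsoid_mask(config$shape, sp, config$ctv$centre, config$ctv$semi,
                        "CTV", "CTV")
  ptv <- expand(ctv, config$planning_margin_mm)
  ptv$name <- "PTV"; ptv$role <- "PTV"
  oars <- lapply(names(config$oars), function(nm) {
    o <- config$oars[[nm]]
    ellipsoid_mask(config$shape, sp, o$centre, o$semi, nm, "OAR")
  })
  names(oars) <- names(config$oars)
  for (o in oars) {
    if (any(o$flags & ctv$flags))
      stop(sprintf("OAR '%s' overlaps the CTV", o$name))
    if (any(o$flags & !body$flags))
      stop(sprintf("OAR '%s' extends outside the BODY", o$name))
  }
  if (any(ctv$flags & !ptv$flags)) stop("CTV not contained in PTV")
  if (any(ptv$flags & !body$flags)) stop("PTV extends outside the BODY")
  structure(list(config = config, seed = as.integer(seed), body = body,
                 ctv = ctv, ptv = ptv, oars = oars),
            class = "anatomy_phantom")
}

#' CTV mask on the anatomy of the day
#'
#' The mobile compartment is re-rasterized at its shifted position rather
#' than resampled, so no interpolation artefacts enter the geometry.
#'
#' @param phantom an [build_phantom()] result.
#' @param shift length-3 displacement (mm, `(z, y, x)`).
#' @return a [mask3d()].
#' @export
shifted_ctv <- function(phantom, shift = c(0, 0, 0)) {
  cfg <- phantom$config
  m <- ellipsoid_mask(cfg$shape, cfg$spacing, cfg$ctv$centre + shift,
                      cfg$ctv$semi, "CTV", "CTV")
  # a compartment leaving the BODY (or the grid, which truncates the
  # rasterization) is anatomically impossible
  if (any(m$flags & !phantom$body$flags) ||
      sum(m$flags) < 0.9 * sum(phantom$ctv$flags))
    stop("shift moves the CTV outside the BODY")
  m
}

#' Idealized dose shaper
#'
#' Replaces the clinical inverse-planning optimizer with its simplest
#' dosimetric caricature: the target-volume indicator smoothed with an
#' isotropic Gaussian penumbra, doubled so the 50% point of a flat penumbra
#' sits on the target surface, and capped at `hot_max` times prescription to
#' mimic the hotspot constraint. The result is prescription-level dose
#' throughout the target interior, a sigmoidal falloff of width
#' `sigma_penumbra_mm` outside, and a maximum bounded by
#' `hot_max * prescription <= 1.15 * prescription`.
#'
#' @param target a [mask3d()] (the PTV being planned for).
#' @param config a [phantom_config()].
#' @return a [grid3d()] of per-fraction dose.
#' @export
shape_dose <- function(target, config) {
  s_vox <- config$sigma_penumbra_mm / config$spacing
  sm <- .gauss_smooth(as.numeric(target$flags), dim(target$flags),
                      as.numeric(s_vox))
  vals <- config$prescription * pmin(config$hot_max, 2 * sm)
  grid3d(array(vals, dim(target$flags)), spacing = config$spacing)
}

#' Scheduled (IGRT) dose of the day
#'
#' The room-fixed reference dose is left unchanged; only the anatomy moved.
#' Returned with the reference plan's grid, to be evaluated against the
#' CTV at its interfractional position.
#'
#' @param phantom phantom anatomy.
#' @param plan reference plan as returned by [reference_plan()].
#' @param shift interfractional displacement (mm).
#' @return a [grid3d()].
#' @export
make_scheduled_dose <- function(phantom, plan, shift) {
  shifted_ctv(phantom, shift)  # validates the shift against the BODY
  plan$dose
}

#' Adaptive dose of the day
#'
#' The same shaping operator applied to the day's PTV: the interfractionally
#' shifted CTV expanded by the (tighter) adaptive margin. Residual
#' intrafractional motion happens after adaptation, so delivered-dose
#' evaluation uses the CTV at `inter + intra`.
#'
#' @inheritParams make_scheduled_dose
#' @return a [grid3d()].
#' @export
make_adaptive_dose <- function(phantom, plan, shift) {
  day_ctv <- shifted_ctv(phantom, shift)
  day_ptv <- expand(day_ctv, phantom$config$adaptive_margin_mm)
  shape_dose(day_ptv, phantom$config)
}

#' Reference plan on the planning anatomy
#'
#' @param phantom phantom anatomy.
#' @return list with the reference dose grid and plan parameters.
#' @export
reference_plan <- function(phantom) {
  list(dose = shape_dose(phantom$ptv, phantom$config),
       prescription = phantom$config$prescription)
}

#' Ground-truth displacement field for a compartment shift
#'
#' A rigid translation of the mobile compartment blended to zero with a
#' cosine taper over `taper_mm` beyond the reference CTV surface. The field
#' is stored on the reference lattice and maps each reference-frame point to
#' its position in the fraction frame (`x + phi(x)`), which is exactly what
#' the pull-back accumulation needs. It is identically zero outside the
#' influence region (CTV expanded by `taper_mm`).
#'
#' @param phantom phantom anatomy.
#' @param shift length-3 compartment displacement (mm).
#' @return 4D array `(z, y, x, component)` of displacements in mm.
#' @export
displacement_field <- function(phantom, shift) {
  d <- signed_distance(phantom$ctv)
  taper <- phantom$config$taper_mm
  w <- ifelse(d <= 0, 1,
              ifelse(d >= taper, 0, 0.5 * (1 + cos(pi * d / taper))))
  dims <- dim(w)
  out <- array(0, c(dims, 3L))
  for (k in 1:3) out[, , , k] <- w * shift[k]
  out
}

# ---- motion model -----------------------------------------------------------

#' Motion model configuration
#'
#' Inter- and intrafractional compartment shifts are drawn per axis from a
#' scaled Student-t (heavy tails allow the occasional > 10 mm excursion);
#' the intrafractional shift is coupled to the interfractional one through
#' `rho`, so large interfractional movers also move more within the
#' fraction. Scales are not set directly: they are solved numerically so
#' that a unit-gain landmark reaches the configured 95th percentiles of
#' absolute deviation.
#'
#' @param inter_p95_mm target 95th percentile of the absolute deviation of a
#'   unit-gain landmark, interfractional.
#' @param intra_p95_mm same target, intrafractional.
#' @param rho inter-intra coupling in `[0, 1)`.
#' @param df Student-t degrees of freedom.
#' @param noise_sd_mm landmark measurement noise (mm).
#' @return a motion config list with solved scales `s_inter`, `s_intra`.
#' @export
motion_config <- function(inter_p95_mm = 8.5, intra_p95_mm = 5.5, rho = 0.5,
                          df = 4, noise_sd_mm = 0.5) {
  if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
  key <- paste(inter_p95_mm, intra_p95_mm, rho, df, noise_sd_mm, sep = "|")
  hit <- .motion_cache[[key]]
  if (!is.null(hit)) return(hit)
  s_inter <- stats::uniroot(function(s)
    landmark_abs_quantile(0.95, scales = s, df = df,
                          noise_sd = noise_sd_mm) - inter_p95_mm,
    c(0.05, 25), tol = 1e-8)$root
  lo_q <- landmark_abs_quantile(0.95, scales = c(rho * s_inter, 1e-6),
                                df = df, noise_sd = noise_sd_mm)
  if (lo_q >= intra_p95_mm)
    stop("rho * inter scale alone exceeds the intra percentile target")
  s_intra <- stats::uniroot(function(s)
    landmark_abs_quantile(0.95, scales = c(rho * s_inter, s), df = df,
                          noise_sd = noise_sd_mm) - intra_p95_mm,
    c(0.01, 25), tol = 1e-8)$root
  out <- list(inter_p95_mm = inter_p95_mm, intra_p95_mm = intra_p95_mm,
              rho = rho, df = df, noise_sd_mm = noise_sd_mm,
              s_inter = s_inter, s_intra = s_intra,
              landmarks = landmark_registry())
  .motion_cache[[key]] <- out
  out
}

# scale calibration is deterministic, so solved configs are memoized
.motion_cache <- new.env(parent = emptyenv())

#' Landmark registry
#'
#' The eight sagittal-midline landmark readouts, keyed (a)-(h) in the order
#' they are measured clinically: pharyngeal wall, mandible, hyoid and tongue
#' parameters. Each is modelled as a gain times one axis component of the
#' compartment shift plus measurement noise; the axis/gain mapping is a
#' declared modelling choice, not an inferred one.
#'
#' @return data.frame with columns `key`, `label`, `axis` (1 = z
#'   craniocaudal, 2 = y anterior-posterior, 3 = x lateral) and `gain`.
#' @export
landmark_registry <- function() {
  data.frame(
    key = letters[1:8],
    label = c("pharyngeal_wall_at_epiglottis_ap", "pharyngeal_wall_max_ap",
              "mandible_max", "hyoid_max_cc", "hyoid_max_overall",
              "tongue_base_max_ap", "tongue_back_max_cc",
              "tongue_base_at_epiglottis_ap"),
    axis = c(2L, 2L, 2L, 1L, 1L, 2L, 1L, 2L),
    gain = c(0.85, 1.00, 0.95, 1.10, 1.25, 1.15, 1.00, 0.90),
    stringsAsFactors = FALSE
  )
}

# Numeric (grid-convolution) distribution of a landmark readout
# L = sum_j t_df(scale_j) + N(0, noise_sd), and its absolute-value quantile.
# This is the sampler's own oracle for calibration and parameter recovery.
landmark_abs_density <- function(scales, df, noise_sd,
                                 lim = 100, dx = 0.05) {
  x <- seq(-lim, lim, by = dx)
  n <- length(x)
  dens <- NULL
  comp <- function(f) {
    f / (sum(f) * dx)
  }
  for (s in scales) {
    if (s <= 0) next
    f <- comp(stats::dt(x / s, df) / s)
    dens <- if (is.null(dens)) f else conv_centred(dens, f, dx)
  }
  if (noise_sd > 0) {
    g <- comp(stats::dnorm(x, sd = noise_sd))
    dens <- if (is.null(dens)) g else conv_centred(dens, g, dx)
  }
  list(x = x, density = dens, dx = dx)
}

conv_centred <- function(f, g, dx) {
  n <- length(f)
  full <- stats::convolve(f, rev(g), type = "open") * dx
  mid <- (length(full) + 1) / 2
  half <- (n - 1) / 2
  full[(mid - half):(mid + half)]
}

#' Quantile of the absolute landmark deviation under the motion model
#'
#' Numerically integrated (grid convolution of the component densities);
#' used both to calibrate scales from percentile targets and as the
#' independent target in parameter-recovery checks.
#'
#' @param q probability.
#' @param scales Student-t scales of the summed components (mm).
#' @param df degrees of freedom.
#' @param noise_sd measurement noise sd (mm).
#' @param gain landmark gain multiplying the shift component.
#' @return quantile of `|L|` in mm.
#' @export
landmark_abs_quantile <- function(q, scales, df = 4, noise_sd = 0.5,
                                  gain = 1) {
  d <- landmark_abs_density(scales * gain, df, noise_sd)
  cdf <- cumsum(d$density) * d$dx
  pos <- d$x >= 0
  f_abs <- 2 * cdf[pos] - 1  # symmetric density
  stats::approx(f_abs, d$x[pos], xout = q, ties = "ordered")$y
}

#' Sample per-fraction compartment shifts and landmark readouts
#'
#' @param n_fractions number of fractions to draw.
#' @param config a [motion_config()].
#' @param seed integer seed (local RNG, restored on exit).
#' @return data.frame with one row per fraction: `inter_z/y/x`,
#'   `intra_z/y/x` (mm) and the 16 landmark columns
#'   `inter_<key>` / `intra_<key>`.
#' @export
sample_shifts <- function(n_fractions, config = motion_config(), seed = 1L) {
  with_local_seed(seed, {
    lm <- config$landmarks
    inter <- matrix(config$s_inter * stats::rt(3 * n_fractions, config$df),
                    ncol = 3)
    intra <- config$rho * inter +
      matrix(config$s_intra * stats::rt(3 * n_fractions, config$df), ncol = 3)
    colnames(inter) <- colnames(intra) <- c("z", "y", "x")
    out <- data.frame(fraction = seq_len(n_fractions))
    for (k in 1:3) {
      out[[paste0("inter_", colnames(inter)[k])]] <- inter[, k]
      out[[paste0("intra_", colnames(intra)[k])]] <- intra[, k]
    }
    for (i in seq_len(nrow(lm))) {
      noise <- stats::rnorm(n_fractions, sd = config$noise_sd_mm)
      out[[paste0("inter_", lm$key[i])]] <-
        lm$gain[i] * inter[, lm$axis[i]] + noise
      noise <- stats::rnorm(n_fractions, sd = config$noise_sd_mm)
      out[[paste0("intra_", lm$key[i])]] <-
        lm$gain[i] * intra[, lm$axis[i]] + noise
    }
    out
  })
}

with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Plan-selection policy
#'
#' The default mirrors the clinical decision: deliver the adaptive plan when
#' it improves target EUD by more than `threshold` percentage points and no
#' organ-at-risk EUD worsens by more than `oar_tolerance` points; ties go to
#' the scheduled plan.
#'
#' @param threshold minimum CTV EUD gain (percentage points).
#' @param oar_tolerance maximum tolerated OAR EUD worsening (points).
#' @return a policy list.
#' @export
selection_policy <- function(threshold = 0, oar_tolerance = 2) {
  list(threshold = threshold, oar_tolerance = oar_tolerance)
}

#' Choose the delivered plan for one fraction
#'
#' @param metrics_scheduled,metrics_adaptive metric tables (rows per
#'   structure) for the two candidate plans; the CTV row is identified by
#'   `structure == "CTV"`, all other rows are treated as OARs.
#' @param policy a [selection_policy()].
#' @return `"adaptive"` or `"scheduled"`.
#' @export
select_delivered <- function(metrics_scheduled, metrics_adaptive,
                             policy = selection_policy()) {
  s_ctv <- metrics_scheduled$eud_pct[metrics_scheduled$structure == "CTV"]
  a_ctv <- metrics_adaptive$eud_pct[metrics_adaptive$structure == "CTV"]
  if (length(s_ctv) != 1L || length(a_ctv) != 1L)
    stop("both metric tables need exactly one CTV row")
  oars_s <- metrics_scheduled[metrics_scheduled$structure != "CTV", ]
  oars_a <- metrics_adaptive[metrics_adaptive$structure != "CTV", ]
  oar_ok <- TRUE
  if (nrow(oars_s) > 0) {
    m <- merge(oars_s[, c("structure", "eud_pct")],
               oars_a[, c("structure", "eud_pct")], by = "structure",
               suffixes = c("_s", "_a"))
    oar_ok <- all(m$eud_pct_a <= m$eud_pct_s + policy$oar_tolerance)
  }
  if (a_ctv > s_ctv + policy$threshold && oar_ok) "adaptive" else "scheduled"
}
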