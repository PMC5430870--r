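#' Brain phantom specification
#'
#' Parametric-analytic description of a synthetic brain: an ellipsoidal
#' brain with a gray-matter cortical ribbon, white-matter interior,
#' ellipsoidal CSF ventricles, optional spherical resection cavity and
#' fiber bundles described by polyline center-lines.  All geometry is in mm
#' (world coordinates = 0-based voxel index times spacing).  Everything is
#' deterministic; the `seed` is carried so that derived randomized phantoms
#' reproduce bit-identically.
#'
#' @param shape Integer length-3 grid dimensions.
#' @param spacing Numeric length-3 voxel size, mm.
#' @param brain_radii Semi-axes of the brain ellipsoid, mm.  Default 42% of
#'   the grid extent per axis.
#' @param gm_thickness Cortical ribbon thickness in voxels (mean spacing).
#' @param ventricles List of `list(center, radii)` ellipsoids (mm) carved as
#'   CSF out of white matter.  `NULL` gives two default para-central
#'   ventricles; `list()` gives none.
#' @param fibers List of `list(points, radius, anisotropy)` bundles: `points`
#'   is an n x 3 polyline (mm), `radius` the Gaussian falloff scale (mm),
#'   `anisotropy` the principal/transverse eigenvalue ratio on the
#'   center-line.
#' @param cavity `list(center, radius)` in mm, or `NULL`; radius 0 means no
#'   cavity voxels.
#' @param seed Integer stored with the spec.
#' @return An object of class `phantom_spec`.
#' @seealso [make_brain_phantom()], [make_tensor_field()]
#' @export
phantom_spec <- function(shape = c(64, 64, 64),
                         spacing = c(2, 2, 2),
                         brain_radii = NULL,
                         gm_thickness = 2,
                         ventricles = NULL,
                         fibers = list(),
                         cavity = NULL,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("shape must be 3 positive integers", call. = FALSE)
  }
  spacing <- check_spacing(spacing)
  extent <- (shape - 1) * spacing
  if (is.null(brain_radii)) brain_radii <- 0.42 * extent
  center <- extent / 2
  if (any(center - brain_radii < 0) || any(center + brain_radii > extent)) {
    stop("invalid phantom spec: brain ellipsoid exceeds the grid", call. = FALSE)
  }
  if (is.null(ventricles)) {
    voff <- 0.25 * brain_radii[2]
    vrad <- pmax(0.18 * brain_radii, spacing)
    ventricles <- list(
      list(center = center + c(-0.25 * brain_radii[1], voff, 0), radii = vrad),
      list(center = center + c(0.25 * brain_radii[1], voff, 0), radii = vrad)
    )
  }
  if (!is.null(cavity)) {
    if (cavity$radius < 0) stop("invalid phantom spec: negative cavity radius", call. = FALSE)
    if (any(cavity$center - cavity$radius < 0) ||
        any(cavity$center + cavity$radius > extent)) {
      stop("invalid phantom spec: cavity exceeds the grid", call. = FALSE)
    }
  }
  for (f in fibers) {
    if (!is.matrix(f$points) || ncol(f$points) != 3L || nrow(f$points) < 2L) {
      stop("invalid phantom spec: fiber points must be an n x 3 matrix (n >= 2)",
           call. = FALSE)
    }
    if (is.null(f$radius) || f$radius <= 0 || is.null(f$anisotropy) ||
        f$anisotropy < 1) {
      stop("invalid phantom spec: fiber needs radius > 0 and anisotropy >= 1",
           call. = FALSE)
    }
  }
  structure(list(shape = shape, spacing = spacing, center = center,
                 brain_radii = brain_radii, gm_thickness = gm_thickness,
                 ventricles = ventricles, fibers = fibers, cavity = cavity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Normalised ellipsoid radius field: <= 1 inside.
ellipsoid_rho <- function(grids, center, radii) {
  sqrt(((grids$x - center[1]) / radii[1])^2 +
       ((grids$y - center[2]) / radii[2])^2 +
       ((grids$z - center[3]) / radii[3])^2)
}

#' Generate a labeled brain phantom
#'
#' Builds the tissue label volume from a [phantom_spec()]: outside shell,
#' gray-matter cortical ribbon, white-matter interior, CSF ventricles and an
#' optional spherical resection cavity.  Purely analytic and deterministic.
#'
#' @param spec A [phantom_spec()].
#' @return A [labeled_volume()].
#' @examples
#' vol <- make_brain_phantom(phantom_spec(shape = c(24, 24, 24)))
#' table(vol$labels)
#' @export
make_brain_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  grids <- coord_grids(spec$shape, spec$spacing)
  rho <- ellipsoid_rho(grids, spec$center, spec$brain_radii)
  labels <- array(LBL$OUTSIDE, spec$shape)
  # ribbon thickness as a fraction of the (axis-mean) normalised radius
  delta <- spec$gm_thickness * mean(spec$spacing / spec$brain_radii)
  labels[rho <= 1] <- LBL$GM
  labels[rho <= 1 - delta] <- LBL$WM
  for (v in spec$ventricles) {
    vr <- ellipsoid_rho(grids, v$center, v$radii)
    labels[vr <= 1 & labels == LBL$WM] <- LBL$CSF
  }
  if (!is.null(spec$cavity) && spec$cavity$radius > 0) {
    d <- sqrt((grids$x - spec$cavity$center[1])^2 +
              (grids$y - spec$cavity$center[2])^2 +
              (grids$z - spec$cavity$center[3])^2)
    labels[d <= spec$cavity$radius & labels != LBL$OUTSIDE] <- LBL$CAVITY
  }
  labeled_volume(labels, spec$spacing)
}

# Distance to, and tangent at, the nearest point of a polyline, vectorised
# over query points (n x 3, mm).  Returns list(dist, tangent n x 3).
polyline_nearest <- function(pts, poly) {
  n <- nrow(pts)
  best_d2 <- rep(Inf, n)
  tang <- matrix(0, n, 3)
  for (s in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[s, ]
    dseg <- poly[s + 1L, ] - p0
    len2 <- sum(dseg^2)
    if (len2 == 0) next
    rel <- sweep(pts, 2, p0)
    tproj <- pmin(pmax((rel %*% dseg)[, 1] / len2, 0), 1)
    dx <- rel[, 1] - tproj * dseg[1]
    dy <- rel[, 2] - tproj * dseg[2]
    dz <- rel[, 3] - tproj * dseg[3]
    d2 <- dx * dx + dy * dy + dz * dz
    upd <- d2 < best_d2
    if (any(upd)) {
      best_d2[upd] <- d2[upd]
      t_unit <- dseg / sqrt(len2)
      tang[upd, ] <- matrix(t_unit, sum(upd), 3, byrow = TRUE)
    }
  }
  list(dist = sqrt(best_d2), tangent = tang)
}

#' Generate a DTI-like tensor field for a phantom
#'
#' White-matter voxels near a declared fiber bundle receive a trace-one
#' tensor whose principal eigenvector follows the bundle tangent, with
#' eigenvalue ratio `a : 1 : 1` where `a` decays from the bundle anisotropy
#' on the center-line towards 1 (isotropic) with a Gaussian falloff of scale
#' `radius`.  Gray matter is isotropic (identity/3); CSF, cavity and
#' outside-brain voxels carry the zero tensor.  All tensors are symmetric
#' positive-semidefinite by construction.
#'
#' @param vol A [labeled_volume()] from [make_brain_phantom()].
#' @param spec The matching [phantom_spec()] (same shape).
#' @return A unitless [tensor_field()] emulating DTI input.
#' @export
make_tensor_field <- function(vol, spec) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(spec, "phantom_spec"))
  if (!identical(vol$shape, spec$shape)) {
    stop("volume and spec shapes differ", call. = FALSE)
  }
  comp <- array(0, c(vol$shape, 6L))
  iso <- 1 / 3
  gm <- gm_mask(vol)
  for (ci in c(1L, 4L, 6L)) {            # diagonal components
    slab <- comp[, , , ci]
    slab[gm] <- iso
    comp[, , , ci] <- slab
  }
  wm_idx <- which(wm_mask(vol))
  if (length(wm_idx) > 0) {
    grids <- coord_grids(vol$shape, vol$spacing)
    pts <- cbind(grids$x[wm_idx], grids$y[wm_idx], grids$z[wm_idx])
    a <- rep(1, length(wm_idx))
    tang <- matrix(0, length(wm_idx), 3)
    best_d <- rep(Inf, length(wm_idx))
    for (f in spec$fibers) {
      near <- polyline_nearest(pts, f$points)
      gain <- 1 + (f$anisotropy - 1) * exp(-near$dist^2 / (2 * f$radius^2))
      upd <- near$dist < best_d
      best_d[upd] <- near$dist[upd]
      a[upd] <- gain[upd]
      tang[upd, ] <- near$tangent[upd, , drop = FALSE]
    }
    lam_perp <- 1 / (a + 2)
    lam_par <- a / (a + 2)
    no_dir <- rowSums(tang^2) == 0
    # tensor = lam_perp*I + (lam_par - lam_perp) * t t^T (trace 1)
    dl <- lam_par - lam_perp
    dl[no_dir] <- 0
    lam_perp[no_dir] <- iso
    wm_comp <- cbind(
      lam_perp + dl * tang[, 1]^2,
      dl * tang[, 1] * tang[, 2],
      dl * tang[, 1] * tang[, 3],
      lam_perp + dl * tang[, 2]^2,
      dl * tang[, 2] * tang[, 3],
      lam_perp + dl * tang[, 3]^2
    )
    nvox <- prod(vol$shape)
    for (ci in 1:6) {
      comp[wm_idx + (ci - 1L) * nvox] <- wm_comp[, ci]
    }
  }
  tensor_field(comp, vol$spacing)
}

#' Seed an initial tumor density
#'
#' Places `u = 1` inside a sphere (center and radius in mm) intersected with
#' white and gray matter; everywhere else `u = 0`.  Radius 0 seeds the
#' single voxel containing the center.  Growth is later simulated from this
#' single region, mimicking growth from a point seed.
#'
#' @param vol A [labeled_volume()].
#' @param center Numeric length-3 world coordinates, mm.
#' @param radius Sphere radius, mm.
#' @return A [density_field()] at time 0.
#' @export
seed_tumor <- function(vol, center, radius = 0) {
  stopifnot(inherits(vol, "labeled_volume"))
  idx <- round(center / vol$spacing) + 1
  if (any(idx < 1) || any(idx > vol$shape)) {
    stop("seed center lies outside the grid", call. = FALSE)
  }
  if (vol$labels[idx[1], idx[2], idx[3]] == LBL$OUTSIDE) {
    stop("seed center lies outside the brain", call. = FALSE)
  }
  u <- array(0, vol$shape)
  permeable <- wm_mask(vol) | gm_mask(vol)
  if (radius <= 0) {
    if (permeable[idx[1], idx[2], idx[3]]) {
      u[idx[1], idx[2], idx[3]] <- 1
    }
  } else {
    grids <- coord_grids(vol$shape, vol$spacing)
    d <- sqrt((grids$x - center[1])^2 + (grids$y - center[2])^2 +
              (grids$z - center[3])^2)
    u[d <= radius & permeable] <- 1
  }
  if (sum(u) == 0) {
    warning("tumor seed does not intersect WM or GM: initial density is all zero",
            call. = FALSE)
  }
  density_field(u, vol$spacing, time = 0)
}

#' Build a standard therapy calendar
#'
#' Radiotherapy follows the conventional post-surgery fractionation of a
#' 60 Gy total dose divided into 30 daily fractions of 2 Gy.  Chemotherapy
#' follows the standard temozolomide schedule of 6 cycles, 5 active days per
#' cycle, 28-day cycle period.  Day indices count days from simulation
#' start; a fraction/active day `d` means the effect applies over
#' `t` in `[d, d+1)`.
#'
#' @param kind `"radiotherapy"` or `"chemotherapy"`.
#' @param start_day First fraction / first active day (integer, default 0).
#' @param dose_per_fraction Gy per radiotherapy fraction.
#' @param n_fractions Number of daily fractions.
#' @param alpha Linear radiobiology coefficient, 1/Gy.
#' @param alpha_beta_ratio Radiobiological ratio in Gy; `beta` is derived as
#'   `alpha / alpha_beta_ratio` unless given.
#' @param beta Quadratic coefficient, 1/Gy^2 (optional).
#' @param n_cycles,days_per_cycle,cycle_period Chemotherapy calendar shape.
#' @param k Chemotherapy cell death rate, 1/day.
#' @return An [rt_plan()] or [chemo_plan()].
#' @examples
#' rt <- make_therapy_calendar("radiotherapy")
#' sum(rep(rt$dose, length(rt$days)))   # 60 Gy total
#' @export
make_therapy_calendar <- function(kind, start_day = 0L,
                                  dose_per_fraction = 2, n_fractions = 30L,
                                  alpha = 0.027, alpha_beta_ratio = 10,
                                  beta = NULL,
                                  n_cycles = 6L, days_per_cycle = 5L,
                                  cycle_period = 28L, k = 0.0196) {
  kind <- match.arg(kind, c("radiotherapy", "chemotherapy"))
  if (kind == "radiotherapy") {
    rt_plan(days = start_day + seq_len(n_fractions) - 1L,
            dose = dose_per_fraction, alpha = alpha,
            beta = beta, alpha_beta_ratio = alpha_beta_ratio)
  } else {
    starts <- start_day + (seq_len(n_cycles) - 1L) * cycle_period
    days <- as.integer(outer(seq_len(days_per_cycle) - 1L, starts, `+`))
    chemo_plan(active_days = sort(days), k = k)
  }
}

#' Radiotherapy plan
#'
#' Fraction calendar with per-fraction dose and linear-quadratic
#' coefficients.  `beta` defaults to `alpha / alpha_beta_ratio`; supplying
#' an inconsistent `alpha`, `beta`, ratio triple is an error.
#'
#' @param days Integer fraction day indices.
#' @param dose Dose per fraction in Gy (scalar, or one value per fraction).
#' @param alpha Linear coefficient, 1/Gy.
#' @param beta Quadratic coefficient, 1/Gy^2, or `NULL` to derive.
#' @param alpha_beta_ratio Ratio in Gy used to derive `beta`.
#' @return Object of class `rt_plan`.
#' @export
rt_plan <- function(days, dose = 2, alpha = 0.027, beta = NULL,
                    alpha_beta_ratio = 10) {
  days <- as.integer(days)
  if (any(dose < 0)) stop("fraction dose must be >= 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (is.null(beta)) {
    beta <- alpha / alpha_beta_ratio
  } else if (beta > 0 && !is.null(alpha_beta_ratio) &&
             abs(alpha / beta - alpha_beta_ratio) > 1e-8 * alpha_beta_ratio) {
    stop("inconsistent alpha, beta, alpha/beta ratio", call. = FALSE)
  }
  if (beta < 0) stop("beta must be >= 0", call. = FALSE)
  if (length(dose) != 1L && length(dose) != length(days)) {
    stop("dose must be scalar or one value per fraction", call. = FALSE)
  }
  structure(list(days = days, dose = dose, alpha = alpha, beta = beta),
            class = "rt_plan")
}

#' Chemotherapy plan
#'
#' @param active_days Integer day indices on which the drug acts.
#' @param k Cell death rate, 1/day.
#' @return Object of class `chemo_plan`.
#' @export
chemo_plan <- function(active_days, k = 0.0196) {
  if (k < 0) stop("chemotherapy rate k must be >= 0", call. = FALSE)
  structure(list(active_days = as.integer(active_days), k = k),
            class = "chemo_plan")
}

#' Is a therapy plan active on a given day?
#'
#' @param plan An [rt_plan()] or [chemo_plan()].
#' @param day Integer day index (vectorised).
#' @return Logical vector.
#' @export
is_active <- function(plan, day) {
  if (inherits(plan, "rt_plan")) day %in% plan$days
  else if (inherits(plan, "chemo_plan")) day %in% plan$active_days
  else stop("not a therapy plan", call. = FALSE)
}

#' Draw a randomized phantom specification
#'
#' Convenience generator for solver stress-testing: random brain semi-axes,
#' one or two fiber bundles with random orientation and anisotropy ratio up
#' to 5, optional cavity.  Fully determined by `seed`.
#'
#' @param shape,spacing Grid geometry passed through to [phantom_spec()].
#' @param seed Integer RNG seed.
#' @param p_cavity Probability of including a resection cavity.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(shape = c(16, 16, 16), spacing = c(2, 2, 2),
                                seed = 1L, p_cavity = 0.5) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  extent <- (shape - 1) * spacing
  center <- extent / 2
  radii <- extent * stats::runif(3, 0.34, 0.44)
  nf <- sample(1:2, 1)
  fibers <- lapply(seq_len(nf), function(i) {
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    mid <- center + stats::runif(3, -0.2, 0.2) * radii
    half <- 0.9 * min(radii)
    list(points = rbind(mid - half * dir, mid + half * dir),
         radius = stats::runif(1, 0.15, 0.35) * min(radii),
         anisotropy = stats::runif(1, 2, 5))
  })
  cavity <- NULL
  if (stats::runif(1) < p_cavity) {
    cavity <- list(center = center + stats::runif(3, -0.25, 0.25) * radii,
                   radius = stats::runif(1, 0.15, 0.3) * min(radii))
  }
  phantom_spec(shape = shape, spacing = spacing, brain_radii = radii,
               gm_thickness = 1, fibers = fibers, cavity = cavity, seed = seed)
}

# Save/restore .Random.seed so generators do not disturb the caller's RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
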