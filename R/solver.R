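# Explicit finite-difference integration of the growth PDE with a
# non-negativity oriented directional stencil for anisotropic diffusion.

# Vectorised largest eigenvalue of symmetric 3x3 tensors stored as
# components (trigonometric closed form).
tensor_lambda_max <- function(comp) {
  xx <- comp[, , , 1]; xy <- comp[, , , 2]; xz <- comp[, , , 3]
  yy <- comp[, , , 4]; yz <- comp[, , , 5]; zz <- comp[, , , 6]
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  lam <- q
  nz <- p > 0
  if (any(nz)) {
    bxx <- (xx - q) / p; byy <- (yy - q) / p; bzz <- (zz - q) / p
    bxy <- xy / p; bxz <- xz / p; byz <- yz / p
    detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    lam2 <- q + 2 * p * cos(phi)
    lam[nz] <- lam2[nz]
  }
  lam
}

#' Stability-safe explicit time step
#'
#' Sufficient CFL-type bound for the explicit anisotropic diffusion scheme:
#' `dt <= safety * min_x 1 / (sum_axis 2 * Dmax(x) / h_axis^2)` with
#' `Dmax(x)` the largest local eigenvalue and `safety = 0.9`.  Because the
#' solver redistributes off-diagonal tensor mass onto diagonal directions
#' without increasing the total stencil weight, this bound guarantees a
#' discrete maximum principle (density stays in `[0, 1]` without clipping).
#'
#' @param diffusion A [tensor_field()] (mm^2/day) or a scalar diffusivity
#'   3D array (mm^2/day).
#' @param spacing Voxel size, mm.
#' @param cadence Fallback step (days) when the diffusivity is zero
#'   everywhere.
#' @param safety Safety factor in `(0, 1]`.
#' @return Step length in days.
#' @export
stable_dt <- function(diffusion, spacing = NULL, cadence = 1, safety = 0.9) {
  if (inherits(diffusion, "tensor_field")) {
    if (is.null(spacing)) spacing <- diffusion$spacing
    dmax <- max(tensor_lambda_max(diffusion$comp))
  } else {
    stopifnot_shape3(diffusion, "diffusion")
    dmax <- max(diffusion)
  }
  spacing <- check_spacing(spacing)
  if (dmax <= 0) return(cadence)
  safety / (2 * dmax * sum(1 / spacing^2))
}

# Precompute the stencil face weights for div(D grad u).
#
# Axis terms use the diagonal entries, reduced by the off-diagonal mass they
# delegate to diagonal directions: A_i = max(0, D_ii - sum_j (h_i/h_j)|D_ij|)
# (the clamp preserves non-negativity of all weights; clamped voxels are
# counted).  Off-diagonal entries are discretised by second differences
# along the plane diagonals (direction e_i + e_j for positive D_ij,
# e_i - e_j for negative), the standard non-negativity oriented treatment.
# All face coefficients are harmonic means of the voxel coefficients, so a
# zero-diffusivity neighbor (CSF/outside) blocks the face and mass
# telescopes exactly: the no-flux brain boundary holds by construction.
aniso_stencil <- function(diffusion, spacing) {
  spacing <- check_spacing(spacing)
  axes_off <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  faces <- list()
  clamped <- 0L
  if (inherits(diffusion, "tensor_field")) {
    comp <- diffusion$comp
    dxx <- comp[, , , 1]; dxy <- comp[, , , 2]; dxz <- comp[, , , 3]
    dyy <- comp[, , , 4]; dyz <- comp[, , , 5]; dzz <- comp[, , , 6]
    h <- spacing
    axis_raw <- list(
      dxx - (h[1] / h[2]) * abs(dxy) - (h[1] / h[3]) * abs(dxz),
      dyy - (h[2] / h[1]) * abs(dxy) - (h[2] / h[3]) * abs(dyz),
      dzz - (h[3] / h[1]) * abs(dxz) - (h[3] / h[2]) * abs(dyz)
    )
    any_off <- abs(dxy) + abs(dxz) + abs(dyz) > 0
    for (ax in 1:3) {
      clamped <- clamped + sum(axis_raw[[ax]] < 0 & any_off)
      a <- pmax(axis_raw[[ax]], 0)
      o <- axes_off[[ax]]
      wp <- harmonic_face(a, shift3(a, o[1], o[2], o[3])) / spacing[ax]^2
      faces[[length(faces) + 1L]] <- list(off = o, wp = wp)
    }
    pairs <- list(list(d = dxy, i = 1L, j = 2L),
                  list(d = dxz, i = 1L, j = 3L),
                  list(d = dyz, i = 2L, j = 3L))
    for (p in pairs) {
      hh <- spacing[p$i] * spacing[p$j]
      cp <- pmax(p$d, 0)
      cm <- pmax(-p$d, 0)
      ei <- axes_off[[p$i]]; ej <- axes_off[[p$j]]
      if (any(cp > 0)) {
        o <- ei + ej
        wp <- harmonic_face(cp, shift3(cp, o[1], o[2], o[3])) / hh
        faces[[length(faces) + 1L]] <- list(off = o, wp = wp)
      }
      if (any(cm > 0)) {
        o <- ei - ej
        wp <- harmonic_face(cm, shift3(cm, o[1], o[2], o[3])) / hh
        faces[[length(faces) + 1L]] <- list(off = o, wp = wp)
      }
    }
  } else {
    stopifnot_shape3(diffusion, "diffusion")
    for (ax in 1:3) {
      o <- axes_off[[ax]]
      wp <- harmonic_face(diffusion, shift3(diffusion, o[1], o[2], o[3])) /
        spacing[ax]^2
      faces[[length(faces) + 1L]] <- list(off = o, wp = wp)
    }
  }
  # drop all-zero faces, precompute the opposite-face weight
  faces <- Filter(function(f) any(f$wp > 0), faces)
  for (i in seq_along(faces)) {
    o <- faces[[i]]$off
    faces[[i]]$wm <- shift3(faces[[i]]$wp, -o[1], -o[2], -o[3])
  }
  list(faces = faces, clamped = clamped)
}

apply_stencil <- function(st, u) {
  out <- array(0, dim(u))
  for (f in st$faces) {
    o <- f$off
    out <- out + f$wp * (shift3(u, o[1], o[2], o[3]) - u) +
      f$wm * (shift3(u, -o[1], -o[2], -o[3]) - u)
  }
  out
}

#' Discrete anisotropic diffusion operator
#'
#' Evaluates `div(D grad u)` with the solver's non-negativity oriented
#' stencil: conservative axis fluxes from the diagonal tensor entries
#' (harmonic face means) plus directional second differences along plane
#' diagonals for the off-diagonal entries.  With a diagonal tensor (or a
#' scalar map) it reduces exactly to the standard 7-point
#' variable-coefficient stencil.
#'
#' @param u Density array or [density_field()].
#' @param diffusion [tensor_field()] or scalar diffusivity array, mm^2/day.
#' @param spacing Voxel size, mm (taken from the inputs when omitted).
#' @return Rate array, 1/day.
#' @export
weickert_divergence <- function(u, diffusion, spacing = NULL) {
  if (inherits(u, "density_field")) {
    if (is.null(spacing)) spacing <- u$spacing
    u <- u$u
  }
  if (is.null(spacing) && inherits(diffusion, "tensor_field")) {
    spacing <- diffusion$spacing
  }
  st <- aniso_stencil(diffusion, spacing)
  apply_stencil(st, u)
}

#' Threshold a density field to a detection mask
#'
#' Voxels with `u >= threshold` are considered imaging-visible tumor; the
#' conventional detection threshold is 0.4.
#'
#' @param u [density_field()], `growth_result` (final field) or array.
#' @param threshold Detection level in `(0, 1)`.
#' @return Logical 3D array.
#' @export
extract_mask <- function(u, threshold = 0.4) {
  if (!(threshold > 0 && threshold < 1)) {
    stop("threshold must lie strictly between 0 and 1", call. = FALSE)
  }
  if (inherits(u, "growth_result")) u <- u$final
  if (inherits(u, "density_field")) u <- u$u
  u >= threshold
}

#' Single explicit step of the growth PDE
#'
#' Advances `u' = clip(u + dt * [div(D grad u) + stress + u((rho - r)(1-u)
#' - kbar)], 0, 1)` and re-imposes zero density outside the growth region
#' (CSF/outside brain).  Intended for inspection and testing; full runs use
#' [simulate_growth()], which precomputes the stencil once.
#'
#' @param u Density array or [density_field()].
#' @param dt Step, days.
#' @param diffusion [tensor_field()] or scalar map (mm^2/day).
#' @param vol [labeled_volume()].
#' @param rho Proliferation rate field or scalar, 1/day.
#' @param r_field,kbar_field Optional therapy rate arrays (1/day).
#' @param stress_term Optional stress-diffusion rate array (1/day).
#' @return Density array after one step.
#' @export
growth_step <- function(u, dt, diffusion, vol, rho = 0.012,
                        r_field = NULL, kbar_field = NULL,
                        stress_term = NULL) {
  if (inherits(u, "density_field")) u <- u$u
  st <- aniso_stencil(diffusion, vol$spacing)
  du <- apply_stencil(st, u)
  if (!is.null(stress_term)) du <- du + stress_term
  r <- if (is.null(r_field)) 0 else r_field
  kb <- if (is.null(kbar_field)) 0 else kbar_field
  du <- du + u * ((rho - r) * (1 - u) - kb)
  un <- u + dt * du
  if (any(!is.finite(un))) stop("non-finite density after step", call. = FALSE)
  un <- pmin(pmax(un, 0), 1)
  un[!growth_mask(vol)] <- 0
  un
}

#' Simulate post-surgery glioma growth
#'
#' Integrates the growth PDE from an initial density over `days` days with
#' explicit first-order time stepping at (or below) the [stable_dt()]
#' bound, honoring radiotherapy and chemotherapy calendars day by day.
#' Tumor density is confined to white matter, gray matter and (by default)
#' the resection cavity; CSF and outside-brain voxels stay at zero and the
#' no-flux brain boundary conserves total mass in the absence of reaction.
#' The run is fully deterministic.
#'
#' Cavity handling: with the default `cavity_policy = "permeable"` tumor
#' may invade the cavity with gray-matter diffusivity, proliferates there
#' unless `cavity_proliferation` is `FALSE`, and receives no therapy effect
#' there; `"sealed"` keeps the cavity tumor-free.
#'
#' @param init [density_field()] at time 0 (e.g. [seed_tumor()]).
#' @param vol [labeled_volume()].
#' @param diffusion [tensor_field()] from [build_growth_tensor()], or a
#'   scalar map from [scalar_diffusion_map()] for the DTI-free variant.
#' @param rt_plan,chemo_plan Optional therapy plans; ignored when the
#'   corresponding `use_rt`/`use_chemo` config flag is off.
#' @param config A configuration list from [default_config()] /
#'   [load_config()].
#' @param days Total simulated time in whole days; defaults to
#'   `config$t_end`.
#' @param save_every Snapshot cadence in days (default `config$save_every`).
#' @return Object of class `growth_result`: saved `times` and `fields`,
#'   `final` density, detection `mask` at `config$u_detect`, per-step
#'   diagnostics in `log` (data.frame with step, time, dt, mass, max_u,
#'   clipped), and `clamped_aniso`, the number of voxels where the
#'   non-negativity clamp was active.
#' @export
simulate_growth <- function(init, vol, diffusion, rt_plan = NULL,
                            chemo_plan = NULL, config = default_config(),
                            days = NULL, save_every = NULL) {
  stopifnot(inherits(init, "density_field"), inherits(vol, "labeled_volume"))
  config <- finalize_config(unclass(config))
  if (!identical(dim(init$u), vol$shape)) stop("shapes differ", call. = FALSE)
  if (is.null(days)) days <- config$t_end
  days <- as.integer(days)
  if (days < 0) stop("days must be >= 0", call. = FALSE)
  if (is.null(save_every)) save_every <- config$save_every
  save_every <- max(1L, as.integer(save_every))
  spacing <- vol$spacing
  if (!isTRUE(config$use_rt)) rt_plan <- NULL
  if (!isTRUE(config$use_chemo)) chemo_plan <- NULL

  permeable_cavity <- identical(config$cavity_policy, "permeable")
  grow <- growth_mask(vol)
  if (!permeable_cavity) grow <- grow & !cavity_mask(vol)
  grow_num <- array(as.numeric(grow), vol$shape)

  # cavity policy on the diffusion input (tumor spreads there like in GM)
  d_gm_mm2 <- 100 * config$d_gm
  cav <- which(cavity_mask(vol))
  if (inherits(diffusion, "tensor_field")) {
    comp <- diffusion$comp
    if (length(cav) > 0 && permeable_cavity) {
      nvox <- prod(vol$shape)
      for (ci in c(1L, 4L, 6L)) comp[cav + (ci - 1L) * nvox] <- d_gm_mm2
      for (ci in c(2L, 3L, 5L)) comp[cav + (ci - 1L) * nvox] <- 0
      diffusion <- tensor_field(comp, spacing)
    }
  } else {
    stopifnot_shape3(diffusion, "diffusion")
    if (length(cav) > 0 && permeable_cavity) diffusion[cav] <- d_gm_mm2
  }
  st <- aniso_stencil(diffusion, spacing)

  # time stepping: steps of equal length dividing one day
  dtmax <- stable_dt(diffusion, spacing, cadence = 1)
  if (identical(config$dt, "auto")) {
    spd <- max(1L, as.integer(ceiling(1 / dtmax - 1e-9)))
  } else {
    dt_req <- as.numeric(config$dt)
    if (dt_req > dtmax * (1 + 1e-9)) {
      stop(sprintf("requested dt = %g days exceeds the stability bound %g days",
                   dt_req, dtmax), call. = FALSE)
    }
    spd <- as.integer(round(1 / dt_req))
    if (spd < 1L || abs(spd * dt_req - 1) > 1e-6) {
      stop("dt must divide one day (therapy calendars are day-resolved)",
           call. = FALSE)
    }
  }
  dt <- 1 / spd

  # proliferation field (optionally silenced in the cavity)
  rho_field <- config$rho * grow_num
  if (!isTRUE(config$cavity_proliferation) && length(cav) > 0) {
    rho_field[cav] <- 0
  }

  # therapy rate templates (identical on every active day: uniform dose,
  # constant k)
  r_tpl <- NULL
  s_tpl <- NULL
  if (!is.null(rt_plan) && length(rt_plan$days) > 0) {
    r_tpl <- rt_rate(rt_plan$days[1], rt_plan, vol)
    if (identical(config$rt_mode, "instant")) s_tpl <- 1 - r_tpl
  }
  kbar_tpl <- NULL
  if (!is.null(chemo_plan) && length(chemo_plan$active_days) > 0) {
    omega <- wm_proportion(vol, config$omega_window)
    kbar_tpl <- chemo_rate(chemo_plan$active_days[1], chemo_plan, vol, omega)
  }
  if (!is.null(r_tpl) || !is.null(kbar_tpl)) {
    check_treatment_assumption(
      if (is.null(r_tpl) || identical(config$rt_mode, "instant")) 0 else max(r_tpl),
      if (is.null(kbar_tpl)) 0 else max(kbar_tpl),
      config$rho)
  }

  # viscoelastic pathway
  dhat <- rep(as.numeric(config$d_hat), length.out = 3)
  use_ve <- isTRUE(config$use_viscoelastic) && config$kappa > 0 &&
    any(dhat != 0)
  if (use_ve) {
    model <- maxwell_weichert(E = config$e1, eta = config$eta1,
                              E_inf = config$e_inf)
    brain <- brain_mask(vol)
    memoryless <- identical(config$stress_formulation, "memoryless")
    if (!memoryless) {
      state <- init_stress_state(vol$shape, model)
      state$sigma <- sum(model$E) * strain_proxy(init$u, config$kappa)
      eps_prev <- strain_proxy(init$u, config$kappa)
    }
  }

  u <- init$u
  n_steps <- days * spd
  log_mass <- numeric(n_steps); log_max <- numeric(n_steps)
  log_clip <- integer(n_steps); log_t <- numeric(n_steps)
  voxvol <- prod(spacing)
  clip_tol <- 1e-9

  times <- init$time
  fields <- list(density_field(u, spacing, time = init$time))
  step_i <- 0L
  if (days > 0) {
    for (d in seq_len(days) - 1L) {
      rt_on <- !is.null(r_tpl) && (d %in% rt_plan$days)
      ch_on <- !is.null(kbar_tpl) && (d %in% chemo_plan$active_days)
      if (rt_on && !is.null(s_tpl)) {   # instantaneous-kill mode
        u <- u * s_tpl
        rt_on <- FALSE
      }
      for (s in seq_len(spd)) {
        step_i <- step_i + 1L
        du <- apply_stencil(st, u)
        if (use_ve) {
          if (memoryless) {
            cc <- sum(model$E) +
              sum(model$E * (1 - exp(-(d + s * dt) / model$tau)))
            sig <- cc * strain_proxy(u, config$kappa)
          } else {
            sig <- state$sigma
          }
          du <- du + stress_divergence_term(sig, dhat, spacing, brain)
        }
        if (rt_on) {
          if (ch_on) du <- du + u * ((rho_field - r_tpl) * (1 - u) - kbar_tpl)
          else du <- du + u * (rho_field - r_tpl) * (1 - u)
        } else if (ch_on) {
          du <- du + u * (rho_field * (1 - u) - kbar_tpl)
        } else {
          du <- du + rho_field * u * (1 - u)
        }
        un <- u + dt * du
        if (any(!is.finite(un))) {
          stop(sprintf("non-finite density at step %d (t = %.3f d): numerical blow-up",
                       step_i, d + s * dt), call. = FALSE)
        }
        clip <- sum(un < -clip_tol | un > 1 + clip_tol)
        un <- pmin(pmax(un, 0), 1) * grow_num
        if (use_ve && !memoryless) {
          eps_now <- strain_proxy(un, config$kappa)
          state <- update_stress(state, eps_now, eps_prev, dt, model)
          eps_prev <- eps_now
        }
        u <- un
        log_mass[step_i] <- sum(u) * voxvol
        log_max[step_i] <- max(u)
        log_clip[step_i] <- clip
        log_t[step_i] <- d + s * dt
      }
      if ((d + 1L) %% save_every == 0L || d + 1L == days) {
        times <- c(times, d + 1L)
        fields[[length(fields) + 1L]] <- density_field(u, spacing, time = d + 1L)
      }
    }
    post <- log_clip[-seq_len(min(10L, n_steps))]
    if (length(post) > 0 && mean(post > 0) > 0.05) {
      stop(sprintf(paste0("persistent clipping: density left [0,1] in %d of %d ",
                          "post-transient steps; stability violation"),
                   sum(post > 0), length(post)), call. = FALSE)
    }
  }

  final <- fields[[length(fields)]]
  structure(list(
    times = times,
    fields = fields,
    final = final,
    mask = extract_mask(final, config$u_detect),
    log = data.frame(step = seq_len(n_steps), time = log_t,
                     dt = rep(dt, n_steps), mass = log_mass, max_u = log_max,
                     clipped = log_clip),
    clamped_aniso = st$clamped,
    dt = dt, days = days
  ), class = "growth_result")
}

#' @export
print.growth_result <- function(x, ...) {
  cat("<growth_result> ", x$days, " days, dt = ", signif(x$dt, 4),
      " d (", nrow(x$log), " steps), ", length(x$times), " snapshots\n",
      "  final: max u = ", signif(max(x$final$u), 4),
      ", mask voxels = ", sum(x$mask),
      ", total clipped = ", sum(x$log$clipped), "\n", sep = "")
  invisible(x)
}

#' Along-axis front position of a density profile
#'
#' Locates the leading edge of the tumor front: the largest world
#' coordinate along `axis` at which the axis-wise maximum-intensity profile
#' crosses `level`, linearly interpolated between voxel centers.  Used to
#' measure traveling-wave speeds on homogeneous media.
#'
#' @param u [density_field()] or array.
#' @param spacing Voxel size, mm (taken from the field when omitted).
#' @param level Density level defining the front (default 0.5).
#' @param axis Axis along which to measure (default 1).
#' @return Front coordinate in mm (`NA` if the profile never crosses).
#' @export
front_position <- function(u, spacing = NULL, level = 0.5, axis = 1L) {
  if (inherits(u, "density_field")) {
    if (is.null(spacing)) spacing <- u$spacing
    u <- u$u
  }
  spacing <- check_spacing(spacing)
  prof <- apply(u, axis, max)
  idx <- which(prof >= level)
  if (length(idx) == 0) return(NA_real_)
  i <- max(idx)
  if (i == length(prof)) return((i - 1) * spacing[axis])
  # interpolate between the last >= level voxel and the next one
  frac <- (prof[i] - level) / (prof[i] - prof[i + 1])
  (i - 1 + frac) * spacing[axis]
}
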