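#' Maxwell-Weichert viscoelastic model
#'
#' A parallel assembly of `n` Maxwell spring-dashpot elements plus a free
#' spring.  Element `k` has Young's modulus `E_k` (Pa) and dashpot viscosity
#' `eta_k` (Pa s); its relaxation time is `tau_k = eta_k / E_k`.  Times are
#' converted to days internally since the growth model is integrated in
#' days.  With the literature parameters (`E1 = 3156` Pa,
#' `eta1 = 8.9e-8` Pa s) the relaxation time is ~2.8e-11 s, i.e. the
#' Maxwell element relaxes essentially instantaneously on the day scale;
#' this is carried literally and the recursive update remains numerically
#' exact in that limit.
#'
#' @param E Young's moduli of the Maxwell springs, Pa (length `n`).
#' @param eta Dashpot viscosities, Pa s (length `n`).
#' @param E_inf Free-spring modulus, Pa; defaults to `E[1] / 6`.
#' @return Object of class `maxwell_weichert` with `E`, `eta`, `E_inf`,
#'   `tau_s` (s) and `tau` (days).
#' @examples
#' m <- maxwell_weichert()          # one element, E1 = 3156 Pa, E_inf = 526 Pa
#' relaxation_modulus(0, m)         # E1 + E_inf
#' @export
maxwell_weichert <- function(E = 3156, eta = 8.9e-8, E_inf = E[1] / 6) {
  if (length(E) != length(eta)) stop("E and eta must have equal length", call. = FALSE)
  if (length(E) < 1L || any(E <= 0) || any(eta <= 0) || E_inf <= 0) {
    stop("all moduli and viscosities must be > 0 (n >= 1)", call. = FALSE)
  }
  tau_s <- eta / E
  structure(list(E = E, eta = eta, E_inf = E_inf, tau_s = tau_s,
                 tau = tau_s / 86400, n = length(E)),
            class = "maxwell_weichert")
}

#' Relaxation modulus E(t)
#'
#' `E(t) = sum_k E_k exp(-t / tau_k) + E_inf`: a Prony series over the
#' Maxwell elements plus the free-spring plateau.  Non-increasing in `t`,
#' equal to `sum(E_k) + E_inf` at `t = 0` and tending to `E_inf`.
#'
#' @param t Time (vectorised, >= 0).
#' @param model A [maxwell_weichert()].
#' @param time_unit `"days"` (default) or `"seconds"` — unit of `t` and of
#'   the relaxation times used.
#' @return Modulus in Pa.
#' @export
relaxation_modulus <- function(t, model, time_unit = c("days", "seconds")) {
  stopifnot(inherits(model, "maxwell_weichert"))
  time_unit <- match.arg(time_unit)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tau <- if (time_unit == "days") model$tau else model$tau_s
  out <- rep(model$E_inf, length(t))
  for (k in seq_len(model$n)) out <- out + model$E[k] * exp(-t / tau[k])
  out
}

#' Volumetric strain proxy from tumor density
#'
#' The growth model needs a strain source for the viscoelastic pathway; the
#' minimal coupling used here is `epsilon = kappa * u`, i.e. local strain
#' proportional to tumor cell density, with a small unitless coefficient
#' `kappa`.  Setting `kappa = 0` disables the stress pathway entirely.
#'
#' @param u Density array (or [density_field()]).
#' @param kappa Strain per unit density (unitless, default 0.01).
#' @return Strain array.
#' @export
strain_proxy <- function(u, kappa = 0.01) {
  if (inherits(u, "density_field")) u <- u$u
  kappa * u
}

#' Initialise a viscoelastic stress state
#'
#' Holds the per-element recursive accumulators of the Boltzmann hereditary
#' integral plus the current stress field.  Memory cost is independent of
#' history length.
#'
#' @param shape Grid dimensions.
#' @param model A [maxwell_weichert()].
#' @return Object of class `stress_state` with `sigma` (Pa) and accumulator
#'   list `a` (one array per element).
#' @export
init_stress_state <- function(shape, model) {
  stopifnot(inherits(model, "maxwell_weichert"))
  structure(list(sigma = array(0, shape),
                 a = lapply(seq_len(model$n), function(k) array(0, shape)),
                 t = 0),
            class = "stress_state")
}

#' Advance the hereditary stress integral one step
#'
#' Updates the Boltzmann-integral stress
#' \deqn{\sigma(t) = (\sum_k E_k)\,\varepsilon(t) +
#'   \int_0^t \sum_k \frac{E_k}{\tau_k} e^{-(t-s)/\tau_k}\,\varepsilon(s)\,ds}
#' using one recursive exponential accumulator per Maxwell element, exact
#' for strain varying piecewise-linearly over the step.  The update is
#' unconditionally stable and numerically robust for relaxation times many
#' orders of magnitude smaller than the step (the literature regime).
#'
#' The convolution is applied to the scalar strain field; the spatial
#' gradient of the constitutive law enters the growth PDE through the
#' stress-diffusion term, see [stress_divergence_term()].
#'
#' @param state A `stress_state` from [init_stress_state()].
#' @param strain_now,strain_prev Strain fields at the end/start of the step
#'   (arrays or scalars).
#' @param dt Step length, days (> 0).
#' @param model A [maxwell_weichert()].
#' @return The updated `stress_state` (with `sigma` at the new time).
#' @export
update_stress <- function(state, strain_now, strain_prev, dt, model) {
  stopifnot(inherits(state, "stress_state"), inherits(model, "maxwell_weichert"))
  if (dt <= 0) stop("dt must be > 0", call. = FALSE)
  sigma <- (sum(model$E)) * strain_now
  for (k in seq_len(model$n)) {
    tau <- model$tau[k]
    theta <- exp(-dt / tau)
    one_m <- -expm1(-dt / tau)        # 1 - theta, accurate for small dt/tau
    cc <- 1 - tau * one_m / dt        # weight of the strain increment
    incr <- model$E[k] *
      (strain_prev * (one_m - cc) + strain_now * cc)
    state$a[[k]] <- theta * state$a[[k]] + incr
    sigma <- sigma + state$a[[k]]
  }
  state$sigma <- sigma
  state$t <- state$t + dt
  state
}

#' Stress-diffusion contribution to the growth PDE
#'
#' Discrete `div(Dhat grad sigma)` with `Dhat` a diagonal tensor with
#' non-positive entries (units cells/(Pa day) up to the carrying-capacity
#' scale).  Central flux differences with a zero-flux closure at the brain
#' mask boundary: faces with a non-brain side carry no flux.
#'
#' @param sigma Stress array, Pa.
#' @param dhat Diagonal entries of the stress-diffusion tensor (scalar or
#'   length 3), all `<= 0`.
#' @param spacing Voxel size, mm.
#' @param mask Logical array of voxels where stress is defined (brain);
#'   default everywhere.
#' @return Rate array, 1/day.
#' @export
stress_divergence_term <- function(sigma, dhat, spacing, mask = NULL) {
  stopifnot_shape3(sigma, "sigma")
  spacing <- check_spacing(spacing)
  dhat <- rep(as.numeric(dhat), length.out = 3)
  if (any(dhat > 0)) {
    stop("stress diffusion entries must be <= 0", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, dim(sigma))
  m <- array(as.numeric(mask), dim(sigma))
  out <- array(0, dim(sigma))
  offs <- list(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  for (ax in 1:3) {
    if (dhat[ax] == 0) next
    o <- offs[[ax]]
    fp <- m * shift3(m, o[1], o[2], o[3])
    fm <- m * shift3(m, -o[1], -o[2], -o[3])
    up <- shift3(sigma, o[1], o[2], o[3])
    um <- shift3(sigma, -o[1], -o[2], -o[3])
    out <- out + dhat[ax] * (fp * (up - sigma) + fm * (um - sigma)) /
      spacing[ax]^2
  }
  out * m
}
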