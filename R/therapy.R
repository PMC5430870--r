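#' Linear-quadratic survival fraction
#'
#' Probability that a cell survives a radiation dose `d`:
#' `S = exp(-alpha * d - beta * d^2)`.
#'
#' @param alpha Linear coefficient, 1/Gy (>= 0).
#' @param beta Quadratic coefficient, 1/Gy^2 (>= 0).
#' @param dose Dose in Gy (vectorised, >= 0).
#' @return Survival fraction in `(0, 1]`.
#' @examples
#' survival_fraction(0.027, 0.0027, 2)   # exp(-0.0648)
#' @export
survival_fraction <- function(alpha, beta, dose) {
  if (any(dose < 0)) stop("dose must be >= 0", call. = FALSE)
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0", call. = FALSE)
  exp(-alpha * dose - beta * dose^2)
}

#' Per-voxel radiotherapy kill rate on a given day
#'
#' Zero everywhere on non-fraction days.  On a fraction day the rate is
#' `1 - S(alpha, beta, dose)` at brain voxels, and stays zero in the
#' resection cavity (therapy is assumed to have no effect there) and outside
#' the brain.  An optional per-voxel dose-weight map scales the fraction
#' dose voxelwise (uniform conformal dose by default).
#'
#' @param day Integer day index.
#' @param plan An [rt_plan()].
#' @param vol A [labeled_volume()].
#' @param dose_map Optional 3D array of voxelwise dose multipliers.
#' @return Numeric 3D array of kill rates (1/day when time steps are in
#'   days).
#' @export
rt_rate <- function(day, plan, vol, dose_map = NULL) {
  stopifnot(inherits(plan, "rt_plan"), inherits(vol, "labeled_volume"))
  r <- array(0, vol$shape)
  hit <- which(plan$days == day)
  if (length(hit) == 0) return(r)
  dose <- if (length(plan$dose) == 1L) plan$dose else plan$dose[hit[1]]
  target <- brain_mask(vol) & !cavity_mask(vol)
  if (is.null(dose_map)) {
    r[target] <- 1 - survival_fraction(plan$alpha, plan$beta, dose)
  } else {
    stopifnot_shape3(dose_map, "dose_map")
    d <- dose * dose_map
    r[target] <- 1 - survival_fraction(plan$alpha, plan$beta, d[target])
  }
  r
}

#' Radiotherapy loss term
#'
#' `R(u) = r * u * (1 - u)`: the kill acts on the proliferating fraction,
#' vanishing at `u = 0` and at carrying capacity.
#'
#' @param u Density array (or [density_field()]).
#' @param r_field Kill-rate array from [rt_rate()].
#' @return Loss array, 1/day.
#' @export
radiotherapy_loss <- function(u, r_field) {
  if (inherits(u, "density_field")) u <- u$u
  r_field * u * (1 - u)
}

#' Per-voxel chemotherapy death rate on a given day
#'
#' Zero on inactive days and in CSF, cavity and outside brain.  On active
#' days gray matter receives the nominal rate `k`, while white matter
#' receives `k / (k + omega)` with `omega` the local white-matter
#' proportion: drug absorption is modulated by tissue heterogeneity.
#'
#' @param day Integer day index.
#' @param plan A [chemo_plan()].
#' @param vol A [labeled_volume()].
#' @param omega A [wm_proportion()] field (or plain array).
#' @return Numeric 3D array of death rates, 1/day.
#' @export
chemo_rate <- function(day, plan, vol, omega) {
  stopifnot(inherits(plan, "chemo_plan"), inherits(vol, "labeled_volume"))
  kbar <- array(0, vol$shape)
  if (!(day %in% plan$active_days)) return(kbar)
  if (inherits(omega, "wm_proportion_field")) omega <- omega$omega
  kbar[gm_mask(vol)] <- plan$k
  wm <- wm_mask(vol)
  kbar[wm] <- plan$k / (plan$k + omega[wm])
  kbar
}

#' Chemotherapy loss term
#'
#' `C(u) = kbar * u`, a log-kill loss proportional to local density.
#'
#' @param u Density array (or [density_field()]).
#' @param kbar_field Death-rate array from [chemo_rate()].
#' @return Loss array, 1/day.
#' @export
chemotherapy_loss <- function(u, kbar_field) {
  if (inherits(u, "density_field")) u <- u$u
  kbar_field * u
}

# Model-assumption guard: the treatment terms are assumed weaker than
# proliferation.  Returns the worst-case combined rate for diagnostics and
# warns when it reaches rho.
check_treatment_assumption <- function(max_r, max_kbar, rho) {
  worst <- max_r + max_kbar
  if (worst >= rho) {
    warning(sprintf(paste0(
      "combined treatment rate (max r + kbar = %.4g/day) is not below the ",
      "proliferation rate (rho = %.4g/day); the modelling assumption that ",
      "treatment is weaker than proliferation is violated on therapy days"),
      worst, rho), call. = FALSE)
  }
  invisible(worst)
}
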