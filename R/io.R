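# NIfTI and configuration I/O. All volumetric files are NIfTI (the MR
# domain standard); tensors travel as 6-component 4D volumes in the fixed
# xx,xy,xz,yy,yz,zz order; therapy plans as JSON; configuration as YAML.

#' Default model configuration
#'
#' The full parameter set of the growth model with its literature defaults:
#' diffusivities `d_gm = 0.0013` cm^2/day and `d_wm = 5 * d_gm`,
#' proliferation `rho = 0.012`/day, one Maxwell element with
#' `e1 = 3156` Pa, `e_inf = e1/6`, `eta1 = 8.9e-8` Pa s, linear-quadratic
#' coefficients `alpha = 0.027`/Gy with `alpha/beta = 10` Gy (so
#' `beta = 0.0027`/Gy^2), chemotherapy rate `k_chemo = 0.0196`/day, stress
#' diffusion `d_hat = -1e-14`, detection threshold `u_detect = 0.4`.
#' Simulation controls: `dt = "auto"` (the [stable_dt()] bound), horizon
#' `t_end`, snapshot cadence `save_every`, feature flags `use_dti`,
#' `use_viscoelastic`, `use_rt`, `use_chemo`, radiotherapy mode `rt_mode`
#' (`"rate"` or `"instant"`), cavity policy, strain coupling `kappa`,
#' `stress_formulation` (`"boltzmann"` hereditary integral or the
#' `"memoryless"` coefficient form) and the white-matter window
#' `omega_window`.
#'
#' @return Named list of class `growth_config`.
#' @export
default_config <- function() {
  structure(list(
    # tissue / growth (Table-standard units: cm^2/day, 1/day)
    d_gm = 0.0013,
    d_wm = NULL,             # -> 5 * d_gm
    rho = 0.012,
    # viscoelasticity
    n_maxwell = 1L,
    e1 = 3156,
    e_inf = NULL,            # -> e1[1] / 6
    eta1 = 8.9e-8,
    kappa = 0.01,
    d_hat = -1e-14,
    stress_formulation = "boltzmann",
    # radiotherapy (LQ)
    alpha = 0.027,
    alpha_beta_ratio = 10,
    beta = NULL,             # -> alpha / alpha_beta_ratio
    rt_mode = "rate",
    # chemotherapy
    k_chemo = 0.0196,
    omega_window = 1L,
    # simulation
    u_detect = 0.4,
    dt = "auto",
    t_end = 180L,
    save_every = 30L,
    use_dti = TRUE,
    use_viscoelastic = TRUE,
    use_rt = TRUE,
    use_chemo = TRUE,
    cavity_policy = "permeable",
    cavity_proliferation = TRUE,
    e1_normalization = "max"
  ), class = "growth_config")
}

finalize_config <- function(cfg) {
  if (is.null(cfg$d_wm)) cfg$d_wm <- 5 * cfg$d_gm
  if (is.null(cfg$e_inf)) cfg$e_inf <- cfg$e1[1] / 6
  if (is.null(cfg$beta)) {
    cfg$beta <- cfg$alpha / cfg$alpha_beta_ratio
  } else if (cfg$beta > 0 &&
             abs(cfg$alpha / cfg$beta - cfg$alpha_beta_ratio) >
             1e-8 * cfg$alpha_beta_ratio) {
    stop("inconsistent alpha, beta, alpha/beta ratio in config", call. = FALSE)
  }
  if (!(cfg$d_gm > 0) || cfg$d_wm < cfg$d_gm) {
    stop("config requires d_wm >= d_gm > 0", call. = FALSE)
  }
  if (cfg$rho < 0) stop("config requires rho >= 0", call. = FALSE)
  if (!(cfg$u_detect > 0 && cfg$u_detect < 1)) {
    stop("u_detect must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(rep(as.numeric(cfg$d_hat), length.out = 3) > 0)) {
    stop("d_hat entries must be <= 0", call. = FALSE)
  }
  if (length(cfg$e1) != cfg$n_maxwell || length(cfg$eta1) != cfg$n_maxwell) {
    stop("e1/eta1 length must equal n_maxwell", call. = FALSE)
  }
  cfg$rt_mode <- match.arg(cfg$rt_mode, c("rate", "instant"))
  cfg$cavity_policy <- match.arg(cfg$cavity_policy, c("permeable", "sealed"))
  cfg$stress_formulation <- match.arg(cfg$stress_formulation,
                                      c("boltzmann", "memoryless"))
  cfg$e1_normalization <- match.arg(cfg$e1_normalization, c("max", "trace"))
  cfg
}

#' Load a model configuration from YAML
#'
#' Reads a YAML file of overrides on top of [default_config()].  Unknown
#' keys are rejected (typo guard); an `alpha`, `beta`, `alpha/beta` triple
#' that disagrees is rejected; overridden values are reported via
#' `message()`.  An empty or missing-file-free call returns the pure
#' defaults.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param quiet Suppress the override messages.
#' @return A finalized `growth_config` list (derived fields `d_wm`,
#'   `e_inf`, `beta` filled in).
#' @export
load_config <- function(path = NULL, quiet = FALSE) {
  cfg <- unclass(default_config())
  if (!is.null(path)) {
    ov <- yaml::read_yaml(path)
    if (length(ov) > 0) {
      unknown <- setdiff(names(ov), names(cfg))
      if (length(unknown) > 0) {
        stop(sprintf("unknown config key(s): %s",
                     paste(unknown, collapse = ", ")), call. = FALSE)
      }
      for (nm in names(ov)) {
        if (!quiet) {
          message(sprintf("config override: %s = %s", nm,
                          paste(format(ov[[nm]]), collapse = ", ")))
        }
        cfg[[nm]] <- ov[[nm]]
      }
    }
  }
  structure(finalize_config(cfg), class = "growth_config")
}

# default_config() users who skip load_config still need derived fields
#' @export
print.growth_config <- function(x, ...) {
  x <- finalize_config(unclass(x))
  cat("<growth_config>\n")
  cat(sprintf("  d_gm = %g cm^2/day, d_wm = %g cm^2/day, rho = %g /day\n",
              x$d_gm, x$d_wm, x$rho))
  cat(sprintf("  LQ: alpha = %g /Gy, beta = %g /Gy^2 (alpha/beta = %g Gy)\n",
              x$alpha, x$beta, x$alpha_beta_ratio))
  cat(sprintf("  chemo k = %g /day; Maxwell n = %d (E1 = %g Pa, E_inf = %g Pa)\n",
              x$k_chemo, x$n_maxwell, x$e1[1], x$e_inf))
  cat(sprintf("  u_detect = %g, dt = %s, t_end = %d d\n",
              x$u_detect, paste(x$dt), x$t_end))
  invisible(x)
}

#' Write a labeled volume or density field as NIfTI
#'
#' @param x A [labeled_volume()] or [density_field()].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "labeled_volume")) {
    img <- RNifti::asNifti(x$labels)
    RNifti::pixdim(img) <- x$spacing
  } else if (inherits(x, "density_field")) {
    img <- RNifti::asNifti(x$u)
    RNifti::pixdim(img) <- x$spacing
  } else {
    stop("x must be a labeled_volume or density_field", call. = FALSE)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a labeled volume or density field from NIfTI
#'
#' Grid and voxel spacing come from the NIfTI header.  With
#' `kind = "auto"`, a volume whose values are all integers in the tissue
#' code set `0:4` is read as labels, anything else as a density field.
#' Label volumes are validated against the code contract and density
#' volumes against the `[0, 1]` range; violations raise an error naming
#' the offending voxels.
#'
#' @param path NIfTI file path.
#' @param kind `"auto"`, `"labels"` or `"density"`.
#' @return A [labeled_volume()] or [density_field()].
#' @export
read_volume <- function(path, kind = c("auto", "labels", "density")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume", call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (kind == "auto") {
    is_lbl <- all(arr == round(arr)) && all(arr >= 0) && all(arr <= 4)
    kind <- if (is_lbl) "labels" else "density"
  }
  if (kind == "labels") {
    if (any(arr != round(arr))) {
      stop("label volume contains non-integer values", call. = FALSE)
    }
    labeled_volume(array(as.integer(round(arr)), dim(arr)), spacing)
  } else {
    density_field(arr, spacing)
  }
}

#' Write a tensor field as a 6-component NIfTI
#'
#' Components are stored along the 4th dimension in the fixed order
#' xx, xy, xz, yy, yz, zz (symmetric upper triangle).
#'
#' @param tf A [tensor_field()].
#' @param path Output `.nii` path.
#' @return `path`, invisibly.
#' @export
write_tensor <- function(tf, path) {
  stopifnot(inherits(tf, "tensor_field"))
  img <- RNifti::asNifti(tf$comp)
  RNifti::pixdim(img) <- c(tf$spacing, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a tensor field from a 6-component NIfTI
#'
#' Symmetry is implied by the storage convention.  Voxels whose tensor is
#' not positive-semidefinite are repaired by clamping negative eigenvalues
#' to zero (the nearest admissible tensor); the number of repaired voxels
#' is reported in the `repaired` attribute and via `message()`.
#'
#' @param path NIfTI file path (4D, 6 components).
#' @return A [tensor_field()] with attribute `repaired`.
#' @export
read_tensor <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != 6L) {
    stop(sprintf("expected a 4D NIfTI with 6 tensor components, got dims [%s]",
                 paste(d, collapse = ", ")), call. = FALSE)
  }
  comp <- array(as.numeric(img), d)
  spacing <- RNifti::pixdim(img)[1:3]
  ok <- tensor_psd_mask(comp)
  bad <- which(!ok)
  if (length(bad) > 0) {
    nvox <- prod(d[1:3])
    for (b in bad) {
      m <- matrix(c(comp[b], comp[b + nvox], comp[b + 2 * nvox],
                    comp[b + nvox], comp[b + 3 * nvox], comp[b + 4 * nvox],
                    comp[b + 2 * nvox], comp[b + 4 * nvox], comp[b + 5 * nvox]),
                  3, 3)
      e <- eigen(m, symmetric = TRUE)
      mfix <- e$vectors %*% diag(pmax(e$values, 0)) %*% t(e$vectors)
      pk <- pack_tensor(mfix)
      for (ci in 1:6) comp[b + (ci - 1L) * nvox] <- pk[ci]
    }
    message(sprintf("read_tensor: repaired %d non-positive-semidefinite voxel(s)",
                    length(bad)))
  }
  out <- tensor_field(comp, spacing)
  attr(out, "repaired") <- length(bad)
  out
}

#' Serialize a therapy plan to JSON
#'
#' Radiotherapy plans are written as
#' `{"type": "radiotherapy", "fractions": [{"day": d, "dose": g}, ...],
#' "alpha": a, "beta": b}`; chemotherapy plans as
#' `{"type": "chemotherapy", "active_days": [...], "k": k}`.
#'
#' @param plan An [rt_plan()] or [chemo_plan()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  if (inherits(plan, "rt_plan")) {
    dose <- rep(plan$dose, length.out = length(plan$days))
    obj <- list(type = "radiotherapy",
                fractions = data.frame(day = plan$days, dose = dose),
                alpha = plan$alpha, beta = plan$beta)
  } else if (inherits(plan, "chemo_plan")) {
    obj <- list(type = "chemotherapy", active_days = plan$active_days,
                k = plan$k)
  } else {
    stop("not a therapy plan", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a therapy plan from JSON
#'
#' @param path JSON path produced by [write_plan()].
#' @return An [rt_plan()] or [chemo_plan()].
#' @export
read_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$type, "radiotherapy")) {
    dose <- obj$fractions$dose
    if (length(unique(dose)) == 1L) dose <- dose[1]
    rt_plan(days = obj$fractions$day, dose = dose, alpha = obj$alpha,
            beta = obj$beta, alpha_beta_ratio = obj$alpha / obj$beta)
  } else if (identical(obj$type, "chemotherapy")) {
    chemo_plan(active_days = obj$active_days, k = obj$k)
  } else {
    stop("unknown plan type in JSON", call. = FALSE)
  }
}

#' Write a run manifest
#'
#' Records the package version, creation time, MD5 checksums and sizes of
#' the listed files, for provenance of a command-line run.
#'
#' @param files Character vector of file paths to inventory.
#' @param path Output JSON path.
#' @param extra Optional named list merged into the manifest (e.g. timing).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(files, path, extra = list()) {
  files <- files[file.exists(files)]
  inv <- data.frame(
    path = files,
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files)),
    stringsAsFactors = FALSE
  )
  manifest <- c(list(
    tool = "gliomaRD",
    version = as.character(utils::packageVersion("gliomaRD")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    files = inv
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
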