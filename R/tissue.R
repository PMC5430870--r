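#' Tissue growth parameters
#'
#' Diffusion coefficients for gray and white matter and the proliferation
#' rate.  Inputs follow the conventional literature units of cm^2/day for
#' diffusivities; all internal computation is in mm^2/day (`* 100`) because
#' voxel spacing is in mm.
#'
#' @param d_gm Diffusion coefficient in GM, cm^2/day (default 0.0013).
#' @param d_wm Diffusion coefficient in WM, cm^2/day (default `5 * d_gm`).
#' @param rho Proliferation rate, 1/day (default 0.012).
#' @return Object of class `tissue_params` with the cm^2/day inputs plus
#'   derived `d_gm_mm2`, `d_wm_mm2`.
#' @export
tissue_params <- function(d_gm = 0.0013, d_wm = 5 * d_gm, rho = 0.012) {
  if (!(d_gm > 0) || d_wm < d_gm) {
    stop("need d_wm >= d_gm > 0", call. = FALSE)
  }
  if (!(rho > 0)) stop("proliferation rate rho must be > 0", call. = FALSE)
  structure(list(d_gm = d_gm, d_wm = d_wm, rho = rho,
                 d_gm_mm2 = 100 * d_gm, d_wm_mm2 = 100 * d_wm),
            class = "tissue_params")
}

# Deterministic symmetric 3x3 eigendecomposition: eigenvalues descending,
# ties broken by lexicographically decreasing eigenvectors, each
# eigenvector's first nonzero component made positive.
sorted_eigen3 <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  vec <- e$vectors
  for (i in 1:3) {
    nz <- which(abs(vec[, i]) > 1e-12)
    if (length(nz) > 0 && vec[nz[1], i] < 0) vec[, i] <- -vec[, i]
  }
  ord <- do.call(order, c(list(-e$values), lapply(1:3, function(r) -vec[r, ])))
  list(values = e$values[ord], vectors = vec[, ord, drop = FALSE])
}

#' Construct the tumor growth diffusion tensor from DTI
#'
#' In white matter the growth tensor is rebuilt in the DTI eigenbasis as
#' `E diag(e1 * D_WM, D_GM, D_GM) E^T`, with `E` the eigenvector matrix of
#' the local DTI tensor sorted by descending eigenvalue and `e1` the largest
#' eigenvalue normalized over the white-matter mask (so `e1` lies in
#' `(0, 1]`): diffusion is fastest along the fiber direction and falls back
#' to gray-matter diffusivity across it.  Gray matter gets the isotropic
#' `D_GM * I`; CSF, cavity and outside-brain voxels get the zero tensor, so
#' tumor cells cannot diffuse there.
#'
#' DTI voxels that fail the positive-semidefiniteness check are replaced by
#' the isotropic gray-matter tensor and counted in the `repaired` attribute
#' of the result.
#'
#' @param dti A unitless [tensor_field()] (e.g. [make_tensor_field()]).
#' @param vol The matching [labeled_volume()].
#' @param params A [tissue_params()].
#' @param normalization `"max"` (largest eigenvalue divided by the maximum
#'   over WM voxels, the default) or `"trace"` (divided by the local trace).
#' @return A [tensor_field()] in mm^2/day with attribute `repaired` (number
#'   of replaced DTI voxels).
#' @export
build_growth_tensor <- function(dti, vol, params = tissue_params(),
                                normalization = c("max", "trace")) {
  stopifnot(inherits(dti, "tensor_field"), inherits(vol, "labeled_volume"),
            inherits(params, "tissue_params"))
  normalization <- match.arg(normalization)
  if (!identical(dti$shape, vol$shape)) stop("shapes differ", call. = FALSE)
  d_gm <- params$d_gm_mm2
  d_wm <- params$d_wm_mm2
  comp <- array(0, c(vol$shape, 6L))
  nvox <- prod(vol$shape)
  gm <- which(gm_mask(vol))
  for (ci in c(1L, 4L, 6L)) comp[gm + (ci - 1L) * nvox] <- d_gm
  wm_idx <- which(wm_mask(vol))
  repaired <- 0L
  if (length(wm_idx) > 0) {
    ok <- tensor_psd_mask(dti$comp)[wm_idx]
    bad_idx <- wm_idx[!ok]
    repaired <- length(bad_idx)
    for (ci in c(1L, 4L, 6L)) comp[bad_idx + (ci - 1L) * nvox] <- d_gm
    good <- wm_idx[ok]
    if (length(good) > 0) {
      dc <- matrix(0, length(good), 6)
      for (ci in 1:6) dc[, ci] <- dti$comp[good + (ci - 1L) * nvox]
      eigs <- vector("list", length(good))
      lam1 <- numeric(length(good))
      for (i in seq_along(good)) {
        m <- matrix(c(dc[i, 1], dc[i, 2], dc[i, 3],
                      dc[i, 2], dc[i, 4], dc[i, 5],
                      dc[i, 3], dc[i, 5], dc[i, 6]), 3, 3)
        e <- sorted_eigen3(m)
        eigs[[i]] <- e
        lam1[i] <- e$values[1]
      }
      denom <- if (normalization == "max") {
        rep(max(lam1), length(good))
      } else {
        pmax(dc[, 1] + dc[, 4] + dc[, 6], .Machine$double.xmin)
      }
      if (all(denom <= 0)) {
        # degenerate DTI (all-zero in WM): treat WM isotropically
        for (ci in c(1L, 4L, 6L)) comp[good + (ci - 1L) * nvox] <- d_gm
      } else {
        e1 <- pmin(pmax(lam1 / denom, 0), 1)
        for (i in seq_along(good)) {
          ee <- eigs[[i]]
          d_here <- ee$vectors %*% diag(c(e1[i] * d_wm, d_gm, d_gm)) %*%
            t(ee$vectors)
          pk <- pack_tensor(d_here)
          for (ci in 1:6) comp[good[i] + (ci - 1L) * nvox] <- pk[ci]
        }
      }
    }
  }
  out <- tensor_field(comp, vol$spacing)
  attr(out, "repaired") <- repaired
  out
}

#' Scalar (DTI-free) diffusion map
#'
#' The tensor-free model variant: per-voxel scalar diffusivity `D_WM` in
#' white matter, `D_GM` in gray matter, 0 in CSF, cavity and outside brain.
#'
#' @param vol A [labeled_volume()].
#' @param params A [tissue_params()].
#' @return Numeric 3D array in mm^2/day.
#' @export
scalar_diffusion_map <- function(vol, params = tissue_params()) {
  stopifnot(inherits(vol, "labeled_volume"), inherits(params, "tissue_params"))
  d <- array(0, vol$shape)
  d[gm_mask(vol)] <- params$d_gm_mm2
  d[wm_mask(vol)] <- params$d_wm_mm2
  d
}

#' Local white-matter proportion
#'
#' Fraction of white-matter voxels among brain voxels inside a cubic window
#' of side `2 * window_radius + 1` centered at each voxel.  This is the
#' heterogeneity weight `omega` entering the chemotherapy loss.
#'
#' @param vol A [labeled_volume()].
#' @param window_radius Window half-width in voxels (>= 1, default 1, i.e. a
#'   3x3x3 window).
#' @return Object of class `wm_proportion_field` with `omega` (3D array in
#'   `[0,1]`) and `window_radius`.
#' @export
wm_proportion <- function(vol, window_radius = 1L) {
  stopifnot(inherits(vol, "labeled_volume"))
  r <- as.integer(window_radius)
  if (r < 1L) stop("window_radius must be >= 1", call. = FALSE)
  wm <- array(as.numeric(wm_mask(vol)), vol$shape)
  br <- array(as.numeric(brain_mask(vol)), vol$shape)
  wm_sum <- array(0, vol$shape)
  br_sum <- array(0, vol$shape)
  for (dx in -r:r) for (dy in -r:r) for (dz in -r:r) {
    wm_sum <- wm_sum + shift3(wm, dx, dy, dz)
    br_sum <- br_sum + shift3(br, dx, dy, dz)
  }
  omega <- array(0, vol$shape)
  pos <- br_sum > 0
  omega[pos] <- wm_sum[pos] / br_sum[pos]
  omega <- pmin(pmax(omega, 0), 1)
  structure(list(omega = omega, window_radius = r),
            class = "wm_proportion_field")
}
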