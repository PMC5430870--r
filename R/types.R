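#' Labeled tissue volume
#'
#' A voxel grid of integer tissue codes (see [tissue_codes()]) plus voxel
#' spacing in mm.  This is the anatomical scaffold every other object is
#' defined on.
#'
#' @param labels Integer 3D array of tissue codes in `0:4`.
#' @param spacing Numeric length-3 voxel size in mm, strictly positive.
#' @return An object of class `labeled_volume` with elements `labels`,
#'   `spacing`, `shape`.
#' @export
labeled_volume <- function(labels, spacing) {
  stopifnot_shape3(labels, "labels")
  spacing <- check_spacing(spacing)
  storage.mode(labels) <- "integer"
  bad <- !(labels %in% 0:4)
  if (any(bad)) {
    stop(sprintf("labels contain %d voxels outside the code set 0:4 (first at linear index %d)",
                 sum(bad), which(bad)[1]), call. = FALSE)
  }
  structure(list(labels = labels, spacing = spacing, shape = dim(labels)),
            class = "labeled_volume")
}

#' @export
print.labeled_volume <- function(x, ...) {
  cts <- table(factor(x$labels, levels = 0:4,
                      labels = names(tissue_codes())))
  cat("<labeled_volume> ", paste(x$shape, collapse = "x"),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  print(cts)
  invisible(x)
}

# Logical masks derived from a labeled volume.
brain_mask <- function(vol) vol$labels != LBL$OUTSIDE
wm_mask <- function(vol) vol$labels == LBL$WM
gm_mask <- function(vol) vol$labels == LBL$GM
csf_mask <- function(vol) vol$labels == LBL$CSF
cavity_mask <- function(vol) vol$labels == LBL$CAVITY
# Voxels tumor cells may occupy (CSF and outside are impermeable).
growth_mask <- function(vol) {
  vol$labels == LBL$WM | vol$labels == LBL$GM | vol$labels == LBL$CAVITY
}

#' Tumor cell density field
#'
#' Per-voxel tumor cell density as a fraction of carrying capacity,
#' `u` in `[0,1]`, zero outside the brain and in CSF.
#'
#' @param u Numeric 3D array in `[0,1]`.
#' @param spacing Numeric length-3 voxel size in mm.
#' @param time Time stamp in days from simulation start.
#' @return An object of class `density_field`.
#' @export
density_field <- function(u, spacing, time = 0) {
  stopifnot_shape3(u, "u")
  spacing <- check_spacing(spacing)
  if (any(!is.finite(u))) stop("density contains non-finite values", call. = FALSE)
  if (any(u < 0) || any(u > 1)) {
    bad <- which(u < 0 | u > 1)
    stop(sprintf("density outside [0,1] at %d voxels (first at linear index %d, value %g)",
                 length(bad), bad[1], u[bad[1]]), call. = FALSE)
  }
  structure(list(u = u, spacing = spacing, time = time), class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat("<density_field> ", paste(dim(x$u), collapse = "x"),
      " voxels, t = ", x$time, " d, max u = ", signif(max(x$u), 4),
      ", nonzero voxels = ", sum(x$u > 0), "\n", sep = "")
  invisible(x)
}

# Symmetric tensor component order used throughout (and on disk).
TENSOR_COMP <- c("xx", "xy", "xz", "yy", "yz", "zz")

#' Symmetric per-voxel tensor field
#'
#' Stores a symmetric positive-semidefinite 3x3 tensor per voxel as six
#' components in the fixed order xx, xy, xz, yy, yz, zz (4th array
#' dimension).  Used both for raw DTI-like input (unitless) and for the
#' growth tensor (mm^2/day).
#'
#' @param comp Numeric 4D array, last dimension 6.
#' @param spacing Numeric length-3 voxel size in mm.
#' @return An object of class `tensor_field`.
#' @export
tensor_field <- function(comp, spacing) {
  if (!(is.array(comp) && length(dim(comp)) == 4L && dim(comp)[4] == 6L)) {
    stop("tensor components must be a 4D array with 6 components (xx,xy,xz,yy,yz,zz)",
         call. = FALSE)
  }
  spacing <- check_spacing(spacing)
  structure(list(comp = comp, spacing = spacing, shape = dim(comp)[1:3]),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  tr <- x$comp[, , , 1] + x$comp[, , , 4] + x$comp[, , , 6]
  cat("<tensor_field> ", paste(x$shape, collapse = "x"),
      " voxels, nonzero voxels = ", sum(tr > 0),
      ", max trace = ", signif(max(tr), 4), "\n", sep = "")
  invisible(x)
}

# Extract the 3x3 matrix at one voxel.
tensor_at <- function(tf, i, j, k) {
  v <- tf$comp[i, j, k, ]
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

# Fill one voxel of a component array from a 3x3 symmetric matrix.
pack_tensor <- function(m) {
  c(m[1, 1], m[1, 2], m[1, 3], m[2, 2], m[2, 3], m[3, 3])
}

# Vectorised admissibility check for symmetric 3x3 tensors stored as
# components: positive semidefinite iff all leading principal minors of the
# symmetric matrix are >= 0 (Sylvester, with symmetry given by storage).
tensor_psd_mask <- function(comp, tol = 1e-10) {
  xx <- comp[, , , 1]; xy <- comp[, , , 2]; xz <- comp[, , , 3]
  yy <- comp[, , , 4]; yz <- comp[, , , 5]; zz <- comp[, , , 6]
  scale <- pmax(abs(xx) + abs(yy) + abs(zz), 1e-300)
  m1 <- xx
  m2 <- xx * yy - xy^2
  m3 <- xx * (yy * zz - yz^2) - xy * (xy * zz - yz * xz) +
    xz * (xy * yz - yy * xz)
  (m1 >= -tol * scale) & (m2 >= -tol * scale^2) & (m3 >= -tol * scale^3)
}
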