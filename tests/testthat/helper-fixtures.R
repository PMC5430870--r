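# Small programmatic fixtures shared across the suite.

# A box-shaped "brain": every interior voxel carries `label`, wrapped in an
# OUTSIDE shell of the given thickness (0 = fill the whole grid).
box_vol <- function(shape, spacing = c(1, 1, 1), label = "WM", shell = 1L) {
  codes <- gliomaRD::tissue_codes()
  lab <- array(codes[[label]], shape)
  if (shell > 0L) {
    full <- array(codes[["OUTSIDE"]], shape)
    idx <- lapply(shape, function(n) {
      if (n > 2L * shell) (shell + 1L):(n - shell) else integer(0)
    })
    if (all(lengths(idx) > 0)) {
      full[idx[[1]], idx[[2]], idx[[3]]] <- codes[[label]]
    }
    lab <- full
  }
  gliomaRD::labeled_volume(lab, spacing)
}

# A 1D line domain of n voxels (shape n x 1 x 1), all WM.
line_vol <- function(n, h = 1) box_vol(c(n, 1L, 1L), c(h, 1, 1), shell = 0L)

# Single-voxel WM domain for 0D (diffusion-free) integration.
point_vol <- function() box_vol(c(1L, 1L, 1L), c(1, 1, 1), shell = 0L)

# Number of 6-connected components of a logical 3D mask (vectorised
# frontier dilation — independent of any package labelling code).
n_components <- function(mask) {
  mask <- array(mask, dim(mask))
  remaining <- mask
  ncomp <- 0L
  dilate <- function(m) {
    d <- m
    d <- d | gliomaRD:::shift3(m, 1, 0, 0) > 0 | gliomaRD:::shift3(m, -1, 0, 0) > 0
    d <- d | gliomaRD:::shift3(m, 0, 1, 0) > 0 | gliomaRD:::shift3(m, 0, -1, 0) > 0
    d <- d | gliomaRD:::shift3(m, 0, 0, 1) > 0 | gliomaRD:::shift3(m, 0, 0, -1) > 0
    d
  }
  while (any(remaining)) {
    ncomp <- ncomp + 1L
    seedidx <- which(remaining)[1]
    comp <- array(FALSE, dim(mask))
    comp[seedidx] <- TRUE
    repeat {
      grown <- dilate(array(as.numeric(comp), dim(mask))) & remaining
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    remaining <- remaining & !comp
  }
  ncomp
}

# A compact anisotropic test scenario used by several suites: ellipsoidal
# brain, one oblique fiber bundle, cavity next to the tumor seed.
small_scenario_inputs <- function(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                                  with_cavity = TRUE) {
  extent <- (shape - 1) * spacing
  ctr <- extent / 2
  spec <- gliomaRD::phantom_spec(
    shape = shape, spacing = spacing,
    fibers = list(list(points = rbind(ctr - c(14, 8, 0), ctr + c(14, 8, 0)),
                       radius = 5, anisotropy = 5)),
    cavity = if (with_cavity) list(center = ctr + c(8, 0, 0), radius = 4.5)
             else NULL
  )
  vol <- gliomaRD::make_brain_phantom(spec)
  dti <- gliomaRD::make_tensor_field(vol, spec)
  init <- gliomaRD::seed_tumor(vol, ctr - c(6, 0, 0), radius = 3.5)
  list(spec = spec, vol = vol, dti = dti, init = init)
}
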