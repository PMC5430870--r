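# Internal 3D array helpers shared by the stencils and the phantom.

# Shift a 3D array by integer offsets (s1, s2, s3), zero-filling: the result
# at index x holds a[x + s].  Out-of-range reads give 0, which together with
# zero diffusivity outside the brain realises the no-flux closure.
shift3 <- function(a, s1, s2, s3) {
  d <- dim(a)
  out <- array(0, d)
  lo <- pmax(1L, 1L + c(s1, s2, s3))
  hi <- pmin(d, d + c(s1, s2, s3))
  if (any(lo > hi)) {
    return(out)
  }
  out[(lo[1] - s1):(hi[1] - s1), (lo[2] - s2):(hi[2] - s2),
      (lo[3] - s3):(hi[3] - s3)] <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  out
}

# Harmonic mean of two non-negative coefficient arrays; exactly zero when
# either side is zero, so faces into CSF/outside/cavity-with-zero-D carry no
# flux and total mass telescopes exactly.
harmonic_face <- function(a, b) {
  s <- a + b
  out <- array(0, dim(a))
  pos <- s > 0
  out[pos] <- 2 * a[pos] * b[pos] / s[pos]
  out
}

# Voxel-center world coordinates (mm) along each axis, 0-based convention:
# world = index * spacing.
axis_coords <- function(shape, spacing) {
  lapply(1:3, function(i) (seq_len(shape[i]) - 1) * spacing[i])
}

# Expanded coordinate grids as 3D arrays (mm).
coord_grids <- function(shape, spacing) {
  cc <- axis_coords(shape, spacing)
  list(
    x = array(rep(cc[[1]], times = shape[2] * shape[3]), shape),
    y = array(rep(rep(cc[[2]], each = shape[1]), times = shape[3]), shape),
    z = array(rep(cc[[3]], each = shape[1] * shape[2]), shape)
  )
}

stopifnot_shape3 <- function(x, what = "volume") {
  if (!(is.array(x) && length(dim(x)) == 3L)) {
    stop(sprintf("%s must be a 3D array", what), call. = FALSE)
  }
}

check_spacing <- function(spacing) {
  if (!(is.numeric(spacing) && length(spacing) == 3L && all(spacing > 0))) {
    stop("spacing must be 3 strictly positive voxel sizes in mm", call. = FALSE)
  }
  as.numeric(spacing)
}
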