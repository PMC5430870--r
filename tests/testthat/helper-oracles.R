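# Independent oracles the implementation is checked against.

# Closed-form logistic growth u(t) for du/dt = rho u (1 - u).
logistic_exact <- function(u0, rho, t) {
  u0 * exp(rho * t) / (1 - u0 + u0 * exp(rho * t))
}

# Independently coded plain reaction-diffusion reference solver: assembles
# the 7-point variable-coefficient operator as an explicit sparse matrix
# (harmonic face means, no-flux closure) and steps
# u <- u + dt (L u + rho u (1 - u)).  Shares no code with the package
# stencil.
ref_build_L <- function(D, spacing) {
  d <- dim(D)
  n <- prod(d)
  lin <- function(i, j, k) (k - 1L) * d[1] * d[2] + (j - 1L) * d[1] + i
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  diag_acc <- numeric(n)
  for (ax in 1:3) {
    e <- c(0L, 0L, 0L); e[ax] <- 1L
    h2 <- spacing[ax]^2
    for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
      i2 <- i + e[1]; j2 <- j + e[2]; k2 <- k + e[3]
      if (i2 > d[1] || j2 > d[2] || k2 > d[3]) next
      da <- D[i, j, k]; db <- D[i2, j2, k2]
      if (da + db <= 0) next
      w <- 2 * da * db / (da + db) / h2
      if (w == 0) next
      a <- lin(i, j, k); b <- lin(i2, j2, k2)
      ii <- c(ii, a, b); jj <- c(jj, b, a); xx <- c(xx, w, w)
      diag_acc[a] <- diag_acc[a] - w
      diag_acc[b] <- diag_acc[b] - w
    }
  }
  nzd <- which(diag_acc != 0)
  Matrix::sparseMatrix(i = c(ii, nzd), j = c(jj, nzd), x = c(xx, diag_acc[nzd]),
                       dims = c(n, n))
}

ref_rd_run <- function(u0, D, spacing, rho, dt, nsteps, grow) {
  L <- ref_build_L(D, spacing)
  u <- as.numeric(u0)
  g <- as.numeric(grow)
  out <- vector("list", nsteps)
  for (s in seq_len(nsteps)) {
    u <- u + dt * (as.numeric(L %*% u) + rho * u * (1 - u) * g)
    u <- pmin(pmax(u, 0), 1) * g
    out[[s]] <- array(u, dim(u0))
  }
  out
}

# Direct trapezoid quadrature of the Boltzmann hereditary integral:
# sigma(t_N) = sum(E) eps(t_N) + int_0^{t_N} K(t_N - s) eps(s) ds,
# K(x) = sum_k (E_k / tau_k) exp(-x / tau_k), on the step grid.
stress_trapezoid <- function(model, times, eps) {
  n <- length(times)
  tn <- times[n]
  kern <- function(x) {
    out <- 0
    for (k in seq_len(model$n)) {
      out <- out + model$E[k] / model$tau[k] * exp(-x / model$tau[k])
    }
    out
  }
  kv <- kern(tn - times)
  integrand <- kv * eps
  integral <- sum(diff(times) * (integrand[-1] + integrand[-n]) / 2)
  sum(model$E) * eps[n] + integral
}

# Brute-force count of lattice points within radius r (mm) of a center, on
# a grid with given spacing — oracle for seed_tumor ball volumes.
discrete_ball_count <- function(shape, spacing, center, r) {
  cnt <- 0L
  for (k in seq_len(shape[3])) for (j in seq_len(shape[2])) for (i in seq_len(shape[1])) {
    x <- c(i - 1, j - 1, k - 1) * spacing
    if (sum((x - center)^2) <= r^2) cnt <- cnt + 1L
  }
  cnt
}
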