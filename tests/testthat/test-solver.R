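make_cfg <- function(...) {
  cfg <- default_config()
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg
}

test_that("stable_dt implements the explicit-diffusion bound", {
  # zero diffusivity falls back to the output cadence
  expect_equal(stable_dt(array(0, c(4, 4, 4)), c(1, 1, 1), cadence = 2), 2)

  # isotropic D on a cubic grid: dt = 0.9 h^2 / (6 D)
  D <- 0.65; h <- 2
  expect_equal(stable_dt(array(D, c(4, 4, 4)), c(h, h, h)),
               0.9 * h^2 / (6 * D))
  # doubling all spacings quadruples the bound
  expect_equal(stable_dt(array(D, c(4, 4, 4)), c(2 * h, 2 * h, 2 * h)),
               4 * 0.9 * h^2 / (6 * D))

  # tensor input uses the largest eigenvalue
  comp <- array(0, c(2, 2, 2, 6))
  comp[, , , 1] <- 0.9; comp[, , , 4] <- 0.1; comp[, , , 6] <- 0.1
  expect_equal(stable_dt(tensor_field(comp, c(1, 1, 1))),
               0.9 / (2 * 0.9 * 3))
})

test_that("the diffusion stencil is consistent on polynomial profiles", {
  n <- 8
  h <- 1.5
  # constant u -> exactly zero
  u <- array(3.3, c(n, n, n))
  D <- array(0.4, c(n, n, n))
  expect_true(all(weickert_divergence(u, D, c(h, h, h)) == 0))

  # 1D quadratic u = x^2 with uniform scalar D: interior value 2D
  x <- (0:(n - 1)) * h
  u1 <- array(rep(x^2, n * n), c(n, n, n))
  out <- weickert_divergence(u1, D, c(h, h, h))
  expect_equal(out[2:(n - 1), 4, 4], rep(2 * 0.4, n - 2), tolerance = 1e-12)

  # cross profile u = x*y with constant full tensor: interior value 2 Dxy
  grids <- gliomaRD:::coord_grids(c(n, n, n), c(h, h, h))
  uxy <- grids$x * grids$y
  m <- matrix(c(0.5, 0.2, 0, 0.2, 0.5, 0, 0, 0, 0.5), 3, 3)
  comp <- array(0, c(n, n, n, 6))
  for (ci in 1:6) comp[, , , ci] <- gliomaRD:::pack_tensor(m)[ci]
  tf <- tensor_field(comp, c(h, h, h))
  outxy <- weickert_divergence(uxy, tf)
  expect_equal(outxy[3:(n - 2), 3:(n - 2), 4],
               array(2 * 0.2, c(n - 4, n - 4)), tolerance = 1e-12)
  # and with a negative off-diagonal (exercises the other diagonal branch)
  comp2 <- comp; comp2[, , , 2] <- -0.2
  outneg <- weickert_divergence(uxy, tensor_field(comp2, c(h, h, h)))
  expect_equal(outneg[3:(n - 2), 3:(n - 2), 4],
               array(-2 * 0.2, c(n - 4, n - 4)), tolerance = 1e-12)
})

test_that("a 90-degree grid rotation permutes the stencil output identically", {
  set.seed(42)
  n <- 12
  # random admissible tensor field: R diag(l) R^T per voxel
  comp <- array(0, c(n, n, n, 6))
  nv <- n^3
  for (v in seq_len(nv)) {
    A <- matrix(rnorm(9), 3, 3)
    qr_ <- qr.Q(qr(A))
    lam <- diag(runif(3, 0.1, 1))
    M <- qr_ %*% lam %*% t(qr_)
    pk <- gliomaRD:::pack_tensor(M)
    for (ci in 1:6) comp[v + (ci - 1) * nv] <- pk[ci]
  }
  u <- array(runif(nv), c(n, n, n))
  sp <- c(1.2, 0.8, 1.0)
  out <- weickert_divergence(u, tensor_field(comp, sp))

  # swap axes 1 and 2: u' = aperm(u), D' components remapped accordingly
  perm <- c(2, 1, 3)
  up <- aperm(u, perm)
  compp <- array(0, c(n, n, n, 6))
  remap <- c(4, 2, 5, 1, 3, 6)  # xx<->yy, xz<->yz under x<->y
  for (ci in 1:6) compp[, , , ci] <- aperm(comp[, , , remap[ci]], perm)
  outp <- weickert_divergence(up, tensor_field(compp, sp[perm]))
  expect_equal(outp, aperm(out, perm), tolerance = 1e-12)
})

test_that("tensor and scalar paths agree exactly for isotropic diffusion", {
  vol <- box_vol(c(10, 10, 10), spacing = c(1.5, 1.5, 2))
  d <- scalar_diffusion_map(vol, tissue_params())
  comp <- array(0, c(vol$shape, 6))
  for (ci in c(1, 4, 6)) comp[, , , ci] <- d
  tf <- tensor_field(comp, vol$spacing)
  set.seed(1)
  u <- array(runif(1000), vol$shape) * (vol$labels == tissue_codes()[["WM"]])
  expect_identical(weickert_divergence(u, d, vol$spacing),
                   weickert_divergence(u, tf))
})

test_that("single steps preserve the trivial fixed points and the logistic law", {
  vol <- point_vol()
  d0 <- array(0, c(1, 1, 1))
  # u = 0 and u = 1 are fixed points without therapy
  expect_equal(growth_step(array(0, c(1, 1, 1)), 0.5, d0, vol), array(0, c(1, 1, 1)))
  expect_equal(growth_step(array(1, c(1, 1, 1)), 0.5, d0, vol), array(1, c(1, 1, 1)))

  # diffusion-free logistic trajectory matches the closed form
  cfg <- make_cfg(dt = 0.1, rho = 0.012, use_rt = FALSE, use_chemo = FALSE,
                  use_viscoelastic = FALSE)
  init <- density_field(array(0.1, c(1, 1, 1)), c(1, 1, 1))
  res <- simulate_growth(init, vol, d0, config = cfg, days = 50, save_every = 50)
  expect_lt(abs(as.numeric(res$final$u) - logistic_exact(0.1, 0.012, 50)),
            1e-4)
})

test_that("simulation conserves mass under pure no-flux diffusion", {
  spec <- phantom_spec(shape = c(20, 20, 20), spacing = c(2, 2, 2))
  vol <- make_brain_phantom(spec)
  dti <- make_tensor_field(vol, spec)
  D <- build_growth_tensor(dti, vol)
  ctr <- (vol$shape - 1) * vol$spacing / 2
  init <- seed_tumor(vol, ctr - c(6, 0, 0), radius = 4)
  cfg <- make_cfg(rho = 0, use_rt = FALSE, use_chemo = FALSE,
                  use_viscoelastic = FALSE)
  res <- simulate_growth(init, vol, D, config = cfg, days = 20, save_every = 20)
  mass <- res$log$mass
  expect_gt(nrow(res$log), 20)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-10)
  # CSF and outside stay identically zero
  blocked <- vol$labels == tissue_codes()[["CSF"]] |
    vol$labels == tissue_codes()[["OUTSIDE"]]
  for (f in res$fields) expect_true(all(f$u[blocked] == 0))
})

test_that("a zero-day simulation returns only the initial state", {
  vol <- box_vol(c(6, 6, 6))
  init <- seed_tumor(vol, c(2, 2, 2), radius = 0)
  res <- simulate_growth(init, vol, scalar_diffusion_map(vol, tissue_params()),
                         config = make_cfg(use_viscoelastic = FALSE), days = 0)
  expect_equal(res$times, 0)
  expect_length(res$fields, 1)
  expect_identical(res$final$u, init$u)
  expect_equal(nrow(res$log), 0)
})

test_that("solver output matches the independent plain-RD reference", {
  vol <- box_vol(c(10, 10, 10), spacing = c(1.5, 1.5, 1.5))
  lab <- vol$labels
  lab[3:5, 3:5, 3:5] <- tissue_codes()[["GM"]]     # heterogeneous D(x)
  vol <- labeled_volume(lab, vol$spacing)
  params <- tissue_params()
  d <- scalar_diffusion_map(vol, params)
  init <- seed_tumor(vol, c(6, 6, 6), radius = 2.2)
  cfg <- make_cfg(use_rt = FALSE, use_chemo = FALSE, use_viscoelastic = FALSE,
                  dt = 1 / 4)
  res <- simulate_growth(init, vol, d, config = cfg, days = 5, save_every = 1)

  ref <- ref_rd_run(init$u, d, vol$spacing, params$rho, dt = 1 / 4,
                    nsteps = 20, grow = gliomaRD:::growth_mask(vol))
  for (day in 1:5) {
    mine <- res$fields[[day + 1]]$u
    expect_lt(max(abs(mine - ref[[day * 4]])), 1e-12)
  }
})

test_that("therapy monotonically suppresses growth", {
  inp <- small_scenario_inputs(shape = c(20, 20, 20))
  D <- build_growth_tensor(inp$dti, inp$vol)
  rt <- make_therapy_calendar("radiotherapy", start_day = 0)
  ch <- make_therapy_calendar("chemotherapy", start_day = 0)
  cfg <- make_cfg(use_viscoelastic = FALSE)
  treated <- suppressWarnings(
    simulate_growth(inp$init, inp$vol, D, rt_plan = rt, chemo_plan = ch,
                    config = cfg, days = 30, save_every = 10))
  untreated <- simulate_growth(inp$init, inp$vol, D, config = cfg,
                               days = 30, save_every = 10)
  for (i in seq_along(treated$fields)) {
    expect_true(all(treated$fields[[i]]$u <= untreated$fields[[i]]$u + 1e-12))
  }
  expect_lt(sum(treated$final$u), sum(untreated$final$u))
})

test_that("density masks nest with the threshold and come from the final field", {
  set.seed(3)
  u <- array(runif(64), c(4, 4, 4))
  expect_true(all(extract_mask(u, 0.5) <= extract_mask(u, 0.3)))
  expect_equal(sum(extract_mask(array(0.39, c(3, 3, 3)), 0.4)), 0)
  expect_error(extract_mask(u, 0), "between 0 and 1")
  expect_error(extract_mask(u, 1), "between 0 and 1")
})

test_that("disabling the viscoelastic pathway reproduces the plain run bit-for-bit", {
  inp <- small_scenario_inputs(shape = c(14, 14, 14), with_cavity = FALSE)
  D <- build_growth_tensor(inp$dti, inp$vol)
  base <- simulate_growth(inp$init, inp$vol, D,
                          config = make_cfg(use_viscoelastic = FALSE),
                          days = 10, save_every = 10)
  off_kappa <- simulate_growth(inp$init, inp$vol, D,
                               config = make_cfg(kappa = 0), days = 10,
                               save_every = 10)
  off_dhat <- simulate_growth(inp$init, inp$vol, D,
                              config = make_cfg(d_hat = 0), days = 10,
                              save_every = 10)
  expect_identical(base$final$u, off_kappa$final$u)
  expect_identical(base$final$u, off_dhat$final$u)

  # the full hereditary pathway runs and stays stable (effect is tiny by
  # the literature parameter magnitudes)
  on <- simulate_growth(inp$init, inp$vol, D, config = make_cfg(),
                        days = 10, save_every = 10)
  expect_equal(on$final$u, base$final$u, tolerance = 1e-8)
  expect_equal(sum(on$log$clipped), 0)
})
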