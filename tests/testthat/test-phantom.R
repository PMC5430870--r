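test_that("phantom label field partitions the grid and respects geometry flags", {
  # degenerate geometry: no ventricles, no cavity -> brain is GM + WM only
  spec0 <- phantom_spec(shape = c(20, 20, 20), spacing = c(2, 2, 2),
                        ventricles = list(), cavity = NULL)
  vol0 <- make_brain_phantom(spec0)
  labs <- sort(unique(as.vector(vol0$labels)))
  expect_setequal(labs, c(tissue_codes()[["OUTSIDE"]], tissue_codes()[["GM"]],
                          tissue_codes()[["WM"]]))

  # cavity radius 0 -> no cavity voxels
  ctr <- (c(20, 20, 20) - 1) * 2 / 2
  spec_r0 <- phantom_spec(shape = c(20, 20, 20), spacing = c(2, 2, 2),
                          cavity = list(center = ctr, radius = 0))
  vol_r0 <- make_brain_phantom(spec_r0)
  expect_equal(sum(vol_r0$labels == tissue_codes()[["CAVITY"]]), 0)

  # label counts partition the voxel total
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                       cavity = list(center = ctr, radius = 5))
  vol <- make_brain_phantom(spec)
  expect_equal(sum(table(vol$labels)), prod(vol$shape))
  expect_gt(sum(vol$labels == tissue_codes()[["CSF"]]), 0)
  expect_gt(sum(vol$labels == tissue_codes()[["CAVITY"]]), 0)

  # geometry exceeding the grid is an invalid spec
  expect_error(phantom_spec(shape = c(16, 16, 16), spacing = c(1, 1, 1),
                            brain_radii = c(20, 20, 20)),
               "exceeds the grid")
  expect_error(phantom_spec(shape = c(16, 16, 16), spacing = c(1, 1, 1),
                            cavity = list(center = c(14, 8, 8), radius = 5)),
               "exceeds the grid")
})

test_that("phantom generation is deterministic and brain voxels are connected", {
  a <- make_brain_phantom(random_phantom_spec(shape = c(20, 20, 20), seed = 7))
  b <- make_brain_phantom(random_phantom_spec(shape = c(20, 20, 20), seed = 7))
  expect_identical(a$labels, b$labels)
  expect_identical(table(a$labels), table(b$labels))

  expect_equal(n_components(a$labels != tissue_codes()[["OUTSIDE"]]), 1L)
})

test_that("phantom tensors are admissible and fiber-aligned", {
  # center-line through exact voxel centers (y = z = 22 mm, index 12)
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(2, 2, 2),
                       fibers = list(list(points = rbind(c(6, 22, 22),
                                                         c(40, 22, 22)),
                                          radius = 4, anisotropy = 5)))
  vol <- make_brain_phantom(spec)
  tf <- make_tensor_field(vol, spec)

  # GM isotropic, CSF/outside/cavity zero
  gm <- which(vol$labels == tissue_codes()[["GM"]])[1]
  ijk <- arrayInd(gm, vol$shape)
  m_gm <- gliomaRD:::tensor_at(tf, ijk[1], ijk[2], ijk[3])
  expect_equal(m_gm, diag(rep(1 / 3, 3)))
  csf <- which(vol$labels == tissue_codes()[["CSF"]])[1]
  ijk <- arrayInd(csf, vol$shape)
  expect_equal(gliomaRD:::tensor_at(tf, ijk[1], ijk[2], ijk[3]),
               matrix(0, 3, 3))

  # a WM voxel on the bundle axis: principal eigenvector (+-1,0,0),
  # eigenvalue ratio 5:1:1
  on_axis <- round(c(22, 22, 22) / vol$spacing) + 1
  expect_equal(vol$labels[on_axis[1], on_axis[2], on_axis[3]],
               tissue_codes()[["WM"]])
  m <- gliomaRD:::tensor_at(tf, on_axis[1], on_axis[2], on_axis[3])
  e <- eigen(m, symmetric = TRUE)
  expect_equal(abs(e$vectors[, 1]), c(1, 0, 0), tolerance = 1e-10)
  expect_equal(e$values[1] / e$values[2], 5, tolerance = 1e-10)
  expect_equal(e$values[2], e$values[3], tolerance = 1e-12)

  # property: symmetric PSD everywhere on randomized phantoms
  for (seed in 1:3) {
    rs <- random_phantom_spec(shape = c(14, 14, 14), seed = seed)
    rv <- make_brain_phantom(rs)
    rt <- make_tensor_field(rv, rs)
    expect_true(all(gliomaRD:::tensor_psd_mask(rt$comp)))
    expect_identical(rt$comp, make_tensor_field(rv, rs)$comp)  # determinism
  }
})

test_that("tumor seeding respects tissue permeability and ball geometry", {
  vol <- box_vol(c(13, 13, 13), spacing = c(1, 1, 1), shell = 1L)

  # radius 0 -> exactly one voxel at density 1
  f0 <- seed_tumor(vol, c(6, 6, 6), radius = 0)
  expect_equal(sum(f0$u > 0), 1)
  expect_equal(max(f0$u), 1)

  # nonzero-voxel count equals the discrete ball volume (oracle)
  f3 <- seed_tumor(vol, c(6, 6, 6), radius = 3)
  expect_equal(sum(f3$u == 1),
               discrete_ball_count(vol$shape, vol$spacing, c(6, 6, 6), 3))
  expect_setequal(unique(as.vector(f3$u)), c(0, 1))

  # seed fully inside CSF -> all-zero with a warning
  lab <- vol$labels
  lab[5:9, 5:9, 5:9] <- tissue_codes()[["CSF"]]
  vol_csf <- labeled_volume(lab, vol$spacing)
  expect_warning(fz <- seed_tumor(vol_csf, c(6, 6, 6), radius = 1),
                 "all zero")
  expect_equal(sum(fz$u), 0)

  # center outside the brain is an error
  expect_error(seed_tumor(vol, c(0, 0, 0), radius = 1), "outside the brain")
})

test_that("therapy calendars follow the standard fractionation and cycling", {
  rt <- make_therapy_calendar("radiotherapy", start_day = 0)
  expect_length(rt$days, 30)
  expect_identical(rt$days, 0:29)                   # 30 consecutive daily fractions
  expect_equal(sum(rep(rt$dose, length(rt$days))), 60)  # 60 Gy total
  expect_equal(rt$beta, rt$alpha / 10)

  ch <- make_therapy_calendar("chemotherapy", start_day = 0)
  expect_length(ch$active_days, 30)                 # 6 cycles x 5 days
  # active days span 5 + 5*28 = 145 calendar days
  expect_equal(max(ch$active_days) - min(ch$active_days) + 1L, 145L)
  expect_true(all(is_active(ch, 0:4)))
  expect_false(is_active(ch, 7))                    # between cycles: inactive
  expect_false(is_active(ch, 200))                  # after the last cycle

  expect_error(make_therapy_calendar("surgery"))
})
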