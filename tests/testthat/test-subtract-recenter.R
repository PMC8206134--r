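test_that("model_to_density is linear, symmetric and mass-preserving", {
  one <- data.frame(x = 0, y = 0, z = 0, sd = 6, w = 1)
  v1 <- model_to_density(one, 4, 32, lowpass = NULL)
  ## radial symmetry: max at the centre, monotone decay along axes
  c0 <- 32 %/% 2 + 1
  expect_equal(which(v1$data == max(v1$data), arr.ind = TRUE)[1, ],
               c(dim1 = c0, dim2 = c0, dim3 = c0))
  prof <- v1$data[c0:(c0 + 6), c0, c0]
  expect_true(all(diff(prof) < 0))
  expect_equal(v1$data[c0 + 3, c0, c0], v1$data[c0, c0 + 3, c0])
  ## superposition
  two <- data.frame(x = c(-20, 20), y = 0, z = 0, sd = 6, w = 1)
  v2 <- model_to_density(two, 4, 32, lowpass = NULL)
  va <- model_to_density(two[1, ], 4, 32, lowpass = NULL)
  vb <- model_to_density(two[2, ], 4, 32, lowpass = NULL)
  expect_lt(max(abs(v2$data - va$data - vb$data)), 1e-9)
  ## mass invariant under low-pass filtering (DC conservation)
  vf <- model_to_density(one, 4, 32, lowpass = 30)
  expect_equal(sum(vf$data), sum(v1$data), tolerance = 1e-3)
  ## atoms outside the box error out
  expect_error(model_to_density(data.frame(x = 500, y = 0, z = 0), 4, 32),
               "outside")
})

test_that("soft masks binarize, dilate and roll off as specified", {
  one <- data.frame(x = 0, y = 0, z = 0, sd = 8, w = 1)
  vol <- model_to_density(one, 4, 32, lowpass = NULL)
  ## degenerate case equals a thresholding oracle
  m0 <- make_soft_mask(vol, 0.3, 0, 0)
  expect_identical(m0$data, (vol$data >= 0.3) + 0)
  expect_true(all(m0$data %in% c(0, 1)))
  ## support monotone non-decreasing in extend_px
  supports <- sapply(0:3, function(e)
    sum(make_soft_mask(vol, 0.3, e, 0)$data > 0))
  expect_true(all(diff(supports) >= 0))
  m2sup <- make_soft_mask(vol, 0.3, 2, 0)$data > 0
  expect_true(all(m2sup[m0$data > 0]))
  ## cosine edge: profile along +x crosses 0.5 at half the edge width
  m <- make_soft_mask(vol, 0.3, 0, 6)
  expect_true(all(m$data >= 0 & m$data <= 1))
  c0 <- 32 %/% 2 + 1
  prof <- m$data[c0:32, c0, c0]
  edge <- which(prof < 1)[1]
  half <- which(prof < 0.5)[1]
  expect_lte(abs((half - edge) - 3), 1)  # half-width 3 px, +/- 1 px
  expect_true(all(diff(prof[prof < 1 & prof > 0]) <= 1e-9))  # monotone edge
  ## z-window restricts the axial extent
  mz <- make_soft_mask(vol, 0.3, 4, 0, z_fraction = 0.25)
  zmass <- apply(mz$data, 3, sum)
  zc <- (seq_len(32) - 1 - 16) / 16  # fraction of half-box
  expect_true(all(zmass[abs(zc) > 0.25] == 0))
  ## centre of mass of a centred blob is the origin
  expect_equal(m0$center_of_mass, c(0, 0, 0), tolerance = 1e-6)
})

test_that("subtraction removes exactly the signal outside the mask", {
  sim <- small_sim()
  ctf <- NULL
  scn <- scene_volume(sim$spec, sim$sym, "open")
  n <- sim$spec$box; apix <- sim$spec$voxel_size
  ## mask identically 1: nothing subtracted
  ones <- make_soft_mask(volume_grid(array(1, dim(scn$data)), apix), 1, 0, 0)
  out1 <- subtract_outside_mask(sim$stack, sim$records, scn, ones, scale = 1)
  expect_equal(out1$stack$data, sim$stack$data, tolerance = 1e-10)
  ## mask identically 0 on matching data: near-total self-subtraction
  zeros <- ones; zeros$data <- array(0, dim(scn$data))
  out0 <- subtract_outside_mask(sim$stack, sim$records, scn, zeros, scale = 1)
  ## residual concentrated at box edges; compare over the interior
  ctr <- 11:54
  r <- out0$stack$data[ctr, ctr, ]; i0 <- sim$stack$data[ctr, ctr, ]
  expect_lt(sqrt(mean(r^2) / mean(i0^2)), 0.1)
  ## masked retention: residual correlates with the masked-scene projection
  mm <- mask_models(sim$spec, sim$sym, "monomer")
  dk <- model_to_density(mm$kinesin, apix, n, 30)
  mk <- make_soft_mask(dk, 0.05 * max(dk$data), 1, 2)
  outk <- subtract_outside_mask(sim$stack, sim$records, scn, mk, scale = 1)
  masked_scene <- volume_grid(scn$data * mk$data, apix)
  pm <- project_volume(masked_scene, sim$records, as_matrix = TRUE)
  ## compare within the mask footprint, where the retained signal lives
  mproj <- project_volume(volume_grid(mk$data, apix), sim$records,
                          as_matrix = TRUE)
  mproj <- pmin(pmax(mproj / max(mproj), 0), 1)
  expect_gt(cor(as.numeric(hasrc:::stack_as_matrix(outk$stack) * mproj),
                as.numeric(pm * mproj)), 0.95)
  ## subtraction is linear in the reference
  half_ref <- volume_grid(scn$data / 2, apix)
  outh <- subtract_outside_mask(sim$stack, sim$records, half_ref, mk, scale = 1)
  lhs <- sim$stack$data - outk$stack$data          # subtracted component
  rhs <- 2 * (sim$stack$data - outh$stack$data)
  expect_equal(lhs, rhs, tolerance = 1e-8)
  ## grid mismatch errors
  small_ref <- volume_grid(scn$data[1:32, 1:32, 1:32], apix)
  expect_error(subtract_outside_mask(sim$stack, sim$records, small_ref, mk),
               "grid")
})

test_that("re-centering is exact, pose-consistent and idempotent", {
  sim <- small_sim()
  apix <- sim$spec$voxel_size
  ## C_M at origin with zero shifts: nothing changes
  rec0 <- sim$records; rec0$sx <- 0; rec0$sy <- 0
  rc <- recenter(sim$stack, rec0, c(0, 0, 0))
  expect_equal(rc$stack$data, sim$stack$data, tolerance = 1e-12)
  expect_equal(rc$records$sx, rec0$sx)
  ## integer-pixel displacement: exact circular shift
  one <- matrix(0, 16, 16); one[5, 9] <- 1
  st1 <- image_stack(array(one, c(16, 16, 1)), 4)
  r1 <- particle_records(1); r1$tilt <- 0
  out <- recenter(st1, r1, c(2 * 4, -3 * 4, 0))  # centre on (+2, -3) px
  shifted <- matrix(0, 16, 16); shifted[5 - 2, 9 + 3] <- 1
  expect_identical(out$stack$data[, , 1], shifted)
  ## sub-pixel shift matches a direct Fourier-shift oracle
  set.seed(6)
  img <- matrix(rnorm(256), 16, 16)
  st2 <- image_stack(array(img, c(16, 16, 1)), 4)
  out2 <- recenter(st2, r1, c(1.7, -2.3, 0))
  oracle <- hasrc:::fourier_shift_image(img, -1.7 / 4, 2.3 / 4)
  expect_lt(sqrt(mean((out2$stack$data[, , 1] - oracle)^2)), 1e-6)
  ## pose consistency: projected C_M lands on the box centre
  C_M <- c(41, 3, -5)
  rc2 <- recenter(sim$stack, symmetry_expand(sim$records, sim$sym), C_M)
  for (i in c(1, 17, 60)) {
    pp <- project_point(rc2$records[i, ], C_M)
    expect_lt(max(abs(pp[1:2])), 1e-6)
  }
  ## idempotence: re-centering again on the same point is a no-op
  rc3 <- recenter(rc2$stack, rc2$records, C_M)
  expect_equal(rc3$stack$data, rc2$stack$data, tolerance = 1e-9)
  expect_equal(rc3$records$sx, rc2$records$sx, tolerance = 1e-9)
  ## cropping keeps the centre and rejects absurd shifts
  rc4 <- recenter(sim$stack, rec0, c(0, 0, 0), new_box = 32)
  expect_identical(dim(rc4$stack$data)[1:2], c(32L, 32L))
  expect_equal(rc4$stack$data[1, 1, 1], sim$stack$data[17, 17, 1])
  expect_error(recenter(sim$stack, rec0, c(1e4, 0, 0)), "croppable")
})
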