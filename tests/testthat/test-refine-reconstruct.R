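test_that("projector and backprojector are mutually consistent", {
  vol <- blob_volume()
  set.seed(1)
  N <- 400
  rec <- particle_records(N, rot = runif(N, 0, 360),
                          tilt = 90 + rnorm(N, 0, 15),
                          psi = runif(N, 0, 360))
  st <- project_volume(vol, rec)
  vr <- backproject(st, rec, wiener = 0.05)
  expect_gt(cor(as.numeric(vr$data), as.numeric(vol$data)), 0.99)
})

test_that("a single identity-pose particle reproduces its central section", {
  vol <- blob_volume()
  rec <- particle_records(1); rec$tilt <- 0
  st <- project_volume(vol, rec)
  ## central-section theorem: the projection's 2D transform equals the
  ## volume transform's central plane
  n <- 48
  P <- hasrc:::fft2(st$data[, , 1] / vol$apix)
  V <- fft(vol$data)
  ## compare on low-frequency components (interpolation-free check needs
  ## the centring phase; compare magnitudes)
  sel <- c(1:5, (n - 3):n)
  expect_equal(abs(P[sel, sel]), abs(V[sel, sel, 1]), tolerance = 1e-2)
  expect_warning(backproject(st, rec, wiener = 0.05), "distinct views")
})

test_that("reconstruction is linear in the particle stream", {
  vol <- blob_volume()
  set.seed(2)
  N <- 40
  rec <- particle_records(N, rot = runif(N, 0, 360), tilt = 90 + rnorm(N, 0, 10),
                          psi = runif(N, 0, 360))
  st <- project_volume(vol, rec)
  ## accumulator additivity: a concatenated (duplicated) stack equals the
  ## same particles inserted once with doubled weights
  rec2 <- rbind(rec, rec)
  rec2$image <- c(rec$image, rec$image)
  st2 <- image_stack(st$data[, , c(seq_len(40), seq_len(40))], st$apix)
  rec2$image <- seq_len(80)
  dup <- backproject(st2, rec2, wiener = 0.1)
  dbl <- backproject(st, rec, wiener = 0.1, weights = rep(2, 40))
  expect_equal(dup$data, dbl$data, tolerance = 1e-6)
})

test_that("perturbed poses are recovered by local refinement", {
  sim <- small_sim()
  scn <- scene_volume(sim$spec, sim$sym, "open")
  ref8 <- filter_to_resolution(scn, 8)
  rp <- sim$records
  set.seed(3)
  rp$sx <- rp$sx + runif(nrow(rp), -2, 2)
  rp$sy <- rp$sy + runif(nrow(rp), -2, 2)
  rr <- local_refine(sim$stack, rp, ref8, sigma_ang = 2, offset_range = 3.5,
                     angle_points = 1)
  expect_lt(mean(abs(rr$sx - sim$records$sx)), 0.5)  # grid step apix/4 ~ 1 A
  expect_lt(mean(abs(rr$sy - sim$records$sy)), 0.5)
  ## sigma_ang = 0 is the infinitely tight prior
  expect_identical(local_refine(sim$stack, rp, ref8, sigma_ang = 0), rp)
  ## returned poses never score below the input poses
  sc <- attr(rr, "scores")
  expect_true(all(sc$refined >= sc$input - 1e-9))
  ## tiny offset range holds shifts fixed
  rfix <- local_refine(sim$stack, rp, ref8, sigma_ang = 2, offset_range = 0.5,
                       angle_points = 1)
  expect_equal(rfix$sx, rp$sx)
})

test_that("angular perturbations are recovered within one grid step", {
  sim <- small_sim()
  scn <- scene_volume(sim$spec, sim$sym, "open")
  ref8 <- filter_to_resolution(scn, 8)
  rp <- sim$records
  set.seed(9)
  drot <- runif(nrow(rp), -1.5, 1.5)
  rp$rot <- rp$rot + drot
  rr <- local_refine(sim$stack, rp, ref8, sigma_ang = 2, offset_range = 0.5,
                     angle_points = 3)
  ## grid is {-2, 0, 2}: recovered rot within one step of the truth
  expect_lt(mean(abs(rr$rot - sim$records$rot)), 1.5)
  expect_lt(mean(abs(rr$rot - sim$records$rot)),
            mean(abs(rp$rot - sim$records$rot)) + 1e-9)
})

test_that("screw averaging fixes symmetric volumes and suppresses noise", {
  spec <- phantom_spec(); sym <- helical_symmetry()
  scn <- scene_volume(spec, sym, "open")
  symd <- impose_helical_symmetry(scn, sym)
  ## fixed point within interpolation tolerance, central region
  ctr <- 17:48
  num <- sqrt(mean((symd$data[ctr, ctr, ctr] - scn$data[ctr, ctr, ctr])^2))
  den <- sqrt(mean(scn$data[ctr, ctr, ctr]^2))
  expect_lt(num / den, 0.07)
  ## idempotence: one further screw application changes little
  symd2 <- impose_helical_symmetry(symd, sym)
  num2 <- sqrt(mean((symd2$data[ctr, ctr, ctr] - symd$data[ctr, ctr, ctr])^2))
  expect_lt(num2 / den, 0.07)
  ## white-noise variance drops roughly by the number of averaged copies
  set.seed(8)
  nv <- volume_grid(array(rnorm(64^3), c(64, 64, 64)), 4)
  nz <- impose_helical_symmetry(nv, sym)
  kmax <- floor(0.85 * 64 * 4 / 2 / sym$rise)
  ctr2 <- 27:38  # central slab: all 2*kmax+1 copies valid
  ratio <- var(as.numeric(nz$data[, , ctr2])) / var(as.numeric(nv$data[, , ctr2]))
  expect_lt(abs(ratio * (2 * kmax + 1) - 1), 0.6)
})

test_that("filaments are split into balanced gold-standard halves", {
  rec <- particle_records(20, filament = rep(1:10, each = 2))
  sp <- split_halves(rec)
  expect_equal(nrow(sp$half1), 10)
  expect_equal(nrow(sp$half2), 10)
  ## stability under row reordering
  perm <- sample(nrow(rec))
  sp2 <- split_halves(rec[perm, ])
  m1 <- tapply(sp$records$half, sp$records$filament, unique)
  m2 <- tapply(sp2$records$half, sp2$records$filament, unique)
  expect_identical(m1, m2)
  ## imbalance bounded by the largest filament
  set.seed(10)
  sizes <- sample(1:40, 12)
  rec2 <- particle_records(sum(sizes), filament = rep(1:12, sizes))
  sp3 <- split_halves(rec2)
  expect_lte(abs(nrow(sp3$half1) - nrow(sp3$half2)), max(sizes))
  ## expanded subunits of one segment never straddle halves
  ex <- symmetry_expand(sp$records, helical_symmetry())
  expect_true(all(tapply(ex$half, ex$filament, function(x) length(unique(x))) == 1))
  expect_error(split_halves(particle_records(5, filament = 1)), "two filaments")
})

test_that("FSC behaves like a correlation and reads resolution correctly", {
  vol <- blob_volume()
  ## self-correlation is 1 in every shell
  curve <- fsc(vol, vol)
  expect_true(all(abs(curve$fsc - 1) < 1e-9))
  expect_equal(resolution_at(curve, 0.143), 2 * vol$apix)  # Nyquist
  ## two independent noise volumes decorrelate beyond the first shells
  set.seed(11)
  fails <- 0L
  for (i in 1:10) {
    a <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 4)
    b <- volume_grid(array(rnorm(32^3), c(32, 32, 32)), 4)
    cn <- fsc(a, b)
    if (any(abs(cn$fsc[cn$shell >= 4]) > 0.1)) fails <- fails + 1L
  }
  expect_lte(fails, 2L)
  ## monotone in threshold
  noisy <- volume_grid(vol$data + array(rnorm(48^3, sd = 0.5 * sd(vol$data)),
                                        c(48, 48, 48)), 4)
  curve2 <- fsc(vol, noisy)
  r_lo <- resolution_at(curve2, 0.1)
  r_hi <- resolution_at(curve2, 0.7)
  expect_lte(r_lo, r_hi)
  ## size mismatch errors
  small <- volume_grid(vol$data[1:32, 1:32, 1:32], 4)
  expect_error(fsc(vol, small), "grid")
})

test_that("noiseless half-reconstructions reach Nyquist", {
  sim <- small_sim()
  sp <- split_halves(sim$records)
  h <- lapply(list(sp$half1, sp$half2), function(rc)
    backproject(sim$stack, rc, wiener = 0.1))
  curve <- fsc(h[[1]], h[[2]])
  expect_equal(resolution_at(curve, 0.143), 2 * sim$spec$voxel_size)
})
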