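test_that("conformer volumes differ only in marker and rod and carry the right mass", {
  spec <- phantom_spec()
  cv <- build_conformer_volumes(spec)
  d <- cv$closed$data - cv$open$data
  ## zero outside the union of marker/rod supports
  supp <- rbind(spec$marker_open, spec$marker_closed, spec$necklinker_rod)
  n <- spec$box; apix <- spec$voxel_size; c0 <- n %/% 2
  coords <- (seq_len(n) - 1 - c0) * apix
  inside <- array(FALSE, dim(d))
  for (i in seq_len(nrow(supp))) {
    dx <- abs(coords - supp$x[i]); dy <- abs(coords - supp$y[i])
    dz <- abs(coords - supp$z[i])
    cut <- 4.5 * supp$sd[i] + apix
    box <- outer(outer(dx <= cut, dy <= cut, "&"), dz <= cut, "&")
    inside <- inside | box
  }
  expect_lt(max(abs(d[!inside])), 1e-9)

  ## closed-minus-open integrated mass equals the rod blobs' analytic mass
  rod_mass <- sum(spec$necklinker_rod$w * (2 * pi)^1.5 *
                    spec$necklinker_rod$sd^3) / apix^3
  expect_equal(sum(d), rod_mass, tolerance = 0.01)

  ## total voxel sums match the closed-form Gaussian integral
  open_blobs <- rbind(spec$body_blobs, spec$marker_open)
  mass <- sum(open_blobs$w * (2 * pi)^1.5 * open_blobs$sd^3) / apix^3
  expect_equal(sum(cv$open$data), mass, tolerance = 0.01)

  expect_error(phantom_spec(marker_open = data.frame(x = 500, y = 0, z = 0,
                                                     sd = 5, w = 1)),
               "outside")
})

test_that("ground-truth labels follow the requested law", {
  expect_true(all(make_labels("mixture", 50, fraction_open = 1, seed = 1)$labels
                  == "open"))
  ## binomial CI at n = 3000
  gt <- make_labels("mixture", 3000, fraction_open = 0.7, seed = 11)
  expect_lt(abs(mean(gt$labels == "open") - 0.7), 3 * sqrt(0.7 * 0.3 / 3000))
  ## dimer construction
  gt2 <- make_labels("dimer", 600)
  expect_equal(sum(gt2$labels == "closed"), 300)
  expect_equal(sum(gt2$labels == "open"), 300)
  ## every subunit in exactly one pair, trailing closed / leading open
  idx <- c(gt2$pairing$trailing, gt2$pairing$leading)
  expect_identical(sort(idx), 1:600)
  expect_true(all(gt2$labels[gt2$pairing$trailing] == "closed"))
  expect_true(all(gt2$labels[gt2$pairing$leading] == "open"))
  expect_error(make_labels("dimer", 601), "even")
})

test_that("simulated images equal the analytic line-integral oracle", {
  sim <- small_sim()
  spec <- sim$spec; sym <- sim$sym
  n <- spec$box; apix <- spec$voxel_size
  margin <- ceiling((n * apix / 2 + 30) / sym$rise) + 1
  rec <- sim$records[1, ]
  ## independent R renderer over the same screw positions (all open)
  blobs <- do.call(rbind, lapply(seq(-margin, 14 + margin), function(k) {
    b <- rbind(spec$body_blobs, spec$marker_open)
    S <- screw_transform(sym, k)
    p <- sweep(as.matrix(b[, c("x", "y", "z")]) %*% t(S$R), 2, S$t, "+")
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3], sd = b$sd, w = b$w)
  }))
  oracle <- analytic_projection(blobs, rec, n, apix)
  got <- sim$stack$data[, , 1]
  expect_lt(sqrt(mean((got - oracle)^2) / mean(oracle^2)), 1e-5)
})

test_that("the simulator is bit-reproducible under a fixed seed", {
  spec <- phantom_spec(); sym <- helical_symmetry()
  a <- simulate_stack(spec, sym, n_segments = 6, n_filaments = 2,
                      noise_sigma = 2, seed = 7)
  b <- simulate_stack(spec, sym, n_segments = 6, n_filaments = 2,
                      noise_sigma = 2, seed = 7)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$records, b$records)
  expect_identical(a$truth$labels, b$truth$labels)
  c <- simulate_stack(spec, sym, n_segments = 6, n_filaments = 2,
                      noise_sigma = 2, seed = 8)
  expect_false(identical(a$stack$data, c$stack$data))
})

test_that("expanded records project subunit centres onto the rendered positions", {
  sim <- small_sim()
  ex <- symmetry_expand(sim$records, sim$sym)
  cM <- c(72, 0, 0)  # motor core
  apix <- sim$spec$voxel_size
  for (i in c(5, 40, 90)) {
    r <- ex[i, ]
    got <- project_point(r, cM)
    seg <- sim$records[sim$records$image == r$image, ]
    R <- euler_matrix(seg$rot, seg$tilt, seg$psi)
    S <- screw_transform(sim$sym, r$subunit)
    w <- as.numeric(R %*% (S$R %*% cM + S$t)) + c(seg$sx, seg$sy, 0)
    expect_lt(max(abs(got[1:2] - w[1:2])), apix)  # within one pixel
  }
})

test_that("noiseless reconstruction at true poses recovers the scene", {
  spec <- phantom_spec(); sym <- helical_symmetry()
  sim <- simulate_stack(spec, sym, n_segments = 120, n_filaments = 120,
                        mode = "mixture", fraction_open = 1,
                        noise_sigma = 0, ctf = NULL, seed = 5)
  cons <- backproject(sim$stack, sim$records, wiener = 0.05)
  scn <- scene_volume(spec, sym, "open")
  ctr <- 12:52
  expect_gt(cor(as.numeric(cons$data[ctr, ctr, ctr]),
                as.numeric(scn$data[ctr, ctr, ctr])), 0.99)
})

test_that("truth stays in its own file and maps onto expanded records", {
  sim <- small_sim()
  path <- tempfile(fileext = ".json")
  write_truth_json(sim$truth, path)
  rt <- read_truth_json(path)
  expect_identical(rt$labels, sim$truth$labels)
  ex <- symmetry_expand(sim$records, sim$sym)
  expect_identical(truth_labels(rt, ex), truth_labels(sim$truth, ex))
  expect_false(anyNA(truth_labels(rt, ex)))
})
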