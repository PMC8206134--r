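test_that("Calpha distances and the beta-sheet twist follow plane geometry", {
  m <- synthetic_motor_model()
  expect_equal(ca_distance(m, "A", 488, 604), 5.0)      # 3-4-5 triangle
  expect_equal(ca_distance(m, "A", 406, 647), 10.0)
  expect_equal(ca_distance(m, "A", 488, 488), 0.0)
  expect_equal(beta_sheet_twist(m, "A"), 90.0)          # orthogonal strands
  ## parallel strands give zero twist
  mp <- m
  mp[mp$resno == 527, c("x", "y", "z")] <- c(10, 0, 0)
  mp[mp$resno == 531, c("x", "y", "z")] <- c(15, 0, 0)
  expect_equal(beta_sheet_twist(mp, "A"), 0.0)
  expect_error(ca_distance(m, "A", 488, 999), "999")
})

test_that("the conformation rule reproduces every printed group label", {
  ref <- kif14_reference_descriptors()
  expect_identical(nrow(ref), 25L)
  got <- classify_conformation(ref)
  want <- ifelse(ref$group %in% c("open", "open_star"), "open_like", ref$group)
  expect_identical(got, want)
  ## metadata refinement separates open* from open
  got2 <- classify_conformation(ref, nucleotide = ref$nucleotide,
                                neck_linker = ref$neck_linker)
  expect_identical(got2[ref$group == "open_star"],
                   rep("open_star", sum(ref$group == "open_star")))
  expect_identical(got2[ref$group == "open"],
                   rep("open_like", sum(ref$group == "open")))
})

test_that("recomputed group statistics match the printed summary rows", {
  ref <- kif14_reference_descriptors()
  open <- ref[ref$group == "open", ]
  expect_equal(round(mean(open$d_sw1_pl), 1), 14.6)
  expect_equal(round(mean(open$d_kh0_sw2), 1), 24.0)
  expect_equal(round(mean(open$beta_twist), 1), 43.7)
  ## sds from the one-decimal printed rows agree with the printed sd row
  ## to within the printed precision (the published sds were computed
  ## from unrounded coordinates)
  expect_lte(abs(sd(open$d_sw1_pl) - 0.3), 0.1)
  expect_lte(abs(sd(open$d_kh0_sw2) - 1.1), 0.1)
  expect_lte(abs(sd(open$beta_twist) - 1.6), 0.1)
  closed <- ref[ref$group == "closed", ]
  expect_equal(round(mean(closed$d_sw1_pl), 1), 12.5)
  expect_equal(round(mean(closed$d_kh0_sw2), 1), 11.7)
  expect_equal(round(mean(closed$beta_twist), 1), 36.0)
})

test_that("map densities are sampled, background-corrected and ratioed", {
  ## synthetic map rendered from a small model; atoms spaced widely so
  ## every site has the same (isolated-blob) local environment
  model <- atom_model(data.frame(
    resno = c(405:410, 480:487, 700),
    atom = c(rep("CA", 14), "N9"),
    resname = c(rep("ALA", 14), "ADP"),
    x = c(seq(-50, -20, by = 6), seq(5, 47, by = 6), 55),
    y = 0, z = 0))
  map <- model_to_density(model[, c("x", "y", "z")], 2, 64, lowpass = NULL)

  ## constant field: mean density is the constant for any selection
  flat <- volume_grid(array(3.5, c(64, 64, 64)), 2)
  expect_equal(as.numeric(map_mean_density(flat, model)), 3.5)
  expect_equal(as.numeric(map_mean_density(flat, model, model$resno > 600)), 3.5)

  ## rendered map: selection mean far exceeds background
  sel_mean <- as.numeric(map_mean_density(map, model))
  bg <- background_density(map, model, seed = 2)
  expect_gt(sel_mean, as.numeric(bg) * 3)

  ## interpolation agrees with a brute-force R oracle
  pts <- as.matrix(model[1:5, c("x", "y", "z")]) / 2 + 32
  oracle <- vapply(seq_len(5), function(i) {
    p <- pts[i, ]; i0 <- floor(p); t <- p - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
      acc <- acc + map$data[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1] *
        (if (dx) t[1] else 1 - t[1]) * (if (dy) t[2] else 1 - t[2]) *
        (if (dz) t[3] else 1 - t[3])
    acc
  }, numeric(1))
  got <- hasrc:::cpp_trilinear_sample(as.numeric(map$data), 64, pts)
  expect_equal(got, oracle, tolerance = 1e-9)

  ## background on a zero map is zero; deterministic under a fixed seed
  zero <- volume_grid(array(0, c(64, 64, 64)), 2)
  expect_equal(as.numeric(background_density(zero, model, seed = 1)), 0)
  b1 <- background_density(map, model, seed = 7)
  b2 <- background_density(map, model, seed = 7)
  expect_identical(b1, b2)
  ## constructed offset: map + c has background approximately c
  offmap <- volume_grid(map$data + 2, 2)
  expect_equal(as.numeric(background_density(offmap, model, seed = 3)) -
                 as.numeric(background_density(map, model, seed = 3)), 2,
               tolerance = 1e-9)

  ## nucleotide relative density: equal-weight render ratios near 1,
  ## and the ratio is invariant under global scaling
  r1 <- nucleotide_relative_density(map, model)
  expect_lt(abs(r1 - 1), 0.1)
  scaled <- volume_grid(map$data * 7.3, 2)
  expect_equal(nucleotide_relative_density(scaled, model), r1)
  ## absent ligand: density at the nucleotide site is background-level
  no_lig <- model[model$resname != "ADP", ]
  map2 <- model_to_density(no_lig[, c("x", "y", "z")], 2, 64, lowpass = NULL)
  r2 <- nucleotide_relative_density(map2, model)
  expect_lt(r2, 0.2)
  expect_error(nucleotide_relative_density(map2, no_lig), "ligand")
})

test_that("open/closed fractions reflect the mixture in the map", {
  ## two reference 'conformers' with non-overlapping KH regions
  mk <- function(xoff) atom_model(data.frame(
    resno = rep(c(403:412, 463:471, 501:515, 577:579), each = 1),
    atom = "CA",
    x = xoff + seq(0, 30, length.out = 37),
    y = ifelse(xoff > 0, 15, -15), z = 0))
  open_model <- mk(10)
  closed_model <- mk(-40)
  render <- function(model, w = 1) {
    b <- data.frame(x = model$x, y = model$y, z = model$z, sd = 2, w = w)
    model_to_density(b, 2, 64, lowpass = NULL)$data
  }
  ## pure open render
  pure <- volume_grid(render(open_model), 2)
  f <- open_closed_fraction(pure, open_model, closed_model)
  expect_gte(f$f_open, 0.95)
  expect_equal(f$f_open + f$f_closed, 1)
  ## 50/50 synthetic average
  mix <- volume_grid((render(open_model) + render(closed_model)) / 2, 2)
  f2 <- open_closed_fraction(mix, open_model, closed_model)
  expect_lt(abs(f2$f_open - 0.5), 0.05)
  ## undefined when the map holds neither conformer
  empty <- volume_grid(array(0, c(64, 64, 64)), 2)
  expect_error(open_closed_fraction(empty, open_model, closed_model),
               "not positive")
})
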