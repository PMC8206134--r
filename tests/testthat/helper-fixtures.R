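## Shared fixtures: small phantoms and simulations built in code.

default_ctf <- function(apix = 4) ctf_params(pixel_size = apix)

## one wide off-centre Gaussian blob on a small grid
blob_volume <- function(n = 48, apix = 4, center = c(20, -12, 8),
                        sd = 9, w = 1) {
  b <- data.frame(x = center[1], y = center[2], z = center[3], sd = sd, w = w)
  model_to_density(b, apix, n, lowpass = NULL)
}

## independent analytic projection of Gaussian blobs (R implementation,
## used as the line-integral oracle against the compiled renderer and
## the Fourier-slice projector)
analytic_projection <- function(blobs, record, n, apix) {
  R <- euler_matrix(record$rot, record$tilt, record$psi)
  xs <- (seq_len(n) - 1 - n %/% 2) * apix
  img <- matrix(0, n, n)
  q <- as.matrix(blobs[, c("x", "y", "z")]) %*% t(R)
  for (i in seq_len(nrow(blobs))) {
    cen <- q[i, 1:2] + c(record$sx, record$sy)
    img <- img + blobs$w[i] * blobs$sd[i] * sqrt(2 * pi) *
      outer(xs, xs, function(x, y)
        exp(-((x - cen[1])^2 + (y - cen[2])^2) / (2 * blobs$sd[i]^2)))
  }
  img
}

## small noiseless homogeneous simulation reused by several tests
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_stack(phantom_spec(), helical_symmetry(),
                               n_segments = 8, n_filaments = 2,
                               mode = "mixture", fraction_open = 1,
                               noise_sigma = 0, ctf = NULL, seed = 3)
    cache
  }
})

## synthetic atom model with the descriptor residues at known positions
synthetic_motor_model <- function() {
  atoms <- data.frame(
    resno = c(488L, 604L, 406L, 647L, 475L, 480L, 527L, 531L),
    atom = "CA",
    x = c(0, 3, 0, 0, 0, 5, 10, 10),
    y = c(0, 4, 0, 8, 0, 0, 0, 5),
    z = c(0, 0, 0, 6, 0, 0, 0, 0))
  atom_model(atoms)
}

## small mixed-conformation simulation for evaluation tests
small_sim2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_stack(phantom_spec(), helical_symmetry(),
                               n_segments = 8, n_filaments = 2,
                               mode = "mixture", fraction_open = 0.6,
                               noise_sigma = 0, ctf = NULL, seed = 14)
    cache
  }
})
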