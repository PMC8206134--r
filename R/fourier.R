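## FFT helpers shared by the projection, subtraction and reconstruction code.
## Images and volumes are kept in natural (unshifted) FFT index order; the
## real-space box centre is voxel n/2 (0-based).

fft2 <- function(x) fft(x)
ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)
ifftn <- function(x) fft(x, inverse = TRUE) / length(x)

## Integer frequency index (cycles per box) for an n-grid in FFT order.
freq_index <- function(n) {
  f <- seq_len(n) - 1L
  ifelse(f > n / 2, f - n, f)
}

## n x n matrices of integer frequencies fx, fy (FFT order).
freq_grid2 <- function(n) {
  f <- freq_index(n)
  list(fx = matrix(f, n, n), fy = matrix(f, n, n, byrow = TRUE))
}

## Radial spatial frequency (1/Angstrom) and azimuth (radians) grids.
freq_polar2 <- function(n, apix) {
  g <- freq_grid2(n)
  s <- sqrt(g$fx^2 + g$fy^2) / (n * apix)
  list(s = s, az = atan2(g$fy, g$fx))
}

## Phase factor applied to an image FT to shift the image by (dx, dy)
## pixels: I(x - d) <-> F * exp(-2 pi i f d / n).
shift_phase2 <- function(n, dx_px, dy_px) {
  g <- freq_grid2(n)
  exp(-2i * pi * (g$fx * dx_px + g$fy * dy_px) / n)
}

## Subpixel circular shift of a real image by (dx, dy) pixels.
fourier_shift_image <- function(img, dx_px, dy_px) {
  n <- nrow(img)
  Re(ifft2(fft2(img) * shift_phase2(n, dx_px, dy_px)))
}

## Batched 2D FFT of an (n^2 x N) matrix of images (columns), via two
## passes of mvfft (much faster than per-image fft calls).
fft2_cols <- function(m, n, inverse = FALSE) {
  N <- ncol(m)
  dim(m) <- c(n, n * N)
  s <- mvfft(m, inverse = inverse)
  dim(s) <- c(n, n, N)
  s <- aperm(s, c(2, 1, 3))
  dim(s) <- c(n, n * N)
  s <- mvfft(s, inverse = inverse)
  dim(s) <- c(n, n, N)
  s <- aperm(s, c(2, 1, 3))
  dim(s) <- c(n * n, N)
  if (inverse) s <- s / (n * n)
  s
}

## Zero-pad a cubic volume to pad*n and circular-shift so the box centre
## lands on index 0; returns the complex FFT cube ready for slicing.
prepare_volume_ft <- function(vol_data, pad = 2L) {
  n <- dim(vol_data)[1]
  pn <- as.integer(pad * n)
  c0 <- n %/% 2L
  vp <- array(0, c(pn, pn, pn))
  idx <- (((seq_len(n) - 1L) - c0) %% pn) + 1L
  vp[idx, idx, idx] <- vol_data
  fft(vp)
}

## Inverse of the centring used in prepare_volume_ft: take a pn^3 complex
## spectrum, invert, undo the circular shift, crop to n^3 real volume,
## and divide out the trilinear gridding kernel (sinc^2 de-apodization).
finish_volume_ift <- function(vhat, n, pad = 2L) {
  pn <- as.integer(pad * n)
  c0 <- n %/% 2L
  vp <- Re(ifftn(vhat))
  idx <- (((seq_len(n) - 1L) - c0) %% pn) + 1L
  out <- vp[idx, idx, idx]
  m <- (seq_len(n) - 1L - c0) / pn
  s <- ifelse(m == 0, 1, (sin(pi * m) / (pi * m))^2)
  out / (s %o% s %o% s)
}

## Low-pass filter a cubic volume with a cosine-edged cutoff at `res_A`.
lowpass_volume <- function(vol_data, apix, res_A, edge_shells = 3) {
  n <- dim(vol_data)[1]
  f <- freq_index(n)
  fx <- array(f, c(n, n, n))
  fy <- aperm(fx, c(2, 1, 3))
  fz <- aperm(fx, c(3, 2, 1))
  s <- sqrt(fx^2 + fy^2 + fz^2) / (n * apix)
  sc <- 1 / res_A
  ds <- edge_shells / (n * apix)
  w <- ifelse(s <= sc, 1, ifelse(s >= sc + ds, 0, 0.5 * (1 + cos(pi * (s - sc) / ds))))
  Re(ifftn(fft(vol_data) * w))
}

## Correlation between two arrays (flattened Pearson).
array_cor <- function(a, b) stats::cor(as.numeric(a), as.numeric(b))

## Sub-voxel 3D shift of a volume by dxyz Angstrom (Fourier phase ramp).
shift_volume <- function(vol, dxyz) {
  n <- dim(vol$data)[1]
  f <- freq_index(n)
  fx <- array(f, c(n, n, n))
  fy <- aperm(fx, c(2, 1, 3))
  fz <- aperm(fx, c(3, 2, 1))
  dpx <- dxyz / vol$apix
  ph <- exp(-2i * pi * (fx * dpx[1] + fy * dpx[2] + fz * dpx[3]) / n)
  volume_grid(Re(ifftn(fft(vol$data) * ph)), vol$apix)
}
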