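## Central-section projection and direct Fourier inversion. The volume is
## zero-padded (oversampling factor `pad`), circularly shifted so the box
## centre is the rotation origin, and transformed once; each particle's
## projection is a trilinearly interpolated central section, with record
## shifts and the box-centre offset applied as Fourier phase ramps.

## Per-particle CTF images as an (n^2 x N) matrix (FFT order), including
## each record's astigmatism and beam-axis depth offset.
ctf_matrix_for_records <- function(records, params, n, apix,
                                   use_depth = TRUE) {
  N <- nrow(records)
  out <- matrix(0, n * n, N)
  for (i in seq_len(N)) {
    p <- ctf_params(voltage = params$voltage, cs = params$cs,
                    amplitude_contrast = params$amplitude_contrast,
                    defocus_u = records$dfu[i], defocus_v = records$dfv[i],
                    astig_angle = records$dfang[i], pixel_size = apix)
    off <- if (use_depth) records$zoff[i] else 0
    out[, i] <- as.numeric(ctf_image(p, n, apix, defocus_offset = off))
  }
  out
}

## Complex phase ramps shifting each projection by (sx, sy) Angstrom plus
## the box-centre offset.
shift_phase_matrix <- function(records, n, apix, sign = -1) {
  g <- freq_grid2(n)
  c2 <- n %/% 2L
  dx <- records$sx / apix + c2
  dy <- records$sy / apix + c2
  exp(sign * 2i * pi * (as.numeric(g$fx) %o% dx + as.numeric(g$fy) %o% dy) / n)
}

#' Project a volume at the poses of an alignment table
#'
#' Fourier central-section projection with trilinear interpolation on a
#' `pad`-fold oversampled transform. The output is the line integral of
#' the density along the beam (units density x Angstrom), shifted by each
#' record's `(sx, sy)`.
#'
#' @param vol A [volume_grid()].
#' @param records Alignment table; one projection per row.
#' @param ctf Optional [ctf_params()]; when given, each projection is
#'   multiplied in the Fourier domain by the record's CTF (including its
#'   `zoff` depth-defocus offset).
#' @param pad Fourier oversampling factor (integer >= 1).
#' @param as_matrix Return an `(n^2 x N)` matrix instead of an
#'   [image_stack()].
#' @return [image_stack()] (or matrix) of projections.
#' @export
project_volume <- function(vol, records, ctf = NULL, pad = 2L,
                           as_matrix = FALSE) {
  n <- dim(vol$data)[1]
  W <- prepare_volume_ft(vol$data, pad)
  out <- project_from_ft(W, n, pad, records, vol$apix, ctf)
  if (as_matrix) return(out)
  matrix_as_stack(out, n, vol$apix)
}

## Projection core reusing a precomputed padded transform (class volumes
## inside the EM loop). Returns an (n^2 x N) real matrix.
project_from_ft <- function(W, n, pad, records, apix, ctf = NULL,
                            chunk = 512L) {
  N <- nrow(records)
  pn <- as.integer(pad * n)
  out <- matrix(0, n * n, N)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    rc <- records[idx, , drop = FALSE]
    rots <- flatten_rots(record_rotations(rc))
    sl <- cpp_fourier_slice(W, rots, pn, n, as.integer(pad))
    sl <- sl * shift_phase_matrix(rc, n, apix, sign = -1)
    if (!is.null(ctf)) sl <- sl * ctf_matrix_for_records(rc, ctf, n, apix)
    out[, idx] <- Re(fft2_cols(sl, n, inverse = TRUE)) * apix
  }
  out
}

#' Reconstruct a volume by direct Fourier inversion
#'
#' Inserts each (optionally CTF-premultiplied) image transform as a
#' central section into a `pad`-fold oversampled accumulator and
#' normalizes by the accumulated CTF^2 plus a Wiener constant, the
#' standard weighted direct-inversion estimator. Fewer than 3 distinct
#' views triggers a warning (anisotropic reconstruction).
#'
#' @param stack An [image_stack()].
#' @param records Alignment table matched to the stack rows via `image`.
#' @param ctf Optional [ctf_params()]; `NULL` treats the data as CTF-free.
#' @param pad Fourier oversampling factor.
#' @param wiener Wiener constant added to the accumulated weights.
#' @param weights Optional per-particle weights (e.g. class
#'   responsibilities); default 1.
#' @return A [volume_grid()] on the stack's grid.
#' @export
backproject <- function(stack, records, ctf = NULL, pad = 2L,
                        wiener = 0.1, weights = NULL, chunk = 512L) {
  n <- box_size(stack)
  apix <- stack$apix
  N <- nrow(records)
  if (length(unique(round(records$rot, 6) * 1e6 +
                    round(records$tilt, 6))) < 3L)
    warning("fewer than 3 distinct views: reconstruction will be anisotropic")
  if (is.null(weights)) weights <- rep(1, N)
  pn <- as.integer(pad * n)
  acc_re <- numeric(pn^3); acc_im <- numeric(pn^3); acc_w <- numeric(pn^3)
  m <- stack_as_matrix(stack)
  for (start in seq(1L, N, by = chunk)) {
    idx <- start:min(N, start + chunk - 1L)
    rc <- records[idx, , drop = FALSE]
    Fi <- fft2_cols(m[, rc$image, drop = FALSE] / apix, n)
    Fi <- Fi * shift_phase_matrix(rc, n, apix, sign = +1)
    C <- if (is.null(ctf)) matrix(1, n * n, length(idx))
         else ctf_matrix_for_records(rc, ctf, n, apix)
    rots <- flatten_rots(record_rotations(rc))
    cpp_backproject_insert(sl_as_cplx(Fi), C, weights[idx], rots,
                           pn, n, as.integer(pad), acc_re, acc_im, acc_w)
  }
  vhat <- array(complex(real = acc_re, imaginary = acc_im) / (acc_w + wiener),
                c(pn, pn, pn))
  volume_grid(finish_volume_ift(vhat, n, pad), apix)
}

## Ensure complex storage mode for the C++ interface.
sl_as_cplx <- function(x) {
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}
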