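#' Microscope and per-particle CTF parameters
#'
#' Weak-phase contrast transfer function state. Underfocus is positive;
#' the aberration phase is `chi = pi * lambda * df * s^2 - (pi/2) * Cs *
#' lambda^3 * s^4`, the dominant single-particle sign convention.
#'
#' @param voltage Acceleration voltage, kV.
#' @param cs Spherical aberration, mm.
#' @param amplitude_contrast Amplitude contrast fraction in \[0, 1\].
#' @param defocus_u,defocus_v Defocus along the astigmatism axes, Angstrom.
#' @param astig_angle Astigmatism axis angle, degrees.
#' @param pixel_size Angstrom per pixel.
#' @return An object of class `ctf_params`.
#' @export
ctf_params <- function(voltage = 300, cs = 2.7, amplitude_contrast = 0.07,
                       defocus_u = 15000, defocus_v = 15000,
                       astig_angle = 0, pixel_size = 4) {
  stopifnot(voltage > 0, pixel_size > 0,
            amplitude_contrast >= 0, amplitude_contrast <= 1)
  structure(list(voltage = voltage, cs = cs,
                 amplitude_contrast = amplitude_contrast,
                 defocus_u = defocus_u, defocus_v = defocus_v,
                 astig_angle = astig_angle, pixel_size = pixel_size),
            class = "ctf_params")
}

#' @export
print.ctf_params <- function(x, ...) {
  cat(sprintf("CTF: %g kV, Cs %g mm, w %.3f, defocus %.0f/%.0f A @ %.1f deg, %.3f A/px\n",
              x$voltage, x$cs, x$amplitude_contrast, x$defocus_u, x$defocus_v,
              x$astig_angle, x$pixel_size))
  invisible(x)
}

## Relativistic electron wavelength in Angstrom.
electron_wavelength <- function(voltage_kV) {
  V <- voltage_kV * 1000
  12.2639 / sqrt(V * (1 + V * 0.97845e-6))
}

#' Evaluate the contrast transfer function
#'
#' `-(sqrt(1 - w^2) * sin(chi) + w * cos(chi))`, bounded in \[-1, 1\];
#' at zero frequency the value is `-w` (the amplitude-contrast limit).
#'
#' @param params A [ctf_params()].
#' @param s Spatial frequency, 1/Angstrom (vectorised, >= 0).
#' @param azimuth Azimuth of the frequency vector, degrees (vectorised).
#' @param defocus_offset Additional defocus added to both axes, Angstrom
#'   (e.g. a subunit's depth along the beam).
#' @return Signed amplitude factor, same length as `s`.
#' @export
ctf_eval <- function(params, s, azimuth = 0, defocus_offset = 0) {
  stopifnot(all(s >= 0))
  lam <- electron_wavelength(params$voltage)
  w <- params$amplitude_contrast
  az <- deg2rad(azimuth)
  df <- 0.5 * (params$defocus_u + params$defocus_v) + defocus_offset +
    0.5 * (params$defocus_u - params$defocus_v) *
      cos(2 * (az - deg2rad(params$astig_angle)))
  chi <- pi * lam * df * s^2 - (pi / 2) * (params$cs * 1e7) * lam^3 * s^4
  -(sqrt(1 - w^2) * sin(chi) + w * cos(chi))
}

## CTF evaluated on the full n x n frequency grid (FFT order).
ctf_image <- function(params, n, apix = params$pixel_size,
                      defocus_offset = 0) {
  g <- freq_polar2(n, apix)
  m <- ctf_eval(params, g$s, g$az * 180 / pi, defocus_offset)
  matrix(m, n, n)
}

#' Apply a CTF to an image
#'
#' Multiplication by the transfer function in the Fourier domain; real
#' input gives real output (up to numerical round-off).
#'
#' @param image Square numeric matrix.
#' @param params A [ctf_params()].
#' @param apix Pixel size of `image`; must equal `params$pixel_size`
#'   when both are given.
#' @param defocus_offset Additional defocus, Angstrom.
#' @return Filtered image (same dimensions).
#' @export
apply_ctf <- function(image, params, apix = NULL, defocus_offset = 0) {
  n <- nrow(image)
  stopifnot(n == ncol(image))
  if (!is.null(apix) && abs(apix - params$pixel_size) > 1e-9)
    stop(sprintf("pixel size mismatch: image %.4f vs CTF %.4f A/px",
                 apix, params$pixel_size))
  C <- ctf_image(params, n, params$pixel_size, defocus_offset)
  Re(ifft2(fft2(image) * C))
}

#' Refine per-particle defocus by grid search
#'
#' Scans a common defocus offset (u and v jointly, astigmatism fixed) on a
#' grid of the given step within +/- range, scoring the normalized
#' cross-correlation between the CTF-modulated reference projection and
#' the particle image. Mirrors the per-particle CTF refinement of helical
#' single-particle workflows (step 50 A, range 1250 A).
#'
#' @param image Particle image (square matrix).
#' @param record Single-row alignment table carrying `dfu`, `dfv`, `dfang`
#'   and `zoff`.
#' @param reference_projection Noise-free reference projection on the same
#'   grid, *without* CTF applied.
#' @param params A [ctf_params()] carrying the microscope constants.
#' @param step Grid step, Angstrom.
#' @param range Half-width of the search window, Angstrom. `range < step`
#'   returns the input defocus unchanged.
#' @param mask Optional real-space mask in \[0,1\] applied to both sides
#'   before scoring.
#' @return List with `dfu`, `dfv` (refined values), `offset` (the chosen
#'   grid offset) and `score`.
#' @export
refine_defocus <- function(image, record, reference_projection, params,
                           step = 50, range = 1250, mask = NULL) {
  dfu0 <- record$dfu[1]; dfv0 <- record$dfv[1]
  if (range < step)
    return(list(dfu = dfu0, dfv = dfv0, offset = 0, score = NA_real_))
  offsets <- seq(-range, range, by = step)
  n <- nrow(image)
  if (!is.null(mask)) {
    image <- image * mask
    reference_projection <- reference_projection * mask
  }
  Fi <- fft2(image)
  Fr <- fft2(reference_projection)
  base <- ctf_params(voltage = params$voltage, cs = params$cs,
                     amplitude_contrast = params$amplitude_contrast,
                     defocus_u = dfu0, defocus_v = dfv0,
                     astig_angle = record$dfang[1],
                     pixel_size = params$pixel_size)
  zoff <- record$zoff[1]
  scores <- vapply(offsets, function(o) {
    C <- ctf_image(base, n, defocus_offset = o + zoff)
    num <- sum(Re(Conj(Fi) * (C * Fr)))
    den <- sqrt(sum(abs(C * Fr)^2) * sum(abs(Fi)^2))
    if (den == 0) -Inf else num / den
  }, numeric(1))
  best <- which.max(scores)
  list(dfu = dfu0 + offsets[best], dfv = dfv0 + offsets[best],
       offset = offsets[best], score = scores[best])
}

#' Moving-median smoothing of a per-filament defocus series
#'
#' Replaces element i by the median of the window of the given width
#' centred on i; the window is truncated (not reflected) at the filament
#' ends, so no values are invented at the boundaries.
#'
#' @param x Defocus values ordered by position along one filament.
#' @param window Odd window width (default 5 contiguous particles).
#' @return Smoothed series, same length.
#' @export
median_smooth_defocus <- function(x, window = 5L) {
  n <- length(x)
  if (n == 0L) return(x)
  h <- window %/% 2L
  vapply(seq_len(n), function(i) {
    median(x[max(1L, i - h):min(n, i + h)])
  }, numeric(1))
}

#' Smooth defocus along every filament of an alignment table
#'
#' Applies [median_smooth_defocus()] to `dfu` and `dfv` within each
#' filament, ordered by `position` (ties broken by `subunit`).
#'
#' @param records Alignment table.
#' @param window Window width.
#' @return Updated alignment table.
#' @export
smooth_defocus_records <- function(records, window = 5L) {
  for (f in unique(records$filament)) {
    sel <- which(records$filament == f)
    ord <- sel[order(records$position[sel], records$subunit[sel])]
    records$dfu[ord] <- median_smooth_defocus(records$dfu[ord], window)
    records$dfv[ord] <- median_smooth_defocus(records$dfv[ord], window)
  }
  records
}
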