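#' Rasterize a coordinate model to a density volume
#'
#' Pseudo-atom rendering followed by low-pass filtration, the standard
#' route from an atomic (or blob) model to a mask-generation density.
#' Input is a data.frame with columns `x, y, z` (Angstrom, box-centre
#' origin) and optional `sd` (default 2 A) and `w` (default 1) columns.
#'
#' @param atoms Coordinate table.
#' @param voxel_size Angstrom per voxel.
#' @param box Output box size, voxels.
#' @param lowpass Low-pass resolution in Angstrom (e.g. 30 for
#'   subtraction masks, 15 for FSC masks); `NULL` skips filtering.
#' @return A [volume_grid()].
#' @export
model_to_density <- function(atoms, voxel_size, box, lowpass = 30) {
  stopifnot(all(c("x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$sd)) atoms$sd <- 2
  if (is.null(atoms$w)) atoms$w <- 1
  half <- box * voxel_size / 2
  if (any(abs(atoms[, c("x", "y", "z")]) >= half))
    stop("model atoms fall outside the box")
  v <- cpp_render_gauss3d(as.matrix(atoms[, c("x", "y", "z")]),
                          atoms$sd, atoms$w, as.integer(box), voxel_size)
  if (!is.null(lowpass)) v <- lowpass_volume(v, voxel_size, lowpass)
  volume_grid(v, voxel_size)
}

## Binary dilation of a logical 3D array by a Euclidean ball of radius r
## voxels, via FFT convolution with a spherical kernel.
dilate_ball <- function(bin, r) {
  if (r <= 0) return(bin)
  n <- dim(bin)[1]
  f <- freq_index(n)
  dx <- array(f, c(n, n, n))
  dy <- aperm(dx, c(2, 1, 3))
  dz <- aperm(dx, c(3, 2, 1))
  ker <- (dx^2 + dy^2 + dz^2) <= r^2
  conv <- Re(ifftn(fft(bin + 0) * fft(ker + 0)))
  conv > 0.5
}

#' Build a soft mask from a density volume
#'
#' Binarize at `threshold`, dilate the support by `extend_px` voxels and
#' append a raised-cosine falloff of width `soft_edge_px` voxels; all
#' values lie in \[0, 1\]. Optionally restrict the mask to the central
#' `z_fraction` of the box along the helical axis (the axial window used
#' when masking helically averaged maps).
#'
#' @param volume A [volume_grid()].
#' @param threshold Binarization threshold (within the volume's range).
#' @param extend_px Hard dilation width, voxels (non-positive = none).
#' @param soft_edge_px Cosine edge width, voxels (non-positive = none).
#' @param z_fraction Optional axial window fraction (e.g. 0.85).
#' @return A `soft_mask` (a [volume_grid()] with provenance and the
#'   mask-weighted centre of mass `center_of_mass`, Angstrom).
#' @export
make_soft_mask <- function(volume, threshold = 0.05, extend_px = 14L,
                           soft_edge_px = 6L, z_fraction = NULL) {
  v <- volume$data
  if (threshold < min(v) || threshold > max(v))
    stop("threshold outside the volume's value range")
  extend_px <- max(0L, as.integer(extend_px))
  soft_edge_px <- max(0L, as.integer(soft_edge_px))
  n <- dim(v)[1]
  supp <- dilate_ball(v >= threshold, extend_px)
  m <- supp + 0
  if (soft_edge_px > 0) {
    prev <- supp
    for (d in seq_len(soft_edge_px)) {
      cur <- dilate_ball(supp, d)
      shell <- cur & !prev
      m[shell] <- 0.5 * (1 + cos(pi * d / soft_edge_px))
      prev <- cur
    }
  }
  if (!is.null(z_fraction)) {
    c0 <- n %/% 2L
    z <- abs(seq_len(n) - 1L - c0)
    zwin <- as.numeric(z <= z_fraction * n / 2)
    m <- sweep(m, 3, zwin, "*")
  }
  tot <- sum(m)
  c0 <- n %/% 2L
  coords <- (seq_len(n) - 1L - c0) * volume$apix
  com <- c(sum(apply(m, 1, sum) * coords),
           sum(apply(m, 2, sum) * coords),
           sum(apply(m, 3, sum) * coords)) / tot
  out <- volume_grid(m, volume$apix)
  out$provenance <- list(threshold = threshold, extend_px = extend_px,
                         soft_edge_px = soft_edge_px, z_fraction = z_fraction)
  out$center_of_mass <- com
  class(out) <- c("soft_mask", class(out))
  out
}

#' @export
print.soft_mask <- function(x, ...) {
  cat(sprintf("soft_mask: %d^3, support %.1f%%, C_M = (%.1f, %.1f, %.1f) A\n",
              dim(x$data)[1], 100 * mean(x$data > 0),
              x$center_of_mass[1], x$center_of_mass[2], x$center_of_mass[3]))
  invisible(x)
}

#' Partial signal subtraction outside a mask
#'
#' Subtracts from every particle image the CTF-modulated projection of
#' `reference * (1 - mask)` at the record's pose, retaining the signal
#' inside the mask. The reference amplitude is matched to the data by a
#' single global least-squares scale (fit of the full-reference
#' projections against the images) unless `scale` is given.
#'
#' @param stack An [image_stack()].
#' @param records Alignment table (rows matched to images via `image`).
#' @param reference A [volume_grid()] of the full assembly (consensus map).
#' @param mask A `soft_mask` on the same grid.
#' @param ctf A [ctf_params()], or `NULL` for CTF-free data.
#' @param scale `"fit"`, or a numeric scale applied to the reference.
#' @param pad Fourier oversampling for the projections.
#' @return List with the subtracted `stack`, the `scale` used, and the
#'   records (unchanged, for pipeline symmetry).
#' @export
subtract_outside_mask <- function(stack, records, reference, mask, ctf = NULL,
                                  scale = "fit", pad = 2L) {
  if (!isTRUE(all.equal(dim(reference$data), dim(mask$data))) ||
      abs(reference$apix - mask$apix) > 1e-9)
    stop("reference and mask must share the same grid")
  if (abs(reference$apix - stack$apix) > 1e-9)
    stop("reference and stack pixel sizes differ")
  imgs <- stack_as_matrix(stack)[, records$image, drop = FALSE]
  if (identical(scale, "fit")) {
    pf <- project_volume(reference, records, ctf = ctf, pad = pad,
                         as_matrix = TRUE)
    scale <- sum(pf * imgs) / sum(pf * pf)
  }
  outside <- volume_grid(reference$data * (1 - mask$data) * scale,
                         reference$apix)
  po <- project_volume(outside, records, ctf = ctf, pad = pad,
                       as_matrix = TRUE)
  out <- imgs - po
  list(stack = matrix_as_stack(out, box_size(stack), stack$apix),
       records = records, scale = scale)
}

#' Re-center particle images on a projected 3D point
#'
#' Shifts every image (Fourier subpixel; exact circular shift for integer
#' displacements) so that the projection of `C_M` lands on the box
#' centre, optionally crops to a smaller box, and updates the record
#' shifts so pose/image consistency is preserved: afterwards
#' `project_point(record, C_M)` is (0, 0, depth). The applied image
#' displacement is stored in `rc_dx`/`rc_dy` (Angstrom) so later stages
#' can map refined poses back onto the original, un-centred images, and
#' the point's beam-axis depth is accumulated into `zoff` for the
#' per-subunit defocus adjustment.
#'
#' @param stack An [image_stack()].
#' @param records Alignment table.
#' @param C_M Length-3 point, Angstrom (e.g. a mask centre of mass).
#' @param new_box Output box size (<= current box).
#' @return List with shifted/cropped `stack` and updated `records`.
#' @export
recenter <- function(stack, records, C_M, new_box = box_size(stack)) {
  n <- box_size(stack); apix <- stack$apix
  new_box <- as.integer(new_box)
  if (new_box > n) stop("new_box must not exceed the current box")
  imgs <- stack_as_matrix(stack)[, records$image, drop = FALSE]
  N <- nrow(records)
  Rm <- record_rotations(records)
  if (length(dim(Rm)) == 2L) Rm <- array(Rm, c(3, 3, 1))
  rc <- t(apply(Rm, 3, function(R) as.numeric(R %*% C_M)))
  px <- rc[, 1] + records$sx   # projected C_M, x (Angstrom)
  py <- rc[, 2] + records$sy
  if (any(sqrt(px^2 + py^2) / apix > n / 2))
    stop("projected C_M outside the croppable region")
  g <- freq_grid2(n)
  fx <- as.numeric(g$fx); fy <- as.numeric(g$fy)
  dxp <- px / apix; dyp <- py / apix
  intshift <- abs(dxp - round(dxp)) < 1e-9 & abs(dyp - round(dyp)) < 1e-9
  for (i in seq_len(N)) {
    im <- matrix(imgs[, i], n, n)
    if (intshift[i]) {
      sh <- c(round(dxp[i]), round(dyp[i]))
      idx <- ((seq_len(n) - 1L + sh[1]) %% n) + 1L
      idy <- ((seq_len(n) - 1L + sh[2]) %% n) + 1L
      imgs[, i] <- as.numeric(im[idx, idy])
    } else {
      ph <- exp(2i * pi * (fx * dxp[i] + fy * dyp[i]) / n)
      imgs[, i] <- as.numeric(Re(ifft2(fft2(im) * matrix(ph, n, n))))
    }
  }
  if (new_box < n) {
    c0 <- n %/% 2L; nb2 <- new_box %/% 2L
    keep <- (c0 - nb2 + 1L):(c0 + nb2)
    dim(imgs) <- c(n, n, N)
    imgs <- imgs[keep, keep, , drop = FALSE]
    dim(imgs) <- c(new_box * new_box, N)
  }
  records$rc_dx <- (if (is.null(records$rc_dx)) 0 else records$rc_dx) + px
  records$rc_dy <- (if (is.null(records$rc_dy)) 0 else records$rc_dy) + py
  records$sx <- records$sx - px
  records$sy <- records$sy - py
  records$zoff <- records$zoff + rc[, 3]
  records$image <- seq_len(N)
  list(stack = matrix_as_stack(imgs, new_box, apix), records = records)
}
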