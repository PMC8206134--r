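#' Local subunit pose refinement with angular priors
#'
#' Per-particle grid search over small Euler perturbations (a Gaussian
#' prior of width `sigma_ang` penalizes deviation from the input pose)
#' and image-plane shifts within `offset_range` Angstrom, maximizing the
#' normalized, mask-weighted, CTF-corrected correlation between reference
#' projections and the images. Shifts are located on the pixel grid by
#' cross-correlation and refined to sub-pixel precision by parabolic
#' interpolation. Each half-set is only ever compared with its own half
#' reference (gold-standard hygiene): pass `reference` as a list of two
#' volumes to enforce this.
#'
#' `sigma_ang = 0` is the infinitely tight prior: records are returned
#' unchanged. `offset_range` below a quarter pixel holds shifts fixed
#' (the correlation peak is interpolated to sub-pixel precision).
#' The returned pose never scores below the input pose.
#'
#' @param stack An [image_stack()].
#' @param records Alignment table.
#' @param reference A [volume_grid()], or `list(half1, half2)` indexed by
#'   `records$half`.
#' @param sigma_ang Angular prior width, degrees.
#' @param offset_range Shift search radius, Angstrom.
#' @param ctf A [ctf_params()] or `NULL`.
#' @param mask Optional `soft_mask` on the reference grid; its projection
#'   weights the reference before scoring.
#' @param angle_points Odd number of grid points per Euler angle
#'   (default 3: -sigma_ang, 0, +sigma_ang).
#' @param prior_scale Weight of the angular prior term on the
#'   correlation scale.
#' @param pad Fourier oversampling factor.
#' @return The records with refined `rot`, `tilt`, `psi`, `sx`, `sy`;
#'   attribute `"scores"` holds input and refined scores.
#' @export
local_refine <- function(stack, records, reference, sigma_ang = 2,
                         offset_range = 3.5, ctf = NULL, mask = NULL,
                         angle_points = 3L, prior_scale = 0.01, pad = 2L) {
  if (sigma_ang == 0) return(records)
  n <- box_size(stack); apix <- stack$apix
  refs <- if (inherits(reference, "volume_grid")) list(reference, reference)
          else reference
  Ws <- lapply(refs, function(v) prepare_volume_ft(v$data, pad))
  pn <- as.integer(pad * n)
  N <- nrow(records)
  imgs <- stack_as_matrix(stack)[, records$image, drop = FALSE]
  Fi <- fft2_cols(imgs, n)
  inorm <- sqrt(colSums(abs(Fi)^2))
  Cm <- if (is.null(ctf)) NULL else ctf_matrix_for_records(records, ctf, n, apix)
  mproj <- if (is.null(mask)) NULL else {
    mp <- project_volume(volume_grid(mask$data, apix), records,
                         pad = pad, as_matrix = TRUE)
    pmin(pmax(mp / max(mp), 0), 1)
  }
  ## the correlation peak is refined to sub-pixel precision, so the
  ## search is meaningful down to a fraction of a pixel; below a quarter
  ## pixel the shifts are held fixed
  search_shifts <- offset_range >= 0.25 * apix
  win <- max(1L, floor(offset_range / apix))
  half_of <- records$half

  dg <- if (angle_points == 1L) 0 else
    seq(-sigma_ang, sigma_ang, length.out = angle_points)
  cand <- expand.grid(dr = dg, dt = dg, dp = dg)

  best_score <- rep(-Inf, N)
  best <- data.frame(rot = records$rot, tilt = records$tilt,
                     psi = records$psi, sx = records$sx, sy = records$sy)
  g <- freq_grid2(n)
  fxv <- as.numeric(g$fx); fyv <- as.numeric(g$fy)
  c2 <- n %/% 2L

  ## reference projection (masked, CTF-modulated) FT for a candidate pose,
  ## centred (zero shift): used both for CC shift search and direct scoring
  cand_proj_ft <- function(rc) {
    out <- matrix(0+0i, n * n, N)
    for (h in unique(half_of)) {
      idx <- which(half_of == h)
      rots <- flatten_rots(record_rotations(rc[idx, , drop = FALSE]))
      sl <- cpp_fourier_slice(Ws[[min(h, length(Ws))]], rots, pn, n,
                              as.integer(pad))
      ## centre the projection on the box centre (no particle shift)
      ph <- exp(-2i * pi * (fxv + fyv) * c2 / n)
      sl <- sl * ph
      if (!is.null(Cm)) sl <- sl * Cm[, idx, drop = FALSE]
      out[, idx] <- sl
    }
    if (!is.null(mproj)) {
      pr <- Re(fft2_cols(out, n, inverse = TRUE))
      out <- fft2_cols(pr * mproj, n)
    }
    out
  }

  score_at_shift <- function(Fp, sx, sy) {
    ## normalized correlation at exact (possibly sub-pixel) shifts
    ph <- exp(-2i * pi * (fxv %o% (sx / apix) + fyv %o% (sy / apix)) / n)
    num <- colSums(Re(Conj(Fi) * (Fp * ph)))
    den <- sqrt(colSums(abs(Fp)^2)) * inorm
    num / pmax(den, 1e-30)
  }

  for (ci in seq_len(nrow(cand))) {
    rc <- records
    rc$rot <- rc$rot + cand$dr[ci]
    rc$tilt <- rc$tilt + cand$dt[ci]
    rc$psi <- rc$psi + cand$dp[ci]
    Fp <- cand_proj_ft(rc)
    prior_pen <- prior_scale *
      (cand$dr[ci]^2 + cand$dt[ci]^2 + cand$dp[ci]^2) / (2 * sigma_ang^2)
    if (search_shifts) {
      cc <- Re(fft2_cols(Fi * Conj(Fp), n, inverse = TRUE)) * n * n
      den <- sqrt(colSums(abs(Fp)^2)) * inorm
      for (i in seq_len(N)) {
        ccm <- matrix(cc[, i], n, n)
        c0x <- round(records$sx[i] / apix); c0y <- round(records$sy[i] / apix)
        vx <- ((c0x - win):(c0x + win)) %% n + 1L
        vy <- ((c0y - win):(c0y + win)) %% n + 1L
        sub <- ccm[vx, vy, drop = FALSE]
        pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
        sxp <- c0x - win + pk[1] - 1L
        syp <- c0y - win + pk[2] - 1L
        ## parabolic sub-pixel refinement, clamped to the search radius
        dx <- parab_offset(sub, pk)
        sxa <- (sxp + dx[1]) * apix; sya <- (syp + dx[2]) * apix
        r2 <- (sxa - records$sx[i])^2 + (sya - records$sy[i])^2
        if (r2 > offset_range^2) {
          f <- offset_range / sqrt(r2)
          sxa <- records$sx[i] + (sxa - records$sx[i]) * f
          sya <- records$sy[i] + (sya - records$sy[i]) * f
        }
        sc <- score_one(Fi[, i], Fp[, i], fxv, fyv, sxa / apix, sya / apix,
                        n, den[i])
        sc <- sc - prior_pen
        if (sc > best_score[i]) {
          best_score[i] <- sc
          best$rot[i] <- rc$rot[i]; best$tilt[i] <- rc$tilt[i]
          best$psi[i] <- rc$psi[i]; best$sx[i] <- sxa; best$sy[i] <- sya
        }
      }
    } else {
      sc <- score_at_shift(Fp, records$sx, records$sy) - prior_pen
      upd <- sc > best_score
      best_score[upd] <- sc[upd]
      best$rot[upd] <- rc$rot[upd]; best$tilt[upd] <- rc$tilt[upd]
      best$psi[upd] <- rc$psi[upd]
    }
  }
  ## never return a pose scoring below the input pose
  Fp0 <- cand_proj_ft(records)
  sc0 <- score_at_shift(Fp0, records$sx, records$sy)
  keep <- sc0 >= best_score
  best[keep, ] <- data.frame(rot = records$rot, tilt = records$tilt,
                             psi = records$psi, sx = records$sx,
                             sy = records$sy)[keep, ]
  best_score[keep] <- sc0[keep]
  out <- records
  out$rot <- best$rot; out$tilt <- best$tilt; out$psi <- best$psi
  out$sx <- best$sx; out$sy <- best$sy
  attr(out, "scores") <- data.frame(input = sc0, refined = best_score)
  out
}

## single-particle normalized correlation at an exact sub-pixel shift
score_one <- function(Fi_i, Fp_i, fxv, fyv, dxp, dyp, n, den) {
  ph <- exp(-2i * pi * (fxv * dxp + fyv * dyp) / n)
  sum(Re(Conj(Fi_i) * (Fp_i * ph))) / max(den, 1e-30)
}

## 3-point parabolic peak offset inside a correlation window
parab_offset <- function(sub, pk) {
  off <- c(0, 0)
  for (d in 1:2) {
    i <- pk[d]
    if (i > 1 && i < dim(sub)[d]) {
      if (d == 1) { ym <- sub[i - 1, pk[2]]; y0 <- sub[i, pk[2]]; yp <- sub[i + 1, pk[2]] }
      else { ym <- sub[pk[1], i - 1]; y0 <- sub[pk[1], i]; yp <- sub[pk[1], i + 1] }
      den <- ym - 2 * y0 + yp
      if (den < 0) off[d] <- max(-0.5, min(0.5, 0.5 * (ym - yp) / den))
    }
  }
  off
}

#' Impose helical symmetry on a volume in real space
#'
#' Averages screw-transformed copies of the map, using only source
#' voxels lying within the central `z_fraction` of the box along the
#' helical axis (trilinear interpolation). A screw-symmetric volume is a
#' fixed point up to interpolation error.
#'
#' @param vol A [volume_grid()] with the helical axis along z.
#' @param sym A [helical_symmetry()].
#' @param z_fraction Central axial fraction contributing as source.
#' @return The symmetrized [volume_grid()].
#' @export
impose_helical_symmetry <- function(vol, sym, z_fraction = 0.85) {
  n <- dim(vol$data)[1]
  kmax <- floor(z_fraction * n * vol$apix / 2 / sym$rise)
  out <- cpp_screw_average(vol$data, n, vol$apix, sym$rise, signed_twist(sym),
                           -kmax, kmax, z_fraction)
  volume_grid(out, vol$apix)
}

#' Split an alignment table into gold-standard halves by filament
#'
#' Whole filaments (never individual subunits) are assigned greedily,
#' largest first, to the half with the smaller particle count, so the
#' imbalance never exceeds the largest filament. The assignment depends
#' only on per-filament counts and ids and is therefore stable under row
#' reordering. Symmetry-expanded subunits of one segment always stay in
#' the same half.
#'
#' @param records Alignment table with `filament` ids (>= 2 filaments).
#' @return List with `half1`, `half2` (record subsets) and `records`
#'   (full table with the `half` column filled).
#' @export
split_halves <- function(records) {
  counts <- table(records$filament)
  if (length(counts) < 2L)
    stop("gold-standard split needs at least two filaments")
  ord <- order(-as.integer(counts), as.numeric(names(counts)))
  tot <- c(0, 0)
  assign <- integer(length(counts))
  for (i in ord) {
    h <- if (tot[1] <= tot[2]) 1L else 2L
    assign[i] <- h
    tot[h] <- tot[h] + as.integer(counts[i])
  }
  names(assign) <- names(counts)
  records$half <- assign[as.character(records$filament)]
  list(half1 = records[records$half == 1L, , drop = FALSE],
       half2 = records[records$half == 2L, , drop = FALSE],
       records = records)
}

#' Fourier shell correlation between two volumes
#'
#' Per-shell normalized cross-correlation of the (optionally soft-
#' masked) volumes. Shells are one Fourier voxel wide.
#'
#' @param vol_a,vol_b [volume_grid()]s on the same grid.
#' @param mask Optional `soft_mask` (values in \[0, 1\]) applied to both.
#' @return A data.frame of class `fsc_curve` with columns `shell`,
#'   `freq` (1/Angstrom) and `fsc`.
#' @export
fsc <- function(vol_a, vol_b, mask = NULL) {
  if (!identical(dim(vol_a$data), dim(vol_b$data)))
    stop("volumes must share the same grid")
  n <- dim(vol_a$data)[1]; apix <- vol_a$apix
  a <- vol_a$data; b <- vol_b$data
  if (!is.null(mask)) { a <- a * mask$data; b <- b * mask$data }
  Fa <- fft(a); Fb <- fft(b)
  f <- freq_index(n)
  fx <- array(f, c(n, n, n))
  r <- sqrt(fx^2 + aperm(fx, c(2, 1, 3))^2 + aperm(fx, c(3, 2, 1))^2)
  shell <- pmin(round(r), n %/% 2L)
  num <- as.numeric(tapply(Re(Fa * Conj(Fb)), shell, sum))
  da <- as.numeric(tapply(abs(Fa)^2, shell, sum))
  db <- as.numeric(tapply(abs(Fb)^2, shell, sum))
  k <- sort(unique(as.integer(names(table(shell)))))
  curve <- data.frame(shell = k, freq = k / (n * apix),
                      fsc = num / sqrt(pmax(da * db, 1e-300)))
  curve <- curve[curve$shell <= n %/% 2L, ]
  class(curve) <- c("fsc_curve", class(curve))
  attr(curve, "apix") <- apix; attr(curve, "n") <- n
  curve
}

#' Resolution at an FSC threshold
#'
#' First crossing of the curve below the threshold, linearly
#' interpolated between shells; a curve that never drops below the
#' threshold reports the Nyquist resolution (2 x pixel size).
#'
#' @param curve An [fsc()] result.
#' @param threshold FSC threshold (default the 0.143 gold-standard
#'   criterion).
#' @return Resolution in Angstrom.
#' @export
resolution_at <- function(curve, threshold = 0.143) {
  freq <- curve$freq; v <- curve$fsc
  below <- which(v < threshold & freq > 0)
  if (!length(below)) return(2 * attr(curve, "apix"))
  i <- below[1]
  if (i == 1L) return(Inf)
  f <- freq[i - 1] + (threshold - v[i - 1]) * (freq[i] - freq[i - 1]) /
    (v[i] - v[i - 1])
  1 / f
}

#' @export
plot.fsc_curve <- function(x, threshold = 0.143, ...) {
  graphics::plot(x$freq, x$fsc, type = "l", xlab = "spatial frequency (1/A)",
                 ylab = "FSC", ylim = c(min(0, min(x$fsc)), 1), ...)
  graphics::abline(h = threshold, lty = 2, col = "grey40")
  res <- resolution_at(x, threshold)
  if (is.finite(res))
    graphics::abline(v = 1 / res, lty = 3, col = "grey40")
  invisible(x)
}

#' Low-pass filter a map to a target resolution
#'
#' Cosine-edged global filter, used in place of local
#' filtering/sharpening: after FSC estimation the final maps are
#' filtered at the masked FSC resolution.
#'
#' @param vol A [volume_grid()].
#' @param resolution_A Cutoff resolution, Angstrom.
#' @return Filtered [volume_grid()].
#' @export
filter_to_resolution <- function(vol, resolution_A) {
  volume_grid(lowpass_volume(vol$data, vol$apix, resolution_A), vol$apix)
}
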