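#' Helical symmetry of a decorated filament
#'
#' The screw operator relating successive asymmetric units of a helical
#' assembly: a rotation by `twist` degrees about the helical axis (the
#' volume z axis) combined with a translation of `rise` Angstrom along it.
#' For a 15-start ("15R") decorated microtubule the refined lattice values
#' are close to rise 5.45 A and twist 168.08 degrees, and one boxed
#' filament segment carries 15 asymmetric units (`n_expand = 15`).
#'
#' @param rise Axial translation per subunit, Angstrom (> 0).
#' @param twist Rotation per subunit, degrees (|twist| <= 360).
#' @param n_expand Number of asymmetric units expanded per segment (>= 1).
#' @param handedness `"right"` (default) or `"left"`; flips the sign of the
#'   twist actually applied. The printed twist of a helical lattice does
#'   not fix its hand, so both are supported.
#' @return An object of class `helical_symmetry`.
#' @examples
#' sym <- helical_symmetry(rise = 5.45, twist = 168.08, n_expand = 15)
#' sym
#' @export
helical_symmetry <- function(rise = 5.45, twist = 168.08, n_expand = 15L,
                             handedness = c("right", "left")) {
  handedness <- match.arg(handedness)
  stopifnot(is.numeric(rise), length(rise) == 1L, rise > 0,
            is.numeric(twist), length(twist) == 1L, abs(twist) <= 360,
            n_expand >= 1L)
  structure(list(rise = rise, twist = twist, n_expand = as.integer(n_expand),
                 handedness = handedness),
            class = "helical_symmetry")
}

#' @export
print.helical_symmetry <- function(x, ...) {
  cat(sprintf("Helical symmetry: rise %.3f A, twist %.3f deg (%s-handed), %d asymmetric units/segment\n",
              x$rise, x$twist, x$handedness, x$n_expand))
  invisible(x)
}

## Signed twist actually applied by the screw operator.
signed_twist <- function(sym) if (sym$handedness == "right") sym$twist else -sym$twist

#' Screw transform for the k-th symmetry-related subunit
#'
#' Returns the rigid transform `S_k: p -> Rz(k * twist) p + k * rise * ez`
#' placing the canonical subunit at the position of subunit `k`. The
#' family satisfies the composition law `S_k1 o S_k2 = S_(k1+k2)`.
#'
#' @param sym A [helical_symmetry()].
#' @param k Integer subunit offset (any sign).
#' @return A list with elements `R` (3x3 rotation) and `t` (length-3
#'   translation, Angstrom), class `rigid_transform`.
#' @examples
#' s <- screw_transform(helical_symmetry(5.5, 168.09), 2)
#' s$t[3]  # 11.0
#' @export
screw_transform <- function(sym, k) {
  stopifnot(inherits(sym, "helical_symmetry"), length(k) == 1L)
  structure(list(R = rot_z(k * signed_twist(sym)),
                 t = c(0, 0, k * sym$rise)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform (rotation + translation, Angstrom):\n")
  print(round(x$R, 6)); cat("t =", format(x$t), "\n")
  invisible(x)
}

## Apply a rigid transform to points (n x 3 matrix or length-3 vector).
apply_transform <- function(tr, pts) {
  pts <- rbind(pts)
  sweep(pts %*% t(tr$R), 2, tr$t, "+")
}

#' Construct a particle alignment table
#'
#' One row per boxed segment (or, after expansion, per subunit): Euler
#' angles (degrees, ZYZ), image-plane shifts (Angstrom), per-particle CTF
#' state, filament bookkeeping and the gold-standard half-set label.
#'
#' @param n Number of records, used only when no columns are given.
#' @param ... Column overrides; any of `image`, `filament`, `position`,
#'   `rot`, `tilt`, `psi`, `sx`, `sy`, `dfu`, `dfv`, `dfang`, `zoff`,
#'   `half`, `subunit`, `class`.
#' @return A `data.frame` with the full column set.
#' @export
particle_records <- function(n = NULL, ...) {
  cols <- list(...)
  if (is.null(n)) {
    n <- if (length(cols)) max(vapply(cols, length, 1L)) else 0L
  }
  def <- list(image = seq_len(n), filament = rep(1L, n),
              position = rep(0L, n),
              rot = numeric(n), tilt = rep(90, n), psi = numeric(n),
              sx = numeric(n), sy = numeric(n),
              dfu = rep(15000, n), dfv = rep(15000, n), dfang = numeric(n),
              zoff = numeric(n), half = rep(1L, n),
              subunit = rep(0L, n), class = rep(NA_integer_, n))
  for (nm in names(cols)) {
    if (!nm %in% names(def)) stop("unknown record column: ", nm)
    def[[nm]] <- rep_len(cols[[nm]], n)
  }
  as.data.frame(def)
}

record_rotations <- function(records) {
  euler_matrix(records$rot, records$tilt, records$psi)
}

#' Symmetry-expand an alignment table
#'
#' Replicates each segment record once per asymmetric unit, composing its
#' pose with the k-th screw transform so that the expanded record views
#' subunit k at the canonical (central) position. Output length is exactly
#' `n_expand` times the input length; filament ids, defocus and half-set
#' labels are propagated, `subunit` is set to k, and the out-of-plane
#' component of the screw translation is accumulated into `zoff` (the
#' subunit's position along the optical axis, used later as a defocus
#' offset).
#'
#' @param records Alignment table as from [particle_records()].
#' @param sym A [helical_symmetry()].
#' @return The expanded alignment table (`nrow = n_expand * nrow(records)`),
#'   ordered with all subunits of record 1 first.
#' @export
symmetry_expand <- function(records, sym) {
  stopifnot(inherits(sym, "helical_symmetry"))
  if (nrow(records) == 0L) return(records)
  ne <- sym$n_expand
  tw <- signed_twist(sym)
  idx <- rep(seq_len(nrow(records)), each = ne)
  k <- rep(seq_len(ne) - 1L, times = nrow(records))
  out <- records[idx, , drop = FALSE]
  rownames(out) <- NULL
  out$subunit <- k
  if (ne == 1L) return(out)
  ## axial translation of subunit k, rotated into the image frame
  Rm <- record_rotations(records)
  if (length(dim(Rm)) == 2L) Rm <- array(Rm, c(3, 3, 1))
  ax <- t(apply(Rm, 3, function(R) R[, 3]))   # image-frame direction of ez
  axr <- ax[idx, , drop = FALSE]
  d <- k * sym$rise
  out$rot <- out$rot + k * tw
  out$sx <- out$sx + d * axr[, 1]
  out$sy <- out$sy + d * axr[, 2]
  out$zoff <- out$zoff + d * axr[, 3]
  out
}

#' Project a 3D point through a particle's pose
#'
#' Image-plane position (and beam-axis depth) of a volume-frame point
#' under a record's orientation and shifts: `(dx, dy) = (R p)[1:2] + (sx,
#' sy)` and `depth_z = (R p)[3] + zoff`. The depth output is the point's
#' coordinate along the optical axis and feeds the per-subunit defocus
#' adjustment.
#'
#' @param record A single-row alignment table (or a list with the pose
#'   fields).
#' @param point Length-3 numeric, Angstrom, volume frame.
#' @return Named numeric vector `c(dx, dy, depth_z)` in Angstrom.
#' @export
project_point <- function(record, point) {
  stopifnot(length(point) == 3L)
  R <- euler_matrix(record$rot[1], record$tilt[1], record$psi[1])
  v <- as.numeric(R %*% point)
  c(dx = v[1] + record$sx[1], dy = v[2] + record$sy[1],
    depth_z = v[3] + record$zoff[1])
}
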