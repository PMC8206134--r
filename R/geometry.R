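## Rotation utilities. Angles in degrees throughout the user-facing API.

deg2rad <- function(x) x * pi / 180

rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_y <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}

#' Euler angles to rotation matrix (intrinsic ZYZ)
#'
#' Builds the matrix mapping volume-frame points to image-frame points,
#' `R = Rz(psi) %*% Ry(tilt) %*% Rz(rot)`, the standard single-particle
#' convention. The projection direction (beam) is the image-frame +z axis.
#'
#' @param rot,tilt,psi Euler angles in degrees (vectorised).
#' @return A 3x3 matrix, or a `3 x 3 x n` array when the inputs have
#'   length > 1.
#' @examples
#' euler_matrix(0, 0, 0)          # identity
#' euler_matrix(90, 0, 0)[1, 2]   # Rz(90) sends y to -x
#' @export
euler_matrix <- function(rot, tilt, psi) {
  n <- max(length(rot), length(tilt), length(psi))
  rot <- rep_len(rot, n); tilt <- rep_len(tilt, n); psi <- rep_len(psi, n)
  if (n == 1L) return(rot_z(psi) %*% rot_y(tilt) %*% rot_z(rot))
  out <- array(0, c(3, 3, n))
  for (i in seq_len(n)) out[, , i] <- rot_z(psi[i]) %*% rot_y(tilt[i]) %*% rot_z(rot[i])
  out
}

## Flatten a 3x3xN rotation array into the 9xN layout the C++ kernels take.
flatten_rots <- function(R) {
  if (length(dim(R)) == 2L) R <- array(R, c(3, 3, 1))
  matrix(R, nrow = 9L)
}
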