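#' Cubic density volume with physical pixel size
#'
#' @param data Cubic 3D numeric array.
#' @param apix Pixel size, Angstrom per voxel (> 0).
#' @return An object of class `volume_grid`. The box centre (voxel `n/2`,
#'   0-based) is the coordinate origin; the helical axis is z.
#' @export
volume_grid <- function(data, apix) {
  d <- dim(data)
  stopifnot(length(d) == 3L, d[1] == d[2], d[2] == d[3], apix > 0)
  structure(list(data = data, apix = apix), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  n <- dim(x$data)[1]
  cat(sprintf("volume_grid: %d^3 voxels, %.3f A/px (box %.1f A), range [%.4g, %.4g]\n",
              n, x$apix, n * x$apix, min(x$data), max(x$data)))
  invisible(x)
}

#' Stack of square particle images
#'
#' @param data `n x n x N` numeric array (one image per slice along the
#'   third dimension).
#' @param apix Pixel size, Angstrom per pixel.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, apix) {
  d <- dim(data)
  if (length(d) == 2L) { data <- array(data, c(d, 1L)); d <- dim(data) }
  stopifnot(length(d) == 3L, d[1] == d[2], apix > 0)
  structure(list(data = data, apix = apix), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("image_stack: %d images of %d x %d px at %.3f A/px\n",
              d[3], d[1], d[2], x$apix))
  invisible(x)
}

n_images <- function(stack) dim(stack$data)[3]
box_size <- function(x) dim(x$data)[1]

## Images as an (n^2 x N) matrix (column per image) without copying layout.
stack_as_matrix <- function(stack) {
  d <- dim(stack$data)
  m <- stack$data
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

matrix_as_stack <- function(m, n, apix) {
  N <- ncol(m)
  dim(m) <- c(n, n, N)
  image_stack(m, apix)
}
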