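## Minimal MRC2014 reader/writer (mode 2, 32-bit float, little-endian).
## Covers maps (MRC) and particle stacks (MRCS); no installed R package
## reads this format, so the 1024-byte header is handled here directly.

#' Write a volume or image stack to an MRC/MRCS file
#'
#' Mode-2 (float32) MRC2014 with the pixel size recorded in the cell
#' dimensions. Volumes write `nz = n`; stacks write one image per section.
#'
#' @param x A [volume_grid()] or [image_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(x, path) {
  d <- dim(x$data)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4L, endian = "little")
  wi(d)                          # nx ny nz
  wi(2L)                         # mode 2 = float32
  wi(c(0L, 0L, 0L))              # nxstart
  wi(d)                          # mx my mz
  wf(d * x$apix)                 # cell a b c
  wf(c(90, 90, 90))              # angles
  wi(c(1L, 2L, 3L))              # mapc mapr maps
  wf(c(min(x$data), max(x$data), mean(x$data)))
  wi(c(0L, 0L))                  # ispg, nsymbt
  writeBin(raw(100), con)        # extra
  wf(c(0, 0, 0))                 # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machine stamp LE
  wf(stats::sd(as.numeric(x$data)))
  wi(0L)                         # nlabl
  writeBin(raw(800), con)        # labels
  writeBin(as.numeric(x$data), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read an MRC/MRCS file
#'
#' @param path File path.
#' @param as `"auto"` (volume if nx == ny == nz, else stack), `"volume"`
#'   or `"stack"`.
#' @return A [volume_grid()] or [image_stack()].
#' @export
read_mrc <- function(path, as = c("auto", "volume", "stack")) {
  as <- match.arg(as)
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", k, size = 4L, endian = "little")
  rf <- function(k) readBin(con, "numeric", k, size = 4L, endian = "little")
  d <- ri(3)
  mode <- ri(1)
  if (mode != 2L) stop("only mode-2 (float32) MRC files are supported, got mode ", mode)
  ri(3)                                   # nxstart
  mx <- ri(3)
  cell <- rf(3)
  apix <- if (mx[1] > 0) cell[1] / mx[1] else 1
  seek(con, 1024L)
  vals <- readBin(con, "numeric", prod(d), size = 4L, endian = "little")
  arr <- array(vals, d)
  vol <- d[1] == d[2] && d[2] == d[3]
  if (as == "volume" || (as == "auto" && vol)) return(volume_grid(arr, apix))
  image_stack(arr, apix)
}
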