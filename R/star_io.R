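## STAR-dialect alignment tables: a single data block with a loop_ header
## and one row per particle, using conventional column names for the
## standard fields.

star_column_map <- c(
  image    = "_rlnImageId",
  filament = "_rlnHelicalTubeID",
  position = "_hxPositionIndex",
  rot      = "_rlnAngleRot",
  tilt     = "_rlnAngleTilt",
  psi      = "_rlnAnglePsi",
  sx       = "_rlnOriginXAngst",
  sy       = "_rlnOriginYAngst",
  dfu      = "_rlnDefocusU",
  dfv      = "_rlnDefocusV",
  dfang    = "_rlnDefocusAngle",
  zoff     = "_hxAxialOffsetAngst",
  half     = "_rlnRandomSubset",
  subunit  = "_hxSubunitIndex",
  class    = "_rlnClassNumber")

#' Write an alignment table as a STAR-dialect text file
#'
#' @param records Alignment table ([particle_records()] layout).
#' @param path Output path.
#' @param block Data block name.
#' @return `path`, invisibly.
#' @export
write_star <- function(records, path, block = "particles") {
  cols <- names(records)
  labels <- ifelse(cols %in% names(star_column_map),
                   star_column_map[cols], paste0("_hx", cols))
  lines <- c(paste0("data_", block), "", "loop_",
             paste0(labels, " #", seq_along(labels)))
  body <- do.call(paste, c(lapply(records, function(v) {
    if (is.numeric(v) && !is.integer(v)) sprintf("%.6f", v) else as.character(v)
  }), sep = "\t"))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a STAR-dialect alignment table
#'
#' Parses the first `loop_` block; columns with known conventional names
#' are mapped back to the package's record layout.
#'
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_star <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  li <- which(trimws(lines) == "loop_")
  if (!length(li)) stop("no loop_ block found in ", path)
  i <- li[1] + 1L
  labels <- character()
  while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
    labels <- c(labels, sub("\\s+#.*$", "", trimws(lines[i])))
    i <- i + 1L
  }
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  body <- body[!grepl("^data_", body)]
  rows <- strsplit(trimws(body), "\\s+")
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  rev_map <- stats::setNames(names(star_column_map), star_column_map)
  names(df) <- ifelse(labels %in% names(rev_map), rev_map[labels],
                      sub("^_hx", "", labels))
  for (nm in names(df)) {
    v <- utils::type.convert(df[[nm]], as.is = TRUE)
    if (nm %in% c("image", "filament", "position", "half", "subunit", "class"))
      v <- as.integer(v)
    df[[nm]] <- v
  }
  df
}

#' Read or write helical symmetry as JSON
#'
#' The on-disk form is `{"rise_A": ..., "twist_deg": ..., "n_expand": ...,
#' "handedness": ...}`.
#'
#' @param sym A [helical_symmetry()].
#' @param path JSON file path.
#' @return For the reader, a [helical_symmetry()]; the writer returns
#'   `path` invisibly.
#' @export
write_symmetry_json <- function(sym, path) {
  jsonlite::write_json(list(rise_A = sym$rise, twist_deg = sym$twist,
                            n_expand = sym$n_expand, handedness = sym$handedness),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_symmetry_json
#' @export
read_symmetry_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  helical_symmetry(rise = j$rise_A, twist = j$twist_deg,
                   n_expand = j$n_expand,
                   handedness = if (is.null(j$handedness)) "right" else j$handedness)
}
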