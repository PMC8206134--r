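#' Gaussian pseudo-atom phantom of a decorated-filament subunit
#'
#' The phantom emulates one asymmetric unit of a kinesin-decorated
#' 15-start microtubule: a tubulin-like lattice body plus a motor-domain
#' core shared by both conformations, a discriminating marker blob whose
#' position differs between the "open" and "closed" conformers (the
#' KH0-like shift), a short rod present only in the closed conformer (the
#' docked neck-linker), and linker blobs joining a trailing subunit to the
#' leading subunit one axial dimer-repeat up the protofilament.
#'
#' All blob tables have columns `x, y, z` (Angstrom, subunit frame with
#' the helical axis through the box centre), `sd` and `w`.
#'
#' @param voxel_size Angstrom per voxel.
#' @param box Box size in voxels.
#' @param body_blobs Shared blobs (tubulin body + motor core).
#' @param marker_open,marker_closed Alternate marker blob positions;
#'   the default displacement between them is 8 Angstrom.
#' @param necklinker_rod Blobs present only in the closed conformer.
#' @param dimer_linker Blobs joining a trailing subunit to the next
#'   leading subunit, in the trailing subunit's frame.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size = 4, box = 64L,
                         body_blobs = NULL,
                         marker_open = NULL, marker_closed = NULL,
                         necklinker_rod = NULL, dimer_linker = NULL) {
  blob_df <- function(x, y, z, sd, w) data.frame(x = x, y = y, z = z, sd = sd, w = w)
  ## the tube wall sits well inside the box and the motor domains decorate
  ## a wider shell, so the beam column through one motor crosses few others
  if (is.null(body_blobs))
    body_blobs <- blob_df(c(45, 72), c(0, 0), c(0, 0), c(7, 6), c(1.0, 0.9))
  ## the marker is a mobile subdomain carrying a sizable share of the
  ## motor density (the open/closed transition repositions whole
  ## subdomains, not a side chain); its centre moves 8 A between states
  if (is.null(marker_open))
    marker_open <- blob_df(82, 2.83, -2.83, 5.5, 2.0)
  if (is.null(marker_closed))
    marker_closed <- blob_df(82, -2.83, 2.83, 5.5, 2.0)
  if (is.null(necklinker_rod))
    necklinker_rod <- blob_df(c(68, 64), c(0, 0), c(9, 16), c(4.5, 4.5), c(0.5, 0.5))
  if (is.null(dimer_linker)) {
    ## interpolate between the motor core and its image one dimer repeat
    ## (15 subunits) up the protofilament of a canonical 15R lattice
    s15 <- screw_transform(helical_symmetry(), 15L)
    a <- c(72, 0, 0); b <- as.numeric(s15$R %*% a + s15$t)
    tt <- c(0.35, 0.65)
    pts <- sapply(tt, function(t) (1 - t) * a + t * b)
    ## the linker stands in for two neck-linkers plus the dimerization
    ## coiled coil -- a substantial connecting density
    dimer_linker <- blob_df(pts[1, ], pts[2, ], pts[3, ], c(6, 6), c(0.8, 0.8))
  }
  spec <- structure(list(voxel_size = voxel_size, box = as.integer(box),
                         body_blobs = body_blobs, marker_open = marker_open,
                         marker_closed = marker_closed,
                         necklinker_rod = necklinker_rod,
                         dimer_linker = dimer_linker),
                    class = "phantom_spec")
  half <- box * voxel_size / 2
  conf <- rbind(body_blobs, marker_open, marker_closed, necklinker_rod)
  if (any(abs(conf[, c("x", "y", "z")]) >= half))
    stop("phantom blob centre outside the box")
  if (any(conf$w <= 0) || any(dimer_linker$w <= 0))
    stop("phantom blob weights must be positive")
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("phantom_spec: %d^3 box at %g A/px; %d body, 1 marker (d = %.1f A), %d rod, %d linker blobs\n",
              x$box, x$voxel_size, nrow(x$body_blobs),
              sqrt(sum((x$marker_open[1, c("x", "y", "z")] -
                        x$marker_closed[1, c("x", "y", "z")])^2)),
              nrow(x$necklinker_rod), nrow(x$dimer_linker)))
  invisible(x)
}

conformer_blobs <- function(spec, label) {
  if (label == "open") rbind(spec$body_blobs, spec$marker_open)
  else rbind(spec$body_blobs, spec$marker_closed, spec$necklinker_rod)
}

#' Rasterize the open and closed conformer volumes
#'
#' Each volume is the sum of the phantom's Gaussian blobs on the grid;
#' the two differ only in the marker position and the neck-linker rod.
#'
#' @param spec A [phantom_spec()].
#' @return List with `open` and `closed` [volume_grid()]s.
#' @export
build_conformer_volumes <- function(spec) {
  render <- function(b) {
    volume_grid(cpp_render_gauss3d(as.matrix(b[, c("x", "y", "z")]),
                                   b$sd, b$w, spec$box, spec$voxel_size),
                spec$voxel_size)
  }
  list(open = render(conformer_blobs(spec, "open")),
       closed = render(conformer_blobs(spec, "closed")))
}

#' Draw per-subunit ground-truth conformation labels
#'
#' Mixture mode assigns independent Bernoulli(`fraction_open`) labels.
#' Dimer mode tiles each protofilament with trailing/leading pairs:
#' subunits are indexed along the 1-start helix, with protofilament
#' `(j-1) %% n_protofilaments` and axial ring `(j-1) %/% n_protofilaments`;
#' even rings are trailing (closed), odd rings leading (open), and each
#' trailing subunit pairs with the subunit one ring up the same
#' protofilament.
#'
#' @param mode `"mixture"` or `"dimer"`.
#' @param n_subunits Number of subunits (even, and in dimer mode a
#'   multiple of `2 * n_protofilaments` so every pair is complete).
#' @param fraction_open Open-state probability in mixture mode.
#' @param seed Integer seed (labels are reproducible).
#' @param n_protofilaments Protofilament count of the lattice.
#' @return An object of class `ground_truth` with `labels` (character),
#'   `mode`, `fraction_open`, `pairing` (dimer mode) and `seed`.
#' @export
make_labels <- function(mode = c("mixture", "dimer"), n_subunits,
                        fraction_open = 0.7, seed = 1,
                        n_protofilaments = 15L) {
  mode <- match.arg(mode)
  n <- as.integer(n_subunits)
  pairing <- NULL
  if (mode == "mixture") {
    set.seed(seed)
    labels <- ifelse(runif(n) < fraction_open, "open", "closed")
  } else {
    if (n %% 2L != 0L) stop("dimer mode requires an even number of subunits")
    if (n %% (2L * n_protofilaments) != 0L)
      stop("dimer mode requires n_subunits to be a multiple of 2 * n_protofilaments")
    r <- (seq_len(n) - 1L) %/% n_protofilaments
    labels <- ifelse(r %% 2L == 0L, "closed", "open")
    tr <- which(r %% 2L == 0L)
    pairing <- data.frame(trailing = tr, leading = tr + n_protofilaments)
  }
  structure(list(labels = labels, mode = mode, fraction_open = fraction_open,
                 pairing = pairing, seed = seed,
                 n_protofilaments = as.integer(n_protofilaments)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d subunits, mode %s, %.1f%% open\n",
              length(x$labels), x$mode, 100 * mean(x$labels == "open")))
  invisible(x)
}

## Extend a filament's core label sequence by `margin` subunits on both
## sides using the same generative rule (deterministic per filament).
extend_labels <- function(core, mode, fraction_open, margin, seed, npf = 15L) {
  n <- length(core)
  if (mode == "dimer") {
    j <- seq(-margin, n - 1L + margin)
    r <- j %/% npf  # floor division handles negatives
    ## the filament's slice of the global lattice may start on either ring
    ## parity; take the trailing/leading phase from the first core label
    phase <- if (core[1] == "closed") 0L else 1L
    lab <- ifelse((r + phase) %% 2L == 0L, "closed", "open")
    lab[j >= 0L & j < n] <- core
    return(lab)
  }
  set.seed(seed)
  extra <- ifelse(runif(2L * margin) < fraction_open, "open", "closed")
  c(extra[seq_len(margin)], core, extra[margin + seq_len(margin)])
}

#' Simulate a decorated-filament particle stack with ground truth
#'
#' Builds labelled helical scenes and projects boxed segments: each
#' filament receives a random orientation (tilt ~ 90 +/- jitter, psi and
#' rot uniform), consecutive segments advance the in-plane rotation by one
#' segment repeat (`n_expand` subunits), a defocus is drawn per segment
#' from the stated range, the CTF is applied in the Fourier domain, and
#' white Gaussian noise of the requested sigma is added. Per-subunit
#' lattice displacements (`lattice_jitter_A`) emulate local lattice
#' disorder. A fixed seed gives a bit-reproducible stack.
#'
#' The ground-truth labels live only in the returned `truth` object;
#' no downstream algorithm reads them.
#'
#' @param spec A [phantom_spec()].
#' @param sym A [helical_symmetry()].
#' @param truth Optional [make_labels()] result for the
#'   `n_expand * n_segments` core subunits; generated when `NULL`.
#' @param n_segments Total number of boxed segments.
#' @param n_filaments Number of filaments the segments are split across.
#' @param mode,fraction_open Passed to [make_labels()] when `truth` is NULL.
#' @param tilt_jitter_deg Standard deviation of the out-of-plane tilt
#'   around 90 degrees.
#' @param defocus_range_A Two-element underfocus range, Angstrom
#'   (default 1.0-1.9 um).
#' @param noise_sigma White-noise standard deviation (image units).
#' @param lattice_jitter_A Per-subunit isotropic 3D displacement sd.
#' @param shift_jitter_A In-plane boxing error sd recorded in the table.
#' @param ctf A [ctf_params()] with the microscope constants, or `NULL`
#'   for an identity CTF.
#' @param seed Integer seed.
#' @return A list of class `hasrc_simulation`: `stack` ([image_stack()]),
#'   `records` (one row per segment), `truth` ([make_labels()] plus the
#'   per-filament layout), `sym`, `spec`, `ctf`.
#' @export
simulate_stack <- function(spec, sym, truth = NULL,
                           n_segments = 20L, n_filaments = 4L,
                           mode = c("mixture", "dimer"), fraction_open = 0.7,
                           tilt_jitter_deg = 2, defocus_range_A = c(10000, 19000),
                           noise_sigma = 0, lattice_jitter_A = 0,
                           shift_jitter_A = 0,
                           ctf = ctf_params(pixel_size = spec$voxel_size),
                           seed = 1) {
  mode <- match.arg(mode)
  n <- spec$box; apix <- spec$voxel_size
  ne <- sym$n_expand
  if (!is.null(ctf) && abs(ctf$pixel_size - apix) > 1e-9)
    stop("CTF pixel size must match the phantom voxel size")
  n_filaments <- min(n_filaments, n_segments)
  if (is.null(truth))
    truth <- make_labels(mode, ne * n_segments, fraction_open, seed = seed + 1L)
  if (length(truth$labels) != ne * n_segments)
    stop("truth has ", length(truth$labels), " labels; need ", ne * n_segments)

  half_span <- n * apix / 2
  margin <- as.integer(ceiling((half_span + 30) / sym$rise) + 1L)
  if (2 * margin * sym$rise < n * apix)
    stop("box too small to contain the masked span of the filament")
  tw <- signed_twist(sym)

  ## distribute segments across filaments
  per <- rep(n_segments %/% n_filaments, n_filaments)
  extra <- n_segments %% n_filaments
  if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L

  set.seed(seed)
  seg_rows <- list(); centers_all <- list(); sd_all <- list(); w_all <- list()
  img_idx_all <- list()
  img <- 0L
  off <- 0L  # core-label offset of the current filament
  truth$layout <- data.frame(filament = integer(), offset = integer(),
                             n_core = integer())
  for (f in seq_len(n_filaments)) {
    M <- per[f]
    n_core <- ne * M
    core <- truth$labels[off + seq_len(n_core)]
    ext <- extend_labels(core, truth$mode, truth$fraction_open, margin,
                         seed = seed + 1000L + f, npf = truth$n_protofilaments)
    set.seed(seed + 2000L + f)
    tilt <- 90 + rnorm(1) * tilt_jitter_deg
    psi <- runif(1, 0, 360)
    rot0 <- runif(1, 0, 360)
    disp <- if (lattice_jitter_A > 0)
      matrix(rnorm(3L * length(ext), sd = lattice_jitter_A), ncol = 3L)
    else matrix(0, length(ext), 3L)
    for (m in seq_len(M) - 1L) {
      img <- img + 1L
      rot <- (rot0 + m * ne * tw) %% 360
      sx <- rnorm(1) * shift_jitter_A; sy <- rnorm(1) * shift_jitter_A
      df <- runif(1, defocus_range_A[1], defocus_range_A[2])
      R <- euler_matrix(rot, tilt, psi)
      base <- m * ne  # 0-based core index of this segment's subunit 0
      ks <- seq(-margin, ne - 1L + margin)
      blb <- segment_blobs(spec, sym, ext, disp, base, ks, margin,
                           dimer = truth$mode == "dimer")
      p2 <- blb$centers %*% t(R)  # world -> image frame
      centers_all[[img]] <- cbind(p2[, 1] + sx, p2[, 2] + sy)
      sd_all[[img]] <- blb$sd
      w_all[[img]] <- blb$w * blb$sd * sqrt(2 * pi)  # line-integral weight
      img_idx_all[[img]] <- rep.int(img, length(blb$sd))
      seg_rows[[img]] <- data.frame(image = img, filament = f, position = m,
                                    rot = rot, tilt = tilt, psi = psi,
                                    sx = sx, sy = sy, dfu = df, dfv = df,
                                    dfang = 0, zoff = 0,
                                    half = if (f %% 2L == 1L) 1L else 2L,
                                    subunit = 0L, class = NA_integer_)
    }
    truth$layout <- rbind(truth$layout,
                          data.frame(filament = f, offset = off, n_core = n_core))
    off <- off + n_core
  }
  records <- do.call(rbind, seg_rows)
  rownames(records) <- NULL

  m2 <- cpp_render_gauss2d_stack(do.call(rbind, centers_all),
                                 unlist(sd_all), unlist(w_all),
                                 unlist(img_idx_all), n, apix, img)
  if (!is.null(ctf)) {
    for (i in seq_len(img)) {
      p <- ctf_params(voltage = ctf$voltage, cs = ctf$cs,
                      amplitude_contrast = ctf$amplitude_contrast,
                      defocus_u = records$dfu[i], defocus_v = records$dfv[i],
                      astig_angle = records$dfang[i], pixel_size = apix)
      m2[, i] <- as.numeric(Re(ifft2(fft2(matrix(m2[, i], n, n)) *
                                       ctf_image(p, n, apix))))
    }
  }
  if (noise_sigma > 0) {
    set.seed(seed + 9L)
    m2 <- m2 + matrix(rnorm(length(m2), sd = noise_sigma), nrow(m2))
  }
  structure(list(stack = matrix_as_stack(m2, n, apix), records = records,
                 truth = truth, sym = sym, spec = spec, ctf = ctf,
                 noise_sigma = noise_sigma, seed = seed),
            class = "hasrc_simulation")
}

## World-frame blob list for one segment: subunits at screw positions `ks`
## (relative to the segment's subunit 0), with conformers chosen by the
## extended label vector and per-subunit displacements added. In dimer
## lattices every trailing (closed) subunit also carries the linker blobs
## joining it to its leading partner, expressed in the trailing frame.
segment_blobs <- function(spec, sym, ext_labels, disp, base, ks, margin,
                          dimer = FALSE) {
  centers <- list(); sds <- list(); ws <- list()
  i <- 0L
  for (k in ks) {
    li <- base + k + margin + 1L  # index into ext_labels
    lab <- ext_labels[li]
    b <- conformer_blobs(spec, lab)
    if (dimer && lab == "closed") b <- rbind(b, spec$dimer_linker)
    S <- screw_transform(sym, k)
    p <- as.matrix(b[, c("x", "y", "z")]) %*% t(S$R)
    p <- sweep(p, 2, S$t, "+")
    p <- sweep(p, 2, disp[li, ], "+")
    i <- i + 1L
    centers[[i]] <- p; sds[[i]] <- b$sd; ws[[i]] <- b$w
  }
  list(centers = do.call(rbind, centers), sd = unlist(sds), w = unlist(ws))
}

#' Render the 3D scene around one segment
#'
#' Rasterizes the labelled lattice in the segment (volume) frame: subunit
#' k at the k-th screw position, conformer chosen by `labels`. Used for
#' projector oracles, mask construction and round-trip tests.
#'
#' @param spec A [phantom_spec()].
#' @param sym A [helical_symmetry()].
#' @param labels Either a single label recycled for every subunit or a
#'   vector indexed over `ks`.
#' @param ks Integer screw positions to render (default: every subunit
#'   whose centre can fall inside the box).
#' @param dimer Add linker blobs to closed subunits.
#' @return A [volume_grid()].
#' @export
scene_volume <- function(spec, sym, labels = "open", ks = NULL, dimer = FALSE) {
  n <- spec$box; apix <- spec$voxel_size
  if (is.null(ks)) {
    margin <- ceiling((n * apix / 2 + 30) / sym$rise)
    ks <- seq(-margin, margin)
  }
  labels <- rep_len(labels, length(ks))
  ext <- labels
  disp <- matrix(0, length(ks), 3L)
  blb <- segment_blobs(spec, sym, ext, disp, base = 0L, ks = ks,
                       margin = -min(ks), dimer = dimer)
  volume_grid(cpp_render_gauss3d(blb$centers, blb$sd, blb$w, n, apix), apix)
}

#' Noise level for a target signal-to-noise ratio
#'
#' Renders a small noiseless batch under the same conditions and returns
#' the white-noise standard deviation giving `var(signal) / sigma^2 =
#' snr`, with the signal variance measured over whole segment images.
#'
#' @param spec,sym,ctf,mode,fraction_open,seed As in [simulate_stack()].
#' @param snr Target variance SNR.
#' @param n_probe Number of probe segments used for the estimate.
#' @return Noise standard deviation (image units).
#' @export
sigma_for_snr <- function(spec, sym, snr, ctf = ctf_params(pixel_size = spec$voxel_size),
                          mode = "mixture", fraction_open = 0.7,
                          n_probe = 12L, seed = 1) {
  sim <- simulate_stack(spec, sym, n_segments = n_probe, n_filaments = 3L,
                        mode = mode, fraction_open = fraction_open,
                        noise_sigma = 0, ctf = ctf, seed = seed)
  v <- mean(apply(sim$stack$data, 3, var))
  sqrt(v / snr)
}

#' Ground-truth labels for (expanded) alignment records
#'
#' Maps each record's `(filament, position, subunit)` to its core label.
#' Only evaluation code should call this; the processing pipeline never
#' sees the truth.
#'
#' @param truth The `truth` element of a [simulate_stack()] result.
#' @param records Alignment table (segment rows or symmetry-expanded).
#' @param n_expand Subunits per segment used in the simulation layout.
#' @return Character vector of labels, one per record row.
#' @export
truth_labels <- function(truth, records, n_expand = 15L) {
  off <- stats::setNames(truth$layout$offset, truth$layout$filament)
  idx <- off[as.character(records$filament)] +
    records$position * n_expand + records$subunit + 1L
  truth$labels[idx]
}

#' Write / read ground truth as JSON
#'
#' Truth lives in its own file so that pipeline code physically cannot
#' read it by accident; only evaluation code consumes it.
#'
#' @param truth A `ground_truth` object (with layout, after simulation).
#' @param path JSON path.
#' @return Reader: the `ground_truth`; writer: `path` invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(list(labels = truth$labels, mode = truth$mode,
                            fraction_open = truth$fraction_open,
                            pairing = truth$pairing,
                            n_protofilaments = truth$n_protofilaments,
                            seed = truth$seed, layout = truth$layout),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(labels = j$labels, mode = j$mode,
                 fraction_open = j$fraction_open,
                 pairing = j$pairing, n_protofilaments = j$n_protofilaments,
                 seed = j$seed, layout = j$layout),
            class = "ground_truth")
}
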