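#' Mask models for the synthetic decorated lattice
#'
#' Blob coordinate tables (scene frame) from which the two subtraction
#' masks are rendered, mirroring the two mask recipes of the workflow:
#' `full` spans one kinesin-decorated tubulin site (monomer mode) or a
#' two-site dimer span plus linker (dimer mode), together with the
#' flanking tubulin; `kinesin` contains only the kinesin (motor,
#' marker envelope, rod, and in dimer mode the linker) parts.
#'
#' @param spec A [phantom_spec()].
#' @param sym A [helical_symmetry()].
#' @param mode `"monomer"` or `"dimer"`.
#' @return List with `full` and `kinesin` blob tables (columns
#'   `x, y, z, sd, w`).
#' @export
mask_models <- function(spec, sym, mode = c("monomer", "dimer")) {
  mode <- match.arg(mode)
  tub <- spec$body_blobs[1, , drop = FALSE]       # lattice body blob
  kin <- rbind(spec$body_blobs[-1, , drop = FALSE],
               spec$marker_open, spec$marker_closed, spec$necklinker_rod)
  place <- function(blobs, k) {
    S <- screw_transform(sym, k)
    p <- as.matrix(blobs[, c("x", "y", "z")]) %*% t(S$R)
    p <- sweep(p, 2, S$t, "+")
    data.frame(x = p[, 1], y = p[, 2], z = p[, 3], sd = blobs$sd, w = blobs$w)
  }
  ## flanking tubulin sits one dimer repeat up/down the same protofilament
  ## (15 subunits along the 1-start helix of a 15-start lattice)
  npf <- 15L
  anchors <- if (mode == "monomer") 0L else c(0L, npf)
  flank <- c(-npf, 0L, npf)  # one dimer repeat up/down fits the desk-scale box
  full <- do.call(rbind, c(lapply(flank, place, blobs = tub),
                           lapply(anchors, place, blobs = kin)))
  kinesin <- do.call(rbind, lapply(anchors, place, blobs = kin))
  if (mode == "dimer") {
    link <- place(spec$dimer_linker, 0L)
    full <- rbind(full, link)
    kinesin <- rbind(kinesin, link)
  }
  list(full = full, kinesin = kinesin)
}

#' Run the subunit refinement and classification workflow end to end
#'
#' Stages: (1) gold-standard split by filament and per-half consensus
#' reconstruction with real-space helical symmetrization; (2) symmetry
#' expansion and re-centering of the original images on the projected
#' centre of mass of the full mask, with the per-subunit beam-axis depth
#' accumulated into the defocus bookkeeping; (3) partial signal
#' subtraction with the full mask and optional local pose refinement;
#' (4) subtraction with the kinesin-only mask, optional resampling, and
#' focused classification without image alignment; (5) local refinement
#' of the selected class(es); (6) reconstruction per class and half-set
#' from the re-centred *original* (non-subtracted) images, helical
#' symmetrization in monomer mode only, masked gold-standard FSC and a
#' resolution report. Reruns with the same inputs and seed are
#' reproducible.
#'
#' The ground truth of a simulation is never an input: the pipeline
#' sees only images, records, symmetry and mask models.
#'
#' @param stack Segment [image_stack()] (original images).
#' @param records Segment alignment table.
#' @param sym A [helical_symmetry()].
#' @param mask_full_model,mask_kinesin_model Blob/atom tables for the
#'   two masks (see [mask_models()]).
#' @param ctf A [ctf_params()] or `NULL`.
#' @param mode `"monomer"` or `"dimer"` (dimer reports the
#'   centred-linker class and skips final symmetrization).
#' @param K,tau,iterations,class_seed Focused-classification controls.
#' @param target_pixel_size Classification sampling; `NULL` keeps the
#'   data sampling.
#' @param sigma_ang,offset_range Local-refinement controls (degrees /
#'   Angstrom); `refine_subtracted` and `refine_selected` toggle the
#'   two refinement passes.
#' @param mask_lowpass,mask_threshold,mask_extend_px,mask_soft_px
#'   Subtraction-mask recipe.
#' @param fsc_lowpass,fsc_threshold,fsc_extend_px,fsc_soft_px FSC-mask
#'   recipe.
#' @param z_fraction Axial fraction for helical symmetrization.
#' @param min_population Classes below this fraction are dropped from
#'   the per-class reconstruction stage.
#' @param wiener Wiener constant for consensus/final reconstructions.
#' @param seed Master seed.
#' @param out_dir Optional directory for MRC/STAR/JSON artifacts.
#' @param verbose Progress messages.
#' @return An object of class `hasrc_run`.
#' @export
run_hasrc <- function(stack, records, sym, mask_full_model, mask_kinesin_model,
                      ctf = NULL, mode = c("monomer", "dimer"),
                      K = 8L, tau = 4, iterations = 25L, class_seed = NULL,
                      target_pixel_size = 8,
                      sigma_ang = 2, offset_range = 3.5,
                      refine_subtracted = FALSE, refine_selected = TRUE,
                      mask_lowpass = 30, mask_threshold = 0.05,
                      mask_extend_px = 1L, mask_soft_px = 2L,
                      fsc_lowpass = 15, fsc_threshold = 0.1,
                      fsc_extend_px = 2L, fsc_soft_px = 6L,
                      z_fraction = 0.85, min_population = 0.05,
                      wiener = 0.1, seed = 1, out_dir = NULL,
                      verbose = FALSE) {
  mode <- match.arg(mode)
  if (is.null(class_seed)) class_seed <- seed + 17L
  n <- box_size(stack); apix <- stack$apix
  say <- function(...) if (verbose) message(sprintf(...))
  log <- list(mode = mode, seed = seed, box = n, apix = apix,
              K = K, tau = tau, iterations = iterations,
              sigma_ang = sigma_ang, offset_range = offset_range,
              mask_recipe = list(lowpass = mask_lowpass, threshold = mask_threshold,
                                 extend_px = mask_extend_px, soft_px = mask_soft_px),
              fsc_mask_recipe = list(lowpass = fsc_lowpass, threshold = fsc_threshold,
                                     extend_px = fsc_extend_px, soft_px = fsc_soft_px),
              gap_defaults = list(
                amplitude_contrast = if (is.null(ctf)) NA else ctf$amplitude_contrast,
                cs_mm = if (is.null(ctf)) NA else ctf$cs,
                wiener = wiener, z_fraction = z_fraction,
                offset_range_is_radius = TRUE,
                handedness = sym$handedness))

  ## ---- stage 1: halves + per-half consensus ----------------------------
  say("stage 1: gold-standard split and consensus reconstruction")
  if (length(unique(records$filament)) < 2L)
    stop("stage consensus: need >= 2 filaments for a gold-standard split")
  sp <- split_halves(records)
  records <- sp$records
  consensus <- lapply(1:2, function(h) {
    rc <- records[records$half == h, , drop = FALSE]
    v <- backproject(stack, rc, ctf = ctf, pad = 2L, wiener = wiener)
    impose_helical_symmetry(v, sym, z_fraction)
  })

  ## ---- masks ------------------------------------------------------------
  say("stage 2: masks and symmetry expansion")
  dens_full <- model_to_density(mask_full_model, apix, n, mask_lowpass)
  dens_kin <- model_to_density(mask_kinesin_model, apix, n, mask_lowpass)
  thr_full <- mask_threshold * max(dens_full$data)
  thr_kin <- mask_threshold * max(dens_kin$data)
  mask_full <- make_soft_mask(dens_full, thr_full, mask_extend_px, mask_soft_px)
  mask_kin <- make_soft_mask(dens_kin, thr_kin, mask_extend_px, mask_soft_px)
  C_M <- mask_full$center_of_mass
  log$C_M <- C_M

  ## ---- stage 2: expansion + re-centering of original images -------------
  ## recenter() folds the centring into the record shifts, so records stay
  ## consistent with volumes in the original scene frame: references and
  ## masks are NOT shifted.
  exp_records <- symmetry_expand(records, sym)
  rc0 <- recenter(stack, exp_records, C_M)
  stack_rc <- rc0$stack; rec_rc <- rc0$records
  cons_rc <- consensus
  mask_full_rc <- mask_full
  mask_kin_rc <- mask_kin
  clamp_mask <- function(v) {
    out <- volume_grid(pmin(pmax(v$data, 0), 1), v$apix)
    class(out) <- c("soft_mask", class(out))
    out$center_of_mass <- c(0, 0, 0)
    out
  }

  ## ---- stage 3: full-mask subtraction (+ optional refinement) -----------
  say("stage 3: full-mask partial signal subtraction")
  sub_full <- subtract_by_half(stack_rc, rec_rc, cons_rc, mask_full_rc, ctf)
  rec_ref <- rec_rc
  if (refine_subtracted) {
    say("stage 3b: local refinement of subtracted subunits")
    refs <- lapply(cons_rc, function(v)
      volume_grid(v$data * mask_full_rc$data, apix))
    refs <- lapply(refs, filter_to_resolution, resolution_A = 8)
    rec_ref <- local_refine(sub_full$stack, rec_ref, refs,
                            sigma_ang = sigma_ang, offset_range = offset_range,
                            ctf = ctf, mask = mask_full_rc)
  }

  ## ---- stage 4: kinesin-mask subtraction + focused classification -------
  say("stage 4: kinesin-mask subtraction and focused classification")
  sub_kin <- subtract_by_half(stack_rc, rec_ref, cons_rc, mask_kin_rc, ctf)
  cls_stack <- sub_kin$stack
  cls_mask <- mask_kin_rc
  if (!is.null(target_pixel_size) && target_pixel_size > apix + 1e-9) {
    cls_stack <- resample_stack(cls_stack, target_pixel_size)
    cls_mask <- clamp_mask(resample_volume(cls_mask, target_pixel_size))
  }
  ensemble <- focused_classify(cls_stack, rec_ref, cls_mask, K = K, tau = tau,
                               n_iter = iterations, seed = class_seed,
                               ctf = ctf, verbose = verbose)
  sel <- select_classes(ensemble, rec_ref,
                        criterion = if (mode == "dimer") "dimer" else "argmax",
                        center_point_A = C_M)
  rec_cls <- sel$records
  keep_classes <- which(sel$populations >= min_population)
  say("populations: %s", paste(sprintf("%.3f", sel$populations), collapse = " "))

  ## ---- stage 5/6: per-class refinement + final reconstruction -----------
  fsc_dens <- model_to_density(mask_full_model, apix, n, fsc_lowpass)
  fsc_mask <- make_soft_mask(fsc_dens, fsc_threshold * max(fsc_dens$data),
                             fsc_extend_px, fsc_soft_px)
  class_results <- list()
  for (cl in keep_classes) {
    rc <- rec_cls[rec_cls$class == cl, , drop = FALSE]
    if (refine_selected && nrow(rc) >= 2L) {
      refs <- lapply(cons_rc, function(v)
        volume_grid(v$data * mask_full_rc$data, apix))
      refs <- lapply(refs, filter_to_resolution, resolution_A = 8)
      sub_cl <- subtract_by_half(stack_rc, rc, cons_rc, mask_full_rc, ctf)
      rc <- local_refine(sub_cl$stack, rc, refs, sigma_ang = sigma_ang,
                         offset_range = offset_range, ctf = ctf,
                         mask = mask_full_rc)
    }
    halves <- lapply(1:2, function(h) {
      rch <- rc[rc$half == h, , drop = FALSE]
      if (!nrow(rch)) return(NULL)
      v <- backproject(stack_rc, rch, ctf = ctf, pad = 2L, wiener = wiener)
      if (mode == "monomer") v else v
    })
    if (any(vapply(halves, is.null, logical(1)))) {
      class_results[[as.character(cl)]] <- list(skipped = "empty half")
      next
    }
    curve <- fsc(halves[[1]], halves[[2]], mask = fsc_mask)
    res <- resolution_at(curve, 0.143)
    merged <- volume_grid((halves[[1]]$data + halves[[2]]$data) / 2, apix)
    filtered <- if (is.finite(res)) filter_to_resolution(merged, res) else merged
    class_results[[as.character(cl)]] <-
      list(records = rc, half_maps = halves, map = filtered,
           fsc = curve, resolution_A = res)
    say("class %d: %d particles, FSC_0.143 at %.2f A", cl, nrow(rc), res)
  }

  out <- structure(list(
    consensus = consensus, masks = list(full = mask_full, kinesin = mask_kin),
    C_M = C_M, records = rec_cls, ensemble = ensemble, selection = sel,
    classes = class_results, sym = sym, mode = mode, log = log),
    class = "hasrc_run")
  if (!is.null(out_dir)) save_hasrc_run(out, stack_rc, out_dir)
  out
}

## subtraction with strict half separation: particles of half h are only
## ever compared with the half-h consensus
subtract_by_half <- function(stack_rc, records, cons_rc, mask_rc, ctf) {
  m <- stack_as_matrix(stack_rc)
  out <- matrix(0, nrow(m), nrow(records))
  scl <- numeric(2)
  for (h in 1:2) {
    idx <- which(records$half == h)
    if (!length(idx)) next
    rch <- records[idx, , drop = FALSE]
    sb <- subtract_outside_mask(stack_rc, rch, cons_rc[[h]], mask_rc, ctf = ctf)
    out[, idx] <- stack_as_matrix(sb$stack)
    scl[h] <- sb$scale
  }
  rec2 <- records; rec2$image <- seq_len(nrow(records))
  list(stack = matrix_as_stack(out, box_size(stack_rc), stack_rc$apix),
       records = rec2, scale = scl)
}

#' @export
print.hasrc_run <- function(x, ...) {
  cat(sprintf("hasrc_run (%s mode): %d expanded subunits, K = %d\n",
              x$mode, nrow(x$records), x$ensemble$K))
  cat("class populations:", sprintf("%.3f", x$selection$populations), "\n")
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    if (!is.null(cl$resolution_A))
      cat(sprintf("  class %s: %d particles, FSC_0.143 = %.2f A\n",
                  nm, nrow(cl$records), cl$resolution_A))
  }
  if (x$mode == "dimer" && !is.null(x$selection$centered_class))
    cat("centered dimer class:", x$selection$centered_class, "\n")
  invisible(x)
}

## Persist the main artifacts of a run as MRC/STAR/JSON.
save_hasrc_run <- function(run, stack_rc, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_star(run$records, file.path(out_dir, "particles_classified.star"))
  for (h in 1:2)
    write_mrc(run$consensus[[h]],
              file.path(out_dir, sprintf("consensus_half%d.mrc", h)))
  for (nm in names(run$classes)) {
    cl <- run$classes[[nm]]
    if (!is.null(cl$map))
      write_mrc(cl$map, file.path(out_dir, sprintf("class%s_map.mrc", nm)))
  }
  jsonlite::write_json(list(log = run$log,
                            populations = run$selection$populations,
                            resolutions = lapply(run$classes, function(cl)
                              cl$resolution_A)),
                       file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

#' Adjusted Rand index between two labelings
#'
#' Contingency-table form of the chance-corrected Rand index.
#'
#' @param x,y Label vectors of equal length.
#' @return ARI in \[-1, 1\].
#' @export
adjusted_rand_index <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * c / choose(n, 2)
  maxi <- (b + c) / 2
  if (maxi == expected) return(0)
  (a - expected) / (maxi - expected)
}

#' Score class assignments against simulation ground truth
#'
#' Maps every class to the conformation it predominantly contains,
#' then reports the adjusted Rand index, the recovered per-conformation
#' fractions, and (dimer mode) the per-subunit trailing/leading
#' accuracy implied by the centred-dimer class.
#'
#' @param records Classified alignment table (`class` filled), expanded.
#' @param truth The simulation's `ground_truth`.
#' @param n_expand Subunits per segment (layout bookkeeping).
#' @param centered_class Optional centred-dimer class id from
#'   [select_classes()].
#' @return List with `ari`, `fraction_open`, `class_map`,
#'   `confusion`, and `pair_accuracy` when applicable.
#' @export
evaluate_against_truth <- function(records, truth, n_expand = 15L,
                                   centered_class = NULL) {
  labels <- truth_labels(truth, records, n_expand)
  if (length(labels) != nrow(records) || anyNA(labels))
    stop("label/particle mismatch between truth and records")
  cls <- records$class
  tab <- table(cls, labels)
  ari <- adjusted_rand_index(cls, labels)
  class_map <- colnames(tab)[apply(tab, 1, which.max)]
  names(class_map) <- rownames(tab)
  open_classes <- names(class_map)[class_map == "open"]
  fraction_open <- mean(cls %in% as.integer(open_classes))
  out <- list(ari = ari, fraction_open = fraction_open,
              class_map = class_map, confusion = tab)
  if (truth$mode == "dimer" && !is.null(centered_class)) {
    ## in the centred class the anchor subunit is the trailing head
    predicted_trailing <- cls == centered_class
    true_trailing <- labels == "closed"
    acc <- mean(predicted_trailing == true_trailing)
    out$pair_accuracy <- max(acc, 1 - acc)  # label-swap invariant
  }
  out
}

#' Lattice-distortion resolution-gain experiment
#'
#' Simulates a homogeneous decorated filament with random per-subunit
#' lattice displacements and compares two routes to a map: (a) plain
#' helical averaging of the boxed segments (backprojection plus
#' real-space screw averaging) and (b) the subunit route - symmetry
#' expansion, re-centering, full-mask signal subtraction, local shift
#' refinement of every subunit, reconstruction from the re-centred
#' original images, and the same screw averaging. Both routes use
#' gold-standard halves and the same soft mask for the FSC, so the only
#' difference is whether per-subunit lattice displacements were
#' refined away.
#'
#' @param spec,sym Phantom and symmetry (defaults as elsewhere).
#' @param snr Variance signal-to-noise ratio of the simulated segments.
#' @param n_segments,n_filaments Dataset size.
#' @param lattice_jitter_A Per-subunit displacement sd, Angstrom.
#' @param sigma_ang,offset_range Refinement controls.
#' @param seed Integer seed.
#' @param ctf A [ctf_params()].
#' @return List with `res_helical_A`, `res_hasrc_A` (FSC 0.143
#'   resolutions in Angstrom), the two `fsc_curves`, and the mean
#'   refined shift magnitude `mean_shift_A`.
#' @export
lattice_gain_experiment <- function(spec = phantom_spec(),
                                    sym = helical_symmetry(),
                                    snr = 0.015, n_segments = 12L,
                                    n_filaments = 4L,
                                    lattice_jitter_A = 2,
                                    sigma_ang = 2, offset_range = 3.5,
                                    seed = 31,
                                    ctf = ctf_params(pixel_size = spec$voxel_size)) {
  apix <- spec$voxel_size; n <- spec$box
  sigma <- sigma_for_snr(spec, sym, snr, ctf = ctf, seed = seed + 1L)
  sim <- simulate_stack(spec, sym, n_segments = n_segments,
                        n_filaments = n_filaments, mode = "mixture",
                        fraction_open = 1, noise_sigma = sigma,
                        lattice_jitter_A = lattice_jitter_A,
                        ctf = ctf, seed = seed)
  mm <- mask_models(spec, sym, "monomer")
  df <- model_to_density(mm$full, apix, n, 30)
  mask_full <- make_soft_mask(df, 0.05 * max(df$data), 1L, 2L)
  fd <- model_to_density(mm$full, apix, n, 15)
  fsc_mask <- make_soft_mask(fd, 0.1 * max(fd$data), 2L, 6L)
  sp <- split_halves(sim$records); records <- sp$records

  ## route A: helical averaging of the distorted lattice
  hA <- lapply(1:2, function(h) {
    rc <- records[records$half == h, , drop = FALSE]
    impose_helical_symmetry(backproject(sim$stack, rc, ctf = ctf,
                                        wiener = 0.1), sym)
  })
  fA <- fsc(hA[[1]], hA[[2]], mask = fsc_mask)

  ## route B: expand -> recenter -> subtract -> refine -> reconstruct
  ex <- symmetry_expand(records, sym)
  rc0 <- recenter(sim$stack, ex, mask_full$center_of_mass)
  cons <- lapply(1:2, function(h) {
    rch <- rc0$records[rc0$records$half == h, , drop = FALSE]
    backproject(rc0$stack, rch, ctf = ctf, wiener = 0.1)
  })
  sub <- subtract_by_half(rc0$stack, rc0$records, cons, mask_full, ctf)
  refs <- lapply(cons, function(v) filter_to_resolution(
    volume_grid(v$data * mask_full$data, apix), 8))
  rr <- local_refine(sub$stack, rc0$records, refs, sigma_ang = sigma_ang,
                     offset_range = offset_range, ctf = ctf,
                     mask = mask_full, angle_points = 1L)
  hB <- lapply(1:2, function(h) {
    rch <- rr[rr$half == h, , drop = FALSE]
    impose_helical_symmetry(backproject(rc0$stack, rch, ctf = ctf,
                                        wiener = 0.1), sym)
  })
  fB <- fsc(hB[[1]], hB[[2]], mask = fsc_mask)
  dsx <- rr$sx - rc0$records$sx; dsy <- rr$sy - rc0$records$sy
  list(res_helical_A = resolution_at(fA, 0.143),
       res_hasrc_A = resolution_at(fB, 0.143),
       fsc_helical = fA, fsc_hasrc = fB,
       mean_shift_A = mean(sqrt(dsx^2 + dsy^2)))
}
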