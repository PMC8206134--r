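#' Resample an image stack by Fourier cropping
#'
#' Coarsens the sampling to `target_pixel_size` by retaining the central
#' block of each image's Fourier transform (no upsampling). The DC
#' component, and hence the mean pixel value, is preserved.
#'
#' @param stack An [image_stack()].
#' @param target_pixel_size Target sampling, Angstrom/px (>= current).
#' @return The resampled [image_stack()].
#' @export
resample_stack <- function(stack, target_pixel_size) {
  n <- box_size(stack); apix <- stack$apix
  if (target_pixel_size < apix - 1e-9)
    stop("no upsampling: target pixel size must be >= ", apix)
  if (abs(target_pixel_size - apix) < 1e-9) return(stack)
  n2 <- 2L * floor(n * apix / target_pixel_size / 2)
  if (n2 < 8L) stop("target pixel size too coarse for this box")
  apix2 <- n * apix / n2
  sel <- (freq_index(n2) %% n) + 1L
  m <- stack_as_matrix(stack)
  N <- ncol(m)
  out <- matrix(0, n2 * n2, N)
  for (i in seq_len(N)) {
    Fv <- fft2(matrix(m[, i], n, n))
    out[, i] <- as.numeric(Re(ifft2(Fv[sel, sel]))) # /n2^2 inside ifft2
  }
  out <- out * (n2 * n2) / (n * n)  # keep real-space amplitudes
  matrix_as_stack(out, n2, apix2)
}

#' Resample a volume by Fourier cropping
#'
#' 3D analogue of [resample_stack()], used to carry masks and references
#' onto a classification grid.
#'
#' @param vol A [volume_grid()].
#' @param target_pixel_size Target sampling (>= current).
#' @return The resampled [volume_grid()].
#' @export
resample_volume <- function(vol, target_pixel_size) {
  n <- dim(vol$data)[1]; apix <- vol$apix
  if (target_pixel_size < apix - 1e-9) stop("no upsampling")
  if (abs(target_pixel_size - apix) < 1e-9) return(vol)
  n2 <- 2L * floor(n * apix / target_pixel_size / 2)
  apix2 <- n * apix / n2
  sel <- (freq_index(n2) %% n) + 1L
  Fv <- fft(vol$data)
  out <- Re(ifftn(Fv[sel, sel, sel])) * (n2 / n)^3
  volume_grid(out, apix2)
}

#' Focused 3D classification without image alignment
#'
#' Regularized-likelihood expectation-maximization over class
#' assignments with all poses held fixed. The E-step computes
#' responsibilities proportional to `weight_c * exp(-||(I - CTF *
#' Proj(V_c)) * m||^2 / (2 sigma^2))` with `m` the projected focus mask;
#' the M-step rebuilds each class volume by responsibility-weighted,
#' CTF-weighted direct Fourier inversion with a Wiener constant
#' `wiener_base / tau` (larger `tau` trusts the data more, mirroring the
#' tau2_fudge regularization multiplier), re-estimates the mixing
#' weights, and re-estimates the noise variance from masked residuals.
#' Class volumes are initialized from seeded random perturbations of the
#' uniform responsibilities, and the run is deterministic given `seed`.
#'
#' @param stack Particle images (typically signal-subtracted,
#'   re-centred, resampled).
#' @param records Alignment table with fixed poses.
#' @param focus_mask A `soft_mask` on the same grid as the would-be class
#'   volumes (box and pixel size of `stack`).
#' @param K Number of classes (>= 1).
#' @param tau Regularization multiplier (tau2_fudge analogue).
#' @param n_iter Iteration budget.
#' @param seed Integer seed for the initialization.
#' @param ctf A [ctf_params()] or `NULL`.
#' @param pad Fourier oversampling factor ("padding 2").
#' @param tol Early-stop threshold on the max responsibility change.
#' @param wiener_base Numerator of the Wiener constant.
#' @param weight_floor Minimum class weight; emptier classes are floored
#'   and the event is recorded in the history.
#' @param weight_update_start Iteration from which the mixing weights are
#'   re-estimated; before that they stay uniform, which prevents the
#'   early rich-get-richer collapse of low-SNR mixtures. The default
#'   (`NULL`) starts weight updates a few iterations after the
#'   annealing schedule has finished.
#' @param anneal_temp,anneal_iters Deterministic-annealing schedule: the
#'   log-likelihood differences are divided by a temperature that decays
#'   geometrically from `anneal_temp` to 1 over `anneal_iters`
#'   iterations. Keeping early responsibilities soft stops the run from
#'   hard-committing to its random initialization and stranding in a
#'   local optimum; `anneal_temp = 1` disables annealing.
#' @param sigma2 Optional fixed noise variance; `NULL` re-estimates it
#'   each iteration.
#' @param verbose Print per-iteration class populations.
#' @return An object of class `class_ensemble`: class volumes, mixing
#'   weights, the N x K responsibility matrix, noise variance, and a
#'   per-iteration history (populations, masked log-likelihood, max
#'   responsibility change, floored-class events).
#' @export
focused_classify <- function(stack, records, focus_mask, K = 8L, tau = 4,
                             n_iter = 25L, seed = 1, ctf = NULL, pad = 2L,
                             tol = 1e-5, wiener_base = 1, weight_floor = 1e-6,
                             weight_update_start = NULL,
                             anneal_temp = 32, anneal_iters = 15L,
                             sigma2 = NULL, verbose = FALSE) {
  if (K < 1L) stop("K must be >= 1")
  n <- box_size(stack); apix <- stack$apix
  if (dim(focus_mask$data)[1] != n || abs(focus_mask$apix - apix) > 1e-9)
    stop("focus mask must live on the stack grid")
  N <- nrow(records)
  imgs <- stack_as_matrix(stack)[, records$image, drop = FALSE]

  ## projected focus mask, normalized to [0, 1] as a per-pixel weight
  mask_vol <- volume_grid(focus_mask$data, apix)
  mproj <- project_volume(mask_vol, records, ctf = NULL, pad = pad,
                          as_matrix = TRUE)
  mproj <- pmin(pmax(mproj / max(mproj), 0), 1)
  imask <- imgs * mproj
  me <- colSums(mproj^2)            # effective masked pixels per particle

  ## poses, shifts and CTFs are fixed: precompute everything per chunk
  chunk <- 512L
  starts <- seq(1L, N, by = chunk)
  cache <- lapply(starts, function(start) {
    idx <- start:min(N, start + chunk - 1L)
    rc <- records[idx, , drop = FALSE]
    ph <- shift_phase_matrix(rc, n, apix, sign = +1)
    C <- if (is.null(ctf)) matrix(1, n * n, length(idx))
         else ctf_matrix_for_records(rc, ctf, n, apix)
    list(idx = idx,
         rots = flatten_rots(record_rotations(rc)),
         fi = sl_as_cplx(fft2_cols(imgs[, idx, drop = FALSE] / apix, n) * ph),
         phc = Conj(ph) * C,  # projection-side phase ramp, CTF folded in
         ctf = C)
  })

  ## single shared noise variance; the annealing schedule (below) takes
  ## care of the early-iteration pathologies a shared sigma would
  ## otherwise cause at very low SNR
  if (is.null(weight_update_start))
    weight_update_start <- anneal_iters + 6L
  est_sigma <- is.null(sigma2)
  if (est_sigma) sigma2 <- sum(imask^2) / sum(me)

  set.seed(seed)
  resp <- matrix(1 / K, N, K) + matrix(runif(N * K, -0.05 / K, 0.05 / K), N, K)
  resp <- resp / rowSums(resp)
  weights <- colMeans(resp)

  wiener <- wiener_base / tau
  pn <- as.integer(pad * n)
  history <- list()
  floored <- integer(0)
  volumes <- vector("list", K)
  resid <- matrix(0, N, K)
  max_change <- Inf
  calm <- 0L  # consecutive sub-tolerance iterations

  accumulate <- function(w) {
    acc_re <- numeric(pn^3); acc_im <- numeric(pn^3); acc_w <- numeric(pn^3)
    for (ch in cache)
      cpp_backproject_insert(ch$fi, ch$ctf, w[ch$idx], ch$rots, pn, n,
                             as.integer(pad), acc_re, acc_im, acc_w)
    list(re = acc_re, im = acc_im, w = acc_w)
  }
  ## the Wiener constant scales with the class's effective particle
  ## count, so light and heavy classes are damped identically per unit
  ## data; a fixed constant would make the heavier class's volume
  ## systematically crisper and let it absorb every particle
  wiener_solve <- function(acc, wbar) {
    vhat <- array(complex(real = acc$re, imaginary = acc$im) /
                    (acc$w + wiener * K * max(wbar, 1e-8)), c(pn, pn, pn))
    finish_volume_ift(vhat, n, pad)
  }
  ## responsibilities sum to 1 per particle, so the class accumulators sum
  ## to the (fixed) full-data accumulator: insert K-1 classes, subtract
  acc_total <- accumulate(rep(1, N))
  mstep_all <- function(resp) {
    accs <- lapply(seq_len(K - 1L), function(cl) accumulate(resp[, cl]))
    rest <- list(re = acc_total$re, im = acc_total$im, w = acc_total$w)
    for (a in accs) {
      rest$re <- rest$re - a$re; rest$im <- rest$im - a$im
      rest$w <- rest$w - a$w
    }
    wbars <- colMeans(resp)
    mapply(function(acc, wb) wiener_solve(acc, wb),
           c(accs, list(rest)), wbars, SIMPLIFY = FALSE)
  }
  estep_resid <- function(vol) {
    W <- prepare_volume_ft(vol, pad)
    out <- numeric(N)
    for (ch in cache) {
      sl <- cpp_fourier_slice(W, ch$rots, pn, n, as.integer(pad))
      P <- Re(fft2_cols(sl * ch$phc, n, inverse = TRUE)) * apix
      out[ch$idx] <- colSums((imask[, ch$idx, drop = FALSE] -
                                P * mproj[, ch$idx, drop = FALSE])^2)
    }
    out
  }

  T0 <- NULL
  for (it in seq_len(n_iter)) {
    ## ----- M-step: responsibility-weighted Wiener reconstructions -----
    volumes <- mstep_all(resp)
    ## ----- E-step -----
    for (cl in seq_len(K)) resid[, cl] <- estep_resid(volumes[[cl]])
    ll_data <- -resid / (2 * sigma2) - 0.5 * me * log(2 * pi * sigma2)
    if (is.null(T0)) {
      ## adapt the annealing start to the observed log-likelihood gaps so
      ## the first responsibilities are genuinely soft even when the
      ## residual scale is far from the noise scale (noiseless data)
      gaps <- apply(ll_data, 1, max) - apply(ll_data, 1, min)
      T0 <- max(anneal_temp, stats::quantile(gaps, 0.9) / 3, 1)
    }
    temp <- max(1, T0^(1 - (it - 1) / max(1L, anneal_iters)))
    lw <- rep(log(pmax(weights, 1e-300)), each = N)
    loglog <- ll_data / temp + lw
    mx <- apply(loglog, 1, max)
    pr <- exp(loglog - mx)
    newresp <- pr / rowSums(pr)
    ## the recorded likelihood is always the untempered one
    ll0 <- ll_data + lw
    mx0 <- apply(ll0, 1, max)
    loglik <- sum(mx0 + log(rowSums(exp(ll0 - mx0))))
    max_change <- max(abs(newresp - resp))
    resp <- newresp
    weights <- if (it >= weight_update_start) colMeans(resp)
               else rep(1 / K, K)
    if (any(weights < weight_floor)) {
      floored <- c(floored, it)
      weights <- pmax(weights, weight_floor)
      weights <- weights / sum(weights)
    }
    if (est_sigma) sigma2 <- sum(resp * resid) / sum(me)
    history[[it]] <- c(iter = it, stats::setNames(weights, paste0("class", seq_len(K))),
                       loglik = loglik, sigma2 = sigma2,
                       max_change = max_change)
    if (verbose)
      message(sprintf("iter %3d: loglik %.4e, populations %s, dmax %.2e",
                      it, loglik, paste(sprintf("%.3f", weights), collapse = " "),
                      max_change))
    ## the iterations right after annealing are a shallow basin: a mode
    ## still growing from tiny amplitude moves the responsibilities by
    ## less than any practical tolerance for a while, so no stop is
    ## allowed until well after the schedule has ended, and then only on
    ## a sustained calm
    calm <- if (max_change < tol && temp <= 1) calm + 1L else 0L
    if (calm >= 3L && it >= anneal_iters + 15L) break
  }
  ## final M-step so the volumes match the final responsibilities
  volumes <- mstep_all(resp)
  structure(list(
    class_volumes = lapply(volumes, volume_grid, apix = apix),
    weights = weights, responsibilities = resp, noise_sigma2 = sigma2,
    history = as.data.frame(do.call(rbind, history)),
    floored_iterations = floored, K = K, tau = tau, seed = seed,
    converged = calm >= 3L, n_iter_run = length(history)),
    class = "class_ensemble")
}



#' @export
print.class_ensemble <- function(x, ...) {
  cat(sprintf("class_ensemble: K = %d, tau = %g, %d iterations%s\n",
              x$K, x$tau, x$n_iter_run,
              if (x$converged) " (converged)" else ""))
  cat("populations:", sprintf("%.3f", x$weights), "\n")
  invisible(x)
}

#' @export
summary.class_ensemble <- function(object, ...) {
  cat(sprintf("Focused classification: K = %d, tau = %g, seed = %d\n",
              object$K, object$tau, object$seed))
  cat(sprintf("iterations run: %d (converged: %s), noise sigma^2 = %.4g\n",
              object$n_iter_run, object$converged, object$noise_sigma2))
  hard <- apply(object$responsibilities, 1, which.max)
  tab <- table(factor(hard, levels = seq_len(object$K)))
  cat("hard-assignment populations:\n")
  print(tab)
  if (length(object$floored_iterations))
    cat("weight floor applied at iterations:",
        object$floored_iterations, "\n")
  invisible(list(populations = as.numeric(tab) / length(hard),
                 weights = object$weights))
}

#' Hard class assignment and class selection
#'
#' Assigns each particle to its maximum-responsibility class (ties to
#' the lowest class index, counted), reports per-class populations, and
#' optionally identifies the "centered dimer" class: the class volume
#' with the largest fraction of its focus-region density in a central
#' axial window, i.e. the class whose linker density sits at the box
#' centre rather than at the edges.
#'
#' @param ensemble A [focused_classify()] result.
#' @param records The alignment table used for classification.
#' @param criterion `"argmax"` (only hard assignment) or `"dimer"`
#'   (additionally score the centred-linker statistic).
#' @param center_halfwidth_A Axial half-width of the central window used
#'   by the dimer statistic.
#' @param center_point_A The point (Angstrom, volume frame) on which the
#'   subunits were re-centred (the full mask's centre of mass); the
#'   linker of a registered dimer sits at its axial coordinate.
#' @return List with `records` (class column filled), `populations`,
#'   `tie_count`, and for `"dimer"` the `centered_class` and per-class
#'   `center_stat`.
#' @export
select_classes <- function(ensemble, records,
                           criterion = c("argmax", "dimer"),
                           center_halfwidth_A = 20,
                           center_point_A = c(0, 0, 0)) {
  criterion <- match.arg(criterion)
  resp <- ensemble$responsibilities
  mx <- apply(resp, 1, max)
  ties <- rowSums(resp == mx) > 1L
  hard <- apply(resp, 1, which.max)  # which.max takes the first (lowest) index
  records$class <- as.integer(hard)
  pop <- as.numeric(table(factor(hard, levels = seq_len(ensemble$K)))) / nrow(resp)
  out <- list(records = records, populations = pop,
              tie_count = sum(ties))
  if (criterion == "dimer") {
    stat <- vapply(ensemble$class_volumes, function(v) {
      n <- dim(v$data)[1]; c0 <- n %/% 2L
      z <- (seq_len(n) - 1L - c0) * v$apix
      central <- abs(z - center_point_A[3]) <= center_halfwidth_A
      d <- pmax(v$data, 0)
      sum(d[, , central]) / (sum(d) + 1e-12)
    }, numeric(1))
    out$center_stat <- stat
    populated <- which(pop >= 0.05)
    out$centered_class <- populated[which.max(stat[populated])]
  }
  out
}
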