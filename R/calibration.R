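# Phase-retrieval calibration of the system aberration from a single
# realigned image of an isolated subdiffraction bead.
#
# Each angular component (u, v) sees the bead through one pupil
# sub-aperture.  A wavefront error W (in wavelengths) tilts each
# sub-aperture locally, displacing its view by
#
#   dx = -(lambda / NA) * dW/drho        (sample-plane um per unit rho)
#
# so the per-angle displacement field between captured and simulated views
# is a Shack-Hartmann-style slope measurement of the residual wavefront.
# The slopes are zonally integrated (least squares), fitted with Zernike
# polynomials, fed back into the wave-optics model, and the loop repeats
# until the phase map converges.

#' Per-angle displacement between captured and simulated bead views
#'
#' For each angular component, finds the sub-pixel displacement maximizing
#' the normalized cross-correlation between the captured view and the
#' simulated PSF view (integer search plus parabolic peak interpolation).
#' Angles whose peak correlation falls below 0.2 are flagged invalid.
#'
#' @param captured A `qlfm_views` array of an isolated bead.
#' @param simulated A `qlfm_psf` whose kernels share the captured angular
#'   layout (the z = 0 plane is used), or a 4D array of views.
#' @param max_shift Largest displacement searched (lens-grid pixels).
#' @return Data frame with one row per angle: `u`, `v`, `dy`, `dx`
#'   (displacement of the captured view relative to the simulated one, in
#'   lens-grid pixels), `score` (peak correlation) and `valid`.
#' @export
estimate_subaperture_shifts <- function(captured, simulated, max_shift = 4L) {
  sim <- if (inherits(simulated, "qlfm_psf")) {
    iz <- which.min(abs(simulated$planes$z))
    simulated$kernels[[iz]]
  } else simulated
  d <- dim(captured)
  ppl <- d[1]
  half <- (ppl - 1L) %/% 2L
  out <- NULL
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      a <- captured[vi, ui, , ]
      b <- sim[vi, ui, , ]
      r <- shift_by_xcorr(a, b, max_shift)
      out <- rbind(out, data.frame(u = ui - half - 1L, v = vi - half - 1L,
                                   dy = r$dy, dx = r$dx, score = r$score))
    }
  }
  out$valid <- out$score >= 0.2
  if (!any(out$valid)) {
    stop("no angular component correlates with the simulated PSF; ",
         "calibration impossible", call. = FALSE)
  }
  out
}

# Normalized cross-correlation over integer shifts with parabolic sub-pixel
# refinement.  Displacement (dy, dx) maps b to a: a(x) ~ b(x - d).
shift_by_xcorr <- function(a, b, max_shift) {
  ny <- nrow(a); nx <- ncol(a)
  if (!all(dim(b) == c(ny, nx))) {
    b <- extract_centered(embed_centered(b, max(ny, nrow(b)), max(nx, ncol(b))),
                          ny, nx)
  }
  best <- -Inf; bdy <- 0L; bdx <- 0L
  scores <- matrix(NA_real_, 2 * max_shift + 1, 2 * max_shift + 1)
  for (sy in -max_shift:max_shift) {
    for (sx in -max_shift:max_shift) {
      ys_a <- max(1, 1 + sy):min(ny, ny + sy)
      xs_a <- max(1, 1 + sx):min(nx, nx + sx)
      ys_b <- ys_a - sy
      xs_b <- xs_a - sx
      av <- a[ys_a, xs_a]; bv <- b[ys_b, xs_b]
      na2 <- sqrt(sum(av^2) * sum(bv^2))
      sc <- if (na2 > 0) sum(av * bv) / na2 else 0
      scores[sy + max_shift + 1, sx + max_shift + 1] <- sc
      if (sc > best) { best <- sc; bdy <- sy; bdx <- sx }
    }
  }
  dy <- bdy; dx <- bdx
  iy <- bdy + max_shift + 1; ix <- bdx + max_shift + 1
  # parabolic interpolation where the integer peak is interior
  if (iy > 1 && iy < nrow(scores)) {
    den <- scores[iy - 1, ix] - 2 * scores[iy, ix] + scores[iy + 1, ix]
    if (is.finite(den) && den < 0) {
      dy <- dy + 0.5 * (scores[iy - 1, ix] - scores[iy + 1, ix]) / den
    }
  }
  if (ix > 1 && ix < ncol(scores)) {
    den <- scores[iy, ix - 1] - 2 * scores[iy, ix] + scores[iy, ix + 1]
    if (is.finite(den) && den < 0) {
      dx <- dx + 0.5 * (scores[iy, ix - 1] - scores[iy, ix + 1]) / den
    }
  }
  list(dy = dy, dx = dx, score = best)
}

#' Integrate sub-aperture displacements into a pupil wavefront
#'
#' Interprets the per-angle displacement field as local wavefront slopes
#' over the corresponding pupil patches and integrates them zonally: the
#' unknown wavefront values at the angular-grid nodes solve a least-squares
#' system of first-difference equations; invalid angles are excluded.  The
#' mean displacement (a pure image translation, indistinguishable from bead
#' position) is removed first, and piston is removed from the result.
#'
#' @param shifts Data frame from [estimate_subaperture_shifts()] with
#'   displacements in lens-grid pixels.
#' @param config A `qlfm_config`.
#' @param pupil_samples Resolution of the returned phase map.
#' @return A `qlfm_wavefront` whose `pupil_phase_map` interpolates the zonal
#'   solution (radians); nodes outside the pupil are `NA`.
#' @export
integrate_shifts_to_wavefront <- function(shifts, config,
                                          pupil_samples = 64L) {
  if (mean(shifts$valid) < 0.6) {
    stop("fewer than 60% of angular positions have valid correlations",
         call. = FALSE)
  }
  ppl <- config$pixels_per_lens
  half <- (ppl - 1L) %/% 2L
  step <- pupil_step(config)        # pupil rho per angular index
  p_s <- lens_sampling(config)      # um per lens-grid pixel
  lambda <- config$emission_wavelength
  # displacement (um) -> local slope dW/drho (wavelengths per unit rho)
  sx <- -shifts$dx * p_s * config$objective_na / lambda
  sy <- -shifts$dy * p_s * config$objective_na / lambda
  ok <- shifts$valid
  sx[ok] <- sx[ok] - mean(sx[ok])   # remove global tilt (bead position)
  sy[ok] <- sy[ok] - mean(sy[ok])
  # node index helpers on the (v, u) angular lattice
  idx <- function(u, v) (u + half) * ppl + (v + half) + 1L
  n_nodes <- ppl * ppl
  rows <- list(); rhs <- c()
  slope_at <- function(u, v, comp) {
    i <- which(shifts$u == u & shifts$v == v)
    if (!length(i) || !ok[i]) return(NA_real_)
    if (comp == "x") sx[i] else sy[i]
  }
  for (u in -half:half) {
    for (v in -half:half) {
      if (u < half) {
        s1 <- slope_at(u, v, "x"); s2 <- slope_at(u + 1L, v, "x")
        if (is.finite(s1) && is.finite(s2)) {
          r <- numeric(n_nodes)
          r[idx(u + 1L, v)] <- 1; r[idx(u, v)] <- -1
          rows <- c(rows, list(r)); rhs <- c(rhs, step * (s1 + s2) / 2)
        }
      }
      if (v < half) {
        s1 <- slope_at(u, v, "y"); s2 <- slope_at(u, v + 1L, "y")
        if (is.finite(s1) && is.finite(s2)) {
          r <- numeric(n_nodes)
          r[idx(u, v + 1L)] <- 1; r[idx(u, v)] <- -1
          rows <- c(rows, list(r)); rhs <- c(rhs, step * (s1 + s2) / 2)
        }
      }
    }
  }
  A <- do.call(rbind, rows)
  used <- colSums(A != 0) > 0
  if (sum(used) < 3L || qr(A[, used, drop = FALSE])$rank < sum(used) - 1L) {
    stop("slope system is rank deficient: too few valid sub-apertures to ",
         "constrain the wavefront", call. = FALSE)
  }
  w <- rep(NA_real_, n_nodes)
  sol <- stats::lsfit(A[, used, drop = FALSE], rhs, intercept = FALSE)
  w[used] <- sol$coefficients
  w[used] <- w[used] - mean(w[used])          # piston removed
  W_nodes <- matrix(w, ppl, ppl)              # [v, u] in wavelengths
  # interpolate node values onto the pupil map
  ax <- seq(-1, 1, length.out = pupil_samples)
  node_pos <- (-half:half) * step
  phase <- matrix(NA_real_, pupil_samples, pupil_samples)
  for (iy in seq_len(pupil_samples)) {
    for (ix in seq_len(pupil_samples)) {
      r2 <- ax[iy]^2 + ax[ix]^2
      if (r2 > 1) next
      phase[iy, ix] <- bilinear_at(node_pos, W_nodes, ax[iy], ax[ix])
    }
  }
  phase <- phase * 2 * pi
  mask <- is.finite(phase)
  structure(list(zernike_coefficients = numeric(0),
                 pupil_phase_map = phase, pupil_mask = mask,
                 node_values = W_nodes, node_positions = node_pos,
                 pupil_samples = as.integer(pupil_samples)),
            class = "qlfm_wavefront")
}

# Bilinear interpolation of a node grid (positions `pos` on both axes) at
# (y, x); clamped to the node hull, NA-aware (nearest valid fallback).
bilinear_at <- function(pos, vals, y, x) {
  n <- length(pos)
  y <- min(max(y, pos[1]), pos[n])
  x <- min(max(x, pos[1]), pos[n])
  iy <- max(1L, min(n - 1L, findInterval(y, pos)))
  ix <- max(1L, min(n - 1L, findInterval(x, pos)))
  ty <- (y - pos[iy]) / (pos[iy + 1] - pos[iy])
  tx <- (x - pos[ix]) / (pos[ix + 1] - pos[ix])
  v <- c(vals[iy, ix], vals[iy, ix + 1], vals[iy + 1, ix], vals[iy + 1, ix + 1])
  wts <- c((1 - ty) * (1 - tx), (1 - ty) * tx, ty * (1 - tx), ty * tx)
  if (all(is.na(v))) return(NA_real_)
  if (anyNA(v)) {
    wts[is.na(v)] <- 0
    if (sum(wts) == 0) return(mean(v, na.rm = TRUE))
    wts <- wts / sum(wts)
    v[is.na(v)] <- 0
  }
  sum(v * wts)
}

#' Calibrate the system PSF from a captured bead frame
#'
#' Iterative phase retrieval: simulate the PSF with the current wavefront
#' estimate, measure per-angle displacements against the captured bead,
#' integrate them to a residual wavefront, fit Zernike modes, accumulate,
#' and repeat until the RMS wavefront change drops below `tol` (default
#' lambda/50) or `max_iterations` is reached.
#'
#' @param captured_frame A `qlfm_frame` (isolated bead, caller-cropped) or a
#'   pre-realigned `qlfm_views` array.
#' @param config A `qlfm_config`.
#' @param n_modes Zernike modes fitted (Noll 1..n_modes); piston/tip/tilt
#'   are reported but excluded from the PSF model.
#' @param tol RMS wavefront-change convergence threshold (wavelengths).
#' @param max_iterations Iteration cap.
#' @param gain Damping applied to each Zernike correction; values below 1
#'   keep the measurement-update feedback loop contractive.
#' @param psf_opts Options for the wave-optics simulation.
#' @return List: `wavefront` (`qlfm_wavefront` from the accumulated Zernike
#'   coefficients), `coefficients`, `psf` (calibrated z = 0 phase-space
#'   PSF), `iterations`, `converged`, `score_trace` (mean per-angle
#'   correlation per iteration).
#' @export
calibrate_psf <- function(captured_frame, config, n_modes = 15L,
                          tol = 1 / 50, max_iterations = 10L, gain = 0.7,
                          psf_opts = psf_options(sim_lenses = NULL)) {
  captured <- if (inherits(captured_frame, "qlfm_frame")) {
    realign(captured_frame)
  } else captured_frame
  if (is.null(psf_opts$sim_lenses)) {
    psf_opts$sim_lenses <- dim(captured)[3]
    if (psf_opts$sim_lenses %% 2L == 0L) {
      psf_opts$sim_lenses <- psf_opts$sim_lenses + 1L
    }
  }
  coeffs <- numeric(n_modes)
  best_coeffs <- coeffs
  best_score <- -Inf
  score_trace <- numeric(0)
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iterations)) {
    iterations <- it
    wf <- zernike_wavefront(coeffs, pupil_samples = 64L)
    sim <- compute_psf(config, 0, wf, opts = psf_opts)
    shifts <- estimate_subaperture_shifts(captured, sim)
    score <- mean(shifts$score[shifts$valid])
    score_trace <- c(score_trace, score)
    if (score < best_score - 1e-4) {
      # the phase map has stopped improving: the previous iterate is the
      # converged estimate
      coeffs <- best_coeffs
      converged <- TRUE
      break
    }
    if (score > best_score) {
      best_score <- score
      best_coeffs <- coeffs
    }
    zon <- integrate_shifts_to_wavefront(shifts, config)
    dc <- gain * fit_zernike(zon, n_modes)
    dc[1] <- 0                       # piston carries no information
    coeffs <- coeffs + dc
    if (sqrt(mean(dc[-1]^2)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("phase retrieval did not converge within ", max_iterations,
            " iterations; returning best iterate", call. = FALSE)
  }
  final_coeffs <- coeffs
  final_coeffs[2:3] <- 0             # tip/tilt only translate the image
  wf <- zernike_wavefront(final_coeffs, pupil_samples = 64L)
  psf <- compute_psf(config, 0, wf, opts = psf_opts)
  list(wavefront = wf, coefficients = coeffs, psf = psf,
       iterations = iterations, converged = converged,
       score_trace = score_trace)
}
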