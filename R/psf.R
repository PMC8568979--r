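# Simulation of the phase-space (per-angular-component) light-field PSF.
#
# Near the native objective plane the PSF is computed with scalar wave
# optics: a Debye-type pupil integral (defocus + aberration phase) gives the
# field at the image plane, the microlens array applies its thin-lens phase,
# Fresnel propagation carries the field to the MLA back focal plane, the
# intensity is box-integrated over camera pixels, and pixel realignment
# yields one lateral convolution kernel per angular component and depth.
#
# Far from focus, where the geometric blur dwarfs diffraction, each angular
# component reduces to a displaced sub-aperture blur: a kernel centered at
# z * tan(theta_u) with a width set by the sub-aperture cone.  Kernels there
# are generated directly at the (coarse) slab sampling from this geometric
# model.  The handoff depth is chosen so the wave simulation grid always
# contains the full blur.
#
# Kernels are shift-invariant on the lens grid (the phase-space
# approximation): spatial variation of the PSF within a lenslet is folded
# into the angular dimension, which is what makes lateral sampling at the
# lens pitch sufficient.

#' Options controlling PSF computation
#'
#' @param oversample Sub-pixel simulation factor per camera pixel (box
#'   integration over pixel areas uses `oversample^2` samples).
#' @param sim_lenses Odd number of lenslets simulated for the wave-optics
#'   path; determines both the maximum kernel support near focus and the
#'   pupil sampling density (default 31, which samples the pupil diameter
#'   with ~250 points for the 13-pixel geometry).
#' @param wave_z_max Depth (um) up to which the wave-optics path is used;
#'   `NULL` chooses the largest |z| whose geometric blur is safely contained
#'   in the simulation field of view.
#' @param support_energy Fraction of kernel energy the cropped support must
#'   retain.
#' @return A list of options.
#' @export
psf_options <- function(oversample = 3L, sim_lenses = 31L,
                        wave_z_max = NULL, support_energy = 0.999) {
  if (sim_lenses %% 2L == 0L) sim_lenses <- sim_lenses + 1L
  list(oversample = as.integer(oversample),
       sim_lenses = as.integer(sim_lenses),
       wave_z_max = wave_z_max,
       support_energy = support_energy)
}

# --- geometry helpers -------------------------------------------------------

# Per-angle pupil patch geometry: disk-overlap weights and disk-weighted
# object-side ray-tangent moments (mean tangent vector and tangent spread),
# computed numerically over each patch.  Edge patches are clipped by the
# pupil rim, which pulls their effective centroid inward -- the wave-optics
# path reproduces this automatically, the geometric path needs the weighted
# moments.
pupil_patches <- function(config) {
  half <- angular_half(config)
  step <- pupil_step(config)
  u <- seq(-half, half)
  grid <- expand.grid(v = u, u = u)  # v varies fastest = kernel dim 1
  cx <- grid$u * step
  cy <- grid$v * step
  na_over_n <- config$objective_na / config$immersion_index
  sub <- (seq_len(24) - 0.5) / 24 - 0.5
  n <- nrow(grid)
  w <- tx <- ty <- tsd <- numeric(n)
  for (i in seq_len(n)) {
    px <- rep(cx[i] + sub * step, each = 24)
    py <- rep(cy[i] + sub * step, times = 24)
    r2 <- px^2 + py^2
    ins <- r2 <= 1
    w[i] <- mean(ins)
    if (!any(ins)) next
    sx <- px[ins] * na_over_n
    sy <- py[ins] * na_over_n
    sc <- 1 / sqrt(pmax(1 - pmin(sx^2 + sy^2, 0.96), 0.04))
    txi <- sx * sc
    tyi <- sy * sc
    tx[i] <- mean(txi); ty[i] <- mean(tyi)
    tsd[i] <- sqrt((stats::var(txi) + stats::var(tyi)) / 2 + 1e-12)
  }
  w <- w * step^2            # patch area x coverage
  w <- w / sum(w)            # total unit energy over all angular components
  list(u = grid$u, v = grid$v, cx = cx, cy = cy, weight = w,
       tan_x = tx, tan_y = ty, tan_sd = tsd,
       half = half, step = step)
}

# Sample-plane chief-ray displacement (um) for pupil position (cx, cy) at
# depth z.  Sign convention: with +z toward the objective, the image of a
# defocused point in angular component u is displaced along +u for z > 0
# (verified against the wave-optics path in the test suite).
geom_displacement <- function(config, cx, cy, z) {
  na_over_n <- config$objective_na / config$immersion_index
  sx <- cx * na_over_n
  sy <- cy * na_over_n
  s2 <- pmin(sx^2 + sy^2, 0.96)
  t <- 1 / sqrt(1 - s2)
  cbind(z * sx * t, z * sy * t)
}

# --- wave-optics PSF --------------------------------------------------------

# Sensor-plane intensity PSF (camera-pixel sampled) for a point source on
# the optical axis at depth z; returns the realigned kernel array
# (ppl, ppl, n_lens, n_lens) in *unnormalized* energy units.
wave_kernel <- function(config, z, wavefront = NULL, opts = psf_options()) {
  ppl <- config$pixels_per_lens
  os <- opts$oversample
  nl <- opts$sim_lenses
  N <- nl * ppl * os
  dx <- config$mla_pitch / (ppl * os)          # image-plane sampling (um)
  lambda <- config$emission_wavelength
  f_max <- config$objective_na / (lambda * config$effective_magnification)
  o <- seq_len(N) - center_index(N)
  fx <- o / (N * dx)
  if (max(abs(fx)) < f_max) {
    stop("pupil exceeds the simulated frequency support; increase oversample",
         call. = FALSE)
  }
  FX <- matrix(fx, N, N, byrow = TRUE)
  FY <- matrix(fx, N, N)
  rho2 <- (FX^2 + FY^2) / f_max^2
  mask <- rho2 <= 1
  n_imm <- config$immersion_index
  na_ratio2 <- (config$objective_na / n_imm)^2
  # defocus: object-side axial phase n*k*z*cos(theta)
  phase <- (2 * pi / lambda) * z * n_imm * sqrt(pmax(0, 1 - na_ratio2 * rho2))
  if (!is.null(wavefront)) {
    phase <- phase + matrix(
      wavefront_phase_at(wavefront, as.vector(FX) / f_max, as.vector(FY) / f_max),
      N, N)
  }
  P <- mask * exp(1i * phase)
  U_mla <- fft2c(P)
  # microlens array: tiled thin-lens quadratic phase, 100% fill, square cells
  xg <- o * dx
  xl <- ((xg + config$mla_pitch / 2) %% config$mla_pitch) - config$mla_pitch / 2
  XL2 <- outer(xl^2, xl^2, `+`)
  U2 <- U_mla * exp(-1i * pi / (lambda * config$mla_focal_length) * XL2)
  # Fresnel propagation over f_mla to the MLA back focal plane
  H <- exp(-1i * pi * lambda * config$mla_focal_length * (FX^2 + FY^2))
  U_s <- ifft2c(fft2c(U2) * H)
  I <- Re(U_s * Conj(U_s))
  # box-integrate over camera pixels (os x os blocks)
  npix <- nl * ppl
  ky <- (seq_len(N) - 1L) %/% os
  I_pix <- t(rowsum(t(rowsum(I, ky)), ky))
  # realign into angular components: kernel[v, u, lens_y, lens_x]
  kern <- array(0, dim = c(ppl, ppl, nl, nl))
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      kern[vi, ui, , ] <- I_pix[seq(vi, npix, by = ppl), seq(ui, npix, by = ppl)]
    }
  }
  kern
}

# Crop kernel support to the smallest centered odd box keeping `frac` of the
# total energy (jointly over all angles).
crop_kernel <- function(kern, frac) {
  d <- dim(kern)
  nl <- d[3]
  marg <- apply(kern, c(3, 4), sum)
  tot <- sum(marg)
  c0 <- center_index(nl)
  r <- 0L
  while (r < c0 - 1L) {
    idx <- (c0 - r):(c0 + r)
    if (sum(marg[idx, idx]) >= frac * tot) break
    r <- r + 1L
  }
  idx <- (c0 - r):(c0 + r)
  kern[, , idx, idx, drop = FALSE]
}

# Reduce a fine (factor-1) kernel to lateral factor s by centered block
# summation (energies add), returning an odd-sized kernel.
kernel_coarsen <- function(kern, s) {
  if (s == 1L) return(kern)
  d <- dim(kern)
  m <- as.integer(ceiling(d[3] / s))
  if (m %% 2L == 0L) m <- m + 1L
  out <- array(0, dim = c(d[1], d[2], m, m))
  for (vi in seq_len(d[1])) {
    for (ui in seq_len(d[2])) {
      out[vi, ui, , ] <- s * s * downsample_lateral(kern[vi, ui, , ], s, m, m)
    }
  }
  out
}

# --- geometric far-field PSF ------------------------------------------------

geom_kernel <- function(config, z, s, wavefront = NULL, patches = NULL) {
  if (is.null(patches)) patches <- pupil_patches(config)
  ppl <- config$pixels_per_lens
  step_lat <- lens_sampling(config) * s
  lambda <- config$emission_wavelength
  disp <- cbind(z * patches$tan_x, z * patches$tan_y)
  if (!is.null(wavefront) && length(wavefront$zernike_coefficients) > 1) {
    # aberration slope shifts each sub-aperture image (same relation the
    # calibration inverts): dx = -(lambda / NA) * dW/drho
    eps <- 1e-3
    gx <- (wavefront_phase_at(wavefront, patches$cx + eps, patches$cy) -
           wavefront_phase_at(wavefront, patches$cx - eps, patches$cy)) /
          (2 * eps * 2 * pi)
    gy <- (wavefront_phase_at(wavefront, patches$cx, patches$cy + eps) -
           wavefront_phase_at(wavefront, patches$cx, patches$cy - eps)) /
          (2 * eps * 2 * pi)
    disp[, 1] <- disp[, 1] - lambda / config$objective_na * gx
    disp[, 2] <- disp[, 2] - lambda / config$objective_na * gy
  }
  na_sub <- config$objective_na * patches$step
  sigma0 <- 0.42 * lambda / na_sub      # diffraction floor of a sub-aperture
  sigma <- sqrt((abs(z) * patches$tan_sd)^2 + sigma0^2)
  R <- ceiling((max(abs(disp)) + 4 * max(sigma)) / step_lat)
  nk <- 2L * as.integer(R) + 1L
  ax <- (seq_len(nk) - center_index(nk)) * step_lat
  kern <- array(0, dim = c(ppl, ppl, nk, nk))
  for (i in seq_along(patches$u)) {
    if (patches$weight[i] <= 0) next
    gy <- exp(-(ax - disp[i, 2])^2 / (2 * sigma[i]^2))
    gx <- exp(-(ax - disp[i, 1])^2 / (2 * sigma[i]^2))
    k2 <- outer(gy, gx)
    ssum <- sum(k2)
    if (ssum <= 0) next
    vi <- patches$v[i] + patches$half + 1L
    ui <- patches$u[i] + patches$half + 1L
    kern[vi, ui, , ] <- k2 / ssum * patches$weight[i]
  }
  kern
}

# --- public API -------------------------------------------------------------

#' Compute the phase-space PSF at a set of depths
#'
#' @param config A `qlfm_config`.
#' @param depths Axial positions (um, signed; z = 0 at the native objective
#'   plane, +z toward the objective).
#' @param wavefront Optional `qlfm_wavefront` aberration (piston ignored).
#' @param factors Integer lateral coarsening factor per depth (recycled);
#'   kernels for factor `s` are sampled at `s` times the lens pitch.
#' @param opts Options from [psf_options()].
#' @return An object of class `qlfm_psf`: list with `planes` (data frame
#'   `z`, `factor`), `kernels` (list of `(ppl, ppl, ky, kx)` arrays),
#'   `config`, `wavefront`, and `energy` (per-depth total energy relative to
#'   the in-focus total).
#' @export
compute_psf <- function(config, depths, wavefront = NULL, factors = 1L,
                        opts = psf_options()) {
  if (!length(depths) || !all(is.finite(depths))) {
    stop("depth list must be non-empty and finite", call. = FALSE)
  }
  factors <- as.integer(rep_len(factors, length(depths)))
  p_s <- lens_sampling(config)
  sin_t <- config$objective_na / config$immersion_index
  tan_t <- sin_t / sqrt(1 - sin_t^2)
  half_fov <- opts$sim_lenses / 2 * p_s
  wave_z_max <- opts$wave_z_max
  if (is.null(wave_z_max)) {
    wave_z_max <- max(0.8 * (half_fov - 2 * p_s) / tan_t, p_s)
  }
  patches <- pupil_patches(config)
  # in-focus reference energy for normalization and bookkeeping
  k0 <- wave_kernel(config, 0, wavefront, opts)
  E0 <- sum(k0)
  kernels <- vector("list", length(depths))
  energy <- numeric(length(depths))
  for (i in seq_along(depths)) {
    z <- depths[i]
    s <- factors[i]
    if (abs(z) <= wave_z_max) {
      k <- if (z == 0) k0 else wave_kernel(config, z, wavefront, opts)
      k <- k / E0
      k <- crop_kernel(k, opts$support_energy)
      if (s > 1L) k <- kernel_coarsen(k, s)
    } else {
      k <- geom_kernel(config, z, s, wavefront, patches)
    }
    kernels[[i]] <- k
    energy[i] <- sum(k)
  }
  structure(list(planes = data.frame(z = depths, factor = factors),
                 kernels = kernels, config = config, wavefront = wavefront,
                 energy = energy, wave_z_max = wave_z_max),
            class = "qlfm_psf")
}

#' Compute the phase-space PSF matched to a multiscale grid
#'
#' One kernel per axial sample plane of the grid, at that plane's lateral
#' sampling factor.
#'
#' @param config A `qlfm_config`.
#' @param grid A `qlfm_grid`.
#' @param wavefront Optional `qlfm_wavefront`.
#' @param opts Options from [psf_options()].
#' @param scan_shifts Optional axial scan positions (um); kernels are then
#'   computed for every `z - shift` combination and stored per shift.
#' @return A `qlfm_psf` (with `shift` column in `planes` when scanning).
#' @export
psf_for_grid <- function(config, grid, wavefront = NULL, opts = psf_options(),
                         scan_shifts = 0) {
  pl <- grid$planes
  z_all <- as.vector(outer(pl$z, scan_shifts, `-`))
  f_all <- rep(pl$factor, times = length(scan_shifts))
  psf <- compute_psf(config, z_all, wavefront, f_all, opts)
  psf$planes$shift <- rep(scan_shifts, each = nrow(pl))
  psf$planes$grid_plane <- rep(seq_len(nrow(pl)), times = length(scan_shifts))
  psf
}

#' @export
print.qlfm_psf <- function(x, ...) {
  cat(sprintf("Phase-space PSF: %d planes, z in [%.1f, %.1f] um, wave-optics |z| <= %.1f um\n",
              nrow(x$planes), min(x$planes$z), max(x$planes$z), x$wave_z_max))
  cat(sprintf("  per-depth energy in [%.3f, %.3f] of in-focus total\n",
              min(x$energy), max(x$energy)))
  invisible(x)
}

# Index of the PSF plane matching (z, factor, shift); error if absent.
psf_plane_index <- function(psf, z, factor, shift = 0) {
  pl <- psf$planes
  sh <- if (!is.null(pl$shift)) pl$shift else rep(0, nrow(pl))
  i <- which(abs(pl$z - z) < 1e-6 & pl$factor == factor & abs(sh - shift) < 1e-6)
  if (length(i) != 1L) {
    stop(sprintf("no PSF plane at z = %.3f (factor %d, shift %.3f); volume grid depths must be a subset of the PSF depth list",
                 z, factor, shift), call. = FALSE)
  }
  i
}
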