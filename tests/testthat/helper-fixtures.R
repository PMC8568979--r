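# Shared fixtures, built lazily and cached for the whole test run.  The
# wave-optics PSF is the expensive piece; everything that can share one
# shares it.

.fx <- new.env(parent = emptyenv())

fx_config <- function() {
  if (is.null(.fx$config)) .fx$config <- lfm_preset_desk()
  .fx$config
}

# Uniform 10-plane grid over +-15 um with its PSF and projector.
fx_small <- function() {
  if (is.null(.fx$small)) {
    config <- fx_config()
    grid <- uniform_grid(-15, 15, 10, config)
    psf <- psf_for_grid(config, grid, opts = psf_options(sim_lenses = 21L))
    proj <- qlfm:::build_projector(psf, grid)
    .fx$small <- list(config = config, grid = grid, psf = psf, proj = proj)
  }
  .fx$small
}

# Tiny 3-depth grid with a 3x3-angle configuration for brute-force oracles.
fx_tiny <- function() {
  if (is.null(.fx$tiny)) {
    config <- optical_config(
      emission_wavelength = 0.525, objective_na = 1.0,
      objective_magnification = 40, immersion_index = 1.33,
      mla_pitch = 100, mla_focal_length = 2100,
      relay_magnification = 0.845, camera_pixel_pitch = 100 * 0.845 / 3,
      num_lenses = c(9L, 9L), effective_magnification = 100 / 2.15)
    grid <- uniform_grid(-6, 6, 3, config)
    psf <- psf_for_grid(config, grid, opts = psf_options(sim_lenses = 15L))
    proj <- qlfm:::build_projector(psf, grid)
    .fx$tiny <- list(config = config, grid = grid, psf = psf, proj = proj)
  }
  .fx$tiny
}

# Unaberrated z = 0 phase-space PSF of the full 13-pixel geometry, used by
# the calibration tests.
fx_calib <- function() {
  if (is.null(.fx$calib)) {
    config <- lfm_preset_40x()
    opts <- psf_options(sim_lenses = 15L)
    sim0 <- compute_psf(config, 0, NULL, opts = opts)
    .fx$calib <- list(config = config, opts = opts, sim0 = sim0)
  }
  .fx$calib
}

as_views <- function(arr, config) {
  structure(arr, class = "qlfm_views", config = config)
}

volume_centroid <- function(volume) {
  grid <- volume$grid
  pl <- grid$planes
  m <- 0; cy <- 0; cx <- 0; cz <- 0
  for (p in seq_len(nrow(pl))) {
    img <- volume$slabs[[pl$slab[p]]][, , pl$iz[p]]
    step <- pl$lateral_step[p]
    ys <- (seq_len(pl$ny[p]) - qlfm:::center_index(pl$ny[p])) * step
    xs <- (seq_len(pl$nx[p]) - qlfm:::center_index(pl$nx[p])) * step
    w <- sum(img)
    m <- m + w
    cy <- cy + sum(img * ys)
    cx <- cx + sum(t(img) * xs)
    cz <- cz + w * pl$z[p]
  }
  c(y = cy / m, x = cx / m, z = cz / m)
}
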