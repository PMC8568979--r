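# End-to-end simulation experiments used for validation: the scaled-down
# signal-to-background improvement study (complete-space multiscale
# scattering model vs incomplete-space reconstruction of the same views).

#' Signal-to-background improvement of the complete-space scattering model
#'
#' Generates a seeded bead-in-scattering phantom (beads in the fine axial
#' range, a smooth scattering potential, nonuniform out-of-focus background
#' in coarse slabs), simulates one noisy raw frame, reconstructs it with
#' (a) an incomplete-space model (fine slabs only, no scattering) and
#' (b) the full multiscale grid with ADMM scattering updates, and computes
#' the SBR of both reconstructions with identical bead/background ROIs.
#'
#' @param seed Integer seed driving the phantom and the noise.
#' @param config A `qlfm_config` (desk-scale default).
#' @param n_beads,bead_diameter Bead count and diameter (um).
#' @param fine_half_range Fine (bead-bearing) axial half-range (um).
#' @param coarse_half_range Complete-space half-range covered by coarse
#'   background slabs (um).
#' @param scattering_level Mean scattering potential.
#' @param background_level Out-of-focus background density relative to bead
#'   interior density.
#' @param peak_counts Poisson scaling: brightest sensor pixel, in counts.
#' @param opts Reconstruction options.
#' @param psf_opts PSF simulation options.
#' @return List: `ratio` (SBR fold-change, full / incomplete), `sbr_full`,
#'   `sbr_incomplete` (lists from [compute_sbr()]), `positions`, grids and
#'   reconstructions.
#' @export
sbr_improvement_experiment <- function(seed = 42L,
                                       config = lfm_preset_desk(),
                                       n_beads = 10L, bead_diameter = 2,
                                       fine_half_range = 60,
                                       coarse_half_range = 300,
                                       scattering_level = 0.05,
                                       background_level = 0.02,
                                       peak_counts = 1000,
                                       opts = recon_options(
                                         outer_iterations = 4L,
                                         inner_rl_iterations = 12L),
                                       psf_opts = psf_options(sim_lenses = 21L)) {
  model <- default_resolution_model(config, z_max = coarse_half_range)
  grid_full <- build_grid(-coarse_half_range, coarse_half_range, model, config,
                          fine_half_range = fine_half_range)
  grid_fine <- build_grid(-fine_half_range, fine_half_range, model, config,
                          fine_half_range = fine_half_range)
  psf_full <- psf_for_grid(config, grid_full, opts = psf_opts)
  proj_full <- build_projector(psf_full, grid_full)

  # Ground truth lives on its own, finer grid (factor <= 2), so the
  # out-of-focus background carries lateral structure the reconstruction
  # grids do not trivially represent -- as in real tissue.
  grid_truth <- build_grid(-coarse_half_range, coarse_half_range, model,
                           config, fine_half_range = fine_half_range,
                           max_factor = 2L)
  psf_truth <- psf_for_grid(config, grid_truth, opts = psf_opts)
  ph <- make_scattering_phantom(grid_truth, n_beads = n_beads,
                                bead_diameter = bead_diameter,
                                intensity = 100,
                                scattering_level = scattering_level,
                                background_level = background_level,
                                seed = seed)
  # Poisson scaling so the brightest sensor pixel sits at `peak_counts`
  proj_truth <- build_projector(psf_truth, grid_truth)
  S <- scattered_intensity(ph$volume, ph$potential, config)
  noiseless <- forward_project(volume_op(ph$volume, S, `+`), psf_truth,
                               proj_truth)
  photon_scale <- peak_counts / max(noiseless)
  cap <- simulate_capture(ph$volume, ph$potential, psf_truth, config,
                          photon_scale = photon_scale, read_noise_sd = 1.6,
                          seed = seed, proj = proj_truth)
  views <- cap$noisy_views

  # (a) incomplete space: fine slabs only, no scattering model
  psf_fine <- subset_psf(psf_full, grid_fine)
  rec_fine <- phase_space_deconvolve(views, psf_fine, grid_fine, opts)
  # (b) complete space with scattering updates
  rec_full <- admm_reconstruct(views, psf_full, grid_full, opts,
                               proj = proj_full)

  rois <- bead_rois(ph$positions)
  bg_roi <- background_roi(ph$positions, config, fine_half_range)
  sbr_inc <- compute_sbr(rec_fine, rois, bg_roi)
  sbr_full <- compute_sbr(rec_full$emission, rois, bg_roi)
  list(ratio = sbr_full$ratio / sbr_inc$ratio,
       sbr_full = sbr_full, sbr_incomplete = sbr_inc,
       positions = ph$positions, grid_full = grid_full,
       grid_fine = grid_fine, rec_full = rec_full, rec_fine = rec_fine,
       views = views, photon_scale = photon_scale)
}

# Restrict a PSF to the planes of a (sub-)grid.
subset_psf <- function(psf, grid) {
  pl <- grid$planes
  idx <- vapply(seq_len(nrow(pl)), function(p) {
    psf_plane_index(psf, pl$z[p], pl$factor[p])
  }, integer(1))
  psf$planes <- psf$planes[idx, , drop = FALSE]
  psf$kernels <- psf$kernels[idx]
  psf$energy <- psf$energy[idx]
  rownames(psf$planes) <- NULL
  psf
}

# Signal ROIs centered on the true bead positions (8 x 8 x 10 um).
bead_rois <- function(positions, extent = c(8, 8, 10)) {
  lapply(seq_len(nrow(positions)), function(i) {
    roi(positions[i, ], extent)
  })
}

# Background ROI: the candidate position in the fine region farthest from
# every bead.
background_roi <- function(positions, config, fine_half_range,
                           extent = c(8, 8, 10)) {
  p_s <- lens_sampling(config)
  half <- (min(config$num_lenses) / 2 - 2) * p_s
  cand <- expand.grid(y = seq(-half, half, length.out = 7),
                      x = seq(-half, half, length.out = 7),
                      z = seq(-fine_half_range * 0.9, fine_half_range * 0.9,
                              length.out = 9))
  dmin <- vapply(seq_len(nrow(cand)), function(i) {
    min(sqrt((positions[, 1] - cand$y[i])^2 + (positions[, 2] - cand$x[i])^2 +
             ((positions[, 3] - cand$z[i]) / 2)^2))
  }, numeric(1))
  best <- which.max(dmin)
  roi(c(cand$y[best], cand$x[best], cand$z[best]), extent)
}
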