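# Phase-space deconvolution, joint ADMM reconstruction, and the axial-scan
# reconstruction path.

test_that("a noiseless bead is localized to within half a sampling interval", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 1, bead_diameter = 2, intensity = 100,
                          seed = 3)
  cap <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                          photon_scale = NULL, read_noise_sd = 0, seed = 1,
                          proj = fx$proj)
  rec <- phase_space_deconvolve(cap$views, fx$psf, fx$grid,
                                recon_options(inner_rl_iterations = 10),
                                proj = fx$proj)
  cen <- volume_centroid(rec)
  expect_lt(abs(cen["y"] - ph$positions[1, "y"]), 0.5 * lens_sampling(fx$config))
  expect_lt(abs(cen["x"] - ph$positions[1, "x"]), 0.5 * lens_sampling(fx$config))
  expect_lt(abs(cen["z"] - ph$positions[1, "z"]),
            0.5 * fx$grid$slabs$axial_step)
  expect_true(all(unlist(rec$slabs) >= 0))
})

test_that("the Poisson loss never increases over accepted RL cycles", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 3, bead_diameter = 2, intensity = 100,
                          seed = 9)
  cap <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                          photon_scale = 5, read_noise_sd = 1.6, seed = 9,
                          proj = fx$proj)
  rec <- phase_space_deconvolve(cap$noisy_views, fx$psf, fx$grid,
                                recon_options(inner_rl_iterations = 6),
                                proj = fx$proj)
  trace <- attr(rec, "nll_trace")
  expect_gte(attr(rec, "cycles"), 1L)
  expect_true(all(diff(trace) <= 0))
})

test_that("uniform views under a uniform single-slab PSF stay flat", {
  cfg <- fx_config()
  g <- uniform_grid(-1, 1, 1, cfg)
  ppl <- cfg$pixels_per_lens
  # a synthetic PSF whose kernels are uniform over their support
  k <- array(1 / (ppl^2 * 9), dim = c(ppl, ppl, 3, 3))
  psf <- structure(list(planes = data.frame(z = g$planes$z, factor = 1L),
                        kernels = list(k), config = cfg, wavefront = NULL,
                        energy = 1, wave_z_max = Inf), class = "qlfm_psf")
  proj <- qlfm:::build_projector(psf, g)
  views <- qlfm:::new_views(cfg, fill = 10)
  ord <- qlfm:::angular_order(ppl)
  norms <- qlfm:::rl_normalizers(proj, g)
  I <- new_volume(g, 7)
  # simultaneous (all-angle) update: the error map of a flat volume under
  # uniform views is spatially constant away from the crop boundary, so no
  # structure is invented
  I <- qlfm:::rl_cycle_global(I, list(views), NULL, proj, 0, ord, norms,
                              eps = 1e-7)
  inner <- I$slabs[[1]][4:12, 4:12, 1]
  expect_lt((max(inner) - min(inner)) / mean(inner), 1e-6)
})

test_that("all-zero views return a zero volume with a warning", {
  fx <- fx_small()
  expect_warning(
    rec <- phase_space_deconvolve(qlfm:::new_views(fx$config), fx$psf,
                                  fx$grid, proj = fx$proj),
    "all-zero")
  expect_true(all(unlist(rec$slabs) == 0))
})

test_that("without scattering, ADMM matches plain deconvolution within 1%", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 2, bead_diameter = 2, intensity = 100,
                          seed = 13)
  cap <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                          photon_scale = NULL, read_noise_sd = 0, seed = 13,
                          proj = fx$proj)
  opts <- recon_options(outer_iterations = 2, inner_rl_iterations = 6)
  rec_rl <- phase_space_deconvolve(cap$views, fx$psf, fx$grid, opts,
                                   proj = fx$proj)
  rec_admm <- admm_reconstruct(cap$views, fx$psf, fx$grid, opts,
                               proj = fx$proj)
  rel <- qlfm:::volume_rel_change(rec_admm$emission, rec_rl)
  expect_lt(rel, 0.01)
  expect_true(all(unlist(rec_admm$emission$slabs) >= 0))
  expect_true(all(unlist(rec_admm$potential$slabs) >= 0))
  expect_true(all(diff(rec_admm$misfit_trace) <= 1e-9))
})

test_that("a single unshifted scan position reduces to the snapshot problem", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 2, bead_diameter = 2, intensity = 100,
                          seed = 17)
  cap <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                          photon_scale = NULL, read_noise_sd = 0, seed = 17,
                          proj = fx$proj)
  opts <- recon_options(outer_iterations = 2, inner_rl_iterations = 5)
  model <- default_resolution_model(fx$config)
  res_scan <- reconstruct_axial_scan(list(cap$views), 0, fx$config, model,
                                     opts, grid = fx$grid, psf = fx$psf)
  res_admm <- admm_reconstruct(cap$views, fx$psf, fx$grid, opts)
  expect_equal(res_scan$emission$slabs, res_admm$emission$slabs,
               tolerance = 1e-10)
})

test_that("a bead midway between scan planes reconstructs unimodally", {
  cfg <- fx_config()
  model <- default_resolution_model(cfg)
  grid <- build_grid(-40, 40, model, cfg, fine_half_range = 40)
  scan <- c(-15, 15)
  psf <- psf_for_grid(cfg, grid, opts = psf_options(sim_lenses = 21L),
                      scan_shifts = scan)
  vol <- qlfm:::add_sphere(new_volume(grid, 0), c(2.5, -3.2, 0), 1, 100)
  frames <- lapply(scan, function(s) {
    simulate_capture(vol, NULL, psf, cfg, photon_scale = NULL,
                     read_noise_sd = 0, seed = 1, shift = s)$views
  })
  res <- reconstruct_axial_scan(frames, scan, cfg, model,
                                recon_options(outer_iterations = 2,
                                              inner_rl_iterations = 8),
                                grid = grid, psf = psf,
                                with_scattering = FALSE)
  prof <- apply(res$emission$slabs[[1]], 3, max)
  pk <- which.max(prof)
  tol <- 1e-9 * max(prof)
  expect_true(all(diff(prof[1:pk]) >= -tol))
  expect_true(all(diff(prof[pk:length(prof)]) <= tol))
  expect_equal(grid$planes$z[pk], 0, tolerance = grid$slabs$axial_step[1])
})

test_that("identical beads across the scanned range reconstruct uniformly", {
  cfg <- fx_config()
  model <- default_resolution_model(cfg)
  grid <- build_grid(-40, 40, model, cfg, fine_half_range = 40)
  scan <- c(-15, 15)
  psf <- psf_for_grid(cfg, grid, opts = psf_options(sim_lenses = 21L),
                      scan_shifts = scan)
  pz <- grid$planes$z
  zi <- vapply(c(-24, -16, -8, 0, 8, 16, 24),
               function(z) pz[which.min(abs(pz - z))], numeric(1))
  lat <- cbind(c(-8.6, -4.3, 0, 4.3, 8.6, -6.45, 6.45),
               c(8.6, -6.45, 0, 6.45, -8.6, 2.15, -2.15))
  vol <- new_volume(grid, 0)
  for (i in seq_along(zi)) {
    vol <- qlfm:::add_sphere(vol, c(lat[i, 1], lat[i, 2], zi[i]), 1, 100)
  }
  frames <- lapply(scan, function(s) {
    simulate_capture(vol, NULL, psf, cfg, photon_scale = 3,
                     read_noise_sd = 1.6, seed = 19, shift = s)$noisy_views
  })
  res <- reconstruct_axial_scan(frames, scan, cfg, model,
                                recon_options(outer_iterations = 3,
                                              inner_rl_iterations = 10),
                                grid = grid, psf = psf,
                                with_scattering = FALSE)
  ms <- vapply(seq_along(zi), function(i) {
    qlfm:::roi_mean(res$emission,
                    roi(c(lat[i, 1], lat[i, 2], zi[i]), c(6.5, 6.5, 8)))
  }, numeric(1))
  expect_lt(stats::sd(ms) / mean(ms), 0.20)
})

test_that("unsorted or duplicate scan positions are rejected", {
  fx <- fx_small()
  model <- default_resolution_model(fx$config)
  v <- qlfm:::new_views(fx$config)
  expect_error(reconstruct_axial_scan(list(v, v), c(10, -10), fx$config,
                                      model),
               "strictly increasing")
  expect_error(reconstruct_axial_scan(list(v, v), c(10, 10), fx$config,
                                      model),
               "strictly increasing")
})
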