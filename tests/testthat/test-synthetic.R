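# Phantom generation and capture simulation.

test_that("an empty phantom has no beads and no intensity", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 0)
  expect_equal(nrow(ph$positions), 0L)
  expect_true(all(unlist(ph$volume$slabs) == 0))
})

test_that("phantom generation is deterministic in the seed", {
  fx <- fx_small()
  a <- make_bead_phantom(fx$grid, 5, seed = 101)
  b <- make_bead_phantom(fx$grid, 5, seed = 101)
  c2 <- make_bead_phantom(fx$grid, 5, seed = 102)
  expect_identical(a$positions, b$positions)
  expect_identical(a$volume$slabs, b$volume$slabs)
  expect_false(identical(a$positions, c2$positions))
})

test_that("rendered bead mass matches the analytic sphere integral", {
  fx <- fx_small()
  for (seed in c(3, 4)) {
    ph <- make_bead_phantom(fx$grid, 1, bead_diameter = 4, intensity = 50,
                            seed = seed)
    analytic <- 4 / 3 * pi * 2^3 * 50
    expect_equal(volume_mass(ph$volume), analytic, tolerance = 0.02)
  }
  # sub-voxel beads carry the full analytic mass into one voxel
  ph2 <- make_bead_phantom(fx$grid, 1, bead_diameter = 0.5, intensity = 50,
                           seed = 5)
  expect_equal(volume_mass(ph2$volume), 4 / 3 * pi * 0.25^3 * 50,
               tolerance = 0.02)
})

test_that("zero scattering level produces an identically zero potential", {
  cfg <- fx_config()
  m <- default_resolution_model(cfg)
  g <- build_grid(-150, 150, m, cfg, fine_half_range = 40)
  ph <- make_scattering_phantom(g, n_beads = 3, scattering_level = 0,
                                seed = 7)
  expect_true(all(unlist(ph$potential$slabs) == 0))
})

test_that("the scattering potential mean tracks the requested level", {
  cfg <- fx_config()
  m <- default_resolution_model(cfg)
  g <- build_grid(-150, 150, m, cfg, fine_half_range = 40)
  ph <- make_scattering_phantom(g, n_beads = 3, scattering_level = 0.08,
                                seed = 11)
  fine <- which(g$slabs$factor == 1L)
  expect_equal(mean(unlist(ph$potential$slabs[fine])), 0.08,
               tolerance = 0.05 * 0.08)
})

test_that("the background layer is confined to the coarse slabs", {
  cfg <- fx_config()
  m <- default_resolution_model(cfg)
  g <- build_grid(-150, 150, m, cfg, fine_half_range = 40)
  ph <- make_scattering_phantom(g, n_beads = 0, background_level = 0.05,
                                seed = 13)
  fine <- which(g$slabs$factor == 1L)
  coarse <- setdiff(seq_len(nrow(g$slabs)), fine)
  expect_true(all(unlist(ph$volume$slabs[fine]) == 0))
  expect_gt(sum(unlist(ph$volume$slabs[coarse])), 0)
})

test_that("capture simulation is deterministic and unbiased under Poisson noise", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 2, bead_diameter = 2, intensity = 100,
                          seed = 17)
  a <- simulate_capture(ph$volume, NULL, fx$psf, fx$config, photon_scale = 2,
                        read_noise_sd = 1.6, seed = 5, proj = fx$proj)
  b <- simulate_capture(ph$volume, NULL, fx$psf, fx$config, photon_scale = 2,
                        read_noise_sd = 1.6, seed = 5, proj = fx$proj)
  expect_identical(a$frame$sensor_image, b$frame$sensor_image)
  # the mean over seeded draws approaches the noiseless frame
  clean <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                            photon_scale = NULL, read_noise_sd = 0,
                            seed = 1, proj = fx$proj)$frame$sensor_image
  scale <- 2
  n_draw <- 200
  acc <- 0
  for (k in seq_len(n_draw)) {
    acc <- acc + simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                                  photon_scale = scale, read_noise_sd = 0,
                                  seed = 1000 + k, proj = fx$proj)$frame$sensor_image
  }
  avg <- acc / n_draw
  # aggregate z-score of the total count: within 3 standard errors
  tot_se <- sqrt(sum(clean) / scale / n_draw)
  expect_lt(abs(sum(avg) - sum(clean)), 3 * tot_se)
})

test_that("a noise-free single bead frame is the translated impulse response", {
  fx <- fx_small()
  vol <- new_volume(fx$grid, 0)
  vol$slabs[[1]][8, 8, 4] <- 1
  cap <- simulate_capture(vol, NULL, fx$psf, fx$config, photon_scale = NULL,
                          read_noise_sd = 0, seed = 1, proj = fx$proj)
  dV <- fx$grid$slabs$lateral_step^2 * fx$grid$slabs$axial_step
  k <- fx$psf$kernels[[4]]
  want <- qlfm:::extract_centered(k[3, 3, , ], 15, 15) * dV
  expect_equal(cap$noisy_views[3, 3, , ], want, tolerance = 1e-10)
})

test_that("negative noise parameters are rejected", {
  fx <- fx_small()
  vol <- new_volume(fx$grid, 0)
  expect_error(simulate_capture(vol, NULL, fx$psf, fx$config,
                                read_noise_sd = -1), ">= 0")
  expect_error(simulate_capture(vol, NULL, fx$psf, fx$config,
                                photon_scale = 0), "positive")
})

test_that("the full loop recovers bead count and positions", {
  fx <- fx_small()
  ph <- make_bead_phantom(fx$grid, 3, bead_diameter = 2, intensity = 100,
                          seed = 23)
  cap <- simulate_capture(ph$volume, NULL, fx$psf, fx$config,
                          photon_scale = 20, read_noise_sd = 1.0, seed = 23,
                          proj = fx$proj)
  rec <- phase_space_deconvolve(cap$noisy_views, fx$psf, fx$grid,
                                recon_options(inner_rl_iterations = 12),
                                proj = fx$proj)
  # each true bead has a local mass peak within half a sampling interval
  p_s <- lens_sampling(fx$config)
  dz <- fx$grid$slabs$axial_step
  for (i in seq_len(nrow(ph$positions))) {
    pos <- ph$positions[i, ]
    r_in <- roi(pos, c(2 * p_s, 2 * p_s, 2 * dz))
    r_out <- roi(pos, c(6 * p_s, 6 * p_s, 5 * dz))
    m_in <- qlfm:::roi_mean(rec, r_in)
    m_out <- qlfm:::roi_mean(rec, r_out)
    expect_gt(m_in, m_out)   # concentration at the true position
  }
})
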