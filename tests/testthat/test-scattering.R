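# Incoherent first-Born scattering operator and the potential update.

# Uniform unit-spacing 8x8x8 grid for closed-form and brute-force checks.
unit_grid8 <- function() {
  cfg <- lfm_preset_desk(num_lenses = c(8L, 8L))
  g <- uniform_grid(-4, 4, 8, cfg)
  g$slabs$lateral_step <- 1; g$planes$lateral_step <- 1
  g$slabs$axial_step <- 1; g$planes$axial_step <- 1
  list(config = cfg, grid = g)
}

test_that("zero potential scatters nothing", {
  u <- unit_grid8()
  I <- new_volume(u$grid, 1)
  F0 <- new_volume(u$grid, 0)
  S <- scattered_intensity(I, F0, u$config)
  expect_true(all(unlist(S$slabs) == 0))
})

test_that("a co-located unit source and potential give 1/8 at two voxels", {
  u <- unit_grid8()
  I <- new_volume(u$grid, 0); I$slabs[[1]][4, 4, 4] <- 1
  F1 <- new_volume(u$grid, 0); F1$slabs[[1]][4, 4, 4] <- 1
  S <- scattered_intensity(I, F1, u$config)
  # (1/2) * 1 * 1 / 2^2 at distance two voxels, voxel volume 1
  expect_equal(S$slabs[[1]][4, 4, 6], 0.125, tolerance = 1e-9)
  expect_equal(S$slabs[[1]][4, 6, 4], 0.125, tolerance = 1e-9)
  expect_equal(S$slabs[[1]][6, 4, 4], 0.125, tolerance = 1e-9)
})

test_that("the frequency-domain operator equals direct double summation", {
  u <- unit_grid8()
  set.seed(41)
  I <- new_volume(u$grid, 0); I$slabs[[1]][] <- runif(512)
  Fv <- new_volume(u$grid, 0); Fv$slabs[[1]][] <- runif(512)
  S <- scattered_intensity(I, Fv, u$config)
  P <- I$slabs[[1]] * Fv$slabs[[1]]
  co <- as.matrix(expand.grid(y = 1:8, x = 1:8, z = 1:8))
  direct <- array(0, c(8, 8, 8))
  for (i in seq_len(nrow(co))) {
    d2 <- (co[, 1] - co[i, 1])^2 + (co[, 2] - co[i, 2])^2 +
      (co[, 3] - co[i, 3])^2
    d2[d2 == 0] <- 3 / 4   # half voxel diagonal squared
    direct[co[i, 1], co[i, 2], co[i, 3]] <- 0.5 * sum(P[co] / d2)
  }
  expect_lt(max(abs(S$slabs[[1]] - direct)) / max(direct), 1e-6)
})

test_that("scattering commutes with translation away from boundaries", {
  u <- unit_grid8()
  I <- new_volume(u$grid, 0); I$slabs[[1]][3, 3, 3] <- 2
  F1 <- new_volume(u$grid, 0); F1$slabs[[1]][3, 3, 3] <- 0.5
  I2 <- new_volume(u$grid, 0); I2$slabs[[1]][5, 4, 5] <- 2
  F2 <- new_volume(u$grid, 0); F2$slabs[[1]][5, 4, 5] <- 0.5
  S1 <- scattered_intensity(I, F1, u$config)$slabs[[1]]
  S2 <- scattered_intensity(I2, F2, u$config)$slabs[[1]]
  # compare on the overlap of the translated supports
  expect_equal(S1[2:6, 2:7, 2:6], S2[4:8, 3:8, 4:8], tolerance = 1e-9)
})

test_that("total scattered energy is bounded by the kernel mass", {
  u <- unit_grid8()
  set.seed(42)
  I <- new_volume(u$grid, 0); I$slabs[[1]][] <- runif(512)
  Fv <- new_volume(u$grid, 0); Fv$slabs[[1]][] <- runif(512)
  S <- scattered_intensity(I, Fv, u$config)
  K <- qlfm:::inverse_square_kernel(8, 8, 8, 1, 1, 1)
  bound <- 0.5 * sum(K) * sum(I$slabs[[1]] * Fv$slabs[[1]])
  expect_lte(sum(S$slabs[[1]]), bound)
})

test_that("the potential update is projected and monotone", {
  fx <- fx_small()
  set.seed(43)
  vol <- new_volume(fx$grid, 1)
  vol$slabs[[1]][8, 8, 5] <- 60
  Ft <- new_volume(fx$grid, 0)
  Ft$slabs[[1]][] <- 0.05
  cap <- simulate_capture(vol, Ft, fx$psf, fx$config, photon_scale = 20,
                          read_noise_sd = 0.5, seed = 43, proj = fx$proj)
  # zero residual: potential unchanged
  S <- scattered_intensity(vol, Ft, fx$config)
  exact <- forward_project(qlfm:::volume_op(vol, S, `+`), fx$psf, fx$proj)
  up0 <- update_potential(vol, exact, fx$psf, Ft, lambda_f = 0,
                          proj = fx$proj, config = fx$config)
  expect_lt(qlfm:::volume_rel_change(up0$potential, Ft), 0.05)
  # noisy views: accepted step decreases the misfit, stays non-negative
  up <- update_potential(vol, cap$noisy_views, fx$psf, new_volume(fx$grid, 0),
                         proj = fx$proj, config = fx$config)
  expect_true(all(unlist(up$potential$slabs) >= 0))
  up2 <- update_potential(vol, cap$noisy_views, fx$psf, up$potential,
                          proj = fx$proj, config = fx$config)
  expect_lte(up2$misfit, up$misfit)
})

test_that("a smooth potential blob is recovered where emission has support", {
  fx <- fx_small()
  vol <- new_volume(fx$grid, 2)   # uniform emission so F is observable
  vol <- qlfm:::add_sphere(vol, c(-6.45, 4.3, -6), 1, 100)
  vol <- qlfm:::add_sphere(vol, c(6.45, -4.3, 6), 1, 100)
  Ft <- new_volume(fx$grid, 0)
  ci <- qlfm:::center_index(15)
  ys <- (seq_len(15) - ci) * 2.15
  zs <- fx$grid$planes$z
  for (p in 1:10) {
    Ft$slabs[[1]][, , p] <- outer(exp(-ys^2 / 72), exp(-ys^2 / 72)) *
      exp(-zs[p]^2 / 128) * 0.1
  }
  cap <- simulate_capture(vol, Ft, fx$psf, fx$config, photon_scale = 10,
                          read_noise_sd = 0.5, seed = 5, proj = fx$proj)
  F_est <- new_volume(fx$grid, 0)
  for (it in 1:10) {
    F_est <- update_potential(vol, cap$noisy_views, fx$psf, F_est,
                              proj = fx$proj, config = fx$config)$potential
  }
  r <- pearson(as.vector(F_est$slabs[[1]]), as.vector(Ft$slabs[[1]]))
  expect_gt(r, 0.8)
})
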