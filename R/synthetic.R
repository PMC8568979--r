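# Ground-truth phantoms and simulated captures: fluorescent beads in a
# clear or scattering medium, a nonuniform out-of-focus background confined
# to the coarse slabs, and the full capture chain (forward projection of
# direct + scattered light, inverse realignment, Poisson shot noise,
# Gaussian read noise).  Everything is seeded and returns exact ground
# truth, so each reconstruction stage can be validated end to end without
# any external data.

#' Random fluorescent-bead phantom
#'
#' Places `n_beads` spheres uniformly at random within the fine (factor-1)
#' region of the grid, rendered with sub-voxel antialiasing (3x3x3
#' supersampled occupancy fractions).  Beads smaller than a voxel become
#' single-voxel sources carrying the full analytic sphere mass.
#'
#' @param grid A `qlfm_grid`.
#' @param n_beads Number of beads.
#' @param bead_diameter Bead diameter (um); 0 gives point sources.
#' @param intensity Emission density of the bead interior (photons per um^3
#'   per exposure, arbitrary linear units).
#' @param seed Integer seed.
#' @param margin Lateral/axial margin (um) kept free at the fine-region
#'   border.
#' @return List: `volume` (a `qlfm_volume`), `positions` (n x 3 matrix of
#'   exact continuous positions: y, x, z in um).
#' @export
make_bead_phantom <- function(grid, n_beads, bead_diameter = 2,
                              intensity = 100, seed = 1L, margin = 4) {
  if (bead_diameter < 0) stop("bead_diameter must be >= 0", call. = FALSE)
  if (n_beads > grid_voxel_count(grid)) {
    stop("more beads than voxels", call. = FALSE)
  }
  vol <- new_volume(grid, 0)
  if (n_beads == 0) {
    return(list(volume = vol, positions = matrix(numeric(0), 0, 3,
                dimnames = list(NULL, c("y", "x", "z")))))
  }
  fine <- which(grid$slabs$factor == 1L)
  if (!length(fine)) fine <- seq_len(nrow(grid$slabs))
  z_lo <- min(grid$slabs$z_start[fine]) + margin
  z_hi <- max(grid$slabs$z_end[fine]) - margin
  half_y <- (grid$num_lenses[1] * grid$base_lateral) / 2 - margin
  half_x <- (grid$num_lenses[2] * grid$base_lateral) / 2 - margin
  set.seed(seed)
  pos <- cbind(y = stats::runif(n_beads, -half_y, half_y),
               x = stats::runif(n_beads, -half_x, half_x),
               z = stats::runif(n_beads, z_lo, z_hi))
  for (i in seq_len(n_beads)) {
    vol <- add_sphere(vol, pos[i, ], bead_diameter / 2, intensity)
  }
  list(volume = vol, positions = pos)
}

# Render one sphere into a multiscale volume by supersampled occupancy.
add_sphere <- function(vol, center, radius, intensity) {
  grid <- vol$grid
  pl <- grid$planes
  sphere_mass <- if (radius > 0) 4 / 3 * pi * radius^3 * intensity else intensity
  touched <- FALSE
  for (p in seq_len(nrow(pl))) {
    dzp <- pl$axial_step[p]
    if (abs(pl$z[p] - center[3]) > radius + dzp / 2) next
    step <- pl$lateral_step[p]
    ny <- pl$ny[p]; nx <- pl$nx[p]
    cy <- (seq_len(ny) - center_index(ny)) * step
    cx <- (seq_len(nx) - center_index(nx)) * step
    iy <- which(abs(cy - center[1]) <= radius + step / 2)
    ix <- which(abs(cx - center[2]) <= radius + step / 2)
    if (!length(iy) || !length(ix)) next
    if (radius == 0) next
    # occupancy: exact chord length along z, supersampled laterally
    nsub <- max(4L, min(16L, ceiling(step / (radius / 8))))
    sub <- ((seq_len(nsub) - 0.5) / nsub - 0.5) * step
    z0 <- pl$z[p] - dzp / 2
    z1 <- pl$z[p] + dzp / 2
    img <- vol$slabs[[pl$slab[p]]][, , pl$iz[p]]
    for (a in iy) for (b in ix) {
      yy <- cy[a] + sub - center[1]
      xx <- cx[b] + sub - center[2]
      d2 <- outer(yy^2, xx^2, `+`)
      h2 <- radius^2 - d2
      h <- sqrt(pmax(h2, 0))
      lo <- pmax(center[3] - h, z0)
      hi <- pmin(center[3] + h, z1)
      frac <- sum(pmax(hi - lo, 0)) / (nsub * nsub * dzp)
      if (frac > 0) {
        img[a, b] <- img[a, b] + intensity * frac
        touched <- TRUE
      }
    }
    vol$slabs[[pl$slab[p]]][, , pl$iz[p]] <- img
  }
  if (radius == 0 || !touched) {
    # sub-voxel bead: all mass into the nearest voxel as density
    p <- which.min(abs(pl$z - center[3]))
    step <- pl$lateral_step[p]
    ny <- pl$ny[p]; nx <- pl$nx[p]
    a <- min(max(round(center[1] / step) + center_index(ny), 1L), ny)
    b <- min(max(round(center[2] / step) + center_index(nx), 1L), nx)
    dV <- step^2 * pl$axial_step[p]
    vol$slabs[[pl$slab[p]]][a, b, pl$iz[p]] <-
      vol$slabs[[pl$slab[p]]][a, b, pl$iz[p]] + sphere_mass / dV
  }
  vol
}

# Smooth non-negative random field on a slab (low-pass filtered white
# noise, rescaled to a given mean).
smooth_field <- function(ny, nx, nz, mean_level, smooth_sigma = 2) {
  raw <- array(stats::rnorm(ny * nx * nz), c(ny, nx, nz))
  k1 <- function(n) {
    if (n == 1) return(matrix(1, 1, 1))
    x <- seq_len(min(2 * ceiling(2 * smooth_sigma) + 1, 2 * n - 1))
    x <- x - center_index(length(x))
    w <- exp(-x^2 / (2 * smooth_sigma^2))
    w / sum(w)
  }
  wy <- k1(ny); wx <- k1(nx); wz <- k1(nz)
  sm <- raw
  if (ny > 1) for (j in seq_len(nx)) for (k in seq_len(nz)) {
    sm[, j, k] <- stats::filter(c(rev(sm[, j, k]), sm[, j, k], rev(sm[, j, k])),
                                wy, sides = 2)[ny + seq_len(ny)]
  }
  if (nx > 1) for (i in seq_len(ny)) for (k in seq_len(nz)) {
    sm[i, , k] <- stats::filter(c(rev(sm[i, , k]), sm[i, , k], rev(sm[i, , k])),
                                wx, sides = 2)[nx + seq_len(nx)]
  }
  if (nz > 1) for (i in seq_len(ny)) for (j in seq_len(nx)) {
    sm[i, j, ] <- stats::filter(c(rev(sm[i, j, ]), sm[i, j, ], rev(sm[i, j, ])),
                                wz, sides = 2)[nz + seq_len(nz)]
  }
  sm <- sm - min(sm)
  m <- mean(sm)
  if (m == 0) return(array(mean_level, c(ny, nx, nz)))
  sm * mean_level / m
}

#' Bead-in-scattering-medium phantom with out-of-focus background
#'
#' A bead phantom (fine region) plus a spatially smooth non-negative
#' scattering potential over the fine region and a nonuniform fluorescent
#' background confined to the coarse (out-of-focus) slabs -- the synthetic
#' analogue of beads embedded in an intralipid/agarose phantom imaged
#' above an extended fluorescent layer.
#'
#' @param grid A `qlfm_grid` (must have coarse slabs for the background).
#' @param n_beads,bead_diameter,intensity Bead parameters as in
#'   [make_bead_phantom()].
#' @param scattering_level Mean of the scattering potential F (per-volume
#'   units); 0 disables scattering.
#' @param background_level Mean emission density of the out-of-focus
#'   background relative to bead interior density (default 0.02: individual
#'   out-of-focus voxels are dim, but the integrated background mass far
#'   exceeds the bead mass, as in densely labelled tissue).
#' @param seed Integer seed.
#' @return List: `volume`, `potential` (`qlfm_volume`s), `positions`,
#'   `background_mass`, `bead_mass`.
#' @export
make_scattering_phantom <- function(grid, n_beads = 10, bead_diameter = 2,
                                    intensity = 100, scattering_level = 0.05,
                                    background_level = 0.02, seed = 1L) {
  if (scattering_level < 0) stop("scattering_level must be >= 0", call. = FALSE)
  ph <- make_bead_phantom(grid, n_beads, bead_diameter, intensity, seed)
  vol <- ph$volume
  bead_mass <- volume_mass(vol)
  set.seed(seed + 1L)
  # scattering potential: smooth blob over the fine region
  F_vol <- new_volume(grid, 0)
  if (scattering_level > 0) {
    for (i in which(grid$slabs$factor == 1L)) {
      d <- dim(F_vol$slabs[[i]])
      F_vol$slabs[[i]] <- smooth_field(d[1], d[2], d[3], scattering_level)
    }
  }
  # nonuniform background in coarse slabs only
  set.seed(seed + 2L)
  bg_mass <- 0
  for (i in which(grid$slabs$factor > 1L)) {
    d <- dim(vol$slabs[[i]])
    bg <- smooth_field(d[1], d[2], d[3], background_level * intensity,
                       smooth_sigma = 1)
    vol$slabs[[i]] <- vol$slabs[[i]] + bg
    bg_mass <- bg_mass + sum(bg) * grid$slabs$lateral_step[i]^2 *
      grid$slabs$axial_step[i]
  }
  list(volume = vol, potential = F_vol, positions = ph$positions,
       background_mass = bg_mass, bead_mass = bead_mass)
}

#' Simulate a raw light-field capture
#'
#' Closes the loop: direct plus first-Born scattered emission is projected
#' through the phase-space PSF, realigned back to the sensor, and corrupted
#' with Poisson shot noise and additive Gaussian read noise.
#'
#' @param volume Emission `qlfm_volume`.
#' @param potential Scattering potential (`qlfm_volume` or NULL for none).
#' @param psf A `qlfm_psf` covering the grid.
#' @param config A `qlfm_config`.
#' @param photon_scale Multiplies the noiseless views before the Poisson
#'   draw (exposure/QE bundle); `NULL` skips shot noise.
#' @param read_noise_sd Gaussian read noise SD in counts (default 1.6,
#'   typical sCMOS); 0 disables.
#' @param seed Integer seed.
#' @param proj Optional precomputed projector.
#' @param shift Axial scan shift (um) applied to the PSF depths.
#' @return List: `frame` (`qlfm_frame`), `views` (noiseless `qlfm_views`),
#'   `noisy_views` (realigned noisy views).
#' @export
simulate_capture <- function(volume, potential, psf, config,
                             photon_scale = 1, read_noise_sd = 1.6,
                             seed = 1L, proj = NULL, shift = 0) {
  if (!is.null(read_noise_sd) && read_noise_sd < 0) {
    stop("read_noise_sd must be >= 0", call. = FALSE)
  }
  if (!is.null(photon_scale) && photon_scale <= 0) {
    stop("photon_scale must be positive", call. = FALSE)
  }
  tot <- volume
  if (!is.null(potential)) {
    S <- scattered_intensity(volume, potential, config)
    tot <- volume_op(volume, S, `+`)
  }
  if (is.null(proj)) proj <- build_projector(psf, volume$grid, shifts = shift)
  views <- forward_project(tot, psf, proj, shift)
  frame0 <- inverse_realign(views, config)
  img <- frame0$sensor_image
  set.seed(seed)
  if (!is.null(photon_scale)) {
    img <- matrix(stats::rpois(length(img), lambda = img * photon_scale),
                  nrow(img), ncol(img)) / photon_scale
  }
  if (!is.null(read_noise_sd) && read_noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), sd = read_noise_sd),
                        nrow(img), ncol(img))
  }
  img[img < 0] <- 0
  frame <- lightfield_frame(img, config)
  list(frame = frame, views = views, noisy_views = realign(frame))
}
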