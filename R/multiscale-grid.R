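# Depth-dependent resolution model and the multiscale complete-space grid.
#
# LFM resolution degrades roughly exponentially with distance from the
# native objective plane, so a volume large enough to contain all
# out-of-focus fluorescence can be sampled coarsely far from focus.  Slabs
# double their lateral (and axial) sampling interval at power-of-two
# transitions, which keeps resampling between slabs and the lens grid exact
# for constant fields and cheap in general.

#' Fit the exponential depth-resolution model
#'
#' Fits `R(z) = alpha * exp(beta * |z|) + gamma` separately to lateral and
#' axial FWHM measurements.  The fitted curves drive the multiscale grid:
#' sampling intervals follow `R(z) / 2` (Nyquist with respect to the modeled
#' resolution).
#'
#' @param depths Axial positions of the measurements (um, signed).
#' @param fwhm_lateral,fwhm_axial Measured FWHMs (um) at `depths`.
#' @return An object of class `qlfm_resolution_model` with elements
#'   `lateral_fit`, `axial_fit` (each `c(alpha, beta, gamma)`),
#'   `high_res_half_range` (|z| where the lateral FWHM has doubled) and
#'   `residual_norm`.
#' @export
fit_resolution_model <- function(depths, fwhm_lateral, fwhm_axial) {
  if (length(depths) < 4L) stop("need at least 4 depth samples", call. = FALSE)
  if (any(fwhm_lateral <= 0) || any(fwhm_axial <= 0)) {
    stop("FWHM values must be positive", call. = FALSE)
  }
  fit1 <- function(z, w) {
    az <- abs(z)
    if (stats::sd(w) < 1e-9 * mean(w)) {
      # constant data: gamma-only fit
      return(list(par = c(alpha = 0, beta = 0, gamma = mean(w)),
                  resid = 0, degenerate = TRUE))
    }
    w0 <- min(w)
    a0 <- max(max(w) - w0, 1e-3)
    b0 <- log(max((max(w) - w0 * 0.9) / a0, 1.1)) / max(max(az), 1)
    df <- data.frame(az = az, w = w)
    # relative weighting: near-focus widths are small but set the fine
    # sampling, so they must be fitted tightly
    fit <- minpack.lm::nlsLM(w ~ a * exp(b * az) + g, data = df,
                             start = list(a = a0, b = b0, g = w0 * 0.9),
                             lower = c(0, 0, 0), weights = 1 / df$w^2,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    p <- stats::coef(fit)
    list(par = c(alpha = unname(p["a"]), beta = unname(p["b"]),
                 gamma = unname(p["g"])),
         resid = sqrt(sum(stats::resid(fit)^2)), degenerate = FALSE)
  }
  lat <- fit1(depths, fwhm_lateral)
  axi <- fit1(depths, fwhm_axial)
  a <- lat$par[["alpha"]]; b <- lat$par[["beta"]]; g <- lat$par[["gamma"]]
  hr <- if (a > 0 && b > 0) log((2 * a + g) / a) / b else Inf
  structure(list(lateral_fit = lat$par, axial_fit = axi$par,
                 high_res_half_range = hr,
                 residual_norm = lat$resid + axi$resid,
                 degenerate = lat$degenerate || axi$degenerate),
            class = "qlfm_resolution_model")
}

# Evaluate the fitted resolution curves (um) at signed depth z.
resolution_lateral <- function(model, z) {
  p <- model$lateral_fit
  p[["alpha"]] * exp(p[["beta"]] * abs(z)) + p[["gamma"]]
}
resolution_axial <- function(model, z) {
  p <- model$axial_fit
  p[["alpha"]] * exp(p[["beta"]] * abs(z)) + p[["gamma"]]
}

#' Default resolution model derived from the instrument geometry
#'
#' Builds FWHM-vs-depth curves from the same geometry the far-field PSF
#' model uses -- the per-angular-component (sub-aperture) geometric blur --
#' and fits the exponential model to them.  Near focus the lateral FWHM is
#' floored at twice the lens sampling interval (the native sampling limit of
#' unfocused LFM) and the axial FWHM at the corresponding geometric depth of
#' field; far from focus both grow linearly with the sub-aperture cone.
#'
#' @param config A `qlfm_config`.
#' @param z_max Largest |z| (um) sampled when generating the curves.
#' @return A `qlfm_resolution_model`.
#' @export
default_resolution_model <- function(config, z_max = 300) {
  p_s <- lens_sampling(config)
  sin_t <- config$objective_na / config$immersion_index
  tan_t <- sin_t / sqrt(1 - sin_t^2)
  tan_sub <- tan_t / config$pixels_per_lens  # half-cone of one sub-aperture
  # quadratically spaced samples: densest near focus, where the exponential
  # has to be tight because it sets the fine sampling interval
  r0_lat <- 2 * p_s
  r0_ax <- 2 * p_s * config$immersion_index / config$objective_na
  # depth at which the sub-aperture blur has doubled the native width; the
  # exponential is fitted over ~4 doublings so its shape matches where the
  # grid transitions actually happen
  z_d <- sqrt(3) * r0_lat / (2 * tan_sub)
  z_fit <- min(z_max, 4 * z_d)
  # quadratically spaced samples: densest near focus, where the exponential
  # has to be tight because it sets the fine sampling interval
  z <- z_fit * seq(0, 1, length.out = 25L)^2
  w_lat <- sqrt(r0_lat^2 + (2 * z * tan_sub)^2)
  w_ax <- sqrt(r0_ax^2 + (2 * z * tan_sub / sin_t)^2)
  fit_resolution_model(z, w_lat, w_ax)
}

#' Build the multiscale complete-space sampling grid
#'
#' Tiles `[z_min, z_max]` with axial slabs whose lateral and axial sampling
#' intervals double (at most once per transition) as the modeled resolution
#' degrades away from the native objective plane.  The finest slab samples
#' laterally at the native lens-grid interval
#' (`mla_pitch / effective_magnification`).
#'
#' @param z_min,z_max Axial range (um, `z_min < z_max`), z = 0 at the native
#'   objective plane.
#' @param model A `qlfm_resolution_model`.
#' @param config A `qlfm_config`.
#' @param base_axial_step Axial step of the finest slab (um); default
#'   `R_z(0) / 2` from the model.
#' @param max_factor Largest lateral coarsening factor allowed (power of 2).
#' @param fine_half_range Optional |z| (um) up to which the grid is forced to
#'   stay at the finest sampling regardless of the resolution model (e.g.
#'   when the targets of interest span a known range).
#' @return An object of class `qlfm_grid`: list with `slabs` (data frame
#'   with `z_start`, `z_end`, `axial_step`, `lateral_step`, `factor`, `ny`,
#'   `nx`, `nz`), `base_lateral` (um), `num_lenses`, and `planes` (one row
#'   per axial sample plane).
#' @export
build_grid <- function(z_min, z_max, model, config,
                       base_axial_step = NULL, max_factor = 16L,
                       fine_half_range = NULL) {
  if (!(z_min < z_max)) stop("z_min must be < z_max", call. = FALSE)
  base_lat <- lens_sampling(config)
  if (is.null(base_axial_step)) {
    base_axial_step <- resolution_axial(model, 0) / 2
  }
  kmax <- as.integer(round(log2(max_factor)))

  # zb[k]: |z| beyond which lateral factor 2^k satisfies step <= R_xy(z)/2
  factor_boundary <- function(k) {
    target <- 2^(k + 1) * base_lat  # R_xy(z) at which factor 2^k is Nyquist
    p <- model$lateral_fit
    a <- p[["alpha"]]; b <- p[["beta"]]; g <- p[["gamma"]]
    if (a <= 0 || b <= 0) return(Inf)
    if (target <= a + g) return(0)
    log((target - g) / a) / b
  }
  zb <- vapply(seq_len(kmax), factor_boundary, numeric(1))
  # ensure the finest slab covers at least the modeled high-resolution range
  if (is.finite(model$high_res_half_range)) {
    zb[1] <- max(zb[1], min(model$high_res_half_range, z_max - z_min))
  }
  if (!is.null(fine_half_range)) {
    zb <- pmax(zb, fine_half_range)
  }
  zb <- cummax(zb)  # factors may only coarsen with distance from focus
  zb_fin <- zb[is.finite(zb)]
  if (length(zb_fin) && sign(z_min) == sign(z_max) &&
      min(abs(c(z_min, z_max))) > max(zb_fin)) {
    warning("z-range lies entirely beyond the modeled resolution curve; ",
            "sampling intervals are extrapolated", call. = FALSE)
  }
  cuts <- sort(unique(c(z_min, z_max, zb[is.finite(zb)], -zb[is.finite(zb)])))
  cuts <- cuts[cuts >= z_min & cuts <= z_max]
  if (cuts[1] > z_min) cuts <- c(z_min, cuts)
  if (cuts[length(cuts)] < z_max) cuts <- c(cuts, z_max)

  nly <- config$num_lenses[1]; nlx <- config$num_lenses[2]
  iv <- data.frame(zs = cuts[-length(cuts)], ze = cuts[-1])
  iv <- iv[iv$ze - iv$zs > 1e-9, , drop = FALSE]
  iv$mid <- (iv$zs + iv$ze) / 2
  iv$k <- vapply(iv$mid, function(mid) {
    k <- 0L
    while (k < kmax && abs(mid) >= zb[k + 1L] - 1e-9) k <- k + 1L
    k
  }, integer(1))
  # the sampling interval may double at most once per slab transition
  for (side in c(1, -1)) {
    ord <- order(abs(iv$mid))
    ord <- ord[sign(iv$mid[ord]) == side]
    kprev <- iv$k[which.min(abs(iv$mid))]  # innermost slab anchors the chain
    for (j in ord) {
      if (kprev >= 0L) iv$k[j] <- min(iv$k[j], kprev + 1L)
      kprev <- iv$k[j]
    }
  }
  slabs <- NULL
  for (i in seq_len(nrow(iv))) {
    zs <- iv$zs[i]; ze <- iv$ze[i]
    s <- 2L^iv$k[i]
    dz_nom <- base_axial_step * s
    nz <- max(1L, as.integer(round((ze - zs) / dz_nom)))
    dz <- (ze - zs) / nz
    slabs <- rbind(slabs, data.frame(
      z_start = zs, z_end = ze, axial_step = dz,
      lateral_step = base_lat * s, factor = s,
      ny = as.integer(ceiling(nly / s)), nx = as.integer(ceiling(nlx / s)),
      nz = nz))
  }
  # merge adjacent slabs with identical factor (keeps the slab list minimal)
  merged <- slabs[1, , drop = FALSE]
  if (nrow(slabs) > 1L) {
    for (i in 2:nrow(slabs)) {
      j <- nrow(merged)
      if (slabs$factor[i] == merged$factor[j]) {
        zs <- merged$z_start[j]; ze <- slabs$z_end[i]
        dz_nom <- base_axial_step * merged$factor[j]
        nz <- max(1L, as.integer(round((ze - zs) / dz_nom)))
        merged$z_end[j] <- ze
        merged$axial_step[j] <- (ze - zs) / nz
        merged$nz[j] <- nz
      } else {
        merged <- rbind(merged, slabs[i, , drop = FALSE])
      }
    }
  }
  slabs <- merged
  rownames(slabs) <- NULL

  planes <- do.call(rbind, lapply(seq_len(nrow(slabs)), function(i) {
    with(slabs[i, ], data.frame(
      slab = i, iz = seq_len(nz),
      z = z_start + (seq_len(nz) - 0.5) * axial_step,
      factor = factor, lateral_step = lateral_step, axial_step = axial_step,
      ny = ny, nx = nx))
  }))
  rownames(planes) <- NULL

  structure(list(slabs = slabs, planes = planes,
                 base_lateral = base_lat, num_lenses = c(nly, nlx),
                 z_min = z_min, z_max = z_max, model = model),
            class = "qlfm_grid")
}

#' @export
print.qlfm_grid <- function(x, ...) {
  cat(sprintf("Multiscale grid over [%.1f, %.1f] um: %d slabs, %d planes, %d voxels\n",
              x$z_min, x$z_max, nrow(x$slabs), nrow(x$planes), grid_voxel_count(x)))
  print(x$slabs, digits = 4)
  invisible(x)
}

#' Total voxel count of a grid
#' @param grid A `qlfm_grid`.
#' @return Integer voxel count.
#' @export
grid_voxel_count <- function(grid) {
  sum(with(grid$slabs, as.numeric(ny) * nx * nz))
}

# Voxel count of the equivalent dense single-scale grid: the whole axial
# range at the finest axial step, sampled laterally at the camera pixel rate
# (pixels_per_lens times the lens pitch per axis), which is what
# single-scale deconvolution with a spatially variant PSF requires.
dense_voxel_count <- function(grid, pixels_per_lens = NULL) {
  fine <- grid$slabs$factor == 1L
  dz0 <- if (any(fine)) min(grid$slabs$axial_step[fine]) else min(grid$slabs$axial_step)
  nz <- ceiling((grid$z_max - grid$z_min) / dz0)
  ppl <- if (is.null(pixels_per_lens)) 1L else pixels_per_lens
  as.numeric(grid$num_lenses[1]) * grid$num_lenses[2] * nz * ppl^2
}

#' Create an empty (or filled) multiscale volume on a grid
#'
#' Volume values are intensity densities (photons per um^3 up to a global
#' scale); the photon mass of a voxel is value * lateral_step^2 * axial_step.
#'
#' @param grid A `qlfm_grid`.
#' @param fill Fill value (default 0).
#' @return An object of class `qlfm_volume`: list(grid, slabs) where
#'   `slabs[[i]]` is a (ny, nx, nz) array.
#' @export
new_volume <- function(grid, fill = 0) {
  slabs <- lapply(seq_len(nrow(grid$slabs)), function(i) {
    with(grid$slabs[i, ], array(fill, dim = c(ny, nx, nz)))
  })
  structure(list(grid = grid, slabs = slabs), class = "qlfm_volume")
}

#' @export
print.qlfm_volume <- function(x, ...) {
  cat(sprintf("Multiscale volume: %d slabs, total mass %.4g\n",
              length(x$slabs), volume_mass(x)))
  invisible(x)
}

# Integral of intensity over the volume (sum of value * voxel volume).
#' Total integrated intensity (mass) of a volume
#' @param volume A `qlfm_volume`.
#' @return Numeric scalar.
#' @export
volume_mass <- function(volume) {
  g <- volume$grid$slabs
  sum(vapply(seq_along(volume$slabs), function(i) {
    sum(volume$slabs[[i]]) * g$lateral_step[i]^2 * g$axial_step[i]
  }, numeric(1)))
}

# Extract plane p (a matrix) given a row of grid$planes.
volume_plane <- function(volume, prow) {
  volume$slabs[[prow$slab]][, , prow$iz]
}
assign_plane <- function(volume, prow, value) {
  volume$slabs[[prow$slab]][, , prow$iz] <- value
  volume
}

# Map every slab array through f (elementwise), returning a new volume.
volume_map <- function(volume, f, ...) {
  volume$slabs <- lapply(volume$slabs, f, ...)
  volume
}

volume_op <- function(a, b, f) {
  a$slabs <- Map(function(x, y) f(x, y), a$slabs, b$slabs)
  a
}

# Inner product under the voxel-volume-weighted measure is NOT used for the
# adjoint tests; forward/backproject are adjoint under the plain elementwise
# inner products, which this computes.
volume_dot <- function(a, b) {
  sum(vapply(seq_along(a$slabs), function(i) sum(a$slabs[[i]] * b$slabs[[i]]),
             numeric(1)))
}

#' Resample a multiscale volume onto another grid
#'
#' Mass-preserving resampling: the integral of intensity over the volume is
#' preserved (to within the overlap of the two axial ranges) and
#' non-negativity is maintained.  Values are treated as densities: lateral
#' resampling replicates/averages power-of-two blocks, axial resampling
#' redistributes each source plane's mass over destination planes in
#' proportion to interval overlap.
#'
#' @param volume A `qlfm_volume`.
#' @param dst A `qlfm_grid` whose axial range covers the source range.
#' @return A `qlfm_volume` on `dst`.
#' @export
resample_between_grids <- function(volume, dst) {
  src_g <- volume$grid
  if (dst$z_min > src_g$z_min + 1e-9 || dst$z_max < src_g$z_max - 1e-9) {
    stop("destination grid does not cover the source axial range",
         call. = FALSE)
  }
  if (identical(src_g$slabs, dst$slabs) &&
      identical(src_g$num_lenses, dst$num_lenses)) {
    out <- volume
    out$grid <- dst
    return(out)
  }
  out <- new_volume(dst, 0)
  dp <- dst$planes
  nly <- dst$num_lenses[1]; nlx <- dst$num_lenses[2]
  sp <- src_g$planes
  for (i in seq_len(nrow(sp))) {
    pr <- sp[i, ]
    img <- volume$slabs[[pr$slab]][, , pr$iz]
    # source plane mass per fine lateral cell: replicate density to factor 1
    fine <- upsample_lateral(img, pr$factor, nly, nlx)
    z0 <- pr$z - pr$axial_step / 2
    z1 <- pr$z + pr$axial_step / 2
    # distribute over destination planes by interval overlap
    for (j in seq_len(nrow(dp))) {
      dzr <- dp[j, ]
      d0 <- dzr$z - dzr$axial_step / 2
      d1 <- dzr$z + dzr$axial_step / 2
      ov <- min(z1, d1) - max(z0, d0)
      if (ov <= 1e-12) next
      wfrac <- ov / pr$axial_step          # fraction of source plane mass
      coarse <- downsample_lateral_cov(fine, dzr$factor, dzr$ny, dzr$nx)
      # density in destination voxel: source mass fraction / dst axial step
      out$slabs[[dzr$slab]][, , dzr$iz] <- out$slabs[[dzr$slab]][, , dzr$iz] +
        coarse * wfrac * pr$axial_step / dzr$axial_step
    }
  }
  out
}

#' Build a single-slab uniform grid (mainly for tests and viewing)
#'
#' @param z_min,z_max Axial range (um).
#' @param nz Number of axial planes.
#' @param config A `qlfm_config` (sets the lateral geometry).
#' @param factor Lateral coarsening factor (power of two, default 1).
#' @return A `qlfm_grid` with one slab.
#' @export
uniform_grid <- function(z_min, z_max, nz, config, factor = 1L) {
  base_lat <- lens_sampling(config)
  nly <- config$num_lenses[1]; nlx <- config$num_lenses[2]
  dz <- (z_max - z_min) / nz
  slabs <- data.frame(z_start = z_min, z_end = z_max, axial_step = dz,
                      lateral_step = base_lat * factor, factor = as.integer(factor),
                      ny = as.integer(ceiling(nly / factor)),
                      nx = as.integer(ceiling(nlx / factor)), nz = as.integer(nz))
  planes <- data.frame(slab = 1L, iz = seq_len(nz),
                       z = z_min + (seq_len(nz) - 0.5) * dz,
                       factor = as.integer(factor),
                       lateral_step = base_lat * factor, axial_step = dz,
                       ny = slabs$ny, nx = slabs$nx)
  structure(list(slabs = slabs, planes = planes, base_lateral = base_lat,
                 num_lenses = c(nly, nlx), z_min = z_min, z_max = z_max,
                 model = NULL),
            class = "qlfm_grid")
}
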