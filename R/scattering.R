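# Incoherent first-Born scattering: scattered photons are generated from the
# local product of emission intensity and scattering potential and spread
# with an inverse-square law,
#
#   I_s(r) = (1/2) * sum_{r'} F(r') I(r') / ||r - r'||^2 * dV',
#
# then imaged through the same PSF as direct fluorescence.  Single
# scattering only: scattered light is never re-scattered, and the kernel is
# isotropic.

# 3D centered shift helpers (odd or even sizes).
fftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    s <- center_index(n) - 1L
    c(seq_len(n - s) + s, seq_len(s))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
ifftshift3 <- function(x) {
  d <- dim(x)
  idx <- lapply(d, function(n) {
    s <- n - (center_index(n) - 1L)
    c(seq_len(n - s) + s, seq_len(s))
  })
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

embed_centered3 <- function(x, dout) {
  d <- dim(x)
  out <- array(0, dout)
  o <- vapply(1:3, function(i) center_index(dout[i]) - center_index(d[i]),
              integer(1))
  out[seq_len(d[1]) + o[1], seq_len(d[2]) + o[2], seq_len(d[3]) + o[3]] <- x
  out
}
extract_centered3 <- function(x, dout) {
  d <- dim(x)
  o <- vapply(1:3, function(i) center_index(d[i]) - center_index(dout[i]),
              integer(1))
  x[seq_len(dout[1]) + o[1], seq_len(dout[2]) + o[2], seq_len(dout[3]) + o[3],
    drop = FALSE]
}

# Linear 3D convolution with a centered kernel, output cropped to dim(img).
conv3_centered <- function(img, kernel) {
  di <- dim(img); dk <- dim(kernel)
  pad <- vapply(1:3, function(i) good_fft_size(di[i] + dk[i] - 1L), integer(1))
  fi <- stats::fft(ifftshift3(embed_centered3(img, pad)))
  fk <- stats::fft(ifftshift3(embed_centered3(kernel, pad)))
  out <- fftshift3(stats::fft(fi * fk, inverse = TRUE)) / prod(pad)
  extract_centered3(Re(out), di)
}

# Inverse-square kernel 1/||dr||^2 on a (ny, nx, nz) voxel lattice with
# spacings (dy, dx, dz); the singular self-voxel takes the kernel value at
# half the voxel diagonal.  Support truncated where the kernel falls below
# `trunc_rel` times its nearest-neighbour value.
inverse_square_kernel <- function(ny, nx, nz, dy, dx, dz, trunc_rel = 1e-4) {
  kdim <- c(2L * ny - 1L, 2L * nx - 1L, 2L * nz - 1L)
  oy <- (seq_len(kdim[1]) - center_index(kdim[1])) * dy
  ox <- (seq_len(kdim[2]) - center_index(kdim[2])) * dx
  oz <- (seq_len(kdim[3]) - center_index(kdim[3])) * dz
  r2 <- outer(outer(oy^2, ox^2, `+`), oz^2, `+`)
  half_diag2 <- (dy^2 + dx^2 + dz^2) / 4
  r2[r2 == 0] <- half_diag2
  K <- 1 / r2
  knn <- 1 / min(dy, dx, dz)^2
  K[K < trunc_rel * knn] <- 0
  K
}

# Scattering is evaluated on a uniform auxiliary grid; the multiscale volume
# is resampled onto it (mass-preserving) and back.  For a single-slab source
# grid the auxiliary grid IS the source grid, so no resampling happens.
scatter_aux_grid <- function(grid, config, aux_factor = 2L, aux_axial_mult = 2L) {
  if (nrow(grid$slabs) == 1L) return(grid)
  fine <- grid$slabs$factor == 1L
  dz0 <- if (any(fine)) min(grid$slabs$axial_step[fine]) else
    min(grid$slabs$axial_step)
  dz_aux <- dz0 * aux_axial_mult
  nz <- max(2L, as.integer(ceiling((grid$z_max - grid$z_min) / dz_aux)))
  uniform_grid(grid$z_min, grid$z_max, nz, config, factor = aux_factor)
}

#' Scattered-photon field from emission and scattering potential
#'
#' Discretized incoherent first-Born model: the scattered intensity is half
#' the 3D convolution of `F * I` with the inverse-square kernel (with the
#' self-voxel regularized at half the voxel diagonal).  On multiscale grids
#' the product is evaluated on a uniform auxiliary grid (mass-preserving
#' resampling both ways); on a single-slab grid the computation is exact on
#' the native lattice.
#'
#' @param emission A `qlfm_volume` of emission intensity.
#' @param potential A `qlfm_volume` (same grid) of scattering potential.
#' @param config A `qlfm_config` (geometry for the auxiliary grid); defaults
#'   to a lens geometry inferred from the grid when `NULL`.
#' @param aux_factor,aux_axial_mult Lateral factor and axial-step multiplier
#'   of the auxiliary scattering grid (multiscale inputs only).
#' @return A `qlfm_volume` of scattered intensity (same grid as the inputs).
#' @export
scattered_intensity <- function(emission, potential, config = NULL,
                                aux_factor = 2L, aux_axial_mult = 2L,
                                clamp = TRUE) {
  grid <- emission$grid
  if (!identical(grid$slabs, potential$grid$slabs)) {
    stop("emission and potential must share one grid", call. = FALSE)
  }
  if (all(vapply(potential$slabs, function(x) all(x == 0), logical(1)))) {
    return(new_volume(grid, 0))
  }
  prod_vol <- volume_op(emission, potential, `*`)
  single <- nrow(grid$slabs) == 1L
  if (single) {
    aux <- grid
    P <- prod_vol$slabs[[1]]
  } else {
    if (is.null(config)) stop("config required for multiscale grids", call. = FALSE)
    aux <- scatter_aux_grid(grid, config, aux_factor, aux_axial_mult)
    P <- resample_between_grids(prod_vol, aux)$slabs[[1]]
  }
  sa <- aux$slabs
  dV <- sa$lateral_step^2 * sa$axial_step
  K <- inverse_square_kernel(sa$ny, sa$nx, sa$nz,
                             sa$lateral_step, sa$lateral_step, sa$axial_step)
  S <- 0.5 * conv3_centered(P * dV, K)
  if (clamp) S[S < 0] <- 0  # FFT round-off only; gradients pass clamp = FALSE
  out_aux <- structure(list(grid = aux, slabs = list(S)), class = "qlfm_volume")
  if (single) return(out_aux)
  resample_between_grids(out_aux, grid)
}

#' One projected-gradient update of the scattering potential
#'
#' Takes a non-negativity-projected gradient step on
#' `||forward(I + scattered(I, F)) - views||^2 + lambda_f * ||F||^2`,
#' holding the emission `I` fixed, with backtracking line search so the
#' accepted step never increases the misfit.
#'
#' @param emission Current emission estimate (`qlfm_volume`).
#' @param views Measured `qlfm_views`.
#' @param psf A `qlfm_psf`.
#' @param potential_prev Previous potential (`qlfm_volume`, same grid).
#' @param lambda_f Tikhonov weight on `F` (relative to data scale).
#' @param proj Optional precomputed projector.
#' @param max_backtracks Backtracking halvings before giving up.
#' @param config A `qlfm_config` for the auxiliary scattering grid.
#' @return List: `potential` (updated `qlfm_volume`), `misfit` (accepted
#'   squared-residual value), `step` (accepted step size; 0 if no decrease
#'   was found).
#' @export
update_potential <- function(emission, views, psf, potential_prev,
                             lambda_f = 1e-3, proj = NULL, config = NULL,
                             max_backtracks = 8L, shift = 0) {
  grid <- emission$grid
  if (is.null(config)) config <- psf$config
  if (is.null(proj)) proj <- build_projector(psf, grid, shifts = shift)
  for (sl in emission$slabs) stopifnot_finite(sl, "emission")
  for (sl in potential_prev$slabs) stopifnot_finite(sl, "potential")

  misfit_of <- function(F_vol) {
    S <- scattered_intensity(emission, F_vol, config)
    tot <- volume_op(emission, S, `+`)
    r <- forward_project(tot, psf, proj, shift) - views
    sum(r^2) + lambda_f * sum(vapply(F_vol$slabs, function(x) sum(x^2),
                                     numeric(1)))
  }

  S0 <- scattered_intensity(emission, potential_prev, config)
  tot0 <- volume_op(emission, S0, `+`)
  r0 <- forward_project(tot0, psf, proj, shift) - views
  m0 <- sum(r0^2) + lambda_f * sum(vapply(potential_prev$slabs,
                                          function(x) sum(x^2), numeric(1)))
  # gradient: dS/dF^T applied to backproject(2 r): multiply the
  # back-propagated residual by the inverse-square spread and the emission
  bp <- backproject(unclass(r0) * 2, psf, grid, proj, shift)
  g_scatter <- scattered_intensity(bp, volume_map(bp, function(x) x * 0 + 1),
                                   config, clamp = FALSE)
  # scattered_intensity computes (1/2) K * (F*I); with F == 1 this is the
  # plain spread of bp -- multiply by emission to complete the chain rule
  g <- volume_op(g_scatter, emission, `*`)
  g <- volume_op(g, volume_map(potential_prev, function(x) 2 * lambda_f * x), `+`)

  gmax <- max(vapply(g$slabs, function(x) max(abs(x)), numeric(1)))
  if (gmax == 0) {
    return(list(potential = potential_prev, misfit = m0, step = 0))
  }
  fmax <- max(vapply(potential_prev$slabs, function(x) max(x), numeric(1)))
  step <- if (fmax > 0) 0.5 * fmax / gmax else
    0.1 * max(vapply(emission$slabs, max, numeric(1))) / gmax
  for (bt in seq_len(max_backtracks)) {
    cand <- volume_op(potential_prev, volume_map(g, function(x) step * x), `-`)
    cand <- volume_map(cand, function(x) pmax(x, 0))
    m1 <- misfit_of(cand)
    if (m1 < m0) {
      return(list(potential = cand, misfit = m1, step = step))
    }
    step <- step / 2
  }
  list(potential = potential_prev, misfit = m0, step = 0)
}

# Arithmetic on views arrays keeps attributes via standard array ops; define
# a subtraction helper that preserves the class for readability.
#' @export
Ops.qlfm_views <- function(e1, e2) {
  r <- NextMethod()
  if (is.array(r)) {
    attr(r, "config") <- attr(if (inherits(e1, "qlfm_views")) e1 else e2, "config")
    class(r) <- "qlfm_views"
  }
  r
}
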