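# Linear projection between a multiscale volume and phase-space views, and
# its exact adjoint.
#
# For each angular component (u, v) and axial plane p (lateral factor s,
# voxel volume dV = lateral_step^2 * axial_step):
#
#   view_{uv} += CropToLensGrid( Replicate_s( conv2(I_p * dV, K_{uv,p}) ) / s^2 )
#
# i.e. each plane is convolved with its own kernel at its own sampling, then
# mass-preservingly resampled to the lens grid.  The adjoint reverses every
# factor exactly (block-average instead of replicate, 180-degree-rotated
# kernel), so <forward(x), y> = <x, backproject(y)> holds to floating
# precision -- a property the multiplicative and gradient updates rely on.

# Precompute padded kernel FFTs for every (plane, angle) pair of a PSF used
# against a given grid.  `shifts` are axial scan positions (psf must have
# been built with matching shifts via psf_for_grid).
build_projector <- function(psf, grid, shifts = 0) {
  config <- psf$config
  ppl <- config$pixels_per_lens
  pl <- grid$planes
  plans <- list()
  for (sh in shifts) {
    for (p in seq_len(nrow(pl))) {
      key <- proj_key(p, sh)
      ip <- psf_plane_index(psf, pl$z[p] - sh, pl$factor[p], shift = sh)
      kern <- psf$kernels[[ip]]
      img_dim <- c(pl$ny[p], pl$nx[p])
      dk <- dim(kern)[3:4]
      pad <- c(good_fft_size(img_dim[1] + dk[1] - 1L),
               good_fft_size(img_dim[2] + dk[2] - 1L))
      kffts <- vector("list", ppl * ppl)
      for (vi in seq_len(ppl)) {
        for (ui in seq_len(ppl)) {
          kffts[[(ui - 1L) * ppl + vi]] <- stats::fft(
            ifftshift2(embed_centered(kern[vi, ui, , ], pad[1], pad[2])))
        }
      }
      plans[[key]] <- list(pad = pad, kffts = kffts,
                           dV = pl$lateral_step[p]^2 * pl$axial_step[p],
                           s = pl$factor[p], ny = pl$ny[p], nx = pl$nx[p])
    }
  }
  structure(list(plans = plans, config = config, grid = grid,
                 ppl = ppl, shifts = shifts),
            class = "qlfm_projector")
}

proj_key <- function(plane, shift) sprintf("p%d_s%.4f", plane, shift)

# Forward projection of one angular component; returns (nly, nlx) matrix.
forward_angle <- function(volume, proj, vi, ui, shift = 0) {
  grid <- volume$grid
  nly <- grid$num_lenses[1]; nlx <- grid$num_lenses[2]
  out <- matrix(0, nly, nlx)
  pl <- grid$planes
  ppl <- proj$ppl
  for (p in seq_len(nrow(pl))) {
    plan <- proj$plans[[proj_key(p, shift)]]
    img <- volume$slabs[[pl$slab[p]]][, , pl$iz[p]]
    if (!any(img != 0)) next
    m <- img * plan$dV
    cm <- conv2_centered(m, kfft = plan$kffts[[(ui - 1L) * ppl + vi]],
                         pad = plan$pad)
    out <- out + upsample_lateral(cm, plan$s, nly, nlx) / plan$s^2
  }
  out
}

# Adjoint of forward_angle applied to a lens-grid image; accumulates into
# (and returns) `into`, a qlfm_volume.
back_angle <- function(img, into, proj, vi, ui, shift = 0) {
  grid <- into$grid
  pl <- grid$planes
  ppl <- proj$ppl
  for (p in seq_len(nrow(pl))) {
    plan <- proj$plans[[proj_key(p, shift)]]
    y <- downsample_lateral(img, plan$s, plan$ny, plan$nx)
    g <- conv2_centered(y, kfft = Conj(plan$kffts[[(ui - 1L) * ppl + vi]]),
                        pad = plan$pad) * plan$dV
    into$slabs[[pl$slab[p]]][, , pl$iz[p]] <-
      into$slabs[[pl$slab[p]]][, , pl$iz[p]] + g
  }
  into
}

#' Project a multiscale volume into phase-space views
#'
#' Applies the linear light-field forward model: every axial plane is
#' convolved (at its own lateral sampling) with its per-angle PSF kernel,
#' resampled to the lens grid mass-preservingly, and summed over depth.
#'
#' @param volume A `qlfm_volume`.
#' @param psf A `qlfm_psf` whose depth list contains every plane of the
#'   volume's grid (at matching lateral factors).
#' @param proj Optional precomputed projector from `build_projector()`
#'   (built internally when omitted; pass one when projecting repeatedly).
#' @param shift Axial scan shift (um) applied to the PSF depths.
#' @return A `qlfm_views` array of photon counts.
#' @export
forward_project <- function(volume, psf, proj = NULL, shift = 0) {
  if (is.null(proj)) proj <- build_projector(psf, volume$grid, shifts = shift)
  config <- proj$config
  views <- new_views(config)
  ppl <- proj$ppl
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      v <- forward_angle(volume, proj, vi, ui, shift)
      v[v < 0] <- 0  # FFT round-off on non-negative inputs
      views[vi, ui, , ] <- v
    }
  }
  views
}

#' Back-project phase-space views into a multiscale volume
#'
#' Exact adjoint of [forward_project()] under the elementwise inner products
#' of the view and volume spaces.
#'
#' @param views A `qlfm_views` array.
#' @param psf A `qlfm_psf`.
#' @param grid Target `qlfm_grid`.
#' @param proj Optional precomputed projector.
#' @param shift Axial scan shift (um).
#' @return A `qlfm_volume`.
#' @export
backproject <- function(views, psf, grid, proj = NULL, shift = 0) {
  if (is.null(proj)) proj <- build_projector(psf, grid, shifts = shift)
  out <- new_volume(grid, 0)
  ppl <- proj$ppl
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      out <- back_angle(views[vi, ui, , ], out, proj, vi, ui, shift)
    }
  }
  out
}
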