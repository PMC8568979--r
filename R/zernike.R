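# Zernike polynomials (Noll indexing, Noll normalization) and the
# AberrationWavefront container used by the wave-optics PSF model and the
# phase-retrieval calibration.

# Noll index j -> (n, m) with the usual sign/parity bookkeeping.
noll_to_nm <- function(j) {
  if (j < 1) stop("Noll index must be >= 1", call. = FALSE)
  n <- 0L
  while (j > n + 1L) {
    j <- j - (n + 1L)
    n <- n + 1L
  }
  # remaining j ranks the azimuthal orders for this n in Noll's order
  m_abs <- if (n %% 2L == 0L) 2L * floor((j) / 2L) else 2L * floor((j - 1L) / 2L) + 1L
  m_abs <- as.integer(m_abs)
  m <- m_abs
  # Noll: even j -> cosine (m >= 0), odd j -> sine (m < 0); m = 0 unsigned
  list(n = as.integer(n), m = m_abs)
}

zernike_radial <- function(n, m, rho) {
  out <- numeric(length(rho))
  for (k in 0:((n - m) / 2)) {
    num <- (-1)^k * factorial(n - k)
    den <- factorial(k) * factorial((n + m) / 2 - k) * factorial((n - m) / 2 - k)
    out <- out + num / den * rho^(n - 2 * k)
  }
  out
}

#' Evaluate a Noll-indexed Zernike polynomial on the unit disk
#'
#' Uses Noll normalization: the piston term is 1 and every mode has unit RMS
#' over the pupil, e.g. `Z4 = sqrt(3) * (2 rho^2 - 1)` (defocus).
#'
#' @param j Noll index (1 = piston, 2/3 = tip/tilt, 4 = defocus, ...).
#' @param rho Normalized pupil radius (values > 1 return 0).
#' @param theta Azimuthal angle in radians.
#' @return Numeric vector of polynomial values.
#' @export
zernike_noll <- function(j, rho, theta) {
  nm <- noll_to_nm(j)
  n <- nm$n; m <- nm$m
  inside <- rho <= 1
  r <- ifelse(inside, rho, 0)
  rad <- zernike_radial(n, m, r)
  if (m == 0L) {
    val <- sqrt(n + 1) * rad
  } else {
    norm <- sqrt(2 * (n + 1))
    ang <- if (j %% 2L == 0L) cos(m * theta) else sin(m * theta)
    val <- norm * rad * ang
  }
  val * inside
}

#' Build an aberration wavefront from Zernike coefficients
#'
#' Constructs the pupil-plane phase map as the coefficient-weighted sum of
#' Noll-ordered Zernike polynomials on the unit disk, scaled by 2*pi so that
#' a coefficient of 1 corresponds to one emission wavelength of wavefront
#' error (the phase map is in radians).  The piston coefficient is stored but
#' ignored by the PSF model.
#'
#' @param coefficients Numeric vector of Noll-ordered Zernike coefficients in
#'   units of the emission wavelength; element `i` multiplies Noll mode `i`.
#'   An empty vector yields a flat (zero) wavefront.
#' @param pupil_samples Number of samples across the pupil diameter (>= 16).
#' @return An object of class `qlfm_wavefront` with elements
#'   `zernike_coefficients`, `pupil_phase_map` (radians; `NA` outside the
#'   pupil), `pupil_mask`, `rho`, `theta` and `pupil_samples`.
#' @examples
#' w <- zernike_wavefront(c(0, 0, 0, 1), pupil_samples = 64)
#' max(w$pupil_phase_map, na.rm = TRUE) / (2 * pi)  # ~ sqrt(3)
#' @export
zernike_wavefront <- function(coefficients = numeric(0), pupil_samples = 256L) {
  if (pupil_samples < 16L) stop("pupil_samples must be >= 16", call. = FALSE)
  if (length(coefficients) && !all(is.finite(coefficients))) {
    stop("Zernike coefficients must be finite", call. = FALSE)
  }
  ax <- seq(-1, 1, length.out = pupil_samples)
  xx <- matrix(ax, pupil_samples, pupil_samples, byrow = TRUE)
  yy <- matrix(ax, pupil_samples, pupil_samples)
  rho <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  mask <- rho <= 1
  phase <- matrix(0, pupil_samples, pupil_samples)
  if (length(coefficients)) {
    for (j in seq_along(coefficients)) {
      if (coefficients[j] != 0) {
        phase <- phase + coefficients[j] * matrix(
          zernike_noll(j, as.vector(rho), as.vector(theta)),
          pupil_samples, pupil_samples)
      }
    }
  }
  phase <- phase * 2 * pi
  phase[!mask] <- NA_real_
  structure(list(zernike_coefficients = as.numeric(coefficients),
                 pupil_phase_map = phase,
                 pupil_mask = mask,
                 rho = rho, theta = theta,
                 pupil_samples = as.integer(pupil_samples)),
            class = "qlfm_wavefront")
}

# Evaluate the wavefront phase (radians) at arbitrary normalized pupil
# coordinates, dropping the piston term.  Prefers the coefficient expansion
# (exact); falls back to bilinear interpolation of the stored map.
wavefront_phase_at <- function(wavefront, px, py) {
  if (is.null(wavefront)) return(numeric(length(px)))
  co <- wavefront$zernike_coefficients
  rho <- sqrt(px^2 + py^2)
  theta <- atan2(py, px)
  out <- numeric(length(px))
  if (length(co) >= 2) {
    for (j in 2:length(co)) {
      if (co[j] != 0) out <- out + co[j] * zernike_noll(j, rho, theta)
    }
  }
  2 * pi * out
}

#' Fit Zernike coefficients to a pupil phase map
#'
#' Least-squares projection of a sampled wavefront onto Noll modes
#' `1..n_modes` over the valid pupil mask.  Piston, tip and tilt are
#' estimated (and reported) like any other mode; the PSF model ignores
#' piston and callers typically zero tip/tilt as well since they only
#' translate the image.
#'
#' @param wavefront A `qlfm_wavefront`, or a list with `pupil_phase_map`
#'   (radians, `NA` outside the pupil) as produced by
#'   [integrate_shifts_to_wavefront()].
#' @param n_modes Number of Noll modes to fit.
#' @return Numeric vector of `n_modes` coefficients in wavelength units.
#' @export
fit_zernike <- function(wavefront, n_modes = 15L) {
  phase <- wavefront$pupil_phase_map
  ns <- nrow(phase)
  ax <- seq(-1, 1, length.out = ns)
  xx <- matrix(ax, ns, ns, byrow = TRUE)
  yy <- matrix(ax, ns, ns)
  rho <- sqrt(xx^2 + yy^2)
  theta <- atan2(yy, xx)
  valid <- is.finite(phase) & rho <= 1
  nv <- sum(valid)
  if (n_modes > nv) stop("n_modes exceeds the number of valid pupil samples",
                         call. = FALSE)
  A <- matrix(0, nv, n_modes)
  for (j in seq_len(n_modes)) {
    A[, j] <- zernike_noll(j, rho[valid], theta[valid])
  }
  b <- phase[valid] / (2 * pi)
  as.numeric(stats::lsfit(A, b, intercept = FALSE)$coefficients)
}

# RMS of the wavefront over the pupil in wavelength units, piston removed.
wavefront_rms <- function(wavefront) {
  ph <- wavefront$pupil_phase_map
  v <- ph[is.finite(ph)] / (2 * pi)
  sqrt(mean((v - mean(v))^2))
}
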