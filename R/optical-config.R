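# Instrument geometry: everything the wave-optics model and the pixel
# realignment need to know about the microscope + microlens array + relay +
# camera chain.

#' Optical configuration for a light-field microscope
#'
#' Collects the instrument parameters required by the wave-optics PSF model
#' and the realignment geometry.  Lengths are in micrometres throughout.
#'
#' `pixels_per_lens` is derived as
#' `round(mla_pitch * relay_magnification / camera_pixel_pitch)` and must be
#' odd so that a central (chief-ray) angular component exists.  The
#' `effective_magnification` is the magnification actually mapping the
#' microlens pitch onto the sample plane; it can differ from the objective's
#' nominal magnification when the tube lens focal length does not match the
#' objective's design (e.g. a nominal 40x objective imaging a 100 um pitch
#' onto a 2.15 um sample-plane cell corresponds to ~46.5x).  It defaults to
#' `objective_magnification`.
#'
#' @param emission_wavelength Emission wavelength (um).
#' @param objective_na Objective numerical aperture.
#' @param objective_magnification Nominal objective magnification.
#' @param immersion_index Refractive index of the immersion/sample medium.
#' @param mla_pitch Microlens pitch (um).
#' @param mla_focal_length Microlens focal length (um).
#' @param relay_magnification Magnification of the relay between the MLA back
#'   focal plane and the camera.
#' @param camera_pixel_pitch Camera pixel pitch (um).
#' @param num_lenses Integer pair: number of microlenses (y, x) covered by
#'   the processed field of view.
#' @param effective_magnification Magnification from sample plane to MLA
#'   plane; defaults to `objective_magnification`.
#' @return An object of class `qlfm_config` (a validated list).
#' @seealso [lfm_preset_40x()], [lfm_preset_desk()]
#' @export
optical_config <- function(emission_wavelength,
                           objective_na,
                           objective_magnification,
                           immersion_index = 1.33,
                           mla_pitch,
                           mla_focal_length,
                           relay_magnification = 1,
                           camera_pixel_pitch,
                           num_lenses = c(15L, 15L),
                           effective_magnification = objective_magnification) {
  num <- list(emission_wavelength = emission_wavelength,
              objective_na = objective_na,
              objective_magnification = objective_magnification,
              immersion_index = immersion_index,
              mla_pitch = mla_pitch,
              mla_focal_length = mla_focal_length,
              relay_magnification = relay_magnification,
              camera_pixel_pitch = camera_pixel_pitch,
              effective_magnification = effective_magnification)
  for (nm in names(num)) {
    v <- num[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("field '", nm, "' must be a single positive finite number",
           call. = FALSE)
    }
  }
  if (objective_na >= immersion_index) {
    stop("objective_na must be smaller than the immersion index", call. = FALSE)
  }
  ppl <- as.integer(round(mla_pitch * relay_magnification / camera_pixel_pitch))
  if (ppl < 1L) stop("geometry yields no pixels per microlens", call. = FALSE)
  if (ppl %% 2L == 0L) {
    stop("pixels_per_lens = ", ppl, " is even; choose a pitch/relay/pixel ",
         "combination with an odd pixel count so a central angular ",
         "component exists", call. = FALSE)
  }
  num_lenses <- as.integer(num_lenses)
  if (length(num_lenses) == 1L) num_lenses <- rep(num_lenses, 2L)
  if (any(num_lenses < 1L)) stop("num_lenses must be positive", call. = FALSE)

  # NA-matching sanity check: image-side NA of the objective vs the MLA
  # acceptance half-angle (pitch / 2f).  A mismatch wastes pixels or overlaps
  # lens images; warn but do not fail.
  na_img <- objective_na / objective_magnification
  na_mla <- mla_pitch / (2 * mla_focal_length)
  if (abs(na_img - na_mla) > 0.2 * na_img) {
    warning(sprintf(paste0("NA mismatch: objective image-side NA %.4f vs MLA ",
                           "acceptance %.4f (>20%%)"), na_img, na_mla),
            call. = FALSE)
  }

  structure(c(num, list(pixels_per_lens = ppl, num_lenses = num_lenses)),
            class = "qlfm_config")
}

#' @export
print.qlfm_config <- function(x, ...) {
  cat("Light-field optical configuration\n")
  cat(sprintf("  objective: %gx / NA %.2f (n = %.2f), effective %gx\n",
              x$objective_magnification, x$objective_na, x$immersion_index,
              x$effective_magnification))
  cat(sprintf("  MLA: pitch %g um, f %g um; relay %gx; camera pixel %g um\n",
              x$mla_pitch, x$mla_focal_length, x$relay_magnification,
              x$camera_pixel_pitch))
  cat(sprintf("  %d x %d pixels per lens, %d x %d lenses, lens sampling %.3f um\n",
              x$pixels_per_lens, x$pixels_per_lens,
              x$num_lenses[1], x$num_lenses[2], lens_sampling(x)))
  invisible(x)
}

# Sample-plane footprint of one microlens (um) -- the native lateral
# sampling interval of the reconstruction.
lens_sampling <- function(config) config$mla_pitch / config$effective_magnification

# Half-count of angular components per axis (u in -half..half).
angular_half <- function(config) (config$pixels_per_lens - 1L) %/% 2L

# Normalized pupil coordinate step per angular component: one sensor pixel at
# the MLA back focal plane subtends (pixel pitch at MLA)/f_mla of image-side
# angle; the full image-side NA (objective_na / effective_magnification)
# corresponds to pupil radius 1.
pupil_step <- function(config) {
  dx_mla <- config$camera_pixel_pitch / config$relay_magnification
  na_img <- config$objective_na / config$effective_magnification
  (dx_mla / config$mla_focal_length) / na_img
}

#' Preset: 40x/1.0 NA water-immersion light-field configuration
#'
#' The 40x/1.0 NA water-immersion geometry: 100 um MLA pitch, 2.1 mm MLA
#' focal length, 0.845x relay onto a 6.5 um-pixel sCMOS camera, which yields
#' 13 x 13 sensor pixels per microlens and a 2.15 um lateral sampling cell at
#' the sample plane (effective magnification 100/2.15 ~ 46.5x).
#'
#' @param num_lenses Number of microlenses per axis retained in the field of
#'   view (full sensors cover ~157; the default keeps a desk-sized patch).
#' @param emission_wavelength Emission wavelength in um (default 0.525,
#'   yellow-green emitters).
#' @return A `qlfm_config`.
#' @export
lfm_preset_40x <- function(num_lenses = c(15L, 15L),
                           emission_wavelength = 0.525) {
  optical_config(emission_wavelength = emission_wavelength,
                 objective_na = 1.0,
                 objective_magnification = 40,
                 immersion_index = 1.33,
                 mla_pitch = 100,
                 mla_focal_length = 2100,
                 relay_magnification = 0.845,
                 camera_pixel_pitch = 6.5,
                 num_lenses = num_lenses,
                 effective_magnification = 100 / 2.15)
}

#' Preset: desk-scale configuration for simulation and testing
#'
#' Same optical train as [lfm_preset_40x()] but with a camera whose pixels
#' are 2.6x larger, so each microlens covers 5 x 5 sensor pixels.  Retaining
#' 5 x 5 angular components keeps end-to-end simulations and reconstructions
#' fast while preserving every geometric relation of the full system.
#'
#' @param num_lenses Number of microlenses per axis (default 15).
#' @return A `qlfm_config`.
#' @export
lfm_preset_desk <- function(num_lenses = c(15L, 15L)) {
  optical_config(emission_wavelength = 0.525,
                 objective_na = 1.0,
                 objective_magnification = 40,
                 immersion_index = 1.33,
                 mla_pitch = 100,
                 mla_focal_length = 2100,
                 relay_magnification = 0.845,
                 camera_pixel_pitch = 16.9,
                 num_lenses = num_lenses,
                 effective_magnification = 100 / 2.15)
}
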