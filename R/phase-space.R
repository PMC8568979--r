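# Pixel realignment between raw sensor frames and 4D phase-space views.
#
# A raw light-field frame tiles the sensor into pixels-per-lens blocks, one
# per microlens.  Realignment regroups pixels by their position *within*
# the block: views[v, u, lens_y, lens_x] collects, for fixed angular offset
# (u, v), one low-resolution spatial image on the lens grid.  For integral
# lens centers this is a pure permutation (photon counts are conserved
# exactly); fractional lens-grid origins are handled by bilinear resampling
# of the sensor first.

#' Construct a raw light-field frame
#'
#' @param sensor_image 2D non-negative matrix of counts (rows = y).
#' @param config A `qlfm_config`.
#' @param lens_grid_origin Sub-pixel sensor position (y, x) of the *corner*
#'   of the first microlens block, 0-based; default `c(0, 0)` means the
#'   sensor starts exactly at a lens boundary.
#' @return An object of class `qlfm_frame`.
#' @export
lightfield_frame <- function(sensor_image, config, lens_grid_origin = c(0, 0)) {
  if (any(sensor_image < 0)) stop("sensor image must be non-negative", call. = FALSE)
  ppl <- config$pixels_per_lens
  need <- config$num_lenses * ppl
  have <- dim(sensor_image) - ceiling(lens_grid_origin)
  if (any(have < need)) {
    stop(sprintf("lens grid (%d x %d px) extends beyond the sensor (%d x %d px)",
                 need[1], need[2], nrow(sensor_image), ncol(sensor_image)),
         call. = FALSE)
  }
  structure(list(sensor_image = sensor_image, config = config,
                 lens_grid_origin = as.numeric(lens_grid_origin)),
            class = "qlfm_frame")
}

#' Realign a raw frame into phase-space views
#'
#' @param frame A `qlfm_frame` (or a plain matrix together with `config`).
#' @param config Required when `frame` is a matrix.
#' @param lens_grid_origin See [lightfield_frame()].
#' @return An object of class `qlfm_views`: 4D array
#'   `(v, u, lens_y, lens_x)` with attribute `config`.  Angular index 1
#'   corresponds to offset `-(pixels_per_lens - 1)/2`.
#' @export
realign <- function(frame, config = NULL, lens_grid_origin = c(0, 0)) {
  if (!inherits(frame, "qlfm_frame")) {
    frame <- lightfield_frame(frame, config, lens_grid_origin)
  }
  config <- frame$config
  ppl <- config$pixels_per_lens
  nly <- config$num_lenses[1]; nlx <- config$num_lenses[2]
  img <- frame$sensor_image
  org <- frame$lens_grid_origin
  if (any(abs(org - round(org)) > 1e-9)) {
    img <- bilinear_shift(img, org - floor(org))
    org <- floor(org)
  }
  oy <- as.integer(org[1]); ox <- as.integer(org[2])
  sub <- img[oy + seq_len(nly * ppl), ox + seq_len(nlx * ppl), drop = FALSE]
  views <- array(0, dim = c(ppl, ppl, nly, nlx))
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      views[vi, ui, , ] <- sub[seq(vi, nly * ppl, by = ppl),
                               seq(ui, nlx * ppl, by = ppl)]
    }
  }
  structure(views, class = "qlfm_views", config = config)
}

# Resample img on a grid shifted by frac (0 <= frac < 1) using bilinear
# interpolation (monotone, non-negativity-preserving); zero outside.
bilinear_shift <- function(img, frac) {
  fy <- frac[1]; fx <- frac[2]
  ny <- nrow(img); nx <- ncol(img)
  pad <- rbind(cbind(img, 0), 0)
  a <- pad[seq_len(ny), seq_len(nx)]
  b <- pad[seq_len(ny), seq_len(nx) + 1L]
  c2 <- pad[seq_len(ny) + 1L, seq_len(nx)]
  d <- pad[seq_len(ny) + 1L, seq_len(nx) + 1L]
  (1 - fy) * (1 - fx) * a + (1 - fy) * fx * b + fy * (1 - fx) * c2 + fy * fx * d
}

#' Map phase-space views back to a raw sensor frame
#'
#' Exact inverse of [realign()] for integral lens-grid origins.
#'
#' @param views A `qlfm_views` array.
#' @param config A `qlfm_config`; defaults to the one attached to `views`.
#' @return A `qlfm_frame` whose sensor image covers exactly the realigned
#'   region.
#' @export
inverse_realign <- function(views, config = NULL) {
  if (is.null(config)) config <- attr(views, "config")
  ppl <- config$pixels_per_lens
  d <- dim(views)
  if (d[1] != ppl || d[2] != ppl ||
      d[3] != config$num_lenses[1] || d[4] != config$num_lenses[2]) {
    stop("views shape is inconsistent with the configuration", call. = FALSE)
  }
  nly <- d[3]; nlx <- d[4]
  img <- matrix(0, nly * ppl, nlx * ppl)
  for (vi in seq_len(ppl)) {
    for (ui in seq_len(ppl)) {
      img[seq(vi, nly * ppl, by = ppl), seq(ui, nlx * ppl, by = ppl)] <-
        views[vi, ui, , ]
    }
  }
  lightfield_frame(img, config)
}

# Empty views container for a configuration.
new_views <- function(config, fill = 0) {
  ppl <- config$pixels_per_lens
  structure(array(fill, dim = c(ppl, ppl, config$num_lenses[1],
                                config$num_lenses[2])),
            class = "qlfm_views", config = config)
}

views_dot <- function(a, b) sum(unclass(a) * unclass(b))
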