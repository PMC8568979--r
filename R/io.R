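# File I/O: structured-text (YAML) configuration, TIFF stacks with scale
# metadata, multiscale volumes as per-slab multi-page TIFFs plus a JSON
# manifest, phase-space views and PSFs with axis metadata.
#
# Axis-order convention for all on-disk 4D/5D data: (u, v, z/t, y, x),
# recorded in every manifest.  Values are stored as 32-bit TIFF samples in
# [0, 1] with a power-of-two scale factor recorded in a JSON sidecar
# (<path>.json); storage quantization is 2^-32 of the scale, i.e. well below
# single-precision round-off for any image data.

config_fields <- c("emission_wavelength", "objective_na",
                   "objective_magnification", "immersion_index", "mla_pitch",
                   "mla_focal_length", "relay_magnification",
                   "camera_pixel_pitch", "num_lenses",
                   "effective_magnification")
config_mandatory <- c("emission_wavelength", "objective_na",
                      "objective_magnification", "mla_pitch",
                      "mla_focal_length", "camera_pixel_pitch")

#' Save an optical configuration (and options) to a YAML file
#'
#' @param config A `qlfm_config`.
#' @param path Output path.
#' @param options Optional reconstruction options list to store alongside.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path, options = NULL) {
  x <- unclass(config)[config_fields]
  out <- list(optics = x)
  if (!is.null(options)) out$reconstruction <- options
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Load an optical configuration (and options) from a YAML file
#'
#' Unknown keys produce a warning; missing mandatory fields or invariant
#' violations produce an error naming the field.
#'
#' @param path YAML file written by [save_config()] (or hand-authored with
#'   an `optics:` block).
#' @return List: `config` (`qlfm_config`), `options` (reconstruction options
#'   or NULL).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  opt <- if (!is.null(raw$optics)) raw$optics else raw
  unknown <- setdiff(names(opt), config_fields)
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  missing <- setdiff(config_mandatory, names(opt))
  if (length(missing)) {
    stop("mandatory config field(s) missing: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  args <- opt[intersect(config_fields, names(opt))]
  config <- do.call(optical_config, args)
  ro <- raw$reconstruction
  options <- if (!is.null(ro)) do.call(recon_options, ro) else NULL
  list(config = config, options = options)
}

# Power-of-two scale bringing data into [0, 1] (exact in binary floats).
tiff_scale <- function(mx) {
  if (mx <= 0) return(1)
  2^ceiling(log2(mx))
}

#' Write a numeric stack as a 32-bit float multi-page TIFF
#'
#' @param stack A matrix, a 3D array (pages = third dim), or list of
#'   matrices.
#' @param path Output path.
#' @param metadata Optional list stored (as JSON) in the sidecar file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, metadata = list()) {
  pages <- if (is.list(stack)) stack
    else if (length(dim(stack)) == 3L) {
      d <- dim(stack)
      lapply(seq_len(d[3]), function(k) matrix(stack[, , k], d[1], d[2]))
    } else list(stack)
  mx <- max(0, vapply(pages, max, numeric(1)))
  mn <- min(0, vapply(pages, min, numeric(1)))
  if (mn < 0) stop("write_stack stores non-negative data only", call. = FALSE)
  sc <- tiff_scale(mx)
  meta <- c(metadata, list(scale = sc))
  pages <- lapply(pages, function(p) p / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by [write_stack()] (or a plain TIFF)
#'
#' Values are rescaled by the sidecar scale factor when a `<path>.json`
#' sidecar exists; 16-bit input without a sidecar is promoted to float
#' counts with the implicit 65535 scale recorded.
#'
#' @param path TIFF path.
#' @return List: `pages` (list of matrices), `data` (3D array when all pages
#'   share a shape), `metadata`, `scale`, `bits_per_sample`.
#' @export
read_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  info <- attributes(pages[[1]])
  bps <- if (!is.null(info$bits.per.sample)) info$bits.per.sample else 32L
  meta <- NULL
  sc <- 1
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::fromJSON(sidecar)
    if (!is.null(meta$scale)) sc <- meta$scale
  } else if (bps == 16L) {
    sc <- 65535  # promote to integer counts
  }
  pages <- lapply(pages, function(p) {
    a <- p
    attributes(a) <- list(dim = dim(p))
    a * sc
  })
  dims <- vapply(pages, function(p) paste(dim(p), collapse = "x"), character(1))
  data <- NULL
  if (length(unique(dims)) == 1L) {
    data <- array(unlist(pages), c(dim(pages[[1]]), length(pages)))
  }
  list(pages = pages, data = data, metadata = meta, scale = sc,
       bits_per_sample = bps)
}

#' Write a multiscale volume (per-slab TIFFs plus a JSON manifest)
#'
#' @param volume A `qlfm_volume`.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return The manifest path, invisibly.
#' @export
write_volume <- function(volume, dir, name = "volume") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- volume$grid
  files <- character(nrow(g$slabs))
  for (i in seq_len(nrow(g$slabs))) {
    files[i] <- sprintf("%s_slab%02d.tif", name, i)
    write_stack(volume$slabs[[i]], file.path(dir, files[i]),
                metadata = list(axis_order = "z,y,x", slab = i))
  }
  manifest <- list(
    name = name, axis_order = "u,v,z,y,x", files = files,
    base_lateral = g$base_lateral, num_lenses = g$num_lenses,
    z_min = g$z_min, z_max = g$z_max,
    slabs = g$slabs)
  mpath <- file.path(dir, paste0(name, "_manifest.json"))
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(mpath)
}

#' Read a multiscale volume written by [write_volume()]
#'
#' @param manifest_path Path to the `_manifest.json` file.
#' @return A `qlfm_volume`.
#' @export
read_volume <- function(manifest_path) {
  man <- jsonlite::fromJSON(manifest_path)
  slabs <- as.data.frame(man$slabs)
  slabs$factor <- as.integer(slabs$factor)
  slabs$ny <- as.integer(slabs$ny); slabs$nx <- as.integer(slabs$nx)
  slabs$nz <- as.integer(slabs$nz)
  planes <- do.call(rbind, lapply(seq_len(nrow(slabs)), function(i) {
    with(slabs[i, ], data.frame(
      slab = i, iz = seq_len(nz),
      z = z_start + (seq_len(nz) - 0.5) * axial_step,
      factor = factor, lateral_step = lateral_step, axial_step = axial_step,
      ny = ny, nx = nx))
  }))
  grid <- structure(list(slabs = slabs, planes = planes,
                         base_lateral = man$base_lateral,
                         num_lenses = as.integer(man$num_lenses),
                         z_min = man$z_min, z_max = man$z_max, model = NULL),
                    class = "qlfm_grid")
  dir <- dirname(manifest_path)
  data <- lapply(seq_along(man$files), function(i) {
    st <- read_stack(file.path(dir, man$files[i]))
    d <- st$data
    if (is.null(d)) d <- array(unlist(st$pages),
                               c(dim(st$pages[[1]]), length(st$pages)))
    d
  })
  structure(list(grid = grid, slabs = data), class = "qlfm_volume")
}

#' Write phase-space views as a multi-page TIFF with axis metadata
#'
#' Pages are ordered angular-component-major: page index = (u-index - 1) *
#' ppl + v-index, each page a (lens_y, lens_x) image.
#'
#' @param views A `qlfm_views` array.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_views <- function(views, path) {
  d <- dim(views)
  pages <- list()
  for (ui in seq_len(d[2])) for (vi in seq_len(d[1])) {
    pages[[length(pages) + 1L]] <- views[vi, ui, , ]
  }
  write_stack(pages, path, metadata = list(
    axis_order = "u,v,y,x", pixels_per_lens = d[1],
    num_lenses = c(d[3], d[4])))
}

#' Read phase-space views written by [write_views()]
#'
#' @param path TIFF path.
#' @param config Optional `qlfm_config` attached to the result.
#' @return A `qlfm_views` array.
#' @export
read_views <- function(path, config = NULL) {
  st <- read_stack(path)
  ppl <- st$metadata$pixels_per_lens
  nl <- st$metadata$num_lenses
  views <- array(0, c(ppl, ppl, nl[1], nl[2]))
  k <- 0L
  for (ui in seq_len(ppl)) for (vi in seq_len(ppl)) {
    k <- k + 1L
    views[vi, ui, , ] <- st$pages[[k]]
  }
  structure(views, class = "qlfm_views", config = config)
}

#' Save a wavefront's Zernike coefficients as structured text
#'
#' @param wavefront A `qlfm_wavefront` (or a calibration result list).
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_wavefront <- function(wavefront, path) {
  co <- if (!is.null(wavefront$coefficients)) wavefront$coefficients
        else wavefront$zernike_coefficients
  yaml::write_yaml(list(
    units = "emission wavelengths",
    indexing = "Noll",
    zernike_coefficients = as.numeric(co)), path)
  invisible(path)
}
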