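# Quantitative evaluation: signal-to-background ratio, FWHM resolution,
# Pearson correlation, and dF/F0 calcium-trace extraction.

#' Define a region of interest
#'
#' @param center 3D position (y, x, z) in um.
#' @param extent 3D size (y, x, z) in um; all positive.
#' @return A list of class `qlfm_roi`.
#' @export
roi <- function(center, extent) {
  if (any(extent <= 0)) stop("ROI extent must be positive", call. = FALSE)
  structure(list(center = as.numeric(center), extent = as.numeric(extent)),
            class = "qlfm_roi")
}

# Mean intensity of a volume inside an ROI (voxel centers within the box).
roi_mean <- function(volume, r) {
  grid <- volume$grid
  pl <- grid$planes
  tot <- 0; n <- 0
  for (p in seq_len(nrow(pl))) {
    if (abs(pl$z[p] - r$center[3]) > r$extent[3] / 2) next
    step <- pl$lateral_step[p]
    ny <- pl$ny[p]; nx <- pl$nx[p]
    cy <- (seq_len(ny) - center_index(ny)) * step
    cx <- (seq_len(nx) - center_index(nx)) * step
    iy <- which(abs(cy - r$center[1]) <= r$extent[1] / 2)
    ix <- which(abs(cx - r$center[2]) <= r$extent[2] / 2)
    if (!length(iy) || !length(ix)) next
    vals <- volume$slabs[[pl$slab[p]]][iy, ix, pl$iz[p]]
    tot <- tot + sum(vals)
    n <- n + length(vals)
  }
  if (n == 0) stop("ROI contains no voxels (outside the volume?)", call. = FALSE)
  tot / n
}

#' Signal-to-background ratio of a reconstruction
#'
#' Ratio of the mean over signal-ROI means (each the reconstructed mean
#' intensity of one bead/neuron) to the mean intensity of a sample-free
#' background ROI.  Reported linearly and in dB; the dB convention is
#' `10 * log10(ratio)` of the intensity ratio.
#'
#' @param recon A `qlfm_volume`.
#' @param signal_rois List of `qlfm_roi`.
#' @param background_roi A `qlfm_roi` placed where no sample is present.
#' @return List: `ratio`, `db`, `signal_mean`, `background_mean`,
#'   `infinite` (TRUE when the background mean is zero).
#' @export
compute_sbr <- function(recon, signal_rois, background_roi) {
  if (inherits(signal_rois, "qlfm_roi")) signal_rois <- list(signal_rois)
  sig <- mean(vapply(signal_rois, function(r) roi_mean(recon, r), numeric(1)))
  bg <- roi_mean(recon, background_roi)
  if (bg <= 0) {
    return(list(ratio = Inf, db = Inf, signal_mean = sig, background_mean = bg,
                infinite = TRUE))
  }
  ratio <- sig / bg
  list(ratio = ratio, db = 10 * log10(ratio), signal_mean = sig,
       background_mean = bg, infinite = FALSE)
}

#' Full width at half maximum of a sampled profile
#'
#' Linear interpolation of the two half-maximum crossings around the peak.
#'
#' @param profile Numeric vector with a unique interior maximum above both
#'   boundary values.
#' @param sampling Sample spacing (um).
#' @return Width in um.
#' @export
fwhm <- function(profile, sampling = 1) {
  n <- length(profile)
  ipk <- which.max(profile)
  pk <- profile[ipk]
  if (sum(profile == pk) > 1L || pk <= max(profile[1], profile[n]) ||
      ipk == 1L || ipk == n) {
    stop("profile must have a unique interior maximum above its boundaries",
         call. = FALSE)
  }
  half <- pk / 2
  left <- NA_real_
  for (i in seq(ipk - 1L, 1L)) {
    if (profile[i] <= half) {
      left <- i + (half - profile[i]) / (profile[i + 1] - profile[i])
      break
    }
  }
  right <- NA_real_
  for (i in seq(ipk + 1L, n)) {
    if (profile[i] <= half) {
      right <- i - (half - profile[i]) / (profile[i - 1] - profile[i])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    stop("profile does not cross half maximum on both sides (truncated)",
         call. = FALSE)
  }
  (right - left) * sampling
}

#' Pearson correlation between two signals
#'
#' `r = E[(X - mean(X)) (Y - mean(Y))] / (sd(X) sd(Y))` with population
#' normalization.
#'
#' @param x,y Numeric vectors of equal length (>= 2).
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L) {
    stop("series must have equal length >= 2", call. = FALSE)
  }
  sx <- sqrt(mean((x - mean(x))^2))
  sy <- sqrt(mean((y - mean(y))^2))
  if (sx == 0 || sy == 0) {
    stop("correlation undefined for zero-variance series", call. = FALSE)
  }
  r <- mean((x - mean(x)) * (y - mean(y))) / (sx * sy)
  min(max(r, -1), 1)
}

#' Extract dF/F0 traces from a reconstruction time series
#'
#' `F(t)` is the mean ROI intensity; the baseline `F0` is the mean of all
#' time points whose `F(t)` lies below 120% of the trace average (if no
#' point qualifies, `F0` falls back to the trace average and the trace is
#' flagged).
#'
#' @param series List of `qlfm_volume`s, time-ordered (>= 2).
#' @param rois List of `qlfm_roi`.
#' @param frame_rate Acquisition rate in Hz (stored on the result).
#' @return List of traces; each has `f` (raw mean intensities), `f0`,
#'   `dff` (`(F - F0)/F0`), `flagged`, `frame_rate`.
#' @export
extract_dff_traces <- function(series, rois, frame_rate = 1) {
  if (length(series) < 2L) stop("need at least 2 time points", call. = FALSE)
  if (inherits(rois, "qlfm_roi")) rois <- list(rois)
  lapply(rois, function(r) {
    f <- vapply(series, function(v) roi_mean(v, r), numeric(1))
    dff_from_trace(f, frame_rate)
  })
}

# The 120%-of-average baseline rule on a plain numeric trace.
dff_from_trace <- function(f, frame_rate = 1) {
  thr <- 1.2 * mean(f)
  base_pts <- f[f < thr]
  flagged <- length(base_pts) == 0L
  f0 <- if (flagged) mean(f) else mean(base_pts)
  structure(list(f = f, f0 = f0, dff = (f - f0) / f0, flagged = flagged,
                 frame_rate = frame_rate), class = "qlfm_trace")
}

# Gaussian-fit R^2 of a bead profile ("fitting degree" used to rank beads).
gaussian_fit_r2 <- function(profile, sampling = 1) {
  x <- (seq_along(profile) - which.max(profile)) * sampling
  df <- data.frame(x = x, y = profile)
  fit <- try(minpack.lm::nlsLM(
    y ~ a * exp(-x^2 / (2 * s^2)) + c0, data = df,
    start = list(a = max(profile) - min(profile),
                 s = sampling * max(2, length(profile) / 6),
                 c0 = min(profile)),
    lower = c(0, sampling / 10, -Inf)), silent = TRUE)
  if (inherits(fit, "try-error")) return(0)
  1 - sum(stats::resid(fit)^2) / sum((profile - mean(profile))^2)
}
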