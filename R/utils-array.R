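# Low-level array helpers shared by the forward model, reconstruction and
# resampling code.  All 2D arrays are indexed [y, x]; "centered" means the
# reference sample sits at index (floor(n/2) + 1) on each axis, which for the
# odd sizes used throughout is the exact middle sample.

center_index <- function(n) as.integer(n) %/% 2L + 1L

#' @noRd
fftshift2 <- function(x) {
  d <- dim(x)
  sy <- center_index(d[1L]) - 1L
  sx <- center_index(d[2L]) - 1L
  x[c(seq_len(d[1L] - sy) + sy, seq_len(sy)),
    c(seq_len(d[2L] - sx) + sx, seq_len(sx)), drop = FALSE]
}

#' @noRd
ifftshift2 <- function(x) {
  d <- dim(x)
  sy <- d[1L] - (center_index(d[1L]) - 1L)
  sx <- d[2L] - (center_index(d[2L]) - 1L)
  x[c(seq_len(d[1L] - sy) + sy, seq_len(sy)),
    c(seq_len(d[2L] - sx) + sx, seq_len(sx)), drop = FALSE]
}

# Centered 2D FFT pair: forward maps a field sampled around the array center
# to a spectrum sampled around the array center.
fft2c <- function(x) fftshift2(stats::fft(ifftshift2(x)))
ifft2c <- function(x) fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / length(x)

# Good FFT length >= n (products of 2 and 3 keep stats::fft fast).
good_fft_size <- function(n) {
  n <- as.integer(n)
  repeat {
    m <- n
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(n)
    n <- n + 1L
  }
}

# Embed a matrix into a py x px zero matrix with its centered sample at the
# centered sample of the target (used for linear convolution via FFT).
embed_centered <- function(x, py, px) {
  d <- dim(x)
  out <- matrix(0, py, px)
  oy <- center_index(py) - center_index(d[1L])
  ox <- center_index(px) - center_index(d[2L])
  out[seq_len(d[1L]) + oy, seq_len(d[2L]) + ox] <- x
  out
}

# Extract a centered ny x nx window (inverse of embed_centered).
extract_centered <- function(x, ny, nx) {
  d <- dim(x)
  oy <- center_index(d[1L]) - center_index(ny)
  ox <- center_index(d[2L]) - center_index(nx)
  x[seq_len(ny) + oy, seq_len(nx) + ox, drop = FALSE]
}

# Linear convolution of img with an odd-sized kernel, output cropped to the
# size of img with the kernel centered; exact adjoint is the same call with
# the kernel rotated by 180 degrees (flip2).  When kfft (the FFT of the
# embedded kernel at padded size p) is supplied it is reused.
conv2_centered <- function(img, kernel = NULL, kfft = NULL, pad = NULL) {
  di <- dim(img)
  if (is.null(pad)) {
    dk <- dim(kernel)
    pad <- c(good_fft_size(di[1L] + dk[1L] - 1L),
             good_fft_size(di[2L] + dk[2L] - 1L))
  }
  fi <- stats::fft(ifftshift2(embed_centered(img, pad[1L], pad[2L])))
  if (is.null(kfft)) {
    kfft <- stats::fft(ifftshift2(embed_centered(kernel, pad[1L], pad[2L])))
  }
  out <- fftshift2(stats::fft(fi * kfft, inverse = TRUE)) / prod(pad)
  extract_centered(Re(out), di[1L], di[2L])
}

# Precompute the padded kernel FFT for conv2_centered given image size.
conv2_plan <- function(kernel, img_dim) {
  dk <- dim(kernel)
  pad <- c(good_fft_size(img_dim[1L] + dk[1L] - 1L),
           good_fft_size(img_dim[2L] + dk[2L] - 1L))
  list(pad = pad,
       kfft = stats::fft(ifftshift2(embed_centered(kernel, pad[1L], pad[2L]))))
}

flip2 <- function(x) x[rev(seq_len(nrow(x))), rev(seq_len(ncol(x))), drop = FALSE]

# Mass-preserving lateral resampling between integer sampling factors.
# A factor-s grid cell corresponds to an s x s block of fine (factor-1) cells
# sharing the same total; values are densities (per-area), so:
#   up  : replicate each coarse value over its s x s fine block
#   down: average each s x s fine block
# Fine grids of size n are covered by m = ceiling(n/s) coarse cells; the
# coarse footprint (m*s) is center-aligned on the fine grid.
upsample_lateral <- function(x, s, ny, nx) {
  if (s == 1L) return(extract_centered(x, ny, nx))
  big <- x[rep(seq_len(nrow(x)), each = s), rep(seq_len(ncol(x)), each = s),
           drop = FALSE]
  extract_centered(big, ny, nx)
}

downsample_lateral <- function(x, s, my = NULL, mx = NULL) {
  if (is.null(my)) my <- as.integer(ceiling(nrow(x) / s))
  if (is.null(mx)) mx <- as.integer(ceiling(ncol(x) / s))
  if (s == 1L) {
    if (my == nrow(x) && mx == ncol(x)) return(x)
    return(embed_centered(x, my, mx))
  }
  big <- embed_centered(x, my * s, mx * s)
  ky <- (seq_len(my * s) - 1L) %/% s
  kx <- (seq_len(mx * s) - 1L) %/% s
  rs <- rowsum(big, ky)
  t(rowsum(t(rs), kx)) / (s * s)
}

# Coverage-weighted block average: like downsample_lateral but dividing by
# the number of covered fine cells per block, so a constant field stays
# constant even when the coarse footprint (m*s) overhangs the fine grid.
# Used by grid resampling; the projection adjoint keeps the unweighted pair.
downsample_lateral_cov <- function(x, s, my = NULL, mx = NULL) {
  if (is.null(my)) my <- as.integer(ceiling(nrow(x) / s))
  if (is.null(mx)) mx <- as.integer(ceiling(ncol(x) / s))
  if (s == 1L && my == nrow(x) && mx == ncol(x)) return(x)
  num <- s * s * downsample_lateral(x, s, my, mx)
  den <- s * s * downsample_lateral(matrix(1, nrow(x), ncol(x)), s, my, mx)
  out <- num / pmax(den, 1e-12)
  out[den <= 0] <- 0
  out
}

# Adjoints under the standard (unweighted) inner products:
#   <upsample(x), y>_fine = <x, s^2 * downsample(y)>_coarse
upsample_adjoint <- function(y, s, my, mx) {
  s * s * downsample_lateral(y, s, my, mx)
}

stopifnot_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop(what, " contains non-finite values", call. = FALSE)
  invisible(TRUE)
}
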