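# SBR, FWHM, Pearson correlation and dF/F0 trace extraction.

# A single-slab volume with hand-set values for ROI arithmetic.
toy_volume <- function(vals = 1) {
  cfg <- fx_config()
  g <- uniform_grid(-15, 15, 10, cfg)
  v <- new_volume(g, 0)
  v$slabs[[1]][] <- vals
  v
}

test_that("SBR follows its closed forms", {
  v <- toy_volume(2)
  r_sig <- roi(c(0, 0, 0), c(5, 5, 5))
  r_bg <- roi(c(10, 10, 10), c(5, 5, 5))
  s <- compute_sbr(v, list(r_sig), r_bg)
  expect_equal(s$ratio, 1)
  expect_equal(s$db, 0)
  # signal 100x background: 20 dB under the 10 log10 intensity convention
  v2 <- toy_volume(1)
  ci <- qlfm:::center_index(15)
  v2$slabs[[1]][ci, ci, 5] <- 100
  s2 <- compute_sbr(v2, list(roi(c(0, 0, v2$grid$planes$z[5]),
                                 c(2, 2, 2))),
                    roi(c(10, 10, 10), c(5, 5, 5)))
  expect_equal(s2$db, 20, tolerance = 1e-9)
  # three-voxel toy: signals 6 and 10, background 4 -> ratio 2
  v3 <- toy_volume(0)
  v3$slabs[[1]][ci, ci, 5] <- 6
  v3$slabs[[1]][ci, ci, 6] <- 10
  v3$slabs[[1]][ci + 4, ci + 4, 5] <- 4
  zs <- v3$grid$planes$z
  sig <- list(roi(c(0, 0, zs[5]), c(2, 2, 2)), roi(c(0, 0, zs[6]), c(2, 2, 2)))
  bg <- roi(c(4 * 2.15, 4 * 2.15, zs[5]), c(2, 2, 2))
  expect_equal(compute_sbr(v3, sig, bg)$ratio, 2.0)
})

test_that("zero background flags infinite SBR instead of crashing", {
  v <- toy_volume(0)
  ci <- qlfm:::center_index(15)
  v$slabs[[1]][ci, ci, 5] <- 1
  s <- compute_sbr(v, list(roi(c(0, 0, v$grid$planes$z[5]), c(2, 2, 2))),
                   roi(c(10, 10, 10), c(4, 4, 4)))
  expect_true(s$infinite)
  expect_true(is.infinite(s$ratio))
})

test_that("SBR is invariant to global intensity scaling", {
  set.seed(37)
  v <- toy_volume(0)
  v$slabs[[1]][] <- runif(length(v$slabs[[1]])) + 0.1
  sig <- list(roi(c(0, 0, 0), c(5, 5, 5)))
  bg <- roi(c(8, -8, 8), c(5, 5, 5))
  s1 <- compute_sbr(v, sig, bg)
  v2 <- qlfm:::volume_map(v, function(x) x * 37.5)
  s2 <- compute_sbr(v2, sig, bg)
  expect_equal(s1$ratio, s2$ratio, tolerance = 1e-12)
})

test_that("FWHM matches Gaussian and triangular closed forms", {
  x <- seq(-15, 15)
  gauss <- exp(-x^2 / (2 * 2^2))
  expect_equal(fwhm(gauss, sampling = 1), 2 * sqrt(2 * log(2)) * 2,
               tolerance = 0.02)
  expect_equal(fwhm(gauss, sampling = 0.5), sqrt(2 * log(2)) * 2,
               tolerance = 0.02)
  tri <- pmax(0, 1 - abs(x) / 4)
  expect_equal(fwhm(tri, sampling = 1), 4)
  expect_error(fwhm(rep(1, 10)), "unique")
  expect_error(fwhm(c(0.6, 0.8, 1, 0.9, 0.8)), "truncated")
})

test_that("Pearson correlation matches hand computations and invariances", {
  expect_equal(pearson(1:5, 1:5), 1)
  expect_equal(pearson(1:5, -(1:5)), -1)
  # population-normalized closed form for X = (1,2,3), Y = (2,4,7)
  x <- c(1, 2, 3); y <- c(2, 4, 7)
  r_hand <- mean((x - 2) * (y - mean(y))) /
    (sqrt(mean((x - 2)^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(pearson(x, y), r_hand)
  expect_equal(r_hand, 0.99340, tolerance = 1e-4)
  # symmetry and affine invariance
  set.seed(41)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pearson(a, b), pearson(b, a))
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  expect_equal(pearson(-3 * a + 2, b), -pearson(a, b), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "zero-variance")
  expect_error(pearson(1:3, 1:4), "equal length")
})

test_that("the 120% baseline rule reproduces its hand-worked examples", {
  # constant trace: baseline is the value, dF/F is zero
  t0 <- qlfm:::dff_from_trace(rep(3, 6))
  expect_equal(t0$f0, 3)
  expect_true(all(t0$dff == 0))
  # (1,1,1,10): mean 3.25, threshold 3.9, F0 = 1
  t1 <- qlfm:::dff_from_trace(c(1, 1, 1, 10))
  expect_equal(t1$f0, 1)
  expect_equal(t1$dff, c(0, 0, 0, 9))
  expect_false(t1$flagged)
  # ramp 1..10: threshold 6.6, F0 = mean(1..6) = 3.5
  t2 <- qlfm:::dff_from_trace(1:10)
  expect_equal(t2$f0, 3.5)
  # all points above threshold: flagged fallback to the overall mean
  t3 <- qlfm:::dff_from_trace(c(5, 5))
  expect_false(t3$flagged)   # equal values sit below 120% of their mean
})

test_that("ROI traces extract dF/F0 from a volume time series", {
  frames <- lapply(c(1, 1, 1, 10), function(v) toy_volume(v))
  tr <- extract_dff_traces(frames, roi(c(0, 0, 0), c(5, 5, 5)),
                          frame_rate = 10)
  expect_equal(tr[[1]]$f, c(1, 1, 1, 10))
  expect_equal(tr[[1]]$f0, 1)
  expect_equal(tr[[1]]$dff[4], 9)
  expect_equal(tr[[1]]$frame_rate, 10)
  expect_error(extract_dff_traces(frames[1], roi(c(0, 0, 0), c(5, 5, 5))),
               "2 time points")
  expect_error(extract_dff_traces(frames, roi(c(500, 0, 0), c(1, 1, 1))),
               "no voxels")
})
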