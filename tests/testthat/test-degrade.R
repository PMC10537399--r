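# The filter's interior behaviour is compared against the analytic squared
# Butterworth gain (1 + (f/fc)^(2*order))^-1, applied twice by the
# forward-backward pass; edges are excluded since start-up transients decay
# over roughly 1/(normalized cutoff) samples.
butter_gain2 <- function(f, fc, order) (1 + (f / fc)^(2 * order))^-2

test_that("zero-phase Butterworth matches the analytic gain oracle", {
  n <- 4096; dx <- 0.5
  mid <- 1024:3072

  # passband: one decade below fc, amplitude within 1%
  p <- sine_profile(0.02, n = n, dx = dx)
  out <- lowpass_profile(p, fc = 0.2, order = 4)
  expect_lt(max(abs(out$z[mid] - p$z[mid])), 0.01)
  g <- sqrt(butter_gain2(0.02, 0.2, 4))
  expect_lt(abs(max(abs(out$z[mid])) - g), 0.01)

  # stopband: one decade above fc, attenuation by at least 10^3
  s <- sine_profile(0.2, n = n, dx = dx)
  outs <- lowpass_profile(s, fc = 0.02, order = 4)
  expect_lt(max(abs(outs$z[mid])), 1e-3)
  expect_lt(max(abs(outs$z[mid])), 10 * butter_gain2(0.2, 0.02, 4) + 1e-8)
})

test_that("low-pass preserves constants and rejects bad cutoffs", {
  const <- slice_profile(0, 0, 0.5, rep(7, 100))
  for (fc in c(0.01, 0.1, 0.9)) {
    expect_lt(max(abs(lowpass_profile(const, fc, 4)$z - 7)), 1e-9)
  }
  expect_error(lowpass_profile(const, 1.0, 4), "Nyquist")
  expect_error(lowpass_profile(const, 1.5, 4), "Nyquist")
})

test_that("downsample_random keeps an exact count, reproducibly", {
  p <- random_smooth_profile(2, n = 100)
  expect_equal(downsample_random(p, 1, seed = 1)$z, p$z)

  d <- downsample_random(p, 0.25, seed = 42)
  expect_equal(sum(!d$missing), 25)
  expect_true(all(is.na(d$z[d$missing])))

  d2 <- downsample_random(p, 0.25, seed = 42)
  expect_identical(d, d2)
  d3 <- downsample_random(p, 0.25, seed = 43)
  expect_false(identical(d$missing, d3$missing))

  expect_error(downsample_random(p, 0.01, seed = 1), "fewer than 2")
})

test_that("quantize_depth rounds to the step with bounded error", {
  p <- slice_profile(0, 0, 1, c(0.4, 0.6, -0.4, -0.6, 1.5))
  q <- quantize_depth(p, 1)
  expect_equal(q$z, c(0, 1, 0, -1, 2))
  expect_equal(quantize_depth(p, 0)$z, p$z)
  expect_error(quantize_depth(p, -1), "non-negative")

  for (seed in 1:5) {
    r <- random_smooth_profile(seed, n = 200)
    step <- 0.3
    expect_lte(max(abs(quantize_depth(r, step)$z - r$z)), step / 2)
  }
})

test_that("add_noise follows its distributional contracts", {
  p0 <- slice_profile(0, 0, 0.5, rep(0, 10000))
  expect_equal(add_noise(p0, "uniform", degrade_params(noise_amplitude = 0))$z,
               p0$z)

  np <- add_noise(p0, "uniform", degrade_params(noise_amplitude = 1, seed = 5))
  expect_lt(abs(mean(np$z)), 0.05)
  expect_lte(max(abs(np$z)), 1)
  # seeded determinism
  np2 <- add_noise(p0, "uniform", degrade_params(noise_amplitude = 1, seed = 5))
  expect_identical(np$z, np2$z)

  # sinusoidal noise shows up at its frequency with its amplitude
  base <- slice_profile(0, 0, 0.5, rep(0, 1000))
  sn <- add_noise(base, "sinusoidal",
                  degrade_params(sine_amplitude = 2, sine_frequency = 0.05))
  s <- profile_spectrum(sn, detrend = "mean", window = "none")
  i <- which(abs(s$frequencies - 0.05) < 1e-12)
  expect_equal(s$magnitudes[i], 2, tolerance = 1e-9)
})

test_that("shape_mae equals the brute-force oracle and is symmetric", {
  a <- make_stack(list(random_smooth_profile(1, n = 60, y_center = 0),
                       random_smooth_profile(2, n = 60, y_center = 10)))
  b <- make_stack(list(random_smooth_profile(3, n = 60, y_center = 0),
                       random_smooth_profile(4, n = 60, y_center = 10)))
  expect_equal(shape_mae(a, a), 0)
  expect_equal(shape_mae(a, b), oracle_shape_mae(a, b))
  expect_equal(shape_mae(a, b), shape_mae(b, a))

  # constant +1 mm depth offset
  bb <- a
  bb$slices <- lapply(a$slices, function(s) { s$z <- s$z + 1; s })
  expect_equal(shape_mae(a, bb), 1)

  # masked cells are excluded on both sides
  am <- a
  am$slices[[1]] <- downsample_random(a$slices[[1]], 0.5, seed = 9)
  expect_equal(shape_mae(am, b), oracle_shape_mae(am, b))
})

test_that("sweep_cutoffs leaves band-limited stacks untouched above the band", {
  # content strictly below 0.02 mm^-1
  st <- make_stack(list(
    sine_profile(0.01, n = 1024, amplitude = 5, y_center = 0),
    sine_profile(0.015, n = 1024, amplitude = 3, y_center = 10)))
  curve <- sweep_cutoffs(st, c(0.1, 0.05))
  expect_true(all(curve$errors < 0.05))
  expect_equal(curve$metric_label, "shape_mae")

  # single sinusoid: removing it entirely leaves MAE ~ mean|A sin| = 2A/pi
  A <- 2
  st2 <- make_stack(list(sine_profile(0.08, n = 4001, amplitude = A)))
  c2 <- sweep_cutoffs(st2, c(0.2, 0.01))
  expect_lt(c2$errors[1], 0.01)
  expect_equal(c2$errors[2], 2 * A / pi, tolerance = 0.05)

  c3 <- sweep_cutoffs(st2, 0.1)
  expect_length(c3$errors, 1)
})

test_that("error curves are non-increasing in the cutoff on band-limited stacks", {
  st <- make_stack(list(random_smooth_profile(7, n = 1024, y_center = 0),
                        random_smooth_profile(8, n = 1024, y_center = 10)))
  cutoffs <- c(0.2, 0.1, 0.05, 0.02, 0.01, 0.005)
  curve <- sweep_cutoffs(st, cutoffs)
  expect_true(all(diff(curve$errors) >= -1e-9))
  # per-subject errors retained with the right shape
  expect_equal(dim(curve$per_subject_errors), c(1L, length(cutoffs)))
})

test_that("find_breakpoint returns the smallest acceptable cutoff and its band", {
  curve <- error_curve(c(0.1, 0.05, 0.02), c(0.01, 0.02, 5.0), "shape_mae")
  bp <- find_breakpoint(curve, 0.5)
  expect_equal(bp$breakpoint, 0.05)
  expect_equal(bp$band, c(0.02, 0.05))

  # analytic curve e(fc) = 0.001/fc crosses tolerance 0.02 at fc = 0.05
  fcs <- seq(0.1, 0.01, by = -0.01)
  ac <- error_curve(fcs, 0.001 / fcs, "shape_mae")
  bp2 <- find_breakpoint(ac, 0.02)
  expect_equal(bp2$breakpoint, 0.05)
  expect_equal(bp2$band, c(0.04, 0.05))

  # if even the smallest error exceeds the tolerance, that is an error
  expect_error(find_breakpoint(curve, 0.001), "tolerance unreachable")

  # all errors acceptable: the lowest cutoff, degenerate band
  bp3 <- find_breakpoint(curve, 10)
  expect_equal(bp3$breakpoint, 0.02)
  expect_equal(bp3$band, c(0.02, 0.02))
})
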