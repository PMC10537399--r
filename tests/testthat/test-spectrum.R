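test_that("profile_spectrum matches a direct DFT summation oracle", {
  p <- sine_profile(0.05, n = 512, dx = 0.5)
  s <- profile_spectrum(p, detrend = "mean", window = "none")
  orc <- oracle_spectrum(p$z - mean(p$z), 0.5)
  expect_equal(s$frequencies, orc$frequencies)
  expect_equal(s$magnitudes, orc$magnitudes, tolerance = 1e-9)
  # peak near 0.05 mm^-1 with magnitude near the sinusoid amplitude
  peak <- which.max(s$magnitudes)
  binw <- 1 / (512 * 0.5)
  expect_lt(abs(s$frequencies[peak] - 0.05), binw)
  expect_equal(s$magnitudes[peak], 1, tolerance = 0.1)
})

test_that("an on-bin sinusoid recovers its amplitude exactly", {
  # 0.05 mm^-1 falls on a DFT bin when n*dx*f is an integer
  p <- sine_profile(0.05, n = 400, dx = 0.5)
  s <- profile_spectrum(p, detrend = "mean", window = "none")
  i <- which(abs(s$frequencies - 0.05) < 1e-12)
  expect_equal(s$magnitudes[i], 1, tolerance = 1e-9)
  expect_lt(max(s$magnitudes[-i]), 1e-9)
})

test_that("a constant profile has no spectral content after mean detrend", {
  p <- slice_profile(0, 0, 0.5, rep(4.2, 64))
  s <- profile_spectrum(p, detrend = "mean", window = "none")
  expect_lt(max(s$magnitudes), 1e-12)
})

test_that("masked profiles and short profiles are rejected", {
  z <- sin(seq_len(32))
  z[10] <- NA
  expect_error(profile_spectrum(slice_profile(0, 0, 1, z)), "not contiguous")
  expect_error(profile_spectrum(slice_profile(0, 0, 1, z[1:6])), "too short")
})

test_that("Parseval energy is conserved without a window", {
  for (seed in 1:5) {
    p <- random_smooth_profile(seed, n = 301, dx = 0.7)
    for (dt in c("none", "mean", "linear")) {
      s <- profile_spectrum(p, detrend = dt, window = "none")
      zd <- switch(dt,
        none = p$z,
        mean = p$z - mean(p$z),
        linear = stats::residuals(stats::lm.fit(cbind(1, profile_x(p)), p$z)))
      expect_equal(spectrum_energy(s), sum(zd^2), tolerance = 1e-9)
    }
  }
})

test_that("aggregate_spectra averages, interpolates and respects Nyquist", {
  s <- profile_spectrum(random_smooth_profile(1), detrend = "mean")
  # idempotence on identical spectra
  agg <- aggregate_spectra(list(s, s, s))
  expect_equal(agg$frequencies, s$frequencies)
  expect_equal(agg$magnitudes, s$magnitudes)

  # plain mean on a shared grid
  s3 <- spectrum_obj(s$frequencies, 3 * s$magnitudes)
  agg2 <- aggregate_spectra(list(s, s3))
  expect_equal(agg2$magnitudes, 2 * s$magnitudes)

  # mixed grids: hand-computed 5-bin example
  a <- spectrum_obj(c(0, 0.1, 0.2, 0.3, 0.4), c(1, 2, 3, 2, 1))
  b <- spectrum_obj(c(0, 0.125, 0.25), c(2, 4, 2))  # Nyquist 0.25
  agg3 <- aggregate_spectra(list(a, b), grid = a$frequencies)
  b_at <- stats::approx(b$frequencies, b$magnitudes,
                        xout = c(0, 0.1, 0.2))$y
  expect_equal(agg3$frequencies, c(0, 0.1, 0.2, 0.3, 0.4))
  expect_equal(agg3$magnitudes,
               c((c(1, 2, 3) + b_at) / 2, 2, 1))
  expect_error(aggregate_spectra(list()), "non-empty")
})

test_that("dominant_frequency follows the cumulative power contract", {
  # all power in one bin
  s <- spectrum_obj(seq(0, 0.25, by = 0.05), c(0, 1, 0, 0, 0, 0))
  expect_equal(dominant_frequency(s, 0.5), 0.05)
  expect_equal(dominant_frequency(s, 1.0), 0.05)

  # equal power at 0.02 and 0.08: cumulative-sum oracle
  f <- seq(0, 0.1, by = 0.02)
  m <- numeric(length(f)); m[f == 0.02] <- 1; m[f == 0.08] <- 1
  s2 <- spectrum_obj(f, m)
  expect_equal(dominant_frequency(s2, 0.95), 0.08)
  expect_equal(dominant_frequency(s2, 0.5), 0.02)

  expect_error(dominant_frequency(spectrum_obj(f, numeric(length(f)))),
               "zero total power")
})

test_that("band-limited profiles keep all power below the cap", {
  # on-bin components below F = 0.06: full power reached within one bin of F
  n <- 500; dx <- 0.5
  x <- (seq_len(n) - 1) * dx
  z <- 3 * sin(2 * pi * 0.02 * x) + 1 * sin(2 * pi * 0.04 * x) +
    0.5 * sin(2 * pi * 0.06 * x)
  s <- profile_spectrum(slice_profile(0, 0, dx, z), detrend = "mean")
  expect_lte(dominant_frequency(s, 1.0), 0.06 + 1 / (n * dx))
})

test_that("nyquist_sampling implements 2 * oversampling * f_max", {
  r1 <- nyquist_sampling(0.1, 1)
  expect_equal(r1$sampling_frequency, 0.2)
  expect_equal(r1$sampling_interval, 5)
  r5 <- nyquist_sampling(0.1, 5)
  expect_equal(r5$sampling_frequency, 1)
  expect_equal(r5$sampling_interval, 1)
  expect_equal(nyquist_sampling(0.5, 1)$sampling_interval, 1)
  expect_error(nyquist_sampling(-0.1, 1), "positive")
  expect_error(nyquist_sampling(0.1, 0.5), ">= 1")

  # interval strictly decreasing in both arguments
  fs <- c(0.01, 0.05, 0.1, 0.5); os <- c(1, 2, 5, 10)
  for (o in os) {
    iv <- vapply(fs, function(f) nyquist_sampling(f, o)$sampling_interval,
                 numeric(1))
    expect_true(all(diff(iv) < 0))
  }
  for (f in fs) {
    iv <- vapply(os, function(o) nyquist_sampling(f, o)$sampling_interval,
                 numeric(1))
    expect_true(all(diff(iv) < 0))
  }
})
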