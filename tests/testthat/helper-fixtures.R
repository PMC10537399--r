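# In-code fixtures shared across the suite. All profiles are built directly on
# exact uniform grids so regularization artefacts never contaminate tests that
# are not about regularization.

sine_profile <- function(freq, n = 512, dx = 0.5, amplitude = 1, phase = 0,
                         y_center = 0, x0 = 0) {
  x <- x0 + (seq_len(n) - 1) * dx
  slice_profile(y_center, x0, dx, amplitude * sin(2 * pi * freq * x + phase))
}

# smooth band-limited pseudo-random profile (fixed seed -> reproducible)
random_smooth_profile <- function(seed, n = 512, dx = 0.5, y_center = 0,
                                  freqs = c(0.004, 0.011, 0.023, 0.041),
                                  amp = 5) {
  z <- withr::with_seed(seed, {
    a <- stats::runif(length(freqs), 0, amp)
    ph <- stats::runif(length(freqs), 0, 2 * pi)
    x <- (seq_len(n) - 1) * dx
    Reduce(`+`, Map(function(ai, fi, pi_) ai * sin(2 * pi * fi * x + pi_),
                    a, freqs, ph))
  })
  slice_profile(y_center, 0, dx, z)
}

make_stack <- function(profiles, slab_thickness = 5, slab_spacing = 10,
                       source_id = "fixture") {
  slice_stack_obj(profiles, slab_thickness, slab_spacing, source_id)
}

# independent oracles -------------------------------------------------------

# direct DFT summation, one-sided amplitude normalization
oracle_spectrum <- function(z, dx) {
  n <- length(z)
  half <- floor(n / 2) + 1
  j <- seq_len(n) - 1
  mag <- vapply(seq_len(half) - 1, function(k) {
    Mod(sum(z * exp(-2i * pi * k * j / n))) / n
  }, numeric(1))
  mult <- rep(2, half)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half] <- 1
  list(frequencies = (seq_len(half) - 1) / (n * dx), magnitudes = mag * mult)
}

# brute-force double loop over slices and cells
oracle_shape_mae <- function(a, b) {
  diffs <- c()
  for (i in seq_along(a$slices)) {
    sa <- a$slices[[i]]; sb <- b$slices[[i]]
    for (k in seq_along(sa$z)) {
      if (!sa$missing[k] && !sb$missing[k])
        diffs <- c(diffs, abs(sa$z[k] - sb$z[k]))
    }
  }
  mean(diffs)
}

# exhaustive grid search for the mirror-RMS minimizer, no refinement
oracle_symmetry_point <- function(profile, half_window, search_margin) {
  z <- profile$z
  x <- profile_x(profile)
  n <- length(z)
  dx <- profile$dx
  m <- floor(half_window / dx)
  lo <- x[1] + half_window + search_margin
  hi <- x[n] - half_window - search_margin
  cand <- which(x >= lo - 1e-9 & x <= hi + 1e-9)
  cand <- cand[cand - m >= 1 & cand + m <= n]
  a <- vapply(cand, function(i)
    sqrt(mean((z[i + seq_len(m)] - z[i - seq_len(m)])^2)), numeric(1))
  x[cand[which.min(a)]]
}
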