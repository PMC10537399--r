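test_that("parameter invariants of the generator are enforced", {
  expect_error(back_model_params(base_components = list(c(1, 0.2, 0, 0)),
                                 f_max = 0.1),
               "exceed f_max")
  expect_error(back_model_params(f_max = 0.1, sample_spacing = 6),
               "Nyquist bound")
})

test_that("a symmetric noise-free back yields a centred symmetry line", {
  par <- back_model_params(width = 320, height = 200, sample_spacing = 2,
                           asymmetry_coefficients = 0, noise_amplitude = 0,
                           seed = 21)
  st <- slice_stack(generate_back(par), slab_thickness = 4, slab_spacing = 20,
                    dx = 2)
  ln <- symmetry_line(st, half_window = 60, search_margin = 10)
  expect_true(all(abs(ln$x_sym[!ln$missing] - 320 / 2) < st$dx / 2))
})

test_that("an imposed scoliotic offset curve is recovered at zero noise", {
  par <- back_model_params(width = 320, height = 240, sample_spacing = 2,
                           jitter_fraction = 0, noise_amplitude = 0,
                           asymmetry_coefficients = c(5, 8, 10),
                           bump_components = list(), seed = 3)
  st <- slice_stack(generate_back(par), slab_thickness = 4, slab_spacing = 20,
                    dx = 2)
  ln <- symmetry_line(st, half_window = 60, search_margin = 10)
  truth <- true_symmetry_curve(par, ln$y_centers)
  expect_true(all(abs(ln$x_sym - truth) < st$dx))
})

test_that("a single-component back is spectrally band-limited at its frequency", {
  # width chosen so 0.05 mm^-1 falls exactly on a DFT bin of the slice grid
  par <- back_model_params(width = 398, height = 80,
                           base_components = list(c(5, 0.05, 0, 0)),
                           asymmetry_coefficients = 0,
                           bump_components = list(),
                           f_max = 0.05, sample_spacing = 2,
                           jitter_fraction = 0, noise_amplitude = 0, seed = 4)
  st <- slice_stack(generate_back(par), slab_thickness = 4, slab_spacing = 20,
                    dx = 2)
  s <- profile_spectrum(st$slices[[1]], detrend = "mean")
  binw <- 1 / (s$n_samples * s$dx)
  expect_lte(dominant_frequency(s, 1.0), 0.05 + binw)
  expect_equal(dominant_frequency(s, 0.5), 0.05)
})

test_that("generation is deterministic under a fixed seed", {
  par <- back_model_params(width = 100, height = 100, seed = 99,
                           noise_amplitude = 0.2)
  a <- generate_back(par)
  b <- generate_back(par)
  expect_identical(a$points, b$points)
  c2 <- generate_back(back_model_params(width = 100, height = 100, seed = 100,
                                        noise_amplitude = 0.2))
  expect_false(identical(a$points, c2$points))
})

test_that("generate_cohort draws from ranges and writes a manifest", {
  ch <- generate_cohort(5, list(amplitude_scale = c(0.8, 1.2),
                                asymmetry_quadratic = c(0, 10)),
                        seed = 6,
                        base_params = back_model_params(width = 120,
                                                        height = 120))
  expect_length(ch$clouds, 5)
  expect_equal(nrow(ch$manifest), 5)
  expect_true(all(c("amplitude_scale", "asymmetry_quadratic") %in%
                    names(ch$manifest)))
  expect_true(all(ch$manifest$amplitude_scale >= 0.8 &
                    ch$manifest$amplitude_scale <= 1.2))

  # degenerate ranges: identical parameters, clouds differ only by seed
  chd <- generate_cohort(3, list(amplitude_scale = c(1, 1)), seed = 6,
                         base_params = back_model_params(width = 120,
                                                         height = 120))
  expect_equal(unique(chd$manifest$amplitude_scale), 1)
  expect_false(identical(chd$clouds[[1]]$points, chd$clouds[[2]]$points))

  expect_error(generate_cohort(2, list(nope = c(0, 1))), "unknown cohort")
  expect_error(generate_cohort(2, list(f_max = c(1, 0))), "invalid range")
})

test_that("degradations above a cohort's content band are harmless", {
  base <- back_model_params(
    width = 398, height = 120,
    base_components = list(c(6, 0.01, 0, 0), c(2, 0.02, 0.002, 0.4),
                           c(0.8, 0.05, 0, 1.1)),
    asymmetry_coefficients = 0, bump_components = list(),
    f_max = 0.05, sample_spacing = 2, jitter_fraction = 0,
    noise_amplitude = 0)
  ch <- generate_cohort(3, list(amplitude_scale = c(0.9, 1.1)), seed = 8,
                        base_params = base)
  stacks <- lapply(ch$clouds, slice_stack, slab_thickness = 4,
                   slab_spacing = 20, dx = 2)
  curve <- sweep_cutoffs(stacks, c(0.1, 0.05, 0.02, 0.01))
  bp <- find_breakpoint(curve, 0.2)
  # the breakpoint cannot fall below half the content cap
  expect_gte(bp$breakpoint, 0.05 / 2)
})
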