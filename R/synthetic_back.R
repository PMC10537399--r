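#' Parameters of the synthetic back-surface generator
#'
#' The generator emulates the surface class the analysis targets: a smooth,
#' band-limited torso-like depth field about 450 mm wide and 520 mm tall whose
#' spatial frequency content lies below roughly 0.1 mm^-1. The depth is a sum
#' of separable sinusoidal components, each even in `x - s(y)` where `s(y)` is
#' a polynomial lateral symmetry-axis curve (a scoliotic back has `s(y)` bent;
#' a healthy one has `s(y)` near 0), plus optional mirrored Gaussian bumps
#' (scapulae, paraspinal prominence) and seeded uniform sensor noise. Sampling
#' happens on a grid with optional lateral jitter, so slice regularization is
#' genuinely exercised. The true `s(y)` and the frequency cap are recorded in
#' the cloud metadata, making each synthetic cloud its own oracle for
#' parameter-recovery tests.
#'
#' @param width,height lateral and vertical extent (mm); defaults 454 and 516,
#'   matching the anthropometric region of interest used by the resolution
#'   module.
#' @param base_components list of `c(amplitude, fx, fy, phase)` rows:
#'   amplitude (mm), lateral frequency (1/mm), vertical frequency (1/mm),
#'   vertical phase (rad). Each contributes
#'   `A * cos(2*pi*fx*(x - s(y))) * cos(2*pi*fy*y + phase)`. Defaults place
#'   nearly all power well below 0.1 mm^-1, from the broad torso roundness
#'   down to faint fine structure near 0.08 mm^-1.
#' @param asymmetry_coefficients polynomial coefficients (mm) of `s(t)` in the
#'   normalized vertical coordinate `t = (y - height/2) / (height/2)`,
#'   constant term first; default `0` (symmetric back).
#' @param bump_components optional list of bumps, each a list with
#'   `amplitude` (mm), `x_center` (mm, lateral offset from the symmetry axis;
#'   mirrored to both sides), `y_center` (mm), `x_sigma`, `y_sigma` (mm).
#' @param f_max cap (1/mm) on all sinusoidal component frequencies; default
#'   0.1.
#' @param sample_spacing grid spacing of generated points (mm); must satisfy
#'   the generator's own Nyquist bound `<= 1/(2*f_max)`; default 2.
#' @param jitter_fraction lateral/vertical sampling jitter as a fraction of
#'   `sample_spacing` (at most 0.2 is sensible); default 0.2.
#' @param noise_amplitude half-width of uniform depth noise (mm); default 0.
#' @param seed integer seed.
#' @return An object of class `BackModelParams`.
#' @export
back_model_params <- function(width = 454, height = 516,
                              base_components = default_base_components(),
                              asymmetry_coefficients = 0,
                              bump_components = default_bump_components(height),
                              f_max = 0.1, sample_spacing = 2,
                              jitter_fraction = 0.2, noise_amplitude = 0,
                              seed = 1L) {
  check_pos(width, "width"); check_pos(height, "height")
  check_pos(f_max, "f_max"); check_pos(sample_spacing, "sample_spacing")
  stopifnot(jitter_fraction >= 0, jitter_fraction <= 0.5,
            noise_amplitude >= 0)
  comp <- do.call(rbind, lapply(base_components, function(c4) {
    stopifnot(length(c4) == 4)
    as.numeric(c4)
  }))
  colnames(comp) <- c("amplitude", "fx", "fy", "phase")
  if (any(comp[, "fx"] > f_max + 1e-12) || any(comp[, "fy"] > f_max + 1e-12))
    stop("component frequencies must not exceed f_max")
  if (sample_spacing > 1 / (2 * f_max) + 1e-12)
    stop("sample_spacing violates the generator's own Nyquist bound 1/(2*f_max)")
  structure(
    list(width = width, height = height, base_components = comp,
         asymmetry_coefficients = as.numeric(asymmetry_coefficients),
         bump_components = bump_components, f_max = f_max,
         sample_spacing = sample_spacing, jitter_fraction = jitter_fraction,
         noise_amplitude = noise_amplitude, seed = as.integer(seed)),
    class = "BackModelParams")
}

#' Default band-limited component set of the synthetic back
#'
#' Amplitudes decay with frequency the way the spectra of real back captures
#' do: tens of millimetres of broad torso roundness, a few millimetres of
#' mid-band musculature, and sub-millimetre fine structure approaching the
#' 0.1 mm^-1 cap.
#' @return List of `c(amplitude, fx, fy, phase)` rows.
#' @export
default_base_components <- function() {
  list(c(40, 0.0011, 0.0005, 0.0),
       c(8, 0.005, 0.001, 0.3),
       c(3, 0.010, 0.002, 1.0),
       c(1.5, 0.020, 0.004, 0.7),
       c(0.6, 0.050, 0.008, 0.2),
       c(0.2, 0.080, 0.010, 1.5))
}

#' Default mirrored bump pair (scapulae)
#' @param height back height (mm); the bumps sit at 68% of it.
#' @return List with one bump description (mirrored about the symmetry axis).
#' @export
default_bump_components <- function(height = 516) {
  list(list(amplitude = 8, x_center = 90, y_center = 0.68 * height,
            x_sigma = 45, y_sigma = 55))
}

#' True symmetry-axis curve of a synthetic back
#'
#' Evaluates the polynomial `s(y)` baked into the generator parameters, in mm
#' lateral offset from the back's midline (x = width/2).
#'
#' @param params a `BackModelParams`.
#' @param y vertical positions (mm).
#' @return Lateral symmetry-axis positions (mm, absolute x).
#' @export
true_symmetry_curve <- function(params, y) {
  stopifnot(inherits(params, "BackModelParams"))
  t <- (y - params$height / 2) / (params$height / 2)
  s <- 0
  for (k in seq_along(params$asymmetry_coefficients))
    s <- s + params$asymmetry_coefficients[k] * t^(k - 1)
  params$width / 2 + s
}

eval_back_depth <- function(params, x, y) {
  sx <- true_symmetry_curve(params, y)
  z <- 0
  comp <- params$base_components
  for (i in seq_len(nrow(comp))) {
    z <- z + comp[i, "amplitude"] *
      cos(2 * pi * comp[i, "fx"] * (x - sx)) *
      cos(2 * pi * comp[i, "fy"] * y + comp[i, "phase"])
  }
  for (b in params$bump_components) {
    g_y <- exp(-(y - b$y_center)^2 / (2 * b$y_sigma^2))
    z <- z + b$amplitude * g_y *
      (exp(-(x - sx - b$x_center)^2 / (2 * b$x_sigma^2)) +
       exp(-(x - sx + b$x_center)^2 / (2 * b$x_sigma^2)))
  }
  z
}

#' Generate a synthetic back point cloud
#'
#' Samples the parameterized depth field on a (optionally jittered) grid and
#' adds seeded uniform noise. The returned cloud's metadata carries the full
#' parameter set, so downstream analyses can be checked against the known
#' ground truth.
#'
#' @param params a [back_model_params()] object.
#' @return A `PointCloud` whose `metadata` holds `params`.
#' @export
generate_back <- function(params = back_model_params()) {
  stopifnot(inherits(params, "BackModelParams"))
  withr::with_seed(params$seed, {
    xs <- seq(0, params$width, by = params$sample_spacing)
    ys <- seq(0, params$height, by = params$sample_spacing)
    g <- expand.grid(x = xs, y = ys)
    j <- params$jitter_fraction * params$sample_spacing
    if (j > 0) {
      g$x <- g$x + stats::runif(nrow(g), -j, j)
      g$y <- g$y + stats::runif(nrow(g), -j, j)
    }
    z <- eval_back_depth(params, g$x, g$y)
    if (params$noise_amplitude > 0)
      z <- z + stats::runif(nrow(g), -params$noise_amplitude,
                            params$noise_amplitude)
    point_cloud(cbind(g$x, g$y, z),
                source_id = sprintf("synthetic-back-seed%d", params$seed),
                metadata = list(params = params))
  })
}

#' Generate a cohort of synthetic backs
#'
#' Draws per-subject parameters uniformly from the given ranges and generates
#' one cloud per subject, each with its own derived seed. Recognized range
#' names: any scalar numeric field of [back_model_params()] (e.g.
#' `noise_amplitude`, `f_max`, `width`), plus `amplitude_scale` (multiplies
#' all base component amplitudes), `asymmetry_linear` and
#' `asymmetry_quadratic` (set the linear/quadratic coefficients of `s(y)`,
#' in mm at the back's vertical ends). A manifest of the drawn true
#' parameters accompanies the clouds.
#'
#' @param n number of subjects (>= 1).
#' @param params_ranges named list of `c(min, max)` ranges; empty ranges list
#'   reproduces the default back n times (differing only by seed).
#' @param seed cohort seed.
#' @param base_params template [back_model_params()].
#' @return List with `clouds` (list of `PointCloud`) and `manifest`
#'   (data.frame of the drawn parameters, one row per subject).
#' @export
generate_cohort <- function(n, params_ranges = list(), seed = 1L,
                            base_params = back_model_params()) {
  stopifnot(n >= 1)
  for (nm in names(params_ranges)) {
    r <- params_ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2 || r[1] > r[2])
      stop(sprintf("invalid range for '%s': need c(min, max)", nm))
  }
  special <- c("amplitude_scale", "asymmetry_linear", "asymmetry_quadratic")
  scalar_fields <- c("width", "height", "f_max", "sample_spacing",
                     "jitter_fraction", "noise_amplitude")
  bad <- setdiff(names(params_ranges), c(special, scalar_fields))
  if (length(bad) > 0)
    stop(sprintf("unknown cohort parameter(s): %s", paste(bad, collapse = ", ")))
  draws <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n), function(i)
      vapply(params_ranges, function(r) stats::runif(1, r[1], r[2]),
             numeric(1)))
  })
  clouds <- vector("list", n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draws[[i]]
    p <- base_params
    for (nm in intersect(names(d), scalar_fields)) p[[nm]] <- d[[nm]]
    if ("amplitude_scale" %in% names(d))
      p$base_components[, "amplitude"] <-
        p$base_components[, "amplitude"] * d[["amplitude_scale"]]
    coefs <- p$asymmetry_coefficients
    if ("asymmetry_linear" %in% names(d)) {
      coefs <- c(coefs, numeric(max(0, 2 - length(coefs))))
      coefs[2] <- d[["asymmetry_linear"]]
    }
    if ("asymmetry_quadratic" %in% names(d)) {
      coefs <- c(coefs, numeric(max(0, 3 - length(coefs))))
      coefs[3] <- d[["asymmetry_quadratic"]]
    }
    p$asymmetry_coefficients <- coefs
    p$seed <- as.integer(seed) + i
    class(p) <- "BackModelParams"
    clouds[[i]] <- generate_back(p)
    rows[[i]] <- data.frame(subject = i, seed = p$seed,
                            t(if (length(d)) d else numeric(0)))
  }
  manifest <- do.call(rbind, rows)
  list(clouds = clouds, manifest = manifest)
}
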