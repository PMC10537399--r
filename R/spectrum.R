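#' Construct a one-sided magnitude spectrum
#'
#' Frequencies run from 0 to the grid Nyquist `1/(2*dx)` in uniform steps of
#' `1/(n_samples*dx)`. Magnitudes follow the one-sided amplitude convention: a
#' pure sinusoid of amplitude A (mm) appears as a peak of magnitude A (mm).
#'
#' @param frequencies spatial frequencies (1/mm), ascending and uniform.
#' @param magnitudes non-negative amplitudes (mm).
#' @param n_samples length of the source series (NA for aggregated spectra).
#' @param dx source grid step (mm; NA for aggregated spectra).
#' @return An object of class `Spectrum`.
#' @export
spectrum_obj <- function(frequencies, magnitudes, n_samples = NA_integer_,
                         dx = NA_real_) {
  stopifnot(length(frequencies) == length(magnitudes))
  if (any(magnitudes < 0)) stop("magnitudes must be non-negative")
  if (length(frequencies) > 2) {
    steps <- diff(frequencies)
    if (max(abs(steps - steps[1])) > 1e-9 * max(steps))
      stop("frequency grid must be uniform")
  }
  structure(
    list(frequencies = as.numeric(frequencies),
         magnitudes = as.numeric(magnitudes),
         n_samples = as.integer(n_samples), dx = as.numeric(dx)),
    class = "Spectrum")
}

#' @export
print.Spectrum <- function(x, ...) {
  cat(sprintf("Spectrum: %d bins, f in [0, %.4g] mm^-1, bin width %.4g mm^-1\n",
              length(x$frequencies), max(x$frequencies),
              if (length(x$frequencies) > 1) diff(x$frequencies[1:2]) else NA))
  invisible(x)
}

#' Spatial magnitude spectrum of a slice profile
#'
#' Computes the one-sided amplitude spectrum of the depth series z = f(x) of a
#' gap-free slice. The series may first be detrended (subtract the mean, or the
#' least-squares line, which suppresses the torso's overall lateral tilt that
#' would otherwise dominate the lowest bins) and optionally Hann-windowed.
#' Window loss is compensated so that an on-bin sinusoid of amplitude A keeps
#' peak magnitude approximately A.
#'
#' @param profile gap-free `SliceProfile` with at least 8 samples.
#' @param detrend `"linear"` (default), `"mean"` or `"none"`.
#' @param window `"none"` (default) or `"hann"`.
#' @return A `Spectrum`.
#' @export
profile_spectrum <- function(profile, detrend = c("linear", "mean", "none"),
                             window = c("none", "hann")) {
  stopifnot(inherits(profile, "SliceProfile"))
  detrend <- match.arg(detrend)
  window <- match.arg(window)
  if (!is_contiguous(profile)) stop("profile not contiguous")
  z <- profile$z
  n <- length(z)
  if (n < 8) stop("profile too short for spectral analysis (need >= 8 samples)")
  x <- profile_x(profile)
  z <- switch(detrend,
    none = z,
    mean = z - mean(z),
    linear = stats::residuals(stats::lm.fit(cbind(1, x), z)))
  w <- switch(window,
    none = rep(1, n),
    hann = 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1)))
  Z <- stats::fft(z * w)
  half <- floor(n / 2) + 1
  mag <- Mod(Z[seq_len(half)]) / sum(w)
  mult <- rep(2, half)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half] <- 1
  spectrum_obj((seq_len(half) - 1) / (n * profile$dx), mag * mult,
               n_samples = n, dx = profile$dx)
}

#' Signal energy implied by a spectrum
#'
#' Under the one-sided amplitude convention, Parseval's identity gives
#' `sum(z^2) = n * sum(mag^2 / mult)` where `mult` is 2 for the doubled
#' interior bins and 1 for the DC (and, for even n, Nyquist) bin. Used to
#' check energy conservation of [profile_spectrum()] with `window = "none"`.
#'
#' @param spectrum a `Spectrum` produced by [profile_spectrum()].
#' @return Energy (mm^2 summed over samples) of the detrended series.
#' @export
spectrum_energy <- function(spectrum) {
  n <- spectrum$n_samples
  if (is.na(n)) stop("spectrum_energy requires an unaggregated profile spectrum")
  half <- length(spectrum$magnitudes)
  mult <- rep(2, half)
  mult[1] <- 1
  if (n %% 2 == 0) mult[half] <- 1
  n * sum(spectrum$magnitudes^2 / mult)
}

#' Average several spectra onto a common frequency grid
#'
#' Each spectrum is linearly interpolated onto the target grid; bins beyond a
#' spectrum's own Nyquist do not receive a value from it. Bins are averaged
#' over the spectra that contribute there, so cohorts recorded at different
#' lateral grid steps can be pooled. Magnitudes (not complex spectra) are
#' averaged: phase is subject-specific and carries no shape-band information.
#'
#' @param spectra non-empty list of `Spectrum` objects.
#' @param grid target frequency grid (1/mm); defaults to the grid of the
#'   spectrum with the finest frequency step.
#' @return A `Spectrum` on the bins of `grid` that received at least one
#'   contribution.
#' @export
aggregate_spectra <- function(spectra, grid = NULL) {
  if (length(spectra) == 0) stop("aggregate_spectra requires a non-empty list")
  stopifnot(all(vapply(spectra, inherits, logical(1), "Spectrum")))
  if (is.null(grid)) {
    steps <- vapply(spectra, function(s) diff(s$frequencies[1:2]), numeric(1))
    grid <- spectra[[which.min(steps)]]$frequencies
  }
  acc <- matrix(NA_real_, nrow = length(spectra), ncol = length(grid))
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    acc[i, ] <- stats::approx(s$frequencies, s$magnitudes, xout = grid,
                              rule = 1)$y
  }
  m <- colMeans(acc, na.rm = TRUE)
  keep <- !is.nan(m)
  if (!any(keep)) stop("no frequency bin receives any contribution")
  spectrum_obj(grid[keep], m[keep])
}

#' Highest frequency carrying a given fraction of the spectral power
#'
#' Returns the smallest grid frequency f such that the cumulative power
#' (sum of squared magnitudes, excluding the 0-frequency bin) up to f reaches
#' `power_fraction` of the total. With the default fraction this locates the
#' band that carries essentially all of the back-shape content; on ground-truth
#' back captures that band ends near 0.1 mm^-1.
#'
#' @param spectrum a `Spectrum` with positive total power.
#' @param power_fraction fraction in (0, 1]; default 0.95.
#' @return Frequency in 1/mm.
#' @export
dominant_frequency <- function(spectrum, power_fraction = 0.95) {
  stopifnot(inherits(spectrum, "Spectrum"),
            power_fraction > 0, power_fraction <= 1)
  f <- spectrum$frequencies[-1]
  p <- spectrum$magnitudes[-1]^2
  total <- sum(p)
  if (total <= 0) stop("spectrum has zero total power")
  cum <- cumsum(p)
  # small relative slack keeps power_fraction = 1 meaningful in floating point
  idx <- which(cum >= power_fraction * total * (1 - 1e-9))[1]
  f[idx]
}

#' Translate a maximal signal frequency into a sampling requirement
#'
#' By the Nyquist theorem a spatial sampling frequency of twice the maximal
#' frequency contained in the surface suffices for a perfect signal; real
#' optical captures are noisy, so a practical oversampling factor (commonly 5)
#' multiplies it. `sampling_frequency = 2 * oversampling * f_max` and
#' `sampling_interval` is its reciprocal.
#'
#' @param f_max highest spatial frequency of interest (1/mm, > 0).
#' @param oversampling dimensionless factor >= 1; default 5.
#' @return An object of class `SamplingRequirement` with fields `f_max`,
#'   `oversampling`, `sampling_frequency` (1/mm), `sampling_interval` (mm).
#' @export
nyquist_sampling <- function(f_max, oversampling = 5) {
  check_pos(f_max, "f_max")
  if (!is.numeric(oversampling) || length(oversampling) != 1 || oversampling < 1)
    stop("'oversampling' must be a single number >= 1")
  sf <- 2 * oversampling * f_max
  structure(
    list(f_max = f_max, oversampling = oversampling,
         sampling_frequency = sf, sampling_interval = 1 / sf),
    class = "SamplingRequirement")
}

#' @export
print.SamplingRequirement <- function(x, ...) {
  cat(sprintf(
    "SamplingRequirement: f_max %.4g mm^-1, oversampling %gx -> sample every %.4g mm (%.4g mm^-1)\n",
    x$f_max, x$oversampling, x$sampling_interval, x$sampling_frequency))
  invisible(x)
}

#' Export a spectrum as CSV
#'
#' Columns: `frequency_mm^-1`, `magnitude_mm`.
#' @param spectrum a `Spectrum`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  df <- data.frame(frequency = spectrum$frequencies,
                   magnitude = spectrum$magnitudes)
  names(df) <- c("frequency_mm^-1", "magnitude_mm")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
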