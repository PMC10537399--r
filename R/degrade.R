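#' Parameters of the shape-quality degradation operators
#'
#' Bundles the knobs of the five degradation operators: Butterworth low-pass
#' order, random-downsampling keep fraction, depth quantization step, uniform
#' noise half-width, sinusoidal noise amplitude/frequency/phase, and the RNG
#' seed that makes the stochastic operators reproducible.
#'
#' @param butterworth_order filter order (integer >= 1); default 4.
#' @param keep_fraction fraction of samples kept by random downsampling (0,1].
#' @param depth_step depth quantization step (mm >= 0; 0 = no quantization).
#' @param noise_amplitude half-width of zero-mean uniform noise (mm >= 0).
#' @param sine_amplitude,sine_frequency,sine_phase sinusoidal noise amplitude
#'   (mm), spatial frequency (1/mm) and phase (rad).
#' @param seed integer seed for the stochastic operators.
#' @return An object of class `DegradeParams`.
#' @export
degrade_params <- function(butterworth_order = 4, keep_fraction = 1,
                           depth_step = 0, noise_amplitude = 0,
                           sine_amplitude = 0, sine_frequency = 0,
                           sine_phase = 0, seed = 1L) {
  stopifnot(butterworth_order >= 1, butterworth_order == round(butterworth_order),
            keep_fraction > 0, keep_fraction <= 1,
            depth_step >= 0, noise_amplitude >= 0, sine_amplitude >= 0)
  structure(
    list(butterworth_order = as.integer(butterworth_order),
         keep_fraction = keep_fraction, depth_step = depth_step,
         noise_amplitude = noise_amplitude, sine_amplitude = sine_amplitude,
         sine_frequency = sine_frequency, sine_phase = sine_phase,
         seed = as.integer(seed)),
    class = "DegradeParams")
}

#' Zero-phase Butterworth low-pass of a slice profile
#'
#' Applies a Butterworth low-pass of the stated order forward and backward
#' along x (zero phase; the squared magnitude response
#' `(1 + (f/fc)^(2*order))^-1` acts twice). Edges are handled by odd-reflection
#' padding of length `3 * order * 2`; the line through the end samples is
#' removed before filtering and restored afterwards, which keeps the DC level
#' and overall tilt exactly and suppresses start-up transients at low cutoffs.
#' Grid and mask are unchanged.
#'
#' @param profile gap-free `SliceProfile`.
#' @param fc cutoff frequency (1/mm), strictly below the grid Nyquist
#'   `1/(2*dx)`.
#' @param order filter order; default 4.
#' @return The filtered `SliceProfile`.
#' @export
lowpass_profile <- function(profile, fc, order = 4) {
  stopifnot(inherits(profile, "SliceProfile"))
  check_pos(fc, "fc")
  if (!is_contiguous(profile)) stop("profile not contiguous")
  fnyq <- 1 / (2 * profile$dx)
  if (fc >= fnyq) stop("cutoff above grid Nyquist")
  z <- profile$z
  n <- length(z)
  # endpoint line: exactly preserved by an ideal unity-DC low-pass
  trend <- z[1] + (z[n] - z[1]) * (seq_len(n) - 1) / (n - 1)
  r <- z - trend
  np <- min(3L * as.integer(order) * 2L, n - 1L)
  front <- 2 * r[1] - r[seq(np + 1, 2)]
  back <- 2 * r[n] - r[seq(n - 1, n - np)]
  rp <- c(front, r, back)
  bf <- signal::butter(order, fc / fnyq)
  y <- as.numeric(signal::filter(bf, rp))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  out <- profile
  out$z <- y[seq(np + 1, np + n)] + trend
  out
}

#' Low-pass an entire slice stack
#'
#' [lowpass_profile()] applied slice-wise; slicing the surface into z = f(x)
#' profiles makes the degradation one-dimensional along x.
#'
#' @param stack a `SliceStack` of gap-free slices.
#' @param fc cutoff frequency (1/mm).
#' @param order filter order; default 4.
#' @return The filtered `SliceStack`.
#' @export
lowpass_stack <- function(stack, fc, order = 4) {
  stopifnot(inherits(stack, "SliceStack"))
  out <- stack
  out$slices <- lapply(stack$slices, lowpass_profile, fc = fc, order = order)
  out
}

#' Random downsampling of a slice profile
#'
#' Keeps exactly `round(keep_fraction * n)` of the usable samples, drawn
#' without replacement; removed positions become missing. Deterministic for a
#' fixed seed.
#'
#' @param profile gap-free `SliceProfile`.
#' @param keep_fraction fraction in (0, 1].
#' @param seed integer seed.
#' @return The downsampled `SliceProfile` (same grid, new mask).
#' @export
downsample_random <- function(profile, keep_fraction, seed = 1L) {
  stopifnot(inherits(profile, "SliceProfile"),
            keep_fraction > 0, keep_fraction <= 1)
  if (!is_contiguous(profile)) stop("profile not contiguous")
  n <- length(profile$z)
  m <- round(keep_fraction * n)
  if (m < 2) stop("fewer than 2 samples would survive downsampling")
  keep <- withr::with_seed(as.integer(seed), sort(sample.int(n, m)))
  out <- profile
  drop <- setdiff(seq_len(n), keep)
  out$z[drop] <- NA_real_
  out$missing[drop] <- TRUE
  out
}

#' Quantize the depth values of a slice profile
#'
#' Emulates limited depth (z-axis) resolution by rounding each depth to the
#' nearest multiple of `step`. `step = 0` is the identity. The induced error
#' is bounded by `step / 2` per sample.
#'
#' @param profile a `SliceProfile`.
#' @param step quantization step (mm >= 0).
#' @return The quantized `SliceProfile`.
#' @export
quantize_depth <- function(profile, step) {
  stopifnot(inherits(profile, "SliceProfile"))
  if (!is.numeric(step) || length(step) != 1 || step < 0)
    stop("'step' must be a single non-negative number")
  if (step == 0) return(profile)
  out <- profile
  out$z <- step * round(profile$z / step)
  out
}

#' Add uniform or sinusoidal spatial noise to a slice profile
#'
#' `kind = "uniform"` adds i.i.d. zero-mean uniform noise of half-width
#' `params$noise_amplitude` (seeded); `kind = "sinusoidal"` adds
#' `A * sin(2*pi*f*x + phase)` evaluated on the grid abscissae, emulating
#' periodic reconstruction artefacts of pattern-projecting scanners.
#'
#' @param profile gap-free `SliceProfile`.
#' @param kind `"uniform"` or `"sinusoidal"`.
#' @param params a [degrade_params()] object.
#' @return The noisy `SliceProfile`.
#' @export
add_noise <- function(profile, kind = c("uniform", "sinusoidal"),
                      params = degrade_params()) {
  stopifnot(inherits(profile, "SliceProfile"), inherits(params, "DegradeParams"))
  kind <- match.arg(kind)
  if (!is_contiguous(profile)) stop("profile not contiguous")
  out <- profile
  n <- length(profile$z)
  if (kind == "uniform") {
    a <- params$noise_amplitude
    if (a > 0)
      out$z <- profile$z +
        withr::with_seed(params$seed, stats::runif(n, -a, a))
  } else {
    x <- profile_x(profile)
    out$z <- profile$z + params$sine_amplitude *
      sin(2 * pi * params$sine_frequency * x + params$sine_phase)
  }
  out
}

check_aligned_stacks <- function(a, b) {
  if (length(a$slices) != length(b$slices))
    stop("stacks not aligned: different slice counts")
  ya <- vapply(a$slices, `[[`, numeric(1), "y_center")
  yb <- vapply(b$slices, `[[`, numeric(1), "y_center")
  if (max(abs(ya - yb)) > 1e-9) stop("stacks not aligned: y_centers differ")
  if (abs(a$dx - b$dx) > 1e-12) stop("stacks not aligned: dx differs")
  for (i in seq_along(a$slices)) {
    sa <- a$slices[[i]]; sb <- b$slices[[i]]
    if (length(sa$z) != length(sb$z) || abs(sa$x0 - sb$x0) > 1e-9)
      stop("stacks not aligned: slice grids differ")
  }
  invisible(TRUE)
}

#' Mean absolute depth error between two aligned slice stacks
#'
#' The shape error metric: the mean of `|z_a - z_b|` pooled over all jointly
#' non-missing grid cells of all slices. Both stacks must share slice
#' y_centers and per-slice grids (degradations in this package never move the
#' grid; inputs that do must be re-regularized first).
#'
#' @param a,b aligned `SliceStack`s.
#' @return MAE in mm.
#' @export
shape_mae <- function(a, b) {
  stopifnot(inherits(a, "SliceStack"), inherits(b, "SliceStack"))
  check_aligned_stacks(a, b)
  total <- 0; count <- 0L
  for (i in seq_along(a$slices)) {
    sa <- a$slices[[i]]; sb <- b$slices[[i]]
    ok <- !sa$missing & !sb$missing
    total <- total + sum(abs(sa$z[ok] - sb$z[ok]))
    count <- count + sum(ok)
  }
  if (count == 0) stop("no overlapping non-missing cells")
  total / count
}

#' Construct an error curve
#'
#' @param cutoffs descending cutoff frequencies (1/mm).
#' @param errors MAE values (mm), one per cutoff.
#' @param metric_label `"shape_mae"` or `"symmetry_mae"`.
#' @param per_subject_errors optional subject-by-cutoff matrix of individual
#'   errors, kept for uncertainty reporting.
#' @return An object of class `ErrorCurve`.
#' @export
error_curve <- function(cutoffs, errors,
                        metric_label = c("shape_mae", "symmetry_mae"),
                        per_subject_errors = NULL) {
  metric_label <- match.arg(metric_label)
  stopifnot(length(cutoffs) == length(errors), all(errors >= 0))
  structure(
    list(cutoffs = as.numeric(cutoffs), errors = as.numeric(errors),
         metric_label = metric_label,
         per_subject_errors = per_subject_errors),
    class = "ErrorCurve")
}

#' @export
print.ErrorCurve <- function(x, ...) {
  cat(sprintf("ErrorCurve (%s):\n", x$metric_label))
  for (i in seq_along(x$cutoffs))
    cat(sprintf("  fc = %.4g mm^-1 -> MAE = %.4g mm\n",
                x$cutoffs[i], x$errors[i]))
  invisible(x)
}

#' @export
as.data.frame.ErrorCurve <- function(x, ...) {
  data.frame(cutoff = x$cutoffs, mae = x$errors)
}

#' Export an error curve as CSV
#' @param curve an `ErrorCurve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_error_curve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  names(df) <- c("cutoff_mm^-1", sprintf("%s_mm", curve$metric_label))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Low-pass cutoff sweep of the shape error
#'
#' For each cutoff (scanned from high to low), every stack is filtered
#' slice-wise and its MAE against its own unfiltered self is computed; the
#' curve error at that cutoff is the unweighted mean over stacks (subjects),
#' with per-subject values retained. Lowering the cutoff removes ever more
#' shape content, so the curve rises slowly at first and then rapidly once the
#' cutoff cuts into the band that carries the back shape.
#'
#' @param stacks a `SliceStack` or list of them.
#' @param cutoffs strictly descending cutoffs (1/mm), all below the grid
#'   Nyquist.
#' @param order Butterworth order; default 4.
#' @return An `ErrorCurve` with `metric_label = "shape_mae"`.
#' @export
sweep_cutoffs <- function(stacks, cutoffs, order = 4) {
  if (inherits(stacks, "SliceStack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1, length(cutoffs) >= 1)
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly descending")
  per <- matrix(NA_real_, nrow = length(stacks), ncol = length(cutoffs))
  for (j in seq_along(cutoffs)) {
    for (i in seq_along(stacks)) {
      filtered <- lowpass_stack(stacks[[i]], cutoffs[j], order = order)
      per[i, j] <- shape_mae(filtered, stacks[[i]])
    }
  }
  error_curve(cutoffs, colMeans(per), "shape_mae", per_subject_errors = per)
}

#' Slope break-point of an error curve
#'
#' The minimal usable cutoff given a user-chosen error tolerance: the smallest
#' scanned cutoff whose error is still within the tolerance. Because the curve
#' is evaluated on a discrete cutoff grid, the true crossing lies between the
#' returned cutoff and the next lower scanned cutoff; that bracketing pair is
#' reported as `band`. When the returned cutoff is the lowest one scanned, the
#' band degenerates to that cutoff.
#'
#' @param curve an `ErrorCurve`.
#' @param tolerance acceptable error (mm, > 0).
#' @return A list of class `Breakpoint` with `breakpoint` (1/mm), `band`
#'   (ascending pair of 1/mm), `tolerance` and `error_at_breakpoint`.
#' @export
find_breakpoint <- function(curve, tolerance) {
  stopifnot(inherits(curve, "ErrorCurve"))
  check_pos(tolerance, "tolerance")
  ok <- curve$errors <= tolerance
  if (!any(ok)) stop("tolerance unreachable in scanned range")
  # cutoffs are descending: the last acceptable entry is the smallest cutoff
  idx <- max(which(ok))
  fc <- curve$cutoffs[idx]
  band <- if (idx < length(curve$cutoffs)) c(curve$cutoffs[idx + 1], fc)
          else c(fc, fc)
  structure(
    list(breakpoint = fc, band = band, tolerance = tolerance,
         error_at_breakpoint = curve$errors[idx]),
    class = "Breakpoint")
}

#' @export
print.Breakpoint <- function(x, ...) {
  cat(sprintf(
    "Breakpoint: fc = %.4g mm^-1 (error %.4g mm <= tolerance %.4g mm), band (%.4g, %.4g) mm^-1\n",
    x$breakpoint, x$error_at_breakpoint, x$tolerance, x$band[1], x$band[2]))
  invisible(x)
}
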