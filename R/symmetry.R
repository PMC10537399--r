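#' Lateral symmetry point of a slice profile
#'
#' Finds the lateral position s* that minimizes the mirror asymmetry of the
#' depth profile: by default the root-mean-square difference between the depth
#' values at s+u and s-u over lags u in (0, half_window]. The vertical
#' connection of these per-slice points forms the back symmetry line, which
#' ideally overlies the spinous processes. Candidates are the grid positions
#' for which the full mirror window stays inside the data, shrunk on both
#' sides by `search_margin`; the discrete minimizer is refined to sub-grid
#' precision by a parabola fitted to the squared functional (locally quadratic
#' around a perfect symmetry axis). Ties are broken toward the profile's
#' lateral midpoint.
#'
#' @param profile gap-free `SliceProfile`.
#' @param half_window mirror half-width (mm); default 100.
#' @param search_margin extra shrinkage of the candidate range (mm); default 20.
#' @param functional optional replacement asymmetry functional
#'   `function(z_plus, z_minus) -> scalar` (e.g. a curvature-based variant);
#'   the default is the mirror-RMS above.
#' @return Symmetry position s* (mm).
#' @export
symmetry_point <- function(profile, half_window = 100, search_margin = 20,
                           functional = NULL) {
  stopifnot(inherits(profile, "SliceProfile"))
  check_pos(half_window, "half_window")
  if (search_margin < 0) stop("'search_margin' must be >= 0")
  if (!is_contiguous(profile)) stop("profile not contiguous")
  z <- profile$z
  n <- length(z)
  dx <- profile$dx
  x <- profile_x(profile)
  m <- floor(half_window / dx)
  if (m < 1) stop("half_window smaller than one grid step")
  lo <- x[1] + half_window + search_margin
  hi <- x[n] - half_window - search_margin
  cand <- which(x >= lo - 1e-9 & x <= hi + 1e-9)
  cand <- cand[cand - m >= 1 & cand + m <= n]
  if (length(cand) == 0) stop("slice too narrow")
  if (is.null(functional)) {
    a2 <- numeric(length(cand))
    for (u in seq_len(m))
      a2 <- a2 + (z[cand + u] - z[cand - u])^2
    a2 <- a2 / m
  } else {
    a2 <- vapply(cand, function(i) {
      v <- functional(z[i + seq_len(m)], z[i - seq_len(m)])
      v * v
    }, numeric(1))
  }
  best <- which(a2 <= min(a2) + 1e-15)
  mid <- (x[1] + x[n]) / 2
  b <- best[which.min(abs(x[cand[best]] - mid))]
  s <- x[cand[b]]
  # sub-grid refinement on the squared functional
  if (b > 1 && b < length(cand) &&
      cand[b] - cand[b - 1] == 1 && cand[b + 1] - cand[b] == 1) {
    denom <- a2[b - 1] - 2 * a2[b] + a2[b + 1]
    if (denom > 0) {
      delta <- 0.5 * dx * (a2[b - 1] - a2[b + 1]) / denom
      s <- s + max(-dx / 2, min(dx / 2, delta))
    }
  }
  s
}

#' Construct a symmetry line
#'
#' @param y_centers slice vertical positions (mm), ascending.
#' @param x_sym per-slice symmetry positions (mm), `NA` where no point was
#'   found.
#' @param missing logical mask; defaults to `is.na(x_sym)`.
#' @return An object of class `SymmetryLine`.
#' @export
symmetry_line_obj <- function(y_centers, x_sym, missing = is.na(x_sym)) {
  stopifnot(length(y_centers) == length(x_sym),
            length(missing) == length(x_sym))
  structure(
    list(y_centers = as.numeric(y_centers), x_sym = as.numeric(x_sym),
         missing = as.logical(missing)),
    class = "SymmetryLine")
}

#' @export
print.SymmetryLine <- function(x, ...) {
  cat(sprintf("SymmetryLine: %d slices (%d missing), x_sym in [%.2f, %.2f] mm\n",
              length(x$x_sym), sum(x$missing),
              suppressWarnings(min(x$x_sym, na.rm = TRUE)),
              suppressWarnings(max(x$x_sym, na.rm = TRUE))))
  invisible(x)
}

#' Symmetry line of a slice stack
#'
#' Applies [symmetry_point()] to every slice; slices that are too narrow (or
#' otherwise fail) are masked. The points are connected vertically as-is, with
#' no smoothing across slices.
#'
#' @inheritParams symmetry_point
#' @param stack a `SliceStack`.
#' @return A `SymmetryLine`.
#' @export
symmetry_line <- function(stack, half_window = 100, search_margin = 20,
                          functional = NULL) {
  stopifnot(inherits(stack, "SliceStack"))
  xs <- vapply(stack$slices, function(s) {
    tryCatch(symmetry_point(s, half_window, search_margin, functional),
             error = function(e) NA_real_)
  }, numeric(1))
  if (all(is.na(xs))) stop("no slice yields a symmetry point")
  symmetry_line_obj(vapply(stack$slices, `[[`, numeric(1), "y_center"), xs)
}

#' Mean absolute lateral error between two symmetry lines
#'
#' @param a,b `SymmetryLine`s sharing y_centers.
#' @return Mean of `|x_sym_a - x_sym_b|` (mm) over jointly unmasked slices.
#' @export
symmetry_mae <- function(a, b) {
  stopifnot(inherits(a, "SymmetryLine"), inherits(b, "SymmetryLine"))
  if (length(a$y_centers) != length(b$y_centers) ||
      max(abs(a$y_centers - b$y_centers)) > 1e-9)
    stop("symmetry lines do not share y_centers")
  ok <- !a$missing & !b$missing
  if (!any(ok)) stop("no overlapping unmasked slices")
  mean(abs(a$x_sym[ok] - b$x_sym[ok]))
}

#' Low-pass cutoff sweep of the symmetry-line error
#'
#' The symmetry line reacts to high-frequency noise (it is a local mirror
#' comparison), so the benchmark is the line extracted after filtering at
#' `reference_cutoff` rather than the raw line. For each scanned cutoff, every
#' stack is filtered, its line recomputed and compared against its own
#' benchmark line via [symmetry_mae()]; the curve is the mean over stacks. By
#' construction the error at the reference cutoff itself is 0.
#'
#' @param stacks a `SliceStack` or list of them.
#' @param cutoffs strictly descending cutoffs (1/mm).
#' @param reference_cutoff benchmark cutoff (1/mm), `>= max(cutoffs)`;
#'   default 0.1.
#' @param order Butterworth order; default 4.
#' @inheritParams symmetry_point
#' @return An `ErrorCurve` with `metric_label = "symmetry_mae"`.
#' @export
sweep_symmetry <- function(stacks, cutoffs, reference_cutoff = 0.1, order = 4,
                           half_window = 100, search_margin = 20,
                           functional = NULL) {
  if (inherits(stacks, "SliceStack")) stacks <- list(stacks)
  stopifnot(length(stacks) >= 1, length(cutoffs) >= 1)
  if (length(cutoffs) > 1 && any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly descending")
  if (reference_cutoff < max(cutoffs))
    stop("reference_cutoff must be >= all scanned cutoffs")
  per <- matrix(NA_real_, nrow = length(stacks), ncol = length(cutoffs))
  for (i in seq_along(stacks)) {
    bench <- symmetry_line(lowpass_stack(stacks[[i]], reference_cutoff, order),
                           half_window, search_margin, functional)
    for (j in seq_along(cutoffs)) {
      line <- symmetry_line(lowpass_stack(stacks[[i]], cutoffs[j], order),
                            half_window, search_margin, functional)
      per[i, j] <- symmetry_mae(line, bench)
    }
  }
  error_curve(cutoffs, colMeans(per), "symmetry_mae", per_subject_errors = per)
}

#' Export a symmetry line as CSV
#'
#' Columns: `y_mm`, `x_sym_mm`.
#' @param line a `SymmetryLine`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_symmetry_line_csv <- function(line, path) {
  df <- data.frame(y_mm = line$y_centers, x_sym_mm = line$x_sym)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
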