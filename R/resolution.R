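#' Minimal spatial sampling interval band from a breakpoint frequency band
#'
#' Converts the break-point cutoff band into the corresponding band of minimal
#' required sampling intervals: `d = 1 / (2 * oversampling * fc)`, applied at
#' both ends. Because d is the reciprocal, the high end of the frequency band
#' gives the small (strict) interval and the low end the large (lenient) one.
#' The effective frequency multiplier `2 * oversampling` is reported alongside.
#'
#' @param fc_low,fc_high break-point band ends (1/mm, `0 < fc_low <= fc_high`).
#' @param oversampling factor >= 1; default 5.
#' @return List with `d_min`, `d_max` (mm) and `frequency_factor`.
#' @export
spatial_resolution_band <- function(fc_low, fc_high, oversampling = 5) {
  check_pos(fc_low, "fc_low"); check_pos(fc_high, "fc_high")
  if (fc_low > fc_high) stop("fc_low must be <= fc_high")
  if (!is.numeric(oversampling) || length(oversampling) != 1 || oversampling < 1)
    stop("'oversampling' must be a single number >= 1")
  list(d_min = 1 / (2 * oversampling * fc_high),
       d_max = 1 / (2 * oversampling * fc_low),
       frequency_factor = 2 * oversampling)
}

#' Minimal camera pixel counts for a sampling interval
#'
#' The sensor must place one sample every `d` mm across the region of
#' interest, of which only a `fill_factor` fraction of the image extent is
#' available: `px = dimension / (fill_factor * d)`, rounded to the nearest
#' integer, independently per axis.
#'
#' @param W_roi,H_roi width and height of the region of interest (mm).
#' @param fill_factor ratio of the image region covering the object of
#'   interest to the full image, in (0, 1].
#' @param d sampling interval (mm).
#' @return Integer vector `c(px_x, px_y)`.
#' @export
camera_resolution <- function(W_roi, H_roi, fill_factor, d) {
  check_pos(W_roi, "W_roi"); check_pos(H_roi, "H_roi"); check_pos(d, "d")
  check_pos(fill_factor, "fill_factor")
  if (fill_factor > 1) stop("'fill_factor' must be <= 1")
  c(px_x = as.integer(round(W_roi / (fill_factor * d))),
    px_y = as.integer(round(H_roi / (fill_factor * d))))
}

#' Full resolution requirement report
#'
#' Composes [spatial_resolution_band()] and [camera_resolution()] at both band
#' ends into one JSON-serializable requirement: the band of minimal sampling
#' intervals and the corresponding band of minimal camera pixel counts per
#' axis. Pixel bands are reported ascending (the coarse interval needs the
#' fewest pixels).
#'
#' @param fc_band ascending pair `(fc_low, fc_high)` in 1/mm.
#' @param oversampling factor >= 1; default 5.
#' @param W_roi,H_roi region of interest (mm); defaults 454 and 516, the
#'   95th-percentile interscye width and waist-back height of an American
#'   male in NASA's anthropometry tables (the larger of the published limit
#'   cases).
#' @param fill_factor image fraction covering the subject; default 0.67, a
#'   practical value for back captures.
#' @return An object of class `ResolutionRequirement`.
#' @export
requirement_report <- function(fc_band, oversampling = 5, W_roi = 454,
                               H_roi = 516, fill_factor = 0.67) {
  stopifnot(length(fc_band) == 2)
  band <- spatial_resolution_band(fc_band[1], fc_band[2], oversampling)
  px_fine <- camera_resolution(W_roi, H_roi, fill_factor, band$d_min)
  px_coarse <- camera_resolution(W_roi, H_roi, fill_factor, band$d_max)
  structure(
    list(fc_band = as.numeric(fc_band), oversampling = oversampling,
         frequency_factor = band$frequency_factor,
         interval_band = c(band$d_min, band$d_max),
         px_x_band = c(px_coarse[["px_x"]], px_fine[["px_x"]]),
         px_y_band = c(px_coarse[["px_y"]], px_fine[["px_y"]]),
         W_roi = W_roi, H_roi = H_roi, fill_factor = fill_factor),
    class = "ResolutionRequirement")
}

#' @export
print.ResolutionRequirement <- function(x, ...) {
  cat("ResolutionRequirement\n")
  cat(sprintf("  breakpoint band : (%.4g, %.4g) mm^-1, oversampling %gx (frequency factor %gx)\n",
              x$fc_band[1], x$fc_band[2], x$oversampling, x$frequency_factor))
  cat(sprintf("  sampling interval: %.4g mm - %.4g mm\n",
              x$interval_band[1], x$interval_band[2]))
  cat(sprintf("  camera pixels    : %d px - %d px (x)  x  %d px - %d px (y)\n",
              x$px_x_band[1], x$px_x_band[2], x$px_y_band[1], x$px_y_band[2]))
  cat(sprintf("  ROI %g mm x %g mm, fill factor %g\n",
              x$W_roi, x$H_roi, x$fill_factor))
  invisible(x)
}

#' Write a resolution requirement as JSON
#' @param req a `ResolutionRequirement`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_requirement_json <- function(req, path) {
  jsonlite::write_json(unclass(req), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
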