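#' Construct a point cloud
#'
#' A `PointCloud` holds the unordered 3D points (in millimetres) of one back
#' capture. The package-wide axis convention is: x lateral (left to right),
#' y vertical (caudal to cranial), z depth towards the sensor. All loaders
#' map file axes onto this convention; all coordinates are in mm.
#'
#' @param points numeric matrix with three columns (x, y, z) in mm.
#' @param source_id free-text label identifying the capture.
#' @param metadata optional list of provenance data (e.g. the true symmetry
#'   curve of a synthetic surface).
#' @return An object of class `PointCloud`.
#' @export
point_cloud <- function(points, source_id = "", metadata = list()) {
  points <- as.matrix(points)
  if (ncol(points) != 3)
    stop("point cloud requires exactly 3 coordinate columns (x, y, z)")
  storage.mode(points) <- "double"
  if (nrow(points) < 3)
    stop("point cloud requires at least 3 points")
  if (!all(is.finite(points)))
    stop("point cloud contains non-finite coordinates")
  colnames(points) <- c("x", "y", "z")
  structure(
    list(points = points, source_id = as.character(source_id)[1],
         metadata = metadata),
    class = "PointCloud")
}

#' @export
print.PointCloud <- function(x, ...) {
  rng <- apply(x$points, 2, range)
  cat(sprintf("PointCloud '%s': %d points\n", x$source_id, nrow(x$points)))
  cat(sprintf("  x [%.1f, %.1f] mm, y [%.1f, %.1f] mm, z [%.1f, %.1f] mm\n",
              rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]))
  invisible(x)
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "obj", "xyz")) ext
  else if (ext %in% c("txt", "csv", "pts", "asc")) "xyz"
  else stop(sprintf("cannot infer point-cloud format from extension '.%s'", ext))
}

#' Load an ASCII point cloud
#'
#' Reads an ASCII PLY, OBJ (`v` lines) or whitespace-delimited XYZ file into a
#' [point_cloud()]. Faces, normals and colour attributes are discarded; only
#' vertex coordinates are kept. Binary PLY is not supported.
#'
#' @param path path to the file.
#' @param format one of `"auto"`, `"ply"`, `"obj"`, `"xyz"`. `"auto"` infers
#'   the format from the file extension.
#' @param source_id label stored in the cloud; defaults to the file name.
#' @return A `PointCloud` in mm using the package axis convention.
#' @export
load_point_cloud <- function(path, format = c("auto", "ply", "obj", "xyz"),
                             source_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  if (format == "auto") format <- infer_format(path)
  pts <- switch(format,
                ply = read_ascii_ply(path),
                obj = read_ascii_obj(path),
                xyz = read_ascii_xyz(path))
  if (nrow(pts) == 0) stop(sprintf("empty point cloud: %s", path))
  point_cloud(pts, source_id = source_id %||% basename(path))
}

read_ascii_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3 || trimws(lines[1]) != "ply")
    stop("malformed PLY header: missing 'ply' magic line")
  end <- match("end_header", trimws(lines))
  if (is.na(end)) stop("malformed PLY header: no 'end_header'")
  header <- trimws(lines[seq_len(end)])
  fmt <- grep("^format\\s", header, value = TRUE)
  if (length(fmt) == 0 || !grepl("ascii", fmt[1]))
    stop("unsupported PLY: only the ASCII format variant is handled")
  # element declarations, in file order, with their property names
  elem_idx <- grep("^element\\s", header)
  if (length(elem_idx) == 0) stop("malformed PLY header: no element declaration")
  elems <- lapply(seq_along(elem_idx), function(i) {
    tok <- strsplit(header[elem_idx[i]], "\\s+")[[1]]
    to <- if (i < length(elem_idx)) elem_idx[i + 1] - 1 else end - 1
    props <- header[seq(elem_idx[i] + 1, to)]
    props <- grep("^property\\s", props, value = TRUE)
    list(name = tok[2], count = as.integer(tok[3]),
         props = vapply(strsplit(props, "\\s+"),
                        function(p) p[length(p)], character(1)))
  })
  names(elems) <- vapply(elems, `[[`, character(1), "name")
  if (!"vertex" %in% names(elems))
    stop("malformed PLY header: no vertex element")
  # vertex rows come first among data rows iff vertex is the first element
  offset <- 0L
  for (e in elems) {
    if (e$name == "vertex") break
    offset <- offset + e$count
  }
  ve <- elems[["vertex"]]
  if (!all(c("x", "y", "z") %in% ve$props))
    stop("malformed PLY header: vertex element lacks x/y/z properties")
  rows <- lines[seq(end + 1, length(lines))]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < offset + ve$count)
    stop("truncated vertex list: fewer vertex rows than declared in header")
  rows <- rows[seq(offset + 1, offset + ve$count)]
  mat <- parse_numeric_rows(rows, min_cols = length(ve$props), what = "PLY vertex")
  mat[, match(c("x", "y", "z"), ve$props), drop = FALSE]
}

read_ascii_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  v <- grep("^v\\s", lines, value = TRUE)
  if (length(v) == 0) return(matrix(numeric(0), ncol = 3))
  rows <- sub("^v\\s+", "", v)
  parse_numeric_rows(rows, min_cols = 3, what = "OBJ vertex")[, 1:3, drop = FALSE]
}

read_ascii_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(matrix(numeric(0), ncol = 3))
  # allow comma- or whitespace-delimited rows
  lines <- gsub(",", " ", lines, fixed = TRUE)
  parse_numeric_rows(lines, min_cols = 3, what = "XYZ")[, 1:3, drop = FALSE]
}

parse_numeric_rows <- function(rows, min_cols, what) {
  toks <- strsplit(trimws(rows), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols < min_cols))
    stop(sprintf("malformed %s row: expected at least %d numeric fields",
                 what, min_cols))
  vals <- suppressWarnings(lapply(toks, function(t) as.numeric(t[seq_len(min_cols)])))
  bad <- vapply(vals, function(v) anyNA(v), logical(1))
  if (any(bad))
    stop(sprintf("non-numeric %s row: '%s'", what, rows[which(bad)[1]]))
  do.call(rbind, vals)
}

#' Write an ASCII point cloud
#'
#' @param cloud a `PointCloud`.
#' @param path output path.
#' @param format `"auto"` (from extension), `"ply"`, `"obj"` or `"xyz"`.
#' @param digits significant digits written (default 10, round-trip safe well
#'   below 1e-6 mm for back-sized coordinates).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "obj", "xyz"),
                              digits = 10) {
  stopifnot(inherits(cloud, "PointCloud"))
  format <- match.arg(format)
  if (format == "auto") format <- infer_format(path)
  p <- cloud$points
  fmt_row <- function(prefix = "") {
    paste0(prefix,
           formatC(p[, 1], digits = digits, format = "g"), " ",
           formatC(p[, 2], digits = digits, format = "g"), " ",
           formatC(p[, 3], digits = digits, format = "g"))
  }
  lines <- switch(format,
    ply = c("ply", "format ascii 1.0",
            sprintf("element vertex %d", nrow(p)),
            "property float x", "property float y", "property float z",
            "end_header", fmt_row()),
    obj = fmt_row("v "),
    xyz = fmt_row())
  writeLines(lines, path)
  invisible(path)
}

#' Construct a slice profile
#'
#' A `SliceProfile` is one horizontal slice of a back surface regularized onto
#' a strictly uniform lateral grid: depth `z[i]` at abscissa `x0 + (i-1)*dx`.
#' Grid cells without supporting data carry `NA` depth and `missing = TRUE`.
#'
#' @param y_center vertical position of the slice (mm).
#' @param x0 lateral grid origin (mm).
#' @param dx lateral grid step (mm, > 0).
#' @param z depth values (mm), `NA` where missing.
#' @param missing logical mask, same length as `z`; defaults to `is.na(z)`.
#' @return An object of class `SliceProfile`.
#' @export
slice_profile <- function(y_center, x0, dx, z, missing = is.na(z)) {
  stopifnot(is.numeric(dx), length(dx) == 1, dx > 0,
            length(missing) == length(z))
  z[missing] <- NA_real_
  structure(
    list(y_center = as.numeric(y_center), x0 = as.numeric(x0),
         dx = as.numeric(dx), z = as.numeric(z), missing = as.logical(missing)),
    class = "SliceProfile")
}

#' Grid abscissae of a slice profile
#' @param profile a `SliceProfile`.
#' @return Numeric vector `x0 + (i-1)*dx`, exactly uniform by construction.
#' @export
profile_x <- function(profile) {
  profile$x0 + (seq_along(profile$z) - 1) * profile$dx
}

#' @export
print.SliceProfile <- function(x, ...) {
  cat(sprintf("SliceProfile at y = %.2f mm: %d cells (dx = %g mm), %d missing\n",
              x$y_center, length(x$z), x$dx, sum(x$missing)))
  invisible(x)
}

n_usable <- function(profile) sum(!profile$missing)

is_contiguous <- function(profile) !any(profile$missing)

#' Regularize a slice onto a uniform lateral grid
#'
#' Points falling in one horizontal slab are reduced to a single-valued depth
#' profile z = f(x) on a uniform grid, a prerequisite for the Fourier analysis
#' and filtering steps. Points are first averaged within dx-wide lateral bins,
#' then linearly interpolated onto the grid covering the lateral data range.
#' Grid cells whose nearest supporting bin is farther than `max_gap` are marked
#' missing, and only the largest contiguous non-missing segment is retained.
#'
#' @param points_in_slab two-column matrix or data frame of (x, z) in mm.
#' @param dx grid step (mm, > 0).
#' @param max_gap largest tolerated distance (mm) from a grid cell to its
#'   nearest supporting datum; default 3 mm.
#' @param y_center slice vertical position recorded in the result.
#' @return A gap-free `SliceProfile` on the retained segment.
#' @export
regularize_slice <- function(points_in_slab, dx, max_gap = 3, y_center = NA_real_) {
  pts <- as.matrix(points_in_slab)
  if (ncol(pts) < 2) stop("points_in_slab requires (x, z) columns")
  if (nrow(pts) < 2) stop("regularize_slice requires at least 2 points")
  stopifnot(dx > 0, max_gap > 0)
  x <- pts[, 1]; z <- pts[, 2]
  x0 <- min(x); x1 <- max(x)
  if (x1 - x0 < dx) stop("slab narrower than one grid step")
  # reduce: average within dx-wide bins anchored at the data minimum
  bin <- floor((x - x0) / dx + 1e-9)
  bx <- as.numeric(tapply(x, bin, mean))
  bz <- as.numeric(tapply(z, bin, mean))
  ord <- order(bx)
  bx <- bx[ord]; bz <- bz[ord]
  ngrid <- floor((x1 - x0) / dx + 1e-9) + 1
  grid <- x0 + (seq_len(ngrid) - 1) * dx
  zi <- if (length(bx) >= 2) stats::approx(bx, bz, xout = grid, rule = 1)$y
        else rep(NA_real_, ngrid)
  # nearest supporting bin distance decides whether a cell is real or bridged
  nearest <- vapply(grid, function(g) min(abs(g - bx)), numeric(1))
  zi[nearest > max_gap] <- NA_real_
  if (all(is.na(zi))) stop("all grid cells missing after regularization")
  keep <- largest_run(!is.na(zi))
  zi[-keep] <- NA_real_
  slice_profile(y_center, x0 = grid[keep[1]], dx = dx,
                z = zi[keep])
}

largest_run <- function(ok) {
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  i <- which(r$values)
  if (length(i) == 0) return(integer(0))
  best <- i[which.max(r$lengths[i])]
  seq(starts[best], ends[best])
}

#' Construct a slice stack
#'
#' @param slices list of `SliceProfile`s ordered by ascending `y_center`.
#' @param slab_thickness,slab_spacing slab geometry (mm).
#' @param source_id capture label.
#' @return An object of class `SliceStack`.
#' @export
slice_stack_obj <- function(slices, slab_thickness, slab_spacing, source_id = "") {
  yc <- vapply(slices, `[[`, numeric(1), "y_center")
  if (length(slices) > 1 && any(diff(yc) <= 0))
    stop("slice y_centers must be strictly increasing")
  dxs <- vapply(slices, `[[`, numeric(1), "dx")
  if (length(unique(dxs)) > 1) stop("all slices must share the same dx")
  structure(
    list(slices = slices, slab_thickness = slab_thickness,
         slab_spacing = slab_spacing, dx = dxs[1],
         source_id = as.character(source_id)[1]),
    class = "SliceStack")
}

#' @export
print.SliceStack <- function(x, ...) {
  yc <- vapply(x$slices, `[[`, numeric(1), "y_center")
  cat(sprintf(
    "SliceStack '%s': %d slices, y in [%.1f, %.1f] mm, dx = %g mm\n",
    x$source_id, length(x$slices), min(yc), max(yc), x$dx))
  invisible(x)
}

#' Slice a back point cloud into horizontal regularized profiles
#'
#' Horizontal slabs of thickness `slab_thickness` are placed with centers from
#' `y_min + slab_thickness/2` to `y_max - slab_thickness/2` in steps of
#' `slab_spacing`; each slab's points are regularized with [regularize_slice()].
#' Slabs yielding fewer than `min_samples` usable cells are dropped (with a
#' message), mirroring the fact that arm pits and shoulders produce sparse
#' extreme slices on real captures.
#'
#' @param cloud a `PointCloud`.
#' @param slab_thickness slab extent in y (mm); default 5.
#' @param slab_spacing distance between slab centers (mm); default 10.
#' @param dx lateral grid step (mm); default 0.5.
#' @param max_gap see [regularize_slice()].
#' @param min_samples minimum usable cells per retained slice; default 8.
#' @return A `SliceStack`.
#' @export
slice_stack <- function(cloud, slab_thickness = 5, slab_spacing = 10, dx = 0.5,
                        max_gap = 3, min_samples = 8) {
  stopifnot(inherits(cloud, "PointCloud"),
            slab_thickness > 0, dx > 0,
            slab_spacing >= slab_thickness / 2)
  p <- cloud$points
  y0 <- min(p[, 2]); y1 <- max(p[, 2])
  lo <- y0 + slab_thickness / 2
  hi <- y1 - slab_thickness / 2
  centers <- if (hi >= lo) seq(lo, hi, by = slab_spacing) else lo
  slices <- list()
  dropped <- 0L
  for (yc in centers) {
    sel <- abs(p[, 2] - yc) <= slab_thickness / 2
    if (sum(sel) < 2) { dropped <- dropped + 1L; next }
    prof <- tryCatch(
      regularize_slice(p[sel, c(1, 3), drop = FALSE], dx = dx,
                       max_gap = max_gap, y_center = yc),
      error = function(e) NULL)
    if (is.null(prof) || n_usable(prof) < min_samples) {
      dropped <- dropped + 1L
      next
    }
    slices[[length(slices) + 1L]] <- prof
  }
  if (length(slices) == 0) stop("no usable slices")
  if (dropped > 0)
    message(sprintf("slice_stack: dropped %d slab(s) with < %d usable samples",
                    dropped, min_samples))
  slice_stack_obj(slices, slab_thickness, slab_spacing, cloud$source_id)
}

#' @export
as.data.frame.SliceStack <- function(x, ...) {
  do.call(rbind, lapply(seq_along(x$slices), function(i) {
    s <- x$slices[[i]]
    data.frame(slice_index = i, y_center = s$y_center, x = profile_x(s),
               z = s$z, missing = s$missing)
  }))
}

#' Export a slice stack as CSV
#'
#' Columns: slice_index, y_center, x, z, missing.
#' @param stack a `SliceStack`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_slice_stack_csv <- function(stack, path) {
  utils::write.csv(as.data.frame(stack), path, row.names = FALSE)
  invisible(path)
}
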