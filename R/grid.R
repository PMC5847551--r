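#' Define the common equal-area analysis grid
#'
#' All rasters and range masks in a `nightrange` analysis live on a single
#' equal-area grid so that pixel counts are proportional to area. The grid is
#' described by its dimensions, pixel size in map units, the map coordinate of
#' the top-left corner of pixel `(0, 0)`, and a free-text CRS label (an
#' equal-area projection such as Behrmann is assumed, not enforced).
#'
#' Row/column indices are 0-based with pixel `(0, 0)` at the top-left; map
#' intervals are half-open, so a point on the shared edge of two pixels belongs
#' to the pixel with the larger index.
#'
#' @param rows,cols Grid dimensions in pixels (positive integers).
#' @param pixel_width,pixel_height Pixel size in map units (positive).
#' @param origin_x,origin_y Map coordinates of the top-left corner of the grid.
#' @param crs CRS label, e.g. `"Behrmann"`.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(64, 64)
#' pixel_area(g)
#' @export
grid_spec <- function(rows, cols, pixel_width = 1, pixel_height = pixel_width,
                      origin_x = 0, origin_y = rows * pixel_height,
                      crs = "Behrmann") {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (length(rows) != 1L || length(cols) != 1L || is.na(rows) || is.na(cols) ||
      rows < 1L || cols < 1L)
    stop("grid dimensions must be positive integers", call. = FALSE)
  if (!is.finite(pixel_width) || !is.finite(pixel_height) ||
      pixel_width <= 0 || pixel_height <= 0)
    stop("pixel sizes must be positive", call. = FALSE)
  structure(list(rows = rows, cols = cols,
                 pixel_width = as.numeric(pixel_width),
                 pixel_height = as.numeric(pixel_height),
                 origin_x = as.numeric(origin_x),
                 origin_y = as.numeric(origin_y),
                 crs = as.character(crs)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, %g x %g map units/pixel, origin (%g, %g), CRS: %s\n",
              x$rows, x$cols, x$pixel_width, x$pixel_height,
              x$origin_x, x$origin_y, x$crs))
  invisible(x)
}

#' Area of one grid pixel in map units squared
#'
#' @param grid A [grid_spec()].
#' @return Numeric scalar, `pixel_width * pixel_height`.
#' @export
pixel_area <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  grid$pixel_width * grid$pixel_height
}

grids_identical <- function(a, b, tol = 1e-9) {
  a$rows == b$rows && a$cols == b$cols &&
    abs(a$pixel_width - b$pixel_width) <= tol &&
    abs(a$pixel_height - b$pixel_height) <= tol &&
    abs(a$origin_x - b$origin_x) <= tol &&
    abs(a$origin_y - b$origin_y) <= tol
}

check_same_grid <- function(a, b, what = "grids") {
  if (!grids_identical(a, b))
    stop(sprintf("grid mismatch: %s are not on an identical grid_spec", what),
         call. = FALSE)
  invisible(TRUE)
}

#' Map coordinates of pixel centers
#'
#' @param grid A [grid_spec()].
#' @param row,col 0-based pixel indices (vectors recycled together).
#' @return A two-column matrix of map `x`, `y` coordinates.
#' @export
pixel_centers <- function(grid, row, col) {
  stopifnot(inherits(grid, "grid_spec"))
  cbind(x = grid$origin_x + (col + 0.5) * grid$pixel_width,
        y = grid$origin_y - (row + 0.5) * grid$pixel_height)
}

#' Pixel indices containing map coordinates
#'
#' Half-open pixel intervals: a point on a shared edge belongs to the pixel
#' with the larger index (further right / further down).
#'
#' @param grid A [grid_spec()].
#' @param x,y Map coordinates.
#' @return Two-column matrix of 0-based `row`, `col`; `NA` for points outside
#'   the grid extent.
#' @export
map_to_pixel <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$pixel_width)
  row <- floor((grid$origin_y - y) / grid$pixel_height)
  bad <- row < 0 | row >= grid$rows | col < 0 | col >= grid$cols
  row[bad] <- NA_integer_; col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# ---- composite grids --------------------------------------------------------

#' A single-year nighttime-light composite
#'
#' Wraps a `rows x cols` matrix of digital numbers (DN). Raw DMSP-style
#' composites hold integers 0-63 (63 = sensor saturation); after
#' intercalibration DN are real-valued but still clamped to `[0, 63]`.
#' Missing pixels are `NA`.
#'
#' @param dn Numeric matrix of DN values (`rows x cols`).
#' @param grid The [grid_spec()] the matrix lives on.
#' @param year Calendar year of the composite.
#' @param satellite Optional satellite label (e.g. `"F10"`).
#' @return An object of class `composite_grid`.
#' @export
composite_grid <- function(dn, grid, year, satellite = NA_character_) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(dn))
  if (nrow(dn) != grid$rows || ncol(dn) != grid$cols)
    stop("dn matrix dimensions do not match grid_spec", call. = FALSE)
  rng <- range(dn, na.rm = TRUE)
  if (!all(is.na(dn)) && (rng[1] < 0 || rng[2] > 63))
    stop("DN values must lie in [0, 63] (clip on read if needed)", call. = FALSE)
  structure(list(year = as.integer(year), satellite = as.character(satellite),
                 dn = dn, grid = grid),
            class = "composite_grid")
}

#' @export
print.composite_grid <- function(x, ...) {
  cat(sprintf("<composite_grid> year %d (%s), %d x %d px, DN range [%g, %g], %d NA\n",
              x$year, x$satellite, x$grid$rows, x$grid$cols,
              suppressWarnings(min(x$dn, na.rm = TRUE)),
              suppressWarnings(max(x$dn, na.rm = TRUE)),
              sum(is.na(x$dn))))
  invisible(x)
}

stack_years <- function(stack) vapply(stack, function(g) g$year, integer(1))

check_stack <- function(stack) {
  if (!length(stack)) stop("empty composite stack", call. = FALSE)
  if (!all(vapply(stack, inherits, logical(1), "composite_grid")))
    stop("stack members must be composite_grid objects", call. = FALSE)
  yrs <- stack_years(stack)
  if (is.unsorted(yrs, strictly = TRUE))
    stop("stack years must be strictly increasing", call. = FALSE)
  for (g in stack[-1]) check_same_grid(stack[[1]]$grid, g$grid, "stack members")
  invisible(yrs)
}

# ---- ESRI ASCII grid I/O ----------------------------------------------------

#' Write a composite grid as an ESRI ASCII grid (.asc)
#'
#' A plain-text single-band raster format readable by all major GIS software.
#' Requires square pixels. `NA` is written as the `nodata` value.
#'
#' @param grid A [composite_grid()].
#' @param path Output file path.
#' @param nodata Nodata marker written to the header (default -9999).
#' @return `path`, invisibly.
#' @export
write_asc <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "composite_grid"))
  g <- grid$grid
  if (abs(g$pixel_width - g$pixel_height) > 1e-9)
    stop("ASCII grid format requires square pixels", call. = FALSE)
  hdr <- c(sprintf("NCOLS %d", g$cols),
           sprintf("NROWS %d", g$rows),
           sprintf("XLLCORNER %.10g", g$origin_x),
           sprintf("YLLCORNER %.10g", g$origin_y - g$rows * g$pixel_height),
           sprintf("CELLSIZE %.10g", g$pixel_width),
           sprintf("NODATA_VALUE %.10g", nodata))
  dn <- grid$dn
  dn[is.na(dn)] <- nodata
  body <- apply(dn, 1L, function(r) paste(format(r, trim = TRUE, digits = 10),
                                          collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid (.asc) as a composite grid
#'
#' DN values outside `[0, 63]` (other than nodata) are clipped with a warning,
#' mirroring the defensive handling of corrupt composites.
#'
#' @param path Input file path.
#' @param year Calendar year to attach to the composite.
#' @param satellite Optional satellite label.
#' @param crs CRS label attached to the grid.
#' @return A [composite_grid()].
#' @export
read_asc <- function(path, year, satellite = NA_character_, crs = "Behrmann") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[toupper(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("NCOLS", "NROWS", "XLLCORNER", "YLLCORNER", "CELLSIZE")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path, call. = FALSE)
  nodata <- if (!is.null(hdr$NODATA_VALUE)) hdr$NODATA_VALUE else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  rows <- as.integer(hdr$NROWS); cols <- as.integer(hdr$NCOLS)
  if (length(vals) != rows * cols)
    stop("ASCII grid body size does not match header in ", path, call. = FALSE)
  dn <- matrix(vals, nrow = rows, ncol = cols, byrow = TRUE)
  dn[dn == nodata] <- NA_real_
  out_of_range <- sum(dn < 0 | dn > 63, na.rm = TRUE)
  if (out_of_range > 0) {
    warning(sprintf("%d DN values outside [0, 63] clipped in %s",
                    out_of_range, path), call. = FALSE)
    dn <- pmin(pmax(dn, 0), 63)
  }
  g <- grid_spec(rows, cols, hdr$CELLSIZE, hdr$CELLSIZE,
                 origin_x = hdr$XLLCORNER,
                 origin_y = hdr$YLLCORNER + rows * hdr$CELLSIZE,
                 crs = crs)
  composite_grid(dn, g, year, satellite)
}

#' Read an annual composite stack from ASCII grid files
#'
#' One raster per year, all on an identical grid (the pipeline never silently
#' resamples: mismatched grids are an error).
#'
#' @param paths Character vector of `.asc` files, one per year.
#' @param years Integer vector of calendar years, same length as `paths`.
#' @return A year-ordered list of [composite_grid()] objects.
#' @export
read_stack <- function(paths, years) {
  if (length(paths) != length(years) || !length(paths))
    stop("need one raster path per year", call. = FALSE)
  if (anyNA(years) || anyDuplicated(years))
    stop("years must be unique and non-missing", call. = FALSE)
  ord <- order(years)
  stack <- mapply(read_asc, paths[ord], years[ord],
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  check_stack(stack)
  stack
}
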