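#' A species geographic range with conservation attributes
#'
#' Geometry is a multipolygon in the grid CRS: a list of polygons, each polygon
#' a list of rings, each ring an `n x 2` coordinate matrix (first ring is the
#' exterior shell, further rings are holes). Rings need not repeat the first
#' vertex. A species is *threatened* when its IUCN Red List category is CR, EN
#' or VU.
#'
#' @param species_id Stable unique key.
#' @param geometry Multipolygon (list of list of coordinate matrices), or a
#'   single ring matrix which is promoted to one polygon.
#' @param name Species name (defaults to the id).
#' @param category IUCN Red List code (`"CR","EN","VU","NT","LC","DD"`, ...).
#' @param used Logical: is the species used by people?
#' @param use_categories Optional character vector of use categories.
#' @return An object of class `species_range` (with `$threatened` derived).
#' @export
species_range <- function(species_id, geometry, name = species_id,
                          category = "LC", used = FALSE,
                          use_categories = character()) {
  if (is.matrix(geometry)) geometry <- list(list(geometry))
  if (!length(geometry) || !length(geometry[[1]]))
    stop("empty geometry for species ", species_id, call. = FALSE)
  geometry <- lapply(geometry, function(poly) lapply(poly, close_ring))
  for (poly in geometry) for (ring in poly)
    if (nrow(ring) < 4L)  # closed ring: >= 3 distinct vertices
      stop("degenerate ring (<3 vertices) for species ", species_id,
           call. = FALSE)
  structure(list(species_id = as.character(species_id),
                 name = as.character(name),
                 geometry = geometry,
                 category = as.character(category),
                 threatened = category %in% c("CR", "EN", "VU"),
                 used = isTRUE(used),
                 use_categories = as.character(use_categories)),
            class = "species_range")
}

close_ring <- function(ring) {
  ring <- as.matrix(ring)
  storage.mode(ring) <- "double"
  if (ncol(ring) != 2L) stop("ring coordinates must be n x 2", call. = FALSE)
  if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
  ring
}

#' A species range rasterized to grid pixels
#'
#' @param species_id Stable key.
#' @param pixels `n x 2` integer matrix of 0-based `(row, col)` indices.
#' @param grid The [grid_spec()] the indices refer to.
#' @return An object of class `range_mask` with fields `species_id`, `pixels`,
#'   `n_pixels` and `idx` (1-based linear indices into the DN matrix).
#' @export
range_mask <- function(species_id, pixels, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  pixels <- matrix(as.integer(pixels), ncol = 2L,
                   dimnames = list(NULL, c("row", "col")))
  if (!nrow(pixels))
    stop("empty mask for species ", species_id, call. = FALSE)
  if (any(pixels[, 1] < 0L | pixels[, 1] >= grid$rows |
          pixels[, 2] < 0L | pixels[, 2] >= grid$cols))
    stop("mask pixels outside grid for species ", species_id, call. = FALSE)
  structure(list(species_id = as.character(species_id),
                 pixels = pixels,
                 n_pixels = nrow(pixels),
                 idx = pixels[, 2] * grid$rows + pixels[, 1] + 1L,
                 grid = grid),
            class = "range_mask")
}

# ---- point in polygon -------------------------------------------------------

# Even-odd ray casting for a set of query points against one closed ring.
# Points exactly on an edge are resolved by the half-open crossing rule
# (consistent, but callers should not rely on edge-point behaviour).
ray_cast_ring <- function(px, py, ring) {
  n <- nrow(ring) - 1L
  inside <- logical(length(px))
  x <- ring[, 1]; y <- ring[, 2]
  for (i in seq_len(n)) {
    x1 <- x[i]; y1 <- y[i]; x2 <- x[i + 1L]; y2 <- y[i + 1L]
    crosses <- ((y1 > py) != (y2 > py))
    if (any(crosses)) {
      xin <- x1 + (py[crosses] - y1) / (y2 - y1) * (x2 - x1)
      hit <- crosses
      hit[crosses] <- px[crosses] < xin
      inside <- xor(inside, hit)
    }
  }
  inside
}

#' Test points against a multipolygon (even-odd rule)
#'
#' Holes are handled by parity: a point inside an odd number of rings of a
#' polygon is inside that polygon.
#'
#' @param px,py Point coordinate vectors.
#' @param geometry Multipolygon as in [species_range()].
#' @return Logical vector.
#' @export
points_in_geometry <- function(px, py, geometry) {
  inside <- logical(length(px))
  for (poly in geometry) {
    in_poly <- logical(length(px))
    for (ring in poly) in_poly <- xor(in_poly, ray_cast_ring(px, py, ring))
    inside <- inside | in_poly
  }
  inside
}

geometry_bbox <- function(geometry) {
  xs <- unlist(lapply(geometry, function(p) lapply(p, function(r) r[, 1])))
  ys <- unlist(lapply(geometry, function(p) lapply(p, function(r) r[, 2])))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

# Area-weighted centroid of the exterior rings (shoelace formula); falls back
# to the vertex mean for zero-area geometries.
geometry_centroid <- function(geometry) {
  A_tot <- 0; cx <- 0; cy <- 0
  for (poly in geometry) {
    r <- poly[[1]]
    x <- r[, 1]; y <- r[, 2]; n <- nrow(r)
    cross <- x[-n] * y[-1] - x[-1] * y[-n]
    A <- sum(cross) / 2
    if (abs(A) > 0) {
      cx <- cx + sum((x[-n] + x[-1]) * cross) / 6
      cy <- cy + sum((y[-n] + y[-1]) * cross) / 6
      A_tot <- A_tot + A
    }
  }
  if (abs(A_tot) > 0) c(cx, cy) / A_tot
  else {
    v <- do.call(rbind, lapply(geometry, `[[`, 1))
    c(mean(v[, 1]), mean(v[, 2]))
  }
}

#' Rasterize a species range to a pixel mask
#'
#' A pixel belongs to the mask when its *center* falls inside the range
#' geometry (even-odd rule). If no pixel center falls inside — a range smaller
#' than one pixel — the single pixel containing the geometry centroid is
#' assigned, so every range on the grid has at least one pixel.
#'
#' @param range A [species_range()].
#' @param grid A [grid_spec()].
#' @return A [range_mask()].
#' @export
rasterize_range <- function(range, grid) {
  stopifnot(inherits(range, "species_range"), inherits(grid, "grid_spec"))
  bb <- geometry_bbox(range$geometry)
  col0 <- max(0L, floor((bb["xmin"] - grid$origin_x) / grid$pixel_width))
  col1 <- min(grid$cols - 1L, ceiling((bb["xmax"] - grid$origin_x) / grid$pixel_width))
  row0 <- max(0L, floor((grid$origin_y - bb["ymax"]) / grid$pixel_height))
  row1 <- min(grid$rows - 1L, ceiling((grid$origin_y - bb["ymin"]) / grid$pixel_height))
  if (col1 < col0 || row1 < row0)
    stop("geometry outside grid extent for species ", range$species_id,
         call. = FALSE)
  cand <- expand.grid(row = row0:row1, col = col0:col1)
  ctr <- pixel_centers(grid, cand$row, cand$col)
  inside <- points_in_geometry(ctr[, 1], ctr[, 2], range$geometry)
  if (any(inside)) {
    range_mask(range$species_id, as.matrix(cand[inside, , drop = FALSE]), grid)
  } else {
    cen <- geometry_centroid(range$geometry)
    px <- map_to_pixel(grid, cen[1], cen[2])
    if (anyNA(px))
      stop("geometry outside grid extent for species ", range$species_id,
           call. = FALSE)
    range_mask(range$species_id, px, grid)
  }
}

# ---- GeoJSON I/O ------------------------------------------------------------

geometry_to_geojson <- function(geometry) {
  ring_coords <- function(ring) lapply(seq_len(nrow(ring)),
                                       function(i) c(ring[i, 1], ring[i, 2]))
  polys <- lapply(geometry, function(poly) lapply(poly, ring_coords))
  if (length(polys) == 1L)
    list(type = "Polygon", coordinates = polys[[1]])
  else
    list(type = "MultiPolygon", coordinates = polys)
}

geojson_to_geometry <- function(geom) {
  ring_from <- function(coords)
    close_ring(do.call(rbind, lapply(coords, function(p) unlist(p)[1:2])))
  if (is.null(geom$type) || is.null(geom$coordinates) ||
      !length(geom$coordinates)) return(NULL)
  switch(geom$type,
         Polygon = list(lapply(geom$coordinates, ring_from)),
         MultiPolygon = lapply(geom$coordinates,
                               function(poly) lapply(poly, ring_from)),
         stop("unsupported GeoJSON geometry type: ", geom$type, call. = FALSE))
}

#' Write species ranges to a GeoJSON FeatureCollection
#'
#' Feature properties: `species_id`, `name`, `category`, `used` (and
#' `use_categories` when present).
#'
#' @param ranges List of [species_range()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranges <- function(ranges, path) {
  features <- lapply(ranges, function(r) {
    props <- list(species_id = r$species_id, name = r$name,
                  category = r$category, used = r$used)
    if (length(r$use_categories)) props$use_categories <- I(r$use_categories)
    list(type = "Feature", properties = props,
         geometry = geometry_to_geojson(r$geometry))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load species ranges from a GeoJSON FeatureCollection
#'
#' Features with empty geometry are rejected and their ids reported in a
#' warning; a missing required property is a schema error; duplicated
#' `species_id` values are an error.
#'
#' @param path GeoJSON file path.
#' @return List of [species_range()] objects.
#' @export
load_ranges <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  out <- list(); dropped <- character()
  for (f in fc$features) {
    p <- f$properties
    for (field in c("species_id", "category", "used"))
      if (is.null(p[[field]]))
        stop("feature missing required property '", field, "' in ", path,
             call. = FALSE)
    geom <- geojson_to_geometry(f$geometry)
    if (is.null(geom)) {
      dropped <- c(dropped, as.character(p$species_id))
      next
    }
    out[[length(out) + 1L]] <- species_range(
      species_id = p$species_id, geometry = geom,
      name = if (!is.null(p$name)) p$name else p$species_id,
      category = p$category, used = isTRUE(p$used),
      use_categories = unlist(p$use_categories))
  }
  if (length(dropped))
    warning("rejected features with empty geometry: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  ids <- vapply(out, `[[`, character(1), "species_id")
  if (anyDuplicated(ids))
    stop("duplicate species_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  out
}

#' Export range masks as a tidy CSV of pixel memberships
#'
#' @param masks List of [range_mask()] objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_masks_csv <- function(masks, path) {
  df <- do.call(rbind, lapply(masks, function(m)
    data.frame(species_id = m$species_id,
               row = m$pixels[, 1], col = m$pixels[, 2])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
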