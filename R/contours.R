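#' Per-slice contour polygons
#'
#' Clinical target contours are drawn as closed planar polygons on axial
#' slices. A contour stack holds, per axial slice index (0-based), a list of
#' polygons with vertices in in-plane voxel coordinates (columns x, y).
#'
#' @param slices a list of entries `list(z = <int>, polygons = <list of n x 2
#'   matrices>)`.
#' @return an object of class `contour_stack`.
#' @export
contour_stack <- function(slices) {
  for (s in slices) {
    if (is.null(s$z) || length(s$z) != 1L)
      stop_propnet("every slice needs a single z index", "propnet_geometry_error")
    for (p in s$polygons) {
      p <- as.matrix(p)
      if (nrow(p) < 3L)
        stop_propnet("polygons need at least 3 vertices", "propnet_geometry_error")
      if (ncol(p) != 2L)
        stop_propnet("polygon vertices must have 2 in-plane coordinates",
                     "propnet_geometry_error")
    }
  }
  structure(list(slices = slices), class = "contour_stack")
}

#' Read contours from JSON
#'
#' Expected layout: `{"slices": [{"z": 10, "polygons": [[[x,y], ...], ...]},
#' ...]}` with vertices in in-plane voxel coordinates.
#'
#' @param path JSON file.
#' @return a [contour_stack].
#' @export
read_contours <- function(path) {
  parsed <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(parsed$slices, function(s) {
    polys <- lapply(s$polygons, function(p) {
      do.call(rbind, lapply(p, function(v) as.numeric(unlist(v))))
    })
    list(z = as.integer(s$z), polygons = polys)
  })
  contour_stack(slices)
}

#' Rasterize contours to a binary mask
#'
#' A voxel is set to 1 iff its center lies inside any polygon of its slice
#' under the even-odd rule. Centers exactly on an edge are resolved by the
#' standard scanline half-open convention: an edge counts as crossed when its
#' endpoints straddle the center's y under `y1 <= yc != y2 <= yc`, and only
#' crossings strictly to the right of the center count, so lower/left
#' boundaries are inside and upper/right boundaries are outside —
#' deterministic and independent of vertex order.
#'
#' @param contours a [contour_stack] with slice indices inside the template's
#'   axial extent.
#' @param template a [volume3d] supplying grid dimensions, spacing and origin.
#' @return a binary mask [volume3d] on the template grid.
#' @export
rasterize_contours <- function(contours, template) {
  if (!inherits(contours, "contour_stack"))
    stop_propnet("`contours` must be a contour_stack", "propnet_type_error")
  assert_volume(template, "template")
  dims <- vol_dims(template)
  mask <- array(0, dims)
  xc <- seq_len(dims[1]) - 1
  yc <- seq_len(dims[2]) - 1
  for (s in contours$slices) {
    z <- s$z
    if (z < 0 || z >= dims[3])
      stop_propnet(sprintf("slice index %d outside axial extent", z),
                   "propnet_geometry_error")
    for (p in s$polygons) {
      p <- as.matrix(p)
      if (nrow(p) < 3L)
        stop_propnet("polygons need at least 3 vertices", "propnet_geometry_error")
      inside <- polygon_interior(p, xc, yc)
      # even-odd across polygons as well: XOR accumulates multiply-wound areas
      mask[, , z + 1] <- (mask[, , z + 1] + inside) %% 2
    }
  }
  volume3d(mask, spacing = template$spacing, origin = template$origin,
           is_mask = TRUE)
}

# Even-odd point-in-polygon test for all grid centers at once. Returns a
# 0/1 matrix of dim (length(xc), length(yc)).
polygon_interior <- function(poly, xc, yc) {
  n <- nrow(poly)
  crossings <- matrix(0L, length(xc), length(yc))
  x1 <- poly[, 1]; y1 <- poly[, 2]
  x2 <- poly[c(2:n, 1), 1]; y2 <- poly[c(2:n, 1), 2]
  for (e in seq_len(n)) {
    if (y1[e] == y2[e]) next  # horizontal edges never cross the scanline rule
    straddle <- (y1[e] <= yc) != (y2[e] <= yc)   # per y center
    if (!any(straddle)) next
    t <- (yc[straddle] - y1[e]) / (y2[e] - y1[e])
    xint <- x1[e] + t * (x2[e] - x1[e])
    # outer(+): for each straddled y, centers strictly left of the crossing
    crossings[, straddle] <- crossings[, straddle] +
      outer(xc, xint, FUN = "<")
  }
  crossings %% 2L
}
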