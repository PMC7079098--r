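#' 3D volume with physical spacing
#'
#' The basic container for images and binary masks: a 3D array of scalars plus
#' per-axis voxel spacing (mm) and the physical position of voxel (0,0,0).
#' Axes are ordered (x, y, z) = (left-right, posterior-anterior,
#' superior-inferior); the axial direction is z. Voxel (i,j,k) (0-based) has
#' its center at `origin + c(i,j,k) * spacing`.
#'
#' @param data numeric 3D array. Masks must be 0/1 valued.
#' @param spacing positive numeric length-3, voxel size in mm.
#' @param origin numeric length-3, physical position of voxel (0,0,0) in mm.
#' @param is_mask logical; selects nearest-neighbor interpolation rules.
#' @return an object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     is_mask = FALSE) {
  if (length(dim(data)) != 3L)
    stop_propnet("volume data must be a 3D array", "propnet_dim_error")
  if (any(dim(data) < 2L))
    stop_propnet("volume must have at least 2 voxels along every axis",
                 "propnet_dim_error")
  spacing <- as.numeric(spacing); origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_propnet("spacing must be 3 positive numbers", "propnet_value_error")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop_propnet("origin must be 3 finite numbers", "propnet_value_error")
  if (is_mask && !all(data %in% c(0, 1)))
    stop_propnet("mask volumes must contain only 0 and 1", "propnet_value_error")
  structure(list(data = data, spacing = spacing, origin = origin,
                 is_mask = isTRUE(is_mask)),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume3d %s> %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              if (x$is_mask) "mask" else "image", d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  if (x$is_mask) cat(sprintf("  foreground voxels: %d\n", sum(x$data)))
  else cat(sprintf("  intensity range: [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @rdname volume3d
#' @param x object to test.
#' @export
is_volume3d <- function(x) inherits(x, "volume3d")

vol_dims <- function(v) dim(v$data)

assert_volume <- function(v, arg = "v") {
  if (!is_volume3d(v))
    stop_propnet(sprintf("`%s` must be a volume3d", arg), "propnet_type_error")
  invisible(v)
}

assert_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)))
    stop_propnet("volumes are not on the same grid", "propnet_shape_error")
  invisible(NULL)
}
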