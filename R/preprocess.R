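#' Network grid specification
#'
#' Defines the fixed grid on which the registration network operates and the
#' center-crop applied when resampling clinical volumes to it. With the
#' default in-plane crop factor 2 on a 400 mm field of view, the effective
#' network field of view is 200 x 200 mm2 in-plane (1.5625 mm voxels at size
#' 128); the axial factor 1.33 gives an axial window of roughly 110-130 mm
#' depending on the acquired slice spacing.
#'
#' @param size per-axis output dimensions; powers of two `>= 8` so the
#'   multi-resolution architecture can pool five times.
#' @param in_plane_scale unitless center-crop factor applied in x and y.
#' @param axial_scale unitless center-crop factor applied in z.
#' @param axial_margin_mm margin used when cropping around the target before
#'   resampling.
#' @return an object of class `network_grid_spec`.
#' @export
network_grid_spec <- function(size = c(128, 128, 128), in_plane_scale = 2,
                              axial_scale = 1.33, axial_margin_mm = 30) {
  size <- as.integer(rep(size, length.out = 3))
  pow2 <- size >= 8 & bitwAnd(size, size - 1L) == 0L
  if (!all(pow2))
    stop_propnet("grid sizes must be powers of two >= 8", "propnet_value_error")
  if (in_plane_scale < 1 || axial_scale < 1)
    stop_propnet("crop scale factors must be >= 1", "propnet_value_error")
  structure(list(size = size, in_plane_scale = in_plane_scale,
                 axial_scale = axial_scale, axial_margin_mm = axial_margin_mm),
            class = "network_grid_spec")
}

#' Linearly rescale image intensities to [0, 1]
#'
#' Min-max normalization applied before images enter the network. A constant
#' image maps to all zeros rather than erroring, which keeps pipelines alive
#' on degenerate crops.
#'
#' @param v an image [volume3d] (masks are rejected).
#' @return the normalized [volume3d].
#' @export
normalize_intensities <- function(v) {
  assert_volume(v)
  if (v$is_mask)
    stop_propnet("intensity normalization applies to images, not masks",
                 "propnet_type_error")
  r <- range(v$data)
  data <- if (r[1] == r[2]) array(0, dim(v$data))
          else (v$data - r[1]) / (r[2] - r[1])
  volume3d(data, spacing = v$spacing, origin = v$origin, is_mask = FALSE)
}

#' Crop a volume axially around a region of interest
#'
#' Keeps the full in-plane extent and restricts the axial (z) extent to the
#' slices occupied by `roi_mask`, expanded by `ceiling(margin_mm / axial
#' spacing)` slices on both sides and clipped to the volume. This mirrors the
#' clinical workflow in which fraction scans are acquired with a reduced
#' axial field of view of the target plus a 30 mm margin.
#'
#' @param image the [volume3d] to crop.
#' @param roi_mask nonempty mask [volume3d] on the same grid.
#' @param margin_mm axial margin in mm.
#' @return the cropped [volume3d].
#' @export
crop_axial_roi <- function(image, roi_mask, margin_mm = 30) {
  assert_volume(image, "image"); assert_volume(roi_mask, "roi_mask")
  assert_same_grid(image, roi_mask)
  occ <- which(apply(roi_mask$data, 3, function(s) any(s != 0)))
  if (length(occ) == 0L)
    stop_propnet("ROI mask is empty", "propnet_roi_error")
  pad <- ceiling(margin_mm / image$spacing[3])
  lo <- max(1L, min(occ) - pad)
  hi <- min(dim(image$data)[3], max(occ) + pad)
  data <- image$data[, , lo:hi, drop = FALSE]
  origin <- image$origin + c(0, 0, (lo - 1) * image$spacing[3])
  volume3d(data, spacing = image$spacing, origin = origin,
           is_mask = image$is_mask)
}

#' Resample a volume to the network grid
#'
#' Produces a `spec$size` volume whose physical extent per axis is the input
#' extent divided by the crop scale factor, centered on the input center
#' (optionally shifted axially). Images are sampled with third-order B-spline
#' interpolation (recursive prefilter, so the spline interpolates the input
#' exactly at integer positions); masks use nearest-neighbor sampling and
#' therefore stay binary.
#'
#' @param v input [volume3d]; the target is assumed centered in its field of
#'   view, as in the clinical patient setup.
#' @param spec a [network_grid_spec].
#' @param axial_shift_mm displacement of the sampling window along z, in mm;
#'   used by the axial-shift robustness experiment.
#' @return a [volume3d] on the network grid.
#' @export
resample_to_network_grid <- function(v, spec, axial_shift_mm = 0) {
  assert_volume(v)
  if (!inherits(spec, "network_grid_spec"))
    stop_propnet("`spec` must be a network_grid_spec", "propnet_type_error")
  dims_in <- vol_dims(v)
  scale <- c(spec$in_plane_scale, spec$in_plane_scale, spec$axial_scale)
  extent_in <- dims_in * v$spacing
  extent_out <- extent_in / scale
  if (any(extent_out > extent_in + 1e-9))
    stop_propnet("requested window exceeds the input extent",
                 "propnet_geometry_error")
  size <- spec$size
  spacing_out <- extent_out / size
  center_vox <- (dims_in - 1) / 2
  shift <- c(0, 0, axial_shift_mm)
  # continuous input voxel coordinate of each output voxel center
  ax <- lapply(1:3, function(a) {
    center_vox[a] +
      ((seq_len(size[a]) - 1 - (size[a] - 1) / 2) * spacing_out[a] +
         shift[a]) / v$spacing[a]
  })
  pts <- cbind(
    rep.int(ax[[1]], size[2] * size[3]),
    rep.int(rep(ax[[2]], each = size[1]), size[3]),
    rep(ax[[3]], each = size[1] * size[2])
  )
  vals <- if (v$is_mask) {
    .sample_nearest(v$data, dims_in, pts, 0)
  } else {
    coefs <- .bspline_prefilter3d(v$data, dims_in)
    .sample_cubic(coefs, dims_in, pts, 0)
  }
  center_phys <- v$origin + center_vox * v$spacing
  origin_out <- center_phys - (size - 1) / 2 * spacing_out + shift
  volume3d(array(vals, size), spacing = spacing_out, origin = origin_out,
           is_mask = v$is_mask)
}
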