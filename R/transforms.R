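#' Spatial transforms
#'
#' All transforms map output (fixed) voxel coordinates to input (moving) voxel
#' coordinates — the backward ("pull") warping convention, under which the
#' warped volume is `out(x) = in(T(x))`. Coordinates are 0-based voxel indices
#' of a grid whose dimensions are carried by the transform (`extent`), which
#' also fixes the rotation/scaling center at the grid center `(D - 1) / 2`.
#'
#' @name spatial_transform
NULL

#' Rigid transform
#'
#' Rotation (radians, about the x, y and z axes through the grid center,
#' applied in the fixed order `Rz %*% Ry %*% Rx`) followed by a translation in
#' voxels.
#'
#' @param angles length-3 rotation angles in radians.
#' @param translation length-3 translation in voxels.
#' @param extent grid dimensions the transform acts on.
#' @return a `rigid_transform`.
#' @export
rigid_transform <- function(angles = c(0, 0, 0), translation = c(0, 0, 0),
                            extent) {
  angles <- as.numeric(angles); translation <- as.numeric(translation)
  structure(list(angles = angles, translation = translation,
                 extent = as.integer(rep(extent, length.out = 3))),
            class = c("rigid_transform", "spatial_transform"))
}

rotation_matrix <- function(angles) {
  cx <- cos(angles[1]); sx <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cz <- cos(angles[3]); sz <- sin(angles[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Free-form B-spline transform
#'
#' A displacement field parameterized by a coarse lattice of control-point
#' vectors interpolated with cubic B-splines. A lattice of size `n` per axis
#' places control points equidistantly over the full voxel extent (knot
#' spacing `(D - 1) / (n - 1)`); coefficients outside the lattice are
#' edge-replicated for evaluation near the borders. Because the cubic basis is
#' a nonnegative partition of unity, every displacement component is bounded
#' by the largest coefficient magnitude.
#'
#' @param coefficients a `(n1, n2, n3, 3)` array of control-point
#'   displacements in voxels.
#' @param extent grid dimensions the lattice spans.
#' @return a `bspline_transform`.
#' @export
bspline_transform <- function(coefficients, extent) {
  d <- dim(coefficients)
  if (length(d) != 4L || d[4] != 3L)
    stop_propnet("coefficients must be an (n1, n2, n3, 3) array",
                 "propnet_lattice_error")
  if (any(d[1:3] < 2L))
    stop_propnet("control lattice needs at least 2 points per axis",
                 "propnet_lattice_error")
  extent <- as.integer(rep(extent, length.out = 3))
  structure(list(coefficients = coefficients, grid_size = d[1:3],
                 extent = extent,
                 knot_spacing = (extent - 1) / (d[1:3] - 1)),
            class = c("bspline_transform", "spatial_transform"))
}

#' Center-anchored scaling transform
#'
#' `T(x) = c + factors * (x - c)` with `c` the grid center: a factor above 1
#' samples the input over a larger window (the content shrinks), which is the
#' "crop by scaling" used to pull a wide field of view onto the network grid.
#'
#' @param factors per-axis positive scale factors.
#' @param extent grid dimensions.
#' @return a `scaling_transform`.
#' @export
scaling_transform <- function(factors, extent) {
  factors <- rep(as.numeric(factors), length.out = 3)
  if (any(factors <= 0))
    stop_propnet("scale factors must be positive", "propnet_value_error")
  structure(list(factors = factors,
                 extent = as.integer(rep(extent, length.out = 3))),
            class = c("scaling_transform", "spatial_transform"))
}

#' Composite transform
#'
#' Function composition `T = c1 o c2 o ... o cn` with `(f o g)(x) = f(g(x))`:
#' points are passed through the last component first. Composition happens on
#' coordinates (no intermediate resampling), so a volume warped by the
#' composite is interpolated exactly once.
#'
#' @param ... transforms, or a single list of transforms.
#' @return a `composite_transform`.
#' @export
composite_transform <- function(...) {
  comps <- list(...)
  if (length(comps) == 1L && !inherits(comps[[1]], "spatial_transform"))
    comps <- comps[[1]]
  if (length(comps) == 0L)
    stop_propnet("composite needs at least one component", "propnet_value_error")
  for (c in comps)
    if (!inherits(c, "spatial_transform"))
      stop_propnet("all components must be spatial transforms",
                   "propnet_type_error")
  structure(list(components = comps),
            class = c("composite_transform", "spatial_transform"))
}

#' Map points through a transform
#'
#' @param t a spatial transform.
#' @param pts an `N x 3` matrix of 0-based voxel coordinates.
#' @return an `N x 3` matrix of mapped coordinates.
#' @export
transform_points <- function(t, pts) UseMethod("transform_points")

#' @export
transform_points.rigid_transform <- function(t, pts) {
  ctr <- (t$extent - 1) / 2
  R <- rotation_matrix(t$angles)
  out <- sweep(pts, 2, ctr) %*% t(R)
  sweep(out, 2, ctr + t$translation, FUN = "+")
}

#' @export
transform_points.bspline_transform <- function(t, pts) {
  pts + .ffd_eval(t$coefficients, t$grid_size, t$knot_spacing, pts)
}

#' @export
transform_points.scaling_transform <- function(t, pts) {
  ctr <- (t$extent - 1) / 2
  sweep(sweep(pts, 2, ctr) %*% diag(t$factors), 2, ctr, FUN = "+")
}

#' @export
transform_points.composite_transform <- function(t, pts) {
  for (comp in rev(t$components)) pts <- transform_points(comp, pts)
  pts
}

#' @export
transform_points.displacement_field <- function(t, pts) {
  dims <- t$grid_size
  u <- vapply(1:3, function(c)
    .sample_linear(t$u[, , , c], dims, pts, 0), numeric(nrow(pts)))
  pts + u
}

# --- random transform samplers ----------------------------------------------

#' Sample a random B-spline transform
#'
#' Every control-point displacement component is drawn independently from
#' `Uniform(-amplitude, amplitude)` (voxels).
#'
#' @param grid_size control lattice size per axis (scalar or length 3).
#' @param amplitude nonnegative coefficient bound in voxels.
#' @param extent grid dimensions the lattice spans.
#' @param seed optional seed for a deterministic draw.
#' @return a [bspline_transform].
#' @export
sample_bspline <- function(grid_size, amplitude, extent, seed = NULL) {
  grid_size <- as.integer(rep(grid_size, length.out = 3))
  if (any(grid_size < 2L))
    stop_propnet("control lattice needs at least 2 points per axis",
                 "propnet_lattice_error")
  if (amplitude < 0)
    stop_propnet("amplitude must be nonnegative", "propnet_value_error")
  coef <- with_seed(seed,
    array(runif(prod(grid_size) * 3, -amplitude, amplitude),
          c(grid_size, 3)))
  bspline_transform(coef, extent)
}

#' Sample the multi-scale transform the network learns to invert
#'
#' The composition `t1 o t2 o t3 o t4` of four random B-spline transforms on
#' lattices of 2^3, 4^3, 8^3, 16^3 control points with coefficient amplitudes
#' 6.4, 3.2, 1.6 and 0.8 voxels. The per-component displacement of the
#' composition is bounded by the amplitude sum, 12.0 voxels.
#'
#' @param extent grid dimensions.
#' @param grids lattice sizes, coarsest first.
#' @param amplitudes uniform bounds in voxels, matching `grids`.
#' @param seed optional seed.
#' @return a [composite_transform].
#' @export
sample_learned_transform <- function(extent, grids = c(2, 4, 8, 16),
                                     amplitudes = c(6.4, 3.2, 1.6, 0.8),
                                     seed = NULL) {
  stopifnot(length(grids) == length(amplitudes))
  with_seed(seed, {
    comps <- lapply(seq_along(grids), function(i)
      sample_bspline(grids[i], amplitudes[i], extent))
    composite_transform(comps)
  })
}

#' Sample a data-augmentation transform
#'
#' A random rigid transform (angles uniform in `[-max_angle, max_angle]`
#' radians, translations uniform in `[-max_translation, max_translation]`
#' voxels) composed with a random coarse B-spline deformation.
#'
#' @param extent grid dimensions.
#' @param max_angle rotation bound in radians.
#' @param max_translation translation bound in voxels.
#' @param bspline_grid lattice size of the deformable part.
#' @param bspline_amplitude coefficient bound of the deformable part (voxels).
#' @param seed optional seed.
#' @return a [composite_transform] (rigid then B-spline component).
#' @export
sample_augmentation_transform <- function(extent, max_angle = 0.1,
                                          max_translation = 12.8,
                                          bspline_grid = 2,
                                          bspline_amplitude = 6.4,
                                          seed = NULL) {
  with_seed(seed, {
    rig <- rigid_transform(angles = runif(3, -max_angle, max_angle),
                           translation = runif(3, -max_translation,
                                               max_translation),
                           extent = extent)
    bsp <- sample_bspline(bspline_grid, bspline_amplitude, extent)
    composite_transform(rig, bsp)
  })
}

# --- dense fields ------------------------------------------------------------

#' Dense displacement field
#'
#' A 3-component grid `u = (ux, uy, uz)` in voxel units on the fixed output
#' grid; `x + u(x)` is the moving-image coordinate sampled for output voxel
#' `x`.
#'
#' @param u a `(d1, d2, d3, 3)` numeric array.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(u) {
  d <- dim(u)
  if (length(d) != 4L || d[4] != 3L)
    stop_propnet("field must be a (d1, d2, d3, 3) array", "propnet_dim_error")
  if (!all(is.finite(u)))
    stop_propnet("field must be finite everywhere", "propnet_value_error")
  structure(list(u = u, grid_size = d[1:3]),
            class = c("displacement_field", "spatial_transform"))
}

#' Evaluate a transform as a dense displacement field
#'
#' `u(x) = T(x) - x` at every voxel of the grid. Composites are evaluated as
#' the exact composed coordinate mapping.
#'
#' @param t a spatial transform.
#' @param grid output grid dimensions (scalar or length 3).
#' @return a [displacement_field].
#' @export
to_dense_field <- function(t, grid) {
  grid <- as.integer(rep(grid, length.out = 3))
  pts <- grid_points(grid)
  u <- transform_points(t, pts) - pts
  displacement_field(array(u, c(grid, 3)))
}

#' Compose two dense displacement fields
#'
#' `u12(x) = u_inner(x) + u_outer(x + u_inner(x))`, the outer field linearly
#' interpolated at non-integer positions (edge values extended constantly
#' outside its grid). Under
#' pull-warping this realizes `T_outer o T_inner`: warping once by the
#' composed field equals warping by `outer` first and then by `inner`.
#'
#' @param outer,inner [displacement_field]s on the same grid.
#' @return the composed [displacement_field].
#' @export
compose_fields <- function(outer, inner) {
  if (!inherits(outer, "displacement_field") ||
      !inherits(inner, "displacement_field"))
    stop_propnet("operands must be displacement fields", "propnet_type_error")
  if (!identical(outer$grid_size, inner$grid_size))
    stop_propnet("fields are on different grids", "propnet_shape_error")
  dims <- inner$grid_size
  pts <- grid_points(dims)
  warped_pts <- pts + matrix(inner$u, ncol = 3)
  # edge-clamp so the outer field extends constantly beyond its grid
  for (a in 1:3) warped_pts[, a] <- pmin(pmax(warped_pts[, a], 0), dims[a] - 1)
  u_out <- vapply(1:3, function(c)
    .sample_linear(outer$u[, , , c], dims, warped_pts, 0),
    numeric(nrow(pts)))
  displacement_field(array(matrix(inner$u, ncol = 3) + u_out, c(dims, 3)))
}

as_field <- function(t, grid) {
  if (inherits(t, "displacement_field")) {
    if (!identical(t$grid_size, as.integer(grid)))
      stop_propnet("field grid does not match the volume grid",
                   "propnet_shape_error")
    t
  } else if (inherits(t, "spatial_transform")) {
    to_dense_field(t, grid)
  } else {
    stop_propnet("expected a spatial transform or displacement field",
                 "propnet_type_error")
  }
}

#' Warp an image by a transform or dense field
#'
#' Backward warping: `out(x) = in(x + u(x))`. Parametric transforms are
#' evaluated exactly at the sample points (single interpolation); out-of-grid
#' samples take `fill`. Interpolation order 3 uses the prefiltered cubic
#' B-spline (exact at integer offsets), order 1 trilinear, order 0 nearest
#' neighbor.
#'
#' @param v the [volume3d] to warp.
#' @param t a spatial transform or [displacement_field] in voxel units of
#'   `v`'s grid.
#' @param order interpolation order: 0, 1 or 3.
#' @param fill value for samples outside the input grid.
#' @return the warped [volume3d].
#' @export
warp_image <- function(v, t, order = 3, fill = 0) {
  assert_volume(v)
  if (v$is_mask && order > 0)
    stop_propnet("masks must be warped with nearest-neighbor interpolation",
                 "propnet_type_error")
  dims <- vol_dims(v)
  pts <- if (inherits(t, "displacement_field")) {
    if (!identical(t$grid_size, dims))
      stop_propnet("field grid does not match the volume grid",
                   "propnet_shape_error")
    grid_points(dims) + matrix(t$u, ncol = 3)
  } else {
    transform_points(t, grid_points(dims))
  }
  vals <- switch(as.character(order),
    "0" = .sample_nearest(v$data, dims, pts, fill),
    "1" = .sample_linear(v$data, dims, pts, fill),
    "3" = .sample_cubic(.bspline_prefilter3d(v$data, dims), dims, pts, fill),
    stop_propnet("interpolation order must be 0, 1 or 3",
                 "propnet_value_error"))
  volume3d(array(vals, dims), spacing = v$spacing, origin = v$origin,
           is_mask = v$is_mask)
}

#' Warp a binary mask (nearest neighbor)
#'
#' `out(x) = m(round(x + u(x)))`; out-of-grid samples become background.
#'
#' @param m a mask [volume3d].
#' @param t a spatial transform or [displacement_field].
#' @return the warped mask [volume3d].
#' @export
warp_mask <- function(m, t) {
  assert_volume(m, "m")
  if (!m$is_mask)
    stop_propnet("warp_mask expects a mask volume", "propnet_type_error")
  warp_image(m, t, order = 0, fill = 0)
}

# --- deformation-field quality ----------------------------------------------

#' Jacobian determinant of a deformation field
#'
#' Computes `det(I + grad u)` per voxel for the deformation `x -> x + u(x)`,
#' with the gradient taken by central differences in the interior and
#' one-sided differences at the faces, in voxel units. Values below zero mark
#' folding (local loss of injectivity).
#'
#' @param f a [displacement_field] with at least 3 voxels per axis.
#' @return a 3D array of determinants.
#' @export
jacobian_determinant <- function(f) {
  if (!inherits(f, "displacement_field"))
    stop_propnet("`f` must be a displacement field", "propnet_type_error")
  dims <- f$grid_size
  if (any(dims < 3L))
    stop_propnet("Jacobian needs at least 3 voxels per axis",
                 "propnet_shape_error")
  g <- array(0, c(dims, 3, 3))  # g[,,,(component),(axis)]
  for (comp in 1:3)
    for (axis in 1:3)
      g[, , , comp, axis] <- axis_gradient(f$u[, , , comp], axis)
  for (axis in 1:3) g[, , , axis, axis] <- g[, , , axis, axis] + 1
  # explicit 3x3 determinant expansion
  a <- g[, , , 1, 1]; b <- g[, , , 1, 2]; cc <- g[, , , 1, 3]
  d <- g[, , , 2, 1]; e <- g[, , , 2, 2]; ff <- g[, , , 2, 3]
  gg <- g[, , , 3, 1]; h <- g[, , , 3, 2]; i <- g[, , , 3, 3]
  a * (e * i - ff * h) - b * (d * i - ff * gg) + cc * (d * h - e * gg)
}

# central differences inside, one-sided on the faces
axis_gradient <- function(arr, axis) {
  d <- dim(arr)
  n <- d[axis]
  idx_hi <- c(2:n, n); idx_lo <- c(1, 1:(n - 1))
  denom <- rep(2, n); denom[1] <- 1; denom[n] <- 1
  sl <- function(i) switch(axis,
    arr[i, , , drop = FALSE], arr[, i, , drop = FALSE], arr[, , i, drop = FALSE])
  hi <- sl(idx_hi); lo <- sl(idx_lo)
  den <- array(rep(denom, each = prod(d[seq_len(axis - 1)])), d)
  (hi - lo) / den
}

#' Fraction of folded voxels
#'
#' Percentage of voxels whose Jacobian determinant is strictly negative,
#' either over the full grid or inside a region mask (e.g. the prostate).
#'
#' @param f a [displacement_field].
#' @param region optional mask [volume3d] or 0/1 array on the same grid.
#' @return percentage in `[0, 100]`.
#' @export
folding_fraction <- function(f, region = NULL) {
  det <- jacobian_determinant(f)
  if (is.null(region)) return(100 * mean(det < 0))
  rdata <- if (is_volume3d(region)) region$data else region
  if (!identical(dim(rdata), dim(det)))
    stop_propnet("region grid does not match the field grid",
                 "propnet_shape_error")
  sel <- rdata != 0
  if (!any(sel))
    stop_propnet("region is empty", "propnet_region_error")
  100 * mean(det[sel] < 0)
}
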