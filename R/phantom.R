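#' Pelvic phantom specification
#'
#' Parameters of the synthetic "patient": a bright smooth-edged ellipsoidal
#' prostate-like target centered in the field of view, optional bladder and
#' rectum analogs, band-limited background texture and additive noise. The
#' physical field of view is fixed (200 x 200 mm2 in-plane, 115 mm axial, the
#' window the network sees after preprocessing), so the same anatomy is
#' produced at any grid resolution.
#'
#' @param grid output dimensions (scalar or length 3).
#' @param prostate_semiaxes_mm target ellipsoid semi-axes (x, y, z) in mm; the
#'   target must fit inside the central third of the grid.
#' @param bladder,rectum include the distractor structures.
#' @param texture_scale_mm correlation length of the background texture.
#' @param noise_sigma additive Gaussian noise level, as a fraction of the
#'   intensity scale.
#' @param edge_mm width of the smooth target edge.
#' @param spacing_mm voxel spacing; default `c(200, 200, 115) / grid`.
#' @param intensity named list of mean intensity offsets for the structures.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = c(128, 128, 128),
                         prostate_semiaxes_mm = c(25, 20, 18),
                         bladder = TRUE, rectum = TRUE,
                         texture_scale_mm = 8, noise_sigma = 0.02,
                         edge_mm = 2, spacing_mm = NULL,
                         intensity = list(background = 0.45, texture = 0.15,
                                          prostate = 0.25, bladder = 0.35,
                                          rectum = -0.25)) {
  grid <- as.integer(rep(grid, length.out = 3))
  if (is.null(spacing_mm)) spacing_mm <- c(200, 200, 115) / grid
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3)
  if (noise_sigma < 0)
    stop_propnet("noise_sigma must be nonnegative", "propnet_spec_error")
  fov <- grid * spacing_mm
  if (any(2 * prostate_semiaxes_mm > fov / 3))
    stop_propnet("prostate must fit inside the central third of the grid",
                 "propnet_spec_error")
  structure(list(grid = grid, spacing = spacing_mm,
                 prostate_semiaxes = as.numeric(prostate_semiaxes_mm),
                 bladder = isTRUE(bladder), rectum = isTRUE(rectum),
                 texture_scale = texture_scale_mm, noise_sigma = noise_sigma,
                 edge_mm = edge_mm, intensity = intensity),
            class = "phantom_spec")
}

# physical coordinates (mm) of voxel centers relative to the grid center,
# returned as three arrays broadcastable by recycling
phantom_coords <- function(spec) {
  d <- spec$grid; s <- spec$spacing
  list(
    x = array(rep((seq_len(d[1]) - 1 - (d[1] - 1) / 2) * s[1], d[2] * d[3]), d),
    y = array(rep(rep((seq_len(d[2]) - 1 - (d[2] - 1) / 2) * s[2],
                      each = d[1]), d[3]), d),
    z = array(rep((seq_len(d[3]) - 1 - (d[3] - 1) / 2) * s[3],
                  each = d[1] * d[2]), d)
  )
}

# periodic Gaussian smoothing via FFT; sigma in voxels per axis
fft_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  kf <- lapply(1:3, function(a) {
    n <- d[a]
    dist <- pmin(0:(n - 1), n - (0:(n - 1)))
    k <- exp(-0.5 * (dist / max(sigma_vox[a], 1e-6))^2)
    fft(k / sum(k))
  })
  K <- outer(outer(kf[[1]], kf[[2]]), kf[[3]])
  Re(fft(fft(arr) * array(K, d), inverse = TRUE)) / prod(d)
}

# smooth 0..1 profile of an ellipsoid with an edge of width edge_mm
ellipsoid_profile <- function(co, center_mm, semiaxes_mm, edge_mm) {
  q <- sqrt(((co$x - center_mm[1]) / semiaxes_mm[1])^2 +
            ((co$y - center_mm[2]) / semiaxes_mm[2])^2 +
            ((co$z - center_mm[3]) / semiaxes_mm[3])^2)
  r_mm <- (q - 1) * exp(mean(log(semiaxes_mm)))
  1 / (1 + exp(r_mm / max(edge_mm, 1e-6)))
}

#' Generate a phantom image and target mask
#'
#' The image is background texture plus smooth-edged structures; the mask is
#' the exact rasterization of the target ellipsoid (voxel centers inside the
#' ellipsoid). Deterministic given `seed`.
#'
#' @param spec a [phantom_spec].
#' @param seed optional seed.
#' @return `list(image = , mask = )` of [volume3d]s.
#' @export
generate_phantom <- function(spec, seed = NULL) {
  if (!inherits(spec, "phantom_spec"))
    stop_propnet("`spec` must be a phantom_spec", "propnet_spec_error")
  with_seed(seed, {
    d <- spec$grid
    co <- phantom_coords(spec)
    lv <- spec$intensity
    img <- array(lv$background, d)
    if (lv$texture != 0) {
      tex <- fft_smooth(array(rnorm(prod(d)), d),
                        spec$texture_scale / spec$spacing)
      img <- img + lv$texture * tex / max(sd(tex), 1e-12)
    }
    img <- img + lv$prostate *
      ellipsoid_profile(co, c(0, 0, 0), spec$prostate_semiaxes, spec$edge_mm)
    if (spec$bladder)
      img <- img + lv$bladder *
        ellipsoid_profile(co, c(0, 12, -34), c(28, 22, 16), spec$edge_mm)
    if (spec$rectum) {
      rq <- sqrt(((co$x - 0) / 14)^2 + ((co$y + 32) / 14)^2)
      img <- img + lv$rectum / (1 + exp((rq - 1) * 14 / max(spec$edge_mm, 1e-6)))
    }
    if (spec$noise_sigma > 0)
      img <- img + rnorm(prod(d), sd = spec$noise_sigma)
    q <- ((co$x / spec$prostate_semiaxes[1])^2 +
          (co$y / spec$prostate_semiaxes[2])^2 +
          (co$z / spec$prostate_semiaxes[3])^2)
    mask <- array(as.double(q <= 1), d)
    list(image = volume3d(img, spacing = spec$spacing),
         mask = volume3d(mask, spacing = spec$spacing, is_mask = TRUE))
  })
}

#' Generate a phantom patient: pretreatment scan plus daily fractions
#'
#' One underlying anatomy is generated; each fraction is the same anatomy
#' warped by an independent small rigid + free-form deformation emulating
#' inter-fraction variation (bladder filling, setup differences). The bounds
#' default to 0.05 rad rotations with translations and coarse B-spline
#' deformations of 2.5 percent of the grid (3.2 voxels, about 5 mm, on a
#' 128-voxel grid) — the few-millimeter inter-fraction prostate motion
#' reported clinically — so the target stays well within 12.8 voxels of the
#' grid center. The true generating transforms are recorded per fraction.
#'
#' @param spec a [phantom_spec].
#' @param n_fractions number of daily fraction scans (the emulated treatment
#'   course has 20).
#' @param seed optional seed.
#' @param max_angle,max_translation_frac,bspline_amplitude_frac,bspline_grid
#'   inter-fraction motion bounds (fractions are of the smallest grid axis).
#' @return an object of class `patient_record` with elements `pretreatment`
#'   (list image/mask), `fractions` (list of such lists), and `provenance`
#'   (list of the true transforms).
#' @export
generate_patient <- function(spec, n_fractions = 20, seed = NULL,
                             max_angle = 0.05, max_translation_frac = 0.025,
                             bspline_amplitude_frac = 0.025, bspline_grid = 2) {
  if (n_fractions < 1)
    stop_propnet("n_fractions must be at least 1", "propnet_value_error")
  with_seed(seed, {
    base <- generate_phantom(spec)
    g <- min(spec$grid)
    fractions <- list()
    provenance <- list()
    for (f in seq_len(n_fractions)) {
      t_f <- sample_augmentation_transform(
        spec$grid, max_angle = max_angle,
        max_translation = max_translation_frac * g,
        bspline_grid = bspline_grid,
        bspline_amplitude = bspline_amplitude_frac * g)
      fractions[[f]] <- list(image = warp_image(base$image, t_f, order = 3),
                             mask = warp_mask(base$mask, t_f))
      provenance[[f]] <- t_f
    }
    structure(list(pretreatment = base, fractions = fractions,
                   provenance = provenance, spec = spec),
              class = "patient_record")
  })
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> 1 pretreatment + %d fraction scans, grid %s\n",
              length(x$fractions), paste(x$spec$grid, collapse = "x")))
  invisible(x)
}

#' Manufacture one supervised training sample
#'
#' From a normalized image and its target mask on the network grid, draws an
#' augmentation transform `T_augm` (rigid + coarse B-spline) and a multi-scale
#' learned transform `T_learned`, and produces the training pair
#' `I(T_augm)` (moving) and `I(T_augm o T_learned)` (fixed) with matching
#' warped masks. The two transforms are concatenated on coordinates before
#' sampling, so each output image is interpolated exactly once; the
#' supervision target is the dense field of `T_learned` on the network grid.
#' A fresh draw per call means every training iteration sees a unique pair.
#' Cubic interpolation can overshoot slightly; warped intensities are clamped
#' back to `[0, 1]`.
#'
#' Transform amplitudes are defined in voxels of a 128-voxel grid and scaled
#' by `min(grid)/128` so smaller training grids see geometrically equivalent
#' deformations; the per-component field bound (12.0 voxels at 128) scales
#' accordingly and is never exceeded.
#'
#' @param image normalized image [volume3d] (values in `[0, 1]`).
#' @param mask target mask [volume3d] on the same grid.
#' @param seed optional seed.
#' @param amplitude_scale overrides the `min(grid)/128` amplitude scaling.
#' @return an object of class `training_sample` with fields `moving_image`,
#'   `fixed_image`, `moving_mask`, `target_mask`, `target_field`, and the
#'   generating `transforms`.
#' @export
make_training_sample <- function(image, mask, seed = NULL,
                                 amplitude_scale = NULL) {
  assert_volume(image, "image"); assert_volume(mask, "mask")
  assert_same_grid(image, mask)
  if (!mask$is_mask)
    stop_propnet("`mask` must be a mask volume", "propnet_type_error")
  if (min(image$data) < 0 || max(image$data) > 1)
    stop_propnet("image must be normalized to [0, 1]", "propnet_range_error")
  grid <- vol_dims(image)
  sc <- amplitude_scale %||% (min(grid) / 128)
  with_seed(seed, {
    t_augm <- sample_augmentation_transform(
      grid, max_translation = 12.8 * sc, bspline_amplitude = 6.4 * sc)
    t_learned <- sample_learned_transform(
      grid, amplitudes = c(6.4, 3.2, 1.6, 0.8) * sc)
    pts <- grid_points(grid)
    pts_learned <- transform_points(t_learned, pts)
    pts_moving <- transform_points(t_augm, pts)          # T_augm
    pts_fixed <- transform_points(t_augm, pts_learned)   # T_augm o T_learned
    coefs <- .bspline_prefilter3d(image$data, grid)
    sample_img <- function(p) {
      v <- .sample_cubic(coefs, grid, p, 0)
      array(pmin(pmax(v, 0), 1), grid)
    }
    sample_msk <- function(p) array(.sample_nearest(mask$data, grid, p, 0), grid)
    mk_vol <- function(a, is_mask = FALSE)
      volume3d(a, spacing = image$spacing, origin = image$origin,
               is_mask = is_mask)
    structure(list(
      moving_image = mk_vol(sample_img(pts_moving)),
      fixed_image = mk_vol(sample_img(pts_fixed)),
      moving_mask = mk_vol(sample_msk(pts_moving), is_mask = TRUE),
      target_mask = mk_vol(sample_msk(pts_fixed), is_mask = TRUE),
      target_field = displacement_field(array(pts_learned - pts, c(grid, 3))),
      transforms = list(augmentation = t_augm, learned = t_learned)
    ), class = "training_sample")
  })
}
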