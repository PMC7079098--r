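test_that("intensity normalization maps the range onto [0, 1] affinely", {
  vals <- rep(c(10, 12.5, 15, 17.5, 20), length.out = 4^3)
  v <- volume3d(array(vals, c(4, 4, 4)))
  n <- normalize_intensities(v)
  expect_equal(range(n$data), c(0, 1))
  expect_equal(n$data[which(v$data == 15)][1], 0.5)
  # already normalized input is unchanged
  expect_equal(normalize_intensities(n)$data, n$data, tolerance = 1e-15)
  # constant volume maps to zeros
  const <- volume3d(array(7, c(4, 4, 4)))
  expect_equal(normalize_intensities(const)$data, array(0, c(4, 4, 4)))
  # masks are rejected
  m <- volume3d(array(1, c(4, 4, 4)), is_mask = TRUE)
  expect_error(normalize_intensities(m), class = "propnet_type_error")
})

test_that("axial cropping keeps the mask extent plus the margin", {
  img <- volume3d(array(runif(4 * 4 * 100), c(4, 4, 100)))
  occ <- array(0, c(4, 4, 100)); occ[, , 41:61] <- 1
  mask <- volume3d(occ, is_mask = TRUE)
  cropped <- crop_axial_roi(img, mask, margin_mm = 30)
  expect_equal(dim(cropped$data)[3], 81)              # slices 10..90 (0-based)
  expect_equal(cropped$data[, , 1], img$data[, , 11])
  expect_equal(cropped$origin[3], img$origin[3] + 10)
  # zero margin keeps exactly the occupied slices
  expect_equal(dim(crop_axial_roi(img, mask, 0)$data)[3], 21)
  # clipping at the volume boundary
  occ2 <- array(0, c(4, 4, 50)); occ2[, , 1:6] <- 1
  img2 <- volume3d(array(0, c(4, 4, 50)))
  expect_equal(dim(crop_axial_roi(img2, volume3d(occ2, is_mask = TRUE),
                                  30)$data)[3], 36)   # slices 0..35
  expect_error(crop_axial_roi(img, volume3d(array(0, c(4, 4, 100)),
                                            is_mask = TRUE)),
               class = "propnet_roi_error")
})

test_that("resampling with the clinical acquisition geometry gives the 200 mm / 1.5625 mm network window", {
  # 480 x 480 in-plane voxels over a 400 mm field of view, crop factor 2
  vin <- volume3d(array(runif(480 * 480 * 8), c(480, 480, 8)),
                  spacing = c(400 / 480, 400 / 480, 4))
  spec <- network_grid_spec(size = c(128, 128, 8), in_plane_scale = 2,
                            axial_scale = 1.33)
  out <- resample_to_network_grid(vin, spec)
  expect_equal(out$spacing[1], 1.5625)
  expect_equal(out$spacing[1] * 128, 200)
  expect_equal(dim(out$data), c(128L, 128L, 8L))
})

test_that("identity resampling reproduces the input and masks stay binary", {
  set.seed(31)
  v <- volume3d(array(runif(16^3), c(16, 16, 16)))
  spec <- network_grid_spec(size = 16, in_plane_scale = 1, axial_scale = 1)
  out <- resample_to_network_grid(v, spec)
  expect_equal(out$data, v$data, tolerance = 1e-8)
  expect_equal(out$spacing, v$spacing)
  m <- random_mask_volume(16, seed = 32)
  rm <- resample_to_network_grid(m, network_grid_spec(size = 16,
                                                      in_plane_scale = 1.5,
                                                      axial_scale = 1))
  expect_true(all(rm$data %in% c(0, 1)))
  expect_true(rm$is_mask)
})

test_that("downscale then upscale reproduces a band-limited image", {
  d <- 32
  v <- volume3d(smooth_phantom_array(d))
  spec_dn <- network_grid_spec(size = d, in_plane_scale = 2, axial_scale = 2)
  dn <- resample_to_network_grid(v, spec_dn)
  # invert the scaling: sample the cropped volume back onto the original grid
  ctr <- (d - 1) / 2
  # original voxel i sits at resampled-grid coordinate ctr + 2 * (i - ctr)
  ax <- ctr + ((seq_len(d) - 1) - ctr) * 2
  pts <- as.matrix(expand.grid(ax, ax, ax))[, c(1, 2, 3)]
  coefs <- propnet:::.bspline_prefilter3d(dn$data, dim(dn$data))
  back <- propnet:::.sample_cubic(coefs, dim(dn$data), pts, 0)
  # the central half of the original grid was preserved by the crop
  orig <- v$data
  keep <- which(abs(propnet:::grid_points(c(d, d, d)) - ctr)[, 1] <= d / 4 &
                abs(propnet:::grid_points(c(d, d, d)) - ctr)[, 2] <= d / 4 &
                abs(propnet:::grid_points(c(d, d, d)) - ctr)[, 3] <= d / 4)
  expect_lt(max(abs(back[keep] - orig[keep])), 1e-2)
})

test_that("grid spec validates sizes and scales", {
  expect_error(network_grid_spec(size = 100), class = "propnet_value_error")
  expect_error(network_grid_spec(size = 4), class = "propnet_value_error")
  expect_error(network_grid_spec(in_plane_scale = 0.5),
               class = "propnet_value_error")
  s <- network_grid_spec()
  expect_equal(s$size, c(128L, 128L, 128L))
  expect_equal(s$axial_margin_mm, 30)
})
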