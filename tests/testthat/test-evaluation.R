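test_that("Dice coefficient covers the standard and degenerate cases", {
  a <- random_mask_volume(8, seed = 81)
  expect_equal(dice_coefficient(a, a), 1)
  empty <- volume3d(array(0, c(8, 8, 8)), is_mask = TRUE)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
  # worked example: two 2x2x2 cubes sharing a 1x2x2 slab
  ca <- array(0, c(6, 6, 6)); ca[2:3, 2:3, 2:3] <- 1
  cb <- array(0, c(6, 6, 6)); cb[3:4, 2:3, 2:3] <- 1
  expect_equal(dice_coefficient(ca, cb), 0.5)
  expect_equal(dice_coefficient(cb, ca), 0.5)
  expect_error(dice_coefficient(a, volume3d(array(0, c(4, 4, 4)))),
               class = "propnet_shape_error")
})

test_that("HD95 and centroid distance match brute-force oracles on random masks", {
  for (s in 1:6) {
    sp <- c(1.1, 0.9, 1.7)
    a <- random_mask_volume(10, seed = 820 + s, spacing = sp)
    b <- random_mask_volume(10, seed = 840 + s, spacing = sp)
    expect_equal(hausdorff_95(a, b), oracle_hd(a$data, b$data, sp, 95),
                 tolerance = 1e-9)
    # symmetry
    expect_equal(hausdorff_95(a, b), hausdorff_95(b, a), tolerance = 1e-12)
    # exact Hausdorff bounds the 95th percentile
    expect_lte(hausdorff_95(a, b),
               hausdorff_95(a, b, percentile = 100) + 1e-12)
    # centroid oracle by explicit moment sums
    ia <- which(a$data != 0, arr.ind = TRUE); ib <- which(b$data != 0, arr.ind = TRUE)
    ora <- sqrt(sum(((colSums(ia) / nrow(ia) - colSums(ib) / nrow(ib)) * sp)^2))
    expect_equal(centroid_distance(a, b), ora, tolerance = 1e-9)
    expect_equal(centroid_distance(a, b), centroid_distance(b, a))
  }
})

test_that("distance metrics behave analytically on constructed masks", {
  a <- array(0, c(12, 12, 12)); a[3, 3, 3] <- 1
  b <- array(0, c(12, 12, 12)); b[8, 3, 3] <- 1
  va <- volume3d(a, is_mask = TRUE); vb <- volume3d(b, is_mask = TRUE)
  expect_equal(hausdorff_95(va, vb), 5)        # two voxels 5 mm apart
  expect_equal(hausdorff_95(va, va), 0)
  expect_equal(centroid_distance(va, va), 0)
  # 3-4-5 triangle
  c2 <- array(0, c(12, 12, 12)); c2[6, 7, 3] <- 1
  expect_equal(centroid_distance(va, volume3d(c2, is_mask = TRUE)), 5)
  expect_error(hausdorff_95(va, volume3d(array(0, c(12, 12, 12)),
                                         is_mask = TRUE)),
               class = "propnet_metric_error")
  # translation invariance under simultaneous integer shifts
  sh <- function(m) { o <- array(0, dim(m)); o[, , 2:12] <- m[, , 1:11]; o }
  a2 <- random_mask_volume(12, seed = 86)$data
  b2 <- random_mask_volume(12, seed = 87)$data
  expect_equal(hausdorff_95(volume3d(a2, is_mask = TRUE),
                            volume3d(b2, is_mask = TRUE)),
               hausdorff_95(volume3d(sh(a2), is_mask = TRUE),
                            volume3d(sh(b2), is_mask = TRUE)),
               tolerance = 1e-12)
})

test_that("evaluate_case assembles the full metric row", {
  a <- random_mask_volume(12, seed = 88)
  z <- displacement_field(array(0, c(12, 12, 12, 3)))
  row <- evaluate_case(a, a, z)
  expect_equal(row$dice, 1)
  expect_equal(row$hd95, 0)
  expect_equal(row$centroid_mm, 0)
  expect_equal(row$folding_fov, 0)
  expect_equal(row$folding_prostate, 0)
  # composition contract: same numbers as calling the metric ops directly
  b <- random_mask_volume(12, seed = 89)
  row2 <- evaluate_case(a, b, NULL, case = list(patient = 1))
  expect_equal(row2$dice, dice_coefficient(a, b))
  expect_equal(row2$hd95, hausdorff_95(a, b))
  expect_equal(row2$centroid_mm, centroid_distance(a, b))
  expect_equal(row2$patient, 1)
  # reflection field folds everywhere
  pts <- propnet:::grid_points(c(12, 12, 12))
  refl <- displacement_field(array(c(-2 * pts[, 1], numeric(2 * 12^3)),
                                   c(12, 12, 12, 3)))
  expect_equal(evaluate_case(a, b, refl)$folding_fov, 100)
  # empty propagated mask: dice 0, distances undefined
  row3 <- evaluate_case(volume3d(array(0, c(12, 12, 12)), is_mask = TRUE), b)
  expect_equal(row3$dice, 0)
  expect_true(is.na(row3$hd95) && is.na(row3$centroid_mm))
})

test_that("the shift experiment produces one row per shift with exact zero-shift equality", {
  spec <- phantom_spec(grid = 16)
  pat <- generate_patient(spec, n_fractions = 2, seed = 90)
  cfg <- unet_config(levels = 2, input_size = 16, base_features = 2,
                     feature_cap = 4)
  model <- init_model(cfg, seed = 91)
  # 16^3 phantom slices are 7.2 mm thick; use super-voxel shifts so the
  # nearest-neighbor resampled mask actually moves
  res <- shift_experiment(model, pat, shifts_mm = c(-8, 0, 8))
  expect_equal(nrow(res$summary), 3)
  expect_equal(res$summary$shift_mm, c(-8, 0, 8))
  # shift 0 must equal the unshifted pipeline bit-for-bit
  gspec <- network_grid_spec(size = 16, in_plane_scale = 1, axial_scale = 1)
  pre_img <- normalize_intensities(resample_to_network_grid(
    pat$pretreatment$image, gspec))
  pre_mask <- resample_to_network_grid(pat$pretreatment$mask, gspec)
  fr <- pat$fractions[[1]]
  direct <- propagate(model, pre_img, pre_mask,
                      normalize_intensities(resample_to_network_grid(fr$image,
                                                                     gspec)))
  row0 <- res$per_case[res$per_case$shift_mm == 0 &
                         res$per_case$fraction == 1, ]
  ref <- evaluate_case(direct$mask, resample_to_network_grid(fr$mask, gspec),
                       direct$field)
  expect_identical(row0$dice, ref$dice)
  expect_identical(row0$hd95, ref$hd95)
  # an identity model under a +8 mm shift degrades HD95 relative to shift 0
  s0 <- res$summary$hd95_mean[res$summary$shift_mm == 0]
  s3 <- res$summary$hd95_mean[res$summary$shift_mm == 8]
  expect_gt(s3, s0)
  expect_error(shift_experiment(model, pat, shifts_mm = 1000),
               class = "propnet_geometry_error")
})

test_that("the cross-validation harness splits patients correctly", {
  spec <- phantom_spec(grid = 16)
  patients <- lapply(1:3, function(p)
    generate_patient(spec, n_fractions = 1, seed = 92 + p))
  cfg <- unet_config(levels = 2, input_size = 16, base_features = 2,
                     feature_cap = 4)
  res <- crossval_harness(patients, cfg, progressive_schedule(2, 2),
                          loss_preset("deformation"), iterations = 4,
                          seed = 93)
  expect_equal(sort(unique(res$per_case$test_patient)), 1:3)
  expect_equal(sort(unique(res$per_case$validation_patient)), 1:3)
  # every patient appears exactly once as test and once as validation
  expect_equal(unname(table(res$per_case$test_patient)), rep(1L, 3),
               ignore_attr = TRUE)
  by_fold <- unique(res$per_case[, c("fold", "test_patient",
                                     "validation_patient")])
  expect_true(all(by_fold$test_patient != by_fold$validation_patient))
  expect_equal(nrow(res$summary), 5)
  expect_error(crossval_harness(patients[1:2], cfg, progressive_schedule(2, 2),
                                loss_preset("overlap"), 1),
               class = "propnet_split_error")
  # pooled mean of a constant metric equals that constant
  expect_equal(res$summary$mean[res$summary$metric == "dice"],
               mean(res$per_case$dice))
})
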