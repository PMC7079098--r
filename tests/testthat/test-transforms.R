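test_that("sampled transform parameters respect their uniform bounds and seeds", {
  ext <- c(32, 32, 32)
  t1 <- sample_bspline(2, 6.4, ext, seed = 41)
  expect_equal(dim(t1$coefficients), c(2L, 2L, 2L, 3L))
  expect_true(all(abs(t1$coefficients) <= 6.4))
  expect_identical(sample_bspline(2, 6.4, ext, seed = 41)$coefficients,
                   t1$coefficients)
  expect_error(sample_bspline(1, 1, ext), class = "propnet_lattice_error")
  # zero amplitude is the identity
  z <- to_dense_field(sample_bspline(2, 0, ext, seed = 1), ext)
  expect_equal(max(abs(z$u)), 0)
  # learned transform lattice structure
  tl <- sample_learned_transform(ext, seed = 42)
  expect_length(tl$components, 4)
  expect_equal(t(vapply(tl$components, function(c) c$grid_size, integer(3))),
               matrix(rep(c(2, 4, 8, 16), 3), 4, 3), ignore_attr = TRUE)
  # augmentation bounds over many draws
  draws <- lapply(1:200, function(i) sample_augmentation_transform(ext, seed = i))
  angles <- t(vapply(draws, function(d) d$components[[1]]$angles, numeric(3)))
  trans <- t(vapply(draws, function(d) d$components[[1]]$translation, numeric(3)))
  expect_true(all(abs(angles) <= 0.1))
  expect_true(all(abs(trans) <= 12.8))
  expect_true(all(abs(draws[[5]]$components[[2]]$coefficients) <= 6.4))
})

test_that("dense B-spline fields match direct basis summation and are linear in coefficients", {
  ext <- c(9, 9, 9)
  coef <- array(0, c(3, 3, 3, 3))
  coef[2, 1, 3, 1] <- 2.5
  coef[1, 2, 2, 3] <- -1.25
  tb <- bspline_transform(coef, ext)
  fld <- to_dense_field(tb, ext)
  pts <- propnet:::grid_points(ext)
  for (r in sample.int(nrow(pts), 20)) {
    expect_equal(fld$u[pts[r, 1] + 1, pts[r, 2] + 1, pts[r, 3] + 1, ],
                 oracle_ffd_point(coef, ext, pts[r, ]), tolerance = 1e-9)
  }
  # superposition
  ca <- array(rnorm(81), c(3, 3, 3, 3)); cb <- array(rnorm(81), c(3, 3, 3, 3))
  fa <- to_dense_field(bspline_transform(ca, ext), ext)$u
  fb <- to_dense_field(bspline_transform(cb, ext), ext)$u
  fab <- to_dense_field(bspline_transform(ca + cb, ext), ext)$u
  expect_equal(fab, fa + fb, tolerance = 1e-9)
})

test_that("dense fields of identity, translation and scaling behave analytically", {
  ext <- c(8, 8, 8)
  expect_equal(max(abs(to_dense_field(rigid_transform(extent = ext), ext)$u)), 0)
  tr <- to_dense_field(rigid_transform(translation = c(2, 0, 0),
                                       extent = ext), ext)
  expect_equal(tr$u[, , , 1], array(2, ext))
  expect_equal(max(abs(tr$u[, , , 2:3])), 0)
  # center-anchored scaling by s has Jacobian determinant prod(s)
  sc <- to_dense_field(scaling_transform(c(1.2, 1.1, 0.9), ext), ext)
  det <- jacobian_determinant(sc)
  expect_equal(det[3:6, 3:6, 3:6], array(1.2 * 1.1 * 0.9, c(4, 4, 4)),
               tolerance = 1e-9)
})

test_that("warping matches brute-force per-voxel oracles", {
  set.seed(44)
  d <- c(8, 8, 8)
  img <- volume3d(array(runif(prod(d)), d))
  u <- array(rnorm(prod(d) * 3, sd = 1.2), c(d, 3))
  fld <- displacement_field(u)
  w1 <- warp_image(img, fld, order = 1)
  expect_equal(w1$data, oracle_warp_linear(img$data, u), tolerance = 1e-10)
  mk <- random_mask_volume(8, seed = 45)
  wm <- warp_mask(mk, fld)
  expect_identical(wm$data, oracle_warp_nearest(mk$data, u))
  expect_true(all(wm$data %in% c(0, 1)))
  # zero field reproduces inputs exactly (all orders)
  z <- displacement_field(array(0, c(d, 3)))
  expect_identical(warp_mask(mk, z)$data, mk$data)
  expect_equal(warp_image(img, z, order = 3)$data, img$data, tolerance = 1e-8)
  # constant +2 shift along x: out(x) = in(x + 2)
  tr <- rigid_transform(translation = c(2, 0, 0), extent = d)
  sh <- warp_image(img, tr, order = 1)
  expect_equal(sh$data[1:6, , ], img$data[3:8, , ], tolerance = 1e-12)
  expect_equal(sh$data[7:8, , ], array(0, c(2, 8, 8)))  # fill
  # integer translations shift masks exactly
  shm <- warp_mask(mk, tr)
  expect_identical(shm$data[1:6, , ], mk$data[3:8, , ])
  # masks reject smooth interpolation
  expect_error(warp_image(mk, z, order = 3), class = "propnet_type_error")
  expect_error(warp_mask(img, z), class = "propnet_type_error")
})

test_that("field composition realizes sequential warping", {
  d <- c(16, 16, 16)
  # translations compose exactly and everywhere
  fa <- to_dense_field(rigid_transform(translation = c(1.5, -0.75, 0.5),
                                       extent = d), d)
  fb <- to_dense_field(rigid_transform(translation = c(0.25, 2, -1),
                                       extent = d), d)
  comp <- compose_fields(fa, fb)
  expect_equal(comp$u[, , , 1], array(1.75, d), tolerance = 1e-12)
  expect_equal(comp$u[, , , 2], array(1.25, d), tolerance = 1e-12)
  expect_equal(comp$u[, , , 3], array(-0.5, d), tolerance = 1e-12)
  # zero inner leaves the outer unchanged
  z <- displacement_field(array(0, c(d, 3)))
  expect_equal(compose_fields(fa, z)$u, fa$u, tolerance = 1e-12)
  # smooth phantom: warp once by the composition == warp outer then inner
  img24 <- volume3d(smooth_phantom_array(24))
  f_out <- smooth_field(24, 1.0, seed = 46)
  f_in <- smooth_field(24, 0.8, seed = 47)
  w_once <- warp_image(img24, compose_fields(f_out, f_in), order = 3)
  w_seq <- warp_image(warp_image(img24, f_out, order = 3), f_in, order = 3)
  interior <- 6:19
  expect_lt(max(abs(w_once$data[interior, interior, interior] -
                    w_seq$data[interior, interior, interior])), 1e-2)
  expect_error(compose_fields(fa, displacement_field(array(0, c(8, 8, 8, 3)))),
               class = "propnet_shape_error")
})

test_that("parametric composition warps with a single interpolation", {
  # composite of parametric transforms equals the exactly composed mapping
  d <- c(12, 12, 12)
  rig <- rigid_transform(angles = c(0.05, -0.03, 0.08),
                         translation = c(1, -0.5, 0.25), extent = d)
  bsp <- sample_bspline(2, 1.5, d, seed = 48)
  comp <- composite_transform(rig, bsp)
  pts <- propnet:::grid_points(d)
  expect_equal(transform_points(comp, pts),
               transform_points(rig, transform_points(bsp, pts)),
               tolerance = 1e-12)
})

test_that("Jacobian determinants and folding fractions are analytic on known fields", {
  d <- c(8, 8, 8)
  z <- displacement_field(array(0, c(d, 3)))
  expect_equal(jacobian_determinant(z), array(1, d))
  expect_equal(folding_fraction(z), 0)
  # ux = 0.1 * x -> det 1.1 on interior voxels
  pts <- propnet:::grid_points(d)
  lin <- displacement_field(array(c(0.1 * pts[, 1], numeric(2 * prod(d))),
                                  c(d, 3)))
  det <- jacobian_determinant(lin)
  expect_equal(det[2:7, , ], array(1.1, c(6, 8, 8)), tolerance = 1e-9)
  # reflection ux = -2x -> det -1 everywhere, 100% folding
  refl <- displacement_field(array(c(-2 * pts[, 1], numeric(2 * prod(d))),
                                   c(d, 3)))
  expect_equal(jacobian_determinant(refl), array(-1, d), tolerance = 1e-9)
  expect_equal(folding_fraction(refl), 100)
  # piecewise fold: ux = -2 * min(x, 4) has slope -2 (det -1) for x <= 3 and
  # slope 0 (det 1) beyond, under the central/one-sided difference scheme
  ux <- -2 * pmin(pts[, 1], 4)
  half <- displacement_field(array(c(ux, numeric(2 * prod(d))), c(d, 3)))
  deth <- jacobian_determinant(half)
  region <- array(as.double(pts[, 1] < 4), d)
  expect_equal(folding_fraction(half, region), 100)
  expect_equal(100 * mean(deth < 0), folding_fraction(half))
  expect_error(folding_fraction(z, array(0, d)),
               class = "propnet_region_error")
  # pure translations always have unit Jacobian
  tr <- to_dense_field(rigid_transform(translation = c(3.3, -1.2, 0.4),
                                       extent = d), d)
  expect_equal(jacobian_determinant(tr), array(1, d), tolerance = 1e-9)
})

test_that("composite fields of the learned transform respect the amplitude bound", {
  # triangle inequality: |u| <= 6.4 + 3.2 + 1.6 + 0.8 = 12 voxels per component
  ext <- c(16, 16, 16)
  worst <- 0
  for (s in 1:50) {
    tl <- sample_learned_transform(ext, seed = 500 + s)
    fld <- to_dense_field(tl, ext)
    worst <- max(worst, max(abs(fld$u)))
  }
  expect_lte(worst, 12.0)
})
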