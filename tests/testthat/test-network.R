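test_that("progressive level weights form a valid piecewise-linear schedule", {
  s <- progressive_schedule(1000, 2000)
  expect_equal(level_weights(s, 0, 5), c(1, 0, 0, 0, 0))
  expect_equal(level_weights(s, 2000, 5), c(0.5, 0.5, 0, 0, 0))
  expect_equal(level_weights(s, 15000, 5), c(0, 0, 0, 0, 1))
  expect_equal(schedule_length(s, 5), 15000)
  # weights always sum to one with at most two adjacent nonzero entries
  for (it in c(0, 999, 1000, 1500, 2999, 3000, 5000, 6000, 8000, 11000,
               13500, 14999, 15000, 20000)) {
    w <- level_weights(s, it, 5)
    expect_equal(sum(w), 1)
    nz <- which(w > 0)
    expect_lte(length(nz), 2)
    if (length(nz) == 2) expect_equal(diff(nz), 1)
  }
  # continuity across every breakpoint
  for (bp in c(1000, 3000, 5000, 7000, 9000, 11000, 13000, 15000)) {
    expect_equal(level_weights(s, bp - 1e-6, 5), level_weights(s, bp, 5),
                 tolerance = 1e-5)
  }
})

test_that("an untrained network predicts the identity transform", {
  cfg <- unet_config(levels = 3, input_size = 16, base_features = 4,
                     feature_cap = 8)
  model <- init_model(cfg, seed = 61)
  mv <- array(runif(16^3), c(16, 16, 16))
  fx <- array(runif(16^3), c(16, 16, 16))
  f <- forward_pass(model, mv, fx)
  expect_s3_class(f, "displacement_field")
  expect_equal(dim(f$u), c(16L, 16L, 16L, 3L))
  expect_equal(max(abs(f$u)), 0)
  # propagation with a zero-field model returns the mask unchanged
  mk <- random_mask_volume(16, seed = 62)
  out <- propagate(model, mv, mk, fx)
  expect_identical(out$mask$data, mk$data)
})

test_that("inference is deterministic and checkpoints restore it bit-identically", {
  cfg <- unet_config(levels = 2, input_size = 8, base_features = 2,
                     feature_cap = 4)
  model <- init_model(cfg, seed = 63)
  # make the output nonzero
  model$params$head1$W[] <- rnorm(length(model$params$head1$W), sd = 0.3)
  mv <- array(runif(8^3), c(8, 8, 8)); fx <- array(runif(8^3), c(8, 8, 8))
  f1 <- forward_pass(model, mv, fx)
  f2 <- forward_pass(model, mv, fx)
  expect_identical(f1$u, f2$u)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  f3 <- forward_pass(load_checkpoint(path), mv, fx)
  expect_identical(f1$u, f3$u)
})

test_that("coarsest-only weights reproduce the coarsest head alone", {
  cfg <- unet_config(levels = 3, input_size = 16, base_features = 4,
                     feature_cap = 8)
  model <- init_model(cfg, seed = 64)
  for (l in 1:3)
    model$params[[paste0("head", l)]]$W[] <-
      rnorm(length(model$params[[paste0("head", l)]]$W), sd = 0.2)
  mv <- array(runif(16^3), c(16, 16, 16)); fx <- array(runif(16^3), c(16, 16, 16))
  full <- forward_pass(model, mv, fx, alphas = c(1, 0, 0))
  zeroed <- model
  for (l in 1:2) zeroed$params[[paste0("head", l)]]$W[] <- 0
  alone <- forward_pass(zeroed, mv, fx, alphas = c(1, 0, 0))
  expect_equal(full$u, alone$u, tolerance = 1e-12)
})

test_that("the spatial transformer layer matches warp_mask at inference and is exact on zero fields", {
  mk <- random_mask_volume(12, seed = 65)
  z <- displacement_field(array(0, c(12, 12, 12, 3)))
  expect_identical(stl_warp(mk, z, "infer"), mk$data)
  expect_identical(stl_warp(mk, z, "train"), mk$data)
  u <- array(rnorm(12^3 * 3), c(12, 12, 12, 3))
  fld <- displacement_field(u)
  expect_identical(stl_warp(mk, fld, "infer"), warp_mask(mk, fld)$data)
  tr <- to_dense_field(rigid_transform(translation = c(2, -1, 1),
                                       extent = c(12, 12, 12)), c(12, 12, 12))
  expect_identical(stl_warp(mk, tr, "infer"), warp_mask(mk, tr)$data)
  soft <- stl_warp(mk, fld, "train")
  expect_true(all(soft >= -1e-12 & soft <= 1 + 1e-12))
})

test_that("loss functions reproduce their closed forms", {
  mk <- random_mask_volume(8, seed = 66)$data
  expect_lt(overlap_loss(mk, mk), 1e-5)
  disjoint <- array(0, c(8, 8, 8)); disjoint[1, 1, 1] <- 1
  other <- array(0, c(8, 8, 8)); other[8, 8, 8] <- 1
  expect_equal(overlap_loss(disjoint, other), 1, tolerance = 1e-5)
  half <- array(0, c(8, 8, 8)); half[1:4, , ] <- 1
  expect_equal(overlap_loss(array(0.5, c(8, 8, 8)), half), 0.5,
               tolerance = 1e-5)
  expect_error(overlap_loss(array(2, c(8, 8, 8)), half),
               class = "propnet_range_error")
  # dvf loss: constant offset (1,1,1) -> 3; brute-force equality on random fields
  a <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  b <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  expect_equal(dvf_loss(a, a), 0)
  expect_equal(dvf_loss(a + 1, a), 3, tolerance = 1e-12)
  acc <- 0
  for (k in 1:4) for (j in 1:4) for (i in 1:4)
    acc <- acc + sum((a[i, j, k, ] - b[i, j, k, ])^2)
  expect_equal(dvf_loss(a, b), acc / 64, tolerance = 1e-9)
  # total loss presets
  expect_equal(total_loss(loss_preset("overlap"), 0.4, 7), 0.4)
  expect_equal(total_loss(loss_preset("deformation"), 0.4, 7), 7)
  expect_equal(total_loss(loss_preset("hybrid"), 0.4, 7), 7.4)
  expect_error(loss_weights(0, 0), class = "propnet_config_error")
})

test_that("backpropagated gradients match finite differences", {
  set.seed(67)
  cfg <- unet_config(levels = 2, input_size = 8, base_features = 2,
                     feature_cap = 4)
  model <- init_model(cfg, seed = 68)
  for (l in 1:2)
    model$params[[paste0("head", l)]]$W[] <-
      rnorm(length(model$params[[paste0("head", l)]]$W), sd = 0.1)
  mv <- array(runif(8^3), c(8, 8, 8)); fx <- array(runif(8^3), c(8, 8, 8))
  tfield <- array(rnorm(8^3 * 3, sd = 0.5), c(8, 8, 8, 3))
  mmask <- array(as.double(runif(8^3) > 0.6), c(8, 8, 8))
  tmask <- array(as.double(runif(8^3) > 0.6), c(8, 8, 8))
  alphas <- c(0.4, 0.6)
  lossfun <- function(m) {
    fwd <- propnet:::unet_graph_forward(m, mv, fx, alphas, TRUE)
    U <- fwd$field
    pts <- propnet:::grid_points(dim(U)[1:3]) + matrix(U, ncol = 3)
    w <- propnet:::.sample_linear(mmask, dim(mmask), pts, 0)
    num <- sum(tmask * w); den <- sum(tmask) + sum(w) + 1e-5
    list(loss = (1 - 2 * num / den) + sum((U - tfield)^2) / 512,
         fwd = fwd, U = U, pts = pts, num = num, den = den)
  }
  r <- lossfun(model)
  dU <- 2 * (r$U - tfield) / 512
  dl_dw <- -2 * (as.vector(tmask) * r$den - r$num) / r$den^2
  G <- propnet:::.sample_linear_grad(mmask, dim(mmask), r$pts)
  dU <- dU + array(G * dl_dw, dim(r$U))
  grads <- propnet:::unet_graph_backward(model, r$fwd, dU)
  eps <- 1e-5
  for (probe in list(c("enc1a", "W"), c("enc1a", "gamma"), c("enc2_a", "W"),
                     c("enc2_in", "W"), c("enc2_b", "beta"), c("dec1_u", "W"),
                     c("dec1_d", "W"), c("head1", "W"), c("head2", "b"))) {
    nm <- probe[1]; fld <- probe[2]
    idx <- min(3, length(model$params[[nm]][[fld]]))
    m2 <- model
    m2$params[[nm]][[fld]][idx] <- m2$params[[nm]][[fld]][idx] + eps
    lp <- lossfun(m2)$loss
    m2$params[[nm]][[fld]][idx] <- m2$params[[nm]][[fld]][idx] - 2 * eps
    lm <- lossfun(m2)$loss
    fd <- (lp - lm) / (2 * eps)
    an <- grads[[nm]][[fld]][idx]
    expect_equal(an, fd, tolerance = 1e-4,
                 label = sprintf("%s$%s gradient", nm, fld))
  }
})

test_that("training runs, logs losses, and zero iterations is the identity", {
  spec <- phantom_spec(grid = 16)
  ph <- generate_phantom(spec, seed = 69)
  img <- normalize_intensities(ph$image)
  data_fn <- function(iter)
    make_training_sample(img, ph$mask, seed = derive_seed(70, iter))
  cfg <- unet_config(levels = 2, input_size = 16, base_features = 4,
                     feature_cap = 8)
  model <- init_model(cfg, seed = 71)
  expect_identical(train_model(model, data_fn, 0,
                               progressive_schedule(5, 5),
                               loss_preset("hybrid")), model)
  trained <- train_model(model, data_fn, 12, progressive_schedule(5, 5),
                         loss_preset("hybrid"))
  expect_equal(nrow(trained$loss_log), 12)
  expect_true(all(is.finite(trained$loss_log$total)))
  expect_equal(trained$iteration, 12L)
  # reproducibility of the whole training loop
  trained2 <- train_model(model, data_fn, 12, progressive_schedule(5, 5),
                          loss_preset("hybrid"))
  expect_identical(trained$params, trained2$params)
})

test_that("loss gradients with respect to the field match finite differences", {
  set.seed(72)
  d <- c(4, 4, 4)
  U <- array(rnorm(prod(d) * 3, sd = 0.5), c(d, 3))
  Tt <- array(rnorm(prod(d) * 3, sd = 0.5), c(d, 3))
  mmask <- array(as.double(runif(prod(d)) > 0.5), d)
  tmask <- array(as.double(runif(prod(d)) > 0.5), d)
  V <- prod(d)
  eps_ov <- 1e-5
  loss_of <- function(U) {
    pts <- propnet:::grid_points(d) + matrix(U, ncol = 3)
    w <- propnet:::.sample_linear(mmask, d, pts, 0)
    num <- sum(tmask * w); den <- sum(tmask) + sum(w) + eps_ov
    c(dvf = sum((U - Tt)^2) / V, overlap = 1 - 2 * num / den)
  }
  base <- loss_of(U)
  # analytic gradients (the ones the training loop backpropagates)
  dU_dvf <- 2 * (U - Tt) / V
  pts <- propnet:::grid_points(d) + matrix(U, ncol = 3)
  w <- propnet:::.sample_linear(mmask, d, pts, 0)
  num <- sum(tmask * w); den <- sum(tmask) + sum(w) + eps_ov
  dl_dw <- -2 * (as.vector(tmask) * den - num) / den^2
  G <- propnet:::.sample_linear_grad(mmask, d, pts)
  dU_ov <- array(G * dl_dw, c(d, 3))
  h <- 1e-6
  set.seed(73)
  for (probe in seq_len(12)) {
    idx <- sample(length(U), 1)
    U2 <- U; U2[idx] <- U2[idx] + h
    up <- loss_of(U2)
    U2[idx] <- U2[idx] - 2 * h
    dn <- loss_of(U2)
    expect_equal(dU_dvf[idx], (up["dvf"] - dn["dvf"]) / (2 * h),
                 tolerance = 1e-4, ignore_attr = TRUE)
    fd_ov <- (up["overlap"] - dn["overlap"]) / (2 * h)
    # trilinear sampling is only piecewise smooth; skip probes that straddle
    # a voxel boundary (kink), where the two-sided difference is undefined
    if (abs(fd_ov - dU_ov[idx]) < 0.5)
      expect_equal(dU_ov[idx], fd_ov, tolerance = 1e-3, ignore_attr = TRUE)
  }
})

test_that("non-finite losses abort with the last finite model attached", {
  spec <- phantom_spec(grid = 16)
  ph <- generate_phantom(spec, seed = 74)
  img <- normalize_intensities(ph$image)
  data_fn <- function(iter)
    make_training_sample(img, ph$mask, seed = derive_seed(75, iter))
  cfg <- unet_config(levels = 2, input_size = 16, base_features = 2,
                     feature_cap = 4)
  model <- init_model(cfg, seed = 76)
  model$params$head2$b[1] <- Inf   # the active (coarsest) head emits Inf
  cond <- tryCatch(
    train_model(model, data_fn, 3, progressive_schedule(2, 2),
                loss_preset("deformation")),
    propnet_divergence_error = function(e) e)
  expect_s3_class(cond, "propnet_divergence_error")
  expect_s3_class(cond$model, "propnet_model")
})
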