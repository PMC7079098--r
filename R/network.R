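#' Configuration of the progressive multi-resolution U-net
#'
#' The network takes the moving (pretreatment) and fixed (fraction) images as
#' two input channels and outputs the three displacement components on the
#' full-resolution grid, in voxel units. It is composed of `levels` resolution
#' levels (level 1 finest); with the defaults the feature-map grid ranges from
#' 128^3 at the top to 8^3 at the bottom. Every level has an input head (an
#' average-pooled copy of the two-channel input followed by one convolution
#' matching the level's feature count, added at the summation node) and an
#' output head (a zero-initialized 1x1x1 convolution to 3 channels whose
#' output is trilinearly upsampled to full resolution); the final field is the
#' weighted sum of the per-level head outputs under the progressive schedule
#' weights. Encoder and decoder blocks use two 3^3 convolutions with batch
#' normalization and ReLU; downsampling is 2^3 max pooling, decoder
#' upsampling is trilinear followed by a convolution.
#'
#' @param levels number of resolution levels (>= 2).
#' @param input_size per-axis input dimensions, divisible by
#'   `2^(levels - 1)`.
#' @param base_features feature maps at the finest level; doubled per level
#'   downward, capped at `feature_cap`.
#' @param feature_cap maximum feature maps per level.
#' @param bn_momentum decay of the exponential moving average of the batch
#'   normalization statistics used at inference.
#' @param bn_eps batch normalization variance floor.
#' @return an object of class `unet_config`.
#' @export
unet_config <- function(levels = 5, input_size = c(128, 128, 128),
                        base_features = 32, feature_cap = 256,
                        bn_momentum = 0.99, bn_eps = 1e-5) {
  levels <- as.integer(levels)
  if (levels < 2L) stop_propnet("need at least 2 levels", "propnet_value_error")
  input_size <- as.integer(rep(input_size, length.out = 3))
  if (any(input_size %% 2L^(levels - 1L) != 0L))
    stop_propnet("input size must be divisible by 2^(levels-1)",
                 "propnet_value_error")
  structure(list(levels = levels, input_size = input_size,
                 base_features = as.integer(base_features),
                 feature_cap = as.integer(feature_cap),
                 bn_momentum = bn_momentum, bn_eps = bn_eps,
                 input_channels = 2L, output_channels = 3L),
            class = "unet_config")
}

level_features <- function(cfg) {
  pmin(cfg$base_features * 2L^(seq_len(cfg$levels) - 1L), cfg$feature_cap)
}

#' Initialize the network
#'
#' Convolution weights use He initialization; the per-level output heads are
#' zero-initialized so the untrained network predicts the identity transform
#' (a zero displacement field).
#'
#' @param config a [unet_config].
#' @param seed optional seed for the weight draw.
#' @return an object of class `propnet_model`.
#' @export
init_model <- function(config, seed = NULL) {
  if (!inherits(config, "unet_config"))
    stop_propnet("`config` must be a unet_config", "propnet_type_error")
  f <- level_features(config)
  L <- config$levels
  with_seed(seed, {
    params <- list()
    params$enc1a <- c(conv_init(2L, f[1]), bn_init(f[1]))
    params$enc1b <- c(conv_init(f[1], f[1]), bn_init(f[1]))
    for (l in seq(2, L)) {
      params[[sprintf("enc%d_a", l)]] <- c(conv_init(f[l - 1], f[l]), bn_init(f[l]))
      params[[sprintf("enc%d_in", l)]] <- conv_init(2L, f[l])
      params[[sprintf("enc%d_b", l)]] <- c(conv_init(f[l], f[l]), bn_init(f[l]))
    }
    for (l in seq_len(L - 1)) {
      params[[sprintf("dec%d_u", l)]] <- c(conv_init(f[l + 1], f[l]), bn_init(f[l]))
      params[[sprintf("dec%d_d", l)]] <- c(conv_init(f[l], f[l]), bn_init(f[l]))
    }
    for (l in seq_len(L))
      params[[sprintf("head%d", l)]] <- conv_init(f[l], 3L, zero = TRUE,
                                                  kernel = 1L)
    bn_stats <- list()
    for (nm in names(params))
      if (!is.null(params[[nm]]$gamma))
        bn_stats[[nm]] <- list(mean = numeric(length(params[[nm]]$gamma)),
                               var = rep(1, length(params[[nm]]$gamma)))
    structure(list(config = config, params = params, bn_stats = bn_stats,
                   iteration = 0L, velocity = NULL, loss_log = NULL),
              class = "propnet_model")
  })
}

#' @export
print.propnet_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p)
    sum(vapply(p, length, 1L)), 1L))
  cat(sprintf("<propnet_model> %d levels, input %s, %d parameters, iteration %d\n",
              x$config$levels, paste(x$config$input_size, collapse = "x"),
              np, x$iteration))
  invisible(x)
}

#' Progressive training schedule
#'
#' Resolution levels are activated coarse-to-fine: the coarsest level trains
#' alone for `N` iterations, then its output weight ramps linearly to the next
#' level over `M` iterations; each subsequent plateau lasts `2N` iterations
#' followed by another `M`-iteration ramp. With 5 levels, `N = 1000` and
#' `M = 2000` the finest level reaches weight one exactly at iteration 15000.
#'
#' @param N length of the first plateau (iterations).
#' @param M length of each linear transition.
#' @return an object of class `progressive_schedule`.
#' @export
progressive_schedule <- function(N = 1000, M = 2000) {
  if (N < 1 || M < 1) stop_propnet("N and M must be >= 1", "propnet_value_error")
  structure(list(N = N, M = M), class = "progressive_schedule")
}

#' Per-level output weights of the progressive schedule
#'
#' Returns the nonnegative weight vector (coarsest level first) applied to the
#' per-level network outputs at a given iteration: weights sum to one, at most
#' two adjacent levels are nonzero, ramps are piecewise linear, and after the
#' schedule ends all weight is on the finest level.
#'
#' @param schedule a [progressive_schedule].
#' @param iteration 0-based iteration index.
#' @param levels number of resolution levels.
#' @return numeric vector of length `levels`, coarsest first.
#' @export
level_weights <- function(schedule, iteration, levels) {
  if (iteration < 0) stop_propnet("iteration must be >= 0", "propnet_value_error")
  N <- schedule$N; M <- schedule$M
  w <- numeric(levels)
  for (k in seq_len(levels - 1)) {
    ramp_start <- N + (k - 1) * (M + 2 * N)
    if (iteration < ramp_start) { w[k] <- 1; return(w) }
    if (iteration < ramp_start + M) {
      t <- (iteration - ramp_start) / M
      w[k] <- 1 - t; w[k + 1] <- t
      return(w)
    }
  }
  w[levels] <- 1
  w
}

#' Total length of the progressive schedule
#'
#' Iteration at which the finest level first carries weight one:
#' `N + M + (levels - 2) * (2N + M)`.
#'
#' @inheritParams level_weights
#' @return integer iteration count.
#' @export
schedule_length <- function(schedule, levels) {
  schedule$N + schedule$M + (levels - 2) * (2 * schedule$N + schedule$M)
}

# ---------------------------------------------------------------------------

as_input_array <- function(x, what) {
  a <- if (is_volume3d(x)) x$data else x
  if (length(dim(a)) != 3L)
    stop_propnet(sprintf("%s must be a 3D volume", what), "propnet_input_error")
  if (min(a) < -1e-9 || max(a) > 1 + 1e-9)
    stop_propnet(sprintf("%s must be normalized to [0, 1]", what),
                 "propnet_input_error")
  a
}

#' Network forward pass
#'
#' Predicts the displacement field (ux, uy, uz) on the full-resolution grid,
#' in voxel units, as the alpha-weighted sum of the upsampled per-level
#' outputs. Inference (`training = FALSE`) uses the exponential-moving-average
#' batch-normalization statistics and is fully deterministic.
#'
#' @param model a [propnet_model].
#' @param moving,fixed normalized images ([volume3d] or array) on the
#'   configured input grid.
#' @param alphas level weights, coarsest first (defaults to weight 1 on the
#'   finest level).
#' @param training use batch statistics and keep gradient caches.
#' @return a [displacement_field] (for `training = FALSE`), or an internal
#'   list with the field, caches and batch statistics.
#' @export
forward_pass <- function(model, moving, fixed, alphas = NULL,
                         training = FALSE) {
  cfg <- model$config
  L <- cfg$levels
  if (is.null(alphas)) alphas <- c(numeric(L - 1), 1)
  if (length(alphas) != L || any(alphas < 0) || abs(sum(alphas) - 1) > 1e-9)
    stop_propnet("alphas must be a nonnegative weight vector summing to 1",
                 "propnet_input_error")
  mv <- as_input_array(moving, "moving image")
  fx <- as_input_array(fixed, "fixed image")
  if (!identical(dim(mv), cfg$input_size) || !identical(dim(fx), cfg$input_size))
    stop_propnet("input images do not match the configured grid",
                 "propnet_input_error")
  res <- unet_graph_forward(model, mv, fx, alphas, training)
  if (!training) return(displacement_field(res$field))
  res
}

# level l (1 = finest) has alpha index L - l + 1
unet_graph_forward <- function(model, mv, fx, alphas, training) {
  cfg <- model$config
  L <- cfg$levels
  eps <- cfg$bn_eps
  p <- model$params
  bs <- model$bn_stats
  dims <- cfg$input_size
  X <- array(c(mv, fx), c(dims, 2L))
  cache <- list(); batch_stats <- list()
  run_cbr <- function(name, x) {
    r <- cbr_fwd(x, p[[name]], bs[[name]], training, eps)
    if (training) {
      cache[[name]] <<- r$cache
      batch_stats[[name]] <<- r$batch_stats
    }
    r$out
  }
  P <- vector("list", L)
  P[[1]] <- X
  for (l in seq(2, L)) P[[l]] <- .avgpool2(P[[l - 1]], dim(P[[l - 1]]))
  E <- vector("list", L)
  h <- run_cbr("enc1a", X)
  E[[1]] <- run_cbr("enc1b", h)
  pool_args <- vector("list", L)
  for (l in seq(2, L)) {
    mp <- .maxpool2_fwd(E[[l - 1]], dim(E[[l - 1]]))
    pool_args[[l]] <- mp$argmax
    h <- run_cbr(sprintf("enc%d_a", l), mp$out)
    nm_in <- sprintf("enc%d_in", l)
    ih <- conv_fwd_plain(P[[l]], p[[nm_in]])
    E[[l]] <- run_cbr(sprintf("enc%d_b", l), h + ih)
  }
  active <- which(rev(alphas) != 0)     # level indices with nonzero weight
  finest_active <- min(active)
  D <- vector("list", L)
  Dsum <- vector("list", L)             # summation-node inputs, kept for bwd
  D[[L]] <- E[[L]]
  if (finest_active < L) {
    for (l in seq(L - 1, finest_active)) {
      up <- .resize_trilinear_fwd(D[[l + 1]], dim(D[[l + 1]]),
                                  c(dim(E[[l]])[1:3], dim(D[[l + 1]])[4]))
      u <- run_cbr(sprintf("dec%d_u", l), up)
      Dsum[[l]] <- u + E[[l]]
      D[[l]] <- run_cbr(sprintf("dec%d_d", l), Dsum[[l]])
    }
  }
  U <- array(0, c(dims, 3L))
  heads <- vector("list", L)
  for (l in active) {
    a <- alphas[L - l + 1]
    H <- head_fwd(D[[l]], p[[sprintf("head%d", l)]])
    heads[[l]] <- H
    Hup <- if (l == 1) H
           else .resize_trilinear_fwd(H, dim(H), c(dims, 3L))
    U <- U + a * Hup
  }
  list(field = U,
       cache = if (training) list(blocks = cache, E = E, D = D, P = P,
                                  pool_args = pool_args, alphas = alphas,
                                  active = active, X = X) else NULL,
       batch_stats = if (training) batch_stats else NULL)
}

# Backpropagate dL/dU through the network; returns gradients for every
# parameter (zeros where a block was inactive this iteration).
unet_graph_backward <- function(model, fwd, dU) {
  cfg <- model$config
  L <- cfg$levels
  p <- model$params
  ca <- fwd$cache
  grads <- rapply(p, function(x) x * 0, how = "replace")
  add_grads <- function(name, g) {
    for (nm in names(g)) grads[[name]][[nm]] <<- grads[[name]][[nm]] + g[[nm]]
  }
  dD <- vector("list", L)
  dims <- cfg$input_size
  for (l in ca$active) {
    a <- ca$alphas[L - l + 1]
    dH <- if (l == 1) a * dU
          else {
            hd <- dim(ca$D[[l]])
            .resize_trilinear_bwd(dU, c(dims, 3L), c(hd[1:3], 3L)) * a
          }
    hb <- head_bwd(dH, ca$D[[l]], p[[sprintf("head%d", l)]])
    add_grads(sprintf("head%d", l), hb$grads)
    dD[[l]] <- if (is.null(dD[[l]])) hb$dx else dD[[l]] + hb$dx
  }
  finest_active <- min(ca$active)
  dE <- vector("list", L)
  if (finest_active < L) {
    for (l in seq(finest_active, L - 1)) {
      if (is.null(dD[[l]])) next
      bd <- cbr_bwd(dD[[l]], ca$blocks[[sprintf("dec%d_d", l)]],
                    p[[sprintf("dec%d_d", l)]])
      add_grads(sprintf("dec%d_d", l), bd$grads)
      dE[[l]] <- if (is.null(dE[[l]])) bd$dx else dE[[l]] + bd$dx
      bu <- cbr_bwd(bd$dx, ca$blocks[[sprintf("dec%d_u", l)]],
                    p[[sprintf("dec%d_u", l)]])
      add_grads(sprintf("dec%d_u", l), bu$grads)
      dup <- .resize_trilinear_bwd(bu$dx, dim(bu$dx), dim(ca$D[[l + 1]]))
      dD[[l + 1]] <- if (is.null(dD[[l + 1]])) dup else dD[[l + 1]] + dup
    }
  }
  if (!is.null(dD[[L]]))
    dE[[L]] <- if (is.null(dE[[L]])) dD[[L]] else dE[[L]] + dD[[L]]
  for (l in seq(L, 2)) {
    if (is.null(dE[[l]])) next
    bb <- cbr_bwd(dE[[l]], ca$blocks[[sprintf("enc%d_b", l)]],
                  p[[sprintf("enc%d_b", l)]])
    add_grads(sprintf("enc%d_b", l), bb$grads)
    nm_in <- sprintf("enc%d_in", l)
    ib <- conv_bwd_plain(bb$dx, ca$P[[l]], p[[nm_in]])
    add_grads(nm_in, ib$grads)
    ba <- cbr_bwd(bb$dx, ca$blocks[[sprintf("enc%d_a", l)]],
                  p[[sprintf("enc%d_a", l)]])
    add_grads(sprintf("enc%d_a", l), ba$grads)
    dpool <- .maxpool2_bwd(ba$dx, ca$pool_args[[l]], dim(ca$E[[l - 1]]))
    dE[[l - 1]] <- if (is.null(dE[[l - 1]])) dpool else dE[[l - 1]] + dpool
  }
  if (!is.null(dE[[1]])) {
    b1b <- cbr_bwd(dE[[1]], ca$blocks$enc1b, p$enc1b)
    add_grads("enc1b", b1b$grads)
    b1a <- cbr_bwd(b1b$dx, ca$blocks$enc1a, p$enc1a)
    add_grads("enc1a", b1a$grads)
  }
  grads
}

#' Spatial transformer warp of a mask or probability map
#'
#' In inference mode the mask is pull-warped with nearest-neighbor sampling
#' (binary output, identical to [warp_mask]); in training mode trilinear
#' sampling produces soft values in `[0, 1]` so that gradients of the overlap
#' loss flow to the displacement field.
#'
#' @param mask_or_probs 3D array or mask [volume3d].
#' @param field a [displacement_field] on the same grid.
#' @param mode `"infer"` (nearest neighbor) or `"train"` (trilinear).
#' @return array of warped values.
#' @export
stl_warp <- function(mask_or_probs, field, mode = c("infer", "train")) {
  mode <- match.arg(mode)
  m <- if (is_volume3d(mask_or_probs)) mask_or_probs$data else mask_or_probs
  if (!inherits(field, "displacement_field"))
    stop_propnet("`field` must be a displacement field", "propnet_type_error")
  if (!identical(dim(m), field$grid_size))
    stop_propnet("mask grid does not match the field grid",
                 "propnet_shape_error")
  pts <- grid_points(dim(m)) + matrix(field$u, ncol = 3)
  vals <- if (mode == "infer") .sample_nearest(m, dim(m), pts, 0)
          else .sample_linear(m, dim(m), pts, 0)
  array(vals, dim(m))
}

# --- losses -----------------------------------------------------------------

#' Segmentation overlap loss (soft Dice complement)
#'
#' `1 - 2 * sum(truth * pred) / (sum(truth) + sum(pred) + eps)`: zero for
#' perfect overlap of identical binary masks, one for disjoint masks. The
#' small `eps` guards empty masks.
#'
#' @param pred warped (possibly soft) segmentation, values in `[0, 1]`.
#' @param truth target segmentation, values in `[0, 1]`.
#' @param eps denominator smoothing.
#' @return scalar loss in `[0, 1]` (up to the `eps` effect).
#' @export
overlap_loss <- function(pred, truth, eps = 1e-5) {
  a <- if (is_volume3d(pred)) pred$data else pred
  b <- if (is_volume3d(truth)) truth$data else truth
  if (!identical(dim(a), dim(b)))
    stop_propnet("prediction and truth are on different grids",
                 "propnet_shape_error")
  if (min(a) < 0 || max(a) > 1 || min(b) < 0 || max(b) > 1)
    stop_propnet("overlap loss needs values in [0, 1]", "propnet_range_error")
  1 - 2 * sum(a * b) / (sum(a) + sum(b) + eps)
}

#' Deformation-field loss
#'
#' Mean over voxels of the squared Euclidean norm of the difference between
#' the true and estimated displacement vectors (the three components are
#' summed, not averaged).
#'
#' @param pred,truth [displacement_field]s (or `(d1,d2,d3,3)` arrays) on the
#'   same grid.
#' @return scalar loss in squared voxels.
#' @export
dvf_loss <- function(pred, truth) {
  a <- if (inherits(pred, "displacement_field")) pred$u else pred
  b <- if (inherits(truth, "displacement_field")) truth$u else truth
  if (!identical(dim(a), dim(b)))
    stop_propnet("fields are on different grids", "propnet_shape_error")
  sum((a - b)^2) / prod(dim(a)[1:3])
}

#' Loss weighting
#'
#' `total = k_overlap * overlap + k_dvf * dvf`. The three supervision
#' variants are presets: overlap `(1, 0)`, deformation `(0, 1)`, hybrid
#' `(1, 1)`.
#'
#' @param k_overlap,k_dvf weights in `[0, 1]`, not both zero.
#' @return an object of class `loss_weights`.
#' @export
loss_weights <- function(k_overlap, k_dvf) {
  if (k_overlap < 0 || k_overlap > 1 || k_dvf < 0 || k_dvf > 1)
    stop_propnet("loss weights must lie in [0, 1]", "propnet_config_error")
  if (k_overlap == 0 && k_dvf == 0)
    stop_propnet("at least one loss weight must be nonzero",
                 "propnet_config_error")
  structure(list(k_overlap = k_overlap, k_dvf = k_dvf),
            class = "loss_weights")
}

#' @rdname loss_weights
#' @param preset `"overlap"`, `"deformation"` or `"hybrid"`.
#' @export
loss_preset <- function(preset = c("overlap", "deformation", "hybrid")) {
  preset <- match.arg(preset)
  switch(preset,
         overlap = loss_weights(1, 0),
         deformation = loss_weights(0, 1),
         hybrid = loss_weights(1, 1))
}

#' @rdname loss_weights
#' @param w a `loss_weights` object.
#' @param overlap,dvf the component loss values.
#' @export
total_loss <- function(w, overlap, dvf) {
  if (!inherits(w, "loss_weights"))
    stop_propnet("`w` must be loss_weights", "propnet_config_error")
  w$k_overlap * overlap + w$k_dvf * dvf
}

# --- training ---------------------------------------------------------------

#' Train the registration network
#'
#' Stochastic gradient descent with momentum 0.5 and learning rate 0.01,
#' batch size one, one freshly drawn synthetic training sample per iteration,
#' per-iteration output weights from the progressive schedule, and
#' exponential-moving-average batch-normalization statistics for inference.
#' Fully reproducible given `seed` (which also seeds `data_fn` through its
#' argument).
#'
#' @param model a [propnet_model] (freshly initialized or resumed).
#' @param data_fn `function(iteration)` returning a `training_sample` (or a
#'   list with the same fields) on the configured grid.
#' @param iterations number of iterations to run.
#' @param schedule a [progressive_schedule].
#' @param weights a [loss_weights].
#' @param lr learning rate.
#' @param momentum SGD momentum parameter.
#' @param checkpoint_every if nonzero, save a checkpoint to `checkpoint_dir`
#'   every that many iterations.
#' @param checkpoint_dir directory for periodic checkpoints.
#' @param verbose print a progress line every 50 iterations.
#' @return the trained [propnet_model]; `model$loss_log` holds the
#'   per-iteration loss curve.
#' @export
train_model <- function(model, data_fn, iterations, schedule, weights,
                        lr = 0.01, momentum = 0.5, checkpoint_every = 0,
                        checkpoint_dir = NULL, verbose = FALSE) {
  if (!inherits(model, "propnet_model"))
    stop_propnet("`model` must be a propnet_model", "propnet_type_error")
  if (!inherits(weights, "loss_weights"))
    stop_propnet("`weights` must be loss_weights", "propnet_config_error")
  if (iterations == 0) return(model)
  cfg <- model$config
  L <- cfg$levels
  dims <- cfg$input_size
  V <- prod(dims)
  eps_ov <- 1e-5
  if (is.null(model$velocity))
    model$velocity <- rapply(model$params, function(x) x * 0, how = "replace")
  log_rows <- vector("list", iterations)
  pts0 <- grid_points(dims)
  for (it in seq_len(iterations)) {
    s <- data_fn(model$iteration)
    mvim <- if (is_volume3d(s$moving_image)) s$moving_image$data else s$moving_image
    fxim <- if (is_volume3d(s$fixed_image)) s$fixed_image$data else s$fixed_image
    mmask <- if (is_volume3d(s$moving_mask)) s$moving_mask$data else s$moving_mask
    tmask <- if (is_volume3d(s$target_mask)) s$target_mask$data else s$target_mask
    tfield <- if (inherits(s$target_field, "displacement_field"))
      s$target_field$u else s$target_field
    alphas <- level_weights(schedule, model$iteration, L)
    fwd <- forward_pass(model, mvim, fxim, alphas, training = TRUE)
    U <- fwd$field
    if (!all(is.finite(U))) {
      cond <- structure(
        class = c("propnet_divergence_error", "propnet_error", "error",
                  "condition"),
        list(message = sprintf("non-finite field at iteration %d",
                               model$iteration),
             call = sys.call(), model = model))
      stop(cond)
    }
    # losses and dL/dU
    l_dvf <- sum((U - tfield)^2) / V
    pts <- pts0 + matrix(U, ncol = 3)
    wsoft <- .sample_linear(mmask, dims, pts, 0)
    s_t <- sum(tmask); s_w <- sum(wsoft)
    num <- sum(tmask * wsoft)
    denom <- s_t + s_w + eps_ov
    l_ov <- 1 - 2 * num / denom
    loss <- weights$k_overlap * l_ov + weights$k_dvf * l_dvf
    if (!is.finite(loss)) {
      cond <- structure(
        class = c("propnet_divergence_error", "propnet_error", "error",
                  "condition"),
        list(message = sprintf("non-finite loss at iteration %d",
                               model$iteration),
             call = sys.call(), model = model))
      stop(cond)
    }
    dU <- if (weights$k_dvf > 0) weights$k_dvf * 2 * (U - tfield) / V
          else array(0, dim(U))
    if (weights$k_overlap > 0) {
      dl_dw <- -2 * (as.vector(tmask) * denom - num) / denom^2
      G <- .sample_linear_grad(mmask, dims, pts)
      dU <- dU + weights$k_overlap * array(G * dl_dw, dim(U))
    }
    grads <- unet_graph_backward(model, fwd, dU)
    # SGD + momentum
    for (nm in names(model$params)) {
      for (fld in c("W", "b", "gamma", "beta")) {
        if (is.null(model$params[[nm]][[fld]])) next
        v <- momentum * model$velocity[[nm]][[fld]] - lr * grads[[nm]][[fld]]
        model$velocity[[nm]][[fld]] <- v
        model$params[[nm]][[fld]] <- model$params[[nm]][[fld]] + v
      }
    }
    # EMA of batch-normalization statistics
    bm <- cfg$bn_momentum
    for (nm in names(fwd$batch_stats)) {
      st <- fwd$batch_stats[[nm]]
      model$bn_stats[[nm]]$mean <- bm * model$bn_stats[[nm]]$mean +
        (1 - bm) * st$mean
      model$bn_stats[[nm]]$var <- bm * model$bn_stats[[nm]]$var +
        (1 - bm) * st$var
    }
    log_rows[[it]] <- c(iteration = model$iteration, overlap = l_ov,
                        dvf = l_dvf, total = loss)
    model$iteration <- model$iteration + 1L
    if (verbose && model$iteration %% 50L == 0L)
      message(sprintf("iter %d  overlap %.4f  dvf %.4f  total %.4f",
                      model$iteration, l_ov, l_dvf, loss))
    if (checkpoint_every > 0 && !is.null(checkpoint_dir) &&
        model$iteration %% checkpoint_every == 0L)
      save_checkpoint(model, file.path(checkpoint_dir,
                                       sprintf("ckpt_%06d.rds",
                                               model$iteration)))
  }
  new_log <- as.data.frame(do.call(rbind, log_rows))
  model$loss_log <- rbind(model$loss_log, new_log)
  model
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single file holding the weights, the
#' batch-normalization moving averages, the iteration counter, the
#' configuration and the loss log; restoring it reproduces forward passes
#' bit-identically.
#'
#' @param model a [propnet_model].
#' @param path checkpoint file.
#' @return `load_checkpoint` returns the model; `save_checkpoint` returns
#'   `path` invisibly.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "propnet_model"))
    stop_propnet("file does not contain a propnet model", "propnet_file_error")
  model
}

#' Propagate a contour from the pretreatment to a fraction image
#'
#' One forward pass with the final (finest-level) output weights, followed by
#' a nearest-neighbor spatial-transformer warp of the pretreatment mask onto
#' the fraction grid.
#'
#' @param model a trained [propnet_model].
#' @param pre_image,fraction_image normalized images on the network grid.
#' @param pre_mask pretreatment target mask on the same grid.
#' @return `list(mask = , field = )`: the propagated binary mask ([volume3d])
#'   and the predicted [displacement_field].
#' @export
propagate <- function(model, pre_image, pre_mask, fraction_image) {
  field <- forward_pass(model, pre_image, fraction_image)
  m <- if (is_volume3d(pre_mask)) pre_mask else
    volume3d(pre_mask, is_mask = TRUE)
  if (!m$is_mask)
    stop_propnet("`pre_mask` must be a mask", "propnet_type_error")
  out <- array(stl_warp(m$data, field, mode = "infer"), dim(m$data))
  list(mask = volume3d(out, spacing = m$spacing, origin = m$origin,
                       is_mask = TRUE),
       field = field)
}
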