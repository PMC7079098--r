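#' Dice coefficient of two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks are defined to agree perfectly
#' (Dice 1); exactly one empty mask gives 0.
#'
#' @param a,b mask [volume3d]s or 0/1 arrays on the same grid.
#' @return unitless value in `[0, 1]`.
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (is_volume3d(a)) a$data else a
  mb <- if (is_volume3d(b)) b$data else b
  if (!identical(dim(ma), dim(mb)))
    stop_propnet("masks are on different grids", "propnet_shape_error")
  sa <- sum(ma != 0); sb <- sum(mb != 0)
  if (sa + sb == 0) return(1)
  2 * sum(ma != 0 & mb != 0) / (sa + sb)
}

# 0-based voxel indices (N x 3) of the 6-connectivity boundary: mask voxels
# with at least one face neighbor outside the mask (the volume border counts
# as background).
boundary_voxels <- function(m) {
  d <- dim(m)
  inside <- m != 0
  shifted_all_inside <- array(TRUE, d)
  for (axis in 1:3) {
    for (dir in c(-1L, 1L)) {
      nb <- array(FALSE, d)
      n <- d[axis]
      src <- if (dir == 1L) 2:n else 1:(n - 1)
      dst <- if (dir == 1L) 1:(n - 1) else 2:n
      if (axis == 1) nb[dst, , ] <- inside[src, , ]
      else if (axis == 2) nb[, dst, ] <- inside[, src, ]
      else nb[, , dst] <- inside[, , src]
      shifted_all_inside <- shifted_all_inside & nb
    }
  }
  idx <- which(inside & !shifted_all_inside, arr.ind = TRUE)
  idx - 1L
}

#' 95th-percentile Hausdorff distance between two segmentations
#'
#' Boundary surfaces are the 6-connectivity boundary voxels of each mask;
#' directed surface-to-surface distances (in mm, anisotropic spacing
#' respected) are computed both ways and by default pooled into one distance
#' multiset whose 95th percentile (linear interpolation between order
#' statistics) is returned. `method = "max_directed"` instead returns the
#' larger of the two directed 95th percentiles.
#'
#' @param a,b nonempty mask [volume3d]s or 0/1 arrays on the same grid.
#' @param spacing voxel spacing in mm (taken from `a` when it is a volume).
#' @param percentile percentile of the distance multiset (95 for HD95, 100
#'   for the exact Hausdorff distance).
#' @param method `"pooled"` (default) or `"max_directed"`.
#' @return distance in mm.
#' @export
hausdorff_95 <- function(a, b, spacing = NULL, percentile = 95,
                         method = c("pooled", "max_directed")) {
  method <- match.arg(method)
  ma <- if (is_volume3d(a)) a$data else a
  mb <- if (is_volume3d(b)) b$data else b
  if (!identical(dim(ma), dim(mb)))
    stop_propnet("masks are on different grids", "propnet_shape_error")
  if (is.null(spacing)) spacing <- if (is_volume3d(a)) a$spacing else c(1, 1, 1)
  if (sum(ma) == 0 || sum(mb) == 0)
    stop_propnet("Hausdorff distance needs two nonempty masks",
                 "propnet_metric_error")
  pa <- sweep(boundary_voxels(ma), 2, spacing, FUN = "*")
  pb <- sweep(boundary_voxels(mb), 2, spacing, FUN = "*")
  dab <- .min_dists(pa, pb)
  dba <- .min_dists(pb, pa)
  p <- percentile / 100
  if (method == "pooled") {
    unname(quantile(c(dab, dba), p, type = 7))
  } else {
    max(quantile(dab, p, type = 7), quantile(dba, p, type = 7))
  }
}

#' Distance between mask centroids
#'
#' Euclidean distance in mm between the binary centers of mass of two masks.
#'
#' @inheritParams hausdorff_95
#' @return distance in mm.
#' @export
centroid_distance <- function(a, b, spacing = NULL) {
  ma <- if (is_volume3d(a)) a$data else a
  mb <- if (is_volume3d(b)) b$data else b
  if (!identical(dim(ma), dim(mb)))
    stop_propnet("masks are on different grids", "propnet_shape_error")
  if (is.null(spacing)) spacing <- if (is_volume3d(a)) a$spacing else c(1, 1, 1)
  if (sum(ma) == 0 || sum(mb) == 0)
    stop_propnet("centroid distance needs two nonempty masks",
                 "propnet_metric_error")
  ca <- colMeans(which(ma != 0, arr.ind = TRUE)) * spacing
  cb <- colMeans(which(mb != 0, arr.ind = TRUE)) * spacing
  sqrt(sum((ca - cb)^2))
}

#' Evaluate one propagated contour
#'
#' Assembles the per-registration metrics: Dice, HD95 (mm), centroid distance
#' (mm), and folding percentages over the full field of view and inside the
#' ground-truth fraction mask. An empty propagated mask yields Dice 0 with
#' the distance metrics flagged undefined (NA).
#'
#' @param propagated propagated mask [volume3d].
#' @param truth ground-truth fraction mask [volume3d].
#' @param field the predicted [displacement_field] (optional; folding is NA
#'   without it).
#' @param case named identifiers stored with the row (patient, fraction, ...).
#' @return a one-row `data.frame`.
#' @export
evaluate_case <- function(propagated, truth, field = NULL, case = list()) {
  assert_volume(propagated, "propagated"); assert_volume(truth, "truth")
  assert_same_grid(propagated, truth)
  empty <- sum(propagated$data) == 0
  row <- data.frame(
    dice = dice_coefficient(propagated, truth),
    hd95 = if (empty) NA_real_ else
      hausdorff_95(propagated, truth, spacing = truth$spacing),
    centroid_mm = if (empty) NA_real_ else
      centroid_distance(propagated, truth, spacing = truth$spacing),
    folding_fov = if (is.null(field)) NA_real_ else folding_fraction(field),
    folding_prostate = if (is.null(field)) NA_real_ else
      folding_fraction(field, truth)
  )
  if (length(case)) row <- cbind(as.data.frame(case), row)
  row
}

#' Axial-shift robustness experiment
#'
#' Emulates setup errors in the superior-inferior direction: for each shift
#' the pretreatment resampling window is displaced axially by that many mm
#' before preprocessing, the network propagates the (shifted) pretreatment
#' mask to every fraction, and the contour-distance metrics are summarized
#' across fractions. Shift 0 reproduces the unshifted evaluation exactly.
#'
#' @param model a trained [propnet_model].
#' @param patient a `patient_record`.
#' @param shifts_mm axial shifts in mm (default -5..5 in 1 mm steps).
#' @param spec a [network_grid_spec] describing the preprocessing; defaults
#'   to an uncropped resampling onto the model grid (phantom patients are
#'   generated with the network window already applied).
#' @return `list(per_case = data.frame, summary = data.frame)`; the summary
#'   has one row per shift with mean and 2.5/97.5 percent quantiles of HD95
#'   and Dice across fractions.
#' @export
shift_experiment <- function(model, patient, shifts_mm = -5:5, spec = NULL) {
  if (!inherits(patient, "patient_record"))
    stop_propnet("`patient` must be a patient_record", "propnet_type_error")
  if (is.null(spec))
    spec <- network_grid_spec(size = model$config$input_size,
                              in_plane_scale = 1, axial_scale = 1)
  pre <- patient$pretreatment
  fracs <- lapply(patient$fractions, function(f)
    list(image = normalize_intensities(
           resample_to_network_grid(f$image, spec)),
         mask = resample_to_network_grid(f$mask, spec)))
  rows <- list()
  axial_extent_mm <- vol_dims(pre$image)[3] * pre$image$spacing[3]
  for (k in shifts_mm) {
    if (abs(k) >= axial_extent_mm / 2)
      stop_propnet("shift moves the window outside the volume",
                   "propnet_geometry_error")
    pre_img <- normalize_intensities(
      resample_to_network_grid(pre$image, spec, axial_shift_mm = k))
    pre_mask <- resample_to_network_grid(pre$mask, spec, axial_shift_mm = k)
    for (f in seq_along(fracs)) {
      res <- propagate(model, pre_img, pre_mask, fracs[[f]]$image)
      rows[[length(rows) + 1]] <- evaluate_case(
        res$mask, fracs[[f]]$mask, res$field,
        case = list(shift_mm = k, fraction = f))
    }
  }
  per_case <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(per_case, per_case$shift_mm),
    function(d) data.frame(
      shift_mm = d$shift_mm[1],
      hd95_mean = mean(d$hd95),
      hd95_lo = unname(quantile(d$hd95, 0.025, type = 7)),
      hd95_hi = unname(quantile(d$hd95, 0.975, type = 7)),
      dice_mean = mean(d$dice))))
  summary <- summary[order(summary$shift_mm), ]
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary)
}

#' Leave-one-out cross-validation harness
#'
#' With `n` patients, runs `n` folds: in fold `i` patient `i` is the test
#' patient, the next patient (cyclically) is the validation patient used for
#' monitoring, and the rest are training patients. Training pairs are
#' manufactured on the fly from the training patients' volumes; all folds use
#' identical hyperparameters. Per-fold test metrics and a pooled mean +/- sd
#' summary are returned.
#'
#' @param patients list of `patient_record`s (at least 3).
#' @param config a [unet_config] matching the patients' grid.
#' @param schedule a [progressive_schedule].
#' @param weights a [loss_weights].
#' @param iterations training iterations per fold.
#' @param seed master seed (weights, data stream).
#' @param include_pretreatment also draw training pairs from the training
#'   patients' pretreatment scans (default yes).
#' @param verbose print progress.
#' @return `list(per_case = data.frame, folds = list of models omitted,
#'   summary = data.frame)` where `summary` holds pooled mean and sd per
#'   metric.
#' @export
crossval_harness <- function(patients, config, schedule, weights,
                             iterations, seed = 1,
                             include_pretreatment = TRUE, verbose = FALSE) {
  n <- length(patients)
  if (n < 3)
    stop_propnet("leave-one-out needs at least 3 patients",
                 "propnet_split_error")
  all_rows <- list()
  for (fold in seq_len(n)) {
    test_id <- fold
    val_id <- fold %% n + 1
    train_ids <- setdiff(seq_len(n), c(test_id, val_id))
    pool <- list()
    for (id in train_ids) {
      pat <- patients[[id]]
      vols <- pat$fractions
      if (include_pretreatment) vols <- c(list(pat$pretreatment), vols)
      for (v in vols)
        pool[[length(pool) + 1]] <- list(
          image = normalize_intensities(v$image), mask = v$mask)
    }
    data_fn <- function(iter) {
      sel <- with_seed(derive_seed(seed, 7919 * fold + iter),
                       sample.int(length(pool), 1))
      make_training_sample(pool[[sel]]$image, pool[[sel]]$mask,
                           seed = derive_seed(seed, 104729 * fold + iter))
    }
    model <- init_model(config, seed = derive_seed(seed, fold))
    model <- train_model(model, data_fn, iterations, schedule, weights,
                         verbose = verbose)
    test <- patients[[test_id]]
    pre_img <- normalize_intensities(test$pretreatment$image)
    pre_mask <- test$pretreatment$mask
    for (f in seq_along(test$fractions)) {
      frac <- test$fractions[[f]]
      res <- propagate(model, pre_img, pre_mask,
                       normalize_intensities(frac$image))
      all_rows[[length(all_rows) + 1]] <- evaluate_case(
        res$mask, frac$mask, res$field,
        case = list(fold = fold, test_patient = test_id,
                    validation_patient = val_id, fraction = f))
    }
    if (verbose) message(sprintf("fold %d/%d done", fold, n))
  }
  per_case <- do.call(rbind, all_rows)
  metrics <- c("dice", "hd95", "centroid_mm", "folding_fov",
               "folding_prostate")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_case[[m]], na.rm = TRUE), 1),
    sd = vapply(metrics, function(m) sd(per_case[[m]], na.rm = TRUE), 1))
  rownames(summary) <- NULL
  list(per_case = per_case, summary = summary)
}
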