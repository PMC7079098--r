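#' Run configuration
#'
#' One YAML file drives the whole pipeline; every stochastic component has an
#' explicit seed and the loss preset maps onto the supervision variants
#' (overlap `(1,0)`, deformation `(0,1)`, hybrid `(1,1)`). The `desk` profile
#' shrinks the problem (32^3 grid, 3 levels, 8 base features, 500 iterations
#' with a proportionally shortened schedule) so the full pipeline runs on one
#' CPU in minutes.
#'
#' @param path optional YAML file; keys override the defaults.
#' @param overrides named list applied on top of the file (CLI flags).
#' @param profile optional profile name (`"desk"` or `"full"`).
#' @return a nested configuration list of class `run_config`.
#' @export
load_run_config <- function(path = NULL, overrides = list(), profile = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path))
      stop_propnet(sprintf("config file not found: %s", path),
                   "propnet_config_error")
    cfg <- deep_merge(cfg, yaml::read_yaml(path))
  }
  if (!is.null(profile)) cfg$profile <- profile
  if (identical(cfg$profile, "desk"))
    cfg <- deep_merge(cfg, desk_profile())
  if (length(overrides)) cfg <- deep_merge(cfg, overrides)
  validate_run_config(cfg)
}

default_run_config <- function() {
  list(
    profile = "full",
    seed = 1L,
    phantom = list(grid = 128L, noise_sigma = 0.02, texture_scale_mm = 8,
                   prostate_semiaxes_mm = c(25, 20, 18),
                   bladder = TRUE, rectum = TRUE),
    simulate = list(n_patients = 5L, n_fractions = 20L),
    grid = list(size = 128L, in_plane_scale = 1, axial_scale = 1,
                axial_margin_mm = 30),
    network = list(levels = 5L, base_features = 32L, feature_cap = 256L),
    schedule = list(N = 1000L, M = 2000L),
    loss = list(preset = "hybrid"),
    optimizer = list(lr = 0.01, momentum = 0.5),
    iterations = 15000L,
    shift = list(shifts_mm = -5:5),
    paths = list(out = "propnet_out", data = NULL, checkpoint = NULL)
  )
}

desk_profile <- function() {
  list(phantom = list(grid = 32L),
       grid = list(size = 32L),
       network = list(levels = 3L, base_features = 8L),
       schedule = list(N = 100L, M = 100L),
       iterations = 500L)
}

deep_merge <- function(base, extra) {
  for (nm in names(extra)) {
    if (is.list(base[[nm]]) && is.list(extra[[nm]]))
      base[[nm]] <- deep_merge(base[[nm]], extra[[nm]])
    else base[[nm]] <- extra[[nm]]
  }
  base
}

validate_run_config <- function(cfg) {
  fail <- function(key, msg)
    stop_propnet(sprintf("config key `%s`: %s", key, msg),
                 "propnet_config_error")
  if (is.null(cfg$seed) || !is.finite(cfg$seed)) fail("seed", "must be set")
  if (!is.null(cfg$loss$preset)) {
    if (!cfg$loss$preset %in% c("overlap", "deformation", "hybrid"))
      fail("loss.preset", "must be overlap, deformation or hybrid")
    w <- loss_preset(cfg$loss$preset)
    cfg$loss$k_overlap <- w$k_overlap
    cfg$loss$k_dvf <- w$k_dvf
  } else if (is.null(cfg$loss$k_overlap) || is.null(cfg$loss$k_dvf)) {
    fail("loss", "needs a preset or explicit k_overlap / k_dvf")
  }
  if (cfg$iterations < 0) fail("iterations", "must be nonnegative")
  structure(cfg, class = c("run_config", "list"))
}

config_objects <- function(cfg) {
  list(
    phantom = phantom_spec(grid = cfg$phantom$grid,
                           prostate_semiaxes_mm = cfg$phantom$prostate_semiaxes_mm,
                           bladder = isTRUE(cfg$phantom$bladder),
                           rectum = isTRUE(cfg$phantom$rectum),
                           texture_scale_mm = cfg$phantom$texture_scale_mm,
                           noise_sigma = cfg$phantom$noise_sigma),
    grid = network_grid_spec(size = cfg$grid$size,
                             in_plane_scale = cfg$grid$in_plane_scale,
                             axial_scale = cfg$grid$axial_scale,
                             axial_margin_mm = cfg$grid$axial_margin_mm),
    network = unet_config(levels = cfg$network$levels,
                          input_size = cfg$grid$size,
                          base_features = cfg$network$base_features,
                          feature_cap = cfg$network$feature_cap),
    schedule = progressive_schedule(N = cfg$schedule$N, M = cfg$schedule$M),
    weights = loss_weights(cfg$loss$k_overlap %||%
                             loss_preset(cfg$loss$preset)$k_overlap,
                           cfg$loss$k_dvf %||%
                             loss_preset(cfg$loss$preset)$k_dvf)
  )
}

transform_manifest <- function(t) {
  if (inherits(t, "composite_transform"))
    return(list(type = "composite",
                components = lapply(t$components, transform_manifest)))
  if (inherits(t, "rigid_transform"))
    return(list(type = "rigid", angles = t$angles,
                translation = t$translation))
  if (inherits(t, "bspline_transform"))
    return(list(type = "bspline", grid_size = t$grid_size,
                coefficients = as.vector(t$coefficients)))
  if (inherits(t, "scaling_transform"))
    return(list(type = "scaling", factors = t$factors))
  list(type = class(t)[1])
}

#' Simulate phantom patients to disk
#'
#' Writes each patient's pretreatment and fraction image/mask pairs as NIfTI
#' files plus a JSON manifest recording paths, seeds and the true generating
#' transform parameters. Idempotent under a fixed seed.
#'
#' @param cfg a `run_config` (see [load_run_config]).
#' @return the manifest (invisibly).
#' @export
cmd_simulate <- function(cfg) {
  obj <- config_objects(cfg)
  out <- cfg$paths$data %||% file.path(cfg$paths$out, "patients")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cfg$seed, patients = list())
  for (p in seq_len(cfg$simulate$n_patients)) {
    pseed <- derive_seed(cfg$seed, p)
    pat <- generate_patient(obj$phantom, n_fractions = cfg$simulate$n_fractions,
                            seed = pseed)
    pdir <- file.path(out, sprintf("patient%02d", p))
    dir.create(pdir, showWarnings = FALSE)
    files <- list(
      pretreatment = c(image = file.path(pdir, "pretreatment_image.nii.gz"),
                       mask = file.path(pdir, "pretreatment_mask.nii.gz")))
    write_volume(pat$pretreatment$image, files$pretreatment[["image"]])
    write_volume(pat$pretreatment$mask, files$pretreatment[["mask"]])
    fr <- list()
    for (f in seq_along(pat$fractions)) {
      fi <- file.path(pdir, sprintf("fraction%02d_image.nii.gz", f))
      fm <- file.path(pdir, sprintf("fraction%02d_mask.nii.gz", f))
      write_volume(pat$fractions[[f]]$image, fi)
      write_volume(pat$fractions[[f]]$mask, fm)
      fr[[f]] <- list(image = fi, mask = fm,
                      transform = transform_manifest(pat$provenance[[f]]))
    }
    manifest$patients[[p]] <- list(id = p, seed = pseed,
                                   pretreatment = as.list(files$pretreatment),
                                   fractions = fr)
  }
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

read_patient_dir <- function(pdir) {
  imgs <- sort(list.files(pdir, pattern = "^fraction[0-9]+_image", full.names = TRUE))
  masks <- sort(list.files(pdir, pattern = "^fraction[0-9]+_mask", full.names = TRUE))
  pre <- list(image = read_volume(file.path(pdir, "pretreatment_image.nii.gz")),
              mask = read_volume(file.path(pdir, "pretreatment_mask.nii.gz")))
  fractions <- Map(function(i, m) list(image = read_volume(i),
                                       mask = read_volume(m)), imgs, masks)
  structure(list(pretreatment = pre, fractions = unname(fractions),
                 provenance = NULL,
                 spec = list(grid = vol_dims(pre$image))),
            class = "patient_record")
}

load_patients <- function(cfg) {
  data_dir <- cfg$paths$data %||% file.path(cfg$paths$out, "patients")
  pdirs <- sort(list.dirs(data_dir, recursive = FALSE))
  if (length(pdirs) == 0L)
    stop_propnet(sprintf("no patient directories under %s (run cmd_simulate)",
                         data_dir), "propnet_file_error")
  lapply(pdirs, read_patient_dir)
}

#' Train one supervision variant
#'
#' Builds the training pool from the configured training patients (all but
#' the last two by default: the canonical split uses three patients for
#' training, one for validation, one for testing), trains the configured
#' variant, and writes the checkpoint and a loss-log CSV.
#'
#' @param cfg a `run_config`.
#' @param patients optional list of `patient_record`s (read from disk when
#'   omitted).
#' @return the trained model (invisibly); checkpoint at
#'   `cfg$paths$checkpoint`.
#' @export
cmd_train <- function(cfg, patients = NULL) {
  obj <- config_objects(cfg)
  if (is.null(patients)) patients <- load_patients(cfg)
  train_ids <- cfg$train$patients %||%
    seq_len(max(1L, length(patients) - 2L))
  pool <- list()
  for (id in train_ids) {
    pat <- patients[[id]]
    for (v in c(list(pat$pretreatment), pat$fractions))
      pool[[length(pool) + 1]] <- list(image = normalize_intensities(v$image),
                                       mask = v$mask)
  }
  data_fn <- function(iter) {
    sel <- with_seed(derive_seed(cfg$seed, 7919 + iter),
                     sample.int(length(pool), 1))
    make_training_sample(pool[[sel]]$image, pool[[sel]]$mask,
                         seed = derive_seed(cfg$seed, 104729 + iter))
  }
  model <- init_model(obj$network, seed = derive_seed(cfg$seed, 0))
  model <- train_model(model, data_fn, cfg$iterations, obj$schedule,
                       obj$weights, lr = cfg$optimizer$lr,
                       momentum = cfg$optimizer$momentum,
                       verbose = isTRUE(cfg$verbose))
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  ckpt <- cfg$paths$checkpoint %||% file.path(cfg$paths$out, "model.rds")
  save_checkpoint(model, ckpt)
  if (!is.null(model$loss_log))
    write.csv(model$loss_log, file.path(cfg$paths$out, "loss_log.csv"),
              row.names = FALSE)
  invisible(model)
}

#' Evaluate a trained model on held-out patients
#'
#' Propagates the pretreatment contour to every fraction of the configured
#' test patients (the last patient by default), writes a per-case metric CSV
#' and a pooled JSON summary, and optionally the no-registration baseline.
#'
#' @param cfg a `run_config`.
#' @param patients optional preloaded patients.
#' @param model optional preloaded model (otherwise the checkpoint is read).
#' @return `list(per_case, summary)` invisibly; files under `cfg$paths$out`.
#' @export
cmd_evaluate <- function(cfg, patients = NULL, model = NULL) {
  if (is.null(patients)) patients <- load_patients(cfg)
  if (is.null(model)) {
    ckpt <- cfg$paths$checkpoint %||% file.path(cfg$paths$out, "model.rds")
    if (!file.exists(ckpt))
      stop_propnet(sprintf("checkpoint not found: %s", ckpt),
                   "propnet_file_error")
    model <- load_checkpoint(ckpt)
  }
  test_ids <- cfg$evaluate$patients %||% length(patients)
  rows <- list()
  for (id in test_ids) {
    pat <- patients[[id]]
    pre_img <- normalize_intensities(pat$pretreatment$image)
    for (f in seq_along(pat$fractions)) {
      frac <- pat$fractions[[f]]
      res <- propagate(model, pre_img, pat$pretreatment$mask,
                       normalize_intensities(frac$image))
      rows[[length(rows) + 1]] <- evaluate_case(
        res$mask, frac$mask, res$field,
        case = list(patient = id, fraction = f, method = "network"))
      rows[[length(rows) + 1]] <- evaluate_case(
        pat$pretreatment$mask, frac$mask, NULL,
        case = list(patient = id, fraction = f, method = "none"))
    }
  }
  per_case <- do.call(rbind, rows)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(per_case, file.path(cfg$paths$out, "metrics.csv"),
            row.names = FALSE)
  summ <- lapply(split(per_case, per_case$method), function(d)
    list(dice_mean = mean(d$dice), dice_sd = sd(d$dice),
         hd95_mean = mean(d$hd95, na.rm = TRUE),
         hd95_sd = sd(d$hd95, na.rm = TRUE),
         centroid_mean = mean(d$centroid_mm, na.rm = TRUE)))
  jsonlite::write_json(summ, file.path(cfg$paths$out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(per_case = per_case, summary = summ))
}

#' Propagate one contour from files
#'
#' Thin wrapper: reads a checkpoint plus pretreatment image/mask and fraction
#' image (already preprocessed to the network grid), propagates, and writes
#' the mask and the 4D displacement field as NIfTI.
#'
#' @param model_path checkpoint file.
#' @param pre_path,mask_path,fraction_path input volumes.
#' @param out_dir output directory.
#' @return paths of the written files (invisibly).
#' @export
cmd_propagate <- function(model_path, pre_path, mask_path, fraction_path,
                          out_dir) {
  model <- load_checkpoint(model_path)
  pre <- normalize_intensities(read_volume(pre_path))
  mask <- read_volume(mask_path)
  frac <- normalize_intensities(read_volume(fraction_path))
  res <- propagate(model, pre, mask, frac)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  mp <- file.path(out_dir, "propagated_mask.nii.gz")
  fp <- file.path(out_dir, "field.nii.gz")
  write_volume(res$mask, mp)
  write_field(res$field, fp)
  invisible(c(mask = mp, field = fp))
}

#' Run the axial-shift experiment from a config
#'
#' @param cfg a `run_config`.
#' @param patients,model optional preloaded inputs.
#' @return the [shift_experiment] result (invisibly); CSV under
#'   `cfg$paths$out`.
#' @export
cmd_shift_experiment <- function(cfg, patients = NULL, model = NULL) {
  if (is.null(patients)) patients <- load_patients(cfg)
  if (is.null(model))
    model <- load_checkpoint(cfg$paths$checkpoint %||%
                               file.path(cfg$paths$out, "model.rds"))
  test_id <- (cfg$evaluate$patients %||% length(patients))[1]
  res <- shift_experiment(model, patients[[test_id]],
                          shifts_mm = cfg$shift$shifts_mm)
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$summary, file.path(cfg$paths$out, "shift_summary.csv"),
            row.names = FALSE)
  write.csv(res$per_case, file.path(cfg$paths$out, "shift_per_case.csv"),
            row.names = FALSE)
  invisible(res)
}

#' Run leave-one-out cross-validation from a config
#'
#' @param cfg a `run_config`.
#' @param patients optional preloaded patients.
#' @return the [crossval_harness] result (invisibly); CSV/JSON under
#'   `cfg$paths$out`.
#' @export
cmd_crossval <- function(cfg, patients = NULL) {
  obj <- config_objects(cfg)
  if (is.null(patients)) patients <- load_patients(cfg)
  res <- crossval_harness(patients, obj$network, obj$schedule, obj$weights,
                          iterations = cfg$iterations, seed = cfg$seed,
                          verbose = isTRUE(cfg$verbose))
  dir.create(cfg$paths$out, recursive = TRUE, showWarnings = FALSE)
  write.csv(res$per_case, file.path(cfg$paths$out, "crossval_per_case.csv"),
            row.names = FALSE)
  jsonlite::write_json(res$summary, file.path(cfg$paths$out,
                                              "crossval_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
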