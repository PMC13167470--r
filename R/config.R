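#' Experiment configuration
#'
#' A single nested list drives the full pipeline
#' (generate -> train -> predict -> evaluate -> calibrate). Configs load
#' from JSON (or YAML when the yaml package is installed), are validated
#' with field-path error messages, and round-trip losslessly through
#' [write_experiment_config()].
#'
#' @param x a named list, or a path to a JSON/YAML file
#' @return a validated `experiment_config`
#' @export
experiment_config <- function(x) {
  cfg <- if (is.character(x)) {
    if (grepl("\\.ya?ml$", x)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("YAML configs need the yaml package; use JSON instead")
      yaml::read_yaml(x)
    } else jsonlite::read_json(x, simplifyVector = TRUE)
  } else x
  cfg <- utils::modifyList(.default_config(), cfg)
  .validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

.default_config <- function() {
  list(
    seed = 1L,
    outdir = "vsplit_run",
    task = list(k = 2L, weights = c(1, 1), mode = "I",
                noise = list(gaussian_sigma = 10, poisson_scale = 2),
                similarity_scale = NULL),
    data = list(kinds = c("filaments", "puncta"), shape = c(256L, 256L),
                density = 8e-4),
    model = list(hierarchy_levels = 2L, base_filters = 16L, L = 1L,
                 z_channels = 8L, variant = "lean_lc", patch_size = 64L),
    loss = list(w = 0.9, alpha = NULL, kl_free_nats = 0,
                likelihood_variance_mode = "learned", fixed_sigma = 1),
    train = list(batch_size = 8L, max_epoch = 12L, learning_rate = 0.001,
                 lr_patience = 150L, steps_per_epoch = 20L, val_batches = 1L),
    inference = list(tile_size = 64L, center_size = 32L, samples = 50L),
    metrics = list(n_bins = 20L)
  )
}

#' Bundled experiment presets
#'
#' `"tiny-2ch"` is the desk-scale preset: 2 hierarchy levels, 16 base
#' filters, one context level, 64x64 patches, a 2-channel
#' filaments-versus-puncta phantom with Poisson-Gaussian noise.
#'
#' @param name preset name
#' @export
preset_config <- function(name = "tiny-2ch") {
  if (name != "tiny-2ch") stop("unknown preset '", name, "'")
  experiment_config(list())
}

.cfg_fail <- function(path, ...) stop("config error at ", path, ": ", ...,
                                      call. = FALSE)

.validate_config <- function(cfg) {
  t <- cfg$task
  if (!t$k %in% 2:4) .cfg_fail("task.k", "must be 2, 3 or 4")
  if (length(t$weights) != t$k)
    .cfg_fail("task.weights", "length must equal task.k")
  if (!t$mode %in% c("I", "II", "IIb", "III"))
    .cfg_fail("task.mode", "must be one of I, II, IIb, III")
  if (t$noise$gaussian_sigma < 0)
    .cfg_fail("task.noise.gaussian_sigma", "must be >= 0")
  if (t$noise$poisson_scale < 0)
    .cfg_fail("task.noise.poisson_scale", "must be >= 0")
  m <- cfg$model
  if (t$mode == "IIb" && m$L > 0L)
    .cfg_fail("model.L", "lateral context must be disabled (L = 0) for ",
              "mode IIb")
  if (m$L > m$hierarchy_levels - 1L)
    .cfg_fail("model.L", "must be <= hierarchy_levels - 1")
  if (m$patch_size %% 2L^m$hierarchy_levels != 0L)
    .cfg_fail("model.patch_size",
              "must be divisible by 2^hierarchy_levels")
  if (length(cfg$data$kinds) < t$k && is.null(t$similarity_scale))
    .cfg_fail("data.kinds", "need one structure kind per channel")
  if (cfg$loss$w < 0 || cfg$loss$w > 1) .cfg_fail("loss.w", "must be in [0,1]")
  if (cfg$inference$center_size > cfg$inference$tile_size)
    .cfg_fail("inference.center_size", "must be <= tile_size")
  invisible(cfg)
}

#' @rdname experiment_config
#' @param cfg an `experiment_config`
#' @param path output path (`.json`)
#' @export
write_experiment_config <- function(cfg, path) {
  drop_nulls <- function(x) {
    if (!is.list(x)) return(x)
    x <- x[!vapply(x, is.null, TRUE)]
    lapply(x, drop_nulls)
  }
  jsonlite::write_json(drop_nulls(unclass(cfg)), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a full experiment from a configuration
#'
#' Executes generate -> train -> predict -> evaluate -> calibrate and
#' writes all artifacts under `cfg$outdir`: generated data (TIFF), the
#' model checkpoint, full-frame predictions (MMSE and RMSE-estimate TIFFs),
#' a metrics JSON, the calibration curve (CSV + PNG), and a manifest
#' listing every written file with its MD5 hash, the seeds and the package
#' version.
#'
#' @param config an `experiment_config`, list, or config file path
#' @param verbose print progress
#' @return list with `model`, `history`, `metrics`, `calibration`,
#'   `manifest` (invisibly written as JSON)
#' @export
run_experiment <- function(config, verbose = FALSE) {
  cfg <- if (inherits(config, "experiment_config")) config
         else experiment_config(config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(p) { written <<- c(written, p); p }
  seed <- cfg$seed
  t <- cfg$task
  nsp <- noise_spec(t$noise$gaussian_sigma, t$noise$poisson_scale,
                    derive_seed(seed, "noise"))
  task <- mix_task(t$k, t$weights, t$mode, nsp, t$similarity_scale)

  # ---- generate ----
  shape <- cfg$data$shape
  gen_stack <- function(tag) {
    chans <- lapply(seq_len(t$k), function(i)
      stack_channel(generate_structure_channel(
        cfg$data$kinds[[min(i, length(cfg$data$kinds))]], shape,
        cfg$data$density, seed = derive_seed(seed, paste0(tag, i))), 1L))
    dat <- array(0, c(t$k, shape[1L], shape[2L]))
    for (i in seq_len(t$k)) dat[i, , ] <- chans[[i]]
    channel_stack(dat, channel_names = unlist(cfg$data$kinds)[seq_len(t$k)])
  }
  train_stack <- gen_stack("train")
  test_stack <- gen_stack("test")
  emit(write_image(file.path(cfg$outdir, "train_channels.tif"),
                   train_stack$data))
  emit(write_image(file.path(cfg$outdir, "test_channels.tif"),
                   test_stack$data))

  sampler <- make_patch_sampler(train_stack, task, cfg$model$patch_size,
                                L = cfg$model$L,
                                frame_seed = derive_seed(seed, "frames"))
  # ---- noise model ----
  nm <- if (t$noise$poisson_scale > 0 || t$noise$gaussian_sigma > 0)
    pg_noise_model(t$noise$poisson_scale, max(t$noise$gaussian_sigma, 1e-3))
  else NULL
  loss_cfg <- loss_config(w = if (is.null(nm)) 0 else cfg$loss$w,
                          alpha = cfg$loss$alpha,
                          kl_free_nats = cfg$loss$kl_free_nats,
                          likelihood_variance_mode =
                            cfg$loss$likelihood_variance_mode,
                          fixed_sigma = cfg$loss$fixed_sigma)
  if (!is.null(nm))
    emit(write_noise_model(nm, file.path(cfg$outdir, "noise_model.json")))

  # ---- train ----
  mcfg <- model_config(t$k, cfg$model$hierarchy_levels,
                       cfg$model$base_filters, cfg$model$L,
                       cfg$model$z_channels, cfg$model$variant,
                       patch_size = cfg$model$patch_size)
  model <- build_model(mcfg, seed = derive_seed(seed, "init"))
  tcfg <- do.call(train_config,
                  c(cfg$train[names(cfg$train) %in%
                                names(formals(train_config))],
                    list(seed = derive_seed(seed, "train"))))
  fit <- train(model, sampler, loss_cfg = loss_cfg, train_cfg = tcfg,
               noise_model = nm, verbose = verbose)
  emit(save_model(fit$model, file.path(cfg$outdir, "checkpoint.rds"),
                  noise_model = nm))
  utils::write.csv(fit$history,
                   emit(file.path(cfg$outdir, "history.csv")),
                   row.names = FALSE)

  # ---- predict on the held-out test frame ----
  noisy_test <- lapply(seq_len(t$k), function(i)
    apply_noise(stack_channel(test_stack, i),
                noise_spec(nsp$gaussian_sigma, nsp$poisson_scale,
                           derive_seed(seed, paste0("tn", i)))))
  mixed <- Reduce(`+`, Map(function(w, m) w * m, as.list(task$weights),
                           noisy_test))
  pred <- tiled_predict(fit$model, mixed,
                        tile_size = cfg$inference$tile_size,
                        center_size = cfg$inference$center_size,
                        S = cfg$inference$samples,
                        seed = derive_seed(seed, "pred"))
  emit(write_image(file.path(cfg$outdir, "pred_mmse.tif"),
                   aperm(pred$mmse, c(3L, 1L, 2L))))
  emit(write_image(file.path(cfg$outdir, "pred_rmse_estimate.tif"),
                   aperm(pred$rmse_estimate, c(3L, 1L, 2L))))

  # ---- evaluate + calibrate ----
  metrics <- lapply(seq_len(t$k), function(i) {
    gt <- task$weights[i] * stack_channel(test_stack, i)
    list(channel = i,
         psnr = care_psnr(pred$mmse[, , i], gt),
         ms_ssim = micro_ms_ssim(pred$mmse[, , i], gt))
  })
  jsonlite::write_json(metrics,
                       emit(file.path(cfg$outdir, "metrics.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gt_all <- array(0, dim(pred$mmse))
  for (i in seq_len(t$k))
    gt_all[, , i] <- task$weights[i] * stack_channel(test_stack, i)
  calib <- calibration_analysis(pred$rmse_estimate, pred$mmse, gt_all,
                                n_bins = cfg$metrics$n_bins)
  if (!calib$degenerate) {
    utils::write.csv(calib$bins,
                     emit(file.path(cfg$outdir, "calibration.csv")),
                     row.names = FALSE)
    grDevices::png(emit(file.path(cfg$outdir, "calibration.png")),
                   width = 600, height = 600)
    plot(calib)
    grDevices::dev.off()
  }

  # ---- manifest ----
  manifest <- list(
    package_version = as.character(utils::packageVersion("vsplit")),
    seed = seed,
    files = lapply(written, function(p)
      list(path = basename(p), md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(model = fit$model, history = fit$history,
                 metrics = metrics, calibration = calib,
                 manifest = manifest))
}
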