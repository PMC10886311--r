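#' Derive a stage seed from the master seed
#'
#' Stage seeds are a documented deterministic function of the master seed and
#' the stage name (`(seed * 31 + sum of UTF-8 codes of the name * 10007) mod
#' (2^31 - 1)`), so any stage can be rerun alone and reproduce its output.
#'
#' @param master_seed integer master seed.
#' @param stage stage name.
#' @return An integer seed.
#' @export
stage_seed <- function(master_seed, stage) {
  as.integer((as.numeric(master_seed) * 31 +
              sum(utf8ToInt(stage)) * 10007) %% (2^31 - 1))
}

pipeline_stages <- c("phantom", "preprocess", "synth", "train", "upscale",
                     "evaluate")

#' Run the end-to-end pipeline
#'
#' Executes the requested stages in order — phantom generation, stack
#' preprocessing, semi-synthetic pair generation, model training, upscaling,
#' evaluation — carrying intermediate objects forward and writing
#' self-describing outputs (TIFF stacks, TSV tables, a YAML report with the
#' fully resolved configuration) into the output directory. Re-running with
#' an identical configuration reproduces the metric tables (floating-point
#' tolerance 1e-6 relative).
#'
#' @param config a named list, or path to a YAML file, with entries:
#'   `seed` (master seed), `out_dir`, `stages` (subset of
#'   `r paste(pipeline_stages, collapse = ", ")`), and one optional block per
#'   stage with its parameters (see the pipeline vignette).
#' @return A run report list (invisibly): resolved config, per-stage outputs,
#'   metric tables.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  stages <- config$stages %||% c("phantom", "synth", "train", "upscale",
                                 "evaluate")
  unknown <- setdiff(stages, pipeline_stages)
  if (length(unknown))
    stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% tempfile("vesselsr_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state <- list()
  report <- list(config = config, seed = seed, out_dir = out_dir,
                 stages = list())
  for (stg in stages) {
    res <- tryCatch(
      switch(stg,
             phantom   = stage_phantom(config, state, seed, out_dir),
             preprocess = stage_preprocess(config, state, out_dir),
             synth     = stage_synth(config, state, seed),
             train     = stage_train(config, state, seed, out_dir),
             upscale   = stage_upscale(config, state, out_dir),
             evaluate  = stage_evaluate(config, state, out_dir)),
      error = function(e) {
        report$stages[[stg]] <- list(status = "failed",
                                     error = conditionMessage(e))
        yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
        stop(sprintf("stage '%s' failed: %s", stg, conditionMessage(e)),
             call. = FALSE)
      })
    state <- res$state
    report$stages[[stg]] <- res$report
  }
  yaml::write_yaml(report, file.path(out_dir, "report.yaml"))
  invisible(report)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_phantom <- function(config, state, seed, out_dir) {
  p <- config$phantom %||% list()
  cfg <- do.call(phantom_config,
                 c(p[setdiff(names(p), "seed")],
                   list(seed = stage_seed(seed, "phantom"))))
  ph <- generate_phantom(cfg)
  write_stack(ph$image, file.path(out_dir, "phantom.tif"))
  utils::write.table(ph$strand_table, file.path(out_dir, "phantom_strands.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  state$hr_stack <- ph$image
  state$truth_mask <- ph$truth_mask
  state$phantom <- ph
  list(state = state,
       report = list(status = "ok", config = unclass(cfg),
                     fg_fraction = mean(ph$truth_mask)))
}

stage_preprocess <- function(config, state, out_dir) {
  p <- config$preprocess %||% list()
  stk <- if (!is.null(p$input)) read_stack(p$input) else state$hr_stack
  if (is.null(stk)) stop("no input stack (give preprocess$input or run phantom)")
  out <- preprocess_stack(stk, radius = p$radius %||% c(1L, 1L, 1L),
                          saturation_frac = p$saturation_frac %||% 0.003)
  write_stack(out, file.path(out_dir, "preprocessed.tif"))
  state$hr_stack <- out
  list(state = state, report = list(status = "ok", bit_depth = out$bit_depth))
}

stage_synth <- function(config, state, seed) {
  p <- config$synth %||% list()
  if (is.null(state$hr_stack)) stop("no HR stack for synth stage")
  cfg <- noise_config(kind = p$noise %||% "additive_gaussian",
                      mu = p$mu %||% 0,
                      sigma = p$sigma %||% NULL,
                      local_var_scale = p$local_var_scale %||% 0.001,
                      gain = p$gain %||% 50)
  samples <- make_single_frame_dataset(state$hr_stack, cfg,
                                       factor = p$factor %||% 4L,
                                       seed = stage_seed(seed, "synth"))
  window <- p$window %||% 1L
  if (window > 1L) samples <- make_multiframe_dataset(samples, window)
  hold <- p$holdout_frac %||% 0.2
  n_hold <- max(1L, round(hold * length(samples)))
  hold_idx <- seq(length(samples) - n_hold + 1L, length(samples))
  state$train_samples <- samples[-hold_idx]
  state$test_samples <- samples[hold_idx]
  state$noise_cfg <- cfg
  list(state = state,
       report = list(status = "ok", n_train = length(state$train_samples),
                     n_test = length(state$test_samples), window = window))
}

stage_train <- function(config, state, seed, out_dir) {
  p <- config$train %||% list()
  if (is.null(state$train_samples)) stop("no training samples (run synth)")
  window <- if (is.list(state$train_samples[[1L]]$lr))
    length(state$train_samples[[1L]]$lr) else 1L
  mcfg <- model_config(in_frames = p$in_frames %||% window,
                       scale = p$scale %||% 4L,
                       encoder_depth = p$encoder_depth %||% 2L,
                       base_channels = p$base_channels %||% 8L,
                       seed = stage_seed(seed, "train"))
  tcfg <- train_config(learning_rate = p$learning_rate %||% NULL,
                       epochs = p$epochs %||% 5L,
                       batch_size = p$batch_size %||% 8L,
                       seed = stage_seed(seed, "train"))
  fit <- pssr(state$train_samples, val = state$test_samples,
              model = mcfg, train = tcfg)
  ckpt <- file.path(out_dir, "model.rds")
  pssr_save(fit, ckpt)
  state$model <- fit
  list(state = state,
       report = list(status = "ok", checkpoint = ckpt,
                     history = fit$history))
}

stage_upscale <- function(config, state, out_dir) {
  p <- config$upscale %||% list()
  model <- if (!is.null(p$model)) pssr_load(p$model) else state$model
  if (is.null(model)) stop("no model (run train or give upscale$model)")
  lr_stack <- if (!is.null(p$input)) read_stack(p$input) else state$lr_stack
  if (is.null(lr_stack)) {
    if (is.null(state$hr_stack)) stop("no LR input for upscale stage")
    f <- model$model$scale
    d <- dim(state$hr_stack$voxels)
    vox <- array(0, c(d[1L], d[2L] %/% f, d[3L] %/% f))
    mxv <- 2^state$hr_stack$bit_depth - 1
    set.seed(stage_seed(config$seed %||% 1L, "upscale"))
    for (i in seq_len(d[1L]))
      vox[i, , ] <- downscale(inject_noise(state$hr_stack$voxels[i, , ] / mxv,
                                           state$noise_cfg %||% noise_config()),
                              f) * mxv
    lr_stack <- image_stack(vox, spacing_um = state$hr_stack$spacing_um,
                            bit_depth = state$hr_stack$bit_depth)
  }
  state$lr_stack <- lr_stack
  state$upscaled <- predict(model, lr_stack)
  state$bilinear <- bilinear_upscale(lr_stack, model$model$scale)
  write_stack(state$upscaled, file.path(out_dir, "upscaled.tif"))
  write_stack(state$bilinear, file.path(out_dir, "bilinear.tif"))
  list(state = state, report = list(status = "ok",
                                    frames = n_frames(state$upscaled)))
}

stage_evaluate <- function(config, state, out_dir) {
  if (is.null(state$upscaled)) stop("nothing to evaluate (run upscale)")
  if (is.null(state$hr_stack)) stop("no reference stack for evaluation")
  tab <- metric_report(state$hr_stack, model = state$upscaled,
                       bilinear = state$bilinear)
  utils::write.table(tab, file.path(out_dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rep <- list(status = "ok",
              median_psnr_model = stats::median(
                tab$psnr[tab$method == "model" & is.finite(tab$psnr)]),
              median_psnr_bilinear = stats::median(
                tab$psnr[tab$method == "bilinear" & is.finite(tab$psnr)]))
  if (!is.null(state$truth_mask)) {
    sw_m <- peak_accuracy_sweep(state$upscaled, state$truth_mask)
    sw_b <- peak_accuracy_sweep(state$bilinear, state$truth_mask)
    rep$peak_accuracy_model <- sw_m$best_accuracy
    rep$peak_accuracy_bilinear <- sw_b$best_accuracy
  }
  state$metrics <- tab
  list(state = state, report = rep)
}
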