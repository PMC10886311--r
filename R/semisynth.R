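#' Noise configuration for semi-synthetic degradation
#'
#' Describes which noise model is injected into a high-resolution frame before
#' downscaling. Frames are handled on the normalized `[0, 1]` scale; parameter
#' conventions follow the analysis environment the models were tuned in:
#'
#' * `"gaussian"`: additive `N(mu, sigma^2)` with `mu`, `sigma` on the
#'   `[0, 1]` scale (default `sigma = 0.1`).
#' * `"additive_gaussian"`: signal-dependent Gaussian noise with `mu` and
#'   `sigma` quoted on the 8-bit `[0, 255]` scale (default `sigma = 5`, used
#'   as `sigma/255`) plus a local-variance term `local_var_scale * I`
#'   (default 0.001) on the `[0, 1]` scale.
#' * `"poisson"`: shot noise; a pixel value `p` is mapped to an expected
#'   photon count `gain * p` and replaced by `Poisson(gain * p) / gain`.
#' * `"none"`: identity (downscale-only reference).
#'
#' @param kind one of `"none"`, `"poisson"`, `"gaussian"`, `"additive_gaussian"`.
#' @param mu Gaussian mean (scale convention as above).
#' @param sigma Gaussian standard deviation, >= 0 (scale convention as above).
#' @param local_var_scale signal-proportional variance coefficient, >= 0
#'   (`additive_gaussian` only).
#' @param gain expected photon count at full scale (`poisson` only).
#' @return A `noise_config` list.
#' @export
noise_config <- function(kind = c("none", "poisson", "gaussian",
                                  "additive_gaussian"),
                         mu = 0, sigma = NULL, local_var_scale = 0.001,
                         gain = 50) {
  kind <- match.arg(kind)
  if (is.null(sigma)) sigma <- switch(kind, gaussian = 0.1,
                                      additive_gaussian = 5, 0)
  if (sigma < 0) stop("`sigma` must be >= 0")
  if (local_var_scale < 0) stop("`local_var_scale` must be >= 0")
  if (gain <= 0) stop("`gain` must be > 0")
  structure(list(kind = kind, mu = mu, sigma = sigma,
                 local_var_scale = local_var_scale, gain = gain),
            class = "noise_config")
}

#' Inject noise into a normalized frame
#'
#' @param frame numeric matrix with values in `[0, 1]`.
#' @param cfg a [noise_config]. The caller controls the RNG state; seed before
#'   calling for reproducibility.
#' @return A matrix of the same shape, clipped to `[0, 1]` (saturating sensor
#'   model).
#' @export
inject_noise <- function(frame, cfg = noise_config()) {
  stopifnot(is.matrix(frame), inherits(cfg, "noise_config"))
  rng <- range(frame)
  if (rng[1L] < 0 || rng[2L] > 1) stop("`frame` values must lie in [0, 1]")
  n <- length(frame)
  out <- switch(cfg$kind,
    none = frame,
    gaussian = frame + stats::rnorm(n, cfg$mu, cfg$sigma),
    additive_gaussian = {
      sd_loc <- sqrt((cfg$sigma / 255)^2 + cfg$local_var_scale * frame)
      frame + cfg$mu / 255 + stats::rnorm(n, 0, 1) * sd_loc
    },
    poisson = stats::rpois(n, cfg$gain * frame) / cfg$gain)
  out[out < 0] <- 0
  out[out > 1] <- 1
  matrix(out, nrow(frame), ncol(frame))
}

#' Downscale a frame by an integer factor
#'
#' `method = "area"` (default) replaces each `factor x factor` block by its
#' exact mean, conserving mean intensity; `"bilinear"` resamples with the
#' half-pixel-centre convention.
#'
#' @param frame numeric matrix whose sides are divisible by `factor`.
#' @param factor integer downscaling factor (default 4, i.e. 512 -> 128).
#' @param method `"area"` or `"bilinear"`.
#' @return A matrix with sides `dim(frame) / factor`.
#' @export
downscale <- function(frame, factor = 4L, method = c("area", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.matrix(frame))
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be a positive integer")
  d <- dim(frame)
  if (any(d %% factor != 0L)) stop("frame sides must be divisible by `factor`")
  if (factor == 1L) return(frame)
  if (method == "area") {
    h2 <- d[1L] %/% factor; w2 <- d[2L] %/% factor
    # mean over factor x factor blocks via two grouped row sums
    g <- rowsum(frame, rep(seq_len(h2), each = factor), reorder = FALSE)
    g <- rowsum(t(g), rep(seq_len(w2), each = factor), reorder = FALSE)
    out <- t(g) / factor^2
    dimnames(out) <- NULL
    out
  } else {
    bilinear_resize(frame, c(d[1L] %/% factor, d[2L] %/% factor))
  }
}

#' Build single-frame training samples from high-resolution frames
#'
#' Each high-resolution frame (normalized to `[0, 1]`) is degraded by noise
#' injection followed by fourfold (by default) downscaling, producing one
#' LR-input / HR-target pair per frame. Deterministic given `seed`.
#'
#' @param hr_frames list of numeric matrices in `[0, 1]`, ordered by z within
#'   each stack, or a single [image_stack] (intensities are rescaled by its
#'   bit-range maximum).
#' @param cfg a [noise_config].
#' @param factor integer downscaling factor.
#' @param seed integer RNG seed.
#' @param stack_id identifier(s) for the source stack; either length 1 or one
#'   per frame. Multi-frame windows never cross stack ids.
#' @return A list of `training_sample` objects, each with elements `lr`
#'   (matrix), `hr` (matrix), `z_index`, `stack_id`.
#' @export
make_single_frame_dataset <- function(hr_frames, cfg = noise_config(),
                                      factor = 4L, seed = 1L,
                                      stack_id = "stack1") {
  if (inherits(hr_frames, "image_stack")) {
    mx <- bit_max(hr_frames)
    hr_frames <- lapply(seq_len(n_frames(hr_frames)),
                        function(i) hr_frames$voxels[i, , ] / mx)
  }
  if (length(hr_frames) == 0L) stop("no frames supplied")
  if (length(stack_id) == 1L) stack_id <- rep(stack_id, length(hr_frames))
  stopifnot(length(stack_id) == length(hr_frames))
  set.seed(as.integer(seed))
  z <- stats::ave(seq_along(hr_frames), stack_id, FUN = seq_along)
  out <- vector("list", length(hr_frames))
  for (i in seq_along(hr_frames)) {
    lr <- downscale(inject_noise(hr_frames[[i]], cfg), factor)
    out[[i]] <- structure(list(lr = lr, hr = hr_frames[[i]],
                               z_index = z[i], stack_id = stack_id[i]),
                          class = "training_sample")
  }
  out
}

#' Assemble multi-frame training samples
#'
#' Groups single-frame samples by stack, slides a window of `window`
#' consecutive z positions, and emits one sample per valid centre: the input
#' is the window's LR frames and the target is the HR frame of the middle
#' (third, for `window = 5`) position. Windows never span stack boundaries,
#' so a stack of `n` frames yields `n - window + 1` samples.
#'
#' @param samples list of `training_sample` objects from
#'   [make_single_frame_dataset()], ordered by z within each stack.
#' @param window odd integer window length (default 5).
#' @return A list of `training_sample` objects whose `lr` element is a list of
#'   `window` LR matrices; empty (with a warning) if every stack is shorter
#'   than `window`.
#' @export
make_multiframe_dataset <- function(samples, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) stop("`window` must be odd")
  ids <- vapply(samples, function(s) s$stack_id, "")
  out <- list()
  for (id in unique(ids)) {
    grp <- samples[ids == id]
    grp <- grp[order(vapply(grp, function(s) s$z_index, 1))]
    n <- length(grp)
    if (n < window) next
    half <- (window - 1L) %/% 2L
    for (c0 in seq(half + 1L, n - half)) {
      out[[length(out) + 1L]] <- structure(
        list(lr = lapply(grp[(c0 - half):(c0 + half)], function(s) s$lr),
             hr = grp[[c0]]$hr, z_index = grp[[c0]]$z_index,
             stack_id = id),
        class = "training_sample")
    }
  }
  if (length(out) == 0L)
    warning("no stack has at least `window` frames; empty dataset")
  out
}
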