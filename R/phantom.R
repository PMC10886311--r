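#' Phantom configuration
#'
#' Parameters of the synthetic 3D tubular-network generator. Defaults emulate
#' the imaging conditions the pipeline targets: 16-bit stacks, ~1.37 um
#' in-plane pixels (700 um field over 512 pixels) with 3 um axial spacing,
#' vascular foreground occupying 5-10% of the volume, and contrast-to-noise
#' ratio 0.94. Foreground/background levels sit mid-range (39768 / 32768) so
#' that CNR-0.94 noise stays more than four standard deviations away from the
#' clip points.
#'
#' @param volume_shape integer length-3 voxel counts (z, y, x).
#' @param spacing_um voxel size (z, y, x) in micrometres.
#' @param n_strands maximum number of strands to lay down; generation stops
#'   early once `target_fg_fraction` is reached.
#' @param radius_range_um min/max vessel radius in micrometres.
#' @param tortuosity_amplitude per-step direction perturbation (0 = straight).
#' @param target_fg_fraction desired foreground voxel fraction in (0, 0.5).
#' @param target_cnr contrast-to-noise ratio of the noisy image (default 0.94).
#' @param psf_sigma_um Gaussian PSF standard deviations (z, y, x) in
#'   micrometres; anisotropy (wider axially) mimics two-photon optics.
#' @param fg_level,bg_level clean foreground/background intensity levels.
#' @param bit_depth 8 or 16.
#' @param step_um centerline step length in micrometres.
#' @param seed RNG seed; the whole phantom is a pure function of the config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(volume_shape = c(48L, 128L, 128L),
                           spacing_um = c(3, 1.37, 1.37),
                           n_strands = 80L,
                           radius_range_um = c(2, 6),
                           tortuosity_amplitude = 0.3,
                           target_fg_fraction = 0.075,
                           target_cnr = 0.94,
                           psf_sigma_um = c(2, 0.5, 0.5),
                           fg_level = 39768, bg_level = 32768,
                           bit_depth = 16L, step_um = 2, seed = 1L) {
  if (any(radius_range_um <= 0)) stop("radii must be positive")
  if (target_fg_fraction <= 0 || target_fg_fraction >= 0.5)
    stop("`target_fg_fraction` must lie in (0, 0.5)")
  if (target_cnr <= 0) stop("`target_cnr` must be > 0")
  structure(list(volume_shape = as.integer(volume_shape),
                 spacing_um = as.numeric(spacing_um),
                 n_strands = as.integer(n_strands),
                 radius_range_um = as.numeric(radius_range_um),
                 tortuosity_amplitude = tortuosity_amplitude,
                 target_fg_fraction = target_fg_fraction,
                 target_cnr = target_cnr,
                 psf_sigma_um = as.numeric(psf_sigma_um),
                 fg_level = fg_level, bg_level = bg_level,
                 bit_depth = as.integer(bit_depth),
                 step_um = step_um, seed = as.integer(seed)),
            class = "phantom_config")
}

# physical extent of the volume in um (z, y, x)
phantom_extent <- function(cfg) cfg$volume_shape * cfg$spacing_um

# one random-walk strand inside the volume, in physical um coordinates
random_strand <- function(cfg) {
  ext <- phantom_extent(cfg)
  start <- stats::runif(3) * ext
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  max_steps <- ceiling(2 * max(ext) / cfg$step_um)
  pts <- matrix(0, max_steps + 1L, 3L)
  pts[1L, ] <- start
  r <- numeric(max_steps + 1L)
  r[1L] <- stats::runif(1, cfg$radius_range_um[1L], cfg$radius_range_um[2L])
  r_jit <- 0.05 * diff(cfg$radius_range_um)
  n <- 1L
  for (i in seq_len(max_steps)) {
    if (cfg$tortuosity_amplitude > 0) {
      dir <- dir + cfg$tortuosity_amplitude * stats::rnorm(3)
      dir <- dir / sqrt(sum(dir^2))
    }
    nxt <- pts[n, ] + cfg$step_um * dir
    if (any(nxt < 0) || any(nxt > ext)) break
    n <- n + 1L
    pts[n, ] <- nxt
    r[n] <- min(max(r[n - 1L] + r_jit * stats::rnorm(1),
                    cfg$radius_range_um[1L]), cfg$radius_range_um[2L])
  }
  if (n < 2L) return(NULL)
  strand(pts[seq_len(n), , drop = FALSE], r[seq_len(n)])
}

# stamp one strand into a logical mask (voxel centre within local radius)
stamp_strand <- function(mask, s, cfg) {
  shp <- cfg$volume_shape; sp <- cfg$spacing_um
  cl <- s$centerline; rr <- s$radii
  ds <- min(sp) / 2                     # dense sub-sampling along the path
  for (k in seq_len(nrow(cl) - 1L)) {
    seg <- cl[k + 1L, ] - cl[k, ]
    slen <- sqrt(sum(seg^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(slen / ds) + 1L))
    for (t in ts) {
      p <- cl[k, ] + t * seg
      r <- (1 - t) * rr[k] + t * rr[k + 1L]
      lo <- pmax(1L, ceiling((p - r) / sp + 0.5))
      hi <- pmin(shp, floor((p + r) / sp + 0.5))
      if (any(lo > hi)) next
      zi <- lo[1L]:hi[1L]; yi <- lo[2L]:hi[2L]; xi <- lo[3L]:hi[3L]
      dz2 <- ((zi - 0.5) * sp[1L] - p[1L])^2
      dy2 <- ((yi - 0.5) * sp[2L] - p[2L])^2
      dx2 <- ((xi - 0.5) * sp[3L] - p[3L])^2
      inside <- outer(outer(dz2, dy2, "+"), dx2, "+") <= r^2
      mask[zi, yi, xi] <- mask[zi, yi, xi, drop = FALSE] | inside
    }
  }
  mask
}

#' Generate a random set of vessel strands
#'
#' Lays down smooth random-walk polylines with slowly varying radii until the
#' rasterized foreground fraction reaches `target_fg_fraction` or `n_strands`
#' strands have been placed; errors if the target is unreachable even after
#' retrying with additional strands. Deterministic given `cfg$seed`.
#'
#' @param cfg a [phantom_config].
#' @return A list of [strand] objects.
#' @export
generate_strands <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  set.seed(cfg$seed)
  mask <- array(FALSE, cfg$volume_shape)
  nvox <- prod(cfg$volume_shape)
  strands <- list()
  max_attempts <- 5L * cfg$n_strands
  attempts <- 0L
  while (attempts < max_attempts) {
    attempts <- attempts + 1L
    s <- random_strand(cfg)
    if (is.null(s)) next
    strands[[length(strands) + 1L]] <- s
    mask <- stamp_strand(mask, s, cfg)
    frac <- sum(mask) / nvox
    if (frac >= cfg$target_fg_fraction) break
    if (length(strands) >= cfg$n_strands && frac >= cfg$target_fg_fraction - 0.02)
      break
  }
  frac <- sum(mask) / nvox
  if (frac < cfg$target_fg_fraction - 0.02)
    stop(sprintf(paste0("cannot reach foreground fraction %.3f ",
                        "(achieved %.3f after %d strands)"),
                 cfg$target_fg_fraction, frac, length(strands)))
  strands
}

# separable Gaussian blur of a 3D array, reflection padding
gauss_blur_3d <- function(vol, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    rad <- max(1L, ceiling(3 * s))
    k <- exp(-(-rad:rad)^2 / (2 * s^2)); k <- k / sum(k)
    n <- dim(vol)[axis]
    idx0 <- seq_len(n)
    acc <- array(0, dim(vol))
    for (j in -rad:rad) {
      src <- idx0 + j
      src[src < 1L] <- 1L - src[src < 1L]          # mirror
      src[src > n] <- 2L * n - src[src > n]
      acc <- acc + k[j + rad + 1L] *
        switch(axis, vol[src, , , drop = FALSE], vol[, src, , drop = FALSE],
               vol[, , src, drop = FALSE])
    }
    vol <- acc
  }
  vol
}

#' Rasterize strands into a ground-truth mask and clean intensity image
#'
#' The mask marks voxels whose centre lies within the locally interpolated
#' radius of any strand centerline (geometry only — independent of intensity
#' levels). The clean image paints foreground/background levels and applies
#' the anisotropic Gaussian PSF blur.
#'
#' @param strands list of [strand] objects.
#' @param cfg a [phantom_config].
#' @return A list with `truth_mask` (logical array) and `clean_image`
#'   ([image_stack]).
#' @export
rasterize <- function(strands, cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  mask <- array(FALSE, cfg$volume_shape)
  for (s in strands) mask <- stamp_strand(mask, s, cfg)
  img <- array(cfg$bg_level, cfg$volume_shape)
  img[mask] <- cfg$fg_level
  img <- gauss_blur_3d(img, cfg$psf_sigma_um / cfg$spacing_um)
  list(truth_mask = mask,
       clean_image = image_stack(img, spacing_um = cfg$spacing_um,
                                 bit_depth = cfg$bit_depth))
}

#' Add background noise calibrated to a target CNR
#'
#' Solves the CNR definition `(mean_fg - mean_bg)/sd_bg` for the Gaussian
#' noise standard deviation that brings the noisy image to `target_cnr`,
#' accounting for the clean image's residual background variance (PSF halo):
#' `sigma = sqrt((contrast/target)^2 - var_bg_clean)`.
#'
#' @param clean_image an [image_stack] (e.g. from [rasterize()]).
#' @param truth_mask logical foreground mask of the same shape.
#' @param target_cnr target contrast-to-noise ratio (default 0.94).
#' @param seed RNG seed.
#' @return A noisy [image_stack], clipped to the bit range.
#' @export
calibrate_noise_to_cnr <- function(clean_image, truth_mask, target_cnr = 0.94,
                                   seed = 1L) {
  stopifnot(inherits(clean_image, "image_stack"))
  v <- clean_image$voxels
  if (!identical(dim(v), dim(truth_mask))) stop("mask shape mismatch")
  fg <- as.logical(truth_mask); bg <- !fg
  if (!any(fg) || !any(bg)) stop("degenerate mask")
  contrast <- mean(v[fg]) - mean(v[bg])
  if (contrast <= 0) stop("target unreachable: zero contrast")
  v0 <- stats::var(v[bg])
  s2 <- (contrast / target_cnr)^2 - v0
  if (s2 <= 0)
    stop("target unreachable: clean background already noisier than target")
  set.seed(as.integer(seed))
  out <- v + stats::rnorm(length(v), 0, sqrt(s2))
  mx <- 2^clean_image$bit_depth - 1
  out[out < 0] <- 0; out[out > mx] <- mx
  image_stack(out, spacing_um = clean_image$spacing_um,
              bit_depth = clean_image$bit_depth)
}

#' Generate one complete phantom
#'
#' Convenience wrapper: strands, ground-truth mask, clean image, CNR-matched
#' noisy image and strand table in one call.
#'
#' @param cfg a [phantom_config].
#' @return A list with `image` (noisy [image_stack]), `clean_image`,
#'   `truth_mask`, `strands`, `strand_table`.
#' @export
generate_phantom <- function(cfg = phantom_config()) {
  strands <- generate_strands(cfg)
  ras <- rasterize(strands, cfg)
  noisy <- calibrate_noise_to_cnr(ras$clean_image, ras$truth_mask,
                                  cfg$target_cnr, seed = cfg$seed + 1L)
  list(image = noisy, clean_image = ras$clean_image,
       truth_mask = ras$truth_mask, strands = strands,
       strand_table = strand_table(strands))
}

#' Generate a phantom dataset of several volumes
#'
#' Produces `n_volumes` independent phantoms with per-volume seeds derived
#' from the master seed; optionally writes each volume's noisy image and mask
#' as TIFF, its strand table as TSV, and a manifest.
#'
#' @param cfg a [phantom_config] (its `seed` is the master seed).
#' @param n_volumes number of phantoms.
#' @param out_dir optional output directory.
#' @return A list of phantoms (see [generate_phantom()]); when `out_dir` is
#'   given, each element also records its file paths, and a `manifest.tsv` is
#'   written.
#' @export
make_phantom_dataset <- function(cfg = phantom_config(), n_volumes = 1L,
                                 out_dir = NULL) {
  vols <- vector("list", n_volumes)
  manifest <- NULL
  for (i in seq_len(n_volumes)) {
    ci <- cfg
    ci$seed <- (cfg$seed + 7919L * i) %% .Machine$integer.max
    vols[[i]] <- generate_phantom(ci)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      img_p <- file.path(out_dir, sprintf("phantom_%03d.tif", i))
      msk_p <- file.path(out_dir, sprintf("phantom_%03d_mask.tif", i))
      tab_p <- file.path(out_dir, sprintf("phantom_%03d_strands.tsv", i))
      write_stack(vols[[i]]$image, img_p)
      mask8 <- image_stack(array(255 * vols[[i]]$truth_mask,
                                 dim(vols[[i]]$truth_mask)),
                           spacing_um = cfg$spacing_um, bit_depth = 8L)
      write_stack(mask8, msk_p)
      utils::write.table(vols[[i]]$strand_table, tab_p, sep = "\t",
                         row.names = FALSE, quote = FALSE)
      vols[[i]]$paths <- list(image = img_p, mask = msk_p, strands = tab_p)
      manifest <- rbind(manifest,
                        data.frame(volume = i, seed = ci$seed, image = img_p,
                                   mask = msk_p, strand_table = tab_p))
    }
  }
  if (!is.null(out_dir))
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  vols
}
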