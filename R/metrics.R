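# separable 1D kernel convolution along both axes, valid mode
conv_valid_sep <- function(m, k) {
  n <- length(k)
  h <- nrow(m) - n + 1L; w <- ncol(m) - n + 1L
  if (h < 1L || w < 1L) stop("frame smaller than SSIM window")
  out <- matrix(0, h, ncol(m))
  for (i in seq_len(n)) out <- out + k[i] * m[i:(i + h - 1L), , drop = FALSE]
  out2 <- matrix(0, h, w)
  for (j in seq_len(n)) out2 <- out2 + k[j] * out[, j:(j + w - 1L), drop = FALSE]
  out2
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(R^2 / MSE)` where `MSE` is the mean squared pixel
#' difference and `R` the peak signal value. Identical frames give `Inf`.
#'
#' @param x,y numeric matrices (or arrays) of identical shape.
#' @param peak peak signal value `R` (> 0); use the bit-range maximum of the
#'   stack, e.g. 255 for 8-bit data.
#' @return PSNR in decibels.
#' @export
psnr <- function(x, y, peak = 255) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (peak <= 0) stop("`peak` must be > 0")
  mse <- mean((as.numeric(x) - as.numeric(y))^2)
  if (mse == 0) return(Inf)
  10 * log10(peak^2 / mse)
}

#' Structural similarity index (SSIM)
#'
#' Standard SSIM with local statistics taken under a Gaussian-weighted window
#' (11 pixels, sigma 1.5 by default) and the variance terms squared in the
#' denominator:
#' `((2 mu_x mu_y + C1)(2 sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))`,
#' averaged over the valid (fully-overlapping) window positions.
#'
#' @inheritParams psnr
#' @param C1,C2 stabilization constants; defaults `(0.01 peak)^2` and
#'   `(0.03 peak)^2`.
#' @param window odd window side in pixels.
#' @param sigma Gaussian window standard deviation in pixels.
#' @return SSIM value in `[-1, 1]`.
#' @export
ssim <- function(x, y, peak = 255, C1 = (0.01 * peak)^2, C2 = (0.03 * peak)^2,
                 window = 11L, sigma = 1.5) {
  if (!identical(dim(x), dim(y))) stop("shape mismatch")
  if (C1 <= 0 || C2 <= 0) stop("C1 and C2 must be > 0")
  x <- matrix(as.numeric(x), nrow(x)); y <- matrix(as.numeric(y), nrow(y))
  t0 <- seq_len(window) - (window + 1) / 2
  k <- exp(-t0^2 / (2 * sigma^2)); k <- k / sum(k)
  mx <- conv_valid_sep(x, k);  my <- conv_valid_sep(y, k)
  sxx <- conv_valid_sep(x * x, k) - mx^2
  syy <- conv_valid_sep(y * y, k) - my^2
  sxy <- conv_valid_sep(x * y, k) - mx * my
  map <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
         ((mx^2 + my^2 + C1) * (sxx + syy + C2))
  mean(map)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (mean(I_fg) - mean(I_bg)) / sd(I_bg)` over the supplied foreground
#' and background masks.
#'
#' @param image an [image_stack], array or matrix of intensities.
#' @param fg_mask,bg_mask logical masks of the same shape as the image,
#'   disjoint and each non-empty.
#' @return The CNR as a single number.
#' @export
cnr <- function(image, fg_mask, bg_mask) {
  if (inherits(image, "image_stack")) image <- image$voxels
  if (!identical(dim(image), dim(fg_mask)) ||
      !identical(dim(image), dim(bg_mask))) stop("mask shape mismatch")
  fg_mask <- as.logical(fg_mask); bg_mask <- as.logical(bg_mask)
  if (!any(fg_mask) || !any(bg_mask)) stop("masks must be non-empty")
  if (any(fg_mask & bg_mask)) stop("masks must be disjoint")
  s <- stats::sd(image[bg_mask])
  if (s == 0) stop("zero background variance")
  (mean(image[fg_mask]) - mean(image[bg_mask])) / s
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired metric series. Zero differences are
#' dropped (Wilcoxon's convention), ties get mid-ranks; the exact null
#' distribution is used for n <= 25 without ties, otherwise the normal
#' approximation with continuity correction.
#'
#' @param a,b numeric vectors of equal length (per-frame metric values for two
#'   methods, aligned by z-index).
#' @return Two-sided p-value.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b)) stop("series must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) stop("all paired differences are zero")
  if (length(d) < 5L) warning("fewer than 5 non-zero differences")
  exact <- length(d) <= 25L && !anyDuplicated(abs(d))
  suppressWarnings(
    stats::wilcox.test(d, alternative = "two.sided", mu = 0,
                       exact = exact, correct = TRUE)$p.value)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha base significance level (default 0.05).
#' @param m number of comparisons (>= 1).
#' @return `alpha / m`; e.g. three upscaling-method comparisons give 0.0167.
#' @export
bonferroni <- function(alpha = 0.05, m) {
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("`m` must be >= 1")
  alpha / m
}

#' Per-frame PSNR/SSIM report for method comparison
#'
#' Computes PSNR and SSIM of each method's stack against a reference stack,
#' frame by frame, and appends median / IQR summary rows — the tabular
#' counterpart of the usual boxplot comparison. Infinite PSNR values
#' (identical frames) are excluded from summaries with a warning.
#'
#' @param reference an [image_stack] (ground truth / acquired HR).
#' @param ... named [image_stack] objects, one per method.
#' @return A data.frame with columns `frame`, `method`, `psnr`, `ssim`;
#'   summary rows carry `frame = NA` and methods suffixed `.median` / `.iqr`.
#' @export
metric_report <- function(reference, ...) {
  methods <- list(...)
  if (length(methods) == 0L || is.null(names(methods)))
    stop("supply named method stacks")
  mx <- bit_max(reference)
  rows <- list()
  for (nm in names(methods)) {
    s <- methods[[nm]]
    stopifnot(n_frames(s) == n_frames(reference))
    p <- vapply(seq_len(n_frames(s)), function(i)
      psnr(s$voxels[i, , ], reference$voxels[i, , ], peak = mx), 1)
    ss <- vapply(seq_len(n_frames(s)), function(i)
      ssim(s$voxels[i, , ], reference$voxels[i, , ], peak = mx), 1)
    if (any(is.infinite(p)))
      warning("infinite PSNR frames excluded from summaries")
    rows[[nm]] <- data.frame(frame = seq_along(p), method = nm,
                             psnr = p, ssim = ss)
  }
  tab <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(names(methods), function(nm) {
    p <- tab$psnr[tab$method == nm & is.finite(tab$psnr)]
    s <- tab$ssim[tab$method == nm]
    data.frame(frame = NA_integer_,
               method = paste0(nm, c(".median", ".iqr")),
               psnr = c(stats::median(p), stats::IQR(p)),
               ssim = c(stats::median(s), stats::IQR(s)))
  }))
  rownames(tab) <- NULL
  rbind(tab, summ)
}
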