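#' Threshold segmentation
#'
#' @param image an [image_stack] or numeric array.
#' @param t intensity threshold; voxels with intensity `>= t` are foreground.
#' @return A logical array of the image's shape.
#' @export
threshold_segment <- function(image, t) {
  if (inherits(image, "image_stack")) image <- image$voxels
  image >= t
}

#' Voxelwise confusion counts
#'
#' @param pred,truth logical arrays of identical shape (predicted and
#'   ground-truth segmentations).
#' @return A `confusion_counts` list with elements `TP`, `TN`, `FP`, `FN`;
#'   their sum equals the number of voxels compared.
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  pred <- as.logical(pred); truth <- as.logical(truth)
  structure(list(TP = sum(pred & truth), TN = sum(!pred & !truth),
                 FP = sum(pred & !truth), FN = sum(!pred & truth)),
            class = "confusion_counts")
}

#' Weighted segmentation accuracy
#'
#' `w_sens * sensitivity + w_spec * specificity`, with sensitivity
#' `TP/(TP+FN)` and specificity `TN/(TN+FP)`. The default weights (0.1, 0.9)
#' reflect that vascular foreground occupies only ~5-10% of the volume;
#' weights (0.5, 0.5) give balanced accuracy.
#'
#' @param c a `confusion_counts` object from [confusion()].
#' @param w_sens,w_spec sensitivity and specificity weights.
#' @return Weighted accuracy in `[0, 1]`.
#' @export
weighted_accuracy <- function(c, w_sens = 0.1, w_spec = 0.9) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$TP + c$FN == 0) stop("no positive voxels: sensitivity undefined")
  if (c$TN + c$FP == 0) stop("no negative voxels: specificity undefined")
  w_sens * c$TP / (c$TP + c$FN) + w_spec * c$TN / (c$TN + c$FP)
}

#' Threshold sweep for peak segmentation accuracy
#'
#' Evaluates weighted accuracy of `image >= t` against ground truth over a
#' grid of thresholds and reports the best (lowest threshold on ties). The
#' sweep uses cumulative intensity histograms, so cost is linear in image
#' size plus grid length.
#'
#' @param image an [image_stack] or numeric array.
#' @param truth logical ground-truth mask of the same shape.
#' @param thresholds numeric grid; default 256 evenly spaced levels across the
#'   image's bit range (or observed range for bare arrays).
#' @inheritParams weighted_accuracy
#' @return A list with `best_threshold`, `best_accuracy`, and `curve`
#'   (data.frame of threshold, sensitivity, specificity, accuracy).
#' @export
peak_accuracy_sweep <- function(image, truth, thresholds = NULL,
                                w_sens = 0.1, w_spec = 0.9) {
  if (inherits(image, "image_stack")) {
    if (is.null(thresholds)) thresholds <- seq(0, bit_max(image), length.out = 256L)
    image <- image$voxels
  }
  if (is.null(thresholds))
    thresholds <- seq(min(image), max(image), length.out = 256L)
  if (length(thresholds) == 0L) stop("empty threshold grid")
  if (!identical(dim(image), dim(truth))) stop("shape mismatch")
  thresholds <- sort(thresholds)
  truth <- as.logical(truth)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) stop("degenerate ground truth")
  # voxels with intensity >= t, counted via findInterval bins
  bin_fg <- tabulate(findInterval(image[truth], thresholds) + 1L,
                     nbins = length(thresholds) + 1L)
  bin_bg <- tabulate(findInterval(image[!truth], thresholds) + 1L,
                     nbins = length(thresholds) + 1L)
  tp <- rev(cumsum(rev(bin_fg)))[-1L]   # fg voxels >= each threshold
  fp <- rev(cumsum(rev(bin_bg)))[-1L]
  sens <- tp / n_pos
  spec <- (n_neg - fp) / n_neg
  acc <- w_sens * sens + w_spec * spec
  best <- which.max(acc)               # which.max returns first (lowest t) tie
  list(best_threshold = thresholds[best], best_accuracy = acc[best],
       curve = data.frame(threshold = thresholds, sensitivity = sens,
                          specificity = spec, accuracy = acc))
}

#' Construct a strand
#'
#' A strand is a one-dimensional centerline trace of a vessel segment with a
#' radius at each point, the unit of vascular morphology statistics.
#'
#' @param centerline numeric matrix (n x 3) of ordered 3D points in
#'   micrometres, columns (z, y, x); n >= 2 and consecutive points distinct.
#' @param radii numeric length-n vector of positive per-point radii (um).
#' @return A `strand` object.
#' @export
strand <- function(centerline, radii) {
  centerline <- as.matrix(centerline)
  if (nrow(centerline) < 2L || ncol(centerline) != 3L)
    stop("`centerline` must be an n x 3 matrix with n >= 2")
  if (length(radii) != nrow(centerline) || any(radii <= 0))
    stop("`radii` must be positive, one per centerline point")
  seg <- diff(centerline)
  if (any(rowSums(seg^2) == 0)) stop("consecutive centerline points coincide")
  structure(list(centerline = centerline, radii = as.numeric(radii)),
            class = "strand")
}

#' Per-strand morphology metrics
#'
#' For a strand with segments `d_i = p_(i+1) - p_i`:
#' length is the summed segment length; mean radius is the length-weighted
#' (trapezoidal) mean of the per-point radii; z-direction is the
#' length-weighted mean of `|dz_i| / |d_i|` (1 for a vessel along the optical
#' axis, 0 in-plane); inverse tortuosity is the endpoint chord distance over
#' the path length (1 iff straight).
#'
#' @param s a [strand].
#' @return A one-row data.frame with columns `length_um`, `mean_radius_um`,
#'   `z_direction`, `inverse_tortuosity`.
#' @export
strand_metrics <- function(s) {
  stopifnot(inherits(s, "strand"))
  seg <- diff(s$centerline)
  slen <- sqrt(rowSums(seg^2))
  len <- sum(slen)
  r_seg <- (s$radii[-length(s$radii)] + s$radii[-1L]) / 2
  chord <- sqrt(sum((s$centerline[nrow(s$centerline), ] - s$centerline[1L, ])^2))
  data.frame(length_um = len,
             mean_radius_um = sum(slen * r_seg) / len,
             z_direction = sum(abs(seg[, 1L])) / len,
             inverse_tortuosity = chord / len)
}

#' Strand table for a set of strands
#'
#' @param strands list of [strand] objects.
#' @return A data.frame with one [strand_metrics()] row per strand plus a
#'   `strand_id` column.
#' @export
strand_table <- function(strands) {
  tab <- do.call(rbind, lapply(strands, strand_metrics))
  cbind(strand_id = seq_along(strands), tab)
}

#' Empirical cumulative distribution function
#'
#' @param values non-empty numeric sample.
#' @return A list with `x` (sorted unique support), `p` (cumulative fractions,
#'   ending at 1) and `fun` (right-continuous step function).
#' @export
ecdf_steps <- function(values) {
  if (length(values) == 0L) stop("empty sample")
  f <- stats::ecdf(values)
  x <- sort(unique(values))
  list(x = x, p = f(x), fun = f)
}

#' Squared Pearson correlation between two CDFs
#'
#' Evaluates both empirical CDFs on a shared grid (by default the union of
#' both samples' values) and returns the squared Pearson correlation of the
#' two curves. Note that any two CDFs that are both near-linear on the grid
#' correlate strongly even when the distributions differ — which is why the
#' K-S test is reported alongside.
#'
#' @param a,b numeric samples, or objects from [ecdf_steps()].
#' @param grid evaluation points; default `sort(union(a, b))`.
#' @return Squared Pearson correlation r^2.
#' @export
cdf_pearson_r2 <- function(a, b, grid = NULL) {
  fa <- if (is.list(a)) a$fun else stats::ecdf(a)
  fb <- if (is.list(b)) b$fun else stats::ecdf(b)
  if (is.null(grid)) {
    va <- if (is.list(a)) a$x else a
    vb <- if (is.list(b)) b$x else b
    grid <- sort(unique(c(va, vb)))
  }
  ya <- fa(grid); yb <- fb(grid)
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0)
    stop("constant CDF on the evaluation grid")
  stats::cor(ya, yb)^2
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D = sup |ECDF_a - ECDF_b|` with a two-sided p-value (exact for small
#' tie-free samples, asymptotic otherwise).
#'
#' @param a,b non-empty numeric samples.
#' @param exact logical or NULL (auto, the default).
#' @return A list with `statistic` (D) and `p.value`.
#' @export
ks_two_sample <- function(a, b, exact = NULL) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  res <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}
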