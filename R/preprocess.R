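#' 3D median filter
#'
#' Replaces each voxel by the median of its `(2r+1)` per-axis neighbourhood.
#' Borders are handled by mirror reflection. The default radius (1, 1, 1) — a
#' 3x3x3 window — is the despeckling step applied to raw stacks before
#' contrast normalization.
#'
#' @param stack an [image_stack].
#' @param radius integer length-3, per-axis window radius (z, y, x), each >= 0.
#' @return A filtered [image_stack] of identical shape.
#' @export
median_filter_3d <- function(stack, radius = c(1L, 1L, 1L)) {
  stopifnot(inherits(stack, "image_stack"))
  radius <- as.integer(radius)
  if (length(radius) != 3L || any(is.na(radius)) || any(radius < 0))
    stop("`radius` must be 3 non-negative integers (z, y, x)")
  if (all(radius == 0L)) return(stack)
  vox <- median_filter_3d_cpp(as.numeric(stack$voxels), dim(stack$voxels), radius)
  image_stack(vox, spacing_um = stack$spacing_um, bit_depth = stack$bit_depth)
}

#' Full-scale contrast stretch (FSCS)
#'
#' Linearly remaps intensities so that the stack fills its whole bit range,
#' saturating (clipping) a small fraction of extreme voxels. Clip bounds are
#' the `saturation_frac/2` and `1 - saturation_frac/2` intensity quantiles
#' computed over the entire stack (linear interpolation between order
#' statistics); `[low, high]` maps onto `[0, 2^bit_depth - 1]` with values
#' outside clipped to the endpoints. A constant stack cannot be stretched and
#' returns all zeros with a warning.
#'
#' @param stack an [image_stack].
#' @param saturation_frac total saturated fraction in `[0, 1)`, split evenly
#'   between the two tails. Default 0.003 (0.3%).
#' @return A stretched [image_stack]; on non-constant input its minimum is
#'   exactly 0 and its maximum exactly the bit-range maximum.
#' @export
fscs_normalize <- function(stack, saturation_frac = 0.003) {
  stopifnot(inherits(stack, "image_stack"))
  if (!is.numeric(saturation_frac) || saturation_frac < 0 || saturation_frac >= 1)
    stop("`saturation_frac` must lie in [0, 1)")
  v <- stack$voxels
  mx <- bit_max(stack)
  qs <- stats::quantile(v, c(saturation_frac / 2, 1 - saturation_frac / 2),
                        names = FALSE, type = 7)
  if (qs[2L] <= qs[1L]) {
    warning("constant (or degenerate) stack: FSCS returns all zeros")
    return(image_stack(array(0, dim(v)), spacing_um = stack$spacing_um,
                       bit_depth = stack$bit_depth))
  }
  out <- (v - qs[1L]) / (qs[2L] - qs[1L]) * mx
  out[out < 0] <- 0
  out[out > mx] <- mx
  image_stack(round(out), spacing_um = stack$spacing_um,
              bit_depth = stack$bit_depth)
}

#' Convert a 16-bit stack to 8-bit
#'
#' Each intensity `i` maps to `round(i * 255 / 65535)`.
#'
#' @param stack a 16-bit [image_stack].
#' @return An 8-bit [image_stack].
#' @export
convert_16_to_8 <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (stack$bit_depth != 16L) stop("`stack` must be 16-bit")
  image_stack(round(stack$voxels * 255 / 65535),
              spacing_um = stack$spacing_um, bit_depth = 8L)
}

#' Standard preprocessing chain for raw stacks
#'
#' Median filter, full-scale contrast stretch, 16-to-8-bit conversion — the
#' normalization applied to every stack before it is used as training or test
#' material.
#'
#' @param stack a raw 16-bit [image_stack].
#' @inheritParams median_filter_3d
#' @inheritParams fscs_normalize
#' @return An 8-bit normalized [image_stack].
#' @export
preprocess_stack <- function(stack, radius = c(1L, 1L, 1L),
                             saturation_frac = 0.003) {
  convert_16_to_8(fscs_normalize(median_filter_3d(stack, radius),
                                 saturation_frac))
}
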