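#' Construct an image stack
#'
#' An `image_stack` is the universal currency of the pipeline: a 3D grayscale
#' intensity volume ordered (z, y, x) with a physical voxel size and a bit
#' depth. Intensities must lie within `[0, 2^bit_depth - 1]`.
#'
#' @param voxels numeric 3D array, dimensions (z, y, x). A matrix is accepted
#'   and treated as a single frame.
#' @param spacing_um numeric length-3, physical voxel size in micrometres
#'   (z, y, x); strictly positive.
#' @param bit_depth integer, 8 or 16.
#' @return An object of class `image_stack`.
#' @examples
#' s <- image_stack(array(0, c(3, 8, 8)), spacing_um = c(3, 1.37, 1.37))
#' dim(s$voxels)
#' @export
image_stack <- function(voxels, spacing_um = c(3, 1.37, 1.37), bit_depth = 16L) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(1L, dim(voxels)))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array ordered (z, y, x)")
  bit_depth <- as.integer(bit_depth)
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16")
  if (length(spacing_um) != 3L || any(!is.finite(spacing_um)) || any(spacing_um <= 0))
    stop("`spacing_um` must be 3 strictly positive values (z, y, x)")
  rng <- range(voxels)
  if (!all(is.finite(rng))) stop("non-finite intensities")
  if (rng[1L] < 0 || rng[2L] > 2^bit_depth - 1)
    stop(sprintf("intensities must lie in [0, %d]", 2^bit_depth - 1L))
  structure(list(voxels = voxels, spacing_um = as.numeric(spacing_um),
                 bit_depth = bit_depth),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d frame(s) of %d x %d, %d-bit\n", d[1], d[2], d[3],
              x$bit_depth))
  cat(sprintf("  voxel spacing (z, y, x): %.3g x %.3g x %.3g um\n",
              x$spacing_um[1], x$spacing_um[2], x$spacing_um[3]))
  cat(sprintf("  intensity range: [%.6g, %.6g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

n_frames <- function(stack) dim(stack$voxels)[1L]

bit_max <- function(stack) 2^stack$bit_depth - 1

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Bit depth is inferred from the file's sample format. Axial spacing is taken
#' from ImageJ-style `spacing=` metadata in the image description when present,
#' otherwise from `spacing_um`.
#'
#' @param path path to a single-channel multi-page TIFF (8- or 16-bit).
#' @param spacing_um fallback voxel spacing (z, y, x) in micrometres, used when
#'   the file carries no spacing metadata.
#' @return An [image_stack].
#' @export
read_stack <- function(path, spacing_um = c(3, 1.37, 1.37)) {
  if (!file.exists(path)) stop("cannot read TIFF: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has no pages: ", path)
  for (p in pages) {
    if (length(dim(p)) > 2L && dim(p)[3L] > 1L)
      stop("single-channel required: multi-channel TIFF not supported")
  }
  bits <- vapply(pages, function(p) as.integer(attr(p, "bits.per.sample")), 1L)
  if (length(unique(bits)) != 1L) stop("mixed bit depths across pages")
  shp <- vapply(pages, function(p) dim(p)[1:2], integer(2))
  if (nrow(unique(t(shp))) != 1L) stop("pages differ in (y, x) shape")
  desc <- attr(pages[[1L]], "description")
  if (!is.null(desc)) {
    m <- regmatches(desc, regexec("spacing=([0-9.eE+-]+)", desc))[[1L]]
    if (length(m) == 2L) spacing_um[1L] <- as.numeric(m[2L])
  }
  vox <- array(0, c(length(pages), shp[1L, 1L], shp[2L, 1L]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  image_stack(vox, spacing_um = spacing_um, bit_depth = bits[1L])
}

#' Write an image stack as a multi-page grayscale TIFF
#'
#' Intensities are rounded to the nearest integer on write;
#' `read_stack(write_stack(s))` is voxel-identical for integer-valued stacks.
#'
#' @param stack an [image_stack].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  mx <- bit_max(stack)
  pages <- lapply(seq_len(n_frames(stack)), function(i)
    round(stack$voxels[i, , ]) / mx)
  ok <- try(tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                            compression = "none", reduce = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write TIFF: ", path)
  invisible(path)
}

#' Split a stack into single frames
#'
#' @param stack an [image_stack].
#' @return A list of single-frame stacks in acquisition (z) order; each element
#'   carries its original `z_index` (1-based) as an attribute.
#' @export
split_frames <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  lapply(seq_len(n_frames(stack)), function(i) {
    f <- image_stack(stack$voxels[i, , , drop = FALSE],
                     spacing_um = stack$spacing_um, bit_depth = stack$bit_depth)
    attr(f, "z_index") <- i
    f
  })
}

#' Reassemble frames into one stack
#'
#' Inverse of [split_frames()]: frames must share shape, spacing and bit depth.
#'
#' @param frames list of single-frame [image_stack] objects in z order.
#' @return An [image_stack].
#' @export
bind_frames <- function(frames) {
  stopifnot(length(frames) >= 1L)
  d <- dim(frames[[1L]]$voxels)
  vox <- array(0, c(length(frames), d[2L], d[3L]))
  for (i in seq_along(frames)) vox[i, , ] <- frames[[i]]$voxels[1L, , ]
  image_stack(vox, spacing_um = frames[[1L]]$spacing_um,
              bit_depth = frames[[1L]]$bit_depth)
}
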