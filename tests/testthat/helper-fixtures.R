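# fixtures shared across test files; everything generated in code

random_stack <- function(dims = c(4L, 6L, 6L), bit_depth = 16L, seed = 1L) {
  set.seed(seed)
  image_stack(array(sample.int(2^bit_depth, prod(dims), replace = TRUE) - 1L,
                    dims),
              bit_depth = bit_depth)
}

# brute-force 3D median filter with mirror reflection, the oracle for the
# Rcpp implementation
median3d_oracle <- function(vox, radius) {
  refl <- function(i, n) {
    while (any(i < 1L | i > n)) {
      i[i < 1L] <- 1L - i[i < 1L]        # symmetric: 0 -> 1, -1 -> 2
      i[i > n] <- 2L * n + 1L - i[i > n] # symmetric: n+1 -> n
    }
    i
  }
  d <- dim(vox)
  out <- array(0, d)
  for (z in seq_len(d[1])) for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zi <- refl((z - radius[1]):(z + radius[1]), d[1])
    yi <- refl((y - radius[2]):(y + radius[2]), d[2])
    xi <- refl((x - radius[3]):(x + radius[3]), d[3])
    out[z, y, x] <- stats::median(vox[zi, yi, xi])
  }
  out
}

# direct per-pixel PSNR from the defining formula
psnr_oracle <- function(x, y, peak) {
  mse <- sum((x - y)^2) / length(x)
  10 * log10(peak^2 / mse)
}

# direct sliding-window SSIM from the defining formula (valid windows,
# Gaussian weights), independent of the package's separable-filter path
ssim_oracle <- function(x, y, peak, window = 11L, sigma = 1.5) {
  C1 <- (0.01 * peak)^2; C2 <- (0.03 * peak)^2
  t0 <- seq_len(window) - (window + 1) / 2
  k1 <- exp(-t0^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  K <- outer(k1, k1)
  vals <- c()
  for (i in seq_len(nrow(x) - window + 1L)) {
    for (j in seq_len(ncol(x) - window + 1L)) {
      wx <- x[i:(i + window - 1L), j:(j + window - 1L)]
      wy <- y[i:(i + window - 1L), j:(j + window - 1L)]
      mx <- sum(K * wx); my <- sum(K * wy)
      vx <- sum(K * wx^2) - mx^2; vy <- sum(K * wy^2) - my^2
      cxy <- sum(K * wx * wy) - mx * my
      vals <- c(vals, ((2 * mx * my + C1) * (2 * cxy + C2)) /
                        ((mx^2 + my^2 + C1) * (vx + vy + C2)))
    }
  }
  mean(vals)
}

# tiny multi-volume phantom + single-frame dataset used by the network tests
tiny_training_setup <- function(n_vols = 2L, nz = 6L, side = 32L, seed = 50L) {
  ncfg <- noise_config("additive_gaussian")
  sets <- list()
  for (i in seq_len(n_vols)) {
    ph <- generate_phantom(phantom_config(volume_shape = c(nz, side, side),
                                          n_strands = 30L, seed = seed + i))
    sets[[i]] <- make_single_frame_dataset(ph$image, ncfg, factor = 4L,
                                           seed = seed + 10L + i,
                                           stack_id = paste0("v", i))
  }
  do.call(c, sets)
}
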