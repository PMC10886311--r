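test_that("model output side is exactly scale times the input side", {
  set.seed(1)
  for (i in 1:4) {
    depth <- sample(1:2, 1)
    scale <- c(2L, 4L)[sample(2, 1)]
    cfg <- model_config(in_frames = 1L, scale = scale, encoder_depth = depth,
                        base_channels = 4L, seed = i)
    side <- 2L^depth * sample(2:5, 1)
    p <- vesselsr:::init_params(cfg)
    out <- vesselsr:::net_predict(array(runif(side^2), c(side, side, 1L)),
                                  p, cfg)
    expect_equal(dim(out), c(side, side) * scale)
  }
  # multi-frame input collapses to a single output frame
  cfg5 <- model_config(in_frames = 5L, scale = 4L, encoder_depth = 2L,
                       base_channels = 4L)
  p5 <- vesselsr:::init_params(cfg5)
  out5 <- vesselsr:::net_predict(array(runif(16 * 16 * 5), c(16L, 16L, 5L)),
                                 p5, cfg5)
  expect_identical(dim(out5), c(64L, 64L))
  expect_error(model_config(in_frames = 3L), "1 or 5")
  expect_error(model_config(scale = 3L), "power of 2")
})

test_that("subpixel upsampling preserves constants and the blur kernel
           averages a checkerboard to 0.5", {
  const <- array(0.7, c(2L, 2L, 4L))
  up <- subpixel_upsample(const, 2L, blur = TRUE)
  expect_identical(dim(up), c(4L, 4L, 1L))
  expect_true(all(abs(up - 0.7) < 1e-12))
  # channels arranged so the shuffle yields alternating 0/1; a 2x2 box then
  # averages interior pixels to exactly 0.5
  ch <- array(0, c(4L, 4L, 4L))
  ch[, , 1] <- 1; ch[, , 4] <- 1   # (dh=1,dw=1) and (dh=2,dw=2) positions
  shuffled <- subpixel_upsample(ch, 2L, blur = FALSE)
  expect_setequal(unique(as.numeric(shuffled)), c(0, 1))
  blurred <- subpixel_upsample(ch, 2L, blur = TRUE)
  expect_true(all(abs(blurred[1:7, 1:7, 1] - 0.5) < 1e-12))
  expect_error(subpixel_upsample(array(0, c(2, 2, 3)), 2L), "divisible")
})

test_that("the zero-order-hold blur operator has unit row sums for any
           factor", {
  for (f in c(2L, 3L, 4L)) {
    P <- vesselsr:::zoh_operator(8L, 10L, f)
    expect_equal(max(abs(Matrix::rowSums(P) - 1)), 0, tolerance = 1e-12)
  }
})

test_that("analytic gradients match finite differences through the whole
           network", {
  set.seed(11)
  for (cfgi in list(model_config(1L, 2L, 1L, 2L, seed = 3L),
                    model_config(5L, 4L, 2L, 4L, seed = 7L))) {
    params <- vesselsr:::init_params(cfgi)
    # keep pre-activations away from the ReLU kink (exact zeros from
    # zero-initialised biases make the central difference ill-defined)
    for (nm in grep("\\.b$", names(params), value = TRUE))
      params[[nm]] <- rnorm(length(params[[nm]]), 0, 0.05)
    side <- 8L
    x <- array(runif(side^2 * cfgi$in_frames), c(side, side, cfgi$in_frames))
    tgt <- matrix(runif((side * cfgi$scale)^2), side * cfgi$scale)
    lossf <- function(p) mean((vesselsr:::net_predict(x, p, cfgi) - tgt)^2)
    fw <- vesselsr:::net_forward(x, params, cfgi)
    lg <- vesselsr:::mse_loss_grad(fw$tape$vals[[fw$out]], tgt)
    g <- vesselsr:::tp_backward(fw$tape, fw$out, lg$grad)
    eps <- 1e-6
    for (nm in names(params)) {
      for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
        p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
        num <- (lossf(p2) - lossf(p3)) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]) /
                    max(1e-4, abs(num) + abs(g[[nm]][i])), 1e-4)
      }
    }
  }
})

test_that("training reduces the loss and is reproducible given seeds", {
  set.seed(12)
  frames <- lapply(1:12, function(i) {
    f <- matrix(0.2, 32, 32)
    f[sample(1024, 200)] <- 0.8
    f
  })
  samples <- make_single_frame_dataset(frames, noise_config("gaussian"),
                                       seed = 13)
  mcfg <- model_config(1L, 4L, encoder_depth = 2L, base_channels = 4L,
                       seed = 14L)
  tcfg <- train_config(epochs = 3L, batch_size = 4L, seed = 15L)
  fit1 <- pssr(samples[1:9], val = samples[10:12], model = mcfg, train = tcfg)
  expect_lt(fit1$history$train_mse[3], fit1$history$train_mse[1])
  expect_true(all(diff(fit1$history$best_val_so_far) <= 0))
  fit2 <- pssr(samples[1:9], val = samples[10:12], model = mcfg, train = tcfg)
  expect_equal(fit1$history$train_mse, fit2$history$train_mse,
               tolerance = 1e-6)
  expect_equal(fit1$params, fit2$params, tolerance = 1e-9)
  expect_error(pssr(list(), model = mcfg, train = tcfg), "empty")
})

test_that("pssr objects support the standard modelling methods", {
  set.seed(16)
  frames <- lapply(1:6, function(i) matrix(runif(256), 16, 16))
  samples <- make_single_frame_dataset(frames, noise_config("none"), seed = 1)
  fit <- pssr(samples,
              model = model_config(1L, 4L, 1L, 2L, seed = 2L),
              train = train_config(epochs = 2L, batch_size = 3L, seed = 3L))
  expect_s3_class(fit, "pssr")
  expect_output(print(fit), "residual U-Net")
  expect_output(summary(fit), "loss history")
  expect_type(coef(fit), "list")
  expect_true(all(c("head.W", "out.b") %in% names(coef(fit))))
  r <- residuals(fit, samples[1:2])
  expect_length(r, 2L)
  expect_identical(dim(r[[1]]), dim(samples[[1]]$hr))
  f <- withr::local_tempfile(fileext = ".rds")
  pssr_save(fit, f)
  fit2 <- pssr_load(f)
  expect_equal(coef(fit2), coef(fit))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("upscaling a stack gives scale-times frames, clipped to the bit
           range; multi-frame edges use reflected windows", {
  set.seed(17)
  fit1 <- pssr(make_single_frame_dataset(
                 lapply(1:4, function(i) matrix(runif(256), 16, 16)),
                 noise_config("none"), seed = 1),
               model = model_config(1L, 4L, 1L, 2L, seed = 2L),
               train = train_config(epochs = 1L, batch_size = 2L, seed = 3L))
  lr <- random_stack(c(3L, 16L, 16L), bit_depth = 8L, seed = 18)
  up <- upscale(fit1, lr)
  expect_identical(dim(up$voxels), c(3L, 64L, 64L))
  expect_gte(min(up$voxels), 0); expect_lte(max(up$voxels), 255)

  frames5 <- lapply(1:7, function(i) matrix(runif(256), 16, 16))
  mf <- make_multiframe_dataset(
    make_single_frame_dataset(frames5, noise_config("none"), seed = 4), 5L)
  fit5 <- pssr(mf, model = model_config(5L, 4L, 1L, 2L, seed = 5L),
               train = train_config(epochs = 1L, batch_size = 2L, seed = 6L))
  lr7 <- random_stack(c(7L, 16L, 16L), bit_depth = 8L, seed = 19)
  up5 <- upscale(fit5, lr7)
  expect_identical(dim(up5$voxels), c(7L, 64L, 64L))
  expect_error(upscale(fit5, random_stack(c(3L, 16L, 16L), bit_depth = 8L)),
               "at least 5")
})

test_that("bilinear upscaling: constants, closed-form column ramp, and the
           128-to-512 contract", {
  const <- matrix(0.4, 8, 8)
  expect_equal(bilinear_upscale(const, 2L), matrix(0.4, 16, 16))
  # columns [0, 1] doubled with half-pixel centres: interior interpolates
  # linearly, rows stay constant
  m <- rbind(c(0, 1), c(0, 1))
  out <- bilinear_upscale(m, 2L)
  expect_identical(dim(out), c(4L, 4L))
  expect_equal(out[1, ], c(0, 0.25, 0.75, 1))
  expect_true(all(apply(out, 2, function(col) max(col) - min(col)) == 0))
  s <- random_stack(c(2L, 128L, 128L), bit_depth = 8L, seed = 20)
  expect_identical(dim(bilinear_upscale(s, 4L)$voxels), c(2L, 512L, 512L))
})
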