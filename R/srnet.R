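# ---------------------------------------------------------------------------
# Compact residual U-Net for point-scanning super-resolution, written directly
# on top of BLAS. 3x3 convolutions are decomposed into nine shifted 1x1
# convolutions (matrix products on an (H*W) x C activation matrix); the
# skip-connection graph is differentiated by a small reverse-mode tape.
# ---------------------------------------------------------------------------

.srnet_cache <- new.env(parent = emptyenv())

# gather indices for a 3x3 conv offset (oy, ox) at the given stride;
# out-of-range positions point at a zero pad row (H*W + 1)
conv_idx <- function(H, W, stride, oy, ox) {
  key <- paste("ci", H, W, stride, oy, ox, sep = "_")
  if (!is.null(.srnet_cache[[key]])) return(.srnet_cache[[key]])
  H2 <- if (stride == 1L) H else ceiling(H / 2)
  W2 <- if (stride == 1L) W else ceiling(W / 2)
  hs <- (seq_len(H2) - 1L) * stride + 1L + oy
  ws <- (seq_len(W2) - 1L) * stride + 1L + ox
  ih <- rep(hs, times = W2)
  iw <- rep(ws, each = H2)
  idx <- ih + (iw - 1L) * H
  idx[ih < 1L | ih > H | iw < 1L | iw > W] <- H * W + 1L
  .srnet_cache[[key]] <- list(idx = idx, H2 = H2, W2 = W2)
  .srnet_cache[[key]]
}

.conv_offsets <- as.matrix(expand.grid(oy = -1:1, ox = -1:1))

# reflection-padded box-blur operator (zero-order hold) as a sparse matrix
zoh_operator <- function(H, W, f) {
  key <- paste("zoh", H, W, f, sep = "_")
  if (!is.null(.srnet_cache[[key]])) return(.srnet_cache[[key]])
  refl <- function(i, n) ifelse(i > n, 2L * n - i, i)
  h2 <- rep(seq_len(H), times = W)
  w2 <- rep(seq_len(W), each = H)
  out_p <- h2 + (w2 - 1L) * H
  ii <- jj <- integer(0)
  for (dy in 0:(f - 1L)) for (dx in 0:(f - 1L)) {
    ii <- c(ii, out_p)
    jj <- c(jj, refl(h2 + dy, H) + (refl(w2 + dx, W) - 1L) * H)
  }
  P <- Matrix::sparseMatrix(i = ii, j = jj, x = 1 / f^2, dims = c(H * W, H * W))
  .srnet_cache[[key]] <- P
  P
}

# ---- reverse-mode tape -----------------------------------------------------

tp_new <- function(params) {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list(); tp$steps <- list(); tp$n <- 0L; tp$params <- params
  tp
}

tp_put <- function(tp, x, step = NULL) {
  force(x)   # nested tp_* calls in the argument must append before we do
  force(step)
  tp$n <- tp$n + 1L
  tp$vals[[tp$n]] <- x
  if (!is.null(step)) { step$out <- tp$n; tp$steps[[length(tp$steps) + 1L]] <- step }
  tp$n
}

tp_conv <- function(tp, id, pname, stride = 1L) {
  force(id)   # nested tape calls mutate tp; resolve ids before touching tp$vals
  x <- tp$vals[[id]]
  d <- dim(x); H <- d[1L]; W <- d[2L]; Cin <- d[3L]
  Wm <- tp$params[[paste0(pname, ".W")]]
  b  <- tp$params[[paste0(pname, ".b")]]
  Cout <- ncol(Wm)
  Xp <- rbind(matrix(x, H * W, Cin), 0)
  ci1 <- conv_idx(H, W, stride, 0L, 0L)
  Y <- matrix(0, ci1$H2 * ci1$W2, Cout)
  for (k in seq_len(9L)) {
    ci <- conv_idx(H, W, stride, .conv_offsets[k, 1L], .conv_offsets[k, 2L])
    blk <- ((k - 1L) * Cin + 1L):(k * Cin)
    Y <- Y + Xp[ci$idx, , drop = FALSE] %*% Wm[blk, , drop = FALSE]
  }
  Y <- sweep(Y, 2L, b, "+")
  tp_put(tp, array(Y, c(ci1$H2, ci1$W2, Cout)),
         list(op = "conv", ins = id, pname = pname, stride = stride,
              H = H, W = W, Cin = Cin))
}

tp_relu <- function(tp, id) {
  force(id)
  tp_put(tp, pmax(tp$vals[[id]], 0), list(op = "relu", ins = id))
}

tp_add <- function(tp, ida, idb) {
  force(ida); force(idb)
  tp_put(tp, tp$vals[[ida]] + tp$vals[[idb]], list(op = "add", ins = c(ida, idb)))
}

tp_concat <- function(tp, ida, idb) {
  force(ida); force(idb)
  a <- tp$vals[[ida]]; b <- tp$vals[[idb]]
  d <- dim(a)
  tp_put(tp, array(c(a, b), c(d[1L], d[2L], d[3L] + dim(b)[3L])),
         list(op = "concat", ins = c(ida, idb), ca = d[3L]))
}

ps_forward <- function(x, r) {
  d <- dim(x); H <- d[1L]; W <- d[2L]; C2 <- d[3L] %/% (r * r)
  y <- array(0, c(H * r, W * r, C2))
  for (dh in seq_len(r)) for (dw in seq_len(r)) {
    cin <- ((dh - 1L) + (dw - 1L) * r) * C2 + seq_len(C2)
    y[seq(dh, H * r, r), seq(dw, W * r, r), ] <- x[, , cin]
  }
  y
}

tp_ps <- function(tp, id, r = 2L) {
  force(id)
  x <- tp$vals[[id]]
  if (dim(x)[3L] %% (r * r) != 0L) stop("channels not divisible by factor^2")
  tp_put(tp, ps_forward(x, r), list(op = "ps", ins = id, r = r, d = dim(x)))
}

# add a constant (parameter-free) offset, e.g. the global interpolation skip
tp_addc <- function(tp, id, const) {
  force(id)
  tp_put(tp, tp$vals[[id]] + const, list(op = "addc", ins = id))
}

tp_blur <- function(tp, id, f = 2L) {
  force(id)
  x <- tp$vals[[id]]
  d <- dim(x)
  P <- zoh_operator(d[1L], d[2L], f)
  Y <- as.matrix(P %*% matrix(x, d[1L] * d[2L], d[3L]))
  tp_put(tp, array(Y, d), list(op = "blur", ins = id, f = f, d = d))
}

tp_backward <- function(tp, out_id, dout) {
  dvals <- vector("list", tp$n)
  dvals[[out_id]] <- dout
  grads <- list()
  for (s in rev(tp$steps)) {
    dy <- dvals[[s$out]]
    if (is.null(dy)) next
    if (s$op == "conv") {
      d <- dim(dy); dYm <- matrix(dy, d[1L] * d[2L], d[3L])
      x <- tp$vals[[s$ins]]
      Xp <- rbind(matrix(x, s$H * s$W, s$Cin), 0)
      Wm <- tp$params[[paste0(s$pname, ".W")]]
      dW <- matrix(0, nrow(Wm), ncol(Wm))
      dXp <- matrix(0, s$H * s$W + 1L, s$Cin)
      for (k in seq_len(9L)) {
        ci <- conv_idx(s$H, s$W, s$stride,
                       .conv_offsets[k, 1L], .conv_offsets[k, 2L])
        blk <- ((k - 1L) * s$Cin + 1L):(k * s$Cin)
        Xs <- Xp[ci$idx, , drop = FALSE]
        dW[blk, ] <- crossprod(Xs, dYm)
        dXp[ci$idx, ] <- dXp[ci$idx, , drop = FALSE] +
          dYm %*% t(Wm[blk, , drop = FALSE])
      }
      nW <- paste0(s$pname, ".W"); nb <- paste0(s$pname, ".b")
      grads[[nW]] <- if (is.null(grads[[nW]])) dW else grads[[nW]] + dW
      grads[[nb]] <- if (is.null(grads[[nb]])) colSums(dYm) else
        grads[[nb]] + colSums(dYm)
      dx <- array(dXp[seq_len(s$H * s$W), , drop = FALSE],
                  c(s$H, s$W, s$Cin))
      dvals[[s$ins]] <- if (is.null(dvals[[s$ins]])) dx else dvals[[s$ins]] + dx
    } else if (s$op == "addc") {
      dvals[[s$ins]] <- if (is.null(dvals[[s$ins]])) dy else dvals[[s$ins]] + dy
    } else if (s$op == "relu") {
      dx <- dy * (tp$vals[[s$ins]] > 0)
      dvals[[s$ins]] <- if (is.null(dvals[[s$ins]])) dx else dvals[[s$ins]] + dx
    } else if (s$op == "add") {
      for (i in s$ins)
        dvals[[i]] <- if (is.null(dvals[[i]])) dy else dvals[[i]] + dy
    } else if (s$op == "concat") {
      da <- dy[, , seq_len(s$ca), drop = FALSE]
      db <- dy[, , -seq_len(s$ca), drop = FALSE]
      i1 <- s$ins[1L]; i2 <- s$ins[2L]
      dvals[[i1]] <- if (is.null(dvals[[i1]])) da else dvals[[i1]] + da
      dvals[[i2]] <- if (is.null(dvals[[i2]])) db else dvals[[i2]] + db
    } else if (s$op == "ps") {
      r <- s$r; d0 <- s$d; C2 <- d0[3L] %/% (r * r)
      dx <- array(0, d0)
      for (dh in seq_len(r)) for (dw in seq_len(r)) {
        cin <- ((dh - 1L) + (dw - 1L) * r) * C2 + seq_len(C2)
        dx[, , cin] <- dy[seq(dh, d0[1L] * r, r), seq(dw, d0[2L] * r, r), ]
      }
      dvals[[s$ins]] <- if (is.null(dvals[[s$ins]])) dx else dvals[[s$ins]] + dx
    } else if (s$op == "blur") {
      P <- zoh_operator(s$d[1L], s$d[2L], s$f)
      dx <- array(as.matrix(Matrix::crossprod(P, matrix(dy, s$d[1L] * s$d[2L],
                                                        s$d[3L]))), s$d)
      dvals[[s$ins]] <- if (is.null(dvals[[s$ins]])) dx else dvals[[s$ins]] + dx
    }
    dvals[s$out] <- list(NULL)  # free without shifting list indices
  }
  grads
}

# ---- model configuration and parameters ------------------------------------

#' Model configuration for the super-resolution network
#'
#' The network is a compact residual U-Net: an encoder of strided residual
#' stages, a decoder that restores and then exceeds the input size through
#' learnable subpixel (pixel-shuffle) convolutions, skip connections joining
#' matching scales, and — to suppress checkerboard artifacts — a normalized
#' zero-order-hold (box) blur after each upsampling layer. The output is a
#' single frame at `scale` times the input side.
#'
#' @param in_frames 1 (single-frame) or 5 (multi-frame axial window).
#' @param scale upsampling factor, a power of 2 realised by `log2(scale)`
#'   subpixel stages (default 4: 128 -> 512 pixels).
#' @param encoder_depth number of strided residual encoder stages.
#' @param base_channels channel width of the first stage; deeper stages
#'   double it (capped at 8x).
#' @param blur_after_upsample apply the anti-checkerboard blur (default TRUE).
#' @param global_residual add a bilinear interpolation of the (centre) input
#'   frame to the network output, so the network learns a correction to plain
#'   interpolation rather than the full mapping (default TRUE; standard
#'   residual-learning practice that makes short CPU training schedules
#'   converge).
#' @param init `"random"` (He initialisation) or `"weights"` to start from
#'   `weights` (e.g. a pretrained encoder); random is the default so training
#'   works at desk scale without external weight files.
#' @param weights optional named list of parameter arrays when
#'   `init = "weights"`.
#' @param seed RNG seed for initialisation.
#' @return A `pssr_config` list.
#' @export
model_config <- function(in_frames = 1L, scale = 4L, encoder_depth = 4L,
                         base_channels = 32L, blur_after_upsample = TRUE,
                         global_residual = TRUE,
                         init = c("random", "weights"), weights = NULL,
                         seed = 42L) {
  init <- match.arg(init)
  in_frames <- as.integer(in_frames)
  if (!in_frames %in% c(1L, 5L)) stop("`in_frames` must be 1 or 5")
  scale <- as.integer(scale)
  if (scale < 1L || bitwAnd(scale, scale - 1L) != 0L)
    stop("`scale` must be a power of 2")
  structure(list(in_frames = in_frames, scale = scale,
                 encoder_depth = as.integer(encoder_depth),
                 base_channels = as.integer(base_channels),
                 blur_after_upsample = isTRUE(blur_after_upsample),
                 global_residual = isTRUE(global_residual),
                 init = init, weights = weights, seed = as.integer(seed)),
            class = "pssr_config")
}

stage_channels <- function(cfg, d) cfg$base_channels * 2L^min(d, 3L)

# He-initialised parameter list for the architecture
init_params <- function(cfg) {
  set.seed(cfg$seed)
  params <- list()
  mk <- function(cin, cout, gain = 2) {
    list(W = matrix(stats::rnorm(9L * cin * cout, 0, sqrt(gain / (9 * cin))),
                    9L * cin, cout),
         b = rep(0, cout))
  }
  put <- function(name, p) {
    params[[paste0(name, ".W")]] <<- p$W
    params[[paste0(name, ".b")]] <<- p$b
  }
  D <- cfg$encoder_depth
  put("head", mk(cfg$in_frames, stage_channels(cfg, 0L)))
  for (d in seq_len(D)) {
    put(sprintf("down%d", d), mk(stage_channels(cfg, d - 1L), stage_channels(cfg, d)))
    put(sprintf("res%dA", d), mk(stage_channels(cfg, d), stage_channels(cfg, d)))
    put(sprintf("res%dB", d), mk(stage_channels(cfg, d), stage_channels(cfg, d)))
    put(sprintf("up%d", d), mk(stage_channels(cfg, d), 4L * stage_channels(cfg, d - 1L)))
    put(sprintf("fuse%d", d), mk(2L * stage_channels(cfg, d - 1L),
                                 stage_channels(cfg, d - 1L)))
  }
  for (s in seq_len(as.integer(log2(cfg$scale))))
    put(sprintf("post%d", s), mk(stage_channels(cfg, 0L),
                                 4L * stage_channels(cfg, 0L)))
  put("out", mk(stage_channels(cfg, 0L), 1L, gain = 0.2))
  if (cfg$init == "weights") {
    if (is.null(cfg$weights)) stop("init = 'weights' requires `weights`")
    miss <- setdiff(names(params), names(cfg$weights))
    if (length(miss)) stop("missing weights: ", paste(miss, collapse = ", "))
    params <- cfg$weights[names(params)]
  }
  params
}

# forward pass; returns tape and output id. x: array (H, W, in_frames)
net_forward <- function(x, params, cfg) {
  d <- dim(x)
  if (d[1L] %% 2L^cfg$encoder_depth != 0L || d[2L] %% 2L^cfg$encoder_depth != 0L)
    stop(sprintf("input sides must be divisible by %d", 2L^cfg$encoder_depth))
  tp <- tp_new(params)
  id <- tp_put(tp, x)
  enc <- integer(cfg$encoder_depth + 1L)
  id <- tp_relu(tp, tp_conv(tp, id, "head"))
  enc[1L] <- id
  for (d0 in seq_len(cfg$encoder_depth)) {
    id <- tp_relu(tp, tp_conv(tp, id, sprintf("down%d", d0), stride = 2L))
    z <- tp_conv(tp, tp_relu(tp, tp_conv(tp, id, sprintf("res%dA", d0))),
                 sprintf("res%dB", d0))
    id <- tp_relu(tp, tp_add(tp, id, z))
    enc[d0 + 1L] <- id
  }
  for (d0 in rev(seq_len(cfg$encoder_depth))) {
    id <- tp_ps(tp, tp_conv(tp, id, sprintf("up%d", d0)), 2L)
    if (cfg$blur_after_upsample) id <- tp_blur(tp, id, 2L)
    id <- tp_concat(tp, id, enc[d0])
    id <- tp_relu(tp, tp_conv(tp, id, sprintf("fuse%d", d0)))
  }
  for (s in seq_len(as.integer(log2(cfg$scale)))) {
    id <- tp_ps(tp, tp_conv(tp, id, sprintf("post%d", s)), 2L)
    if (cfg$blur_after_upsample) id <- tp_blur(tp, id, 2L)
    id <- tp_relu(tp, id)
  }
  id <- tp_conv(tp, id, "out")
  if (isTRUE(cfg$global_residual)) {
    centre <- x[, , (dim(x)[3L] + 1L) %/% 2L]
    skip <- bilinear_resize(centre, dim(centre) * cfg$scale)
    id <- tp_addc(tp, id, array(skip, c(dim(skip), 1L)))
  }
  list(tape = tp, out = id)
}

sample_input <- function(s, cfg) {
  lr <- s$lr
  if (is.list(lr)) {
    if (cfg$in_frames != length(lr))
      stop("sample frame count does not match model `in_frames`")
    array(unlist(lr), c(dim(lr[[1L]]), length(lr)))
  } else {
    if (cfg$in_frames != 1L) stop("single-frame sample fed to multi-frame model")
    array(lr, c(dim(lr), 1L))
  }
}

net_predict <- function(x, params, cfg) {
  fw <- net_forward(x, params, cfg)
  fw$tape$vals[[fw$out]][, , 1L]
}

mse_loss_grad <- function(pred, target) {
  r <- pred - array(target, dim(pred))
  list(loss = mean(r^2), grad = 2 * r / length(r))
}

# ---- training --------------------------------------------------------------

#' Training configuration
#'
#' @param learning_rate Adam step size; defaults to 9e-4 for single-frame and
#'   1e-4 for multi-frame models when left `NULL`.
#' @param epochs number of passes over the training set.
#' @param batch_size mini-batch size.
#' @param loss only `"mse"` (mean squared error) is supported.
#' @param seed RNG seed for shuffling.
#' @return A `pssr_train_config` list.
#' @export
train_config <- function(learning_rate = NULL, epochs = 5L, batch_size = 8L,
                         loss = "mse", seed = 1L) {
  if (!identical(loss, "mse")) stop("only MSE loss is supported")
  if (!is.null(learning_rate) && learning_rate <= 0)
    stop("`learning_rate` must be > 0")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 seed = as.integer(seed)),
            class = "pssr_train_config")
}

#' Fit a super-resolution network
#'
#' Trains the residual U-Net of [model_config()] on LR/HR training samples by
#' minimising mean squared error with Adam, and keeps the checkpoint with the
#' best validation loss (training loss when no validation set is given).
#' Deterministic given the configuration seeds.
#'
#' @param samples list of training samples from [make_single_frame_dataset()]
#'   or [make_multiframe_dataset()]; LR and HR frames on the `[0, 1]` scale.
#' @param val optional validation samples of the same layout.
#' @param model a [model_config()].
#' @param train a [train_config()].
#' @param verbose print per-epoch losses.
#' @return An object of class `pssr` with `params` (best checkpoint),
#'   `history` (per-epoch train/val MSE and best-so-far validation loss),
#'   and the configurations. Methods: [predict.pssr()], [print.pssr()],
#'   [summary.pssr()], [coef.pssr()], [plot.pssr()], [residuals.pssr()].
#' @export
pssr <- function(samples, val = NULL, model = model_config(),
                 train = train_config(), verbose = FALSE) {
  if (length(samples) == 0L) stop("empty training set")
  stopifnot(inherits(model, "pssr_config"), inherits(train, "pssr_train_config"))
  lr_rate <- train$learning_rate
  if (is.null(lr_rate)) lr_rate <- if (model$in_frames > 1L) 1e-4 else 9e-4
  params <- init_params(model)
  # check geometry on the first sample
  x1 <- sample_input(samples[[1L]], model)
  if (!identical(dim(samples[[1L]]$hr), dim(x1)[1:2] * model$scale))
    stop("HR side must be `scale` times the LR side")
  adam_m <- lapply(params, function(p) p * 0)
  adam_v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; tstep <- 0L
  eval_mse <- function(set) {
    if (is.null(set) || length(set) == 0L) return(NA_real_)
    mean(vapply(set, function(s) {
      p <- net_predict(sample_input(s, model), params, model)
      mean((p - s$hr)^2)
    }, 1))
  }
  set.seed(train$seed)
  hist_rows <- vector("list", train$epochs)
  best <- list(loss = Inf, params = params)
  for (ep in seq_len(train$epochs)) {
    ord <- sample(length(samples))
    ep_loss <- 0; n_batches <- 0L
    for (b0 in seq(1L, length(ord), by = train$batch_size)) {
      batch <- ord[b0:min(b0 + train$batch_size - 1L, length(ord))]
      grads <- NULL
      bl <- 0
      for (si in batch) {
        s <- samples[[si]]
        fw <- net_forward(sample_input(s, model), params, model)
        lg <- mse_loss_grad(fw$tape$vals[[fw$out]], s$hr)
        bl <- bl + lg$loss
        g <- tp_backward(fw$tape, fw$out, lg$grad)
        grads <- if (is.null(grads)) g else
          stats::setNames(lapply(names(g), function(n) grads[[n]] + g[[n]]),
                          names(g))
      }
      nb <- length(batch)
      tstep <- tstep + 1L
      for (nm in names(params)) {
        g <- grads[[nm]] / nb
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * g
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * g^2
        mh <- adam_m[[nm]] / (1 - beta1^tstep)
        vh <- adam_v[[nm]] / (1 - beta2^tstep)
        params[[nm]] <- params[[nm]] - lr_rate * mh / (sqrt(vh) + eps)
      }
      ep_loss <- ep_loss + bl / nb
      n_batches <- n_batches + 1L
    }
    train_mse <- ep_loss / n_batches
    val_mse <- eval_mse(val)
    monitor <- if (is.na(val_mse)) train_mse else val_mse
    if (monitor < best$loss) best <- list(loss = monitor, params = params)
    hist_rows[[ep]] <- data.frame(epoch = ep, train_mse = train_mse,
                                  val_mse = val_mse)
    if (verbose)
      message(sprintf("epoch %d: train MSE %.6g, val MSE %.6g",
                      ep, train_mse, val_mse))
  }
  history <- do.call(rbind, hist_rows)
  mon <- if (all(is.na(history$val_mse))) history$train_mse else history$val_mse
  history$best_val_so_far <- cummin(mon)
  structure(list(params = best$params, model = model, train = train,
                 learning_rate = lr_rate, history = history,
                 n_train = length(samples),
                 n_val = if (is.null(val)) 0L else length(val),
                 call = match.call()),
            class = "pssr")
}

# ---- S3 methods ------------------------------------------------------------

#' @export
print.pssr <- function(x, ...) {
  npar <- sum(vapply(x$params, length, 1))
  cat(sprintf(paste0("pssr: residual U-Net super-resolution model\n",
                     "  input frames: %d, scale: x%d, encoder depth: %d, ",
                     "base channels: %d\n",
                     "  parameters: %d; trained %d epoch(s) on %d sample(s)",
                     " (lr %.2g)\n"),
              x$model$in_frames, x$model$scale, x$model$encoder_depth,
              x$model$base_channels, npar, nrow(x$history), x$n_train,
              x$learning_rate))
  last <- x$history[nrow(x$history), ]
  cat(sprintf("  final train MSE: %.6g", last$train_mse))
  if (!is.na(last$val_mse)) cat(sprintf(", best val MSE: %.6g",
                                        min(x$history$val_mse)))
  cat("\n")
  invisible(x)
}

#' @export
summary.pssr <- function(object, ...) {
  print(object)
  cat("\nloss history:\n")
  print(object$history, row.names = FALSE)
  sizes <- vapply(object$params, length, 1)
  cat(sprintf("\nlargest layers:\n"))
  print(utils::head(sort(sizes, decreasing = TRUE), 5L))
  invisible(object)
}

#' @export
coef.pssr <- function(object, ...) object$params

#' Plot training history
#'
#' @param x a fitted [pssr] model.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pssr <- function(x, ...) {
  h <- x$history
  ys <- cbind(train = h$train_mse, val = h$val_mse)
  graphics::matplot(h$epoch, ys, type = "b", pch = c(1, 2), lty = 1,
                    log = "y", xlab = "epoch", ylab = "MSE",
                    main = "training history", ...)
  graphics::legend("topright", legend = colnames(ys), pch = c(1, 2),
                   col = 1:2, bty = "n")
  invisible(x)
}

#' Upscale with a fitted model
#'
#' For an [image_stack], runs per-frame (single-frame model) or per-window
#' (multi-frame model; edge windows use reflected z indices) inference and
#' returns a stack whose frame sides are `scale` times larger, clipped to the
#' bit range. For a list of training samples, returns the predicted HR frames
#' on the `[0, 1]` scale.
#'
#' @param object a fitted [pssr] model.
#' @param newdata an [image_stack] of LR frames, or a list of training
#'   samples.
#' @param ... unused.
#' @return An [image_stack] or a list of matrices, matching `newdata`.
#' @export
predict.pssr <- function(object, newdata, ...) {
  cfg <- object$model
  if (inherits(newdata, "image_stack")) {
    mx <- bit_max(newdata)
    n <- n_frames(newdata)
    if (cfg$in_frames > 1L && n < cfg$in_frames)
      stop(sprintf("multi-frame model needs at least %d frames", cfg$in_frames))
    d <- dim(newdata$voxels)
    out <- array(0, c(n, d[2L] * cfg$scale, d[3L] * cfg$scale))
    half <- (cfg$in_frames - 1L) %/% 2L
    for (i in seq_len(n)) {
      if (cfg$in_frames == 1L) {
        x <- array(newdata$voxels[i, , ] / mx, c(d[2L], d[3L], 1L))
      } else {
        zi <- (i - half):(i + half)
        zi[zi < 1L] <- 2L - zi[zi < 1L]          # reflect at stack edges
        zi[zi > n] <- 2L * n - zi[zi > n]
        x <- array(0, c(d[2L], d[3L], cfg$in_frames))
        for (j in seq_along(zi)) x[, , j] <- newdata$voxels[zi[j], , ] / mx
      }
      p <- net_predict(x, object$params, cfg)
      p[p < 0] <- 0; p[p > 1] <- 1
      out[i, , ] <- p * mx
    }
    image_stack(out, spacing_um = newdata$spacing_um,
                bit_depth = newdata$bit_depth)
  } else if (is.list(newdata)) {
    lapply(newdata, function(s) {
      p <- net_predict(sample_input(s, cfg), object$params, cfg)
      p[p < 0] <- 0; p[p > 1] <- 1
      p
    })
  } else stop("`newdata` must be an image_stack or a list of samples")
}

#' Prediction residuals on a sample set
#'
#' @param object a fitted [pssr] model.
#' @param newdata list of training samples (LR/HR pairs).
#' @param ... unused.
#' @return A list of `prediction - target` matrices.
#' @export
residuals.pssr <- function(object, newdata, ...) {
  if (missing(newdata))
    stop("supply `newdata` (the model does not store its training samples)")
  preds <- predict(object, newdata)
  Map(function(p, s) p - s$hr, preds, newdata)
}

#' Upscale a low-resolution stack
#'
#' Thin wrapper around [predict.pssr()] mirroring the pipeline vocabulary.
#'
#' @param model a fitted [pssr] model.
#' @param stack an [image_stack] of LR frames.
#' @return The upscaled [image_stack].
#' @export
upscale <- function(model, stack) predict(model, stack)

#' Save / load a fitted model
#'
#' Checkpoints are single-file archives holding the weights, the model and
#' training configurations and the loss history, with a schema version.
#'
#' @param object a fitted [pssr] model.
#' @param path checkpoint file path.
#' @return `pssr_save` returns `path` invisibly; `pssr_load` the model.
#' @export
pssr_save <- function(object, path) {
  stopifnot(inherits(object, "pssr"))
  saveRDS(list(schema = 1L, object = object), path)
  invisible(path)
}

#' @rdname pssr_save
#' @export
pssr_load <- function(path) {
  x <- readRDS(path)
  if (is.null(x$schema) || x$schema != 1L) stop("unknown checkpoint schema")
  x$object
}

# ---- non-learned baselines and building blocks ------------------------------

#' Subpixel (pixel-shuffle) upsampling with anti-checkerboard blur
#'
#' Rearranges `factor^2` channel blocks into a `factor`-times larger spatial
#' grid; when `blur` is on, follows with a normalized zero-order-hold (box)
#' kernel of width `factor` (reflection padding) to suppress checkerboard
#' artifacts.
#'
#' @param feature_map numeric array (H, W, C) with `C` divisible by
#'   `factor^2`, or a matrix (treated as one channel for `factor = 1`).
#' @param factor integer upsampling factor.
#' @param blur apply the box blur.
#' @return An array (H*factor, W*factor, C/factor^2).
#' @export
subpixel_upsample <- function(feature_map, factor = 2L, blur = TRUE) {
  if (is.matrix(feature_map))
    feature_map <- array(feature_map, c(dim(feature_map), 1L))
  factor <- as.integer(factor)
  if (dim(feature_map)[3L] %% factor^2 != 0L)
    stop("channel count not divisible by factor^2")
  y <- ps_forward(feature_map, factor)
  if (blur && factor > 1L) {
    d <- dim(y)
    P <- zoh_operator(d[1L], d[2L], factor)
    y <- array(as.matrix(P %*% matrix(y, d[1L] * d[2L], d[3L])), d)
  }
  y
}

# 1D half-pixel-centre bilinear interpolation matrix (n_out x n_in)
bilinear_matrix <- function(n_out, n_in) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src[src < 0] <- 0; src[src > n_in - 1] <- n_in - 1
  lo <- floor(src); w <- src - lo
  M <- matrix(0, n_out, n_in)
  M[cbind(seq_len(n_out), lo + 1L)] <- 1 - w
  hi <- pmin(lo + 2L, n_in)
  M[cbind(seq_len(n_out), hi)] <- M[cbind(seq_len(n_out), hi)] + w
  M
}

bilinear_resize <- function(frame, out_dim) {
  Rr <- bilinear_matrix(out_dim[1L], nrow(frame))
  Rc <- bilinear_matrix(out_dim[2L], ncol(frame))
  Rr %*% frame %*% t(Rc)
}

#' Bilinear upscaling baseline
#'
#' Standard separable bilinear interpolation with the half-pixel-centre
#' convention (no corner alignment), applied per frame — the traditional
#' non-learned upscaling the network is compared against.
#'
#' @param stack an [image_stack] or a single frame matrix.
#' @param factor integer upscaling factor (default 4).
#' @return An upscaled [image_stack] (or matrix).
#' @export
bilinear_upscale <- function(stack, factor = 4L) {
  if (is.matrix(stack))
    return(bilinear_resize(stack, dim(stack) * as.integer(factor)))
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  out <- array(0, c(d[1L], d[2L] * factor, d[3L] * factor))
  for (i in seq_len(d[1L]))
    out[i, , ] <- bilinear_resize(stack$voxels[i, , ],
                                  c(d[2L] * factor, d[3L] * factor))
  mx <- bit_max(stack)
  out[out < 0] <- 0; out[out > mx] <- mx
  image_stack(out, spacing_um = stack$spacing_um, bit_depth = stack$bit_depth)
}
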