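# Trainable prior model: a compact residual convolutional network that maps
# an artifact-laden half-size reconstruction to a cleaner slice, trained
# with the Smooth L1 loss, Adam (weight decay 1e-2), Kaiming-uniform
# initialization and two-phase fine-tuning (encoder first at lr 1e-4, then
# end-to-end at lr 1e-7). The network runs at half the reconstruction size;
# its output is bilinearly upsampled by the caller, which limits the spatial
# scale at which hallucinated structure can enter the prior.

#' Smooth L1 training loss
#'
#' Mean over elements of the piecewise residual penalty
#' `l(r) = 0.5 r^2` for `|r| <= 1` and `|r| - 0.5` otherwise: quadratic
#' (stable updates) for small residuals, linear (stable gradients) for
#' large ones, continuous at `|r| = 1`.
#'
#' @param x predicted values: a matrix, array or list of matrices.
#' @param u target values, same shape as `x`.
#' @return A single nonnegative number.
#' @examples
#' smooth_l1_loss(matrix(2), matrix(0)) # linear branch: 2 - 0.5
#' @export
smooth_l1_loss <- function(x, u) {
  if (is.list(x)) x <- unlist(x, use.names = FALSE)
  if (is.list(u)) u <- unlist(u, use.names = FALSE)
  if (length(x) != length(u) || length(x) < 1L)
    stop_input("`x` and `u` must be non-empty and the same shape")
  r <- abs(x - u)
  mean(ifelse(r <= 1, 0.5 * r^2, r - 0.5))
}

smooth_l1_grad <- function(x, u) {
  r <- x - u
  ifelse(abs(r) <= 1, r, sign(r)) / length(r)
}

#' Prior-network architecture description
#'
#' Records the full-scale architecture the prior model family is designed
#' around -- a U-Net-style encoder/decoder with a residual-network-34
#' encoder (initial 7x7 convolution, stages of 3/4/6/3 residual blocks),
#' sub-pixel-convolution (pixel shuffle) upsampling blocks with
#' resize-consistent initialization, each followed by two conv+ReLU blocks,
#' and stage-wise skip connections -- together with the desk-scale settings
#' (`channels`) used by the bundled trainable model. Inputs and outputs are
#' single-channel images at half the reconstruction grid.
#'
#' @param channels hidden channel count of the desk-scale model.
#' @param input_scale relative scale of the model input (0.5 = half the
#'   reconstruction grid).
#' @return An object of class `network_spec`.
#' @export
network_spec <- function(channels = 8L, input_scale = 0.5) {
  channels <- check_count(channels, "channels")
  check_scalar_num(input_scale, "input_scale", lower = 0, upper = 1)
  structure(
    list(encoder_stages = c(3L, 4L, 6L, 3L), initial_kernel = 7L,
         decoder = "pixel-shuffle upsampling, resize-consistent init, 2x (conv + ReLU)",
         skip_connections = "encoder stage i -> decoder stage i",
         channels_in = 1L, channels_out = 1L,
         channels = channels, input_scale = input_scale),
    class = "network_spec"
  )
}

#' Training configuration for the prior model
#'
#' @param loss loss name; only `"smooth_l1"` is available.
#' @param weight_decay Adam weight decay.
#' @param lr_phase1 learning rate of phase 1 (one sub-network trained).
#' @param lr_phase2 learning rate of the end-to-end phase 2.
#' @param phase1_scope which sub-network phase 1 updates: `"encoder"`
#'   (default) or `"decoder"`.
#' @param init weight initialization; only `"kaiming_uniform"`.
#' @param seed integer seed fixed before any weight draw.
#' @param epochs_phase1,epochs_phase2 epoch counts.
#' @return An object of class `train_config`.
#' @export
train_config <- function(loss = "smooth_l1", weight_decay = 1e-2,
                         lr_phase1 = 1e-4, lr_phase2 = 1e-7,
                         phase1_scope = c("encoder", "decoder"),
                         init = "kaiming_uniform", seed = 1L,
                         epochs_phase1 = 800L, epochs_phase2 = 20L) {
  phase1_scope <- match.arg(phase1_scope)
  stopifnot(loss == "smooth_l1", init == "kaiming_uniform")
  check_scalar_num(weight_decay, "weight_decay", lower = 0, allow_zero_lower = TRUE)
  check_scalar_num(lr_phase1, "lr_phase1", lower = 0)
  check_scalar_num(lr_phase2, "lr_phase2", lower = 0)
  structure(
    list(loss = loss, weight_decay = weight_decay,
         lr_phase1 = lr_phase1, lr_phase2 = lr_phase2,
         phase1_scope = phase1_scope, init = init, seed = as.integer(seed),
         epochs_phase1 = check_count(epochs_phase1, "epochs_phase1", min = 0L),
         epochs_phase2 = check_count(epochs_phase2, "epochs_phase2", min = 0L)),
    class = "train_config"
  )
}

# 3x3 "same" convolution with zero padding, via shifted slices.
conv3 <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(0, nr, nc)
  for (a in -1:1) for (b in -1:1) {
    w <- k[a + 2L, b + 2L]
    if (w == 0) next
    ri <- seq(max(1, 1 + a), min(nr, nr + a))
    ci <- seq(max(1, 1 + b), min(nc, nc + b))
    out[ri - a, ci - b] <- out[ri - a, ci - b] + w * x[ri, ci]
  }
  out
}

rot180 <- function(k) k[3:1, 3:1]

kaiming_uniform <- function(n, fan_in) {
  bound <- sqrt(6 / fan_in)
  runif(n, -bound, bound)
}

net_forward <- function(params, x) {
  C <- length(params$b1)
  a1 <- vector("list", C)
  for (c in seq_len(C)) {
    z <- conv3(x, params$W1[, , c]) + params$b1[c]
    a1[[c]] <- pmax(z, 0)
  }
  out <- x + params$b2
  for (c in seq_len(C)) out <- out + conv3(a1[[c]], params$W2[, , c])
  list(out = out, a1 = a1)
}

net_backward <- function(params, x, fwd, dout) {
  C <- length(params$b1)
  gW1 <- array(0, dim(params$W1)); gb1 <- numeric(C)
  gW2 <- array(0, dim(params$W2)); gb2 <- sum(dout)
  for (c in seq_len(C)) {
    a1 <- fwd$a1[[c]]
    # grads through conv2
    for (a in -1:1) for (b in -1:1) {
      nr <- nrow(x); nc <- ncol(x)
      ri <- seq(max(1, 1 + a), min(nr, nr + a))
      ci <- seq(max(1, 1 + b), min(nc, nc + b))
      gW2[a + 2L, b + 2L, c] <- sum(dout[ri - a, ci - b] * a1[ri, ci])
    }
    da1 <- conv3(dout, rot180(params$W2[, , c]))
    dz1 <- da1 * (a1 > 0)
    gb1[c] <- sum(dz1)
    for (a in -1:1) for (b in -1:1) {
      nr <- nrow(x); nc <- ncol(x)
      ri <- seq(max(1, 1 + a), min(nr, nr + a))
      ci <- seq(max(1, 1 + b), min(nc, nc + b))
      gW1[a + 2L, b + 2L, c] <- sum(dz1[ri - a, ci - b] * x[ri, ci])
    }
  }
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
}

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, st, lr, wd, t, mask) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (nm in names(params)) {
    if (!mask[[nm]]) next
    g <- grads[[nm]] + wd * params[[nm]]
    st[[nm]]$m <- b1 * st[[nm]]$m + (1 - b1) * g
    st[[nm]]$v <- b2 * st[[nm]]$v + (1 - b2) * g^2
    mhat <- st[[nm]]$m / (1 - b1^t)
    vhat <- st[[nm]]$v / (1 - b2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, st = st)
}

#' Train the prior model on degraded/clean slice pairs
#'
#' Fits the compact residual network on half-size slice pairs. Each pair's
#' input is normalized to unit range (the affine map is inverted at
#' prediction time). Training is two-phase fine-tuning: phase 1 updates one
#' sub-network (`cfg$phase1_scope`, default the encoder) at `lr_phase1`,
#' phase 2 trains end-to-end at `lr_phase2`. Deterministic for a fixed
#' `cfg$seed`.
#'
#' @param pairs list of pairs, each a list with elements `input` and
#'   `target` ([ct_image()]s or matrices of identical shape, at the
#'   half-size grid).
#' @param spec a [network_spec()].
#' @param cfg a [train_config()].
#' @return An object of class `prior_model` with the trained parameters and
#'   a `loss_curve` data frame (epoch, phase, loss).
#' @export
train_prior_model <- function(pairs, spec = network_spec(),
                              cfg = train_config()) {
  if (!is.list(pairs) || length(pairs) < 2L)
    stop_input("`pairs` must be a list of at least 2 (input, target) pairs")
  as_mat <- function(z) if (inherits(z, "ct_image")) z$values else z
  xs <- lapply(pairs, function(p) as_mat(p$input))
  ts <- lapply(pairs, function(p) as_mat(p$target))
  shp <- dim(xs[[1]])
  for (i in seq_along(xs))
    if (!identical(dim(xs[[i]]), shp) || !identical(dim(ts[[i]]), shp))
      stop_input("all training pairs must share one shape")

  # per-pair normalization by the input's range
  norms <- lapply(xs, function(x) {
    lo <- min(x); rg <- max(x) - lo
    if (rg <= 0) rg <- 1
    list(lo = lo, rg = rg)
  })
  xs_n <- Map(function(x, nm) (x - nm$lo) / nm$rg, xs, norms)
  ts_n <- Map(function(t, nm) (t - nm$lo) / nm$rg, ts, norms)

  C <- spec$channels
  model <- with_fixed_seed(cfg$seed, {
    params <- list(
      W1 = array(kaiming_uniform(9L * C, fan_in = 9L), c(3L, 3L, C)),
      b1 = numeric(C),
      W2 = array(kaiming_uniform(9L * C, fan_in = 9L * C), c(3L, 3L, C)),
      b2 = 0
    )
    st <- adam_state(params)
    enc <- list(W1 = TRUE, b1 = TRUE, W2 = FALSE, b2 = FALSE)
    dec <- list(W1 = FALSE, b1 = FALSE, W2 = TRUE, b2 = TRUE)
    all <- list(W1 = TRUE, b1 = TRUE, W2 = TRUE, b2 = TRUE)
    mask1 <- if (cfg$phase1_scope == "encoder") enc else dec

    curve <- data.frame(epoch = integer(), phase = integer(), loss = double())
    t_step <- 0L
    run_phase <- function(n_epochs, lr, mask, phase) {
      for (ep in seq_len(n_epochs)) {
        ep_loss <- 0
        for (i in seq_along(xs_n)) {
          fwd <- net_forward(params, xs_n[[i]])
          ep_loss <- ep_loss + smooth_l1_loss(fwd$out, ts_n[[i]])
          dout <- smooth_l1_grad(fwd$out, ts_n[[i]])
          grads <- net_backward(params, xs_n[[i]], fwd, dout)
          t_step <<- t_step + 1L
          upd <- adam_step(params, grads, st, lr, cfg$weight_decay, t_step, mask)
          params <<- upd$params; st <<- upd$st
        }
        curve <<- rbind(curve, data.frame(epoch = ep, phase = phase,
                                          loss = ep_loss / length(xs_n)))
      }
    }
    run_phase(cfg$epochs_phase1, cfg$lr_phase1, mask1, 1L)
    run_phase(cfg$epochs_phase2, cfg$lr_phase2, all, 2L)
    list(params = params, curve = curve)
  })

  structure(
    list(params = model$params, loss_curve = model$curve,
         spec = spec, cfg = cfg, input_shape = shp),
    class = "prior_model"
  )
}

#' @export
print.prior_model <- function(x, ...) {
  lc <- x$loss_curve
  cat(sprintf("<prior_model> %d channels, %d epochs, loss %.4g -> %.4g\n",
              x$spec$channels, nrow(lc), lc$loss[1], lc$loss[nrow(lc)]))
  invisible(x)
}

#' Predict a prior slice from a degraded half-size reconstruction
#'
#' Applies the trained model to one half-size slice. The input is
#' normalized by its own range, mapped through the network, and the affine
#' normalization is inverted.
#'
#' @param model a trained [train_prior_model()] handle.
#' @param fbp_slice a [ct_image()] (or matrix) at the model's input shape.
#' @return A [ct_image()] of the same shape.
#' @export
predict_prior <- function(model, fbp_slice) {
  x <- if (inherits(fbp_slice, "ct_image")) fbp_slice$values else fbp_slice
  if (!identical(dim(x), model$input_shape))
    stop_input("input shape does not match the model's training scale")
  lo <- min(x); rg <- max(x) - lo
  if (rg <= 0) rg <- 1
  out <- net_forward(model$params, (x - lo) / rg)$out * rg + lo
  if (inherits(fbp_slice, "ct_image")) return(as_ct_image(out, fbp_slice))
  ct_image(out, 1)
}
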