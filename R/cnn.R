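# Compact 3D convolutional regression network for control-free fill-state
# estimation. Implemented directly in R: 3x3x3 convolutions are evaluated
# as im2col + matrix products (BLAS), trained with Adam on a mean-absolute
# -error loss. Sized for 32^3 volumes on one CPU.

#' Configuration of the fill-state CNN estimator
#'
#' Architecture: fixed 2x average-pooling stem, then three 3x3x3 conv
#' blocks (ReLU, 2x average pooling after the first two), global average
#' pooling, and a single dense unit with sigmoid output in [0, 1]
#' (interpreted as a fraction; x100 for percent). Inputs are scaled as
#' `(x - input_center) * input_scale` so typical SUVR maps land near unit
#' range.
#'
#' @param input_shape Expected volume shape; all entries must be divisible
#'   by 8 (one stem and two block poolings).
#' @param channels Channel widths of the three conv blocks.
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param val_fraction Held-out validation fraction in (0, 1).
#' @param input_center,input_scale Fixed input normalization constants
#'   (defaults suit SUVR maps around 1.2).
#' @param bounded If `TRUE` (default) the output head is a sigmoid bounded
#'   to [0, 1]; if `FALSE` the head is linear and estimates are clipped to
#'   [0, 100]% at prediction time with a log message (estimates beyond
#'   100% can then occur internally, as unbounded regression permits).
#' @param seed RNG seed governing initialization, the train/validation
#'   split, and data order.
#' @export
cnn_config <- function(input_shape = c(32L, 32L, 32L),
                       channels = c(8L, 16L, 32L),
                       lr = 3e-3, batch_size = 16L, epochs = 30L,
                       val_fraction = 0.3,
                       input_center = 1.2, input_scale = 4,
                       bounded = TRUE, seed = 1L) {
  input_shape <- as.integer(input_shape)
  stopifnot(length(input_shape) == 3L, all(input_shape %% 8L == 0L),
            length(channels) == 3L, all(channels >= 1L),
            lr > 0, epochs >= 1L, batch_size >= 1L,
            val_fraction > 0, val_fraction < 1)
  structure(list(input_shape = input_shape, channels = as.integer(channels),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), val_fraction = val_fraction,
                 input_center = input_center, input_scale = input_scale,
                 bounded = bounded, seed = as.integer(seed)),
            class = "cnn_config")
}

# ---- layer primitives ------------------------------------------------------

# x4: [d1, d2, d3, C] feature map -> (n_vox x 27C) patch matrix, zero padded.
im2col3 <- function(x4) {
  d <- dim(x4)
  xp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, d[4]))
  xp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), ] <- x4
  nvox <- d[1] * d[2] * d[3]
  cols <- matrix(0, nvox, 27L * d[4])
  k <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    blk <- xp[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3]), ,
              drop = FALSE]
    dim(blk) <- c(nvox, d[4])
    cols[, ((k - 1L) * d[4] + 1L):(k * d[4])] <- blk
  }
  cols
}

# Adjoint of im2col3: scatter-add patch-matrix gradient back to the input.
col2im3 <- function(dcols, d, C) {
  gp <- array(0, c(d[1] + 2L, d[2] + 2L, d[3] + 2L, C))
  nvox <- d[1] * d[2] * d[3]
  k <- 0L
  for (dz in 0:2) for (dy in 0:2) for (dx in 0:2) {
    k <- k + 1L
    blk <- array(dcols[, ((k - 1L) * C + 1L):(k * C)], c(d, C))
    gp[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3]), ] <-
      gp[dx + seq_len(d[1]), dy + seq_len(d[2]), dz + seq_len(d[3]), ,
         drop = FALSE] + blk
  }
  gp[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L), , drop = FALSE]
}

# 2x2x2 average pooling of [d1,d2,d3,C]; dims must be even.
avgpool2 <- function(x4) {
  d <- dim(x4)
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    out <- out + x4[seq(1L + dx, d[1], 2L), seq(1L + dy, d[2], 2L),
                    seq(1L + dz, d[3], 2L), , drop = FALSE]
  out / 8
}

avgpool2_back <- function(dy4, d_in) {
  C <- dim(dy4)[4]
  g <- array(0, c(d_in, C))
  gshare <- dy4 / 8
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
    g[seq(1L + dx, d_in[1], 2L), seq(1L + dy, d_in[2], 2L),
      seq(1L + dz, d_in[3], 2L), ] <- gshare
  g
}

# ---- network ---------------------------------------------------------------

cnn_init_params <- function(config) {
  ch <- config$channels
  he <- function(nin, nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nin)),
                                     nr, nc)
  list(W1 = he(27, 27L, ch[1]), b1 = numeric(ch[1]),
       W2 = he(27 * ch[1], 27L * ch[1], ch[2]), b2 = numeric(ch[2]),
       W3 = he(27 * ch[2], 27L * ch[2], ch[3]), b3 = numeric(ch[3]),
       w4 = stats::rnorm(ch[3], 0, sqrt(1 / ch[3])), b4 = 0)
}

# Forward pass for one preprocessed (stem-pooled, scaled) volume.
# Returns prediction (fraction scale) and, if keep = TRUE, the caches
# needed for backprop.
cnn_forward <- function(x4, params, bounded, keep = FALSE) {
  d1 <- dim(x4)[1:3]
  c1 <- im2col3(x4)
  a1 <- sweep(c1 %*% params$W1, 2, params$b1, `+`)
  r1 <- pmax(a1, 0)
  f1 <- array(r1, c(d1, ncol(r1)))
  p1 <- avgpool2(f1)
  d2 <- dim(p1)[1:3]
  c2 <- im2col3(p1)
  a2 <- sweep(c2 %*% params$W2, 2, params$b2, `+`)
  r2 <- pmax(a2, 0)
  f2 <- array(r2, c(d2, ncol(r2)))
  p2 <- avgpool2(f2)
  d3 <- dim(p2)[1:3]
  c3 <- im2col3(p2)
  a3 <- sweep(c3 %*% params$W3, 2, params$b3, `+`)
  r3 <- pmax(a3, 0)
  g <- colMeans(r3)                      # global average pool
  s <- sum(g * params$w4) + params$b4
  yhat <- if (bounded) 1 / (1 + exp(-s)) else s
  if (!keep) return(list(yhat = yhat))
  list(yhat = yhat, s = s, g = g, c1 = c1, a1 = a1, c2 = c2, a2 = a2,
       c3 = c3, a3 = a3, r3 = r3, d1 = d1, d2 = d2, d3 = d3)
}

# Backward pass for MAE loss; returns gradient list matching params.
cnn_backward <- function(fw, target, params, bounded) {
  dyhat <- sign(fw$yhat - target)
  ds <- if (bounded) dyhat * fw$yhat * (1 - fw$yhat) else dyhat
  dg <- ds * params$w4
  dw4 <- ds * fw$g
  db4 <- ds
  nv3 <- nrow(fw$r3)
  dr3 <- matrix(dg / nv3, nv3, length(dg), byrow = TRUE)
  da3 <- dr3 * (fw$a3 > 0)
  dW3 <- crossprod(fw$c3, da3)
  db3 <- colSums(da3)
  dp2 <- col2im3(da3 %*% t(params$W3), fw$d3, ncol(fw$c3) / 27L)
  df2 <- avgpool2_back(dp2, fw$d2)
  dr2 <- matrix(df2, nrow(fw$a2), ncol(fw$a2))
  da2 <- dr2 * (fw$a2 > 0)
  dW2 <- crossprod(fw$c2, da2)
  db2 <- colSums(da2)
  dp1 <- col2im3(da2 %*% t(params$W2), fw$d2, ncol(fw$c2) / 27L)
  df1 <- avgpool2_back(dp1, fw$d1)
  dr1 <- matrix(df1, nrow(fw$a1), ncol(fw$a1))
  da1 <- dr1 * (fw$a1 > 0)
  dW1 <- crossprod(fw$c1, da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3,
       w4 = dw4, b4 = db4)
}

# Stem: fixed 2x average pooling + affine input scaling.
cnn_preprocess <- function(volume, config) {
  if (inherits(volume, "volume_grid")) volume <- volume$values
  if (!identical(as.integer(dim(volume)), config$input_shape))
    stop("shape mismatch: volume is ", paste(dim(volume), collapse = "x"),
         " but estimator expects ",
         paste(config$input_shape, collapse = "x"), call. = FALSE)
  x <- (volume - config$input_center) * config$input_scale
  x4 <- array(x, c(dim(volume), 1L))
  avgpool2(x4)
}

#' Train the fill-state CNN estimator
#'
#' Trains the compact 3D CNN of [cnn_config()] to regress ground-truth
#' fill states (percent) directly from SUVR volumes, with no control model
#' involved. Deterministic for a given config seed: initialization, the
#' train/validation split and the per-epoch data order all derive from it.
#' Training uses Adam on mean absolute error.
#'
#' @param volumes List of [volume_grid()]s (or 3D arrays) matching
#'   `config$input_shape`; at least 50.
#' @param fill_states_pct Ground-truth fill states in [0, 100], one per
#'   volume.
#' @param config A [cnn_config()].
#' @param verbose Print per-epoch losses.
#' @return Object of class `fill_estimator`: `params`, `config`, `history`
#'   (per-epoch training and validation MAE, percentage points), and the
#'   validation indices.
#' @export
train_estimator <- function(volumes, fill_states_pct, config = cnn_config(),
                            verbose = FALSE) {
  n <- length(volumes)
  if (n < 50L) stop("need >= 50 labeled volumes", call. = FALSE)
  if (length(fill_states_pct) != n)
    stop("one label per volume required", call. = FALSE)
  if (any(!is.finite(fill_states_pct)) ||
      any(fill_states_pct < 0 | fill_states_pct > 100))
    stop("labels must be fill states in [0, 100]", call. = FALSE)
  targets <- fill_states_pct / 100
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(restore_seed(old), add = TRUE)
  set.seed(config$seed)
  xs <- lapply(volumes, cnn_preprocess, config = config)
  perm <- sample.int(n)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- perm[seq_len(n_val)]
  train_idx <- perm[(n_val + 1L):n]
  params <- cnn_init_params(config)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0
  history <- data.frame(epoch = integer(0), train_mae = numeric(0),
                        val_mae = numeric(0))
  for (epoch in seq_len(config$epochs)) {
    order_ep <- sample(train_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / config$batch_size))
    ep_abs <- 0
    for (batch in batches) {
      grads <- NULL
      for (i in batch) {
        fw <- cnn_forward(xs[[i]], params, config$bounded, keep = TRUE)
        ep_abs <- ep_abs + abs(fw$yhat - targets[i])
        gi <- cnn_backward(fw, targets[i], params, config$bounded)
        grads <- if (is.null(grads)) gi
                 else mapply(`+`, grads, gi, SIMPLIFY = FALSE)
      }
      grads <- lapply(grads, function(g) g / length(batch))
      tstep <- tstep + 1
      for (nm in names(params)) {
        m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grads[[nm]]
        v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grads[[nm]]^2
        mhat <- m[[nm]] / (1 - beta1^tstep)
        vhat <- v[[nm]] / (1 - beta2^tstep)
        params[[nm]] <- params[[nm]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_preds <- vapply(val_idx, function(i)
      cnn_forward(xs[[i]], params, config$bounded)$yhat, numeric(1))
    tr_mae <- 100 * ep_abs / length(train_idx)
    va_mae <- 100 * mean(abs(val_preds - targets[val_idx]))
    history <- rbind(history, data.frame(epoch = epoch, train_mae = tr_mae,
                                         val_mae = va_mae))
    if (verbose)
      message(sprintf("epoch %3d  train MAE %.2f  val MAE %.2f pp",
                      epoch, tr_mae, va_mae))
  }
  structure(list(params = params, config = config, history = history,
                 val_idx = val_idx, train_idx = train_idx),
            class = "fill_estimator")
}

#' Estimate a fill state from a single volume (no control model)
#'
#' @param estimator A trained `fill_estimator`.
#' @param volume A [volume_grid()] or 3D array matching the estimator's
#'   input shape.
#' @return Fill-state estimate in percent, clipped to [0, 100]; clipping
#'   (possible only with an unbounded head) is reported via a message.
#' @export
estimate <- function(estimator, volume) {
  x <- cnn_preprocess(volume, estimator$config)
  raw <- 100 * cnn_forward(x, estimator$params, estimator$config$bounded)$yhat
  if (raw < 0 || raw > 100) {
    message(sprintf("fill-state estimate %.2f%% clipped to [0, 100]", raw))
    raw <- min(max(raw, 0), 100)
  }
  raw
}

#' Evaluate the estimator on a labeled test set
#'
#' @param estimator A trained `fill_estimator`.
#' @param volumes Nonempty list of test volumes.
#' @param fill_states_pct Ground-truth fill states in percent.
#' @return List with `mae` (percentage points), `r2`
#'   (1 - SS_res / SS_tot against the truth), and `pairs`
#'   (data frame of truth and estimate).
#' @export
evaluate_estimator <- function(estimator, volumes, fill_states_pct) {
  if (length(volumes) == 0) stop("empty test set", call. = FALSE)
  est <- vapply(volumes, function(vol)
    suppressMessages(estimate(estimator, vol)), numeric(1))
  truth <- fill_states_pct
  mae <- mean(abs(est - truth))
  ss_res <- sum((est - truth)^2)
  ss_tot <- sum((truth - mean(truth))^2)
  r2 <- 1 - ss_res / ss_tot
  list(mae = mae, r2 = r2,
       pairs = data.frame(truth = truth, estimate = est))
}

#' Save / load a trained estimator
#'
#' Weights go to an RDS checkpoint with a JSON sidecar recording the
#' configuration, seed, and training history.
#'
#' @param estimator A `fill_estimator`.
#' @param path Checkpoint path (`.rds`); the sidecar is `path` +
#'   `".json"`.
#' @export
save_estimator <- function(estimator, path) {
  saveRDS(estimator[c("params", "config")], path)
  sidecar <- list(config = unclass(estimator$config),
                  history = estimator$history,
                  n_train = length(estimator$train_idx),
                  n_val = length(estimator$val_idx))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_estimator
#' @export
load_estimator <- function(path) {
  obj <- readRDS(path)
  structure(list(params = obj$params, config = obj$config,
                 history = NULL, val_idx = NULL, train_idx = NULL),
            class = "fill_estimator")
}

#' @export
print.fill_estimator <- function(x, ...) {
  cat(sprintf("<fill_estimator> input %s, channels %s%s\n",
              paste(x$config$input_shape, collapse = "x"),
              paste(x$config$channels, collapse = "-"),
              if (!is.null(x$history))
                sprintf(", final val MAE %.2f pp",
                        x$history$val_mae[nrow(x$history)]) else ""))
  invisible(x)
}
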