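## A small trainable reference CNN so the audit loop runs against a
## genuine learned model. Architecture: two convolutional blocks of two
## 3x3 convolutions each (batch norm + ReLU), an identity residual skip
## in block 2 (added after the final batch norm, post-activation style),
## 2x2 max pooling, global average pooling, dropout 0.5, a 512-unit ReLU
## fully connected layer and a linear 4-way softmax head. Implemented
## directly on BLAS matrix products (im2col); no external deep-learning
## dependency.

## ---- tensor helpers (arrays are H x W x C x N) ----------------------------

im2col <- function(x, pad = 1L) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  xp <- array(0, c(h + 2 * pad, w + 2 * pad, cc, n))
  xp[pad + seq_len(h), pad + seq_len(w), , ] <- x
  col <- matrix(0, h * w * n, 9 * cc)
  for (c_i in seq_len(cc)) {
    for (k in 1:9) {
      dr <- (k - 1) %% 3L
      dc <- (k - 1) %/% 3L
      col[, (c_i - 1) * 9 + k] <-
        as.vector(xp[dr + seq_len(h), dc + seq_len(w), c_i, ])
    }
  }
  col
}

col2im_grad <- function(dcol, h, w, cc, n, pad = 1L) {
  dxp <- array(0, c(h + 2 * pad, w + 2 * pad, cc, n))
  for (c_i in seq_len(cc)) {
    for (k in 1:9) {
      dr <- (k - 1) %% 3L
      dc <- (k - 1) %/% 3L
      dxp[dr + seq_len(h), dc + seq_len(w), c_i, ] <-
        dxp[dr + seq_len(h), dc + seq_len(w), c_i, ] +
        array(dcol[, (c_i - 1) * 9 + k], c(h, w, n))
    }
  }
  dxp[pad + seq_len(h), pad + seq_len(w), , , drop = FALSE]
}

conv_forward <- function(x, K, b) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[4]
  col <- im2col(x)
  out <- sweep(col %*% K, 2, b, `+`)
  f <- ncol(K)
  list(y = aperm(array(out, c(h, w, n, f)), c(1, 2, 4, 3)), col = col)
}

conv_backward <- function(dy, x, K, cache_col) {
  d <- dim(x); h <- d[1]; w <- d[2]; cc <- d[3]; n <- d[4]
  f <- ncol(K)
  dout <- matrix(aperm(dy, c(1, 2, 4, 3)), h * w * n, f)
  dK <- crossprod(cache_col, dout)
  db <- colSums(dout)
  dcol <- tcrossprod(dout, K)
  dx <- col2im_grad(dcol, h, w, cc, n)
  list(dx = dx, dK = dK, db = db)
}

## channel-last matrix view: H x W x C x N -> (H*W*N) x C
to_cmat <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1, 2, 4, 3)), d[1] * d[2] * d[4], d[3])
}
from_cmat <- function(m, d) {
  aperm(array(m, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
}

bn_forward <- function(x, gamma, beta, state, training, eps = 1e-5) {
  d <- dim(x)
  xm <- to_cmat(x)
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(sweep(xm, 2, mu)^2)
    # cumulative average of batch statistics: calibrates the evaluation
    # path quickly even when an epoch is only a handful of batches
    state$n_batches <- (state$n_batches %||% 0) + 1
    k <- state$n_batches
    state$running_mean <- state$running_mean + (mu - state$running_mean) / k
    state$running_var <- state$running_var + (va - state$running_var) / k
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(sweep(xm, 2, mu), 2, inv, `*`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(y = from_cmat(y, d), xhat = xhat, inv = inv, state = state, dims = d)
}

bn_backward <- function(dy, cache, gamma) {
  dym <- to_cmat(dy)
  m <- nrow(dym)
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- sweep(dym, 2, gamma, `*`)
  # dx = inv/m * (m*dxhat - colSums(dxhat) - xhat * colSums(dxhat*xhat))
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$inv, `*`)
  list(dx = from_cmat(dx, cache$dims), dgamma = dgamma, dbeta = dbeta)
}

maxpool_forward <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]
  ri <- seq(1, h - 1, by = 2); ci <- seq(1, w - 1, by = 2)
  cand <- list(
    x[ri, ci, , , drop = FALSE],
    x[ri + 1, ci, , , drop = FALSE],
    x[ri, ci + 1, , , drop = FALSE],
    x[ri + 1, ci + 1, , , drop = FALSE]
  )
  best <- cand[[1]]
  arg <- array(1L, dim(best))
  for (j in 2:4) {
    upd <- cand[[j]] > best
    arg[upd] <- j
    best[upd] <- cand[[j]][upd]
  }
  list(y = best, arg = arg, in_dim = d)
}

maxpool_backward <- function(dy, cache) {
  d <- cache$in_dim
  dx <- array(0, d)
  ri <- seq(1, d[1] - 1, by = 2); ci <- seq(1, d[2] - 1, by = 2)
  for (j in 1:4) {
    sel <- cache$arg == j
    g <- array(0, dim(dy))
    g[sel] <- dy[sel]
    rr <- ri + (j - 1) %% 2L
    cc <- ci + (j - 1) %/% 2L
    dx[rr, cc, , ] <- dx[rr, cc, , ] + g
  }
  dx
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

## ---- model ----------------------------------------------------------------

init_bn <- function(f) {
  list(gamma = rep(1, f), beta = rep(0, f))
}
init_bn_state <- function(f) {
  e <- new.env()
  e$running_mean <- rep(0, f)
  e$running_var <- rep(1, f)
  e$n_batches <- 0
  e
}

#' Build the reference CNN predictor
#'
#' Randomly initialized (He initialization, seeded) small CNN with the
#' architecture described in the package overview. Inputs are
#' `input_size` x `input_size` x 3 preprocessed tensors in [-1, 1].
#'
#' @param width Number of convolution filters (>= 8; default 64).
#' @param n_classes Number of output classes (default 4).
#' @param input_size Side length of the input tensor (default 64 for
#'   desk-scale phantom work; the audit layer is size-agnostic).
#' @param seed Seed for weight initialization.
#' @param model_id Identifier recorded into decision traces.
#' @return Object of class `fdt_predictor`.
#' @export
build_pure_cnn <- function(width = 64L, n_classes = 4L, input_size = 64L,
                           seed = 1L, model_id = sprintf("pure_cnn_w%d", width)) {
  if (width < 8) stop_fdt("width must be >= 8")
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  params <- with_seed(seed, list(
    K1 = matrix(he(9 * 3, 9 * 3 * width), 9 * 3, width), b1 = rep(0, width),
    bn1 = init_bn(width),
    K2 = matrix(he(9 * width, 9 * width * width), 9 * width, width), b2 = rep(0, width),
    bn2 = init_bn(width),
    K3 = matrix(he(9 * width, 9 * width * width), 9 * width, width), b3 = rep(0, width),
    bn3 = init_bn(width),
    K4 = matrix(he(9 * width, 9 * width * width), 9 * width, width), b4 = rep(0, width),
    bn4 = init_bn(width),
    Wfc1 = matrix(he(width, width * 512), width, 512), bfc1 = rep(0, 512),
    Wfc2 = matrix(he(512, 512 * n_classes), 512, n_classes), bfc2 = rep(0, n_classes)
  ))
  structure(list(
    params = params,
    bn_states = list(bn1 = init_bn_state(width), bn2 = init_bn_state(width),
                     bn3 = init_bn_state(width), bn4 = init_bn_state(width)),
    width = as.integer(width),
    n_classes = as.integer(n_classes),
    input_size = as.integer(input_size),
    dropout = 0.5,
    model_id = model_id
  ), class = "fdt_predictor")
}

#' Trainable parameter count of the reference CNN
#'
#' @param predictor An [build_pure_cnn()] object.
#' @return Integer number of trainable scalars (convolution and dense
#'   weights and biases, batch-norm scale and shift).
#' @export
param_count <- function(predictor) {
  p <- predictor$params
  n <- 0L
  for (v in p) {
    if (is.list(v)) n <- n + length(v$gamma) + length(v$beta)
    else n <- n + length(v)
  }
  n
}

## full forward pass; returns logits and (optionally) all caches
cnn_forward <- function(model, x, training = FALSE, dropout_mask = NULL) {
  p <- model$params
  st <- model$bn_states
  c1 <- conv_forward(x, p$K1, p$b1)
  b1 <- bn_forward(c1$y, p$bn1$gamma, p$bn1$beta, st$bn1, training)
  r1 <- pmax(b1$y, 0)
  c2 <- conv_forward(r1, p$K2, p$b2)
  b2 <- bn_forward(c2$y, p$bn2$gamma, p$bn2$beta, st$bn2, training)
  r2 <- pmax(b2$y, 0)                       # block 1 output = block 2 input
  c3 <- conv_forward(r2, p$K3, p$b3)
  b3 <- bn_forward(c3$y, p$bn3$gamma, p$bn3$beta, st$bn3, training)
  r3 <- pmax(b3$y, 0)
  c4 <- conv_forward(r3, p$K4, p$b4)
  b4 <- bn_forward(c4$y, p$bn4$gamma, p$bn4$beta, st$bn4, training)
  s4 <- b4$y + r2                           # identity skip, post-activation style
  r4 <- pmax(s4, 0)
  mp <- maxpool_forward(r4)
  # global average pooling: mean over h,w -> N x C
  gm <- apply(mp$y, c(3, 4), mean)          # C x N
  feat <- t(gm)                             # N x C
  if (training) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(length(feat)) >= model$dropout,
                             nrow(feat), ncol(feat)) / (1 - model$dropout)
    }
    featd <- feat * dropout_mask
  } else {
    featd <- feat
    dropout_mask <- NULL
  }
  h1 <- sweep(featd %*% p$Wfc1, 2, p$bfc1, `+`)
  a1 <- pmax(h1, 0)
  logits <- sweep(a1 %*% p$Wfc2, 2, p$bfc2, `+`)
  list(logits = logits,
       cache = list(x = x, c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2,
                    r2 = r2, c3 = c3, b3 = b3, r3 = r3, c4 = c4, b4 = b4,
                    s4 = s4, r4 = r4, mp = mp, feat = feat, featd = featd,
                    dropout_mask = dropout_mask, h1 = h1, a1 = a1))
}

cnn_backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  g$Wfc2 <- crossprod(cache$a1, dlogits)
  g$bfc2 <- colSums(dlogits)
  da1 <- tcrossprod(dlogits, p$Wfc2)
  dh1 <- da1 * (cache$h1 > 0)
  g$Wfc1 <- crossprod(cache$featd, dh1)
  g$bfc1 <- colSums(dh1)
  dfeatd <- tcrossprod(dh1, p$Wfc1)
  dfeat <- if (!is.null(cache$dropout_mask)) dfeatd * cache$dropout_mask else dfeatd
  # undo GAP: spread over h,w
  d <- dim(cache$mp$y)
  dmp <- array(0, d)
  per <- t(dfeat) / (d[1] * d[2])           # C x N
  for (n_i in seq_len(d[4])) {
    dmp[, , , n_i] <- rep(per[, n_i], each = d[1] * d[2])
  }
  dr4 <- maxpool_backward(dmp, cache$mp)
  ds4 <- dr4 * (cache$s4 > 0)
  db4 <- bn_backward(ds4, cache$b4, p$bn4$gamma)
  g$bn4 <- list(gamma = db4$dgamma, beta = db4$dbeta)
  cb4 <- conv_backward(db4$dx, cache$r3, p$K4, cache$c4$col)
  g$K4 <- cb4$dK; g$b4 <- cb4$db
  dr3 <- cb4$dx * (cache$b3$y > 0)
  db3 <- bn_backward(dr3, cache$b3, p$bn3$gamma)
  g$bn3 <- list(gamma = db3$dgamma, beta = db3$dbeta)
  cb3 <- conv_backward(db3$dx, cache$r2, p$K3, cache$c3$col)
  g$K3 <- cb3$dK; g$b3 <- cb3$db
  dr2 <- cb3$dx + ds4                       # skip connection gradient
  dr2 <- dr2 * (cache$b2$y > 0)
  db2 <- bn_backward(dr2, cache$b2, p$bn2$gamma)
  g$bn2 <- list(gamma = db2$dgamma, beta = db2$dbeta)
  cb2 <- conv_backward(db2$dx, cache$r1, p$K2, cache$c2$col)
  g$K2 <- cb2$dK; g$b2 <- cb2$db
  dr1 <- cb2$dx * (cache$b1$y > 0)
  db1 <- bn_backward(dr1, cache$b1, p$bn1$gamma)
  g$bn1 <- list(gamma = db1$dgamma, beta = db1$dbeta)
  cb1 <- conv_backward(db1$dx, cache$x, p$K1, cache$c1$col)
  g$K1 <- cb1$dK; g$b1 <- cb1$db
  g
}

#' Predict the class of one slice
#'
#' Preprocesses the raw [0,1] slice to the predictor's input size and
#' runs the deterministic (evaluation-mode) forward pass.
#'
#' @param predictor An `fdt_predictor`.
#' @param img Numeric matrix in [0,1], any size.
#' @return An [prediction()] object.
#' @export
predict_slice <- function(predictor, img) {
  UseMethod("predict_slice")
}

#' @export
predict_slice.fdt_predictor <- function(predictor, img) {
  pp <- preprocess_eval(img, size = predictor$input_size)
  x <- array(pp$tensor, c(dim(pp$tensor), 1))
  out <- cnn_forward(predictor, x, training = FALSE)
  sm <- softmax_rows(out$logits)[1, ]
  prediction(sm)
}

#' Batch softmax predictions for preprocessed tensors
#'
#' @param predictor An `fdt_predictor`.
#' @param x `H x W x 3 x N` array of preprocessed inputs.
#' @return `N x n_classes` softmax matrix.
#' @export
predict_proba <- function(predictor, x) {
  out <- cnn_forward(predictor, x, training = FALSE)
  softmax_rows(out$logits)
}

## ---- training -------------------------------------------------------------

#' Training configuration for the reference CNN
#'
#' Defaults follow the shared training protocol: AdamW
#' (beta1 0.9, beta2 0.999), initial learning rate 3e-4, weight decay
#' 1e-4, batch size 32, at most 20 epochs, early stopping on validation
#' macro-F1 with patience 5, and learning-rate halving on a 2-epoch
#' plateau of the same metric.
#'
#' @param lr,weight_decay,batch_size,max_epochs,beta1,beta2 Optimizer
#'   settings.
#' @param es_patience Early-stopping patience (epochs without
#'   improvement in validation macro-F1).
#' @param lr_patience,lr_factor Plateau scheduler settings.
#' @param seed RNG seed controlling shuffling and dropout.
#' @return List of class `fdt_train_config`.
#' @export
train_config <- function(lr = 3e-4, weight_decay = 1e-4, batch_size = 32L,
                         max_epochs = 20L, beta1 = 0.9, beta2 = 0.999,
                         es_patience = 5L, lr_patience = 2L, lr_factor = 0.5,
                         seed = 1L) {
  cfg <- list(lr = lr, weight_decay = weight_decay,
              batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs),
              beta1 = beta1, beta2 = beta2,
              es_patience = as.integer(es_patience),
              lr_patience = as.integer(lr_patience), lr_factor = lr_factor,
              seed = as.integer(seed))
  if (any(vapply(cfg, function(v) !is.numeric(v) || v <= 0, logical(1)))) {
    stop_fdt("all training configuration values must be positive")
  }
  class(cfg) <- "fdt_train_config"
  cfg
}

#' Early-stopping and plateau-scheduler bookkeeping
#'
#' Pure function over a validation-metric history (higher is better):
#' computes, for each epoch, the learning rate in force and whether
#' training halts. The learning rate is multiplied by `lr_factor` after
#' `lr_patience` consecutive epochs without improvement (counter resets
#' on reduction); training halts after `es_patience` consecutive epochs
#' without improvement.
#'
#' @param metrics Numeric vector of per-epoch validation metrics.
#' @param lr0 Initial learning rate.
#' @param es_patience,lr_patience,lr_factor Schedule parameters.
#' @return List with `lr` (learning rate used at each epoch),
#'   `stop_epoch` (first epoch after which training halts, or `NA`),
#'   `best_epoch`.
#' @export
training_schedule <- function(metrics, lr0, es_patience = 5L,
                              lr_patience = 2L, lr_factor = 0.5) {
  n <- length(metrics)
  lr <- numeric(n)
  cur <- lr0
  best <- -Inf; best_epoch <- NA_integer_
  bad_es <- 0L; bad_lr <- 0L
  stop_epoch <- NA_integer_
  for (e in seq_len(n)) {
    lr[e] <- cur
    if (metrics[e] > best) {
      best <- metrics[e]; best_epoch <- e
      bad_es <- 0L; bad_lr <- 0L
    } else {
      bad_es <- bad_es + 1L; bad_lr <- bad_lr + 1L
      if (bad_lr >= lr_patience) {
        cur <- cur * lr_factor
        bad_lr <- 0L
      }
      if (is.na(stop_epoch) && bad_es >= es_patience) stop_epoch <- e
    }
  }
  list(lr = lr, stop_epoch = stop_epoch, best_epoch = best_epoch)
}

adamw_step <- function(par, grad, state, lr, cfg, t) {
  if (is.null(state$m)) {
    state$m <- par * 0
    state$v <- par * 0
  }
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * grad
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * grad^2
  mh <- state$m / (1 - cfg$beta1^t)
  vh <- state$v / (1 - cfg$beta2^t)
  par <- par - lr * (mh / (sqrt(vh) + 1e-8) + cfg$weight_decay * par)
  list(par = par, state = state)
}

## flatten params into a named list of numeric leaves for the optimizer
flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      out[[paste0(nm, ".gamma")]] <- p[[nm]]$gamma
      out[[paste0(nm, ".beta")]] <- p[[nm]]$beta
    } else out[[nm]] <- p[[nm]]
  }
  out
}
unflatten_params <- function(flat, template) {
  for (nm in names(template)) {
    if (is.list(template[[nm]])) {
      template[[nm]]$gamma <- flat[[paste0(nm, ".gamma")]]
      template[[nm]]$beta <- flat[[paste0(nm, ".beta")]]
    } else template[[nm]] <- flat[[nm]]
  }
  template
}

## build the H x W x 3 x N tensor for a set of cohort slices
cohort_tensor <- function(cohort, idx, size) {
  x <- array(0, c(size, size, 3, length(idx)))
  for (j in seq_along(idx)) {
    pp <- preprocess_eval(cohort$slices[[idx[j]]]$image, size = size)
    x[, , , j] <- pp$tensor
  }
  x
}

#' Train the reference CNN on a phantom cohort
#'
#' Optimizes the class-weighted cross-entropy with AdamW, logging
#' per-epoch train/validation loss and accuracy plus the learning rate,
#' with early stopping and plateau-based learning-rate halving on the
#' validation macro-F1. The checkpoint with the best validation macro-F1
#' is returned. Fully seeded and reproducible.
#'
#' @param predictor An [build_pure_cnn()] object.
#' @param cohort An `fdt_phantom_cohort`.
#' @param split An [stratified_split()] holdout assignment for the
#'   cohort (train/val), or `NULL` to create one (seed from `cfg`).
#' @param weights `fdt_class_weights` computed from the training
#'   partition, or `NULL` for unweighted training.
#' @param cfg An [train_config()].
#' @param augment Apply training-time augmentation to each training
#'   slice (re-sampled per epoch)?
#' @return List with `predictor` (best checkpoint), `log` (per-epoch data
#'   frame), `best_epoch`.
#' @export
train_cnn <- function(predictor, cohort, split = NULL, weights = NULL,
                      cfg = train_config(), augment = FALSE) {
  stopifnot(inherits(predictor, "fdt_predictor"),
            inherits(cohort, "fdt_phantom_cohort"))
  classes <- fdt_classes()
  labels <- cohort$labels
  if (is.null(split)) split <- stratified_split(labels, "holdout",
                                                fractions = c(0.8, 0.2, 0.0),
                                                seed = cfg$seed)
  tr_idx <- which(split$assignment == "train")
  va_idx <- which(split$assignment == "val")
  if (length(tr_idx) == 0 || length(va_idx) == 0) stop_fdt("empty train or validation split")
  size <- predictor$input_size
  y_tr <- match(labels[tr_idx], classes)
  y_va <- labels[va_idx]
  w <- if (is.null(weights)) rep(1, length(classes)) else weights$normalized_weights
  xva <- cohort_tensor(cohort, va_idx, size)
  xtr_clean <- cohort_tensor(cohort, tr_idx, size)

  flat <- flatten_params(predictor$params)
  opt_state <- lapply(flat, function(z) NULL)
  lr <- cfg$lr
  best_f1 <- -Inf
  best_params <- predictor$params
  best_epoch <- NA_integer_
  bad_es <- 0L; bad_lr <- 0L
  t_step <- 0L
  log_rows <- list()

  for (epoch in seq_len(cfg$max_epochs)) {
    ep_seed <- derive_seed(cfg$seed, epoch)
    perm <- with_seed(ep_seed, sample(seq_along(tr_idx)))
    xtr <- xtr_clean
    if (augment) {
      for (j in seq_along(tr_idx)) {
        raw <- cohort$slices[[tr_idx[j]]]$image
        aug <- augment_train(raw, seed = derive_seed(ep_seed, j))
        xtr[, , , j] <- preprocess_eval(aug, size = size)$tensor
      }
    }
    tr_loss <- 0; tr_correct <- 0
    nb <- ceiling(length(perm) / cfg$batch_size)
    for (b in seq_len(nb)) {
      sel <- perm[((b - 1) * cfg$batch_size + 1):min(b * cfg$batch_size, length(perm))]
      xb <- xtr[, , , sel, drop = FALSE]
      yb <- y_tr[sel]
      nbt <- length(sel)
      dm_seed <- derive_seed(ep_seed, 10000 + b)
      dmask <- with_seed(dm_seed,
        matrix(stats::runif(nbt * predictor$width) >= predictor$dropout,
               nbt, predictor$width) / (1 - predictor$dropout))
      fw <- cnn_forward(predictor, xb, training = TRUE, dropout_mask = dmask)
      probs <- softmax_rows(fw$logits)
      p_y <- pmax(probs[cbind(seq_len(nbt), yb)], 1e-12)
      loss <- mean(-w[yb] * log(p_y))
      onehot <- matrix(0, nbt, length(classes))
      onehot[cbind(seq_len(nbt), yb)] <- 1
      dlogits <- (probs - onehot) * (w[yb] / nbt)
      grads <- cnn_backward(predictor, fw$cache, dlogits)
      gflat <- flatten_params(grads)
      t_step <- t_step + 1L
      for (nm in names(flat)) {
        upd <- adamw_step(flat[[nm]], gflat[[nm]], opt_state[[nm]] %||% list(),
                          lr, cfg, t_step)
        flat[[nm]] <- upd$par
        opt_state[[nm]] <- upd$state
      }
      predictor$params <- unflatten_params(flat, predictor$params)
      tr_loss <- tr_loss + loss * nbt
      tr_correct <- tr_correct + sum(max.col(probs, ties.method = "first") == yb)
    }
    tr_loss <- tr_loss / length(perm)
    tr_acc <- tr_correct / length(perm)

    pv <- predict_proba(predictor, xva)
    pred_va <- classes[max.col(pv, ties.method = "first")]
    rep_va <- classification_report(y_va, pred_va, classes = classes)
    val_f1 <- rep_va$macro_f1
    val_loss <- weighted_cross_entropy(pv, match(y_va, classes), NULL)

    log_rows[[epoch]] <- data.frame(
      epoch = epoch, train_loss = tr_loss, train_acc = tr_acc,
      val_loss = val_loss, val_acc = rep_va$accuracy,
      val_macro_f1 = val_f1, lr = lr
    )

    if (val_f1 > best_f1) {
      best_f1 <- val_f1; best_epoch <- epoch
      best_params <- predictor$params
      bad_es <- 0L; bad_lr <- 0L
    } else {
      bad_es <- bad_es + 1L; bad_lr <- bad_lr + 1L
      if (bad_lr >= cfg$lr_patience) {
        lr <- lr * cfg$lr_factor
        bad_lr <- 0L
      }
      if (bad_es >= cfg$es_patience) break
    }
  }
  predictor$params <- best_params
  list(predictor = predictor, log = do.call(rbind, log_rows),
       best_epoch = best_epoch, best_val_macro_f1 = best_f1)
}
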