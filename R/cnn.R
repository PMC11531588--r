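#' Specification of a voxel classifier network
#'
#' A compact 3D convolutional network mapping a `w x w x nz` local voxel to
#' class probabilities: optional depth pre-pooling (the depth axis is far
#' longer than the scan axes), a few conv3d+relu+maxpool blocks, global
#' average pooling, optional hidden dense layers, and a softmax output.
#' The presence task has 2 classes (`absence`, `presence`); the count task
#' has 3 (`0`, `1`, `ge2`).
#'
#' @param task `"presence"` or `"count"`
#' @param input_shape length-3 integer vector `(w, w, nz)`
#' @param conv_blocks list of blocks, each `list(channels, kernel, pool)`
#'   with length-3 `kernel` and `pool`
#' @param dense_widths integer vector of hidden dense widths (may be empty)
#' @param input_pool_z `"auto"` (pool depth down to ~32 samples before the
#'   first convolution) or an explicit integer factor
#' @return object of class `model_spec`
#' @export
model_spec <- function(task = c("presence", "count"),
                       input_shape = c(25L, 25L, 173L),
                       conv_blocks = list(
                         list(channels = 8L, kernel = c(3L, 3L, 5L),
                              pool = c(2L, 2L, 2L)),
                         list(channels = 16L, kernel = c(3L, 3L, 3L),
                              pool = c(2L, 2L, 2L))),
                       dense_widths = integer(0),
                       input_pool_z = "auto") {
  task <- match.arg(task)
  n_classes <- if (task == "presence") 2L else 3L
  class_names <- if (task == "presence") c("absence", "presence") else
    c("0", "1", "ge2")
  if (identical(input_pool_z, "auto")) {
    input_pool_z <- max(1L, input_shape[3] %/% 32L)
  }
  structure(list(task = task, n_classes = n_classes,
                 class_names = class_names,
                 input_shape = as.integer(input_shape),
                 conv_blocks = conv_blocks,
                 dense_widths = as.integer(dense_widths),
                 input_pool_z = as.integer(input_pool_z)),
            class = "model_spec")
}

#' Build (initialize) a classifier network from its spec
#'
#' Weights use He-normal initialization; biases start at zero. The layer
#' schedule is validated against the input shape, so a pooling plan that
#' collapses an axis is rejected at build time.
#'
#' @param spec a [model_spec()]
#' @param seed RNG seed for weight initialization
#' @return object of class `cnn_model`; `print()` reports the layer sizes
#'   and parameter count
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    d <- c(spec$input_shape, 1L)
    layers <- list()
    if (spec$input_pool_z > 1L) {
      nb <- d[3] %/% spec$input_pool_z
      if (nb < 1L) stop("input_pool_z exceeds input depth")
      layers[[length(layers) + 1L]] <-
        list(type = "avgpool_z", factor = spec$input_pool_z)
      d[3] <- nb
    }
    for (blk in spec$conv_blocks) {
      k <- as.integer(blk$kernel)
      if (any(k > d[1:3])) {
        stop("input shape incompatible with conv kernel ",
             paste(k, collapse = "x"), " at dims ",
             paste(d[1:3], collapse = "x"))
      }
      co <- as.integer(blk$channels)
      sd_he <- sqrt(2 / (prod(k) * d[4]))
      W <- array(stats::rnorm(prod(k) * d[4] * co, sd = sd_he),
                 c(k, d[4], co))
      layers[[length(layers) + 1L]] <-
        list(type = "conv", W = W, b = numeric(co))
      d <- c(d[1:3] - k + 1L, co)
      p <- as.integer(blk$pool)
      if (any(p > 1L)) {
        nb <- d[1:3] %/% p
        if (any(nb < 1L)) {
          stop("input shape incompatible with pooling schedule: dims ",
               paste(d[1:3], collapse = "x"), " pooled by ",
               paste(p, collapse = "x"))
        }
        layers[[length(layers) + 1L]] <- list(type = "maxpool", pool = p)
        d <- c(nb, d[4])
      }
    }
    layers[[length(layers) + 1L]] <- list(type = "gap")
    feat <- 2L * d[4]                 # per-channel global mean + max
    for (wd in spec$dense_widths) {
      layers[[length(layers) + 1L]] <-
        list(type = "dense", relu = TRUE,
             W = matrix(stats::rnorm(feat * wd, sd = sqrt(2 / feat)),
                        feat, wd),
             b = numeric(wd))
      feat <- wd
    }
    layers[[length(layers) + 1L]] <-
      list(type = "dense", relu = FALSE,
           W = matrix(stats::rnorm(feat * spec$n_classes,
                                   sd = sqrt(2 / feat)),
                      feat, spec$n_classes),
           b = numeric(spec$n_classes))
    structure(list(spec = spec, layers = layers,
                   cache_env = new.env(parent = emptyenv())),
              class = "cnn_model")
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  np <- n_parameters(x)
  cat(sprintf("<cnn_model %s> %d layers, %d parameters, input %s\n",
              x$spec$task, length(x$layers), np,
              paste(x$spec$input_shape, collapse = "x")))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param model a `cnn_model`
#' @return integer parameter count
#' @export
n_parameters <- function(model) {
  sum(vapply(model$layers, function(l) {
    if (is.null(l$W)) 0L else length(l$W) + length(l$b)
  }, integer(1)))
}

# forward pass for one sample; returns logits plus per-layer caches
cnn_forward <- function(model, x, keep_cache = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(all(dim(x)[1:3] == model$spec$input_shape))
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  a <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    r <- switch(l$type,
      avgpool_z = avgpool_z_forward(a, l$factor),
      conv = conv3d_forward(a, l$W, l$b, model$cache_env),
      maxpool = maxpool3d_forward(a, l$pool),
      gap = gap_forward(a),
      dense = dense_forward(a, l$W, l$b, l$relu))
    a <- r$out
    if (keep_cache) caches[[i]] <- r$cache
  }
  list(logits = a, caches = caches)
}

# backward pass from dlogits; returns per-layer parameter grads.
# If stop_at_conv is the index of a conv layer, returns instead the
# gradient flowing into that layer's (post-relu) output together with the
# activation itself — the quantities Grad-CAM needs.
cnn_backward <- function(model, caches, dlogits, stop_at_conv = NULL) {
  grads <- vector("list", length(model$layers))
  g <- dlogits
  first_param <- which(vapply(model$layers,
                              function(l) !is.null(l$W), logical(1)))[1]
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    if (!is.null(stop_at_conv) && i == stop_at_conv) {
      co <- dim(l$W)[5]
      return(list(d_activation = array(g, c(caches[[i]]$out_dim, co)),
                  activation = array(caches[[i]]$A,
                                     c(caches[[i]]$out_dim, co))))
    }
    g <- switch(l$type,
      dense = {
        r <- dense_backward(g, l$W, caches[[i]])
        grads[[i]] <- r[c("dW", "db")]
        r$dx
      },
      gap = gap_backward(g, caches[[i]]),
      maxpool = maxpool3d_backward(array(g, c(caches[[i]]$nb,
                                              caches[[i]]$in_dim[4])),
                                   caches[[i]]),
      conv = {
        want_dx <- i > first_param || !is.null(stop_at_conv)
        r <- conv3d_backward(g, l$W, caches[[i]], want_dx = want_dx)
        grads[[i]] <- r[c("dW", "db")]
        r$dx
      },
      avgpool_z = NULL)   # first layer; input gradient not needed
    if (is.null(g) && i > 1L && is.null(stop_at_conv)) break
  }
  grads
}

# loss and parameter grads for one labelled sample
cnn_sample_grads <- function(model, x, y) {
  fwd <- cnn_forward(model, x)
  lg <- xent_loss_grad(fwd$logits, y)
  grads <- cnn_backward(model, fwd$caches, lg$dlogits)
  list(loss = lg$loss, probs = lg$probs, grads = grads)
}

#' Training configuration
#'
#' Defaults follow the study protocol: Adam, batch size 3, learning rate
#' 1e-6, up to 50 epochs with early stopping on validation loss after 10
#' epochs without improvement. Scaled-down runs use a larger learning
#' rate and fewer epochs.
#'
#' @param batch_size samples per Adam step
#' @param lr learning rate
#' @param max_epochs epoch budget (50 presence / 30 count in the protocol)
#' @param patience stop when `epoch - best_epoch >= patience`
#' @param seed RNG seed for shuffling
#' @param verbose print per-epoch progress
#' @return list of class `train_config`
#' @export
train_config <- function(batch_size = 3L, lr = 1e-6, max_epochs = 50L,
                         patience = 10L, seed = 1L, verbose = FALSE) {
  stopifnot(batch_size >= 1L, patience < max_epochs || max_epochs == 1L)
  structure(list(batch_size = as.integer(batch_size), lr = lr,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Assemble a classifier dataset
#'
#' @param x list of voxel arrays, or a function `function(i)` returning the
#'   i-th voxel array (lazy slicing from in-memory volumes)
#' @param y class labels: integers `1..n_classes` or characters matching
#'   the model's class names
#' @param n number of samples (required when `x` is a function)
#' @return list of class `cnn_dataset`
#' @export
cnn_dataset <- function(x, y, n = NULL) {
  if (is.function(x)) {
    stopifnot(!is.null(n))
    get_x <- x
    n <- as.integer(n)
  } else {
    stopifnot(is.list(x))
    n <- length(x)
    get_x <- function(i) x[[i]]
  }
  stopifnot(length(y) == n)
  structure(list(get_x = get_x, y = y, n = n), class = "cnn_dataset")
}

encode_labels <- function(y, class_names) {
  if (is.numeric(y)) return(as.integer(y))
  m <- match(as.character(y), class_names)
  if (anyNA(m)) stop("unknown class label(s): ",
                     paste(unique(y[is.na(m)]), collapse = ", "))
  m
}

#' Train a voxel classifier
#'
#' Mini-batch Adam with shuffling, validation-loss monitoring, early
#' stopping, and best-epoch weight restoration. Deterministic for a fixed
#' seed (single-threaded R; BLAS matmuls are reproducible on one machine).
#'
#' @param model a built [build_model()] network
#' @param train_set,val_set [cnn_dataset()]s with disjoint samples
#' @param config a [train_config()]
#' @return the model with trained weights; `attr(, "history")` holds a
#'   data frame of per-epoch train/validation loss and accuracy, and
#'   `attr(, "best_epoch")` the restored epoch
#' @export
train_cnn <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "cnn_model"), inherits(train_set, "cnn_dataset"),
            inherits(val_set, "cnn_dataset"))
  if (train_set$n == 0L || val_set$n == 0L) stop("empty train or val split")
  y_tr <- encode_labels(train_set$y, model$spec$class_names)
  y_va <- encode_labels(val_set$y, model$spec$class_names)

  adam <- adam_init(model)
  best <- list(loss = Inf, epoch = 0L, layers = NULL)
  hist <- list()

  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      perm <- sample.int(train_set$n)
      ep_loss <- 0; ep_hit <- 0L
      for (start in seq(1L, train_set$n, by = config$batch_size)) {
        idx <- perm[start:min(start + config$batch_size - 1L, train_set$n)]
        acc_grads <- NULL
        for (i in idx) {
          sg <- cnn_sample_grads(model, train_set$get_x(i), y_tr[i])
          if (!is.finite(sg$loss)) {
            stop("non-finite training loss at epoch ", epoch,
                 ", sample ", i)
          }
          ep_loss <- ep_loss + sg$loss
          ep_hit <- ep_hit + (which.max(sg$probs) == y_tr[i])
          acc_grads <- add_grads(acc_grads, sg$grads)
        }
        adam <- adam_step(model, adam, acc_grads, length(idx), config$lr)
        model <- adam$model
      }
      vl <- evaluate_loss(model, val_set, y_va)
      hist[[epoch]] <- data.frame(
        epoch = epoch, train_loss = ep_loss / train_set$n,
        train_acc = ep_hit / train_set$n,
        val_loss = vl$loss, val_acc = vl$acc)
      if (config$verbose) {
        message(sprintf("epoch %d: train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, ep_loss / train_set$n, ep_hit / train_set$n,
                        vl$loss, vl$acc))
      }
      if (vl$loss < best$loss) {
        best <- list(loss = vl$loss, epoch = epoch,
                     layers = model$layers)
      }
      if (epoch - best$epoch >= config$patience) break
    }
  })
  if (!is.null(best$layers)) model$layers <- best$layers
  history <- do.call(rbind, hist)
  attr(model, "history") <- history
  attr(model, "best_epoch") <- best$epoch
  model
}

evaluate_loss <- function(model, ds, y_enc) {
  loss <- 0; hit <- 0L
  for (i in seq_len(ds$n)) {
    fwd <- cnn_forward(model, ds$get_x(i), keep_cache = FALSE)
    lg <- xent_loss_grad(fwd$logits, y_enc[i])
    loss <- loss + lg$loss
    hit <- hit + (which.max(lg$probs) == y_enc[i])
  }
  list(loss = loss / ds$n, acc = hit / ds$n)
}

#' Predict class probabilities for voxels
#'
#' @param model a trained `cnn_model`
#' @param x a single voxel array, a list of arrays, or a [cnn_dataset()]
#' @return matrix `n x n_classes` of probabilities, columns named by class;
#'   `attr(, "class_ids")` holds the argmax labels
#' @export
predict_cnn <- function(model, x) {
  if (inherits(x, "cnn_dataset")) {
    n <- x$n; get_x <- x$get_x
  } else if (is.list(x) && !is.array(x)) {
    n <- length(x); get_x <- function(i) x[[i]]
  } else {
    n <- 1L; get_x <- function(i) x
  }
  out <- matrix(NA_real_, n, model$spec$n_classes,
                dimnames = list(NULL, model$spec$class_names))
  for (i in seq_len(n)) {
    fwd <- cnn_forward(model, get_x(i), keep_cache = FALSE)
    out[i, ] <- softmax_probs(fwd$logits)
  }
  attr(out, "class_ids") <- model$spec$class_names[
    apply(out, 1L, which.max)]
  out
}

# ---- Adam ------------------------------------------------------------

adam_init <- function(model) {
  state <- lapply(model$layers, function(l) {
    if (is.null(l$W)) return(NULL)
    list(mW = array(0, dim(l$W) %||% length(l$W)), vW = array(0, dim(l$W) %||% length(l$W)),
         mb = numeric(length(l$b)), vb = numeric(length(l$b)))
  })
  list(model = model, state = state, t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

add_grads <- function(acc, grads) {
  if (is.null(acc)) return(grads)
  for (i in seq_along(grads)) {
    if (!is.null(grads[[i]])) {
      acc[[i]]$dW <- acc[[i]]$dW + grads[[i]]$dW
      acc[[i]]$db <- acc[[i]]$db + grads[[i]]$db
    }
  }
  acc
}

adam_step <- function(model, adam, grads, batch_n, lr) {
  adam$t <- adam$t + 1L
  b1 <- adam$beta1; b2 <- adam$beta2
  corr1 <- 1 - b1^adam$t
  corr2 <- 1 - b2^adam$t
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    gW <- grads[[i]]$dW / batch_n
    gb <- grads[[i]]$db / batch_n
    st <- adam$state[[i]]
    st$mW <- b1 * st$mW + (1 - b1) * gW
    st$vW <- b2 * st$vW + (1 - b2) * gW^2
    st$mb <- b1 * st$mb + (1 - b1) * gb
    st$vb <- b2 * st$vb + (1 - b2) * gb^2
    model$layers[[i]]$W <- model$layers[[i]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + adam$eps)
    model$layers[[i]]$b <- model$layers[[i]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + adam$eps)
    adam$state[[i]] <- st
  }
  adam$model <- model
  adam
}
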