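## A compact convolutional network engine in base R.  Convolutions are
## expressed as BLAS matrix products via im2col gathers with precomputed
## index tables; backpropagation is implemented for every layer, including
## the gradient with respect to the input image (required by the
## gradient-based attribution stage).  Arrays are (N, H, W, C), column-major,
## so the batch dimension varies fastest.

#' CNN configuration
#'
#' Defaults follow the package's reference architecture for pathway-PC
#' images: four convolution blocks (conv 3x3 -> batch norm -> ReLU -> max
#' pool), a flatten, one dense block with batch norm, ReLU and dropout, and
#' a softmax output.  The pooling schedule halves the pathway axis at every
#' block and the narrow (omics x PC) axis only once, respecting the tall,
#' thin image geometry.
#'
#' @param filters integer vector, convolution filters per block.
#' @param kernel convolution kernel: a scalar (square), a `c(height, width)`
#'   pair, or a list of such per block.  A height-1 first-block kernel keeps
#'   feature extraction within a pathway row, which suits the image's
#'   unordered row set.
#' @param pool list of `c(height, width)` pool sizes, one per block.
#' @param dense width of the fully connected layer.
#' @param dropout dropout rate on the dense block (default 0.3).
#' @param augment_sd standard deviation of Gaussian noise added to training
#'   images each step (default 0.05, on the [0, 1] image scale; 0 disables).
#'   Input-noise augmentation discourages memorization of individual cells,
#'   which matters when informative cells are sparse and samples few.
#' @param weight_decay decoupled (AdamW-style) weight decay applied to
#'   convolution and dense weight matrices (default 1e-4; 0 disables).
#' @param mixup_alpha Beta-distribution parameter for mixup training
#'   (default 0 = off).  Each batch is blended with a shuffled copy of
#'   itself (one `Beta(alpha, alpha)` coefficient per batch) and the loss
#'   mixes both label sets; this pushes the network toward linear behaviour
#'   between samples, a strong regularizer when the discriminative signal
#'   is itself linear and sparse.
#' @param lr Adam learning rate.
#' @param epochs training epochs (default 100).
#' @param batch_size minibatch size (default 32).
#' @param validation_split fraction of the training data held out to monitor
#'   validation accuracy (default 0.2); best-validation weights are kept.
#' @param seed integer seed governing initialization, shuffling and dropout.
#' @return list of class `cnn_config`.
#' @export
cnn_config <- function(filters = c(16L, 32L, 32L, 64L), kernel = 3L,
                       pool = list(c(2L, 2L), c(2L, 1L), c(2L, 1L), c(2L, 1L)),
                       dense = 64L, dropout = 0.3, augment_sd = 0.05,
                       weight_decay = 1e-4, mixup_alpha = 0, lr = 1e-3,
                       epochs = 100L, batch_size = 32L,
                       validation_split = 0.2, seed = 1L) {
  stopifnot(length(filters) == length(pool), all(unlist(kernel) >= 1L),
            dropout >= 0, dropout < 1, augment_sd >= 0, weight_decay >= 0,
            mixup_alpha >= 0, lr > 0, epochs >= 1L, batch_size >= 1L,
            validation_split >= 0, validation_split < 1)
  if (is.list(kernel)) stopifnot(length(kernel) == length(filters))
  structure(list(filters = as.integer(filters),
                 kernel = if (is.list(kernel)) lapply(kernel, as.integer)
                          else as.integer(kernel),
                 pool = lapply(pool, as.integer), dense = as.integer(dense),
                 dropout = dropout, augment_sd = augment_sd,
                 weight_decay = weight_decay, mixup_alpha = mixup_alpha,
                 lr = lr,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 validation_split = validation_split, seed = as.integer(seed)),
            class = "cnn_config")
}

## ---- geometry helpers -----------------------------------------------------

## im2col geometry for 'same' padding, stride 1.  `idx` is an (H*W) x K
## table: row j holds the K = k*k*C linear indices (into the zero-padded
## (Hp, Wp, C) volume) of output position j's receptive field.  With the
## batch dimension stored fastest, gathering `Xp[, as.vector(idx)]` and
## reshaping to (N*H*W, K) needs no transposes at all.
im2col_index <- function(H, W, C, k) {
  k <- rep_len(as.integer(k), 2L)              # c(kh, kw); scalar = square
  pad_h <- (k[1L] - 1L) %/% 2L; pad_w <- (k[2L] - 1L) %/% 2L
  Hp <- H + 2L * pad_h; Wp <- W + 2L * pad_w
  off <- as.vector(outer(seq_len(k[1L]), seq_len(k[2L]),
                         function(i, j) (i - 1L) + (j - 1L) * Hp))
  off <- as.vector(outer(off, (seq_len(C) - 1L) * Hp * Wp, "+"))
  corner <- as.vector(outer(seq_len(H), seq_len(W),
                            function(h, w) (h - 1L) + (w - 1L) * Hp)) + 1L
  idx <- outer(corner, off, "+")   # (H*W) x K
  storage.mode(idx) <- "integer"
  list(idx = idx, pad_h = pad_h, pad_w = pad_w, Hp = Hp, Wp = Wp,
       P = Hp * Wp * C)
}

pad_input <- function(x, pad_h, pad_w) {
  if (pad_h == 0L && pad_w == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1L], d[2L] + 2L * pad_h, d[3L] + 2L * pad_w, d[4L]))
  xp[, (pad_h + 1L):(pad_h + d[2L]), (pad_w + 1L):(pad_w + d[3L]), ] <- x
  xp
}

## ---- layer forward/backward ----------------------------------------------

conv_forward <- function(x, W, b, geom, H, W_out_w, need_cache = TRUE,
                         cache_A = TRUE) {
  d <- dim(x)                       # N, H, W, C
  N <- d[1L]; HW <- H * W_out_w
  xp <- pad_input(x, geom$pad_h, geom$pad_w)
  dim(xp) <- c(N, length(xp) / N)
  A <- xp[, as.vector(geom$idx), drop = FALSE]   # N x (HW*K)
  K <- ncol(geom$idx)
  dim(A) <- c(N * HW, K)            # rows: (n, j) with n fastest
  out <- A %*% W                    # (N*HW) x F
  out <- out + rep(b, each = N * HW)
  Fn <- ncol(W)
  dim(out) <- c(N, H, W_out_w, Fn)
  list(out = out,
       cache = if (need_cache) list(A = if (cache_A) A, N = N, H = H,
                                    Wd = W_out_w, C = d[4L],
                                    Hin = d[2L], Win = d[3L]) else NULL)
}

conv_backward <- function(dout, W, geom, cache, need_dx = TRUE, need_dw = TRUE) {
  N <- cache$N; HW <- cache$H * cache$Wd
  Fn <- ncol(W)
  dm <- dout
  dim(dm) <- c(N * HW, Fn)
  res <- list()
  if (need_dw) {
    res$dW <- crossprod(cache$A, dm)
    res$db <- colSums(dm)
  }
  if (need_dx) {
    dA <- tcrossprod(dm, W)          # (N*HW) x K
    dim(dA) <- c(N, length(dA) / N)  # columns (j, k), j fastest: matches idx
    dXp <- col2im_cpp(dA, as.vector(geom$idx), geom$P)
    dim(dXp) <- c(N, geom$Hp, geom$Wp, cache$C)
    res$dx <- dXp[, (geom$pad_h + 1L):(geom$pad_h + cache$Hin),
                  (geom$pad_w + 1L):(geom$pad_w + cache$Win), ,
                  drop = FALSE]
  }
  res
}

pool_forward <- function(x, ph, pw) {
  d <- dim(x)
  r <- maxpool_forward_cpp(x, d[1L], d[2L], d[3L], d[4L], ph, pw)
  list(out = r$out, cache = list(code = r$code, dim_in = d, ph = ph, pw = pw))
}

pool_backward <- function(dout, cache) {
  d <- cache$dim_in
  maxpool_backward_cpp(dout, cache$code, d[1L], d[2L], d[3L], d[4L],
                       cache$ph, cache$pw)
}

## Batch norm over all but the channel (last) axis.  `x` may be a 4-D array
## or an (N, D) matrix (dense case, channel = unit).  The compiled kernels
## fuse the statistics and normalization passes; the backward pass
## recomputes xhat from the cached input instead of storing it.
bn_forward <- function(x, p, training, eps = 1e-5, momentum = 0.9) {
  d <- dim(x)
  C <- d[length(d)]
  xm <- x; dim(xm) <- c(length(x) / C, C)
  if (training) {
    r <- bn_train_forward_cpp(xm, p$gamma, p$beta, eps)
    p$running_mean <- momentum * p$running_mean + (1 - momentum) * r$mu
    p$running_var <- momentum * p$running_var + (1 - momentum) * r$var
    y <- r$y
    dim(y) <- d
    return(list(out = y, p = p,
                cache = list(x = xm, mu = r$mu, ivar = r$ivar, d = d)))
  }
  ivar <- 1 / sqrt(p$running_var + eps)
  scale <- p$gamma * ivar
  y <- bn_eval_forward_cpp(xm, scale, p$beta - p$running_mean * scale)
  dim(y) <- d
  list(out = y, p = p, cache = list(ivar = ivar, d = d, eval = TRUE))
}

bn_backward <- function(dout, p, cache) {
  d <- cache$d
  C <- d[length(d)]
  dy <- dout; dim(dy) <- c(length(dout) / C, C)
  if (isTRUE(cache$eval)) {
    ## inference mode (input-gradient path): affine per channel
    dx <- bn_eval_forward_cpp(dy, p$gamma * cache$ivar, numeric(C))
    dim(dx) <- d
    return(list(dx = dx))
  }
  r <- bn_backward_cpp(dy, cache$x, cache$mu, cache$ivar, p$gamma)
  dx <- r$dx
  dim(dx) <- d
  list(dx = dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

## ---- model construction ---------------------------------------------------

#' Build an untrained CNN for a given input shape
#'
#' Validates the pooling schedule against the input geometry (a pool that
#' would collapse a spatial dimension to zero raises an error naming the
#' offending block), initializes all parameters (He-normal weights,
#' unit-gamma batch norm) from the config seed, and returns the model
#' skeleton.
#'
#' @param config a [cnn_config()].
#' @param input_shape `c(height, width)` of the input images (channels = 1).
#' @param n_classes number of output classes (default 2).
#' @return object of class `cnn_model` (untrained).
#' @export
build_cnn <- function(config, input_shape, n_classes = 2L) {
  stopifnot(inherits(config, "cnn_config"), length(input_shape) == 2L)
  H <- input_shape[1L]; W <- input_shape[2L]; C <- 1L
  kern <- function(i) {
    k <- if (is.list(config$kernel)) config$kernel[[i]] else config$kernel
    rep_len(as.integer(k), 2L)
  }
  plan <- list()
  for (i in seq_along(config$filters)) {
    geom <- im2col_index(H, W, C, kern(i))
    plan[[length(plan) + 1L]] <- list(type = "conv", idx = i, geom = geom,
                                      H = H, W = W, C_in = C,
                                      F_out = config$filters[i],
                                      kernel = kern(i))
    C <- config$filters[i]
    plan[[length(plan) + 1L]] <- list(type = "bn", channels = C)
    plan[[length(plan) + 1L]] <- list(type = "relu")
    pp <- config$pool[[i]]
    Ho <- H %/% pp[1L]; Wo <- W %/% pp[2L]
    if (Ho < 1L || Wo < 1L) {
      stop(sprintf("pooling %dx%d in block %d collapses the %dx%d feature map to zero",
                   pp[1L], pp[2L], i, H, W), call. = FALSE)
    }
    plan[[length(plan) + 1L]] <- list(type = "pool", ph = pp[1L], pw = pp[2L])
    H <- Ho; W <- Wo
  }
  flat_dim <- H * W * C
  plan[[length(plan) + 1L]] <- list(type = "flatten", H = H, W = W, C = C)
  plan[[length(plan) + 1L]] <- list(type = "dense", d_in = flat_dim,
                                    d_out = config$dense)
  plan[[length(plan) + 1L]] <- list(type = "bn", channels = config$dense)
  plan[[length(plan) + 1L]] <- list(type = "relu")
  if (config$dropout > 0) {
    plan[[length(plan) + 1L]] <- list(type = "dropout", rate = config$dropout)
  }
  plan[[length(plan) + 1L]] <- list(type = "dense", d_in = config$dense,
                                    d_out = as.integer(n_classes))

  params <- with_seed(config$seed, {
    lapply(plan, function(ly) {
      switch(ly$type,
        conv = {
          K <- ly$C_in * prod(ly$kernel)
          list(W = matrix(stats::rnorm(K * ly$F_out, 0, sqrt(2 / K)), K, ly$F_out),
               b = numeric(ly$F_out))
        },
        dense = {
          list(W = matrix(stats::rnorm(ly$d_in * ly$d_out, 0, sqrt(2 / ly$d_in)),
                          ly$d_in, ly$d_out),
               b = numeric(ly$d_out))
        },
        bn = list(gamma = rep(1, ly$channels), beta = numeric(ly$channels),
                  running_mean = numeric(ly$channels),
                  running_var = rep(1, ly$channels)),
        NULL)
    })
  })
  n_par <- sum(vapply(params, function(p) if (is.null(p)) 0L else
    sum(vapply(p, length, integer(1))), integer(1)))
  pcn_log("built CNN with ", n_par, " parameters, output dim ", n_classes)
  structure(list(plan = plan, params = params, config = config,
                 input_shape = as.integer(input_shape),
                 n_classes = as.integer(n_classes), n_parameters = n_par,
                 trained = FALSE, history = NULL, classes = NULL),
            class = "cnn_model")
}

## Forward pass.  x: (N, H, W) or (N, H, W, 1) array.  Returns probs and,
## when `keep_cache`, everything backward needs.
cnn_forward <- function(model, x, training = FALSE, keep_cache = FALSE,
                        params = model$params, cache_conv_A = TRUE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  caches <- if (keep_cache) vector("list", length(model$plan))
  cur <- x
  for (i in seq_along(model$plan)) {
    ly <- model$plan[[i]]
    p <- params[[i]]
    cur <- switch(ly$type,
      conv = {
        r <- conv_forward(cur, p$W, p$b, ly$geom, ly$H, ly$W,
                          need_cache = keep_cache, cache_A = cache_conv_A)
        if (keep_cache) caches[[i]] <- r$cache
        r$out
      },
      bn = {
        r <- bn_forward(cur, p, training)
        if (training) params[[i]] <- r$p
        if (keep_cache) caches[[i]] <- r$cache
        r$out
      },
      relu = {
        y <- relu_forward_cpp(cur)
        if (keep_cache) caches[[i]] <- y
        y
      },
      pool = {
        r <- pool_forward(cur, ly$ph, ly$pw)
        if (keep_cache) caches[[i]] <- r$cache
        r$out
      },
      flatten = {
        d <- dim(cur)
        if (keep_cache) caches[[i]] <- d
        dim(cur) <- c(d[1L], prod(d[-1L]))
        cur
      },
      dense = {
        if (keep_cache) caches[[i]] <- cur
        cur %*% p$W + rep(p$b, each = nrow(cur))
      },
      dropout = {
        if (training) {
          mask <- matrix(stats::runif(length(cur)) >= ly$rate,
                         nrow(cur)) / (1 - ly$rate)
          if (keep_cache) caches[[i]] <- mask
          cur * mask
        } else {
          cur   # eval mode: identity; cache slot stays NULL
        }
      })
  }
  logits <- cur
  mx <- logits[, 1L]
  for (j in seq_len(ncol(logits))[-1L]) mx <- pmax(mx, logits[, j])
  e <- exp(logits - mx)
  probs <- e / rowSums(e)
  list(probs = probs, logits = logits, caches = caches, params = params)
}

## Backward pass from dlogits.  Returns parameter gradients (unless
## `input_grad_only`) and the gradient w.r.t. the input image.
cnn_backward <- function(model, fw, dlogits, params = fw$params,
                         input_grad_only = FALSE) {
  grads <- vector("list", length(model$plan))
  cur <- dlogits
  for (i in rev(seq_along(model$plan))) {
    ly <- model$plan[[i]]
    p <- params[[i]]
    cache <- fw$caches[[i]]
    cur <- switch(ly$type,
      dense = {
        if (!input_grad_only) {
          grads[[i]] <- list(W = crossprod(cache, cur), b = colSums(cur))
        }
        cur %*% t(p$W)
      },
      dropout = {
        if (is.null(cache)) cur else cur * cache
      },
      relu = relu_backward_cpp(cur, cache),
      bn = {
        r <- bn_backward(cur, p, cache)
        if (!input_grad_only && !isTRUE(cache$eval)) {
          grads[[i]] <- list(gamma = r$dgamma, beta = r$dbeta)
        }
        r$dx
      },
      flatten = {
        dim(cur) <- cache
        cur
      },
      pool = pool_backward(cur, cache),
      conv = {
        r <- conv_backward(cur, p$W, ly$geom, cache,
                           need_dx = TRUE, need_dw = !input_grad_only)
        if (!input_grad_only) grads[[i]] <- list(W = r$dW, b = r$db)
        r$dx
      })
  }
  list(grads = grads, dx = cur)
}

## Gradient of the target-class output (softmax probability, or raw logit)
## w.r.t. the input, in inference mode (running batch-norm statistics, no
## dropout).  Large batches are processed in chunks to bound the transient
## im2col memory.
cnn_input_gradient <- function(model, x, target_class, chunk = 64L,
                               output = c("prob", "logit")) {
  output <- match.arg(output)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  N_all <- dim(x)[1L]
  tc_all <- rep_len(target_class, N_all)
  out <- array(0, dim(x)[1:3])
  for (start in seq(1L, N_all, by = chunk)) {
    ix <- start:min(start + chunk - 1L, N_all)
    xb <- x[ix, , , , drop = FALSE]
    fw <- cnn_forward(model, xb, training = FALSE, keep_cache = TRUE,
                      cache_conv_A = FALSE)
    p <- fw$probs
    N <- nrow(p)
    tc <- tc_all[ix]
    if (output == "prob") {
      ## d p_t / d logit_j = p_t (1[j = t] - p_j)
      pt <- p[cbind(seq_len(N), tc)]
      dlog <- -p * pt
      dlog[cbind(seq_len(N), tc)] <- dlog[cbind(seq_len(N), tc)] + pt
    } else {
      dlog <- matrix(0, N, ncol(p))
      dlog[cbind(seq_len(N), tc)] <- 1
    }
    bw <- cnn_backward(model, fw, dlog, input_grad_only = TRUE)
    dx <- bw$dx
    dim(dx) <- dim(dx)[1:3]
    out[ix, , ] <- dx
  }
  out
}

## ---- training -------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) {
    if (is.null(p)) return(NULL)
    lapply(p[intersect(names(p), c("W", "b", "gamma", "beta"))],
           function(v) list(m = v * 0, v = v * 0))
  })
}

adam_step <- function(params, grads, state, lr, t, weight_decay = 0,
                      b1 = 0.9, b2 = 0.999, eps = 1e-7) {
  for (i in seq_along(params)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (nm in names(g)) {
      st <- state[[i]][[nm]]
      st$m <- b1 * st$m + (1 - b1) * g[[nm]]
      st$v <- b2 * st$v + (1 - b2) * g[[nm]]^2
      mhat <- st$m / (1 - b1^t)
      vhat <- st$v / (1 - b2^t)
      upd <- lr * mhat / (sqrt(vhat) + eps)
      if (weight_decay > 0 && nm == "W") {
        upd <- upd + lr * weight_decay * params[[i]][[nm]]  # decoupled decay
      }
      params[[i]][[nm]] <- params[[i]][[nm]] - upd
      state[[i]][[nm]] <- st
    }
  }
  list(params = params, state = state)
}

#' Train a CNN on an image stack
#'
#' Minibatch Adam with cross-entropy loss for `epochs` epochs.  A stratified
#' `validation_split` fraction is held out to monitor validation accuracy;
#' the weights achieving the best validation accuracy are retained (the
#' final-epoch weights are kept when the split is empty).  A non-finite
#' loss aborts with a diagnostic.
#'
#' @param model an untrained [build_cnn()] model, or `NULL` to build one
#'   from `config` and the data shape.
#' @param x an `image_stack`, or a numeric array `(N, H, W)`.
#' @param y class labels (factor or character), aligned with `x`.
#' @param config a [cnn_config()] (used when `model` is `NULL`; otherwise
#'   the model's own config is used).
#' @return a trained `cnn_model` with `history` (per-epoch loss/accuracy)
#'   and `classes` (label level order defining the softmax units).
#' @export
train_cnn <- function(model = NULL, x, y, config = cnn_config()) {
  if (inherits(x, "image_stack")) x <- x$images
  stopifnot(length(dim(x)) == 3L)
  y <- factor(y)
  if (nlevels(y) < 2L) stop("training data must contain both classes", call. = FALSE)
  if (is.null(model)) model <- build_cnn(config, dim(x)[2:3], nlevels(y))
  config <- model$config
  yi <- as.integer(y)
  N <- dim(x)[1L]

  with_seed(derive_seed(config$seed, "train"), {
    ## stratified validation split
    n_val <- round(config$validation_split * N)
    val_idx <- integer(0)
    if (n_val >= 2L) {
      val_idx <- unlist(lapply(split(seq_len(N), yi), function(ix) {
        k <- max(1L, round(config$validation_split * length(ix)))
        sample(ix, min(k, length(ix) - 1L))
      }), use.names = FALSE)
    }
    tr_idx <- setdiff(seq_len(N), val_idx)
    if (length(unique(yi[tr_idx])) < 2L) {
      stop("both classes must be present in the training split", call. = FALSE)
    }
    params <- model$params
    state <- adam_init(params)
    best <- list(acc = -Inf, params = params)
    hist <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                       acc = NA_real_, val_loss = NA_real_, val_acc = NA_real_)
    t_step <- 0L
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      ep_loss <- 0; ep_correct <- 0L
      for (start in seq(1L, length(ord), by = config$batch_size)) {
        bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
        xb <- x[bi, , , drop = FALSE]
        if (config$augment_sd > 0) {
          xb <- xb + array(stats::rnorm(length(xb), 0, config$augment_sd),
                           dim(xb))
        }
        nb <- length(bi)
        yb <- yi[bi]
        lam <- 1; y2 <- yb
        if ((config$mixup_alpha %||% 0) > 0 && nb > 1L) {
          lam <- stats::rbeta(1, config$mixup_alpha, config$mixup_alpha)
          perm <- sample.int(nb)
          xb <- lam * xb + (1 - lam) * xb[perm, , , drop = FALSE]
          y2 <- yb[perm]
        }
        fw <- cnn_forward(model, xb, training = TRUE, keep_cache = TRUE,
                          params = params)
        params <- fw$params          # running BN stats updated
        pt1 <- fw$probs[cbind(seq_len(nb), yb)]
        pt2 <- fw$probs[cbind(seq_len(nb), y2)]
        loss <- -sum(lam * log(pmax(pt1, 1e-12)) +
                       (1 - lam) * log(pmax(pt2, 1e-12)))
        if (!is.finite(loss)) {
          stop(sprintf("non-finite loss at epoch %d (exploding gradients?); lower the learning rate", ep),
               call. = FALSE)
        }
        ep_loss <- ep_loss + loss
        ep_correct <- ep_correct + sum(max.col(fw$probs) == yb)
        dlog <- fw$probs
        dlog[cbind(seq_len(nb), yb)] <- dlog[cbind(seq_len(nb), yb)] - lam
        dlog[cbind(seq_len(nb), y2)] <- dlog[cbind(seq_len(nb), y2)] - (1 - lam)
        dlog <- dlog / nb
        bw <- cnn_backward(model, fw, dlog, params = params)
        t_step <- t_step + 1L
        upd <- adam_step(params, bw$grads, state, config$lr, t_step,
                         weight_decay = config$weight_decay %||% 0)
        params <- upd$params; state <- upd$state
      }
      hist$loss[ep] <- ep_loss / length(ord)
      hist$acc[ep] <- ep_correct / length(ord)
      if (length(val_idx)) {
        fv <- cnn_forward(model, x[val_idx, , , drop = FALSE],
                          training = FALSE, params = params)
        ptv <- fv$probs[cbind(seq_along(val_idx), yi[val_idx])]
        hist$val_loss[ep] <- -mean(log(pmax(ptv, 1e-12)))
        hist$val_acc[ep] <- mean(max.col(fv$probs) == yi[val_idx])
        if (hist$val_acc[ep] > best$acc) {
          best <- list(acc = hist$val_acc[ep], params = params)
        }
      } else {
        best <- list(acc = hist$acc[ep], params = params)
      }
    }
    model$params <- best$params
    model$history <- hist
    model$classes <- levels(y)
    model$trained <- TRUE
    model
  })
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: input %dx%d, %d classes, %d parameters, %s>\n",
              x$input_shape[1L], x$input_shape[2L], x$n_classes,
              x$n_parameters, if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' @export
summary.cnn_model <- function(object, ...) {
  print(object)
  for (i in seq_along(object$plan)) {
    ly <- object$plan[[i]]
    cat(sprintf("  %2d %-8s %s\n", i, ly$type, switch(ly$type,
      conv = sprintf("%dx%d, %d -> %d channels", ly$kernel[1L], ly$kernel[2L],
                     ly$C_in, ly$F_out),
      pool = sprintf("%dx%d", ly$ph, ly$pw),
      dense = sprintf("%d -> %d", ly$d_in, ly$d_out),
      bn = sprintf("%d channels", ly$channels),
      dropout = sprintf("rate %.2f", ly$rate),
      "")))
  }
  if (object$trained) {
    h <- object$history
    cat(sprintf("  final epoch: loss %.4f acc %.3f val_acc %s\n",
                h$loss[nrow(h)], h$acc[nrow(h)],
                format(h$val_acc[nrow(h)], digits = 3)))
  }
  invisible(object)
}

#' Predict class probabilities or labels from a trained CNN
#'
#' @param object a trained `cnn_model`.
#' @param newdata an `image_stack` or `(N, H, W)` array.
#' @param type `"prob"` (matrix of class probabilities, columns in
#'   `object$classes` order) or `"class"`.
#' @param ... unused.
#' @export
predict.cnn_model <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (!object$trained) stop("model is not trained", call. = FALSE)
  if (inherits(newdata, "image_stack")) newdata <- newdata$images
  if (length(dim(newdata)) == 2L) {
    newdata <- array(newdata, c(1L, dim(newdata)))
  }
  p <- cnn_forward(object, newdata, training = FALSE)$probs
  colnames(p) <- object$classes
  if (type == "prob") p else factor(object$classes[max.col(p)],
                                    levels = object$classes)
}

#' Plot the training history of a CNN
#' @param x a trained `cnn_model`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cnn_model <- function(x, ...) {
  if (!x$trained) stop("model is not trained", call. = FALSE)
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$acc, h$val_acc), type = "l", lty = 1,
                    col = c("steelblue", "firebrick"), xlab = "epoch",
                    ylab = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
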