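# A compact convolutional-network engine on base-R arrays.
#
# Tensors are 4-D arrays [N, H, W, C]. Convolution is im2col + matrix
# multiplication; training is softmax cross-entropy with Adam. The engine
# supports exactly the layer vocabulary the package's classifiers need:
# conv (stride/padding), batch norm, ReLU, identity residual blocks,
# dropout, global average pooling and dense, and exposes per-layer input
# gradients so Grad-CAM can read the gradient at the last convolutional
# stage.

nn_init_conv <- function(kh, kw, cin, cout, stride = 1, pad = 1) {
  fan_in <- kh * kw * cin
  list(type = "conv",
       W = array(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)),
                 c(kh, kw, cin, cout)),
       b = numeric(cout),
       stride = stride, pad = pad)
}

nn_init_bn <- function(c) {
  list(type = "bn", gamma = rep(1, c), beta = numeric(c),
       run_mean = numeric(c), run_var = rep(1, c), momentum = 0.9,
       eps = 1e-5)
}

nn_init_dense <- function(cin, cout) {
  list(type = "dense",
       W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

nn_init_resblock <- function(c) {
  list(type = "resblock",
       conv1 = nn_init_conv(3, 3, c, c), bn1 = nn_init_bn(c),
       conv2 = nn_init_conv(3, 3, c, c), bn2 = nn_init_bn(c))
}

pad_nhwc <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1], d[2] + 2 * p, d[3] + 2 * p, d[4]))
  xp[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ] <- x
  xp
}

conv_out_dim <- function(h, k, s, p) (h + 2 * p - k) %/% s + 1L

im2col <- function(xp, kh, kw, stride, ho, wo) {
  d <- dim(xp)  # N, Hp, Wp, C
  n <- d[1]; cin <- d[4]
  cols <- matrix(0, n * ho * wo, kh * kw * cin)
  k <- 0L
  for (ci in seq_len(cin)) {
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        k <- k + 1L
        hseq <- seq.int(ki, by = stride, length.out = ho)
        wseq <- seq.int(kj, by = stride, length.out = wo)
        cols[, k] <- xp[, hseq, wseq, ci]
      }
    }
  }
  cols
}

col2im <- function(dcols, dims_p, kh, kw, stride, ho, wo) {
  n <- dims_p[1]; cin <- dims_p[4]
  dxp <- array(0, dims_p)
  k <- 0L
  for (ci in seq_len(cin)) {
    for (kj in seq_len(kw)) {
      for (ki in seq_len(kh)) {
        k <- k + 1L
        hseq <- seq.int(ki, by = stride, length.out = ho)
        wseq <- seq.int(kj, by = stride, length.out = wo)
        cur <- array(dxp[, hseq, wseq, ci, drop = FALSE], c(n, ho, wo))
        dxp[, hseq, wseq, ci] <- cur + array(dcols[, k], c(n, ho, wo))
      }
    }
  }
  dxp
}

conv_forward <- function(layer, x) {
  d <- dim(x)
  kh <- dim(layer$W)[1]; kw <- dim(layer$W)[2]; cout <- dim(layer$W)[4]
  ho <- conv_out_dim(d[2], kh, layer$stride, layer$pad)
  wo <- conv_out_dim(d[3], kw, layer$stride, layer$pad)
  xp <- pad_nhwc(x, layer$pad)
  cols <- im2col(xp, kh, kw, layer$stride, ho, wo)
  wmat <- matrix(layer$W, ncol = cout)
  ymat <- cols %*% wmat
  ymat <- sweep(ymat, 2, layer$b, "+")
  list(out = array(ymat, c(d[1], ho, wo, cout)),
       cache = list(cols = cols, dims_p = dim(xp), dims_x = d,
                    ho = ho, wo = wo))
}

conv_backward <- function(layer, cache, dout) {
  d <- dim(dout)
  cout <- d[4]
  dmat <- matrix(dout, ncol = cout)
  grads <- list(W = array(crossprod(cache$cols, dmat), dim(layer$W)),
                b = colSums(dmat))
  dcols <- dmat %*% t(matrix(layer$W, ncol = cout))
  dxp <- col2im(dcols, cache$dims_p, dim(layer$W)[1], dim(layer$W)[2],
                layer$stride, cache$ho, cache$wo)
  p <- layer$pad
  dx <- if (p > 0) {
    dxp[, (p + 1):(p + cache$dims_x[2]), (p + 1):(p + cache$dims_x[3]), ,
        drop = FALSE]
  } else dxp
  list(grads = grads, dx = array(dx, cache$dims_x))
}

bn_forward <- function(layer, x, train) {
  d <- dim(x)
  cc <- d[4]
  m <- matrix(x, ncol = cc)
  if (train) {
    mu <- colMeans(m)
    vr <- colMeans(sweep(m, 2, mu)^2)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * vr
  } else {
    mu <- layer$run_mean
    vr <- layer$run_var
  }
  inv <- 1 / sqrt(vr + layer$eps)
  xhat <- sweep(sweep(m, 2, mu), 2, inv, "*")
  y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(out = array(y, d), layer = layer,
       cache = list(xhat = xhat, inv = inv, dims = d, train = train))
}

bn_backward <- function(layer, cache, dout) {
  d <- cache$dims
  nm <- prod(d[-4])
  dy <- matrix(dout, ncol = d[4])
  dgamma <- colSums(dy * cache$xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, layer$gamma, "*")
  dx <- if (cache$train) {
    # batch statistics: mean/variance terms propagate
    sweep(dxhat - matrix(colSums(dxhat) / nm, nm, d[4], byrow = TRUE) -
            cache$xhat * matrix(colSums(dxhat * cache$xhat) / nm, nm,
                                d[4], byrow = TRUE),
          2, cache$inv, "*")
  } else {
    # running statistics are constants
    sweep(dxhat, 2, cache$inv, "*")
  }
  list(grads = list(gamma = dgamma, beta = dbeta), dx = array(dx, d))
}

gap_forward <- function(x) {
  d <- dim(x)
  xm <- array(x, c(d[1], d[2] * d[3], d[4]))
  out <- apply(xm, 3, rowMeans)
  if (d[1] == 1L) out <- matrix(out, 1)
  list(out = out, cache = d)
}

gap_backward <- function(cache, dout) {
  d <- cache
  hw <- d[2] * d[3]
  dx <- array(0, c(d[1], hw, d[4]))
  for (ci in seq_len(d[4])) dx[, , ci] <- dout[, ci] / hw
  array(dx, d)
}

# Forward pass. Returns the output and per-layer caches (train = TRUE uses
# batch statistics and live dropout; the returned model carries updated
# running statistics).
nn_forward <- function(model, x, train = FALSE) {
  caches <- vector("list", length(model$layers))
  outs <- vector("list", length(model$layers))
  for (li in seq_along(model$layers)) {
    layer <- model$layers[[li]]
    res <- switch(layer$type,
      conv = conv_forward(layer, x),
      bn = bn_forward(layer, x, train),
      relu = list(out = pmax(x, 0), cache = x > 0),
      dropout = {
        if (train && layer$p > 0) {
          mask <- array(stats::rbinom(length(x), 1, 1 - layer$p),
                        dim(x)) / (1 - layer$p)
          list(out = x * mask, cache = mask)
        } else list(out = x, cache = NULL)
      },
      gap = gap_forward(x),
      dense = list(out = sweep(x %*% layer$W, 2, layer$b, "+"),
                   cache = x),
      resblock = {
        r1 <- conv_forward(layer$conv1, x)
        b1 <- bn_forward(layer$bn1, r1$out, train)
        layer$bn1 <- b1$layer
        a1 <- pmax(b1$out, 0)
        r2 <- conv_forward(layer$conv2, a1)
        b2 <- bn_forward(layer$bn2, r2$out, train)
        layer$bn2 <- b2$layer
        pre <- b2$out + x
        list(out = pmax(pre, 0), layer = layer,
             cache = list(c1 = r1$cache, b1 = b1$cache, m1 = b1$out > 0,
                          c2 = r2$cache, b2 = b2$cache, mo = pre > 0))
      },
      stop("unknown layer type: ", layer$type)
    )
    if (!is.null(res$layer)) model$layers[[li]] <- res$layer
    caches[[li]] <- res$cache
    outs[[li]] <- res$out
    x <- res$out
  }
  list(out = x, caches = caches, outs = outs, model = model)
}

# Backward pass from dout (gradient at the network output). Returns
# parameter gradients mirroring the layer structure and the gradient of
# the input of every layer (dx_in[[li]]), so callers can read activation
# gradients at any depth.
nn_backward <- function(model, caches, dout) {
  nl <- length(model$layers)
  grads <- vector("list", nl)
  dx_in <- vector("list", nl)
  dx <- dout
  for (li in rev(seq_len(nl))) {
    layer <- model$layers[[li]]
    cache <- caches[[li]]
    res <- switch(layer$type,
      conv = conv_backward(layer, cache, dx),
      bn = bn_backward(layer, cache, dx),
      relu = list(grads = NULL, dx = dx * cache),
      dropout = list(grads = NULL,
                     dx = if (is.null(cache)) dx else dx * cache),
      gap = list(grads = NULL, dx = gap_backward(cache, dx)),
      dense = list(grads = list(W = crossprod(cache, dx),
                                b = colSums(dx)),
                   dx = dx %*% t(layer$W)),
      resblock = {
        dpre <- dx * cache$mo
        b2 <- bn_backward(layer$bn2, cache$b2, dpre)
        c2 <- conv_backward(layer$conv2, cache$c2, b2$dx)
        da1 <- c2$dx * cache$m1
        b1 <- bn_backward(layer$bn1, cache$b1, da1)
        c1 <- conv_backward(layer$conv1, cache$c1, b1$dx)
        list(grads = list(conv1 = c1$grads, bn1 = b1$grads,
                          conv2 = c2$grads, bn2 = b2$grads),
             dx = c1$dx + dpre)
      }
    )
    grads[li] <- list(res$grads)  # keep NULL placeholders in place
    dx <- res$dx
    dx_in[[li]] <- dx
  }
  list(grads = grads, dx_in = dx_in)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Cross-entropy loss and gradient. y: integer class labels 1..K.
softmax_ce <- function(logits, y, class_weights = NULL) {
  p <- softmax(logits)
  n <- nrow(p)
  w <- if (is.null(class_weights)) rep(1, n) else class_weights[y]
  idx <- cbind(seq_len(n), y)
  loss <- -sum(w * log(pmax(p[idx], 1e-12))) / sum(w)
  dlogits <- p * w
  dlogits[idx] <- dlogits[idx] - w
  list(loss = loss, dlogits = dlogits / sum(w))
}

# Flatten/unflatten parameter trees for the Adam update.
nn_param_names <- c("W", "b", "gamma", "beta")

walk_params <- function(layers, grads, fn) {
  for (li in seq_along(layers)) {
    if (layers[[li]]$type == "resblock") {
      for (sub in c("conv1", "bn1", "conv2", "bn2")) {
        for (pn in nn_param_names) {
          if (!is.null(layers[[li]][[sub]][[pn]])) {
            layers[[li]][[sub]][[pn]] <- fn(
              layers[[li]][[sub]][[pn]],
              if (is.null(grads)) NULL else grads[[li]][[sub]][[pn]],
              paste0("l", li, ".", sub, ".", pn))
          }
        }
      }
    } else {
      for (pn in nn_param_names) {
        if (!is.null(layers[[li]][[pn]])) {
          layers[[li]][[pn]] <- fn(
            layers[[li]][[pn]],
            if (is.null(grads)) NULL else grads[[li]][[pn]],
            paste0("l", li, ".", pn))
        }
      }
    }
  }
  layers
}

adam_state_new <- function() new.env(parent = emptyenv())

adam_step <- function(layers, grads, st, lr, weight_decay, t) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  walk_params(layers, grads, function(p, g, name) {
    if (is.null(g)) return(p)
    # decoupled weight decay on weights only (not biases / BN params)
    if (weight_decay > 0 && grepl("\\.W$", name)) g <- g + weight_decay * p
    mkey <- paste0(name, ".m"); vkey <- paste0(name, ".v")
    m <- if (is.null(st[[mkey]])) g * 0 else st[[mkey]]
    v <- if (is.null(st[[vkey]])) g * 0 else st[[vkey]]
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    st[[mkey]] <- m
    st[[vkey]] <- v
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    p - lr * mh / (sqrt(vh) + eps)
  })
}

# One SGD epoch over shuffled minibatches; returns updated model/state and
# the mean training loss.
nn_epoch <- function(model, st, x, y, batch, lr, weight_decay,
                     class_weights, t0) {
  n <- dim(x)[1]
  ord <- sample.int(n)
  losses <- numeric(0)
  t <- t0
  for (start in seq(1, n, by = batch)) {
    sel <- ord[start:min(start + batch - 1, n)]
    if (length(sel) < 2) next  # batch norm needs >= 2 samples
    xb <- x[sel, , , , drop = FALSE]
    fw <- nn_forward(model, xb, train = TRUE)
    model <- fw$model
    l <- softmax_ce(fw$out, y[sel], class_weights)
    bw <- nn_backward(model, fw$caches, l$dlogits)
    t <- t + 1
    model$layers <- adam_step(model$layers, bw$grads, st, lr,
                              weight_decay, t)
    losses <- c(losses, l$loss)
  }
  list(model = model, t = t, loss = mean(losses))
}

# Class scores (softmax probabilities) in evaluation mode.
nn_predict <- function(model, x) {
  softmax(nn_forward(model, x, train = FALSE)$out)
}
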