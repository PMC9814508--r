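# Layer engine: initialisation, forward and backward passes.
#
# Activation storage conventions (shared with src/convops.cpp):
#   image tensors -> (N * H * W) x C matrix, sample-major rows, column-major
#                    spatial positions within a sample (row = n*H*W + w*H + h);
#   sequences     -> (N, T, F) array;
#   flat vectors  -> N x d matrix.
# A `shape` list travels with the activation: list(type = "image", H, W, C),
# list(type = "seq", T, F) or list(type = "flat", d).

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

rep_row <- function(v, n) matrix(v, nrow = n, ncol = length(v), byrow = TRUE)

# fast column-wise affine helpers (recycled vectors, no aperm/sweep)
scale_cols <- function(x, a) x * rep(a, each = nrow(x))
shift_cols <- function(x, b) x + rep(b, each = nrow(x))

# ---- initialisation ---------------------------------------------------------

# spec: one parsed layer; shape: incoming shape. Returns list(layer, shape).
init_layer <- function(spec, shape, bn_eps = 1e-3, bn_momentum = 0.9) {
  kind <- spec$kind
  layer <- list(kind = kind)
  out <- shape
  if (kind == "conv2d") {
    stopifnot(shape$type == "image")
    kh <- spec$kernel[1]; kw <- spec$kernel[2]
    sh <- spec$stride %||% c(1L, 1L)
    f <- spec$filters
    layer$kernel <- c(kh, kw); layer$stride <- as.integer(sh)
    layer$params <- list(
      W = glorot_uniform(kh * kw * shape$C, kh * kw * f,
                         c(kh * kw * shape$C, f)),
      b = numeric(f))
    out$H <- ceiling(shape$H / sh[1]); out$W <- ceiling(shape$W / sh[2])
    out$C <- f
  } else if (kind == "separable_conv2d") {
    stopifnot(shape$type == "image")
    kh <- spec$kernel[1]; kw <- spec$kernel[2]; f <- spec$filters
    layer$kernel <- c(kh, kw)
    layer$params <- list(
      Wd = glorot_uniform(kh * kw, kh * kw, c(kh * kw, shape$C)),
      bd = numeric(shape$C),
      Wp = glorot_uniform(shape$C, f, c(shape$C, f)),
      bp = numeric(f))
    out$C <- f
  } else if (kind == "batch_norm") {
    ch <- if (shape$type == "image") shape$C else shape$d
    layer$params <- list(gamma = rep(1, ch), beta = numeric(ch))
    layer$state <- list(running_mean = numeric(ch), running_var = rep(1, ch))
    layer$eps <- bn_eps; layer$momentum <- bn_momentum
  } else if (kind == "max_pool") {
    stopifnot(shape$type == "image")
    layer$pool <- as.integer(spec$pool)
    out$H <- ceiling(shape$H / spec$pool[1])
    out$W <- ceiling(shape$W / spec$pool[2])
  } else if (kind == "dropout") {
    layer$rate <- spec$rate
  } else if (kind == "dense") {
    if (shape$type != "flat") {
      stop("build error: dense layer needs a flat input, got ", shape$type,
           call. = FALSE)
    }
    layer$params <- list(
      W = glorot_uniform(shape$d, spec$units, c(shape$d, spec$units)),
      b = numeric(spec$units))
    out <- list(type = "flat", d = spec$units)
  } else if (kind == "lstm") {
    stopifnot(shape$type == "seq")
    u <- spec$units; f <- shape$F
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- 1 # forget-gate bias
    layer$units <- u
    layer$params <- list(
      Wx = glorot_uniform(f, 4 * u, c(f, 4 * u)),
      Wh = glorot_uniform(u, 4 * u, c(u, 4 * u)),
      b = b)
    out <- list(type = "flat", d = u)
  } else if (kind == "gru") {
    stopifnot(shape$type == "seq")
    u <- spec$units; f <- shape$F
    layer$units <- u
    layer$params <- list(
      Wx = glorot_uniform(f, 3 * u, c(f, 3 * u)),
      Wh = glorot_uniform(u, 3 * u, c(u, 3 * u)),
      bx = numeric(3 * u),
      bh = numeric(3 * u))
    out <- list(type = "flat", d = u)
  } else if (kind == "global_avg_pool") {
    stopifnot(shape$type == "image")
    out <- list(type = "flat", d = shape$C)
  } else if (kind == "relu") {
    # activation, no parameters
  } else {
    stop("build error: cannot initialise layer kind '", kind, "'",
         call. = FALSE)
  }
  list(layer = layer, shape = out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- forward ----------------------------------------------------------------

layer_forward <- function(layer, x, shape, training = FALSE) {
  kind <- layer$kind
  if (kind == "conv2d") {
    N <- nrow(x) / (shape$H * shape$W)
    r <- cpp_conv2d_fw(x, shape$H, shape$W, N, layer$params$W,
                       layer$params$b, layer$kernel[1], layer$kernel[2],
                       layer$stride[1], layer$stride[2])
    out <- shape
    out$H <- r$ho; out$W <- r$wo; out$C <- ncol(r$y)
    return(list(y = r$y, shape = out, cache = list(x = x, shape = shape,
                                                   N = N)))
  }
  if (kind == "separable_conv2d") {
    N <- nrow(x) / (shape$H * shape$W)
    z <- cpp_depthwise_fw(x, shape$H, shape$W, N, layer$params$Wd,
                          layer$params$bd, layer$kernel[1], layer$kernel[2])
    y <- shift_cols(z %*% layer$params$Wp, layer$params$bp)
    out <- shape; out$C <- ncol(y)
    return(list(y = y, shape = out,
                cache = list(x = x, z = z, shape = shape)))
  }
  if (kind == "batch_norm") {
    if (training) {
      r <- cpp_bn_fw(x, layer$params$gamma, layer$params$beta, layer$eps)
      cache <- list(x = x, inv_sd = as.numeric(r$inv_sd),
                    mu = as.numeric(r$mu), v = as.numeric(r$v))
      return(list(y = r$y, shape = shape, cache = cache))
    }
    inv_sd <- 1 / sqrt(layer$state$running_var + layer$eps)
    a <- layer$params$gamma * inv_sd
    b <- layer$params$beta - a * layer$state$running_mean
    return(list(y = cpp_col_affine(x, a, b), shape = shape, cache = NULL))
  }
  if (kind == "max_pool") {
    N <- nrow(x) / (shape$H * shape$W)
    r <- cpp_maxpool_fw(x, shape$H, shape$W, N, layer$pool[1], layer$pool[2])
    out <- shape; out$H <- r$ho; out$W <- r$wo
    return(list(y = r$y, shape = out,
                cache = list(argmax = r$argmax, n_in = nrow(x))))
  }
  if (kind == "dropout") {
    if (!training || layer$rate == 0) {
      return(list(y = x, shape = shape, cache = NULL))
    }
    keep <- 1 - layer$rate
    mask <- matrix((stats::runif(length(x)) < keep) / keep,
                   nrow = nrow(x))
    return(list(y = x * mask, shape = shape, cache = list(mask = mask)))
  }
  if (kind == "dense") {
    y <- x %*% layer$params$W + rep_row(layer$params$b, nrow(x))
    return(list(y = y, shape = list(type = "flat", d = ncol(y)),
                cache = list(x = x)))
  }
  if (kind == "relu") {
    y <- cpp_relu_fw(x)
    return(list(y = y, shape = shape, cache = list(y = y)))
  }
  if (kind == "global_avg_pool") {
    hw <- shape$H * shape$W
    N <- nrow(x) / hw
    y <- rowsum(x, group = rep(seq_len(N), each = hw), reorder = FALSE) / hw
    return(list(y = y, shape = list(type = "flat", d = ncol(y)),
                cache = list(hw = hw, N = N)))
  }
  if (kind == "lstm") return(lstm_forward(layer, x))
  if (kind == "gru") return(gru_forward(layer, x))
  stop("forward: unhandled layer kind '", kind, "'", call. = FALSE)
}

# ---- backward ---------------------------------------------------------------

# returns list(dx, grads); grads mirrors layer$params (NULL if none)
layer_backward <- function(layer, cache, dy, shape_in) {
  kind <- layer$kind
  if (kind == "conv2d") {
    sh <- cache$shape
    r <- cpp_conv2d_bw(cache$x, sh$H, sh$W, cache$N, layer$params$W, dy,
                       layer$kernel[1], layer$kernel[2],
                       layer$stride[1], layer$stride[2])
    return(list(dx = r$dx, grads = list(W = r$dw, b = as.numeric(r$db))))
  }
  if (kind == "separable_conv2d") {
    sh <- cache$shape
    N <- nrow(cache$x) / (sh$H * sh$W)
    dWp <- t(cache$z) %*% dy
    dbp <- colSums(dy)
    dz <- dy %*% t(layer$params$Wp)
    r <- cpp_depthwise_bw(cache$x, sh$H, sh$W, N, layer$params$Wd, dz,
                          layer$kernel[1], layer$kernel[2])
    return(list(dx = r$dx,
                grads = list(Wd = r$dw, bd = as.numeric(r$db),
                             Wp = dWp, bp = dbp)))
  }
  if (kind == "batch_norm") {
    r <- cpp_bn_bw(cache$x, dy, layer$params$gamma, cache$mu, cache$inv_sd)
    return(list(dx = r$dx, grads = list(gamma = as.numeric(r$dgamma),
                                        beta = as.numeric(r$dbeta))))
  }
  if (kind == "max_pool") {
    dx <- cpp_maxpool_bw(dy, cache$argmax, cache$n_in)
    return(list(dx = dx, grads = NULL))
  }
  if (kind == "dropout") {
    if (is.null(cache)) return(list(dx = dy, grads = NULL))
    return(list(dx = dy * cache$mask, grads = NULL))
  }
  if (kind == "dense") {
    return(list(dx = dy %*% t(layer$params$W),
                grads = list(W = t(cache$x) %*% dy, b = colSums(dy))))
  }
  if (kind == "relu") {
    return(list(dx = cpp_relu_bw(dy, cache$y), grads = NULL))
  }
  if (kind == "global_avg_pool") {
    dx <- dy[rep(seq_len(cache$N), each = cache$hw), , drop = FALSE] /
      cache$hw
    return(list(dx = dx, grads = NULL))
  }
  if (kind == "lstm") return(lstm_backward(layer, cache, dy))
  if (kind == "gru") return(gru_backward(layer, cache, dy))
  stop("backward: unhandled layer kind '", kind, "'", call. = FALSE)
}

# ---- recurrent layers -------------------------------------------------------

# x: (N, T, F) array; returns last hidden state (N x U)
lstm_forward <- function(layer, x) {
  N <- dim(x)[1]; Tn <- dim(x)[2]; Fd <- dim(x)[3]
  u <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh; b <- layer$params$b
  h <- matrix(0, N, u); cc <- matrix(0, N, u)
  steps <- vector("list", Tn)
  idx <- list(i = 1:u, f = (u + 1):(2 * u), g = (2 * u + 1):(3 * u),
              o = (3 * u + 1):(4 * u))
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], nrow = N, ncol = Fd)
    z <- xt %*% Wx + h %*% Wh + rep_row(b, N)
    gi <- sigmoid(z[, idx$i, drop = FALSE])
    gf <- sigmoid(z[, idx$f, drop = FALSE])
    gg <- tanh(z[, idx$g, drop = FALSE])
    go <- sigmoid(z[, idx$o, drop = FALSE])
    c_prev <- cc
    cc <- gf * c_prev + gi * gg
    tc <- tanh(cc)
    h_prev <- if (t == 1) matrix(0, N, u) else steps[[t - 1]]$h
    steps[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev, i = gi,
                       f = gf, g = gg, o = go, tc = tc, h = go * tc)
    h <- steps[[t]]$h
  }
  list(y = h, shape = list(type = "flat", d = u),
       cache = list(steps = steps, idx = idx, N = N, Fd = Fd))
}

lstm_backward <- function(layer, cache, dy) {
  steps <- cache$steps; idx <- cache$idx
  N <- cache$N; Fd <- cache$Fd
  Tn <- length(steps); u <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4 * u)
  dx <- array(0, dim = c(N, Tn, Fd))
  dh <- dy
  dc <- matrix(0, N, u)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    do <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    dg <- dc * st$i
    df <- dc * st$c_prev
    dz <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do * st$o * (1 - st$o))
    dWx <- dWx + t(st$xt) %*% dz
    dWh <- dWh + t(st$h_prev) %*% dz
    db <- db + colSums(dz)
    dx[, t, ] <- dz %*% t(Wx)
    dh <- dz %*% t(Wh)
    dc <- dc * st$f
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# dual-bias GRU (separate input and recurrent bias per gate); gate order
# [update z | reset r | candidate h]
gru_forward <- function(layer, x) {
  N <- dim(x)[1]; Tn <- dim(x)[2]; Fd <- dim(x)[3]
  u <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  bx <- layer$params$bx; bh <- layer$params$bh
  h <- matrix(0, N, u)
  steps <- vector("list", Tn)
  iz <- 1:u; ir <- (u + 1):(2 * u); ih <- (2 * u + 1):(3 * u)
  for (t in seq_len(Tn)) {
    xt <- matrix(x[, t, ], nrow = N, ncol = Fd)
    ax <- xt %*% Wx + rep_row(bx, N)
    ah <- h %*% Wh + rep_row(bh, N)
    z <- sigmoid(ax[, iz, drop = FALSE] + ah[, iz, drop = FALSE])
    r <- sigmoid(ax[, ir, drop = FALSE] + ah[, ir, drop = FALSE])
    sh <- ah[, ih, drop = FALSE]
    hh <- tanh(ax[, ih, drop = FALSE] + r * sh)
    h_prev <- h
    h <- z * h_prev + (1 - z) * hh
    steps[[t]] <- list(xt = xt, h_prev = h_prev, z = z, r = r, sh = sh,
                       hh = hh)
  }
  list(y = h, shape = list(type = "flat", d = u),
       cache = list(steps = steps, N = N, Fd = Fd))
}

gru_backward <- function(layer, cache, dy) {
  steps <- cache$steps
  N <- cache$N; Fd <- cache$Fd
  Tn <- length(steps); u <- layer$units
  Wx <- layer$params$Wx; Wh <- layer$params$Wh
  dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh))
  dbx <- numeric(3 * u); dbh <- numeric(3 * u)
  dx <- array(0, dim = c(N, Tn, Fd))
  dh <- dy
  iz <- 1:u; ir <- (u + 1):(2 * u); ih <- (2 * u + 1):(3 * u)
  for (t in rev(seq_len(Tn))) {
    st <- steps[[t]]
    dz <- dh * (st$h_prev - st$hh)
    dhh <- dh * (1 - st$z)
    dh_next <- dh * st$z
    dah_h_pre <- dhh * (1 - st$hh^2) # grad wrt (ax_h + r*sh)
    dr <- dah_h_pre * st$sh
    dsh <- dah_h_pre * st$r
    daz <- dz * st$z * (1 - st$z)
    dar <- dr * st$r * (1 - st$r)
    dax <- cbind(daz, dar, dah_h_pre)
    dah <- cbind(daz, dar, dsh)
    dWx <- dWx + t(st$xt) %*% dax
    dbx <- dbx + colSums(dax)
    dWh <- dWh + t(st$h_prev) %*% dah
    dbh <- dbh + colSums(dah)
    dx[, t, ] <- dax %*% t(Wx)
    dh <- dh_next + dah %*% t(Wh)
  }
  list(dx = dx, grads = list(Wx = dWx, Wh = dWh, bx = dbx, bh = dbh))
}
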