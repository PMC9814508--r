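# Finite-difference verification of the backward passes. For each layer kind
# the analytic gradient of the cross-entropy loss is compared against central
# differences on a tiny network. Parameters whose true gradient is ~0 (e.g. a
# convolution bias feeding a batch norm) are compared absolutely.

fd_check <- function(model, x, y, n_probe = 4, eps = 1e-5, tol = 1e-5) {
  loss_of <- function(m) {
    fw <- cardiomel:::model_forward(m, x, training = TRUE)
    cardiomel:::xent_loss(fw$logits, y)
  }
  fw <- cardiomel:::model_forward(model, x, training = TRUE)
  grads <- cardiomel:::model_backward(model, fw$caches,
                                      cardiomel:::xent_grad(fw$logits, y))
  probe <- function(get_param, set_param, g_ana) {
    p0 <- get_param(model)
    idx <- sample(length(p0), min(n_probe, length(p0)))
    for (k in idx) {
      mp <- set_param(model, k, p0[k] + eps)
      mm <- set_param(model, k, p0[k] - eps)
      g_num <- (loss_of(mp) - loss_of(mm)) / (2 * eps)
      err <- abs(g_num - g_ana[k]) / max(1e-4, abs(g_num) + abs(g_ana[k]))
      expect_lt(err, tol)
    }
  }
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (!is.null(ly$branch)) {
      for (j in seq_along(ly$branch)) {
        for (nm in names(ly$branch[[j]]$params)) {
          probe(
            function(m) m$layers[[i]]$branch[[j]]$params[[nm]],
            function(m, k, v) {
              m$layers[[i]]$branch[[j]]$params[[nm]][k] <- v; m
            },
            grads[[i]]$branch[[j]][[nm]])
        }
      }
    }
    if (is.null(ly$params)) next
    for (nm in names(ly$params)) {
      probe(
        function(m) m$layers[[i]]$params[[nm]],
        function(m, k, v) { m$layers[[i]]$params[[nm]][k] <- v; m },
        grads[[i]][[nm]])
    }
  }
}

test_that("convolutional/residual backward passes match finite differences", {
  set.seed(31)
  s <- paste0("Conv [3, (3,3)]-BN-residual {Conv [4, (1,1)]-BN}-",
              "SeparableConv [4, (3,3)]-BN-MaxPooling (2,2)-add-",
              "Conv [3, (3,3)]-GlobalAveragePooling ()")
  m <- build_model(s, input_shape = c(7L, 5L), input = "image", seed = 3)
  x <- matrix(rnorm(4 * 7 * 5), ncol = 1)
  fd_check(m, x, c(1, 2, 3, 1))
})

test_that("recurrent backward passes match finite differences", {
  set.seed(32)
  xs <- array(rnorm(3 * 6 * 4), c(3, 6, 4))
  m_lstm <- build_model("LSTM (5)-FC(4)-FC (3)", input_shape = c(6L, 4L),
                        input = "sequence", seed = 5)
  fd_check(m_lstm, xs, c(1, 3, 2))
  m_gru <- build_model("GRU (5)-FC(4)-FC (3)", input_shape = c(6L, 4L),
                       input = "sequence", seed = 6)
  fd_check(m_gru, xs, c(2, 1, 3))
})

test_that("plain CNN backward pass matches finite differences", {
  set.seed(33)
  m <- build_model("cnn", input_shape = c(13L, 9L), input = "image", seed = 8)
  # deterministic loss for differencing: disable dropout
  for (i in seq_along(m$layers)) {
    if (m$layers[[i]]$kind == "dropout") m$layers[[i]]$rate <- 0
  }
  x <- matrix(rnorm(2 * 13 * 9), ncol = 1)
  fd_check(m, x, c(3, 1))
})

test_that("convolution kernels agree with a direct R implementation", {
  # independent oracle: convolution as an explicit loop over output positions
  set.seed(34)
  H <- 6L; W <- 5L; C <- 2L; Fo <- 3L; N <- 2L
  x <- matrix(rnorm(N * H * W * C), ncol = C)
  Wm <- matrix(rnorm(9 * C * Fo), 9 * C, Fo)
  b <- rnorm(Fo)
  out <- cardiomel:::cpp_conv2d_fw(x, H, W, N, Wm, b, 3L, 3L, 1L, 1L)
  get_x <- function(n, h, w, c) {
    if (h < 1 || h > H || w < 1 || w > W) return(0)
    x[(n - 1) * H * W + (w - 1) * H + h, c]
  }
  for (n in 1:N) for (h in 1:H) for (w in 1:W) for (f in 1:Fo) {
    acc <- b[f]
    for (c in 1:C) for (j in 1:3) for (i in 1:3) {
      acc <- acc + get_x(n, h + i - 2, w + j - 2, c) *
        Wm[(c - 1) * 9 + (j - 1) * 3 + i, f]
    }
    expect_equal(out$y[(n - 1) * H * W + (w - 1) * H + h, f], acc,
                 tolerance = 1e-12)
  }
})

test_that("max pooling uses ceil-division output sizes and true maxima", {
  set.seed(35)
  H <- 7L; W <- 4L; N <- 2L
  x <- matrix(rnorm(N * H * W * 2), ncol = 2)
  r <- cardiomel:::cpp_maxpool_fw(x, H, W, N, 3L, 3L)
  expect_equal(r$ho, 3L) # ceil(7/3)
  expect_equal(r$wo, 2L) # ceil(4/3)
  # every pooled value is the max over its (possibly truncated) window
  for (c in 1:2) for (n in 1:N) for (wo in 1:2) for (ho in 1:3) {
    rows <- c()
    for (wi in ((wo - 1) * 3 + 1):min(wo * 3, W)) {
      for (hi in ((ho - 1) * 3 + 1):min(ho * 3, H)) {
        rows <- c(rows, (n - 1) * H * W + (wi - 1) * H + hi)
      }
    }
    expect_equal(r$y[(n - 1) * 6 + (wo - 1) * 3 + ho, c], max(x[rows, c]))
  }
})
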