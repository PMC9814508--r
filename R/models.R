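#' Built-in architecture zoo
#'
#' The four benchmark architectures, stored as structure strings in
#' `extdata/architectures.yaml` so they are data rather than code: `lstm` and
#' `gru` recurrent baselines, a plain `cnn` baseline, and the `resnet`
#' residual network with depthwise-separable convolutions.
#'
#' @param path Optional alternative YAML file.
#' @return Named list with `input` ("sequence"/"image") and `structure` per
#'   model.
#' @export
model_zoo <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "architectures.yaml",
                        package = "cardiomel", mustWork = TRUE)
  }
  yaml::read_yaml(path)
}

# relu insertion rule: relu after every main-path BN; after conv/separable
# not followed by BN (unless it produces the logits, i.e. it is followed only
# by global average pooling at the very end); after every dense except the
# last. Projection branches get no activations.
insert_activations <- function(layers) {
  n <- length(layers)
  kinds <- vapply(layers, `[[`, "", "kind")
  out <- list()
  for (i in seq_len(n)) {
    ly <- layers[[i]]
    out[[length(out) + 1]] <- ly
    nxt <- if (i < n) kinds[i + 1] else ""
    add_relu <- FALSE
    if (ly$kind == "batch_norm") add_relu <- TRUE
    if (ly$kind %in% c("conv2d", "separable_conv2d") && nxt != "batch_norm") {
      logits_conv <- i == n - 1 && nxt == "global_avg_pool"
      add_relu <- !logits_conv
    }
    if (ly$kind == "dense" && i < n) add_relu <- TRUE
    if (add_relu) out[[length(out) + 1]] <- list(kind = "relu")
  }
  out
}

#' Build a trainable model from a structure string or zoo name
#'
#' Walks the parsed layer list, inserting ReLU activations after
#' convolution/batch-norm blocks and hidden dense layers, computing the shape
#' flow, and initialising parameters (Glorot uniform) under the given seed.
#' Residual blocks get an Xception-style projection branch: the braced 1x1
#' convolution (+BN) is applied to the block input with stride equal to the
#' pooling factor of the main path, so shapes match exactly at each `add`.
#' Convolutions use same padding; pooling uses same padding with stride equal
#' to the pool size. The final layer produces 3-way class scores; softmax is
#' applied by [predict.pcg_model()] and inside the loss.
#'
#' @param name_or_structure A zoo name (`"resnet"`, `"lstm"`, `"gru"`,
#'   `"cnn"`) or a raw structure string.
#' @param input_shape For sequences `c(T, F)`; for images `c(H, W)` (one
#'   channel is implied). Default `c(199, 39)`.
#' @param n_classes Number of classes (3).
#' @param input `"sequence"` or `"image"`; inferred from the zoo for named
#'   models, otherwise from the first layer.
#' @param seed Integer seed controlling weight initialisation.
#' @param bn_eps Batch-norm smoothing term.
#' @return An object of class `pcg_model`.
#' @export
build_model <- function(name_or_structure, input_shape = c(199L, 39L),
                        n_classes = 3L, input = NULL, seed = 1L,
                        bn_eps = 1e-3) {
  zoo <- tryCatch(model_zoo(), error = function(e) list())
  if (name_or_structure %in% names(zoo)) {
    entry <- zoo[[name_or_structure]]
    structure_string <- entry$structure
    input <- input %||% entry$input
    name <- name_or_structure
  } else {
    structure_string <- name_or_structure
    name <- "custom"
  }
  parsed <- parse_structure(structure_string)
  if (is.null(input)) {
    input <- if (parsed[[1]]$kind %in% c("lstm", "gru")) "sequence" else
      "image"
  }
  shape <- if (input == "sequence") {
    list(type = "seq", T = as.integer(input_shape[1]),
         F = as.integer(input_shape[2]))
  } else {
    list(type = "image", H = as.integer(input_shape[1]),
         W = as.integer(input_shape[2]), C = 1L)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  main <- insert_activations(parsed)
  layers <- list()
  res_stack <- list() # pending residual blocks: list(shape_at_start, branch)
  for (ly in main) {
    if (ly$kind == "residual_branch_start") {
      res_stack[[length(res_stack) + 1]] <- list(shape = shape,
                                                 branch = ly$branch)
      layers[[length(layers) + 1]] <- list(kind = "residual_start")
      next
    }
    if (ly$kind == "add_residual") {
      if (length(res_stack) == 0) {
        stop("build error: 'add' without open residual block", call. = FALSE)
      }
      blk <- res_stack[[length(res_stack)]]
      res_stack[[length(res_stack)]] <- NULL
      # stride of the projection = downsampling of the main path in the block
      sh <- ceiling(blk$shape$H / shape$H)
      sw <- ceiling(blk$shape$W / shape$W)
      branch_layers <- list()
      bshape <- blk$shape
      for (bly in blk$branch) {
        if (bly$kind == "conv2d") bly$stride <- c(sh, sw)
        r <- init_layer(bly, bshape, bn_eps = bn_eps)
        branch_layers[[length(branch_layers) + 1]] <- r$layer
        bshape <- r$shape
      }
      if (!identical(bshape[c("H", "W", "C")], shape[c("H", "W", "C")])) {
        stop("build error: residual add with mismatched shapes (",
             paste(unlist(bshape[c("H", "W", "C")]), collapse = "x"), " vs ",
             paste(unlist(shape[c("H", "W", "C")]), collapse = "x"), ")",
             call. = FALSE)
      }
      layers[[length(layers) + 1]] <- list(kind = "residual_add",
                                           branch = branch_layers)
      next
    }
    r <- init_layer(ly, shape, bn_eps = bn_eps)
    layers[[length(layers) + 1]] <- r$layer
    shape <- r$shape
  }
  if (shape$type != "flat" || shape$d != n_classes) {
    stop("build error: network output shape (",
         paste(unlist(shape[-1]), collapse = "x"),
         ") does not produce ", n_classes, " class scores", call. = FALSE)
  }
  structure(
    list(name = name, structure_string = structure_string, input = input,
         input_shape = as.integer(input_shape), n_classes = n_classes,
         layers = layers, seed = seed, scaler = NULL),
    class = "pcg_model")
}

#' Count model parameters
#'
#' Totals every parameter array, batch-norm running statistics included
#' (the standard layer-summary convention of counting trainable and
#' non-trainable parameters together).
#'
#' @param model A `pcg_model`.
#' @return Integer total.
#' @export
count_parameters <- function(model) {
  count_layers <- function(layers) {
    tot <- 0L
    for (ly in layers) {
      if (!is.null(ly$params)) {
        tot <- tot + sum(vapply(ly$params, length, 1L))
      }
      if (!is.null(ly$state)) {
        tot <- tot + sum(vapply(ly$state, length, 1L))
      }
      if (!is.null(ly$branch)) tot <- tot + count_layers(ly$branch)
    }
    tot
  }
  count_layers(model$layers)
}

#' @export
print.pcg_model <- function(x, ...) {
  cat(sprintf("<pcg_model '%s'> input %s (%s), %s parameters\n", x$name,
              paste(x$input_shape, collapse = "x"), x$input,
              format(count_parameters(x), big.mark = ",")))
  cat("  ", x$structure_string, "\n")
  invisible(x)
}

#' Layer-by-layer summary table
#'
#' @param object A `pcg_model`.
#' @param ... Unused.
#' @return A tibble with layer kind, output shape and parameter count; the
#'   parameter column sums to [count_parameters()].
#' @export
summary.pcg_model <- function(object, ...) {
  rows <- list()
  walk <- function(layers, prefix = "") {
    for (ly in layers) {
      n_par <- 0L
      if (!is.null(ly$params)) n_par <- n_par + sum(vapply(ly$params, length, 1L))
      if (!is.null(ly$state)) n_par <- n_par + sum(vapply(ly$state, length, 1L))
      rows[[length(rows) + 1]] <<- tibble::tibble(
        layer = paste0(prefix, ly$kind), params = n_par)
      if (!is.null(ly$branch)) walk(ly$branch, paste0(prefix, "  branch/"))
    }
  }
  walk(object$layers)
  out <- dplyr::bind_rows(rows)
  attr(out, "total") <- sum(out$params)
  out
}

# ---- forward / backward over the whole network ------------------------------

# x: input in the network's native representation (see nn-layers.R).
model_forward <- function(model, x, training = FALSE) {
  shape <- if (model$input == "sequence") {
    list(type = "seq", T = model$input_shape[1], F = model$input_shape[2])
  } else {
    list(type = "image", H = model$input_shape[1], W = model$input_shape[2],
         C = 1L)
  }
  caches <- vector("list", length(model$layers))
  saved <- list() # residual inputs
  for (i in seq_along(model$layers)) {
    ly <- model$layers[[i]]
    if (ly$kind == "residual_start") {
      saved[[length(saved) + 1]] <- list(x = x, shape = shape)
      next
    }
    if (ly$kind == "residual_add") {
      inp <- saved[[length(saved)]]
      saved[[length(saved)]] <- NULL
      bx <- inp$x; bshape <- inp$shape
      bcaches <- vector("list", length(ly$branch))
      for (j in seq_along(ly$branch)) {
        r <- layer_forward(ly$branch[[j]], bx, bshape, training)
        bcaches[j] <- list(r$cache)
        bx <- r$y; bshape <- r$shape
      }
      x <- x + bx
      caches[[i]] <- list(branch = bcaches)
      next
    }
    r <- layer_forward(ly, x, shape, training)
    caches[i] <- list(r$cache)
    x <- r$y
    shape <- r$shape
  }
  list(logits = x, caches = caches)
}

# returns grads: list per layer (NULL where no params); residual_add entries
# hold list(branch = list of grads)
model_backward <- function(model, caches, dlogits) {
  n <- length(model$layers)
  grads <- vector("list", n)
  dy <- dlogits
  pending <- list() # branch input-gradients waiting for residual_start
  for (i in rev(seq_len(n))) {
    ly <- model$layers[[i]]
    if (ly$kind == "residual_add") {
      bdy <- dy # same gradient flows into the branch
      bgrads <- vector("list", length(ly$branch))
      for (j in rev(seq_along(ly$branch))) {
        r <- layer_backward(ly$branch[[j]], caches[[i]]$branch[[j]], bdy)
        bgrads[j] <- list(r$grads)
        bdy <- r$dx
      }
      grads[[i]] <- list(branch = bgrads)
      pending[[length(pending) + 1]] <- bdy
      next
    }
    if (ly$kind == "residual_start") {
      dy <- dy + pending[[length(pending)]]
      pending[[length(pending)]] <- NULL
      next
    }
    r <- layer_backward(ly, caches[[i]], dy)
    grads[i] <- list(r$grads) # [[<-]] with NULL would drop the slot
    dy <- r$dx
  }
  grads
}

softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean categorical cross-entropy; y is an integer class vector (1..K)
xent_loss <- function(logits, y) {
  p <- softmax(logits)
  eps <- 1e-12
  -mean(log(pmax(p[cbind(seq_along(y), y)], eps)))
}

xent_grad <- function(logits, y) {
  p <- softmax(logits)
  Y <- matrix(0, nrow(p), ncol(p))
  Y[cbind(seq_along(y), y)] <- 1
  (p - Y) / nrow(p)
}

# ---- input assembly ---------------------------------------------------------

# features: list of T x F matrices -> network-native batch
assemble_batch <- function(model, features) {
  if (model$input == "sequence") {
    Tn <- nrow(features[[1]]); Fd <- ncol(features[[1]])
    x <- array(0, dim = c(length(features), Tn, Fd))
    for (i in seq_along(features)) x[i, , ] <- features[[i]]
    x
  } else {
    matrix(unlist(features, use.names = FALSE), ncol = 1)
  }
}

fit_scaler <- function(features) {
  all_rows <- do.call(rbind, features)
  mu <- colMeans(all_rows)
  sd <- apply(all_rows, 2, stats::sd)
  sd[sd < 1e-12] <- 1
  list(mean = mu, sd = sd)
}

apply_scaler <- function(features, scaler) {
  if (is.null(scaler)) return(features)
  lapply(features, function(f) {
    sweep(sweep(f, 2, scaler$mean), 2, scaler$sd, "/")
  })
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly) {
    st <- NULL
    if (!is.null(ly$params)) {
      st <- list(m = lapply(ly$params, function(p) array(0, dim(p) %||% length(p))),
                 v = lapply(ly$params, function(p) array(0, dim(p) %||% length(p))))
    }
    if (!is.null(ly$branch)) {
      st <- c(st %||% list(), list(branch = adam_init(ly$branch)))
    }
    st
  })
}

adam_step <- function(layers, grads, opt, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  for (i in seq_along(layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    if (!is.null(layers[[i]]$branch)) {
      r <- adam_step(layers[[i]]$branch, g$branch, opt[[i]]$branch, lr, t,
                     beta1, beta2, eps)
      layers[[i]]$branch <- r$layers
      opt[[i]]$branch <- r$opt
      next
    }
    for (nm in names(layers[[i]]$params)) {
      gi <- g[[nm]]
      opt[[i]]$m[[nm]] <- beta1 * opt[[i]]$m[[nm]] + (1 - beta1) * gi
      opt[[i]]$v[[nm]] <- beta2 * opt[[i]]$v[[nm]] + (1 - beta2) * gi^2
      mhat <- opt[[i]]$m[[nm]] / (1 - beta1^t)
      vhat <- opt[[i]]$v[[nm]] / (1 - beta2^t)
      layers[[i]]$params[[nm]] <- layers[[i]]$params[[nm]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(layers = layers, opt = opt)
}

# update batch-norm running statistics after a training forward pass
bn_update_running <- function(layers, caches) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$kind == "batch_norm" && !is.null(caches[[i]])) {
      mom <- ly$momentum
      layers[[i]]$state$running_mean <-
        mom * ly$state$running_mean + (1 - mom) * caches[[i]]$mu
      layers[[i]]$state$running_var <-
        mom * ly$state$running_var + (1 - mom) * caches[[i]]$v
    }
    if (!is.null(ly$branch)) {
      layers[[i]]$branch <- bn_update_running(ly$branch,
                                              caches[[i]]$branch %||%
                                                vector("list",
                                                       length(ly$branch)))
    }
  }
  layers
}

# ---- training ---------------------------------------------------------------

#' Train a model on labelled feature matrices
#'
#' Mini-batch training with adaptive moment estimation (Adam) and categorical
#' cross-entropy. One integer seed controls shuffling and dropout; together
#' with the build seed it makes a run fully reproducible. Features are
#' standardised per column with statistics fitted on the training set (stored
#' in the returned object and re-applied at prediction time).
#'
#' @param model A `pcg_model` from [build_model()].
#' @param features List of `T x F` feature matrices (see
#'   [extract_features()]).
#' @param labels Character or factor labels, levels
#'   `c("normal", "abnormal", "noise")` by default.
#' @param epochs,batch_size,lr Training hyper-parameters (defaults 30, 32,
#'   1e-3).
#' @param seed Integer seed for shuffling and dropout.
#' @param validation Optional list(features, labels) evaluated each epoch.
#' @param class_levels Class order defining the output units.
#' @param scale Standardise features with training-set statistics.
#' @param patience Early-stopping patience on validation loss; `Inf` (the
#'   default) trains the fixed number of epochs.
#' @param verbose Print a line per epoch.
#' @return An object of class `pcg_model_fit`: the trained model plus a
#'   `history` tibble (epoch, loss, accuracy, optional validation metrics).
#' @export
train_model <- function(model, features, labels, epochs = 30L,
                        batch_size = 32L, lr = 1e-3, seed = 1L,
                        validation = NULL,
                        class_levels = c("normal", "abnormal", "noise"),
                        scale = TRUE, patience = Inf, verbose = FALSE) {
  stopifnot(inherits(model, "pcg_model"), length(features) == length(labels))
  y <- match(as.character(labels), class_levels)
  if (anyNA(y)) stop("labels outside class_levels", call. = FALSE)

  if (scale) {
    model$scaler <- fit_scaler(features)
    features <- apply_scaler(features, model$scaler)
  }
  val <- NULL
  if (!is.null(validation)) {
    val <- list(features = apply_scaler(validation$features, model$scaler),
                y = match(as.character(validation$labels), class_levels))
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  opt <- adam_init(model$layers)
  n <- length(features)
  hist <- list()
  step <- 0L
  best_val <- Inf; wait <- 0L
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0; ep_correct <- 0
    for (b in seq(1, n, by = batch_size)) {
      ids <- ord[b:min(b + batch_size - 1, n)]
      xb <- assemble_batch(model, features[ids])
      yb <- y[ids]
      fw <- model_forward(model, xb, training = TRUE)
      model$layers <- bn_update_running(model$layers, fw$caches)
      loss <- xent_loss(fw$logits, yb)
      grads <- model_backward(model, fw$caches, xent_grad(fw$logits, yb))
      step <- step + 1L
      r <- adam_step(model$layers, grads, opt, lr, step)
      model$layers <- r$layers
      opt <- r$opt
      ep_loss <- ep_loss + loss * length(ids)
      ep_correct <- ep_correct + sum(max.col(fw$logits) == yb)
    }
    row <- tibble::tibble(epoch = ep, loss = ep_loss / n,
                          accuracy = ep_correct / n)
    if (!is.null(val)) {
      vp <- predict_logits(model, val$features)
      row$val_loss <- xent_loss(vp, val$y)
      row$val_accuracy <- mean(max.col(vp) == val$y)
      if (row$val_loss < best_val - 1e-8) {
        best_val <- row$val_loss; wait <- 0L
      } else {
        wait <- wait + 1L
      }
    }
    hist[[ep]] <- row
    if (verbose) {
      cat(sprintf("epoch %3d  loss %.4f  acc %.3f%s\n", ep, row$loss,
                  row$accuracy,
                  if (!is.null(val)) sprintf("  val_loss %.4f  val_acc %.3f",
                                             row$val_loss, row$val_accuracy)
                  else ""))
    }
    if (!is.null(val) && wait >= patience) break
  }
  structure(list(model = model, history = dplyr::bind_rows(hist),
                 class_levels = class_levels, seed = seed),
            class = "pcg_model_fit")
}

# forward in eval mode, in prediction batches (features already scaled)
predict_logits <- function(model, features, batch_size = 64L) {
  out <- matrix(0, length(features), model$n_classes)
  for (b in seq(1, length(features), by = batch_size)) {
    ids <- b:min(b + batch_size - 1, length(features))
    xb <- assemble_batch(model, features[ids])
    out[ids, ] <- model_forward(model, xb, training = FALSE)$logits
  }
  out
}

#' Predict class probabilities or labels
#'
#' @param object A `pcg_model` (with fitted scaler) or `pcg_model_fit`.
#' @param features List of feature matrices.
#' @param type `"prob"` for a probability tibble, `"class"` for labels.
#' @param ... Unused.
#' @return A tibble of class probabilities (columns named by class, rows
#'   summing to 1) or a character vector of labels.
#' @export
predict.pcg_model <- function(object, features, type = c("prob", "class"),
                              class_levels = c("normal", "abnormal", "noise"),
                              ...) {
  type <- match.arg(type)
  feats <- apply_scaler(features, object$scaler)
  p <- softmax(predict_logits(object, feats))
  colnames(p) <- class_levels
  if (type == "class") {
    return(class_levels[max.col(p)])
  }
  tibble::as_tibble(p)
}

#' @rdname predict.pcg_model
#' @export
predict.pcg_model_fit <- function(object, features,
                                  type = c("prob", "class"), ...) {
  predict.pcg_model(object$model, features, type = type,
                    class_levels = object$class_levels, ...)
}

#' @export
print.pcg_model_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<pcg_model_fit '%s'> %d epochs, final loss %.4f, accuracy %.3f\n",
    x$model$name, nrow(x$history), last$loss, last$accuracy))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a fitted model
#'
#' @param x A `pcg_model_fit`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.pcg_model_fit <- function(x, ...) x$history

#' One-row summary of a fitted model
#'
#' @param x A `pcg_model_fit`.
#' @param ... Unused.
#' @return Tibble with model name, parameter count, epochs and final
#'   training (and validation, if tracked) loss/accuracy.
#' @export
glance.pcg_model_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  out <- tibble::tibble(model = x$model$name,
                        parameters = count_parameters(x$model),
                        epochs = nrow(x$history),
                        loss = last$loss, accuracy = last$accuracy)
  if ("val_loss" %in% names(last)) {
    out$val_loss <- last$val_loss
    out$val_accuracy <- last$val_accuracy
  }
  out
}
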