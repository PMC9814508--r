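#' Grouped, stratified split plan
#'
#' Reserves a fixed test pool (20% of recordings, stratified by class with
#' largest-remainder rounding so the pool size is exactly
#' `round(test_fraction * n)`), then partitions the remaining recordings into
#' `n_folds` rotating validation folds, again stratified by class. Splitting
#' is by *parent recording*, never by segment, so no recording contributes
#' segments to both sides of any boundary (leakage guard). Deterministic
#' under `seed`.
#'
#' @param recordings Tibble with one row per recording: columns `id` and
#'   `label` (a segment tibble also works; it is collapsed by `parent_id`).
#' @param test_fraction Fraction of recordings held out for testing (0.2).
#' @param n_folds Number of validation folds (5).
#' @param seed Integer seed.
#' @return A `split_plan` tibble: `id`, `label`, `role` (`"test"` or
#'   `"pool"`), `fold` (1..n_folds, `NA` for test rows), with the plan
#'   parameters as attributes.
#' @export
make_splits <- function(recordings, test_fraction = 0.2, n_folds = 5L,
                        seed = 1L) {
  if ("parent_id" %in% names(recordings) &&
      !"id" %in% names(recordings)) {
    recordings <- dplyr::distinct(
      dplyr::tibble(id = recordings$parent_id, label = recordings$label))
  }
  recs <- dplyr::distinct(recordings[c("id", "label")])
  counts <- table(recs$label)
  if (any(counts < n_folds)) {
    stop("stratification error: class '",
         names(counts)[which.min(counts)], "' has fewer than ", n_folds,
         " recordings", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  n_total <- nrow(recs)
  n_test <- round(test_fraction * n_total)
  # largest-remainder apportionment of the test pool across classes
  raw <- test_fraction * as.numeric(counts)
  base <- floor(raw)
  rem <- n_test - sum(base)
  if (rem > 0) {
    order_frac <- order(raw - base, decreasing = TRUE)
    base[order_frac[seq_len(rem)]] <- base[order_frac[seq_len(rem)]] + 1
  }
  names(base) <- names(counts)

  plan <- recs
  plan$role <- "pool"
  plan$fold <- NA_integer_
  for (cl in names(counts)) {
    ids_cl <- which(plan$label == cl)
    shuffled <- sample(ids_cl)
    take <- base[[cl]]
    if (take > 0) plan$role[shuffled[seq_len(take)]] <- "test"
    pool <- shuffled[setdiff(seq_along(shuffled), seq_len(take))]
    if (length(pool) > 0) {
      plan$fold[pool] <- rep_len(seq_len(n_folds), length(pool))
    }
  }
  plan <- tibble::as_tibble(plan)
  attr(plan, "test_fraction") <- test_fraction
  attr(plan, "n_folds") <- n_folds
  attr(plan, "seed") <- seed
  class(plan) <- c("split_plan", class(plan))
  plan
}

# time-shift + gain augmentation for one segment (label preserving for
# quasi-periodic signals): circular shift up to max_shift_s, gain +/- gain_db
augment_segment <- function(samples, sr = 2000L, max_shift_s = 0.2,
                            gain_db = 3) {
  shift <- sample.int(2L * round(max_shift_s * sr) + 1L, 1L) -
    round(max_shift_s * sr) - 1L
  if (shift != 0) {
    n <- length(samples)
    shift <- ((shift %% n) + n) %% n
    if (shift > 0) samples <- c(samples[(shift + 1):n], samples[1:shift])
  }
  g <- 10^(stats::runif(1, -gain_db, gain_db) / 20)
  pmin(pmax(samples * g, -1), 1)
}

#' Oversample minority classes in a training set
#'
#' Minority classes are brought up to the majority count by sampling segments
#' with replacement and lightly augmenting each copy (random circular time
#' shift up to 0.2 s and gain jitter of +/-3 dB) so duplicates are not
#' bit-identical. Intended for training folds only; an already balanced input
#' is returned unchanged (up to row order).
#'
#' @param segments Segment tibble with `label` and `samples` columns.
#' @param seed Integer seed.
#' @param max_shift_s,gain_db Augmentation magnitudes.
#' @return A balanced segment tibble.
#' @export
balance_classes <- function(segments, seed = 1L, max_shift_s = 0.2,
                            gain_db = 3) {
  counts <- table(segments$label)
  if (any(counts == 0) || length(counts) == 0) {
    stop("balance error: empty class in training data", call. = FALSE)
  }
  target <- max(counts)
  if (all(counts == target)) return(segments)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  extra <- list()
  for (cl in names(counts)) {
    deficit <- target - counts[[cl]]
    if (deficit == 0) next
    rows <- which(segments$label == cl)
    picked <- rows[sample.int(length(rows), deficit, replace = TRUE)]
    aug <- segments[picked, ]
    aug$samples <- lapply(aug$samples, augment_segment,
                          max_shift_s = max_shift_s, gain_db = gain_db)
    aug$segment_id <- sprintf("%s_aug%04d", aug$segment_id,
                              seq_len(nrow(aug)))
    extra[[length(extra) + 1]] <- aug
  }
  dplyr::bind_rows(c(list(segments), extra))
}

#' Confusion matrix for the three-class task
#'
#' @param truth,predicted Character/factor vectors of labels.
#' @param class_levels Class order (rows = truth, columns = predicted).
#' @return A `confusion_matrix`: integer matrix with class dimnames.
#' @export
confusion_matrix <- function(truth, predicted,
                             class_levels = c("normal", "abnormal",
                                              "noise")) {
  t_f <- factor(as.character(truth), levels = class_levels)
  p_f <- factor(as.character(predicted), levels = class_levels)
  if (anyNA(t_f) || anyNA(p_f)) {
    stop("labels outside class_levels", call. = FALSE)
  }
  m <- unclass(table(truth = t_f, predicted = p_f))
  structure(m, class = c("confusion_matrix", "matrix"))
}

#' Accuracy, sensitivity, specificity and precision from a confusion matrix
#'
#' Accuracy is trace/total. The other three are computed one-vs-rest per
#' class from the collapsed 2x2 counts — sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, precision `TP/(TP+FP)` — and macro-averaged
#' (unweighted mean over classes). A zero denominator yields `NaN` with a
#' warning rather than an error.
#'
#' @param cm A [confusion_matrix()] (any square integer matrix with
#'   dimnames works).
#' @return A `metrics_report`: list with `accuracy`, `per_class` tibble and
#'   `macro` one-row tibble.
#' @export
evaluate_metrics <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  classes <- rownames(cm) %||% as.character(seq_len(nrow(cm)))
  acc <- sum(diag(cm)) / total
  safe_div <- function(num, den, what, cl) {
    if (den == 0) {
      warning("undefined ", what, " for class '", cl,
              "' (zero denominator)", call. = FALSE)
      return(NaN)
    }
    num / den
  }
  per <- lapply(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    fn <- sum(cm[i, ]) - tp
    fp <- sum(cm[, i]) - tp
    tn <- total - tp - fn - fp
    tibble::tibble(
      class = classes[i],
      sensitivity = safe_div(tp, tp + fn, "sensitivity", classes[i]),
      specificity = safe_div(tn, tn + fp, "specificity", classes[i]),
      precision = safe_div(tp, tp + fp, "precision", classes[i]))
  })
  per <- dplyr::bind_rows(per)
  macro <- tibble::tibble(
    accuracy = acc,
    sensitivity = mean(per$sensitivity),
    specificity = mean(per$specificity),
    precision = mean(per$precision))
  structure(list(accuracy = acc, per_class = per, macro = macro,
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> accuracy %.4f\n", x$accuracy))
  print(x$per_class)
  invisible(x)
}

#' @rdname evaluate_metrics
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @return `tidy()`: the per-class metric tibble; `glance()`: one row with
#'   accuracy and macro-averaged metrics.
#' @export
tidy.metrics_report <- function(x, ...) x$per_class

#' @rdname evaluate_metrics
#' @export
glance.metrics_report <- function(x, ...) x$macro

#' Five-fold cross-validation with a fixed test pool
#'
#' The evaluation protocol: hold out 20% of recordings as a fixed test pool;
#' split the remainder into five stratified validation folds; for each fold,
#' train a fresh model on the other four folds (class-balanced with
#' augmentation) while monitoring that fold, then evaluate on the fixed test
#' pool. The study result is the arithmetic mean of the five test accuracies.
#'
#' @param segments Segment tibble with extracted `features` (see
#'   [extract_features()]); must carry `parent_id` and `label`.
#' @param model_name Zoo name or structure string for [build_model()].
#' @param epochs,batch_size,lr Training hyper-parameters.
#' @param seed Master seed: drives the split plan, per-fold build/training
#'   seeds and balancing.
#' @param balance Oversample training folds to class balance.
#' @param patience Early-stopping patience (off by default).
#' @param verbose Print per-epoch progress.
#' @return A `cv_result`: list with `fold_reports` (list of
#'   `metrics_report`), `mean_accuracy`, `history` (per-fold training
#'   curves), `plan` and `fold_models`.
#' @export
cross_validate <- function(segments, model_name = "resnet", epochs = 30L,
                           batch_size = 32L, lr = 1e-3, seed = 1L,
                           balance = TRUE, patience = Inf, verbose = FALSE) {
  stopifnot("features" %in% names(segments))
  plan <- make_splits(
    tibble::tibble(id = segments$parent_id, label = segments$label),
    seed = seed)
  n_folds <- attr(plan, "n_folds")
  seg_role <- plan$role[match(segments$parent_id, plan$id)]
  seg_fold <- plan$fold[match(segments$parent_id, plan$id)]
  test_idx <- which(seg_role == "test")

  input_shape <- dim(segments$features[[1]])
  reports <- list(); histories <- list(); models <- list()
  for (k in seq_len(n_folds)) {
    train_idx <- which(seg_role == "pool" & seg_fold != k)
    val_idx <- which(seg_role == "pool" & seg_fold == k)
    train_segs <- segments[train_idx, ]
    if (balance) {
      train_segs <- balance_classes(train_segs, seed = derive_seed(seed, k))
      # augmented copies need features recomputed from their samples
      need <- grepl("_aug[0-9]+$", train_segs$segment_id)
      if (any(need)) {
        train_segs$features[need] <- lapply(train_segs$samples[need],
                                            function(s) {
          improved_mfcc(s, sample_rate_hz = 2000L)$stacked
        })
      }
    }
    model <- build_model(model_name, input_shape = input_shape,
                         seed = derive_seed(seed, 100 + k))
    fit <- train_model(model, train_segs$features, train_segs$label,
                       epochs = epochs, batch_size = batch_size, lr = lr,
                       seed = derive_seed(seed, 200 + k),
                       validation = list(features = segments$features[val_idx],
                                         labels = segments$label[val_idx]),
                       patience = patience, verbose = verbose)
    pred <- predict(fit, segments$features[test_idx], type = "class")
    cm <- confusion_matrix(segments$label[test_idx], pred)
    reports[[k]] <- evaluate_metrics(cm)
    histories[[k]] <- dplyr::mutate(fit$history, fold = k, .before = 1)
    models[[k]] <- fit
    if (verbose) {
      cat(sprintf("fold %d: test accuracy %.4f\n", k,
                  reports[[k]]$accuracy))
    }
  }
  structure(
    list(fold_reports = reports,
         mean_accuracy = mean(vapply(reports, `[[`, 0, "accuracy")),
         history = dplyr::bind_rows(histories), plan = plan,
         fold_models = models, model_name = model_name),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  accs <- vapply(x$fold_reports, `[[`, 0, "accuracy")
  cat(sprintf("<cv_result '%s'> mean test accuracy %.4f (folds: %s)\n",
              x$model_name, x$mean_accuracy,
              paste(sprintf("%.3f", accs), collapse = ", ")))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return `tidy()`: per-fold, per-class metrics; `glance()`: one row with
#'   the mean test accuracy and macro metrics averaged over folds.
#' @export
tidy.cv_result <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$fold_reports), function(k) {
    dplyr::mutate(x$fold_reports[[k]]$per_class, fold = k, .before = 1)
  }))
}

#' @rdname cross_validate
#' @export
glance.cv_result <- function(x, ...) {
  macros <- dplyr::bind_rows(lapply(x$fold_reports, `[[`, "macro"))
  tibble::tibble(model = x$model_name,
                 mean_accuracy = x$mean_accuracy,
                 sensitivity = mean(macros$sensitivity),
                 specificity = mean(macros$specificity),
                 precision = mean(macros$precision),
                 n_folds = length(x$fold_reports))
}
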