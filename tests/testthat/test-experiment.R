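recordings_fixture <- function(n_per_class = 20) {
  tibble::tibble(
    id = sprintf("rec%03d", seq_len(3 * n_per_class)),
    label = rep(c("normal", "abnormal", "noise"), each = n_per_class))
}

test_that("split plans are deterministic, sized and stratified", {
  recs <- recordings_fixture(20)
  p1 <- make_splits(recs, seed = 3)
  p2 <- make_splits(recs, seed = 3)
  expect_identical(as.data.frame(p1), as.data.frame(p2))
  p3 <- make_splits(recs, seed = 4)
  expect_false(identical(p1$role, p3$role))

  expect_equal(sum(p1$role == "test"), round(0.2 * 60))
  # stratified: each class contributes ~20% of its recordings
  by_class <- table(p1$label[p1$role == "test"])
  expect_true(all(by_class == 4))

  # the five folds partition the pool and are pairwise disjoint by construction
  pool <- p1[p1$role == "pool", ]
  expect_true(all(!is.na(pool$fold)))
  expect_true(all(is.na(p1$fold[p1$role == "test"])))
  expect_setequal(unique(pool$fold), 1:5)

  expect_error(make_splits(recordings_fixture(3)), "stratification error")
})

test_that("test pool size follows largest-remainder rounding on odd totals", {
  recs <- tibble::tibble(
    id = sprintf("r%02d", 1:37),
    label = c(rep("normal", 17), rep("abnormal", 13), rep("noise", 7)))
  p <- make_splits(recs, seed = 1)
  expect_equal(sum(p$role == "test"), round(0.2 * 37))
})

test_that("splitting groups by parent recording (no segment leakage)", {
  segs <- make_segment_table(6, duration_s = 4, cfg = synth_config(seed = 2))
  plan <- make_splits(tibble::tibble(id = segs$parent_id,
                                     label = segs$label), seed = 1)
  role <- plan$role[match(segs$parent_id, plan$id)]
  test_parents <- unique(segs$parent_id[role == "test"])
  pool_parents <- unique(segs$parent_id[role == "pool"])
  expect_length(intersect(test_parents, pool_parents), 0)
})

test_that("oversampling balances classes with label-preserving augmentation", {
  set.seed(5)
  segs <- dplyr::bind_rows(
    suppressWarnings(make_segment_table(2, cfg = synth_config(seed = 5))),
    make_segment_table(2, cfg = synth_config(seed = 6)))
  # (10, 100, 10)-style imbalance in miniature: drop most of two classes
  unbal <- segs[c(which(segs$label == "normal"),
                  which(segs$label == "abnormal")[1],
                  which(segs$label == "noise")[1]), ]
  bal <- balance_classes(unbal, seed = 9)
  expect_equal(unname(table(bal$label)), rep(4L, 3), ignore_attr = TRUE)

  # already balanced input is returned as-is
  expect_identical(balance_classes(segs, seed = 9), segs)

  # augmented copies share the label but not the samples of their source
  aug <- bal[grepl("_aug", bal$segment_id), ]
  for (i in seq_len(nrow(aug))) {
    src_id <- sub("_aug[0-9]+$", "", aug$segment_id[i])
    src <- bal[bal$segment_id == src_id, ]
    expect_equal(aug$label[i], src$label[1])
    expect_false(identical(aug$samples[[i]], src$samples[[1]]))
    expect_equal(length(aug$samples[[i]]), 4000L)
  }
})

test_that("metrics reproduce the worked binary example exactly", {
  cm <- matrix(c(9, 2, 1, 8), 2, 2,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- evaluate_metrics(cm)
  expect_equal(rep$accuracy, 0.85)
  pos <- rep$per_class[rep$per_class$class == "pos", ]
  expect_equal(pos$sensitivity, 0.9)
  expect_equal(pos$specificity, 0.8)
  expect_equal(pos$precision, 9 / 11)
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(11)
  for (rep_i in 1:25) {
    cm <- matrix(rpois(9, 8), 3, 3,
                 dimnames = list(c("normal", "abnormal", "noise"),
                                 c("normal", "abnormal", "noise")))
    if (sum(cm) == 0) next
    r <- evaluate_metrics(cm)
    expect_equal(r$accuracy, sum(diag(cm)) / sum(cm))
    for (i in 1:3) {
      tp <- cm[i, i]
      expect_equal(tp + sum(cm[i, -i]), sum(cm[i, ])) # TP + FN = row sum
      expect_equal(tp + sum(cm[-i, i]), sum(cm[, i])) # TP + FP = col sum
      sens <- r$per_class$sensitivity[i]
      if (!is.nan(sens)) expect_equal(sens, tp / sum(cm[i, ]))
    }
    vals <- unlist(r$macro)
    expect_true(all(vals[!is.nan(vals)] >= 0 & vals[!is.nan(vals)] <= 1))
  }
})

test_that("degenerate predictors and empty denominators are handled", {
  # everything predicted as one class on balanced data: accuracy 1/3
  cm <- confusion_matrix(rep(c("normal", "abnormal", "noise"), each = 10),
                         rep("normal", 30))
  w <- testthat::capture_warnings(r <- evaluate_metrics(cm))
  expect_length(w, 2) # precision undefined for both unpredicted classes
  expect_match(w, "zero denominator", all = TRUE)
  expect_equal(r$accuracy, 1 / 3)
  expect_true(is.nan(r$per_class$precision[2]))

  perfect <- evaluate_metrics(diag(c(5, 5, 5)))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$per_class$sensitivity, rep(1, 3))

  expect_error(confusion_matrix("normal", "murmur"), "class_levels")
})

test_that("cross-validation trains on disjoint folds and averages accuracies", {
  segs <- make_segment_table(10, duration_s = 2, cfg = synth_config(seed = 3))
  segs <- extract_features(segs)
  cv <- cross_validate(segs, "LSTM (6)-FC (3)", epochs = 2, batch_size = 8,
                       seed = 5)
  accs <- vapply(cv$fold_reports, `[[`, 0, "accuracy")
  expect_length(accs, 5)
  expect_equal(cv$mean_accuracy, mean(accs))
  expect_equal(nrow(glance(cv)), 1)
  expect_equal(sort(unique(tidy(cv)$fold)), 1:5)

  # the plan's folds partition the pool; test rows have no fold
  plan <- cv$plan
  expect_setequal(plan$fold[plan$role == "pool"], 1:5)
  expect_true(all(is.na(plan$fold[plan$role == "test"])))

  # per-fold histories tracked validation on the held-out fold
  expect_true(all(c("val_loss", "val_accuracy") %in% names(cv$history)))
})
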