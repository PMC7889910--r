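test_that("split sizes follow floor-with-train-first-remainder", {
  labels <- class_label(rep(0:2, c(55, 89, 56)))
  parts <- split_data(labels, split_spec(seed = 1))
  expect_equal(lengths(parts[c("train", "validation", "test")]),
               c(train = 140L, validation = 30L, test = 30L))
  # disjoint and exhaustive
  all_idx <- sort(unlist(parts))
  expect_equal(unname(all_idx), seq_along(labels))

  # (1, 0, 0) puts everything in train
  p1 <- split_data(labels, split_spec(c(1, 0, 0)))
  expect_length(p1$train, 200L)
  expect_length(p1$test, 0L)

  # determinism
  pa <- split_data(labels, split_spec(seed = 42))
  pb <- split_data(labels, split_spec(seed = 42))
  expect_identical(pa, pb)
})

test_that("stratified split preserves class proportions within one sample", {
  labels <- class_label(rep(0:2, c(55, 89, 56)))
  parts <- split_data(labels, split_spec(seed = 3))
  for (nm in names(parts)) {
    tab <- table(labels[parts[[nm]]])
    frac <- c(0.70, 0.15, 0.15)[match(nm, names(parts))]
    for (cl in class_levels()) {
      expect_lte(abs(tab[[cl]] - sum(labels == cl) * frac), 1.0)
    }
  }
})

test_that("grouped samples never straddle partitions", {
  labels <- class_label(rep(0:2, each = 20))
  groups <- rep(sprintf("g%02d", 1:30), 2)  # each group: one original + one copy
  parts <- split_data(labels, split_spec(seed = 5), groups = groups)
  for (nm in names(parts)) {
    gs <- groups[parts[[nm]]]
    other <- setdiff(unlist(parts), parts[[nm]])
    expect_length(intersect(gs, groups[other]), 0L)
  }
})

test_that("split errors when a positive fraction gets no samples", {
  labels <- class_label(c(0, 1))
  expect_error(split_data(labels, split_spec(c(0.34, 0.33, 0.33))),
               "not enough samples|zero samples")
})

test_that("confusion matrix counts by true row / predicted column", {
  cm <- confusion(class_label(c(0, 0, 1, 2)), class_label(c(0, 1, 1, 2)))
  expect_equal(cm["EGC", "EGC"], 1L)
  expect_equal(cm["EGC", "AGC"], 1L)
  expect_equal(cm["AGC", "AGC"], 1L)
  expect_equal(cm["HEALTHY", "HEALTHY"], 1L)
  expect_equal(sum(cm), 4L)

  perfect <- confusion(rep(0:2, each = 10), rep(0:2, each = 10))
  expect_equal(diag(perfect), c(EGC = 10L, AGC = 10L, HEALTHY = 10L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  all_egc <- confusion(rep(0:2, each = 2), rep(0L, 6))
  expect_equal(sum(all_egc[, c("AGC", "HEALTHY")]), 0L)

  expect_error(confusion(0:1, 0L), "length mismatch")
})

test_that("confusion counts are invariant to sample order", {
  withr::with_seed(14, {
    truth <- sample(0:2, 40, replace = TRUE)
    pred <- sample(0:2, 40, replace = TRUE)
    perm <- sample(40)
  })
  expect_equal(confusion(truth, pred), confusion(truth[perm], pred[perm]))
})

test_that("one-vs-rest collapse partitions the total for every class", {
  cm <- confusion(class_label(c(0, 0, 1, 2)), class_label(c(0, 1, 1, 2)))
  bc <- binary_counts(cm, "EGC")
  expect_equal(bc, c(TP = 1L, TN = 2L, FP = 0L, FN = 1L))
  for (cl in class_levels()) {
    expect_equal(sum(binary_counts(cm, cl)), sum(cm))
  }
  perfect <- confusion(rep(0:2, 5), rep(0:2, 5))
  for (cl in class_levels()) {
    bc <- binary_counts(perfect, cl)
    expect_equal(bc[["FP"]] + bc[["FN"]], 0L)
  }
})

test_that("precision, recall and F behave per definition with NA on 0/0", {
  expect_equal(precision_score(10, 0), 1)
  expect_equal(recall_score(1, 1), 0.5)
  expect_true(is.na(precision_score(0, 0)))
  expect_true(is.na(recall_score(0, 0)))
  expect_true(is.na(f_score(0, 0)))
  expect_true(is.na(f_score(NA_real_, 0.5)))
  expect_error(precision_score(-1, 0))

  # harmonic mean of equals is the value itself; F between min and max
  for (x in c(0.2, 0.5, 1)) expect_equal(f_score(x, x), x)
  withr::with_seed(2, {
    ps <- runif(20); rs <- runif(20)
  })
  f <- mapply(f_score, ps, rs)
  expect_true(all(f >= pmin(ps, rs) - 1e-12 & f <= pmax(ps, rs) + 1e-12))
})

test_that("accuracy is trace over total", {
  perfect <- confusion(rep(0:2, 4), rep(0:2, 4))
  expect_equal(accuracy(perfect), 1)
  uniform <- matrix(3L, 3, 3, dimnames = list(true = class_levels(),
                                              predicted = class_levels()))
  expect_equal(accuracy(uniform), 1 / 3)
  cm <- confusion(class_label(c(0, 0, 1, 2)), class_label(c(0, 1, 1, 2)))
  expect_equal(accuracy(cm), 3 / 4)
})

test_that("ROC handles the canonical cases", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)  # 4 pairs: 3 concordant, 1 discordant

  sep <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sep$auc, 1)

  tied <- roc_curve(rep(0.5, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")

  # curve is monotone nondecreasing in both coordinates
  withr::with_seed(10, {
    sc <- round(runif(30), 2)
    lab <- runif(30) < 0.4
  })
  rr <- roc_curve(sc, lab)
  expect_true(all(diff(rr$fpr) >= 0))
  expect_true(all(diff(rr$tpr) >= 0))
  expect_gte(rr$auc, 0)
  expect_lte(rr$auc, 1)
})

test_that("trapezoid AUC equals brute-force pair counting on small inputs", {
  set.seed(77)
  for (rep in 1:60) {
    n <- sample(2:12, 1)
    pos <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    # discrete scores force ties regularly
    sc <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(roc_curve(sc, pos)$auc, pairwise_auc(sc, pos),
                 tolerance = 1e-12)
  }
})

test_that("trapezoid AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(21, {
    sc <- runif(50)
    lab <- runif(50) < 0.5
    lab[1:2] <- c(TRUE, FALSE)
  })
  ours <- roc_curve(sc, lab)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = sc,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("metrics_report is internally consistent and flags undefined cells", {
  truth <- class_label(c(0, 0, 1, 2, 1, 2))
  pred <- class_label(c(0, 1, 1, 2, 1, 0))
  rep1 <- metrics_report(truth, pred)
  pc <- rep1$per_class
  # per-class F equals f_score(P, R) recomputed from the same report
  for (i in seq_len(nrow(pc))) {
    if (pc$f_score_defined[i]) {
      expect_equal(pc$f_score[i], f_score(pc$precision[i], pc$recall[i]),
                   tolerance = 1e-12)
    }
  }
  expect_equal(rep1$accuracy, accuracy(rep1$confusion))

  # never-predicted class: precision undefined, flagged, reported as 0
  truth2 <- class_label(c(0, 0, 1, 1))
  pred2 <- class_label(c(0, 0, 0, 0))
  rep2 <- metrics_report(truth2, pred2)
  agc_row <- rep2$per_class[rep2$per_class$class == "AGC", ]
  expect_false(agc_row$precision_defined)
  expect_equal(agc_row$precision, 0)

  # perfect predictions: everything 1
  repp <- metrics_report(rep(0:2, 4), rep(0:2, 4),
                         prob = diag(3)[rep(1:3, 4), ])
  expect_equal(repp$accuracy, 1)
  expect_equal(repp$macro_f, 1)
  expect_equal(repp$macro_auc, 1)
})

test_that("random confusion matrices satisfy the counting identities", {
  set.seed(33)
  for (rep in 1:50) {
    n <- sample(3:40, 1)
    truth <- sample(0:2, n, replace = TRUE)
    pred <- sample(0:2, n, replace = TRUE)
    cm <- confusion(truth, pred)
    expect_equal(sum(cm), n)
    acc <- accuracy(cm)
    expect_gte(acc, 0); expect_lte(acc, 1)
    for (cl in class_levels()) expect_equal(sum(binary_counts(cm, cl)), n)
  }
})
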