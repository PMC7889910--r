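#' Train/validation/test split specification
#'
#' @param fractions Three fractions (train, validation, test) summing to 1;
#'   default 0.70/0.15/0.15. The alternative 0.75/0.25/0 preset matches a
#'   two-way training/validation protocol.
#' @param stratified Preserve class proportions per partition (default TRUE).
#' @param seed Integer seed for the shuffle.
#' @return A `split_spec` list.
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), stratified = TRUE,
                       seed = 1L) {
  stopifnot(length(fractions) == 3L, all(fractions >= 0), all(fractions <= 1),
            abs(sum(fractions) - 1) < 1e-9)
  structure(list(fractions = fractions, stratified = isTRUE(stratified),
                 seed = as.integer(seed)), class = "split_spec")
}

allocate_counts <- function(n, fractions) {
  sizes <- floor(n * fractions)
  rem <- n - sum(sizes)
  i <- 1L
  while (rem > 0L) {  # remainders assigned train-first
    if (fractions[i] > 0 || all(fractions == 0)) {
      sizes[i] <- sizes[i] + 1L
      rem <- rem - 1L
    }
    i <- if (i == 3L) 1L else i + 1L
  }
  sizes
}

#' Split samples into disjoint train/validation/test index sets
#'
#' Partition sizes follow floor(n * fraction) with remainders assigned
#' train-first. With `stratified = TRUE` the allocation is done per
#' class. When `groups` is given (e.g. augmented copies sharing a source
#' sample), all members of a group land in the same partition, so an
#' augmented copy can never leak into a different partition than its
#' source.
#'
#' @param labels Class labels (length n).
#' @param spec A [split_spec()].
#' @param groups Optional character vector of group ids (length n).
#' @return List of integer index vectors `train`, `validation`, `test`.
#' @export
split_data <- function(labels, spec = split_spec(), groups = NULL) {
  labels <- class_label(labels)
  n <- length(labels)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  stopifnot(length(groups) == n)

  # one representative label per group (groups are label-pure by construction)
  gids <- unique(groups)
  glab <- labels[match(gids, groups)]
  ng <- length(gids)
  if (ng < sum(spec$fractions > 0)) {
    stop("not enough samples for the requested positive fractions")
  }

  # global partition sizes: floor(n * fraction), remainders train-first
  global_sizes <- allocate_counts(ng, spec$fractions)

  strata <- if (spec$stratified) split(seq_len(ng), glab) else list(all = seq_len(ng))
  strata <- strata[lengths(strata) > 0L]
  # per-stratum sizes by controlled rounding: start from floors, then give
  # the remaining units to the (stratum, partition) cells with the largest
  # fractional remainders while respecting the global partition totals
  floors <- t(vapply(strata, function(st)
    floor(length(st) * spec$fractions), numeric(3)))
  targets <- t(vapply(strata, function(st)
    length(st) * spec$fractions, numeric(3)))
  remainders <- targets - floors
  stratum_deficit <- lengths(strata) - rowSums(floors)
  part_deficit <- global_sizes - colSums(floors)
  cells <- expand.grid(s = seq_along(strata), p = 1:3)
  cells <- cells[order(-remainders[as.matrix(cells)], cells$p, cells$s), ]
  while (any(stratum_deficit > 0)) {
    progressed <- FALSE
    for (r in seq_len(nrow(cells))) {
      s <- cells$s[r]; p <- cells$p[r]
      if (stratum_deficit[s] > 0 && part_deficit[p] > 0) {
        floors[s, p] <- floors[s, p] + 1
        stratum_deficit[s] <- stratum_deficit[s] - 1
        part_deficit[p] <- part_deficit[p] - 1
        progressed <- TRUE
      }
    }
    if (!progressed) stop("internal error: split allocation did not converge")
  }

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(spec$seed)
  assign_part <- integer(ng)
  for (k in seq_along(strata)) {
    st <- strata[[k]]
    st <- st[sample.int(length(st))]
    assign_part[st] <- rep.int(1:3, floors[k, ])
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  for (p in which(spec$fractions > 0)) {
    if (!any(assign_part == p)) {
      stop("positive fraction ", c("train", "validation", "test")[p],
           " received zero samples")
    }
  }
  part_of_sample <- assign_part[match(groups, gids)]
  list(train = which(part_of_sample == 1L),
       validation = which(part_of_sample == 2L),
       test = which(part_of_sample == 3L))
}

#' Confusion matrix for the three-class problem
#'
#' Rows are true classes, columns predicted, both ordered
#' EGC, AGC, HEALTHY.
#'
#' @param truth,predicted Aligned label vectors.
#' @return 3 x 3 integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(truth, predicted) {
  truth <- class_label(truth)
  predicted <- class_label(predicted)
  if (length(truth) != length(predicted)) stop("label length mismatch")
  if (length(truth) < 1L) stop("empty label vectors")
  cm <- table(truth = truth, predicted = predicted)
  out <- matrix(as.integer(cm), 3L, 3L,
                dimnames = list(true = class_levels(),
                                predicted = class_levels()))
  class(out) <- c("confusion_matrix", class(out))
  out
}

#' @export
print.confusion_matrix <- function(x, ...) {
  y <- x
  attr(y, "class") <- NULL
  print(y, ...)
  invisible(x)
}

#' One-vs-rest binary counts for a class
#'
#' @param cm A [confusion()] matrix.
#' @param positive Class treated as positive.
#' @return Named vector `TP`, `TN`, `FP`, `FN`; the four always sum to
#'   the matrix total.
#' @export
binary_counts <- function(cm, positive) {
  positive <- as.character(class_label(positive))
  tp <- cm[positive, positive]
  fn <- sum(cm[positive, ]) - tp
  fp <- sum(cm[, positive]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, TN = tn, FP = fp, FN = fn)
}

#' Precision, recall, F-score and accuracy
#'
#' Precision = TP/(TP+FP); Recall = TP/(TP+FN);
#' F = 2 P R / (P + R). A zero denominator yields `NA` (an explicit
#' undefined marker, never a silent zero); reports carry a `defined`
#' flag alongside each value.
#'
#' @param tp,fp,fn Nonnegative counts.
#' @return A single number in [0,1], or `NA` when undefined.
#' @export
precision_score <- function(tp, fp) {
  stopifnot(tp >= 0, fp >= 0)
  if (tp + fp == 0) NA_real_ else tp / (tp + fp)
}

#' @rdname precision_score
#' @export
recall_score <- function(tp, fn) {
  stopifnot(tp >= 0, fn >= 0)
  if (tp + fn == 0) NA_real_ else tp / (tp + fn)
}

#' @rdname precision_score
#' @param precision,recall Values in [0,1] (or `NA`).
#' @export
f_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  stopifnot(precision >= 0, precision <= 1, recall >= 0, recall <= 1)
  if (precision + recall == 0) return(NA_real_)
  2 * precision * recall / (precision + recall)
}

#' Overall accuracy of a confusion matrix
#'
#' Multiclass accuracy is trace/total; the binary one-vs-rest form
#' (TN+TP)/n for a single class is available through [binary_counts()].
#'
#' @param cm A [confusion()] matrix.
#' @return Accuracy in [0,1].
#' @export
accuracy <- function(cm) {
  total <- sum(cm)
  if (total < 1) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' One-vs-rest ROC curve and AUC
#'
#' Threshold sweep over the unique scores; AUC by the trapezoidal rule,
#' which equals the Mann-Whitney concordance probability with ties
#' counted 1/2.
#'
#' @param scores Numeric score for the positive class, higher = more
#'   positive.
#' @param truth Label vector (any type accepted by [class_label()]), or
#'   a logical vector of positives.
#' @param positive Positive class (ignored when `truth` is logical).
#' @return A `roc_points` list: `thresholds`, `fpr`, `tpr`, `auc`.
#' @export
roc_curve <- function(scores, truth, positive = "EGC") {
  pos <- if (is.logical(truth)) truth
         else class_label(truth) == as.character(class_label(positive))
  stopifnot(length(scores) == length(pos))
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative sample")
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = thr, fpr = fpr, tpr = tpr, auc = auc),
            class = "roc_points")
}

class_metrics_row <- function(cm, cls) {
  bc <- binary_counts(cm, cls)
  p <- precision_score(bc["TP"], bc["FP"])
  r <- recall_score(bc["TP"], bc["FN"])
  f <- f_score(p, r)
  data.frame(class = cls, TP = bc["TP"], TN = bc["TN"], FP = bc["FP"],
             FN = bc["FN"],
             precision = ifelse(is.na(p), 0, p), precision_defined = !is.na(p),
             recall = ifelse(is.na(r), 0, r), recall_defined = !is.na(r),
             f_score = ifelse(is.na(f), 0, f), f_score_defined = !is.na(f),
             accuracy_ovr = (bc["TP"] + bc["TN"]) / sum(bc),
             row.names = NULL)
}

#' Full metrics report for a set of predictions
#'
#' Confusion matrix, per-class one-vs-rest precision/recall/F-score (with
#' defined-ness flags for 0/0 cases), overall trace/total accuracy,
#' macro averages (over classes with defined values), and, when class
#' probabilities are supplied, per-class one-vs-rest AUC plus macro AUC.
#'
#' @param truth True labels.
#' @param predicted Predicted labels.
#' @param prob Optional n x 3 class-probability matrix (columns ordered
#'   EGC, AGC, HEALTHY).
#' @return A `metrics_report` list: `confusion`, `per_class` (data.frame),
#'   `accuracy`, `macro_precision`, `macro_recall`, `macro_f`, `auc`
#'   (named per-class vector or NULL), `macro_auc`, `n`.
#' @export
metrics_report <- function(truth, predicted, prob = NULL) {
  cm <- confusion(truth, predicted)
  per_class <- do.call(rbind, lapply(class_levels(), function(cl)
    class_metrics_row(cm, cl)))
  macro <- function(col, flag) {
    v <- per_class[[col]][per_class[[flag]]]
    if (length(v) == 0L) NA_real_ else mean(v)
  }
  auc <- NULL; macro_auc <- NULL
  if (!is.null(prob)) {
    prob <- as.matrix(prob)
    if (is.null(colnames(prob))) colnames(prob) <- class_levels()
    truth_lab <- class_label(truth)
    auc <- vapply(class_levels(), function(cl) {
      if (length(unique(truth_lab == cl)) < 2L) return(NA_real_)
      roc_curve(prob[, cl], truth_lab, positive = cl)$auc
    }, numeric(1))
    macro_auc <- mean(auc, na.rm = TRUE)
  }
  structure(list(confusion = cm, per_class = per_class,
                 accuracy = accuracy(cm),
                 macro_precision = macro("precision", "precision_defined"),
                 macro_recall = macro("recall", "recall_defined"),
                 macro_f = macro("f_score", "f_score_defined"),
                 auc = auc, macro_auc = macro_auc, n = sum(cm)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d accuracy=%.3f macroF=%.3f%s\n",
              x$n, x$accuracy, x$macro_f,
              if (!is.null(x$macro_auc)) sprintf(" macroAUC=%.3f", x$macro_auc)
              else ""))
  print(x$confusion)
  invisible(x)
}

#' Evaluate a trained model on partitioned features
#'
#' Produces one [metrics_report()] per partition (train, validation,
#' test) plus the pooled report over all evaluated samples.
#'
#' @param model An [ssae_model()].
#' @param fm A scaled `feature_matrix`.
#' @param partitions List of index vectors as returned by [split_data()].
#' @return Named list of `metrics_report`s (`train`, `validation`,
#'   `test`, `all`; empty partitions are skipped).
#' @export
evaluate_model <- function(model, fm, partitions) {
  used <- sort(unlist(partitions, use.names = FALSE))
  parts <- c(partitions, list(all = used))
  out <- list()
  for (nm in names(parts)) {
    idx <- parts[[nm]]
    if (length(idx) == 0L) next
    pred <- predict(model, fm$values[idx, , drop = FALSE])
    out[[nm]] <- metrics_report(fm$labels[idx], pred$labels, pred$prob)
  }
  out
}

#' Export a metrics report to JSON and CSV
#'
#' Writes `<stem>.json` (full report), `<stem>_per_class.csv` and
#' `<stem>_confusion.csv`.
#'
#' @param report A `metrics_report`.
#' @param stem Output path stem (no extension).
#' @export
write_metrics <- function(report, stem) {
  js <- list(n = report$n, accuracy = report$accuracy,
             macro_precision = report$macro_precision,
             macro_recall = report$macro_recall,
             macro_f = report$macro_f,
             auc = as.list(report$auc), macro_auc = report$macro_auc,
             confusion = unclass(report$confusion),
             per_class = report$per_class)
  jsonlite::write_json(js, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(report$per_class, paste0(stem, "_per_class.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(unclass(report$confusion)),
                   paste0(stem, "_confusion.csv"))
  invisible(stem)
}
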