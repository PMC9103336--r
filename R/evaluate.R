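# Nested stratified cross-validation harness, classification metrics,
# recording-level majority voting and per-minute error rates. The good
# quality class is the positive label throughout.

#' Stratified fold assignment
#'
#' Items of each class are shuffled and dealt round-robin, so per-fold
#' class counts differ from the ideal proportional count by at most one.
#' With `grouping = "recording"` all segments of one recording share a
#' fold; stratification then applies at the recording level.
#'
#' @param labels character vector of class labels.
#' @param k number of folds.
#' @param seed integer seed.
#' @param grouping `"segment"` (default) or `"recording"`.
#' @param groups recording ids, required when `grouping = "recording"`.
#' @return Integer vector of fold indices in `1..k`, one per item.
#' @export
stratified_folds <- function(labels, k, seed = 1L, grouping = "segment",
                             groups = NULL) {
  k <- as.integer(k)
  if (grouping == "recording") {
    if (is.null(groups)) stop("groups required for recording-level folds")
    ug <- unique(groups)
    glab <- vapply(ug, function(g) labels[match(g, groups)], character(1))
    gf <- stratified_folds(glab, k, seed = seed)
    return(gf[match(groups, ug)])
  }
  if (k < 2L) stop("k must be >= 2")
  if (min(table(labels)) < k) {
    stop("k exceeds the minority class count")
  }
  set.seed(as.integer(seed))
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

# AUC via the rank statistic (Mann-Whitney, mid-ranks for ties)
.rank_auc <- function(scores, y) {
  y <- as.integer(y)
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics at a threshold
#'
#' Accuracy, precision, recall and F1 from the confusion matrix at the
#' threshold, plus AUC from the rank statistic over the scores. The good
#' class is positive.
#'
#' @param scores numeric vector of good-class scores.
#' @param labels class labels (`"good"`/`"bad"` or 1/0).
#' @param threshold decision threshold on the scores.
#' @return Named list: `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  y <- .as_binary_labels(labels)
  if (length(unique(y)) < 2L) stop("AUC undefined: only one class present")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & y == 1L); fp <- sum(pred == 1L & y == 0L)
  tn <- sum(pred == 0L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  list(accuracy = (tp + tn) / length(y), precision = precision,
       recall = recall, f1 = f1, auc = .rank_auc(scores, y),
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' False-prediction rates per minute
#'
#' @param fp,fn false positive / false negative counts.
#' @param total_minutes minutes of evaluated signal.
#' @return Named list `fp_per_min`, `fn_per_min`.
#' @export
error_rate_per_minute <- function(fp, fn, total_minutes) {
  if (total_minutes <= 0) stop("total_minutes must be positive")
  list(fp_per_min = fp / total_minutes, fn_per_min = fn / total_minutes)
}

#' Recording label by majority vote over segment labels
#'
#' Ties resolve to `"bad"`: when segment votes are split it is preferable
#' to reject the borderline recording and repeat it.
#'
#' @param segment_labels character vector of `"good"`/`"bad"` votes.
#' @return `"good"` or `"bad"`.
#' @export
majority_vote <- function(segment_labels) {
  if (!length(segment_labels)) stop("empty vote list")
  if (sum(segment_labels == "good") > length(segment_labels) / 2) "good" else "bad"
}

#' Cross-validation fold specification
#'
#' @param outer_k outer folds (testing).
#' @param inner_k inner folds (validation / model selection).
#' @param repetitions number of repetitions with re-randomized folds.
#' @param grouping `"segment"` or `"recording"` (no-leakage variant).
#' @param seed integer master seed.
#' @return An object of class `fold_spec`.
#' @export
fold_spec <- function(outer_k = 10, inner_k = 5, repetitions = 1,
                      grouping = "segment", seed = 1L) {
  if (outer_k < 2 || inner_k < 2) stop("outer_k and inner_k must be >= 2")
  structure(list(outer_k = as.integer(outer_k), inner_k = as.integer(inner_k),
                 repetitions = as.integer(repetitions), grouping = grouping,
                 seed = as.integer(seed)), class = "fold_spec")
}

# ---- learners --------------------------------------------------------------

#' Classical learner for the nested CV harness
#' @param grid a `grid_spec`.
#' @return A learner object for [nested_cv()].
#' @export
learner_classical <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  structure(list(
    name = grid$model_type,
    fit_select = function(data, idx, inner_k, seed) {
      train_benchmark(data$X[idx, , drop = FALSE], data$y[idx], grid,
                      inner_folds = inner_k, seed = seed)
    },
    predict = function(model, data, idx) {
      predict_benchmark(model, data$X[idx, , drop = FALSE])
    }), class = "cv_learner")
}

#' CNN learner for the nested CV harness
#'
#' Inside each outer-training split, each inner fold in turn serves as the
#' validation set; the training run whose best epoch attains the highest
#' validation AUC supplies the weights evaluated on the outer test fold.
#'
#' @param arch an `arch_config`.
#' @param config a `train_config`.
#' @return A learner object for [nested_cv()].
#' @export
learner_cnn <- function(arch = arch_config(), config = train_config()) {
  structure(list(
    name = "cnn",
    fit_select = function(data, idx, inner_k, seed) {
      folds <- stratified_folds(data$y[idx], inner_k, seed = seed)
      best <- NULL; best_auc <- -Inf
      for (f in seq_len(inner_k)) {
        tr <- idx[folds != f]; va <- idx[folds == f]
        cfg <- config
        cfg$seed <- seed + f
        mdl <- build_model(arch, seed = seed + f)
        res <- train_cnn(mdl, data$X[, , , tr, drop = FALSE], data$y[tr],
                         data$X[, , , va, drop = FALSE], data$y[va], cfg)
        auc <- max(res$history$val_auc)
        if (auc > best_auc) { best_auc <- auc; best <- res$model }
      }
      best
    },
    predict = function(model, data, idx) {
      predict_cnn(model, data$X[, , , idx, drop = FALSE])
    }), class = "cv_learner")
}

#' Nested stratified cross-validation
#'
#' The outer loop holds out one fold for testing; the remaining data enter
#' the inner loop, which selects the best model (best-epoch weights for the
#' CNN, best grid point for classical learners) by inner-fold validation
#' AUC. The winner is evaluated once on the held-out outer fold. The whole
#' procedure is repeated `repetitions` times with re-randomized folds; the
#' aggregate is the mean and sample (n-1) standard deviation over all outer
#' evaluations.
#'
#' @param data for a classical learner, list with `X` (n x 45 feature
#'   matrix) and `y` (labels); for the CNN learner, list with `X`
#'   (H x W x n_paths x n array) and `y`. An optional `recording_id` vector
#'   enables recording-level grouping and majority voting.
#' @param learner a `cv_learner` from [learner_classical()] or
#'   [learner_cnn()].
#' @param spec a `fold_spec`.
#' @return An object of class `cv_result`: `records` (per repetition x
#'   outer fold metric data.frame), `aggregate` (mean and sd per metric),
#'   `confusion` (summed TP/FP/TN/FN), `votes` (per-recording majority-vote
#'   data.frame, when recording ids are supplied).
#' @export
nested_cv <- function(data, learner, spec = fold_spec()) {
  stopifnot(inherits(learner, "cv_learner"), inherits(spec, "fold_spec"))
  y <- data$y
  n <- length(y)
  records <- NULL
  conf <- c(tp = 0L, fp = 0L, tn = 0L, fn = 0L)
  votes <- NULL
  seg_pred <- rep(NA_character_, n)
  for (rep_i in seq_len(spec$repetitions)) {
    rep_seed <- spec$seed + 1000L * (rep_i - 1L)
    folds <- stratified_folds(y, spec$outer_k, seed = rep_seed,
                              grouping = spec$grouping,
                              groups = data$recording_id)
    for (f in seq_len(spec$outer_k)) {
      tr <- which(folds != f); te <- which(folds == f)
      if (length(unique(y[tr])) < 2L) stop("single-class outer training split")
      model <- learner$fit_select(data, tr, spec$inner_k, rep_seed + f)
      scores <- learner$predict(model, data, te)
      m <- compute_metrics(scores, y[te])
      conf <- conf + c(tp = m$tp, fp = m$fp, tn = m$tn, fn = m$fn)
      seg_pred[te] <- ifelse(scores > 0.5, "good", "bad")
      records <- rbind(records, data.frame(
        repetition = rep_i, fold = f, accuracy = m$accuracy,
        precision = m$precision, recall = m$recall, f1 = m$f1, auc = m$auc))
    }
    if (!is.null(data$recording_id) && rep_i == 1L) {
      votes <- do.call(rbind, lapply(unique(data$recording_id), function(rid) {
        sel <- data$recording_id == rid
        data.frame(recording_id = rid,
                   true_label = y[sel][1],
                   voted_label = majority_vote(seg_pred[sel]),
                   stringsAsFactors = FALSE)
      }))
    }
  }
  metric_cols <- c("accuracy", "precision", "recall", "f1", "auc")
  aggregate <- data.frame(
    metric = metric_cols,
    mean = vapply(metric_cols, function(mc) mean(records[[mc]]), numeric(1)),
    sd = vapply(metric_cols, function(mc) stats::sd(records[[mc]]), numeric(1))
  )
  structure(list(records = records, aggregate = aggregate, confusion = conf,
                 votes = votes, learner = learner$name),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result: %s> %d outer evaluations\n", x$learner,
              nrow(x$records)))
  for (i in seq_len(nrow(x$aggregate))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", x$aggregate$metric[i],
                x$aggregate$mean[i], x$aggregate$sd[i]))
  }
  invisible(x)
}
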