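#' Phase sets of the three training strategies
#'
#' Strategy S1 trains on reaching + resting windows, S2 on grasping +
#' resting, S3 on reaching + grasping + resting. The returning phase is
#' never used for training under any strategy.
#'
#' @param strategy one of `"S1"`, `"S2"`, `"S3"`.
#' @return Character vector of phase names.
#' @export
strategy_phases <- function(strategy = c("S1", "S2", "S3")) {
  strategy <- match.arg(strategy)
  switch(strategy,
         S1 = c("reaching", "resting"),
         S2 = c("grasping", "resting"),
         S3 = c("reaching", "grasping", "resting"))
}

#' Per-object 3-fold split plan
#'
#' Each object's 6 trials are randomly partitioned into 3 disjoint pairs;
#' fold f validates on pair f and trains on the remaining 4 trials (66.7% /
#' 33.3% shares). Every trial is validated exactly once across the folds.
#'
#' @param manifest session manifest with `trial_id` and `object_id`.
#' @param seed integer seed for the pair assignment.
#' @param n_folds number of folds (trials per object must be divisible by
#'   it).
#' @return Data frame `trial_id`, `object_id`, `fold` (the fold in which
#'   the trial is validation).
#' @export
build_split <- function(manifest, seed = 1L, n_folds = 3L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  objects <- unique(manifest$object_id)
  rows <- lapply(objects, function(ob) {
    ids <- manifest$trial_id[manifest$object_id == ob]
    if (length(ids) %% n_folds != 0L)
      stop(sprintf("object %s has %d trials, not divisible into %d folds",
                   ob, length(ids), n_folds))
    per <- length(ids) %/% n_folds
    data.frame(trial_id = sample(ids), object_id = ob,
               fold = rep(seq_len(n_folds), each = per))
  })
  do.call(rbind, rows)
}

#' Select training windows for a strategy
#'
#' Keeps only windows whose (centre-sample) phase belongs to the
#' strategy's phase set; resting windows carry the rest label 0, motional
#' windows the trial gesture. Returning-phase windows are excluded by
#' construction.
#'
#' @param features feature table with `phase` and `label` columns.
#' @param strategy `"S1"`, `"S2"` or `"S3"`.
#' @return Filtered feature table.
#' @export
select_training_windows <- function(features, strategy) {
  keep <- features$phase %in% strategy_phases(strategy)
  if (!any(keep)) stop("strategy selects no training windows")
  features[keep, , drop = FALSE]
}

# Columns of a feature table holding the 3C feature contract, in order.
feature_columns <- function(features) {
  grep("^(rms|mav|var)_", names(features), value = TRUE)
}

#' Train the gesture classifier
#'
#' Fits an ensemble of 50 extremely randomized trees (extra-trees: no
#' bootstrap, full sample per tree, random split thresholds) on the
#' `3C`-dimensional window features, predicting the 14 classes 0 (rest)
#' and 1..13 (grasp gestures). The feature column order is recorded as a
#' contract and enforced at prediction time.
#'
#' @param features training feature table (see [featurize_session()]),
#'   already filtered by [select_training_windows()].
#' @param n_trees ensemble size.
#' @param seed integer seed for the tree randomization.
#' @param classes full class set of the task.
#' @param strategy optional strategy tag stored in the model.
#' @return Object of class `gesture_model`.
#' @export
train_gesture_model <- function(features, n_trees = 50, seed = 1L,
                                classes = 0:13, strategy = NULL) {
  cols <- feature_columns(features)
  if (!length(cols)) stop("no feature columns found")
  y <- factor(features$label, levels = sort(unique(features$label)))
  if (nlevels(y) < 2L) stop("training data contains a single class")
  df <- features[, cols, drop = FALSE]
  df$.label <- y
  fit <- ranger::ranger(
    dependent.variable.name = ".label", data = df,
    num.trees = n_trees, splitrule = "extratrees", num.random.splits = 1,
    replace = FALSE, sample.fraction = 1, probability = TRUE,
    seed = seed, num.threads = 1
  )
  structure(list(fit = fit, feature_names = cols,
                 classes = classes,
                 trained_classes = as.integer(levels(y)),
                 n_trees = n_trees, seed = seed, strategy = strategy),
            class = "gesture_model")
}

#' @export
print.gesture_model <- function(x, ...) {
  cat(sprintf("<gesture_model> %d extra trees, %d features, classes {%s}%s\n",
              x$n_trees, length(x$feature_names),
              paste(x$trained_classes, collapse = ","),
              if (!is.null(x$strategy)) paste0(", strategy ", x$strategy) else ""))
  invisible(x)
}

#' Predicted class probabilities
#'
#' Returns, for every window, the full 14-class probability vector
#' (non-negative, summing to 1); classes absent from training get
#' probability 0.
#'
#' @param model a `gesture_model`.
#' @param features feature table (or matrix) containing the model's
#'   feature columns.
#' @return Numeric matrix, one row per window, columns named `"0".."13"`.
#' @export
predict_gesture_proba <- function(model, features) {
  if (is.matrix(features)) features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing))
    stop("feature columns missing: ", paste(missing, collapse = ", "))
  newx <- features[, model$feature_names, drop = FALSE]
  pr <- stats::predict(model$fit, data = newx, num.threads = 1)$predictions
  out <- matrix(0, nrow(pr), length(model$classes),
                dimnames = list(NULL, as.character(model$classes)))
  out[, colnames(pr)] <- pr
  out
}

#' Predicted class labels
#'
#' Argmax of [predict_gesture_proba()]; ties go to the lowest class index.
#'
#' @inheritParams predict_gesture_proba
#' @return Integer vector of class labels.
#' @export
predict_gesture <- function(model, features) {
  p <- predict_gesture_proba(model, features)
  model$classes[max.col(p, ties.method = "first")]
}
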