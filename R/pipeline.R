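#' Evaluate one training strategy over all folds
#'
#' For every fold, fits the extra-trees classifier on the strategy's
#' training windows of the fold's training trials, predicts all windows of
#' the fold's validation trials (and of their session predecessors, whose
#' trailing resting predictions provide the prepended rest context), and
#' aligns each validation trial at grasp onset. The aligned trials of all
#' folds are pooled into averaged curves and summary metrics.
#'
#' @param features session feature table from [featurize_session()].
#' @param split fold plan from [build_split()].
#' @param manifest session manifest (`trial_id`, `gesture`, `order`).
#' @param strategy `"S1"`, `"S2"` or `"S3"`.
#' @param b1_ms named vector of grasp-onset breakpoints (ms) per trial,
#'   normally from segmentation.
#' @param n_trees,model_seed classifier settings; the fold index is added
#'   to the seed so folds draw different trees but reruns are identical.
#' @param step_ms,prepend_ms alignment settings, see [align_trial()].
#' @param confusion_window time window of the pre-shaping confusion matrix;
#'   `NULL` uses `[t_i, 0]` when the curves cross, else `[-700, 0]`.
#' @return List of class `strategy_evaluation` with `strategy`, `curves`,
#'   `t_i_ms`, `d_p`, `t_peak_ms`, `phase_accuracy`, `confusion`,
#'   `n_trials`.
#' @export
evaluate_strategy <- function(features, split, manifest, strategy, b1_ms,
                              n_trees = 50, model_seed = 1L, step_ms = 40,
                              prepend_ms = 700, confusion_window = NULL) {
  prev_of <- stats::setNames(
    manifest$trial_id[match(manifest$order - 1L, manifest$order)],
    manifest$trial_id)
  gesture_of <- stats::setNames(manifest$gesture, manifest$trial_id)
  aligned <- list()
  for (f in sort(unique(split$fold))) {
    val_ids <- split$trial_id[split$fold == f]
    train_ids <- setdiff(split$trial_id, val_ids)
    train_feats <- select_training_windows(
      features[features$trial_id %in% train_ids, , drop = FALSE], strategy)
    model <- train_gesture_model(train_feats, n_trees = n_trees,
                                 seed = model_seed + f, strategy = strategy)
    val_ids <- val_ids[order(match(val_ids, manifest$trial_id))]
    for (id in val_ids) {
      w <- features[features$trial_id == id, , drop = FALSE]
      p <- predict_gesture_proba(model, w)
      pid <- prev_of[[id]]
      pw <- pp <- NULL
      if (!is.na(pid)) {
        pw <- features[features$trial_id == pid, , drop = FALSE]
        pp <- predict_gesture_proba(model, pw)
      }
      aligned[[id]] <- align_trial(w, p, b1_ms[[id]], gesture_of[[id]],
                                   pw, pp, step_ms, prepend_ms)
    }
  }
  curves <- average_curves(aligned)
  t_i <- intersection_time(curves)
  marg <- probability_margin(curves)
  cw <- confusion_window
  if (is.null(cw)) cw <- c(if (is.finite(t_i) && t_i < 0) t_i else -700, 0)
  structure(list(strategy = strategy, curves = curves, t_i_ms = t_i,
                 d_p = marg$d_p, t_peak_ms = marg$t_peak_ms,
                 phase_accuracy = phase_accuracy(aligned),
                 confusion = confusion_summary(aligned, cw),
                 n_trials = length(aligned)),
            class = "strategy_evaluation")
}

#' @export
print.strategy_evaluation <- function(x, ...) {
  cat(sprintf(
    "<strategy_evaluation> %s: t_i = %s ms, d_p = %.3f (%d trials)\n",
    x$strategy,
    if (is.finite(x$t_i_ms)) sprintf("%.0f", x$t_i_ms) else "none",
    x$d_p, x$n_trials))
  acc <- x$phase_accuracy
  cat(sprintf("  accuracy: %s\n",
              paste(sprintf("%s %.2f", names(acc), acc), collapse = ", ")))
  invisible(x)
}

#' Run the full decoding pipeline on a synthetic session
#'
#' simulate -> preprocess -> segment -> featurize -> split -> train ->
#' evaluate, end-to-end deterministic under the configured seeds.
#'
#' @param config a [protocol_config()] (its `seed` drives generation).
#' @param ggs_cfg a [ggs_config()].
#' @param win_cfg a [window_config()].
#' @param strategies training strategies to evaluate.
#' @param split_seed,model_seed seeds of the fold plan and the tree
#'   ensembles.
#' @param n_trees ensemble size.
#' @param segmentation `"ggs"` aligns and tags windows with breakpoints
#'   recovered by greedy Gaussian segmentation (as in deployment);
#'   `"truth"` uses the generator's ground-truth timelines, separating
#'   segmentation error from classification error.
#' @param out_dir optional directory; when given, the session manifest,
#'   per-trial segmentations, per-strategy curves (CSV) and a metrics JSON
#'   are written there.
#' @return List of class `pipeline_run`: `session` config echo,
#'   `segmentations`, `breakpoint_error_ms` (per trial, vs ground truth),
#'   `evaluations` (one `strategy_evaluation` per strategy), `metrics`
#'   (flat summary list).
#' @export
run_pipeline <- function(config = protocol_config(),
                         ggs_cfg = ggs_config(),
                         win_cfg = window_config(),
                         strategies = c("S1", "S2", "S3"),
                         split_seed = 1L, model_seed = 1L, n_trees = 50,
                         segmentation = c("ggs", "truth"),
                         out_dir = NULL) {
  segmentation <- match.arg(segmentation)
  session <- generate_session(config)
  prep <- preprocess_session(session)
  segs <- segment_session(prep$envelopes, ggs_cfg)
  bp_err <- vapply(session$manifest$trial_id, function(id)
    stats::median(abs(segs[[id]]$breakpoints_ms -
                        session$timelines[[id]]$breakpoints_ms)),
    numeric(1))
  tls <- if (segmentation == "truth") session$timelines else
    lapply(segs, as_phase_timeline)
  feats <- featurize_session(prep$envelopes, tls, session$manifest, win_cfg)
  split <- build_split(session$manifest, seed = split_seed)
  b1 <- vapply(tls, function(tl) tl$breakpoints_ms[1], numeric(1))
  evals <- lapply(strategies, function(s)
    evaluate_strategy(feats, split, session$manifest, s, b1,
                      n_trees = n_trees, model_seed = model_seed))
  names(evals) <- strategies
  metrics <- list(
    n_trials = nrow(session$manifest),
    n_objects = length(unique(session$manifest$object_id)),
    median_breakpoint_error_ms = stats::median(bp_err),
    strategies = lapply(evals, function(e) list(
      t_i_ms = e$t_i_ms, d_p = e$d_p,
      phase_accuracy = as.list(e$phase_accuracy),
      preshape_mean_accuracy = e$confusion$mean_accuracy))
  )
  run <- structure(list(config = config, manifest = session$manifest,
                        segmentations = segs, breakpoint_error_ms = bp_err,
                        evaluations = evals, metrics = metrics),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat(sprintf("<pipeline_run> %d trials, median breakpoint error %.1f ms\n",
              x$metrics$n_trials, x$metrics$median_breakpoint_error_ms))
  for (e in x$evaluations) print(e)
  invisible(x)
}

#' Write pipeline artifacts to a directory
#'
#' Emits `metrics.json` (flat summary), one `curves_<strategy>.csv` per
#' strategy, `segmentations.json` (breakpoints in ms per trial) and
#' `confusion_<strategy>.csv`. Output is deterministic: a rerun with the
#' same seeds produces byte-identical files.
#'
#' @param run a `pipeline_run`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(run$metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  segs <- lapply(run$segmentations, function(s)
    list(breakpoints_ms = s$breakpoints_ms, objective = s$objective))
  jsonlite::write_json(segs, file.path(out_dir, "segmentations.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in names(run$evaluations)) {
    e <- run$evaluations[[s]]
    utils::write.csv(e$curves,
                     file.path(out_dir, sprintf("curves_%s.csv", s)),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(e$confusion$matrix),
                     file.path(out_dir, sprintf("confusion_%s.csv", s)),
                     row.names = TRUE)
  }
  invisible(out_dir)
}
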