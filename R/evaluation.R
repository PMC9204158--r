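#' Align one validation trial at grasp onset
#'
#' Re-expresses window times relative to the start of the grasping phase
#' (time 0 = breakpoint b1, from segmentation), snapping to the 40-ms
#' window grid. When the predictions of the session's preceding trial are
#' supplied, its last `prepend_ms` of resting-phase predictions are
#' prepended at negative times, extending the rest context before the
#' reach begins; otherwise the trial is flagged unprepended.
#'
#' @param windows window bookkeeping of the trial (`start_ms`, `phase`).
#' @param probs matrix of 14-class probabilities, one row per window.
#' @param b1_ms grasp-onset breakpoint of the trial in ms.
#' @param gesture the trial's true gesture label.
#' @param prev_windows,prev_probs same for the preceding trial (optional).
#' @param step_ms window step defining the grid.
#' @param prepend_ms how much preceding resting context to prepend.
#' @return Object of class `aligned_trial`: `t_ms`, `phase`, `probs`,
#'   `gesture`, `prepended` (logical per grid point), `has_prepend`.
#' @export
align_trial <- function(windows, probs, b1_ms, gesture,
                        prev_windows = NULL, prev_probs = NULL,
                        step_ms = 40, prepend_ms = 700) {
  if (nrow(windows) != nrow(probs))
    stop("windows and probs must have one row per window")
  t_ms <- round((windows$start_ms - b1_ms) / step_ms) * step_ms
  phase <- windows$phase
  prepended <- rep(FALSE, length(t_ms))
  has_prepend <- FALSE
  if (!is.null(prev_windows) && !is.null(prev_probs)) {
    rest_idx <- which(prev_windows$phase == "resting")
    k_max <- floor(prepend_ms / step_ms)
    if (length(rest_idx) && k_max > 0) {
      take <- utils::tail(rest_idx, k_max)
      k <- length(take)
      t_pre <- min(t_ms) - step_ms * (k:1)
      t_ms <- c(t_pre, t_ms)
      phase <- c(rep("resting", k), phase)
      probs <- rbind(prev_probs[take, , drop = FALSE], probs)
      prepended <- c(rep(TRUE, k), prepended)
      has_prepend <- TRUE
    }
  }
  structure(list(t_ms = t_ms, phase = phase, probs = probs,
                 gesture = as.integer(gesture), prepended = prepended,
                 has_prepend = has_prepend, step_ms = step_ms),
            class = "aligned_trial")
}

# Per-trial derived series: grasp/rest/top-competitor probability and
# correctness indicators, on the trial's own grid.
aligned_series <- function(tr) {
  cls <- as.integer(colnames(tr$probs))
  g_col <- match(tr$gesture, cls)
  r_col <- match(0L, cls)
  comp_cols <- which(!(cls %in% c(0L, tr$gesture)))
  pred <- cls[max.col(tr$probs, ties.method = "first")]
  list(
    t_ms = tr$t_ms,
    p_grasp = tr$probs[, g_col],
    p_rest = tr$probs[, r_col],
    p_top = apply(tr$probs[, comp_cols, drop = FALSE], 1, max),
    motional = tr$phase %in% c("reaching", "grasping", "returning"),
    correct_grasp = pred == tr$gesture,
    correct_rest = pred == 0L,
    phase = tr$phase
  )
}

#' Average probability and accuracy curves over aligned trials
#'
#' At each grid time the grasp-gesture probability `p[t, l]`, the rest
#' probability `p[t, 0]` and the top-competitor probability
#' `max_{j != 0, l} p[t, j]` (computed per trial before averaging — the
#' competitor gesture may differ between trials and time points) are
#' averaged over the trials that have a window there. Accuracy curves
#' count, among trials whose phase at `t` is motional (resp. resting), the
#' fraction predicting the trial gesture (resp. rest).
#'
#' @param aligned list of `aligned_trial`s.
#' @return Data frame of class `evaluation_curves`: `t_ms`, `p_grasp`,
#'   `p_rest`, `p_top`, `acc_grasp`, `acc_rest`, `support`, `n_motional`,
#'   `n_resting`.
#' @export
average_curves <- function(aligned) {
  if (!length(aligned)) stop("no aligned trials supplied")
  step <- aligned[[1]]$step_ms
  series <- lapply(aligned, aligned_series)
  t_all <- unlist(lapply(series, `[[`, "t_ms"))
  grid <- seq(min(t_all), max(t_all), by = step)
  acc <- list(p_grasp = numeric(length(grid)), p_rest = numeric(length(grid)),
              p_top = numeric(length(grid)), support = integer(length(grid)),
              hit_grasp = numeric(length(grid)), n_mot = integer(length(grid)),
              hit_rest = numeric(length(grid)), n_rest = integer(length(grid)))
  for (s in series) {
    gi <- match(s$t_ms, grid)
    ok <- !is.na(gi)
    gi <- gi[ok]
    acc$p_grasp[gi] <- acc$p_grasp[gi] + s$p_grasp[ok]
    acc$p_rest[gi] <- acc$p_rest[gi] + s$p_rest[ok]
    acc$p_top[gi] <- acc$p_top[gi] + s$p_top[ok]
    acc$support[gi] <- acc$support[gi] + 1L
    mot <- s$motional[ok]
    acc$n_mot[gi[mot]] <- acc$n_mot[gi[mot]] + 1L
    acc$hit_grasp[gi[mot]] <- acc$hit_grasp[gi[mot]] + s$correct_grasp[ok][mot]
    acc$n_rest[gi[!mot]] <- acc$n_rest[gi[!mot]] + 1L
    acc$hit_rest[gi[!mot]] <- acc$hit_rest[gi[!mot]] + s$correct_rest[ok][!mot]
  }
  keep <- acc$support > 0L
  out <- data.frame(
    t_ms = grid[keep],
    p_grasp = acc$p_grasp[keep] / acc$support[keep],
    p_rest = acc$p_rest[keep] / acc$support[keep],
    p_top = acc$p_top[keep] / acc$support[keep],
    acc_grasp = ifelse(acc$n_mot[keep] > 0, acc$hit_grasp[keep] / acc$n_mot[keep], NA),
    acc_rest = ifelse(acc$n_rest[keep] > 0, acc$hit_rest[keep] / acc$n_rest[keep], NA),
    support = acc$support[keep],
    n_motional = acc$n_mot[keep],
    n_resting = acc$n_rest[keep]
  )
  class(out) <- c("evaluation_curves", "data.frame")
  attr(out, "step_ms") <- step
  out
}

# Grid points with enough trial support for curve-level metrics.
supported_rows <- function(curves, min_support_frac) {
  curves$support >= min_support_frac * max(curves$support)
}

#' Intersection time of grasp and rest probability curves
#'
#' Earliest grid time at which the averaged grasp-gesture probability
#' reaches the rest probability and stays at or above it for `h`
#' consecutive grid points, refined below the grid step by linear
#' interpolation between the bracketing points. Reported in ms relative to
#' grasp onset (negative = before the grasping phase begins). Grid points
#' supported by fewer than `min_support_frac` of the trials are masked.
#'
#' @param curves an `evaluation_curves` data frame.
#' @param h persistence requirement in grid points.
#' @param min_support_frac support mask threshold (fraction of the maximum
#'   per-point trial count).
#' @return Intersection time in ms, or `NA` if the curves never cross.
#' @export
intersection_time <- function(curves, h = 3, min_support_frac = 0.2) {
  cv <- curves[supported_rows(curves, min_support_frac), , drop = FALSE]
  d <- cv$p_grasp - cv$p_rest
  n <- length(d)
  if (n < h) return(NA_real_)
  above <- d >= 0
  for (i in seq_len(n - h + 1L)) {
    if (all(above[i:(i + h - 1L)])) {
      if (i == 1L || !is.finite(d[i - 1L])) return(cv$t_ms[i])
      d0 <- d[i - 1L]; d1 <- d[i]
      if (d1 == d0) return(cv$t_ms[i])
      return(cv$t_ms[i - 1L] + (0 - d0) / (d1 - d0) *
               (cv$t_ms[i] - cv$t_ms[i - 1L]))
    }
  }
  NA_real_
}

#' Probability margin at the grasp-probability peak
#'
#' `d_p` is the distance from the peak of the averaged grasp-gesture
#' probability to the simultaneous top-competitor probability; ties in the
#' peak location go to the earliest time.
#'
#' @inheritParams intersection_time
#' @return List with `d_p`, `t_peak_ms` and `p_peak`.
#' @export
probability_margin <- function(curves, min_support_frac = 0.2) {
  cv <- curves[supported_rows(curves, min_support_frac), , drop = FALSE]
  if (!nrow(cv)) stop("no supported grid points")
  i <- which.max(cv$p_grasp)          # first maximum -> earliest tie-break
  list(d_p = cv$p_grasp[i] - cv$p_top[i],
       t_peak_ms = cv$t_ms[i], p_peak = cv$p_grasp[i])
}

#' Per-phase classification accuracy of aligned trials
#'
#' For each phase, the fraction of windows predicting the trial gesture
#' (motional phases) or rest (resting phase).
#'
#' @param aligned list of `aligned_trial`s.
#' @return Named numeric vector over the four phases.
#' @export
phase_accuracy <- function(aligned) {
  hits <- c(reaching = 0, grasping = 0, returning = 0, resting = 0)
  tot <- hits
  for (tr in aligned) {
    s <- aligned_series(tr)
    ok <- ifelse(s$motional, s$correct_grasp, s$correct_rest)
    for (ph in names(hits)) {
      sel <- s$phase == ph
      hits[ph] <- hits[ph] + sum(ok[sel])
      tot[ph] <- tot[ph] + sum(sel)
    }
  }
  ifelse(tot > 0, hits / tot, NA)
}

#' Pre-shaping confusion matrix
#'
#' Row-normalized 14 x 14 confusion matrix over all aligned windows with
#' time in `[t_a, 0]` (the pre-shaping period before grasp onset); the true
#' label of a window is its trial's grasp gesture. The mean diagonal over
#' populated rows summarizes pre-shaping accuracy.
#'
#' @param aligned list of `aligned_trial`s.
#' @param window length-2 time window in ms, `window[1] < 0`.
#' @param classes full class set.
#' @return Object of class `confusion_summary`: `matrix` (row-normalized),
#'   `counts`, `mean_accuracy`, `window_ms`.
#' @export
confusion_summary <- function(aligned, window = c(-700, 0), classes = 0:13) {
  if (window[1] >= 0) stop("`window` must start before grasp onset")
  k <- length(classes)
  cm <- matrix(0L, k, k, dimnames = list(classes, classes))
  for (tr in aligned) {
    sel <- tr$t_ms >= window[1] & tr$t_ms <= window[2]
    if (!any(sel)) next
    cls <- as.integer(colnames(tr$probs))
    pred <- cls[max.col(tr$probs[sel, , drop = FALSE], ties.method = "first")]
    ti <- match(tr$gesture, classes)
    for (p in pred) cm[ti, match(p, classes)] <- cm[ti, match(p, classes)] + 1L
  }
  if (!sum(cm)) stop("no windows fall inside the confusion window")
  rs <- rowSums(cm)
  norm <- cm / ifelse(rs > 0, rs, 1)
  populated <- rs > 0
  structure(list(matrix = norm, counts = cm,
                 mean_accuracy = mean(diag(norm)[populated]),
                 window_ms = window),
            class = "confusion_summary")
}

#' @export
print.confusion_summary <- function(x, ...) {
  cat(sprintf("<confusion_summary> window [%g, %g] ms, mean accuracy %.3f\n",
              x$window_ms[1], x$window_ms[2], x$mean_accuracy))
  invisible(x)
}
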