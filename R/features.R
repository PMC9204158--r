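#' Sliding-window configuration
#'
#' @param window_ms window length T in ms.
#' @param step_ms step between consecutive window starts in ms.
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_ms = 320, step_ms = 40) {
  if (!(step_ms > 0 && step_ms <= window_ms))
    stop("require 0 < step_ms <= window_ms")
  structure(list(window_ms = window_ms, step_ms = step_ms),
            class = "window_config")
}

#' Window time-domain features
#'
#' Root mean square, mean absolute value and population variance of a
#' single-channel window: `rms = sqrt(mean(x^2))`, `mav = mean(|x|)`,
#' `var_pop = mean((x - mean(x))^2)`. The identity
#' `rms^2 = var_pop + mean^2` ties the three together.
#'
#' @param x non-empty numeric vector.
#' @return Scalar feature value.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty window")
  sqrt(mean(x^2))
}

#' @rdname rms
#' @export
mav <- function(x) {
  if (!length(x)) stop("empty window")
  mean(abs(x))
}

#' @rdname rms
#' @export
var_pop <- function(x) {
  if (!length(x)) stop("empty window")
  mean((x - mean(x))^2)
}

#' Expected window count for a trial
#'
#' Start indices are `floor(k * step_ms * fs / 1000)` for `k = 0, 1, ...`
#' while the window fits inside the trial; computing starts in ms and
#' flooring per window keeps the mean step exact even when the step is a
#' non-integer number of samples (40 ms at 1562.5 Hz is 62.5 samples).
#'
#' @param n trial length in samples.
#' @param fs sampling rate in Hz.
#' @param cfg a [window_config()].
#' @return Integer window count.
#' @export
count_windows <- function(n, fs, cfg = window_config()) {
  t_samp <- round(cfg$window_ms * fs / 1000)
  k <- 0L; cnt <- 0L
  repeat {
    start <- floor(k * cfg$step_ms * fs / 1000)
    if (start + t_samp > n) break
    cnt <- cnt + 1L; k <- k + 1L
  }
  cnt
}

#' Slice a recording into overlapping windows
#'
#' Returns per-window bookkeeping (start index/ms, centre ms) and, when a
#' phase timeline and gesture are supplied, the phase containing each
#' window's centre sample and the window label (the trial gesture on
#' motional phases, 0 on resting). Windows never cross trial ends; a trial
#' shorter than one window yields zero windows with a warning.
#'
#' @param rec an `emg_recording` (normally the normalized envelope).
#' @param cfg a [window_config()].
#' @param timeline optional [phase_timeline()] used to tag window centres.
#' @param gesture optional trial gesture label for window labelling.
#' @return Data frame with columns `k`, `start_idx`, `start_ms`,
#'   `center_ms`, and when tagged `phase`, `label`; attribute `windows`
#'   holds the list of channel-by-sample matrices.
#' @export
slide_windows <- function(rec, cfg = window_config(), timeline = NULL,
                          gesture = NULL) {
  n <- ncol(rec$samples); fs <- rec$fs
  t_samp <- round(cfg$window_ms * fs / 1000)
  starts <- integer(0); k <- 0L
  repeat {
    s <- floor(k * cfg$step_ms * fs / 1000)
    if (s + t_samp > n) break
    starts <- c(starts, s); k <- k + 1L
  }
  if (!length(starts)) {
    warning("trial shorter than one window: no windows produced")
    return(data.frame(k = integer(0), start_idx = integer(0),
                      start_ms = numeric(0), center_ms = numeric(0)))
  }
  df <- data.frame(
    k = seq_along(starts) - 1L,
    start_idx = starts + 1L,
    start_ms = (seq_along(starts) - 1L) * cfg$step_ms,
    center_ms = (starts + t_samp / 2) * 1000 / fs
  )
  if (!is.null(timeline)) {
    df$phase <- phase_at(timeline, df$center_ms)
    if (!is.null(gesture))
      df$label <- ifelse(df$phase == "resting", 0L, as.integer(gesture))
  }
  attr(df, "windows") <- lapply(starts, function(s)
    rec$samples[, (s + 1L):(s + t_samp), drop = FALSE])
  attr(df, "t_samples") <- t_samp
  df
}

#' Feature vector of one window
#'
#' Concatenates the per-channel features in the fixed order
#' `[RMS_1..C, MAV_1..C, VAR_1..C]`; with C = 12 channels the vector has
#' length 36. This ordering is the feature contract shared with the
#' classifier.
#'
#' @param w channels-by-samples numeric matrix.
#' @param channel_names optional channel labels used to name the features.
#' @return Named numeric vector of length `3 * nrow(w)`.
#' @export
featurize <- function(w, channel_names = NULL) {
  if (!is.matrix(w) || ncol(w) < 1L) stop("empty window")
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(w)))
  z <- c(apply(w, 1, rms), apply(w, 1, mav), apply(w, 1, var_pop))
  names(z) <- c(paste0("rms_", channel_names), paste0("mav_", channel_names),
                paste0("var_", channel_names))
  z
}

#' Feature table of one trial
#'
#' Slides windows over the recording and computes the feature vector of
#' each, yielding one row per window with bookkeeping, phase tag, label and
#' the `3C` features in contract order.
#'
#' @param rec an `emg_recording`.
#' @param cfg a [window_config()].
#' @param timeline [phase_timeline()] for phase tagging (ground truth or
#'   recovered by segmentation).
#' @param gesture trial gesture label.
#' @param trial_id identifier copied into every row.
#' @return Data frame: `trial_id`, `start_ms`, `center_ms`, `phase`,
#'   `label`, then `rms_*`, `mav_*`, `var_*` columns.
#' @export
featurize_trial <- function(rec, cfg = window_config(), timeline = NULL,
                            gesture = NULL, trial_id = NA_character_) {
  df <- slide_windows(rec, cfg, timeline, gesture)
  wins <- attr(df, "windows")
  if (!length(wins)) return(df)
  Z <- t(vapply(wins, featurize, numeric(3 * nrow(rec$samples)),
                channel_names = rec$channel_names))
  meta <- data.frame(trial_id = trial_id, start_ms = df$start_ms,
                     center_ms = df$center_ms)
  if (!is.null(df$phase)) meta$phase <- df$phase
  if (!is.null(df$label)) meta$label <- df$label
  cbind(meta, as.data.frame(Z))
}

#' Feature table of a whole session
#'
#' @param envelopes named list of normalized envelope `emg_recording`s.
#' @param segmentations named list of phase-labelled `segmented_trial`s (or
#'   [phase_timeline()]s) aligned with `envelopes`; ground-truth timelines
#'   may be passed to separate segmentation error from classification
#'   error.
#' @param manifest session manifest data frame (`trial_id`, `gesture`,
#'   `object_id`, `order`).
#' @param cfg a [window_config()].
#' @return Data frame of all windows with `object_id`, `gesture` and
#'   session `order` joined in.
#' @export
featurize_session <- function(envelopes, segmentations, manifest,
                              cfg = window_config()) {
  out <- lapply(manifest$trial_id, function(id) {
    seg <- segmentations[[id]]
    tl <- if (inherits(seg, "phase_timeline")) seg else as_phase_timeline(seg)
    g <- manifest$gesture[manifest$trial_id == id]
    featurize_trial(envelopes[[id]], cfg, tl, g, id)
  })
  feats <- do.call(rbind, out)
  i <- match(feats$trial_id, manifest$trial_id)
  cbind(feats[, "trial_id", drop = FALSE],
        object_id = manifest$object_id[i], gesture = manifest$gesture[i],
        order = manifest$order[i],
        feats[, setdiff(names(feats), "trial_id"), drop = FALSE])
}
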