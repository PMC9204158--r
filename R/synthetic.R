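#' Protocol configuration for synthetic reach-to-grasp sessions
#'
#' Describes one recording session of the grasp protocol: 13 grasp gestures,
#' each performed with 4 different objects (52 objects per session) and 6
#' trials per object, recorded on 12 bipolar surface-EMG channels at
#' 1562.5 Hz. Each 4-s trial traverses the four phases reaching, grasping,
#' returning and resting at the subject's natural pace.
#'
#' The signal model is a zero-mean band-limited (20--450 Hz) Gaussian
#' carrier per channel, amplitude-modulated by a piecewise-constant
#' per-phase activation envelope with raised-cosine ramps at phase
#' boundaries, plus a white noise floor. Gesture identity is carried by the
#' per-channel grasp activation pattern; during reaching the pattern is a
#' convex blend between the resting baseline and the full grasp pattern
#' (`reach_blend`), emulating pre-shaping muscle activity that is partially
#' expressed before object contact.
#'
#' @param n_channels number of EMG channels.
#' @param fs sampling rate in Hz; must exceed twice the upper carrier edge.
#' @param n_gestures number of non-rest grasp gestures.
#' @param objects_per_gesture objects grasped with each gesture.
#' @param trials_per_object repetitions per object.
#' @param trial_length_ms trial duration in ms.
#' @param min_phase_ms minimum duration of any phase in ms.
#' @param carrier_band length-2 pass band of the Gaussian carrier in Hz.
#' @param noise_floor standard deviation of the additive white noise floor,
#'   in the same (arbitrary) amplitude units as the activations.
#' @param baseline_amplitude resting muscle-tone activation level.
#' @param reach_blend convex weight of the grasp pattern during reaching
#'   (0 = resting baseline, 1 = full grasp pattern).
#' @param return_blend convex weight of the grasp pattern during returning.
#' @param ramp_ms raised-cosine transition width at phase boundaries.
#' @param amp_jitter_sd log-normal sd of per-trial, per-channel amplitude
#'   jitter (trial-to-trial variability).
#' @param mvc_margin factor by which the maximum-voluntary-contraction
#'   amplitude exceeds the largest task activation of a channel.
#' @param mvc_length_ms duration of each MVC recording in ms.
#' @param seed integer seed making the whole session reproducible.
#' @return A validated list of class `protocol_config`.
#' @export
protocol_config <- function(n_channels = 12, fs = 1562.5, n_gestures = 13,
                            objects_per_gesture = 4, trials_per_object = 6,
                            trial_length_ms = 4000, min_phase_ms = 300,
                            carrier_band = c(20, 450), noise_floor = 0.02,
                            baseline_amplitude = 0.05, reach_blend = 0.6,
                            return_blend = 0.35, ramp_ms = 50,
                            amp_jitter_sd = 0.05, mvc_margin = 1.25,
                            mvc_length_ms = 3000, seed = 1L) {
  cfg <- list(n_channels = as.integer(n_channels), fs = fs,
              n_gestures = as.integer(n_gestures),
              objects_per_gesture = as.integer(objects_per_gesture),
              trials_per_object = as.integer(trials_per_object),
              trial_length_ms = trial_length_ms, min_phase_ms = min_phase_ms,
              carrier_band = carrier_band, noise_floor = noise_floor,
              baseline_amplitude = baseline_amplitude,
              reach_blend = reach_blend, return_blend = return_blend,
              ramp_ms = ramp_ms, amp_jitter_sd = amp_jitter_sd,
              mvc_margin = mvc_margin, mvc_length_ms = mvc_length_ms,
              seed = as.integer(seed))
  counts <- c(cfg$n_channels, cfg$n_gestures, cfg$objects_per_gesture,
              cfg$trials_per_object)
  if (any(counts < 1L)) stop("all protocol counts must be >= 1")
  if (length(carrier_band) != 2L || carrier_band[1] <= 0 ||
      carrier_band[1] >= carrier_band[2])
    stop("`carrier_band` must be an increasing pair of positive frequencies")
  if (fs <= 2 * carrier_band[2])
    stop("sampling rate must exceed twice the upper carrier band edge")
  if (4 * min_phase_ms > trial_length_ms)
    stop("infeasible: 4 x min_phase_ms exceeds the trial length")
  class(cfg) <- "protocol_config"
  cfg
}

#' Gesture-specific activation profile
#'
#' Draws, once per session, a per-channel grasp activation amplitude for
#' every gesture (uniform on `amp_range`) and derives the reaching and
#' returning amplitudes as convex blends between the resting baseline and
#' the full grasp pattern. Consumes the current RNG stream.
#'
#' @param config a [protocol_config()].
#' @param amp_range range of grasp-phase activation amplitudes.
#' @return Object of class `activation_profile` with an
#'   `amp[gesture, phase, channel]` array (phases in protocol order).
#' @export
activation_profile <- function(config, amp_range = c(0.1, 1)) {
  G <- config$n_gestures; C <- config$n_channels
  grasp <- matrix(stats::runif(G * C, amp_range[1], amp_range[2]), G, C)
  rest <- rep(config$baseline_amplitude, C)
  amp <- array(0, dim = c(G, 4, C),
               dimnames = list(NULL,
                               c("reaching", "grasping", "returning", "resting"),
                               NULL))
  for (g in seq_len(G)) {
    amp[g, "reaching", ] <- (1 - config$reach_blend) * rest +
      config$reach_blend * grasp[g, ]
    amp[g, "grasping", ] <- grasp[g, ]
    amp[g, "returning", ] <- (1 - config$return_blend) * rest +
      config$return_blend * grasp[g, ]
    amp[g, "resting", ] <- rest
  }
  structure(list(amp = amp, ramp_ms = config$ramp_ms), class = "activation_profile")
}

#' Draw a random phase timeline for one trial
#'
#' Breakpoints are uniform over all feasible placements given the minimum
#' phase duration, emulating subjects moving at their own natural pace:
#' three points are drawn uniformly in the slack interval, sorted, and
#' shifted by the accumulated minimum durations.
#'
#' @param config a [protocol_config()].
#' @return A [phase_timeline()].
#' @export
sample_trial_timeline <- function(config) {
  L <- config$trial_length_ms; m <- config$min_phase_ms
  slack <- L - 4 * m
  if (slack < 0) stop("infeasible timeline constraint")
  u <- sort(stats::runif(3, 0, slack))
  phase_timeline(u + m * (1:3), L)
}

# Unit-variance band-limited Gaussian carrier of length n.
synth_carrier <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf, stats::rnorm(n))
  x / stats::sd(x)
}

# Piecewise-constant envelope over the trial with raised-cosine ramps of
# width ramp_ms centred on each breakpoint. `levels` has one value per phase.
phase_envelope <- function(timeline, levels, fs, ramp_ms) {
  n <- round(timeline$trial_length_ms * fs / 1000)
  t_ms <- (seq_len(n) - 0.5) * 1000 / fs
  idx <- findInterval(t_ms, c(0, timeline$breakpoints_ms),
                      rightmost.closed = FALSE)
  env <- levels[pmin(pmax(idx, 1L), 4L)]
  half <- ramp_ms / 2
  for (k in 1:3) {
    b <- timeline$breakpoints_ms[k]
    in_ramp <- which(t_ms > b - half & t_ms < b + half)
    if (length(in_ramp)) {
      w <- 0.5 * (1 - cos(pi * (t_ms[in_ramp] - (b - half)) / ramp_ms))
      env[in_ramp] <- (1 - w) * levels[k] + w * levels[k + 1]
    }
  }
  env
}

#' Synthesize one reach-to-grasp EMG trial
#'
#' Each channel is an independent unit-variance band-limited Gaussian
#' carrier multiplied by the phase activation envelope of the trial's
#' gesture, plus a white noise floor. Per-trial log-normal amplitude jitter
#' models trial-to-trial variability. Consumes the current RNG stream.
#'
#' @param timeline a [phase_timeline()] for the trial.
#' @param gesture_id gesture label in `1..n_gestures`.
#' @param profile an [activation_profile()].
#' @param config a [protocol_config()].
#' @return An `emg_recording` whose `meta` carries the gesture label and the
#'   ground-truth timeline.
#' @export
synth_trial <- function(timeline, gesture_id, profile, config) {
  if (gesture_id < 1 || gesture_id > config$n_gestures)
    stop("`gesture_id` out of range")
  C <- config$n_channels
  n <- round(timeline$trial_length_ms * config$fs / 1000)
  jit <- exp(stats::rnorm(C, 0, config$amp_jitter_sd))
  x <- matrix(0, C, n)
  for (c in seq_len(C)) {
    levels <- profile$amp[gesture_id, , c] * jit[c]
    env <- phase_envelope(timeline, levels, config$fs, profile$ramp_ms)
    x[c, ] <- synth_carrier(n, config$fs, config$carrier_band) * env +
      stats::rnorm(n, 0, config$noise_floor)
  }
  emg_recording(x, config$fs,
                channel_names = if (C == length(emg_channel_names))
                  emg_channel_names else paste0("ch", seq_len(C)),
                meta = list(gesture = as.integer(gesture_id),
                            timeline = timeline))
}

#' Synthesize maximum-voluntary-contraction recordings
#'
#' One 3-s isometric recording per channel. The target channel holds a
#' constant activation exceeding its largest task activation (by
#' `mvc_margin`); the other channels stay at resting baseline.
#' Consumes the current RNG stream.
#'
#' @param config a [protocol_config()].
#' @param profile an [activation_profile()].
#' @return List of `emg_recording`, one per channel, `meta$target_channel`
#'   set.
#' @export
synth_mvc <- function(config, profile) {
  C <- config$n_channels
  n <- round(config$mvc_length_ms * config$fs / 1000)
  peak <- apply(profile$amp, 3, max)            # max task activation per channel
  lapply(seq_len(C), function(ch) {
    x <- matrix(0, C, n)
    for (c in seq_len(C)) {
      a <- if (c == ch) config$mvc_margin * peak[c] else config$baseline_amplitude
      x[c, ] <- synth_carrier(n, config$fs, config$carrier_band) * a +
        stats::rnorm(n, 0, config$noise_floor)
    }
    emg_recording(x, config$fs,
                  channel_names = if (C == length(emg_channel_names))
                    emg_channel_names else paste0("ch", seq_len(C)),
                  meta = list(target_channel = ch, kind = "mvc"))
  })
}

#' Generate a full synthetic session with ground truth
#'
#' Seeds the RNG from `config$seed`, draws one activation profile, the MVC
#' set, and `n_gestures * objects_per_gesture * trials_per_object` trials in
#' session order (objects presented sequentially, trials consecutive within
#' an object). The manifest records gesture, object, session order and the
#' ground-truth breakpoints of every trial.
#'
#' @param config a [protocol_config()].
#' @return Object of class `emg_session`: `trials` (list of
#'   `emg_recording`), `timelines` (list of [phase_timeline()]), `manifest`
#'   (data frame), `mvc`, `profile`, `config`.
#' @export
generate_session <- function(config = protocol_config()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)
  profile <- activation_profile(config)
  mvc <- synth_mvc(config, profile)
  trials <- list(); timelines <- list(); rows <- list()
  ord <- 0L
  for (g in seq_len(config$n_gestures)) {
    for (o in seq_len(config$objects_per_gesture)) {
      object_id <- sprintf("g%02d_o%d", g, o)
      for (tr in seq_len(config$trials_per_object)) {
        ord <- ord + 1L
        tl <- sample_trial_timeline(config)
        rec <- synth_trial(tl, g, profile, config)
        trial_id <- sprintf("%s_t%d", object_id, tr)
        rec$meta$trial_id <- trial_id
        rec$meta$object_id <- object_id
        rec$meta$order <- ord
        trials[[trial_id]] <- rec
        timelines[[trial_id]] <- tl
        rows[[ord]] <- data.frame(
          trial_id = trial_id, object_id = object_id, gesture = g,
          trial_in_object = tr, order = ord,
          b1_ms = tl$breakpoints_ms[1], b2_ms = tl$breakpoints_ms[2],
          b3_ms = tl$breakpoints_ms[3],
          trial_length_ms = tl$trial_length_ms)
      }
    }
  }
  structure(list(trials = trials, timelines = timelines,
                 manifest = do.call(rbind, rows), mvc = mvc,
                 profile = profile, config = config),
            class = "emg_session")
}

#' @export
print.emg_session <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<emg_session> %d trials, %d objects, %d gestures, seed %d\n",
              nrow(m), length(unique(m$object_id)), length(unique(m$gesture)),
              x$config$seed))
  invisible(x)
}

#' Write the session manifest (ground truth) as JSON
#'
#' @param session an `emg_session`.
#' @param path output file.
#' @export
write_session_manifest <- function(session, path) {
  jsonlite::write_json(
    list(seed = session$config$seed,
         n_trials = nrow(session$manifest),
         trials = session$manifest),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write one trial as CSV (one column per channel)
#'
#' @param rec an `emg_recording`.
#' @param path output file.
#' @export
write_trial_csv <- function(rec, path) {
  df <- as.data.frame(t(rec$samples))
  names(df) <- rec$channel_names
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial written by [write_trial_csv()]
#'
#' @param path CSV file, one column per channel.
#' @param fs sampling rate in Hz to attach.
#' @return An `emg_recording`.
#' @export
read_trial_csv <- function(path, fs) {
  df <- utils::read.csv(path, check.names = FALSE)
  emg_recording(t(as.matrix(df)), fs, channel_names = names(df))
}
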