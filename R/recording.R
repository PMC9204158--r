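#' Muscle channel labels used throughout the package
#'
#' Twelve surface-EMG channels spanning hand, forearm and upper-arm muscles,
#' ordered distal to proximal: first dorsal interosseous (FDI), abductor
#' pollicis brevis (APB), flexor digiti minimi (FDM), extensor indicis (EI),
#' extensor digitorum communis (EDC), flexor digitorum superficialis (FDS),
#' brachioradialis (BRD), extensor carpi radialis (ECR), extensor carpi
#' ulnaris (ECU), flexor carpi ulnaris (FCU), biceps brachii (BIC) and
#' triceps brachii (TRI).
#'
#' @export
emg_channel_names <- c("FDI", "APB", "FDM", "EI", "EDC", "FDS",
                       "BRD", "ECR", "ECU", "FCU", "BIC", "TRI")

#' Construct a multichannel EMG recording
#'
#' Container for a channels-by-samples signal matrix with its sampling rate,
#' channel labels and free-form metadata (subject/session/object/trial ids,
#' processing flags).
#'
#' @param samples numeric matrix, channels in rows, samples in columns.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of length `nrow(samples)`.
#' @param meta named list of identifiers and flags.
#' @return An object of class `emg_recording`.
#' @export
emg_recording <- function(samples, fs, channel_names = NULL, meta = list()) {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || nrow(samples) < 1L || ncol(samples) < 1L)
    stop("`samples` must be a non-empty numeric channels-by-samples matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_names))
    channel_names <- if (nrow(samples) == length(emg_channel_names))
      emg_channel_names else paste0("ch", seq_len(nrow(samples)))
  if (length(channel_names) != nrow(samples))
    stop("`channel_names` length must equal the number of channels")
  structure(
    list(samples = samples, fs = fs,
         channel_names = as.character(channel_names), meta = meta),
    class = "emg_recording"
  )
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%.0f ms)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              1000 * ncol(x$samples) / x$fs))
  cat("  channels:", paste(x$channel_names, collapse = " "), "\n")
  flags <- names(x$meta)
  if (length(flags)) cat("  meta:", paste(flags, collapse = " "), "\n")
  invisible(x)
}

#' Number of samples and duration helpers
#' @param rec an `emg_recording`.
#' @return `n_samples()`: integer sample count; `duration_ms()`: duration in ms.
#' @export
n_samples <- function(rec) ncol(rec$samples)

#' @rdname n_samples
#' @export
duration_ms <- function(rec) 1000 * ncol(rec$samples) / rec$fs

#' Phase timeline of a reach-to-grasp trial
#'
#' Three ordered breakpoints split a trial into the four protocol phases
#' reaching, grasping, returning and resting. Breakpoints are stored in ms
#' from trial start.
#'
#' @param breakpoints_ms numeric vector of 3 strictly increasing times (ms).
#' @param trial_length_ms total trial duration in ms.
#' @return An object of class `phase_timeline`.
#' @export
phase_timeline <- function(breakpoints_ms, trial_length_ms = 4000) {
  b <- as.numeric(breakpoints_ms)
  if (length(b) != 3L || any(!is.finite(b)))
    stop("`breakpoints_ms` must be 3 finite times")
  if (!(0 < b[1] && b[1] < b[2] && b[2] < b[3] && b[3] < trial_length_ms))
    stop("breakpoints must satisfy 0 < b1 < b2 < b3 < trial length")
  structure(
    list(breakpoints_ms = b, trial_length_ms = trial_length_ms,
         phase_names = c("reaching", "grasping", "returning", "resting")),
    class = "phase_timeline"
  )
}

#' Phase durations of a timeline
#' @param tl a `phase_timeline`.
#' @return named numeric vector of 4 phase durations in ms.
#' @export
phase_durations_ms <- function(tl) {
  d <- diff(c(0, tl$breakpoints_ms, tl$trial_length_ms))
  names(d) <- tl$phase_names
  d
}

#' Phase containing a time point
#' @param tl a `phase_timeline`.
#' @param t_ms time(s) in ms from trial start.
#' @return character vector of phase names.
#' @export
phase_at <- function(tl, t_ms) {
  idx <- findInterval(t_ms, c(0, tl$breakpoints_ms, tl$trial_length_ms),
                      rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), 4L)
  tl$phase_names[idx]
}
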