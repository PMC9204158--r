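#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (default 40--500 Hz, order 4) to every
#' channel using forward-backward filtering, so the output has no phase
#' lag. A cutoff at or above Nyquist is clipped to 0.99 x Nyquist with a
#' warning. The first and last 100 ms are flagged in `meta$edge_ms` because
#' forward-backward filtering leaves transients there.
#'
#' @param rec an `emg_recording`.
#' @param low_hz,high_hz band edges in Hz.
#' @param order filter order (of the analogue low-pass prototype).
#' @return Filtered `emg_recording`.
#' @export
emg_bandpass <- function(rec, low_hz = 40, high_hz = 500, order = 4) {
  nyq <- rec$fs / 2
  if (high_hz >= nyq) {
    high_hz <- 0.99 * nyq
    warning(sprintf("high cutoff clipped to %.1f Hz (0.99 x Nyquist)", high_hz))
  }
  if (!(low_hz > 0 && low_hz < high_hz))
    stop("require 0 < low_hz < high_hz < Nyquist after clipping")
  if (order %% 2 != 0) stop("`order` must be even for a band-pass")
  n <- ncol(rec$samples)
  if (n <= 3 * order)
    stop("signal too short for the requested filter order")
  bf <- signal::butter(order / 2, c(low_hz, high_hz) / nyq, type = "pass")
  out <- rec
  out$samples <- t(apply(rec$samples, 1, function(x) signal::filtfilt(bf, x)))
  out$meta$bandpass_hz <- c(low_hz, high_hz)
  out$meta$edge_ms <- 100
  out
}

#' Linear envelope of a band-passed EMG recording
#'
#' Full-wave rectification followed by a zero-phase low-pass Butterworth
#' (default 6 Hz, order 2); residual negative values from the filter are
#' clamped at zero.
#'
#' @param rec a band-passed `emg_recording`.
#' @param lp_cutoff_hz envelope low-pass cutoff in Hz.
#' @param lp_order low-pass order.
#' @return Non-negative `emg_recording` with `meta$envelope = TRUE`.
#' @export
emg_envelope <- function(rec, lp_cutoff_hz = 6, lp_order = 2) {
  if (lp_cutoff_hz <= 0 || lp_cutoff_hz >= rec$fs / 2)
    stop("envelope cutoff must lie inside (0, Nyquist)")
  lf <- signal::butter(lp_order, lp_cutoff_hz / (rec$fs / 2), type = "low")
  out <- rec
  out$samples <- t(apply(abs(rec$samples), 1,
                         function(x) pmax(signal::filtfilt(lf, x), 0)))
  out$meta$envelope <- TRUE
  out
}

#' Per-muscle MVC normalization profile
#'
#' The normalization constant of a channel is the maximum of its envelope
#' over all supplied maximum-voluntary-contraction recordings. MVC
#' envelopes must have been computed with the same settings as the task
#' data.
#'
#' @param mvc_envs list of envelope `emg_recording`s covering all channels.
#' @param channel_names channels that must be covered; defaults to those of
#'   the first recording.
#' @return Named numeric vector of per-channel maxima (class `mvc_profile`).
#' @export
mvc_profile <- function(mvc_envs, channel_names = NULL) {
  if (!length(mvc_envs)) stop("no MVC recordings supplied")
  if (is.null(channel_names)) channel_names <- mvc_envs[[1]]$channel_names
  m <- stats::setNames(rep(-Inf, length(channel_names)), channel_names)
  for (rec in mvc_envs) {
    hit <- intersect(rec$channel_names, channel_names)
    if (!length(hit)) next
    mx <- apply(rec$samples[match(hit, rec$channel_names), , drop = FALSE], 1, max)
    m[hit] <- pmax(m[hit], mx)
  }
  if (any(!is.finite(m)))
    stop("channels missing from all MVC recordings: ",
         paste(channel_names[!is.finite(m)], collapse = ", "))
  if (any(m <= 0)) stop("non-positive MVC maxima: ",
                        paste(channel_names[m <= 0], collapse = ", "))
  class(m) <- "mvc_profile"
  m
}

#' Normalize a task envelope by the MVC profile
#'
#' Divides each channel by its MVC envelope maximum so amplitudes become
#' fractions of maximum voluntary contraction, making channels with very
#' different absolute signal power (hand vs upper-arm muscles) comparable.
#'
#' @param env an envelope `emg_recording`.
#' @param mvc an [mvc_profile()].
#' @return Normalized `emg_recording` with `meta$normalized = TRUE`.
#' @export
mvc_normalize <- function(env, mvc) {
  missing <- setdiff(env$channel_names, names(mvc))
  if (length(missing))
    stop("no MVC value for channels: ", paste(missing, collapse = ", "))
  out <- env
  out$samples <- env$samples / unclass(mvc)[env$channel_names]
  out$meta$normalized <- TRUE
  out
}

#' Full preprocessing of a session
#'
#' Band-pass filters and envelopes every trial and every MVC recording,
#' builds the MVC profile, and returns the MVC-normalized trial envelopes.
#'
#' @param session an `emg_session` (or any list with `trials` and `mvc`).
#' @param low_hz,high_hz,order band-pass settings, see [emg_bandpass()].
#' @param lp_cutoff_hz,lp_order envelope settings, see [emg_envelope()].
#' @return List with `envelopes` (named list of normalized
#'   `emg_recording`s, same order as `session$trials`) and `mvc_profile`.
#' @export
preprocess_session <- function(session, low_hz = 40, high_hz = 500, order = 4,
                               lp_cutoff_hz = 6, lp_order = 2) {
  proc <- function(rec)
    emg_envelope(emg_bandpass(rec, low_hz, high_hz, order),
                 lp_cutoff_hz, lp_order)
  mvc_envs <- lapply(session$mvc, proc)
  prof <- mvc_profile(mvc_envs)
  envs <- lapply(session$trials, function(rec) mvc_normalize(proc(rec), prof))
  list(envelopes = envs, mvc_profile = prof)
}
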