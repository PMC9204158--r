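#' Configuration for greedy Gaussian segmentation
#'
#' @param n_breakpoints number of breakpoints K (3 splits a trial into the
#'   four protocol phases).
#' @param lambda unitless covariance regularizer; the segment covariance is
#'   diagonally loaded with `lambda * trace(Sigma)/d` (absolute floor
#'   1e-12, so constant segments stay finite).
#' @param min_segment_ms minimum segment duration in ms.
#' @param decimate_to_hz rate the input is resampled to before
#'   segmentation; envelopes are band-limited far below this, so plain
#'   subsampling is alias-free.
#' @param max_sweeps maximum number of cyclic breakpoint-adjustment sweeps
#'   after each insertion.
#' @return A list of class `ggs_config`.
#' @export
ggs_config <- function(n_breakpoints = 3, lambda = 1e-3, min_segment_ms = 100,
                       decimate_to_hz = 100, max_sweeps = 20) {
  if (n_breakpoints < 0) stop("`n_breakpoints` must be >= 0")
  if (lambda <= 0) stop("`lambda` must be positive")
  if (min_segment_ms <= 0) stop("`min_segment_ms` must be positive")
  if (max_sweeps < 1) stop("`max_sweeps` must be >= 1")
  structure(list(n_breakpoints = as.integer(n_breakpoints), lambda = lambda,
                 min_segment_ms = min_segment_ms,
                 decimate_to_hz = decimate_to_hz,
                 max_sweeps = as.integer(max_sweeps)),
            class = "ggs_config")
}

# Cumulative first and second moments of an N x d series. Row k+1 holds the
# sums over rows 1..k, so segment [i, j) statistics are O(d^2) differences.
ggs_cumstats <- function(X) {
  N <- nrow(X); d <- ncol(X)
  outer_rows <- X[, rep(seq_len(d), each = d), drop = FALSE] *
    X[, rep(seq_len(d), times = d), drop = FALSE]
  list(
    S1 = rbind(0, apply(X, 2, cumsum)),
    S2 = rbind(0, apply(outer_rows, 2, cumsum)),
    N = N, d = d
  )
}

# Regularized Gaussian log-likelihood score of segment [i, j) (half-open,
# 1-based), up to partition-independent constants. Compiled kernel.
ggs_score_cs <- function(cs, i, j, lambda) {
  if (j - i < 2) stop("degenerate segment")
  cpp_seg_score(cs$S1, cs$S2, i, j, lambda)
}

#' Gaussian segment score
#'
#' Score of modelling rows `i..j-1` of a multivariate series as one
#' Gaussian segment: `-(n/2) log det(Sigma + lambda * tr(Sigma)/d * I)`
#' with the segment's empirical mean and covariance (population form).
#' Higher is better; constants independent of the partition are dropped.
#'
#' @param X numeric matrix, time in rows.
#' @param i,j half-open 1-based segment bounds, `1 <= i < j <= nrow(X)+1`.
#' @param lambda covariance regularizer (see [ggs_config()]).
#' @return Scalar score.
#' @export
segment_score <- function(X, i, j, lambda = 1e-3) {
  X <- as.matrix(X)
  if (i < 1 || j > nrow(X) + 1 || j - i < 2) stop("invalid segment bounds")
  ggs_score_cs(ggs_cumstats(X), i, j, lambda)
}

# Best split of [s, e) into [s, t) + [t, e): earliest argmax over feasible t.
ggs_best_split <- function(cs, s, e, m, lambda) {
  res <- cpp_best_split(cs$S1, cs$S2, s, e, m, lambda)
  if (!length(res$t)) return(NULL)
  res
}

# Map original-rate sample indices to segmentation-rate row indices.
ggs_decimate_idx <- function(n, fs, to_hz) {
  step <- fs / to_hz
  idx <- unique(pmin(floor(seq(0, n - 1, by = step)) + 1L, n))
  idx
}

#' Fit a greedy Gaussian segmentation
#'
#' Partitions a multichannel series into `K + 1` Gaussian segments by
#' greedy breakpoint insertion: each breakpoint is inserted at the split
#' maximizing the total regularized log-likelihood, and after every
#' insertion all breakpoints are cyclically re-optimized within their
#' neighbours' interval until none moves (or `max_sweeps` is reached). The
#' total objective never decreases across sweeps. An `emg_recording` input
#' is resampled to `decimate_to_hz` first; recovered breakpoints are mapped
#' back to original-rate sample indices and ms.
#'
#' @param x an `emg_recording` (typically the MVC-normalized envelope) or a
#'   channels-by-samples / samples-by-channels numeric matrix (a matrix is
#'   taken as-is at rate `decimate_to_hz`, time along the longer dimension
#'   resolved by `time_in_rows`).
#' @param config a [ggs_config()].
#' @param time_in_rows for matrix input: `TRUE` if rows index time.
#' @return Object of class `segmented_trial`: `breakpoints` (segmentation-
#'   rate row indices, each the first row of the next segment),
#'   `breakpoints_orig`, `breakpoints_ms`, `segments` (half-open index
#'   pairs), `objective`, `objective_trace`, `n`, `fs_seg`, `fs_orig`,
#'   `trial_length_ms`, `config`.
#' @export
ggs_fit <- function(x, config = ggs_config(), time_in_rows = TRUE) {
  if (inherits(x, "emg_recording")) {
    fs_orig <- x$fs
    keep <- ggs_decimate_idx(ncol(x$samples), fs_orig, config$decimate_to_hz)
    X <- t(x$samples[, keep, drop = FALSE])
    fs_seg <- config$decimate_to_hz
    orig_idx <- keep
    trial_len_ms <- 1000 * ncol(x$samples) / fs_orig
  } else {
    X <- as.matrix(x)
    if (!time_in_rows) X <- t(X)
    fs_seg <- config$decimate_to_hz
    fs_orig <- fs_seg
    orig_idx <- seq_len(nrow(X))
    trial_len_ms <- 1000 * nrow(X) / fs_seg
  }
  N <- nrow(X); d <- ncol(X)
  K <- config$n_breakpoints
  # fewer rows than channels makes the segment covariance rank-deficient;
  # keep at least d + 2 rows per segment on top of the configured minimum
  m <- max(2L, ceiling(config$min_segment_ms * fs_seg / 1000), d + 2L)
  if (N < (K + 1) * m)
    stop(sprintf("series too short: need >= %d rows for K = %d", (K + 1) * m, K))
  cs <- ggs_cumstats(X)
  lambda <- config$lambda
  bounds <- c(1L, N + 1L)
  total <- function(b) {
    sum(vapply(seq_len(length(b) - 1L),
               function(k) ggs_score_cs(cs, b[k], b[k + 1L], lambda),
               numeric(1)))
  }
  trace <- total(bounds)
  if (K > 0) {
    for (k in seq_len(K)) {
      best <- NULL
      for (s in seq_len(length(bounds) - 1L)) {
        sp <- ggs_best_split(cs, bounds[s], bounds[s + 1L], m, lambda)
        if (is.null(sp)) next
        gain <- sp$val - ggs_score_cs(cs, bounds[s], bounds[s + 1L], lambda)
        if (is.null(best) || gain > best$gain)
          best <- list(t = sp$t, gain = gain)
      }
      if (is.null(best)) stop("no feasible insertion position")
      bounds <- sort(c(bounds, best$t))
      trace <- c(trace, total(bounds))
      # cyclic adjustment sweeps: single-breakpoint moves, then joint moves
      # of adjacent pairs (exact 2-split of their outer span), which escape
      # local optima a lone breakpoint cannot leave
      for (sw in seq_len(config$max_sweeps)) {
        moved <- FALSE
        for (i in seq_len(length(bounds) - 2L)) {
          s <- bounds[i]; e <- bounds[i + 2L]; cur <- bounds[i + 1L]
          sp <- ggs_best_split(cs, s, e, m, lambda)
          cur_val <- ggs_score_cs(cs, s, cur, lambda) +
            ggs_score_cs(cs, cur, e, lambda)
          if (!is.null(sp) && sp$t != cur && sp$val > cur_val) {
            bounds[i + 1L] <- sp$t
            moved <- TRUE
          }
        }
        if (!moved && length(bounds) >= 4L) {
          for (i in seq_len(length(bounds) - 3L)) {
            s <- bounds[i]; e <- bounds[i + 3L]
            b1 <- bounds[i + 1L]; b2 <- bounds[i + 2L]
            pr <- cpp_best_pair(cs$S1, cs$S2, s, e, m, lambda)
            if (!length(pr$t)) next
            cur_val <- ggs_score_cs(cs, s, b1, lambda) +
              ggs_score_cs(cs, b1, b2, lambda) +
              ggs_score_cs(cs, b2, e, lambda)
            if (pr$val > cur_val + 1e-9 && !all(pr$t == c(b1, b2))) {
              bounds[i + 1L] <- pr$t[1]
              bounds[i + 2L] <- pr$t[2]
              moved <- TRUE
            }
          }
        }
        trace <- c(trace, total(bounds))
        if (!moved) break
      }
    }
  }
  bps <- bounds[-c(1L, length(bounds))]
  segs <- cbind(start = bounds[-length(bounds)], end = bounds[-1L])
  bp_orig <- orig_idx[bps]
  structure(list(
    breakpoints = bps,
    breakpoints_orig = bp_orig,
    breakpoints_ms = 1000 * (bp_orig - 1L) / fs_orig,
    segments = segs,
    objective = trace[length(trace)],
    objective_trace = trace,
    n = N, fs_seg = fs_seg, fs_orig = fs_orig,
    trial_length_ms = trial_len_ms,
    config = config
  ), class = "segmented_trial")
}

#' @export
print.segmented_trial <- function(x, ...) {
  cat(sprintf("<segmented_trial> %d breakpoints at %s ms (objective %.2f)\n",
              length(x$breakpoints),
              paste(round(x$breakpoints_ms), collapse = ", "), x$objective))
  if (!is.null(x$phase_names))
    cat("  phases:", paste(x$phase_names, collapse = " -> "), "\n")
  invisible(x)
}

#' Exact segmentation by dynamic programming (test oracle)
#'
#' Globally optimal placement of `K` breakpoints under the same objective
#' as [ggs_fit()], by exact dynamic programming over all feasible
#' partitions. Intended for small instances; refuses when the number of
#' candidate partitions exceeds `max_partitions`.
#'
#' @param X numeric matrix, time in rows, already at the segmentation rate.
#' @param K number of breakpoints.
#' @param lambda covariance regularizer.
#' @param min_segment minimum segment length in rows.
#' @param max_partitions refusal threshold on the feasible-partition count.
#' @return List with `breakpoints` (row indices) and `objective`.
#' @export
exhaustive_fit <- function(X, K, lambda = 1e-3, min_segment = 10,
                           max_partitions = 1e6) {
  X <- as.matrix(X)
  N <- nrow(X); m <- as.integer(min_segment)
  if (m < 2) stop("`min_segment` must be >= 2")
  if (N < (K + 1) * m) stop("series too short for this K and min_segment")
  n_part <- choose(N - (K + 1) * m + K, K)
  if (!is.finite(n_part) || n_part > max_partitions)
    stop(sprintf("instance too large: %g candidate partitions", n_part))
  cs <- ggs_cumstats(X)
  if (K == 0)
    return(list(breakpoints = integer(0),
                objective = ggs_score_cs(cs, 1L, N + 1L, lambda)))
  J <- N + 1L
  # score lookup for every feasible segment [i, j), j - i >= m
  S <- cpp_score_matrix(cs$S1, cs$S2, m, lambda)
  # best[k, j]: optimal score of covering rows [1, j) with k segments
  best <- matrix(-Inf, K + 1L, J)
  argb <- matrix(NA_integer_, K + 1L, J)
  best[1L, ] <- S[1L, ]
  for (k in 2:(K + 1L)) {
    for (j in seq.int(k * m + 1L, J)) {
      is <- seq.int((k - 1L) * m + 1L, j - m)
      vals <- best[k - 1L, is] + S[is, j]
      w <- which.max(vals)
      best[k, j] <- vals[w]
      argb[k, j] <- is[w]
    }
  }
  bps <- integer(K)
  j <- J
  for (k in (K + 1L):2L) {
    bps[k - 1L] <- argb[k, j]
    j <- argb[k, j]
  }
  list(breakpoints = bps, objective = best[K + 1L, J])
}

#' Label the four movement phases of a segmented trial
#'
#' With `K = 3` breakpoints the segments are assigned, in temporal order,
#' the protocol phases reaching, grasping, returning and resting.
#'
#' @param seg a `segmented_trial` with 3 breakpoints.
#' @return The segmentation with `phase_names` set.
#' @export
assign_phases <- function(seg) {
  if (length(seg$breakpoints) != 3L)
    stop("phase assignment requires exactly 3 breakpoints")
  seg$phase_names <- c("reaching", "grasping", "returning", "resting")
  seg
}

#' Convert a phase-labelled segmentation to a phase timeline
#'
#' @param seg a phase-labelled `segmented_trial` (see [assign_phases()]).
#' @return A [phase_timeline()] in ms.
#' @export
as_phase_timeline <- function(seg) {
  if (is.null(seg$phase_names)) seg <- assign_phases(seg)
  phase_timeline(seg$breakpoints_ms, seg$trial_length_ms)
}

#' Per-sample gesture annotation of a segmented trial
#'
#' Samples in the motional phases (reaching, grasping, returning) receive
#' the trial's gesture label; resting samples receive the rest label 0.
#'
#' @param seg a phase-labelled `segmented_trial`, or a [phase_timeline()]
#'   together with `n` and `fs`.
#' @param gesture trial gesture label, a positive integer.
#' @param n,fs sample count and rate of the label sequence; taken from the
#'   segmentation when omitted.
#' @return Integer vector of per-sample labels.
#' @export
annotate_gesture <- function(seg, gesture, n = NULL, fs = NULL) {
  if (!is.numeric(gesture) || length(gesture) != 1L || gesture < 1 ||
      gesture != round(gesture))
    stop("`gesture` must be a positive integer label")
  if (inherits(seg, "segmented_trial")) {
    tl <- as_phase_timeline(seg)
    if (is.null(n)) n <- round(seg$trial_length_ms * seg$fs_orig / 1000)
    if (is.null(fs)) fs <- seg$fs_orig
  } else if (inherits(seg, "phase_timeline")) {
    tl <- seg
    if (is.null(n) || is.null(fs))
      stop("`n` and `fs` are required with a phase_timeline input")
  } else stop("unsupported segmentation object")
  t_ms <- (seq_len(n) - 0.5) * 1000 / fs
  ifelse(phase_at(tl, t_ms) == "resting", 0L, as.integer(gesture))
}

#' Segment every trial of a preprocessed session
#'
#' @param envelopes named list of normalized envelope `emg_recording`s.
#' @param config a [ggs_config()].
#' @return Named list of phase-labelled `segmented_trial`s.
#' @export
segment_session <- function(envelopes, config = ggs_config()) {
  lapply(envelopes, function(env) assign_phases(ggs_fit(env, config)))
}
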