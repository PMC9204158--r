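# Shared fixtures. Heavier artefacts (full pipeline runs) are memoized so
# several test files can reuse the same computation within one test session.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) assign(name, build(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Small but protocol-shaped session config: 3 gestures, 6 trials each.
tiny_config <- function(...) {
  protocol_config(n_gestures = 3, objects_per_gesture = 1,
                  trials_per_object = 6, seed = 11, ...)
}

# Activation profile with explicit per-phase levels, identical on all
# channels, for tests that need exact amplitude control.
manual_profile <- function(config, reaching, grasping,
                           returning = reaching,
                           resting = config$baseline_amplitude,
                           ramp_ms = config$ramp_ms) {
  G <- config$n_gestures; C <- config$n_channels
  amp <- array(0, dim = c(G, 4, C),
               dimnames = list(NULL,
                               c("reaching", "grasping", "returning", "resting"),
                               NULL))
  amp[, "reaching", ] <- reaching
  amp[, "grasping", ] <- grasping
  amp[, "returning", ] <- returning
  amp[, "resting", ] <- resting
  structure(list(amp = amp, ramp_ms = ramp_ms), class = "activation_profile")
}

# Evaluation-curves data frame from explicit curve values.
make_curves <- function(t_ms, p_grasp, p_rest, p_top = 0, support = 10L) {
  out <- data.frame(t_ms = t_ms, p_grasp = p_grasp, p_rest = p_rest,
                    p_top = p_top, acc_grasp = NA, acc_rest = NA,
                    support = support, n_motional = support, n_resting = 0L)
  class(out) <- c("evaluation_curves", "data.frame")
  attr(out, "step_ms") <- if (length(t_ms) > 1) diff(t_ms[1:2]) else 40
  out
}

# Aligned trial from an explicit probability matrix (columns "0".."13").
make_aligned <- function(t_ms, probs, gesture, phase = NULL, step_ms = 40) {
  if (is.null(phase)) phase <- rep("reaching", length(t_ms))
  structure(list(t_ms = t_ms, phase = phase, probs = probs,
                 gesture = as.integer(gesture),
                 prepended = rep(FALSE, length(t_ms)),
                 has_prepend = FALSE, step_ms = step_ms),
            class = "aligned_trial")
}

# Probability matrix that puts mass p on one class, the rest spread evenly.
prob_matrix <- function(n, class, p = 0.9, classes = 0:13) {
  k <- length(classes)
  m <- matrix((1 - p) / (k - 1), n, k, dimnames = list(NULL, classes))
  m[, as.character(class)] <- p
  m
}

# Small classification fixture: S3 training on 5 trials per object of the
# tiny session, holding out fold-1 trials.
clf_fixture <- function() {
  fixture("clf_fixture", function() {
    sess <- fixture("tiny_session", function() generate_session(tiny_config()))
    prep <- fixture("tiny_prep", function()
      preprocess_session(fixture("tiny_session", function()
        generate_session(tiny_config()))))
    feats <- fixture("tiny_feats", function()
      featurize_session(prep$envelopes, sess$timelines, sess$manifest))
    split <- build_split(sess$manifest, seed = 1)
    val <- split$trial_id[split$fold == 1]
    train <- select_training_windows(feats[!feats$trial_id %in% val, ], "S3")
    model <- train_gesture_model(train, seed = 5, strategy = "S3")
    hold <- feats[feats$trial_id %in% val & feats$phase == "grasping", ]
    list(model = model, train = train, hold = hold, feats = feats)
  })
}

# Full pipeline run on a reduced session (13 gestures x 1 object x 6
# trials), memoized; `name` distinguishes independent repetitions.
pipeline_fixture <- function(name) {
  fixture(name, function() {
    dir <- file.path(tempdir(), name)
    run <- run_pipeline(protocol_config(objects_per_gesture = 1, seed = 1),
                        split_seed = 7, model_seed = 11, out_dir = dir)
    list(run = run, dir = dir)
  })
}

# Piecewise-stationary multichannel series: one row block per std value.
block_series <- function(stds, block_len, d) {
  do.call(rbind, lapply(stds, function(s)
    matrix(stats::rnorm(block_len * d, 0, s), block_len, d)))
}
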