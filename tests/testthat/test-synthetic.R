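test_that("timeline sampling respects the minimum-phase constraint", {
  # with zero slack there is exactly one feasible timeline
  cfg <- protocol_config(min_phase_ms = 1000, trial_length_ms = 4000)
  set.seed(1)
  tl <- sample_trial_timeline(cfg)
  expect_equal(tl$breakpoints_ms, c(1000, 2000, 3000))

  cfg <- protocol_config()
  set.seed(5)
  a <- sample_trial_timeline(cfg)
  set.seed(5)
  b <- sample_trial_timeline(cfg)
  expect_identical(a$breakpoints_ms, b$breakpoints_ms)

  set.seed(2)
  for (i in 1:10000) {
    tl <- sample_trial_timeline(cfg)
    d <- phase_durations_ms(tl)
    expect_true(all(diff(tl$breakpoints_ms) > 0))
    expect_true(all(d >= cfg$min_phase_ms - 1e-9))
  }

  expect_error(protocol_config(min_phase_ms = 1500), "infeasible")
})

test_that("trial synthesis realizes the configured amplitude structure", {
  cfg <- protocol_config(n_gestures = 1, amp_jitter_sd = 0)

  # zero activation everywhere -> only the noise floor remains
  prof0 <- manual_profile(cfg, reaching = 0, grasping = 0, resting = 0)
  set.seed(3)
  tl <- phase_timeline(c(1000, 2000, 3000), 4000)
  rec <- synth_trial(tl, 1, prof0, cfg)
  expect_equal(ncol(rec$samples), 6250)   # round(4000 ms * 1562.5 / 1000)
  expect_lt(abs(stats::sd(rec$samples[1, ]) - cfg$noise_floor),
            0.3 * cfg$noise_floor)

  # 2:1 grasping:reaching activation -> phase RMS ratio ~ 2 (Monte Carlo)
  prof <- manual_profile(cfg, reaching = 0.25, grasping = 0.5)
  fs <- cfg$fs
  reach_idx <- round(0.2 * fs):round(0.8 * fs)       # phase interiors
  grasp_idx <- round(1.2 * fs):round(1.8 * fs)
  set.seed(4)
  ratios <- replicate(50, {
    r <- synth_trial(tl, 1, prof, cfg)
    sqrt(mean(r$samples[1, grasp_idx]^2)) / sqrt(mean(r$samples[1, reach_idx]^2))
  })
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("per-phase signal variance matches activation^2 within MC tolerance", {
  cfg <- protocol_config(n_gestures = 1, amp_jitter_sd = 0, noise_floor = 0)
  prof <- manual_profile(cfg, reaching = 0.3, grasping = 0.8, returning = 0.2,
                         resting = 0.05)
  tl <- phase_timeline(c(1000, 2000, 3000), 4000)
  fs <- cfg$fs
  interior <- function(a, b) round((a + 0.1) * fs):round((b - 0.1) * fs)
  idx <- list(reaching = interior(0, 1), grasping = interior(1, 2),
              returning = interior(2, 3), resting = interior(3, 4))
  set.seed(8)
  v <- sapply(names(idx), function(ph) {
    mean(replicate(50, {
      r <- synth_trial(tl, 1, prof, cfg)
      mean(r$samples[2, idx[[ph]]]^2)
    }))
  })
  want <- c(0.3, 0.8, 0.2, 0.05)^2
  expect_true(all(abs(v - want) / want < 0.1))
})

test_that("MVC recordings dominate task amplitudes after normalization", {
  cfg <- tiny_config()
  sess <- fixture("tiny_session", function() generate_session(tiny_config()))
  prep <- fixture("tiny_prep", function()
    preprocess_session(fixture("tiny_session", function()
      generate_session(tiny_config()))))

  # MVC length = 3 s worth of samples
  expect_equal(ncol(sess$mvc[[1]]$samples), round(3000 * cfg$fs / 1000))
  expect_equal(length(sess$mvc), cfg$n_channels)
  expect_equal(sess$mvc[[5]]$meta$target_channel, 5)

  # normalized task envelopes stay at or below MVC level
  mx <- max(vapply(prep$envelopes, function(e) max(e$samples), numeric(1)))
  expect_lte(mx, 1.05)
  expect_true(all(vapply(prep$envelopes,
                         function(e) all(e$samples >= 0), logical(1))))
})

test_that("session layout and manifest follow the protocol counts", {
  cfg <- protocol_config()
  expect_equal(cfg$n_gestures * cfg$objects_per_gesture, 52)
  expect_equal(cfg$n_gestures * cfg$objects_per_gesture *
                 cfg$trials_per_object, 312)

  sess <- fixture("tiny_session", function() generate_session(tiny_config()))
  tiny <- tiny_config()
  expect_equal(nrow(sess$manifest),
               tiny$n_gestures * tiny$objects_per_gesture * tiny$trials_per_object)
  expect_equal(length(unique(sess$manifest$object_id)),
               tiny$n_gestures * tiny$objects_per_gesture)
  expect_setequal(unique(sess$manifest$gesture), seq_len(tiny$n_gestures))
  expect_equal(sess$manifest$order, seq_len(nrow(sess$manifest)))

  # one-trial degenerate layout
  one <- generate_session(protocol_config(objects_per_gesture = 1,
                                          trials_per_object = 1, seed = 2))
  expect_equal(nrow(one$manifest), 13)
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- protocol_config(n_gestures = 2, objects_per_gesture = 1,
                         trials_per_object = 2, seed = 99)
  a <- generate_session(cfg)
  b <- generate_session(cfg)
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$trials[[1]]$samples, b$trials[[1]]$samples)
  expect_identical(a$mvc[[1]]$samples, b$mvc[[1]]$samples)
})

test_that("trial CSV round-trips through the disk format", {
  sess <- fixture("tiny_session", function() generate_session(tiny_config()))
  rec <- sess$trials[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_trial_csv(rec, path)
  back <- read_trial_csv(path, rec$fs)
  expect_equal(back$channel_names, rec$channel_names)
  expect_equal(back$samples, rec$samples, tolerance = 1e-6,
               ignore_attr = TRUE)
})
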