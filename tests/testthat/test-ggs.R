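test_that("segment score matches its closed form and its invariances", {
  set.seed(1)
  x <- matrix(rnorm(100), 100, 1)
  # direct evaluation of -(n/2) log det(Sigma + reg) in one dimension
  s2 <- mean((x - mean(x))^2)
  lam <- 1e-9
  want <- -(100 / 2) * log(s2 + max(lam * s2, 1e-12))
  expect_equal(segment_score(x, 1, 101, lam), want)
  expect_lt(abs(segment_score(x, 1, 101, lam)), 25)  # s2 ~ 1 so score ~ 0

  # constant segment: trace 0, absolute regularizer floor keeps it finite
  const <- matrix(5, 50, 2)
  expect_true(is.finite(segment_score(const, 1, 51)))

  # mean-centred covariance: offsets do not change the score
  set.seed(2)
  y <- matrix(rnorm(200), 100, 2)
  expect_equal(segment_score(y, 10, 60), segment_score(y + 7, 10, 60))

  expect_error(segment_score(y, 50, 51), "invalid segment")
})

test_that("scaling all channels shifts scores uniformly, keeping argmax splits", {
  set.seed(3)
  x <- block_series(c(0.2, 1.5), 60, 2)
  cfg <- ggs_config(n_breakpoints = 1, decimate_to_hz = 100)
  a <- ggs_fit(x, cfg)
  b <- ggs_fit(10 * x, cfg)
  expect_identical(a$breakpoints, b$breakpoints)
  # shift is n * d * log(10) overall, independent of the partition
  expect_equal(b$objective - a$objective, -120 * 2 * log(10), tolerance = 1e-6)
})

test_that("greedy fit recovers well-separated blocks and never decreases", {
  set.seed(4)
  x <- block_series(c(0.1, 1.0, 0.5, 0.1), 100, 12)
  fit <- ggs_fit(x, ggs_config(n_breakpoints = 3))
  expect_true(all(abs(fit$breakpoints - c(101, 201, 301)) <= 2))
  expect_true(all(diff(fit$objective_trace) >= -1e-8))

  # K = 0 degenerates to the single-segment score
  f0 <- ggs_fit(x, ggs_config(n_breakpoints = 0))
  expect_equal(f0$objective, segment_score(x, 1, nrow(x) + 1, 1e-3))
  expect_length(f0$breakpoints, 0)

  expect_error(ggs_fit(x[1:20, ], ggs_config(n_breakpoints = 3)),
               "too short")
})

test_that("exact dynamic programming bounds and matches the greedy fit", {
  set.seed(5)
  # K = 1 on a clean 2-block series finds the true boundary
  x2 <- block_series(c(0.1, 1.2), 50, 2)
  ex <- exhaustive_fit(x2, K = 1, min_segment = 10)
  expect_true(abs(ex$breakpoints - 51) <= 1)

  # exhaustive >= greedy on any instance; equality on separated blocks
  for (i in 1:5) {
    x <- block_series(runif(4, 0.1, 2), 30, 2)
    gr <- ggs_fit(x, ggs_config(n_breakpoints = 3, min_segment_ms = 100))
    ex <- exhaustive_fit(x, K = 3, min_segment = 10)
    expect_gte(ex$objective, gr$objective - 1e-8)
  }

  expect_error(exhaustive_fit(matrix(rnorm(4000), 2000, 2), K = 3,
                              min_segment = 2, max_partitions = 1e6),
               "too large")
})

test_that("greedy matches the exact optimum on separated small instances", {
  set.seed(6)
  for (i in 1:50) {
    ratio <- sample(c(4, 10, 20), 1)
    base <- runif(1, 0.1, 0.3)
    stds <- base * c(1, sqrt(ratio), 1, sqrt(ratio) * 1.5)
    d <- sample(2:3, 1)       # multivariate, the method's operating regime
    x <- block_series(stds, 30, d)
    gr <- ggs_fit(x, ggs_config(n_breakpoints = 3, min_segment_ms = 100))
    ex <- exhaustive_fit(x, K = 3, min_segment = 10)
    gap <- (ex$objective - gr$objective) / max(abs(ex$objective), 1)
    expect_lte(gap, 0.01)
  }
  # breakpoint-exact agreement whenever variances are strongly separated
  set.seed(60)
  for (i in 1:15) {
    stds <- runif(1, 0.1, 0.3) * c(1, sqrt(10), 1, sqrt(20))
    x <- block_series(stds, 30, 2)
    gr <- ggs_fit(x, ggs_config(n_breakpoints = 3, min_segment_ms = 100))
    ex <- exhaustive_fit(x, K = 3, min_segment = 10)
    expect_identical(gr$breakpoints, as.integer(ex$breakpoints))
  }
})

test_that("phase assignment and gesture annotation follow the protocol", {
  set.seed(7)
  x <- block_series(c(0.1, 1.0, 0.5, 0.1), 100, 3)
  seg <- assign_phases(ggs_fit(x, ggs_config(n_breakpoints = 3)))
  expect_equal(seg$phase_names,
               c("reaching", "grasping", "returning", "resting"))
  tl <- as_phase_timeline(seg)
  expect_equal(sum(phase_durations_ms(tl)), seg$trial_length_ms)
  expect_equal(tl$breakpoints_ms[1], seg$breakpoints_ms[1])

  lab <- annotate_gesture(seg, 5)
  expect_setequal(unique(lab), c(5L, 0L))
  n <- round(seg$trial_length_ms * seg$fs_orig / 1000)
  expect_length(lab, n)
  # resting span = count of 0 labels / fs
  expect_equal(sum(lab == 0) * 1000 / seg$fs_orig,
               phase_durations_ms(tl)[["resting"]], tolerance = 20)

  expect_error(annotate_gesture(seg, 0), "positive integer")
  seg2 <- ggs_fit(x, ggs_config(n_breakpoints = 1))
  expect_error(assign_phases(seg2), "3 breakpoints")
})
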