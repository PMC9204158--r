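test_that("alignment zeroes grasp onset and prepends prior rest context", {
  n <- 10
  w <- data.frame(start_ms = seq(0, by = 40, length.out = n),
                  phase = c(rep("reaching", 5), rep("grasping", 5)))
  p <- prob_matrix(n, class = 2)
  # a window starting exactly at b1 gets aligned time 0
  al <- align_trial(w, p, b1_ms = 200, gesture = 2)
  expect_equal(al$t_ms[6], 0)
  expect_false(al$has_prepend)

  # prepended block spans floor(700/40) = 17 grid points
  pw <- data.frame(start_ms = seq(0, by = 40, length.out = 93),
                   phase = c(rep("returning", 60), rep("resting", 33)))
  pp <- prob_matrix(93, class = 0)
  al2 <- align_trial(w, p, b1_ms = 200, gesture = 2,
                     prev_windows = pw, prev_probs = pp)
  expect_true(al2$has_prepend)
  expect_equal(sum(al2$prepended), 17)
  expect_equal(al2$t_ms[1], -200 - 17 * 40)
  expect_true(all(al2$phase[al2$prepended] == "resting"))

  expect_error(align_trial(w, p[1:3, ], 200, 2), "one row per window")
})

test_that("curve averaging pools trials pointwise with support counts", {
  t <- seq(-200, 200, by = 40)
  a <- make_aligned(t, prob_matrix(length(t), 3, p = 0.2), gesture = 3)
  b <- make_aligned(t, prob_matrix(length(t), 3, p = 0.6), gesture = 3)
  cv <- average_curves(list(a, b))
  expect_equal(cv$p_grasp, rep(0.4, length(t)))
  expect_equal(cv$support, rep(2L, length(t)))

  # a single trial reproduces its own values
  cv1 <- average_curves(list(a))
  expect_equal(cv1$p_grasp, rep(0.2, length(t)))

  # partial overlap: support reflects who covers each grid point
  c2 <- make_aligned(t + 400, prob_matrix(length(t), 3, p = 0.6), gesture = 3)
  cv2 <- average_curves(list(a, c2))
  expect_equal(range(cv2$support), c(1L, 2L))
  # convex combination: min <= mean <= max pointwise
  expect_true(all(cv2$p_grasp >= 0.2 - 1e-12 & cv2$p_grasp <= 0.6 + 1e-12))

  expect_error(average_curves(list()), "no aligned trials")
})

test_that("intersection time finds the persistent crossing with refinement", {
  t <- seq(-1000, 0, by = 40)
  # constant curves: grasp already above rest -> earliest grid time
  cv <- make_curves(t, p_grasp = 0.6, p_rest = 0.4)
  expect_equal(intersection_time(cv), -1000)

  # symmetric linear crossing at the midpoint
  up <- seq(0, 1, length.out = length(t))
  cv2 <- make_curves(t, p_grasp = up, p_rest = rev(up))
  expect_equal(intersection_time(cv2), -500)

  # crossing between grid points -520 and -480: (0.45, 0.55) vs (0.50, 0.50)
  pg <- ifelse(t < -520, 0.45, 0.55); pg[t == -520] <- 0.45
  pr <- rep(0.50, length(t))
  expect_equal(intersection_time(make_curves(t, pg, pr)), -500)

  # no crossing -> undefined
  cv3 <- make_curves(t, p_grasp = 0.2, p_rest = 0.6)
  expect_true(is.na(intersection_time(cv3)))

  # a blip shorter than the persistence horizon is ignored
  pg4 <- rep(0.3, length(t)); pg4[5] <- 0.9
  expect_true(is.na(intersection_time(make_curves(t, pg4, 0.5))))

  # low-support tail points are masked from the search
  cv5 <- make_curves(t, p_grasp = 0.6, p_rest = 0.4,
                     support = c(1L, rep(50L, length(t) - 1L)))
  expect_equal(intersection_time(cv5), t[2])
})

test_that("probability margin is the peak-to-competitor distance", {
  t <- seq(-400, 400, by = 40)
  pg <- 0.3 + 0.6 * exp(-(t / 200)^2)      # peak 0.9 at t = 0
  cv <- make_curves(t, pg, p_rest = 0.2, p_top = 0.05)
  m <- probability_margin(cv)
  expect_equal(m$d_p, 0.85)
  expect_equal(m$t_peak_ms, 0)

  # coinciding curves give zero margin
  cv2 <- make_curves(t, pg, p_rest = 0.2, p_top = pg)
  expect_equal(probability_margin(cv2)$d_p, 0)

  # hand-computed three-class toy: peak 0.7 at -80, competitor 0.25 there
  t3 <- c(-160, -120, -80, -40, 0)
  cv3 <- make_curves(t3, p_grasp = c(0.2, 0.5, 0.7, 0.6, 0.4),
                     p_rest = c(0.6, 0.3, 0.05, 0.1, 0.3),
                     p_top = c(0.2, 0.2, 0.25, 0.3, 0.3))
  m3 <- probability_margin(cv3)
  expect_equal(m3$d_p, 0.45)
  expect_equal(m3$t_peak_ms, -80)
})

test_that("accuracy curves hit 1 for perfect and 1/14 for random predictors", {
  t <- seq(-200, 200, by = 40)
  phase <- c(rep("resting", 3), rep("reaching", 4), rep("grasping", 4))
  perfect <- lapply(1:5, function(g) {
    p <- prob_matrix(length(t), g, p = 0.99)
    p[phase == "resting", ] <- prob_matrix(sum(phase == "resting"), 0, 0.99)
    make_aligned(t, p, gesture = g, phase = phase)
  })
  cv <- average_curves(perfect)
  expect_true(all(cv$acc_grasp[!is.na(cv$acc_grasp)] == 1))
  expect_true(all(cv$acc_rest[!is.na(cv$acc_rest)] == 1))
  expect_true(all(cv$p_grasp >= 0 & cv$p_grasp <= 1))

  set.seed(9)
  rand <- lapply(1:1000, function(i) {
    p <- matrix(runif(length(t) * 14), length(t), 14,
                dimnames = list(NULL, 0:13))
    make_aligned(t, p / rowSums(p), gesture = sample(1:13, 1), phase = phase)
  })
  cvr <- average_curves(rand)
  expect_lt(abs(mean(cvr$acc_grasp, na.rm = TRUE) - 1 / 14), 0.02)
  expect_lt(abs(mean(cvr$acc_rest, na.rm = TRUE) - 1 / 14), 0.02)
})

test_that("pre-shaping confusion matrix reflects the predictor", {
  t <- seq(-600, 200, by = 40)
  perfect <- lapply(1:13, function(g)
    make_aligned(t, prob_matrix(length(t), g, 0.99), gesture = g))
  cm <- confusion_summary(perfect, window = c(-600, 0))
  expect_equal(cm$mean_accuracy, 1)
  expect_equal(unname(diag(cm$matrix)[2:14]), rep(1, 13))
  expect_true(all(abs(rowSums(cm$matrix)[rowSums(cm$counts) > 0] - 1) < 1e-12))

  always3 <- lapply(1:13, function(g)
    make_aligned(t, prob_matrix(length(t), 3, 0.99), gesture = g))
  cm3 <- confusion_summary(always3, window = c(-600, 0))
  expect_true(all(cm3$matrix[rowSums(cm3$counts) > 0, "3"] == 1))
  expect_equal(sum(cm3$matrix[, setdiff(colnames(cm3$matrix), "3")]), 0)

  expect_error(confusion_summary(perfect, window = c(100, 200)),
               "before grasp onset")
})
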