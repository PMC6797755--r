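test_that("embryo_mask recovers the embryo footprint", {
  st <- image_stack(matrix(100, 20, 20))
  expect_true(all(embryo_mask(st)))

  half <- cbind(matrix(0, 10, 10), matrix(100, 10, 10))
  m <- embryo_mask(image_stack(half))[, , 1]
  expect_identical(m, half > 0)

  # synthetic embryo disc on zero background: Jaccard >= 0.95
  yy <- row(matrix(0, 60, 60)); xx <- col(matrix(0, 60, 60))
  disc <- (yy - 30)^2 + (xx - 30)^2 <= 20^2
  frame <- ifelse(disc, 80, 0)
  m <- embryo_mask(image_stack(frame))[, , 1]
  jac <- sum(m & disc) / sum(m | disc)
  expect_gte(jac, 0.95)

  expect_false(any(embryo_mask(image_stack(matrix(0, 5, 5)))))
})

test_that("classify_frame applies the fold rule against the neighbour mean", {
  mask <- matrix(TRUE, 9, 9)
  cl <- classify_frame(matrix(100, 9, 9), mask)
  expect_true(all(cl$labels == 0))
  expect_true(all(cl$fold == 1))

  frame <- matrix(100, 9, 9); frame[5, 5] <- 300
  cl <- classify_frame(frame, mask)
  expect_equal(cl$labels[5, 5], 1L)
  expect_equal(cl$fold[5, 5], 3)
  expect_equal(sum(cl$labels != 0), 1)
  # an 8-neighbour of the outlier sees mean (7*100 + 300)/8 = 125
  expect_equal(cl$fold[5, 4], 100 / 125)

  frame[5, 5] <- 40
  cl <- classify_frame(frame, mask)
  expect_equal(cl$labels[5, 5], -1L)
  expect_equal(cl$fold[5, 5], 0.4)

  # strict threshold: a fold of exactly 2.0 is not noise
  frame <- matrix(100, 9, 9); frame[5, 5] <- 200
  cl <- classify_frame(frame, mask)
  expect_equal(cl$fold[5, 5], 2)
  expect_equal(cl$labels[5, 5], 0L)

  # zero neighbour statistic: positive pixel flagged High with Inf fold;
  # its zero-valued neighbours sit strictly below half their neighbour
  # mean and classify Low
  frame <- matrix(0, 5, 5); frame[3, 3] <- 10
  cl <- classify_frame(frame, matrix(TRUE, 5, 5))
  expect_equal(cl$labels[3, 3], 1L)
  expect_equal(cl$fold[3, 3], Inf)
  expect_equal(sum(cl$labels == -1L), 8)
  expect_true(all(cl$labels[abs(row(frame) - 3) > 1 |
                              abs(col(frame) - 3) > 1] == 0))

  # median neighbour statistic is robust to one bright neighbour
  frame <- matrix(100, 9, 9); frame[5, 4] <- 1e5; frame[5, 5] <- 300
  cl_med <- classify_frame(frame, mask,
                           noise_params(neighbour_stat = "median"))
  expect_equal(cl_med$labels[5, 5], 1L)
  expect_equal(cl_med$fold[5, 5], 3)
})

test_that("persistence filter separates events, transients and short runs", {
  lab <- array(0L, c(4, 4, 10))
  lab[2, 2, 3:5] <- 1L       # 3-frame run: 10.5 min > 6 -> event
  lab[3, 3, 7] <- 1L         # single frame -> transient
  lab[4, 4, c(1, 3, 5)] <- 1L  # alternating -> 3 transients
  pf <- persistence_filter(lab, noise_params(), frame_interval_min = 3.5)
  expect_equal(nrow(pf$events), 1)
  expect_equal(pf$events$start_frame, 3)
  expect_equal(pf$events$end_frame, 5)
  expect_equal(pf$events$event_class, "High")
  expect_equal(sum(pf$transients_per_frame), 4)
  expect_equal(pf$transients_per_frame[7], 1)
  expect_equal(pf$transients_per_frame[c(1, 3, 5)], c(1L, 1L, 1L))

  # both criteria enforced: 2 frames at 2.5 min = 5 min <= 6 -> no event,
  # logged as a short run, not a transient
  lab2 <- array(0L, c(3, 3, 5)); lab2[2, 2, 2:3] <- 1L
  pf2 <- persistence_filter(lab2, noise_params(), frame_interval_min = 2.5)
  expect_equal(nrow(pf2$events), 0)
  expect_equal(sum(pf2$transients_per_frame), 0)
  expect_equal(pf2$n_short_runs, 1)

  # a class switch terminates the run: High then Low, each 2 frames
  lab3 <- array(0L, c(3, 3, 6)); lab3[2, 2, 1:2] <- 1L; lab3[2, 2, 3:4] <- -1L
  pf3 <- persistence_filter(lab3, noise_params(), frame_interval_min = 3.5)
  expect_equal(pf3$events$event_class, c("High", "Low"))
})

test_that("detect_noise recovers planted events and excludes all spikes", {
  sc <- planted_scene(n_events = 12, n_spikes = 30, seed = 5)
  det <- detect_noise(sc$stack)
  expect_equal(nrow(det$events), 12)
  expect_equal(sum(det$transients_per_frame), 30)
  m <- match_events(det$events, sc$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)

  # peak fold reflects the planted multiplicative deviation
  expect_true(all(abs(det$events$peak_fold - 3) < 0.2))

  # spike amplitude never creates an event; every excursion it causes
  # (including the depressed one-frame halo a very bright spike leaves in
  # its neighbours' fold maps) is excluded as a transient
  for (amp in c(5, 50, 1000)) {
    sc2 <- planted_scene(n_events = 0, n_spikes = 10, seed = 2)
    sc2$truth$events$fold <- amp
    st <- render_stack(sc2$field, sc2$truth)
    det2 <- detect_noise(st)
    expect_equal(nrow(det2$events), 0)
    expect_gte(sum(det2$transients_per_frame), 10)
  }
  sc3 <- planted_scene(n_events = 0, n_spikes = 10, seed = 2)
  det3 <- detect_noise(render_stack(sc3$field, sc3$truth))
  expect_equal(sum(det3$transients_per_frame), 10)  # moderate folds: 1:1
})

test_that("detection is invariant to global intensity scaling", {
  sc <- planted_scene(n_events = 8, n_spikes = 15, seed = 11,
                      noise_model = "gaussian")
  det1 <- detect_noise(sc$stack)
  scaled <- image_stack(sc$stack$data * 7.3, sc$stack$pixel_size_um,
                        sc$stack$frame_interval_min)
  det2 <- detect_noise(scaled)
  discrete <- setdiff(names(det1$events), "peak_fold")
  expect_identical(det1$events[discrete], det2$events[discrete])
  expect_equal(det1$events$peak_fold, det2$events$peak_fold,
               tolerance = 1e-12)
  expect_identical(det1$time_course, det2$time_course)
})

test_that("smooth inputs yield zero events and zero transients", {
  det <- detect_noise(image_stack(array(42, c(30, 30, 8))))
  expect_equal(nrow(det$events), 0)
  expect_equal(sum(det$transients_per_frame), 0)

  # exponential gradient with per-pixel neighbour ratio far below 2
  cfg <- sim_config(width_px = 80, height_px = 40, n_frames = 6,
                    unfit_rate = 0, spike_rate = 0, decay_length_um = 100)
  sc <- simulate_scene(cfg)
  det <- detect_noise(sc$stack)
  expect_equal(nrow(det$events), 0)
  expect_equal(sum(det$transients_per_frame), 0)
})

test_that("time-course pixel counts conserve event run lengths", {
  sc <- planted_scene(n_events = 15, n_spikes = 20, seed = 8)
  det <- detect_noise(sc$stack)
  expect_equal(sum(det$time_course$high_px + det$time_course$low_px),
               sum(det$events$run_length))
  expect_equal(sum(det$time_course$transients), 20)
  expect_true(all(det$time_course[, -1] >= 0))
})

test_that("too-short stacks fail cleanly", {
  st <- image_stack(array(1, c(5, 5, 1)))
  expect_error(detect_noise(st), "stack too short")
})
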