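test_that("gradient fields follow their analytic forms", {
  cfg <- sim_config(width_px = 20, height_px = 10,
                    gradient_kind = "constant", posterior_level = 100)
  expect_true(all(make_gradient_field(cfg) == 100))

  # exponential: at 10 columns from the posterior edge with 6.5-um pixels
  # and a 65-um decay length, intensity is posterior_level / e
  cfg <- sim_config(width_px = 40, height_px = 5,
                    gradient_kind = "exponential", posterior_level = 100,
                    anterior_level = 1, decay_length_um = 65)
  f <- make_gradient_field(cfg)
  expect_equal(f[1, 40 - 10], 100 / exp(1))
  expect_equal(f[1, 40], 100)  # posterior edge

  # linear ramp 200 -> 100 over 50 columns: the midpoint value is 150
  cfg <- sim_config(width_px = 50, height_px = 4, gradient_kind = "linear",
                    posterior_level = 200, anterior_level = 100)
  f <- make_gradient_field(cfg)
  expect_equal(mean(f[1, 25:26]), 150)
  expect_equal(f[1, 1], 100)
  expect_equal(f[1, 50], 200)
})

test_that("gradient fields are monotone toward the posterior, any axis", {
  for (axis in c("x+", "x-", "y+", "y-")) {
    for (kind in c("exponential", "linear")) {
      cfg <- sim_config(width_px = 30, height_px = 25, ap_axis = axis,
                        gradient_kind = kind, posterior_level = 150,
                        anterior_level = 10, decay_length_um = 60)
      f <- make_gradient_field(cfg)
      prof <- switch(axis, "x+" = f[1, ], "x-" = rev(f[1, ]),
                     "y+" = f[, 1], "y-" = rev(f[, 1]))
      expect_true(all(diff(prof) >= 0), info = paste(axis, kind))
    }
  }
})

test_that("spawn_events honours rates, lifetimes and the seed", {
  cfg <- sim_config(unfit_rate = 0, spike_rate = 0)
  expect_equal(nrow(spawn_events(cfg)$events), 0)

  # elimination off: every event lives exactly max_lifetime_frames unless
  # truncated by the movie end
  cfg <- sim_config(elimination_rate = 0, max_lifetime_frames = 5,
                    n_frames = 10, spike_rate = 0, unfit_rate = 1,
                    seed = 42)
  ev <- spawn_events(cfg)$events
  expect_true(all(ev$end_frame ==
                    pmin(ev$start_frame + 4L, cfg$n_frames)))
  started_early <- ev$start_frame == 2
  if (any(started_early))
    expect_true(all(ev$end_frame[started_early] == 6))

  # bit-identical reproduction from (config, seed)
  t1 <- spawn_events(cfg); t2 <- spawn_events(cfg)
  expect_identical(t1$events, t2$events)
  s1 <- render_stack(make_gradient_field(cfg), t1)
  s2 <- render_stack(make_gradient_field(cfg), t2)
  expect_identical(s1$data, s2$data)

  # geometry and fold invariants over several seeds
  for (s in 1:5) {
    cfg <- sim_config(seed = s)
    ev <- spawn_events(cfg)$events
    expect_true(all(ev$x >= 1 & ev$x <= cfg$width_px &
                      ev$y >= 1 & ev$y <= cfg$height_px))
    expect_true(all(ev$end_frame >= ev$start_frame))
    expect_true(all(ev$fold > 0))
    tr <- ev$event_class == "Transient"
    expect_true(all(ev$start_frame[tr] == ev$end_frame[tr]))
    expect_true(all(ev$fold[ev$event_class == "High"] > 1))
    expect_true(all(ev$fold[ev$event_class == "Low"] < 1))
  }
})

test_that("persistent-event counts are Poisson with mean rate * frames", {
  cfg <- sim_config(unfit_rate = 0.5, n_frames = 40, spike_rate = 0)
  counts <- vapply(1:1000, function(s) {
    cfg$seed <- s
    sum(spawn_events(cfg)$events$event_class != "Transient")
  }, numeric(1))
  se <- sqrt(20 / 1000)
  expect_lt(abs(mean(counts) - 20), 3 * se)
})

test_that("stronger elimination shortens mean event lifetime", {
  mean_dur <- function(rate) {
    durs <- unlist(lapply(1:100, function(s) {
      cfg <- sim_config(elimination_rate = rate, spike_rate = 0, seed = s)
      ev <- spawn_events(cfg)$events
      ev$end_frame - ev$start_frame + 1
    }))
    mean(durs)
  }
  expect_lte(mean_dur(0.6), mean_dur(0.2))
})

test_that("render_stack is an exact piecewise-multiplicative forward model", {
  cfg <- sim_config(width_px = 30, height_px = 30, n_frames = 6,
                    gradient_kind = "constant", posterior_level = 100,
                    unfit_rate = 0, spike_rate = 0)
  # no events: every frame equals the field
  st <- render_stack(make_gradient_field(cfg), spawn_events(cfg))
  expect_true(all(st$data == 100))

  # one High event, fold 3: in-disc pixels read 300 during the span only
  ev <- data.frame(x = 15, y = 10, event_class = "High", fold = 3,
                   start_frame = 2, end_frame = 4)
  st <- render_stack(make_gradient_field(cfg), ground_truth(ev, cfg))
  expect_equal(st$data[10, 15, 2:4], rep(300, 3))
  expect_equal(st$data[10, 15, c(1, 5, 6)], rep(100, 3))
  expect_true(all(st$data[-10, , ] == 100))

  # noiseless renders take only field or field*fold values
  sc <- planted_scene(n_events = 10, n_spikes = 10, seed = 3)
  vals <- sc$stack$data / array(sc$field, dim(sc$stack$data))
  near <- function(v, t) abs(v - t) < 1e-12
  expect_true(all(near(vals, 1) | near(vals, 3) | near(vals, 1 / 3)))
})

test_that("poisson detector noise is unbiased", {
  cfg <- sim_config(width_px = 4, height_px = 4, n_frames = 10000,
                    gradient_kind = "constant", posterior_level = 200,
                    unfit_rate = 0, spike_rate = 0,
                    noise_model = "poisson", noise_scale = 5)
  st <- render_stack(make_gradient_field(cfg), spawn_events(cfg))
  px_means <- apply(st$data, c(1, 2), mean)
  expect_true(all(abs(px_means - 200) / 200 < 0.01))
})

test_that("make_cell_table plants per-bin marker probabilities", {
  cells <- make_cell_table(30, 50, c(0.5, 0.1), seed = 9)
  expect_equal(nrow(cells), 1500)
  expect_true(all(cells$is_population))
  left <- cells$x < 0.5
  expect_gt(mean(cells$is_marker[left]), mean(cells$is_marker[!left]))
  expect_identical(cells, make_cell_table(30, 50, c(0.5, 0.1), seed = 9))
})

test_that("make_de_table plants the requested contrast structure", {
  de <- make_de_table(8, 3, 2, seed = 1)
  truth <- attr(de, "truth")
  expect_equal(sum(truth$label == "mosaic_specific"), 3)
  expect_equal(sum(truth$label == "shared"), 2)
  expect_equal(nrow(de), 16)
  m <- de[de$contrast == "mosaic_vs_uninjected", ]
  u <- de[de$contrast == "ubiquitous_vs_uninjected", ]
  sig_m <- m$gene_id[m$fdr < 0.1]; sig_u <- u$gene_id[u$fdr < 0.1]
  expect_setequal(setdiff(sig_m, sig_u),
                  truth$gene_id[truth$label == "mosaic_specific"])
  expect_setequal(sig_u, truth$gene_id[truth$label == "shared"])
})
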