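# Scene builders shared across tests. All fixtures are generated in code.

# Deterministic planted scene: n_events persistent events (fixed fold and
# duration) and n_spikes single-frame spikes on a grid of well-separated
# centres over the default smooth exponential gradient.
planted_scene <- function(n_events = 20, n_spikes = 50, fold = 3,
                          duration = 3, width = 100, height = 100,
                          n_frames = 40, gradient_kind = "exponential",
                          noise_model = "none", noise_scale = 0.05,
                          seed = 1L) {
  cfg <- sim_config(width_px = width, height_px = height,
                    n_frames = n_frames, gradient_kind = gradient_kind,
                    unfit_rate = 0, spike_rate = 0,
                    noise_model = noise_model, noise_scale = noise_scale,
                    seed = seed)
  grid <- expand.grid(x = seq(5, width - 5, by = 10),
                      y = seq(5, height - 5, by = 10))
  stopifnot(nrow(grid) >= n_events + n_spikes)
  ev <- NULL
  if (n_events > 0) {
    starts <- 1 + (seq_len(n_events) - 1) %% (n_frames - duration + 1)
    ev <- data.frame(x = grid$x[seq_len(n_events)],
                     y = grid$y[seq_len(n_events)],
                     event_class = if (fold > 1) "High" else "Low",
                     fold = fold, start_frame = starts,
                     end_frame = starts + duration - 1)
  }
  if (n_spikes > 0) {
    idx <- n_events + seq_len(n_spikes)
    frames <- 1 + (seq_len(n_spikes) - 1) %% n_frames
    sp_fold <- rep(c(3, 1 / 3), length.out = n_spikes)
    ev <- rbind(ev, data.frame(x = grid$x[idx], y = grid$y[idx],
                               event_class = "Transient", fold = sp_fold,
                               start_frame = frames, end_frame = frames))
  }
  truth <- ground_truth(ev, cfg)
  list(cfg = cfg, truth = truth, field = make_gradient_field(cfg),
       stack = render_stack(make_gradient_field(cfg), truth))
}

# Planted persistent events that satisfy both persistence criteria
# (the ones the classifier is required to recover).
eligible_events <- function(truth) {
  ev <- truth$events[truth$events$event_class != "Transient", ,
                     drop = FALSE]
  len <- ev$end_frame - ev$start_frame + 1
  ev[len >= 2 & len * truth$config$frame_interval_min > 6, , drop = FALSE]
}

# Recall of eligible planted events and precision of detected events
# (a detection is true if it falls within the 1-px dilation of a planted
# persistent event and overlaps it in time).
match_events <- function(detected, truth) {
  el <- eligible_events(truth)
  planted <- truth$events[truth$events$event_class != "Transient", ,
                          drop = FALSE]
  hits <- 0L
  for (i in seq_len(nrow(el))) {
    ok <- detected$x == el$x[i] & detected$y == el$y[i] &
      detected$start_frame <= el$end_frame[i] &
      detected$end_frame >= el$start_frame[i]
    if (any(ok)) hits <- hits + 1L
  }
  good <- 0L
  for (i in seq_len(nrow(detected))) {
    near <- abs(planted$x - detected$x[i]) <= 1 &
      abs(planted$y - detected$y[i]) <= 1
    if (any(near)) good <- good + 1L
  }
  list(recall = if (nrow(el)) hits / nrow(el) else 1,
       precision = if (nrow(detected)) good / nrow(detected) else 1,
       n_eligible = nrow(el))
}

# Independent Fisher oracle: exhaustive hypergeometric enumeration with
# plain binomial coefficients.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  ks <- max(0, r1 - c2):min(r1, c1)
  pk <- choose(c1, ks) * choose(c2, r1 - ks) / choose(n, r1)
  po <- choose(c1, a) * choose(c2, r1 - a) / choose(n, r1)
  min(1, sum(pk[pk <= po * (1 + 1e-7)]))
}
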