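#' Configuration for a synthetic reporter time-lapse scene
#'
#' Builds the full parameterization of a synthetic single-channel
#' morphogen-reporter movie: a smooth anterior-posterior (AP) intensity
#' gradient, plus three stochastic ingredients layered on top of it:
#'
#' * *persistent outlier cells* ("unfit" cells whose reporter activity
#'   deviates multiplicatively from their surroundings, appearing at rate
#'   `unfit_rate` per frame and surviving a geometric number of frames
#'   governed by `elimination_rate`),
#' * *single-frame spikes* (cosmic-ray / detector hits, rate `spike_rate`
#'   per frame), and
#' * *detector noise* (`noise_model`).
#'
#' The defaults mirror wide-field bioluminescence imaging of an early
#' zebrafish embryo: 6.5 um pixels (at most one deep-cell diameter,
#' ~10 um), and a 3.5 min frame interval so that two consecutive frames
#' span more than 6 minutes.
#'
#' @param width_px,height_px image size in pixels.
#' @param pixel_size_um physical pixel edge length, micrometres.
#' @param frame_interval_min time between frames, minutes.
#' @param n_frames number of frames in the movie.
#' @param gradient_kind `"exponential"`, `"linear"` or `"constant"`.
#' @param posterior_level,anterior_level intensity at the posterior edge and
#'   the floor/level toward the anterior (arbitrary units);
#'   `posterior_level >= anterior_level > 0`.
#' @param decay_length_um exponential decay length, micrometres
#'   (exponential kind only).
#' @param ap_axis direction of increasing posterior: `"x+"`, `"x-"`,
#'   `"y+"` or `"y-"`.
#' @param cell_diameter_um rendered diameter of a planted outlier cell.
#' @param unfit_rate expected new persistent outlier cells per frame.
#' @param unfit_fold_min,unfit_fold_max bounds (> 1) of the multiplicative
#'   deviation; Low cells use the reciprocal fold.
#' @param unfit_class_prob_high probability a planted outlier is High.
#' @param elimination_rate per-frame probability an active outlier cell is
#'   eliminated (apoptosis); 0 encodes the apoptosis-inhibited condition.
#' @param max_lifetime_frames hard cap on outlier lifetime, frames.
#' @param spike_rate expected single-frame spikes per frame.
#' @param noise_model `"none"`, `"gaussian"` or `"poisson"`.
#' @param noise_scale gaussian: noise s.d. as a fraction of local intensity;
#'   poisson: photons per intensity unit (larger = cleaner).
#' @param seed integer master seed; all stochastic draws derive from it.
#' @return A validated `sim_config` list.
#' @seealso [spawn_events()], [render_stack()], [simulate_scene()]
#' @export
sim_config <- function(width_px = 100, height_px = 100,
                       pixel_size_um = 6.5, frame_interval_min = 3.5,
                       n_frames = 40,
                       gradient_kind = c("exponential", "linear", "constant"),
                       posterior_level = 100, anterior_level = 10,
                       decay_length_um = 200,
                       ap_axis = c("x+", "x-", "y+", "y-"),
                       cell_diameter_um = 10,
                       unfit_rate = 0.5,
                       unfit_fold_min = 2.5, unfit_fold_max = 4,
                       unfit_class_prob_high = 0.5,
                       elimination_rate = 0.3,
                       max_lifetime_frames = 8,
                       spike_rate = 1.25,
                       noise_model = c("none", "gaussian", "poisson"),
                       noise_scale = 0.05,
                       seed = 1L) {
  cfg <- list(
    width_px = as.integer(width_px), height_px = as.integer(height_px),
    pixel_size_um = pixel_size_um, frame_interval_min = frame_interval_min,
    n_frames = as.integer(n_frames),
    gradient_kind = match.arg(gradient_kind),
    posterior_level = posterior_level, anterior_level = anterior_level,
    decay_length_um = decay_length_um,
    ap_axis = match.arg(ap_axis),
    cell_diameter_um = cell_diameter_um,
    unfit_rate = unfit_rate,
    unfit_fold_min = unfit_fold_min, unfit_fold_max = unfit_fold_max,
    unfit_class_prob_high = unfit_class_prob_high,
    elimination_rate = elimination_rate,
    max_lifetime_frames = as.integer(max_lifetime_frames),
    spike_rate = spike_rate,
    noise_model = match.arg(noise_model),
    noise_scale = noise_scale,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$width_px < 1 || cfg$height_px < 1 || cfg$n_frames < 1)
    stopf("image dimensions and n_frames must be >= 1")
  if (cfg$pixel_size_um <= 0 || cfg$frame_interval_min <= 0)
    stopf("pixel_size_um and frame_interval_min must be > 0")
  if (cfg$unfit_rate < 0 || cfg$spike_rate < 0)
    stopf("rates must be >= 0")
  if (cfg$unfit_fold_min <= 1 || cfg$unfit_fold_max < cfg$unfit_fold_min)
    stopf("need unfit_fold_max >= unfit_fold_min > 1")
  if (cfg$unfit_class_prob_high < 0 || cfg$unfit_class_prob_high > 1 ||
      cfg$elimination_rate < 0 || cfg$elimination_rate > 1)
    stopf("probabilities must lie in [0, 1]")
  if (!(cfg$posterior_level >= cfg$anterior_level &&
        cfg$anterior_level > 0))
    stopf("need posterior_level >= anterior_level > 0")
  if (cfg$gradient_kind == "exponential" && cfg$decay_length_um <= 0)
    stopf("decay_length_um must be > 0 for the exponential gradient")
  if (cfg$max_lifetime_frames < 1)
    stopf("max_lifetime_frames must be >= 1")
  invisible(cfg)
}

# Distance (um) of each pixel from the posterior edge, as a height x width
# matrix. ap_axis gives the direction of increasing posterior.
posterior_distance_um <- function(cfg) {
  w <- cfg$width_px; h <- cfg$height_px; px <- cfg$pixel_size_um
  switch(cfg$ap_axis,
    "x+" = matrix(rep((w - seq_len(w)) * px, each = h), h, w),
    "x-" = matrix(rep((seq_len(w) - 1) * px, each = h), h, w),
    "y+" = matrix(rep((h - seq_len(h)) * px, h * 0 + w), h, w),
    "y-" = matrix(rep((seq_len(h) - 1) * px, w), h, w))
}

#' Smooth AP gradient field
#'
#' Renders the noiseless background intensity field: monotone non-increasing
#' from the posterior edge toward the anterior edge along `ap_axis`.
#' The exponential kind is
#' `I(d) = posterior_level * exp(-d / decay_length_um)` floored at
#' `anterior_level`, with `d` the distance (um) from the posterior edge;
#' the linear kind ramps from `posterior_level` to `anterior_level` over the
#' axis extent; `constant` is `posterior_level` everywhere.
#'
#' @param cfg a [sim_config()].
#' @return A `height_px` x `width_px` numeric matrix (rows = y, cols = x).
#' @export
make_gradient_field <- function(cfg) {
  validate_sim_config(cfg)
  d <- posterior_distance_um(cfg)
  switch(cfg$gradient_kind,
    constant = matrix(cfg$posterior_level, cfg$height_px, cfg$width_px),
    exponential = pmax(cfg$posterior_level * exp(-d / cfg$decay_length_um),
                       cfg$anterior_level),
    linear = {
      dmax <- max(d)
      if (dmax == 0) {
        matrix(cfg$posterior_level, cfg$height_px, cfg$width_px)
      } else {
        cfg$posterior_level -
          (cfg$posterior_level - cfg$anterior_level) * d / dmax
      }
    })
}

#' Draw planted events for a synthetic scene
#'
#' Spawns the ground-truth event list for one movie. The number of
#' persistent outlier cells over the movie is Poisson with mean
#' `unfit_rate * n_frames`; each survives
#' `1 + min(Geometric(elimination_rate), max_lifetime_frames - 1)` frames
#' (with `elimination_rate = 0`, exactly `max_lifetime_frames`, truncated at
#' the movie end), holds a fold drawn uniformly from
#' `[unfit_fold_min, unfit_fold_max]` (reciprocal for Low cells), and is
#' rendered as a disc of `cell_diameter_um`. Single-frame spikes are Poisson
#' with mean `spike_rate * n_frames` and occupy one pixel for one frame.
#'
#' Event centres are placed uniformly at random but with a minimum
#' centre-to-centre separation (rejection sampling), so that every planted
#' event is spatially identifiable against the others -- a property the
#' ground-truth labels rely on when used as a test oracle.
#'
#' @param cfg a [sim_config()]; `cfg$seed` drives all draws.
#' @return A `ground_truth` object: `list(events, config)` where `events`
#'   is a data frame with columns `x`, `y` (1-based pixel centre),
#'   `event_class` (`"High"`, `"Low"`, `"Transient"`), `fold`,
#'   `start_frame`, `end_frame` (1-based, inclusive).
#' @export
spawn_events <- function(cfg) {
  validate_sim_config(cfg)
  radius_px <- cfg$cell_diameter_um / 2 / cfg$pixel_size_um
  min_sep <- 2 * ceiling(radius_px) + 3   # keeps discs + 1-px halo disjoint
  with_seed(cfg$seed, {
    n_persist <- rpois(1, cfg$unfit_rate * cfg$n_frames)
    n_spike <- rpois(1, cfg$spike_rate * cfg$n_frames)
    margin <- ceiling(radius_px)
    lo_x <- 1 + margin; hi_x <- cfg$width_px - margin
    lo_y <- 1 + margin; hi_y <- cfg$height_px - margin
    if (lo_x > hi_x || lo_y > hi_y)
      stopf("image too small for cell_diameter_um")
    xs <- integer(0); ys <- integer(0)
    place <- function(n) {
      placed <- 0L; tries <- 0L
      while (placed < n && tries < 1000L * n + 1000L) {
        tries <- tries + 1L
        x <- sample(lo_x:hi_x, 1); y <- sample(lo_y:hi_y, 1)
        if (!length(xs) ||
            all(pmax(abs(xs - x), abs(ys - y)) >= min_sep)) {
          xs <<- c(xs, x); ys <<- c(ys, y); placed <- placed + 1L
        }
      }
      if (placed < n)
        warning("event density too high; placed ", placed, " of ", n,
                " events", call. = FALSE)
      placed
    }
    n_persist <- place(n_persist)
    events <- NULL
    if (n_persist > 0) {
      cls <- ifelse(runif(n_persist) < cfg$unfit_class_prob_high,
                    "High", "Low")
      fold_raw <- runif(n_persist, cfg$unfit_fold_min, cfg$unfit_fold_max)
      fold <- ifelse(cls == "High", fold_raw, 1 / fold_raw)
      start <- sample.int(cfg$n_frames, n_persist, replace = TRUE)
      dur <- if (cfg$elimination_rate == 0) {
        rep(cfg$max_lifetime_frames, n_persist)
      } else {
        1 + pmin(rgeom(n_persist, cfg$elimination_rate),
                 cfg$max_lifetime_frames - 1)
      }
      events <- data.frame(
        x = xs[seq_len(n_persist)], y = ys[seq_len(n_persist)],
        event_class = cls, fold = fold, start_frame = start,
        end_frame = pmin(start + dur - 1L, cfg$n_frames))
    }
    n_spike <- place(n_spike)
    if (n_spike > 0) {
      idx <- n_persist + seq_len(n_spike)
      cls <- ifelse(runif(n_spike) < cfg$unfit_class_prob_high,
                    "High", "Low")
      fold_raw <- runif(n_spike, cfg$unfit_fold_min, cfg$unfit_fold_max)
      frame <- sample.int(cfg$n_frames, n_spike, replace = TRUE)
      spikes <- data.frame(
        x = xs[idx], y = ys[idx], event_class = "Transient",
        fold = ifelse(cls == "High", fold_raw, 1 / fold_raw),
        start_frame = frame, end_frame = frame)
      events <- rbind(events, spikes)
    }
    if (is.null(events))
      events <- data.frame(x = integer(0), y = integer(0),
                           event_class = character(0), fold = numeric(0),
                           start_frame = integer(0), end_frame = integer(0))
    structure(list(events = events, config = cfg), class = "ground_truth")
  })
}

#' Construct a ground truth from an explicit event table
#'
#' Lets callers plant an exact set of events (rather than drawing them via
#' [spawn_events()]) and render them with [render_stack()] -- the natural
#' way to build fully controlled validation scenes.
#'
#' @param events data frame with `x`, `y`, `event_class`
#'   (`"High"`/`"Low"`/`"Transient"`), `fold`, `start_frame`, `end_frame`
#'   (1-based, inclusive).
#' @param cfg the [sim_config()] describing geometry, calibration and
#'   noise.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(events, cfg) {
  validate_sim_config(cfg)
  req <- c("x", "y", "event_class", "fold", "start_frame", "end_frame")
  stopifnot(all(req %in% names(events)))
  ev <- events[, req, drop = FALSE]
  if (nrow(ev)) {
    if (any(ev$x < 1 | ev$x > cfg$width_px |
            ev$y < 1 | ev$y > cfg$height_px))
      stopf("event centres must lie inside the image")
    if (any(ev$start_frame < 1 | ev$end_frame > cfg$n_frames |
            ev$end_frame < ev$start_frame))
      stopf("event frame spans must lie inside the movie")
    if (any(ev$fold <= 0)) stopf("folds must be > 0")
    tr <- ev$event_class == "Transient"
    if (any(tr & ev$start_frame != ev$end_frame))
      stopf("Transient events must span exactly one frame")
    if (any(ev$event_class == "High" & ev$fold <= 1) ||
        any(ev$event_class == "Low" & ev$fold >= 1))
      stopf("High events need fold > 1, Low events fold < 1")
  }
  structure(list(events = ev, config = cfg), class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(factor(x$events$event_class,
                      levels = c("High", "Low", "Transient")))
  cat(sprintf("ground_truth: %d events (High %d, Low %d, Transient %d)\n",
              nrow(x$events), tab["High"], tab["Low"], tab["Transient"]))
  invisible(x)
}

# Pixel offsets of a disc of the given radius around a centre pixel.
disc_offsets <- function(radius_px) {
  r <- floor(radius_px)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[g$dx^2 + g$dy^2 <= radius_px^2, , drop = FALSE]
}

#' Render a scene into an image stack
#'
#' Forward model: every pixel starts at the background field value in every
#' frame; inside an active event's disc the value is `field * fold`
#' (single-frame spikes occupy one pixel for one frame); where discs
#' overlap, the most recently started event wins (ties broken by event
#' order). Detector noise, if any, is applied last.
#'
#' @param field background matrix from [make_gradient_field()].
#' @param truth a `ground_truth` from [spawn_events()].
#' @return An [image_stack()].
#' @export
render_stack <- function(field, truth) {
  cfg <- truth$config
  stopifnot(nrow(field) == cfg$height_px, ncol(field) == cfg$width_px)
  h <- cfg$height_px; w <- cfg$width_px; tt <- cfg$n_frames
  data <- array(field, dim = c(h, w, tt))
  ev <- truth$events
  if (nrow(ev)) {
    radius_px <- cfg$cell_diameter_um / 2 / cfg$pixel_size_um
    offs <- disc_offsets(radius_px)
    # ascending start order => later-started events overwrite earlier ones
    ord <- order(ev$start_frame, seq_len(nrow(ev)))
    for (i in ord) {
      if (ev$event_class[i] == "Transient") {
        data[ev$y[i], ev$x[i], ev$start_frame[i]] <-
          field[ev$y[i], ev$x[i]] * ev$fold[i]
      } else {
        yy <- ev$y[i] + offs$dy; xx <- ev$x[i] + offs$dx
        keep <- yy >= 1 & yy <= h & xx >= 1 & xx <= w
        pix <- cbind(yy[keep], xx[keep])
        vals <- field[pix] * ev$fold[i]
        for (f in ev$start_frame[i]:ev$end_frame[i]) {
          data[cbind(pix, f)] <- vals
        }
      }
    }
  }
  if (cfg$noise_model != "none") {
    data <- with_seed(cfg$seed + 1L, {
      switch(cfg$noise_model,
        gaussian = pmax(data * (1 + cfg$noise_scale *
                                  rnorm(length(data))), 0),
        poisson = array(rpois(length(data), data * cfg$noise_scale) /
                          cfg$noise_scale, dim = dim(data)))
    })
  }
  image_stack(data, pixel_size_um = cfg$pixel_size_um,
              frame_interval_min = cfg$frame_interval_min)
}

#' Simulate a full synthetic scene
#'
#' Convenience wrapper: gradient field, planted events and rendered stack
#' in one call.
#'
#' @param cfg a [sim_config()].
#' @return `list(field, truth, stack)`.
#' @export
simulate_scene <- function(cfg) {
  field <- make_gradient_field(cfg)
  truth <- spawn_events(cfg)
  list(field = field, truth = truth, stack = render_stack(field, truth))
}

#' Simulate embryos with AP-bin-dependent marker probabilities
#'
#' Generates a cell table (one row per cell) for `n_embryos` embryos, each
#' with `cells_per_embryo` population cells placed uniformly along a unit
#' AP coordinate. A cell is marker-positive (e.g. caspase-3 active) with
#' probability `bin_probs[b]`, where `b` is the AP bin (equal division of
#' `[0, 1]` into `length(bin_probs)` bins, anterior first). The planted
#' probabilities are attached as `attr(, "bin_probs")` for use as a test
#' oracle.
#'
#' @param n_embryos,cells_per_embryo counts.
#' @param bin_probs per-bin marker probability, anterior to posterior.
#' @param seed integer seed.
#' @return Data frame with `embryo_id`, `x`, `y`, `is_population`,
#'   `is_marker` (AP axis is `x+`).
#' @export
make_cell_table <- function(n_embryos, cells_per_embryo, bin_probs,
                            seed = 1L) {
  stopifnot(n_embryos >= 1, cells_per_embryo >= 1,
            all(bin_probs >= 0 & bin_probs <= 1))
  nb <- length(bin_probs)
  with_seed(seed, {
    n <- n_embryos * cells_per_embryo
    x <- runif(n)
    bin <- pmin(nb, 1L + floor(x * nb))
    cells <- data.frame(
      embryo_id = rep(seq_len(n_embryos), each = cells_per_embryo),
      x = x, y = runif(n),
      is_population = TRUE,
      is_marker = runif(n) < bin_probs[bin])
    attr(cells, "bin_probs") <- bin_probs
    cells
  })
}

#' Build a toy differential-expression table with planted gate structure
#'
#' Generates per-gene statistics for two contrasts, `mosaic_vs_uninjected`
#' and `ubiquitous_vs_uninjected`: exactly `n_mosaic_specific` genes
#' significant (FDR < `fdr_threshold`) only in the mosaic contrast,
#' `n_shared` significant in both, and the rest in neither. Directions
#' (sign of the log2 fold change) are drawn at random and recorded in the
#' ground-truth attribute.
#'
#' @param n_genes total genes; `n_mosaic_specific + n_shared <= n_genes`.
#' @param n_mosaic_specific,n_shared planted set sizes.
#' @param seed integer seed.
#' @param fdr_threshold significance threshold the table is built around.
#' @return Long data frame (`gene_id`, `contrast`, `log2_fold_change`,
#'   `fdr`) with a `truth` attribute: data frame (`gene_id`, `label`,
#'   `direction`).
#' @export
make_de_table <- function(n_genes, n_mosaic_specific, n_shared, seed = 1L,
                          fdr_threshold = 0.1) {
  stopifnot(n_mosaic_specific + n_shared <= n_genes,
            fdr_threshold > 0, fdr_threshold < 1)
  with_seed(seed, {
    gene_id <- sprintf("gene%05d", seq_len(n_genes))
    label <- rep("null", n_genes)
    if (n_mosaic_specific > 0)
      label[seq_len(n_mosaic_specific)] <- "mosaic_specific"
    if (n_shared > 0)
      label[n_mosaic_specific + seq_len(n_shared)] <- "shared"
    label <- sample(label)   # shuffle gene order
    direction <- sample(c("up", "down"), n_genes, replace = TRUE)
    sig_fdr <- function(n) runif(n, 0, fdr_threshold * 0.999)
    ns_fdr <- function(n) runif(n, fdr_threshold, 1)
    lfc <- function(dir) ifelse(dir == "up", 1, -1) *
      runif(length(dir), 0.5, 3)
    sig_m <- label %in% c("mosaic_specific", "shared")
    sig_u <- label == "shared"
    fdr_m <- ifelse(sig_m, NA, 0); fdr_u <- fdr_m
    fdr_m[sig_m] <- sig_fdr(sum(sig_m)); fdr_m[!sig_m] <- ns_fdr(sum(!sig_m))
    fdr_u[sig_u] <- sig_fdr(sum(sig_u)); fdr_u[!sig_u] <- ns_fdr(sum(!sig_u))
    records <- rbind(
      data.frame(gene_id = gene_id, contrast = "mosaic_vs_uninjected",
                 log2_fold_change = lfc(direction), fdr = fdr_m),
      data.frame(gene_id = gene_id, contrast = "ubiquitous_vs_uninjected",
                 log2_fold_change = lfc(direction), fdr = fdr_u))
    # shared genes keep the same direction in both contrasts
    attr(records, "truth") <- data.frame(
      gene_id = gene_id, label = label,
      direction = ifelse(label == "null", NA, direction))
    records
  })
}
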