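#' Calibrated image stack
#'
#' The raw object all imaging operations consume: a single-channel
#' time-lapse as a `height x width x frames` numeric array of nonnegative
#' intensities (arbitrary units), with physical calibration.
#'
#' @param data numeric array, dims `c(height, width, n_frames)`; a matrix
#'   is promoted to a single-frame stack.
#' @param pixel_size_um pixel edge length, micrometres.
#' @param frame_interval_min frame spacing, minutes.
#' @return An `image_stack` object.
#' @export
image_stack <- function(data, pixel_size_um = 6.5,
                        frame_interval_min = 3.5) {
  if (is.matrix(data)) data <- array(data, dim = c(dim(data), 1L))
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(data < 0)) stopf("intensities must be >= 0")
  if (pixel_size_um <= 0 || frame_interval_min <= 0)
    stopf("calibration values must be > 0")
  structure(list(data = data, pixel_size_um = pixel_size_um,
                 frame_interval_min = frame_interval_min),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "image_stack: %d x %d px, %d frames (%.3g um/px, %.3g min/frame)\n",
    d[1], d[2], d[3], x$pixel_size_um, x$frame_interval_min))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

#' Noise-classifier parameters
#'
#' Parameters of the noise-pixel classifier. A pixel retaining more than
#' `fold_threshold`-fold, or less than `1/fold_threshold`-fold, intensity
#' compared with its neighbouring pixels for at least `min_frames` frames
#' *and* strictly longer than `min_duration_min` minutes is a High or Low
#' noise pixel; single-frame excursions are excluded as detector/cosmic-ray
#' transients. Thresholds are strict: a fold of exactly `fold_threshold`
#' is not noise.
#'
#' @param fold_threshold intensity ratio defining High/Low (> 1).
#' @param min_frames minimum run length in frames.
#' @param min_duration_min minimum run duration in minutes, strict; a run of
#'   k frames covers `k * frame_interval_min` minutes.
#' @param neighbourhood_radius_px half-width of the square neighbour ring
#'   (1 = the 8-connected neighbours).
#' @param neighbour_stat `"mean"` or `"median"` of the masked neighbours.
#' @param mask_quantile quantile of frame intensity used by the automatic
#'   embryo mask.
#' @return A `noise_params` list.
#' @export
noise_params <- function(fold_threshold = 2.0, min_frames = 2L,
                         min_duration_min = 6.0,
                         neighbourhood_radius_px = 1L,
                         neighbour_stat = c("mean", "median"),
                         mask_quantile = 0.1) {
  stopifnot(fold_threshold > 1, min_frames >= 1,
            neighbourhood_radius_px >= 1,
            mask_quantile >= 0, mask_quantile <= 1)
  structure(list(fold_threshold = fold_threshold,
                 min_frames = as.integer(min_frames),
                 min_duration_min = min_duration_min,
                 neighbourhood_radius_px = as.integer(neighbourhood_radius_px),
                 neighbour_stat = match.arg(neighbour_stat),
                 mask_quantile = mask_quantile),
            class = "noise_params")
}

#' Automatic per-frame embryo mask
#'
#' Masks the embryo against the dark background: pixels at or above the
#' `mask_quantile` intensity quantile of the frame and strictly positive,
#' then a 3x3 morphological closing. An externally supplied mask always
#' overrides this heuristic in [detect_noise()].
#'
#' @param stack an [image_stack()].
#' @param params a [noise_params()].
#' @return Logical array, same dims as `stack$data`.
#' @export
embryo_mask <- function(stack, params = noise_params()) {
  d <- dim(stack$data)
  out <- array(FALSE, d)
  for (f in seq_len(d[3])) {
    fr <- stack$data[, , f]
    thr <- quantile(fr, params$mask_quantile, names = FALSE)
    m <- fr >= thr & fr > 0
    if (any(m) && !all(m)) {
      m <- EBImage::closing(matrix(as.numeric(m), d[1], d[2]),
                            EBImage::makeBrush(3, "box")) > 0
    }
    out[, , f] <- m
  }
  out
}

# Sum of 2-D shifts of `m` over the ring offsets (zero-padded borders).
shift_sum <- function(m, offsets) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets$dy[k]; dx <- offsets$dx[k]
    ys <- max(1, 1 - dy):min(h, h - dy)
    xs <- max(1, 1 - dx):min(w, w - dx)
    out[ys, xs] <- out[ys, xs] + m[ys + dy, xs + dx]
  }
  out
}

ring_offsets <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g[!(g$dy == 0 & g$dx == 0), , drop = FALSE]
}

#' Classify one frame against its neighbourhood
#'
#' For each masked pixel `p`, `s` is the `neighbour_stat` of the masked
#' pixels in the ring of radius `neighbourhood_radius_px` around `p`
#' (excluding `p` itself). The pixel is High iff `I(p) > fold_threshold*s`
#' and Low iff `I(p) < s / fold_threshold` (strict). Pixels without any
#' masked neighbour are unclassifiable. `s = 0` with `I(p) > 0` is High
#' with an infinite fold (flagged for review); `s = 0` with `I(p) = 0` is
#' none.
#'
#' @param frame numeric matrix.
#' @param mask logical matrix, same shape.
#' @param params a [noise_params()].
#' @return `list(labels, fold)`: `labels` is an integer matrix
#'   (1 = High, -1 = Low, 0 = none), `fold` the ratio `I(p)/s`
#'   (1 where undefined).
#' @export
classify_frame <- function(frame, mask, params = noise_params()) {
  stopifnot(all(dim(frame) == dim(mask)))
  offs <- ring_offsets(params$neighbourhood_radius_px)
  mnum <- mask * 1
  if (params$neighbour_stat == "mean") {
    n_nb <- shift_sum(mnum, offs)
    s <- shift_sum(frame * mnum, offs) / pmax(n_nb, 1)
  } else {
    h <- nrow(frame); w <- ncol(frame)
    vals <- array(NA_real_, c(h, w, nrow(offs)))
    for (k in seq_len(nrow(offs))) {
      dy <- offs$dy[k]; dx <- offs$dx[k]
      ys <- max(1, 1 - dy):min(h, h - dy)
      xs <- max(1, 1 - dx):min(w, w - dx)
      sl <- matrix(NA_real_, h, w)
      src <- frame[ys + dy, xs + dx, drop = FALSE]
      src[!mask[ys + dy, xs + dx, drop = FALSE]] <- NA
      sl[ys, xs] <- src
      vals[, , k] <- sl
    }
    s <- apply(vals, c(1, 2), median, na.rm = TRUE)
    s[is.na(s)] <- 0
    n_nb <- apply(!is.na(vals), c(1, 2), sum)
  }
  labels <- matrix(0L, nrow(frame), ncol(frame))
  fold <- matrix(1, nrow(frame), ncol(frame))
  ok <- mask & n_nb > 0
  pos_s <- ok & s > 0
  fold[pos_s] <- frame[pos_s] / s[pos_s]
  zero_s <- ok & s == 0 & frame > 0
  fold[zero_s] <- Inf
  labels[pos_s & frame > params$fold_threshold * s] <- 1L
  labels[zero_s] <- 1L
  labels[pos_s & frame * params$fold_threshold < s] <- -1L
  list(labels = labels, fold = fold)
}

#' Persistence filter: runs, events and transients
#'
#' Collapses per-frame calls into pixel-wise temporal runs. A maximal
#' same-class consecutive run at a fixed pixel becomes a noise event iff
#' its length is at least `min_frames` frames and its duration
#' (`length * frame_interval_min`) strictly exceeds `min_duration_min`.
#' Length-1 runs failing the criteria are counted as transients (detector /
#' cosmic-ray noise) at their frame; longer runs failing either threshold
#' are dropped and tallied in `n_short_runs`.
#'
#' @param labels integer array `height x width x frames` of per-frame calls
#'   (1 High, -1 Low, 0 none), e.g. stacked [classify_frame()] output.
#' @param params a [noise_params()].
#' @param frame_interval_min frame spacing in minutes.
#' @param fold optional array of per-frame folds; supplies `peak_fold`.
#' @return `list(events, transients_per_frame, n_short_runs)`; `events` is
#'   a data frame (`x`, `y`, `event_class`, `start_frame`, `end_frame`,
#'   `run_length`, `duration_min`, `peak_fold`), 1-based coordinates.
#' @export
persistence_filter <- function(labels, params = noise_params(),
                               frame_interval_min = 3.5, fold = NULL) {
  d <- dim(labels)
  if (d[3] < params$min_frames)
    stopf("stack too short: %d frame(s) < min_frames = %d",
          d[3], params$min_frames)
  transients <- integer(d[3])
  n_short <- 0L
  ev <- list()
  flat <- matrix(labels, d[1] * d[2], d[3])
  active <- which(rowSums(flat != 0L) > 0L)
  for (p in active) {
    r <- rle(flat[p, ])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    y <- (p - 1L) %% d[1] + 1L
    x <- (p - 1L) %/% d[1] + 1L
    for (j in seq_along(r$values)) {
      v <- r$values[j]
      if (v == 0L) next
      len <- r$lengths[j]
      dur <- len * frame_interval_min
      if (len >= params$min_frames && dur > params$min_duration_min) {
        pk <- NA_real_
        if (!is.null(fold)) {
          fr <- fold[y, x, starts[j]:ends[j]]
          pk <- if (v > 0) max(fr) else min(fr)
        }
        ev[[length(ev) + 1L]] <- data.frame(
          x = x, y = y,
          event_class = if (v > 0) "High" else "Low",
          start_frame = starts[j], end_frame = ends[j],
          run_length = len, duration_min = dur, peak_fold = pk)
      } else if (len == 1L) {
        transients[starts[j]] <- transients[starts[j]] + 1L
      } else {
        n_short <- n_short + 1L
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(x = integer(0), y = integer(0), event_class = character(0),
               start_frame = integer(0), end_frame = integer(0),
               run_length = integer(0), duration_min = numeric(0),
               peak_fold = numeric(0))
  events <- events[order(events$start_frame, events$y, events$x), ,
                   drop = FALSE]
  rownames(events) <- NULL
  list(events = events, transients_per_frame = transients,
       n_short_runs = n_short)
}

#' Detect persistent noise pixels in a time-lapse stack
#'
#' Full classifier: per-frame fold-change classification against the local
#' neighbourhood, inside the embryo mask, followed by the temporal
#' persistence filter. Because only intensity *ratios* enter the
#' classification, the result is invariant to global intensity rescaling.
#'
#' @param stack an [image_stack()].
#' @param params a [noise_params()].
#' @param mask optional logical mask: a matrix (applied to every frame) or
#'   an array matching `stack$data`; if missing, [embryo_mask()] is used.
#' @return `list(events, time_course, transients_per_frame, n_short_runs)`.
#'   `time_course` is a data frame per frame: `frame`, `high_px` (pixels in
#'   active High events), `low_px`, `transients` (excluded transients first
#'   seen that frame).
#' @export
detect_noise <- function(stack, params = noise_params(), mask = NULL) {
  d <- dim(stack$data)
  if (d[3] < params$min_frames)
    stopf("stack too short: %d frame(s) < min_frames = %d",
          d[3], params$min_frames)
  if (is.null(mask)) {
    mask <- embryo_mask(stack, params)
  } else if (is.matrix(mask)) {
    mask <- array(mask, dim = d)
  }
  stopifnot(all(dim(mask) == d))
  labels <- array(0L, d)
  fold <- array(1, d)
  for (f in seq_len(d[3])) {
    cl <- classify_frame(stack$data[, , f], mask[, , f], params)
    labels[, , f] <- cl$labels
    fold[, , f] <- cl$fold
  }
  pf <- persistence_filter(labels, params, stack$frame_interval_min, fold)
  high <- integer(d[3]); low <- integer(d[3])
  if (nrow(pf$events)) {
    for (i in seq_len(nrow(pf$events))) {
      fr <- pf$events$start_frame[i]:pf$events$end_frame[i]
      if (pf$events$event_class[i] == "High") high[fr] <- high[fr] + 1L
      else low[fr] <- low[fr] + 1L
    }
  }
  time_course <- data.frame(frame = seq_len(d[3]), high_px = high,
                            low_px = low,
                            transients = pf$transients_per_frame)
  list(events = pf$events, time_course = time_course,
       transients_per_frame = pf$transients_per_frame,
       n_short_runs = pf$n_short_runs)
}
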