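#' AP-axis specification
#'
#' @param ap_axis direction of increasing posterior: `"x+"`, `"x-"`,
#'   `"y+"` or `"y-"`.
#' @param n_regions number of evenly divided regions along the axis
#'   (>= 2; the classical profile uses 3).
#' @return An `ap_spec` list.
#' @export
ap_spec <- function(ap_axis = c("x+", "x-", "y+", "y-"), n_regions = 3L) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2) stopf("n_regions must be >= 2")
  structure(list(ap_axis = match.arg(ap_axis), n_regions = n_regions),
            class = "ap_spec")
}

#' Partition a mask into evenly divided AP regions
#'
#' Splits the masked pixels into `n_regions` contiguous bands of equal
#' coordinate span along the AP axis (span of the mask's bounding range,
#' not equal pixel count). When the span does not divide evenly, anterior
#' bands absorb the remainder (anterior-first rule). Region 1 is the most
#' anterior, region `n_regions` the most posterior.
#'
#' @param mask logical matrix.
#' @param spec an [ap_spec()].
#' @return Integer matrix: region id (1..n) for masked pixels, `NA`
#'   elsewhere.
#' @export
partition_regions <- function(mask, spec = ap_spec()) {
  if (!any(mask)) stopf("mask is empty")
  along_x <- spec$ap_axis %in% c("x+", "x-")
  idx <- if (along_x) which(colSums(mask) > 0) else which(rowSums(mask) > 0)
  lo <- min(idx); hi <- max(idx)
  span <- hi - lo + 1L
  n <- spec$n_regions
  if (span < n)
    stopf("mask spans %d pixel(s) along the axis; need >= %d", span, n)
  base <- span %/% n; rem <- span %% n
  widths <- rep(base, n)                     # widths[1] = anterior band
  if (rem > 0) widths[seq_len(rem)] <- widths[seq_len(rem)] + 1L
  # anterior end sits at the low-coordinate end for "+" axes
  anterior_low <- spec$ap_axis %in% c("x+", "y+")
  region_of_coord <- if (anterior_low) {
    rep(seq_len(n), times = widths)
  } else {
    rep(rev(seq_len(n)), times = rev(widths))
  }
  out <- matrix(NA_integer_, nrow(mask), ncol(mask))
  coord <- if (along_x) col(mask) else row(mask)
  inside <- mask & coord >= lo & coord <= hi
  out[inside] <- region_of_coord[coord[inside] - lo + 1L]
  out
}

#' Sampled per-region intensity profile
#'
#' Draws `n_samples_per_region` sample points without replacement from the
#' intersection of `sample_mask` (e.g. membrane/intercellular pixels) with
#' each region, and summarizes intensity per region as mean, SEM and n.
#' If a region offers fewer candidates than requested, all are used and
#' `n_samples` records the actual count.
#'
#' @param image numeric matrix.
#' @param sample_mask logical matrix of candidate sample pixels.
#' @param regions integer region map from [partition_regions()].
#' @param n_samples_per_region samples per region (default 12).
#' @param seed integer seed for reproducible sampling.
#' @return A `region_profile` data frame: `region`, `mean`, `sem`,
#'   `n_samples`, ordered anterior to posterior.
#' @export
sample_intensity <- function(image, sample_mask, regions,
                             n_samples_per_region = 12L, seed = 1L) {
  stopifnot(all(dim(image) == dim(sample_mask)),
            all(dim(image) == dim(regions)))
  ids <- sort(unique(regions[!is.na(regions)]))
  rows <- with_seed(seed, lapply(ids, function(r) {
    cand <- which(sample_mask & !is.na(regions) & regions == r)
    if (!length(cand))
      stopf("region %d has no sample-mask pixels", r)
    take <- if (length(cand) <= n_samples_per_region) cand else
      sample(cand, n_samples_per_region)
    v <- image[take]
    data.frame(region = r, mean = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               n_samples = length(v))
  }))
  out <- do.call(rbind, rows)
  class(out) <- c("region_profile", class(out))
  out
}

#' Gradient shape summary
#'
#' @param profile a `region_profile` from [sample_intensity()] (or any data
#'   frame with a `mean` column ordered anterior to posterior).
#' @return `list(is_monotone_posterior_high, posterior_anterior_ratio)`;
#'   the flag is `TRUE` iff region means are non-decreasing anterior to
#'   posterior; the ratio is posterior mean / anterior mean (`NA` if the
#'   anterior mean is 0).
#' @export
gradient_shape <- function(profile) {
  m <- profile$mean
  if (length(m) < 2) stopf("need >= 2 regions")
  list(is_monotone_posterior_high = all(diff(m) >= 0),
       posterior_anterior_ratio =
         if (m[1] == 0) NA_real_ else m[length(m)] / m[1])
}

#' Local-smoothness index of a frame
#'
#' Median over masked pixels of `|log(I(p) / s(p))|`, where `s(p)` is the
#' same neighbourhood statistic the noise classifier uses. Exactly 0 for
#' locally smooth images (a shallow gradient contributes only its tiny
#' per-pixel step); grows with the number and amplitude of planted
#' outlier cells. Pixels with undefined or zero neighbour statistic are
#' excluded.
#'
#' @param frame numeric matrix (or an [image_stack()], in which case the
#'   per-frame indices are averaged).
#' @param mask logical matrix.
#' @param params a [noise_params()] (supplies the neighbourhood).
#' @return Scalar index (>= 0).
#' @export
smoothness_index <- function(frame, mask, params = noise_params()) {
  if (inherits(frame, "image_stack")) {
    d <- dim(frame$data)
    vals <- vapply(seq_len(d[3]),
                   function(f) smoothness_index(frame$data[, , f], mask,
                                                params),
                   numeric(1))
    return(mean(vals))
  }
  cl <- classify_frame(frame, mask, params)
  ok <- mask & is.finite(cl$fold) & cl$fold > 0
  if (!any(ok)) return(0)
  median(abs(log(cl$fold[ok])))
}
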