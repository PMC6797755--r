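#' AP-binned marker-positive cell frequencies
#'
#' Bins cells along the AP axis and computes, per embryo and bin, the
#' frequency of marker-positive cells among population cells (the embryo,
#' not the pooled cell, is the unit of analysis). The AP extent is the
#' coordinate range occupied by population cells; bins divide it into
#' `n_bins` equal intervals, ordered anterior to posterior. An embryo with
#' no population cells in a bin contributes no value there.
#'
#' @param cells data frame with `embryo_id`, `x`, `y`, `is_population`,
#'   `is_marker`; marker-positive cells must be population cells.
#' @param spec an [ap_spec()] (only `ap_axis` is used).
#' @param n_bins number of AP bins (>= 2; default 5).
#' @return `list(per_bin, per_embryo)`: `per_bin` has `bin`, `mean`, `sem`,
#'   `n_embryos`, `n_cells`; `per_embryo` the underlying frequencies.
#' @export
bin_frequencies <- function(cells, spec = ap_spec(), n_bins = 5L) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  stopifnot(all(c("embryo_id", "x", "y", "is_population", "is_marker")
                %in% names(cells)))
  if (any(cells$is_marker & !cells$is_population))
    stopf("marker-positive cells must belong to the population")
  pop <- cells[cells$is_population, , drop = FALSE]
  if (!nrow(pop)) stopf("no population cells")
  if (any(tapply(pop$is_population, pop$embryo_id, sum) < 1))
    stopf("every embryo needs >= 1 population cell")
  along_x <- spec$ap_axis %in% c("x+", "x-")
  coord <- if (along_x) pop$x else pop$y
  if (spec$ap_axis %in% c("x-", "y-")) coord <- -coord  # posterior = high
  rng <- range(coord)
  width <- diff(rng)
  bin <- if (width == 0) rep(1L, length(coord)) else
    pmin(n_bins, 1L + floor((coord - rng[1]) / width * n_bins))
  per_embryo <- do.call(rbind, lapply(split(seq_along(bin), pop$embryo_id),
    function(i) {
      tab_pop <- tabulate(bin[i], n_bins)
      tab_mark <- tabulate(bin[i][pop$is_marker[i]], n_bins)
      data.frame(embryo_id = pop$embryo_id[i[1]], bin = seq_len(n_bins),
                 n_population = tab_pop, n_marker = tab_mark,
                 frequency = ifelse(tab_pop > 0, tab_mark / tab_pop, NA))
    }))
  rownames(per_embryo) <- NULL
  per_bin <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    f <- per_embryo$frequency[per_embryo$bin == b]
    f <- f[!is.na(f)]
    data.frame(bin = b, mean = if (length(f)) mean(f) else NA,
               sem = if (length(f) > 1) sd(f) / sqrt(length(f)) else 0,
               n_embryos = length(f),
               n_cells = sum(per_embryo$n_population[per_embryo$bin == b]))
  }))
  list(per_bin = per_bin, per_embryo = per_embryo)
}

#' Per-cell nuclear/cytoplasmic intensity ratios
#'
#' For each labelled cell, the ratio of the mean intensity over its nuclear
#' pixels to the mean over its cytoplasmic pixels -- the standard readout
#' of nuclear translocation of a tagged protein (e.g. GFP-Smad2).
#'
#' @param image numeric matrix.
#' @param nuclear_mask,cyto_mask disjoint logical matrices.
#' @param cell_labels integer matrix of cell ids (0 or `NA` = no cell).
#' @return Data frame (`cell`, `nuclear_mean`, `cyto_mean`, `ratio`).
#'   Cells with a zero cytoplasmic mean are omitted with a warning.
#' @export
nc_ratio <- function(image, nuclear_mask, cyto_mask, cell_labels) {
  stopifnot(all(dim(image) == dim(nuclear_mask)),
            all(dim(image) == dim(cyto_mask)),
            all(dim(image) == dim(cell_labels)))
  if (any(nuclear_mask & cyto_mask))
    stopf("nuclear and cytoplasmic masks overlap")
  ids <- sort(unique(cell_labels[!is.na(cell_labels) & cell_labels > 0]))
  rows <- lapply(ids, function(id) {
    inc <- !is.na(cell_labels) & cell_labels == id
    nm <- image[inc & nuclear_mask]
    cm <- image[inc & cyto_mask]
    if (!length(nm) || !length(cm)) return(NULL)
    data.frame(cell = id, nuclear_mean = mean(nm), cyto_mean = mean(cm))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(cell = integer(0), nuclear_mean = numeric(0),
                      cyto_mean = numeric(0), ratio = numeric(0)))
  bad <- out$cyto_mean == 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero cytoplasmic mean omitted",
            call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  out$ratio <- out$nuclear_mean / out$cyto_mean
  rownames(out) <- NULL
  out
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact two-sided p-value by summation of hypergeometric probabilities:
#' with margins fixed, every table whose probability is at most that of the
#' observed table (up to a relative tolerance of 1e-7) contributes
#' (the minimum-likelihood convention used by the common desktop tools).
#' A zero margin gives p = 1 by convention, with a warning.
#'
#' @param tab 2x2 matrix of nonnegative integer counts.
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == c(2, 2)))
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  if (min(r1, r2, c1, c2) == 0) {
    warning("zero margin: p = 1 by convention", call. = FALSE)
    return(1)
  }
  k <- max(0, r1 - c2):min(r1, c1)
  pk <- dhyper(k, c1, c2, r1)
  p_obs <- dhyper(tab[1, 1], c1, c2, r1)
  min(1, sum(pk[pk <= p_obs * (1 + 1e-7)]))
}

#' Group summary: quartiles, range, mean and SEM
#'
#' The box-plot summary used for per-embryo and per-cell readouts: 25th,
#' 50th and 75th percentiles (linear interpolation, R quantile type 7),
#' whisker endpoints (min/max), mean and SEM.
#'
#' @param values numeric vector, length >= 1 (NAs dropped).
#' @return Named list: `q25`, `median`, `q75`, `min`, `max`, `mean`,
#'   `sem`, `n`.
#' @export
summarize_values <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stopf("no values to summarize")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  list(q25 = q[1], median = q[2], q75 = q[3],
       min = min(values), max = max(values), mean = mean(values),
       sem = if (length(values) > 1) sd(values) / sqrt(length(values))
             else 0,
       n = length(values))
}
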