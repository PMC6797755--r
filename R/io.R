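# Standard-format I/O: multi-page TIFF stacks with a JSON calibration
# sidecar, and versioned CSV tables. TIFF float samples are stored in
# [0, 1], so stacks are normalized by their maximum and the scale kept in
# the sidecar; analysis is ratio-based, so this loses nothing.

SCHEMA_VERSION <- "wntnoise-1"

sidecar_path <- function(path) paste0(path, ".json")

#' Write an image stack as a multi-page TIFF
#'
#' Writes one 32-bit float page per frame, normalized to `[0, 1]`, with a
#' JSON sidecar (`<path>.json`) carrying the intensity scale and physical
#' calibration so [read_stack()] restores the stack exactly.
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  scale <- max(stack$data, 1e-12)
  frames <- lapply(seq_len(n_frames(stack)),
                   function(f) stack$data[, , f] / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32)
  jsonlite::write_json(
    list(schema = SCHEMA_VERSION, intensity_scale = scale,
         pixel_size_um = stack$pixel_size_um,
         frame_interval_min = stack$frame_interval_min,
         n_frames = n_frames(stack)),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' Plain TIFFs without a sidecar are read with unit scale and the given
#' default calibration.
#'
#' @param path TIFF path.
#' @param pixel_size_um,frame_interval_min calibration used when no
#'   sidecar is present.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size_um = 6.5,
                       frame_interval_min = 3.5) {
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  scale <- 1
  if (file.exists(sidecar_path(path))) {
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
    scale <- meta$intensity_scale
    pixel_size_um <- meta$pixel_size_um
    frame_interval_min <- meta$frame_interval_min
  }
  data <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3) fr <- fr[, , 1]   # drop extra channels
    data[, , f] <- fr * scale
  }
  image_stack(data, pixel_size_um, frame_interval_min)
}

# Versioned CSV: header row plus a leading '# <schema>' comment line.
write_table_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", SCHEMA_VERSION), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write a detected-event or ground-truth event table
#'
#' Frame indices and pixel coordinates are written 0-based (origin at the
#' top-left pixel), the convention of the on-disk format; in-memory tables
#' are 1-based.
#'
#' @param events event data frame with `x`, `y`, `start_frame`,
#'   `end_frame` (1-based) plus any other columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  for (col in intersect(c("x", "y", "start_frame", "end_frame"),
                        names(out)))
    out[[col]] <- out[[col]] - 1L
  write_table_csv(out, path)
}

#' Read an event table written by [write_events()]
#'
#' @param path CSV path.
#' @return Event data frame with 1-based coordinates and frames.
#' @export
read_events <- function(path) {
  ev <- read_table_csv(path)
  for (col in intersect(c("x", "y", "start_frame", "end_frame"),
                        names(ev)))
    ev[[col]] <- ev[[col]] + 1L
  ev
}

#' Read a binary mask from a TIFF
#'
#' Any strictly positive pixel is inside the mask.
#'
#' @param path TIFF path.
#' @return Logical matrix (single frame) or array (multi-frame).
#' @export
read_mask <- function(path) {
  stack <- read_stack(path)
  m <- stack$data > 0
  if (dim(m)[3] == 1) m[, , 1] else m
}

#' Read a two-contrast differential-expression table
#'
#' @param path CSV with columns `gene_id`, `contrast`, `log2_fold_change`
#'   (or `log2fc`), `fdr`.
#' @return Data frame ready for [gate_de()].
#' @export
read_de_table <- function(path) {
  df <- read_table_csv(path)
  if ("log2fc" %in% names(df) && !"log2_fold_change" %in% names(df))
    names(df)[names(df) == "log2fc"] <- "log2_fold_change"
  df
}
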