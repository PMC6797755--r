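#' Run a reproducible simulate/detect/profile experiment
#'
#' End-to-end workflow over one synthetic scene: simulate a reporter movie,
#' detect persistent noise pixels, profile the AP gradient of the first
#' frame, and write every artifact plus a manifest with MD5 checksums and
#' a config echo sufficient to reproduce the run bit-for-bit.
#'
#' @param config nested list:
#'   * `seed`: master seed (overrides `simulate$seed`),
#'   * `outdir`: output directory (created if needed),
#'   * `simulate`: arguments for [sim_config()],
#'   * `detect`: arguments for [noise_params()],
#'   * `profile`: `n_regions` (default 3) and `n_samples_per_region`
#'     (default 12).
#' @return Invisibly, `list(paths, results)`; `results` holds the in-memory
#'   detection and profile objects.
#' @export
run_experiment <- function(config) {
  outdir <- config$outdir %||% stopf("config$outdir is required")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim_args <- config$simulate %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  cfg <- do.call(sim_config, sim_args)
  scene <- simulate_scene(cfg)
  params <- do.call(noise_params, config$detect %||% list())
  det <- detect_noise(scene$stack, params)
  prof_args <- config$profile %||% list()
  mask <- embryo_mask(scene$stack, params)[, , 1]
  regions <- partition_regions(
    mask, ap_spec(cfg$ap_axis, prof_args$n_regions %||% 3L))
  profile <- sample_intensity(
    scene$stack$data[, , 1], mask, regions,
    n_samples_per_region = prof_args$n_samples_per_region %||% 12L,
    seed = cfg$seed)
  shape <- gradient_shape(profile)
  smooth <- smoothness_index(scene$stack$data[, , 1], mask, params)

  paths <- list(
    stack = file.path(outdir, "stack.tif"),
    truth = file.path(outdir, "ground_truth.csv"),
    events = file.path(outdir, "events.csv"),
    time_course = file.path(outdir, "time_course.csv"),
    regions = file.path(outdir, "regions.csv"),
    shape = file.path(outdir, "shape.json"),
    config = file.path(outdir, "config.json"),
    manifest = file.path(outdir, "manifest.json"))
  write_stack(scene$stack, paths$stack)
  write_events(scene$truth$events, paths$truth)
  write_events(det$events, paths$events)
  write_table_csv(det$time_course, paths$time_course)
  write_table_csv(profile, paths$regions)
  jsonlite::write_json(c(shape, list(smoothness_index = smooth)),
                       paths$shape, auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(schema = SCHEMA_VERSION, simulate = unclass(cfg),
                            detect = unclass(params)),
                       paths$config, auto_unbox = TRUE, digits = NA)
  artifacts <- setdiff(names(paths), "manifest")
  files <- c(unlist(paths[artifacts]), sidecar_path(paths$stack))
  jsonlite::write_json(
    list(schema = SCHEMA_VERSION,
         artifacts = data.frame(file = basename(files),
                                md5 = unname(tools::md5sum(files)))),
    paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths,
                 results = list(scene = scene, detection = det,
                                profile = profile, shape = shape,
                                smoothness_index = smooth)))
}

# ---- command-line interface -------------------------------------------
# The exec/wntnoise script forwards commandArgs() here. Flags are
# "--name value" pairs; see each subcommand's usage string.

cli_flags <- function(args) {
  flags <- list(); pos <- character(0); i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      flags[[substring(a, 3)]] <- args[i + 1]; i <- i + 2
    } else {
      pos <- c(pos, a); i <- i + 1
    }
  }
  list(flags = flags, pos = pos)
}

cli_main <- function(args) {
  if (!length(args)) {
    cat("usage: wntnoise <simulate|detect|profile|spatial|fisher|gate|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]; rest <- cli_flags(args[-1])
  f <- rest$flags
  switch(cmd,
    simulate = {
      sim_args <- if (!is.null(f$config))
        jsonlite::read_json(f$config, simplifyVector = TRUE) else list()
      sim_args <- sim_args[names(sim_args) %in% names(formals(sim_config))]
      if (!is.null(f$seed)) sim_args$seed <- as.integer(f$seed)
      run_experiment(list(outdir = f$out %||% ".", simulate = sim_args))
      cat("scene written to", f$out %||% ".", "\n")
    },
    detect = {
      stack <- read_stack(f$stack)
      params <- noise_params(
        fold_threshold = as.numeric(f[["fold-threshold"]] %||% 2),
        min_frames = as.integer(f[["min-frames"]] %||% 2),
        min_duration_min = as.numeric(f[["min-duration"]] %||% 6))
      mask <- if (!is.null(f$mask)) read_mask(f$mask) else NULL
      det <- detect_noise(stack, params, mask)
      out <- f$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_events(det$events, file.path(out, "events.csv"))
      write_table_csv(det$time_course, file.path(out, "time_course.csv"))
      cat(nrow(det$events), "events,",
          sum(det$transients_per_frame), "transients\n")
    },
    profile = {
      stack <- read_stack(f$image)
      img <- stack$data[, , 1]
      mask <- if (!is.null(f$mask)) read_mask(f$mask) else
        embryo_mask(stack)[, , 1]
      spec <- ap_spec(f$axis %||% "x+", as.integer(f$regions %||% 3))
      regions <- partition_regions(mask, spec)
      smask <- if (!is.null(f[["sample-mask"]])) read_mask(f[["sample-mask"]])
        else mask
      prof <- sample_intensity(img, smask, regions,
                               as.integer(f$samples %||% 12),
                               as.integer(f$seed %||% 1))
      out <- f$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(prof, file.path(out, "regions.csv"))
      sh <- gradient_shape(prof)
      jsonlite::write_json(
        c(sh, list(smoothness_index = smoothness_index(img, mask))),
        file.path(out, "shape.json"), auto_unbox = TRUE, digits = NA)
      print(prof)
    },
    spatial = {
      cells <- read_table_csv(f$cells)
      cells$is_population <- as.logical(cells$is_population)
      cells$is_marker <- as.logical(cells$is_marker)
      bf <- bin_frequencies(cells, ap_spec(f$axis %||% "x+"),
                            as.integer(f$bins %||% 5))
      out <- f$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      write_table_csv(bf$per_bin, file.path(out, "binned_frequencies.csv"))
      jsonlite::write_json(
        lapply(split(bf$per_embryo$frequency, bf$per_embryo$bin),
               function(v) summarize_values(v[!is.na(v)])),
        file.path(out, "summary.json"), auto_unbox = TRUE, digits = NA)
      print(bf$per_bin)
    },
    fisher = {
      a <- as.integer(rest$pos)
      if (length(a) != 4) stopf("fisher needs four integers: a b c d")
      p <- fisher_exact_2x2(matrix(a, 2, 2, byrow = TRUE))
      cat(sprintf("two-sided p = %.6g\n", p))
    },
    gate = {
      records <- read_de_table(f$de)
      res <- gate_de(records, as.numeric(f$threshold %||% 0.1))
      if (!is.null(f$panel)) {
        nmfile <- strsplit(f$panel, "=", fixed = TRUE)[[1]]
        res <- annotate_gate(res, nmfile[1], readLines(nmfile[2]))
      }
      out <- f$out %||% "."
      dir.create(out, recursive = TRUE, showWarnings = FALSE)
      sets <- data.frame(
        gene_id = c(res$mosaic_specific_up, res$mosaic_specific_down,
                    res$shared),
        set = rep(c("mosaic_specific_up", "mosaic_specific_down", "shared"),
                  c(length(res$mosaic_specific_up),
                    length(res$mosaic_specific_down), length(res$shared))))
      write_table_csv(sets, file.path(out, "gated_sets.csv"))
      jsonlite::write_json(res$annotations,
                           file.path(out, "annotations.json"),
                           auto_unbox = TRUE, digits = NA)
      print(res)
    },
    run = {
      config <- jsonlite::read_json(f$config, simplifyVector = TRUE)
      config$outdir <- f$out %||% config$outdir
      if (!is.null(f$seed)) config$seed <- as.integer(f$seed)
      run_experiment(config)
      cat("experiment written to", config$outdir, "\n")
    },
    stopf("unknown subcommand '%s'", cmd))
  invisible(0L)
}
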