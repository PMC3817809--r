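utils::globalVariables(c("sigma", "corr", "filtering", "n_recovered"))

known_config_keys <- c(
  "input", "layout", "output_dir", "stabilise", "stabilise_radius",
  "zscore", "filter_width", "temporal_width", "k", "c", "min_similarity",
  "seed", "windows", "divide",
  # simulate / evaluate
  "n_sources", "m", "height", "width", "cluster_radius", "sigma_noise",
  "source_kind", "sigmas", "reps")

#' Read and validate a pipeline configuration
#'
#' Configurations are YAML (or JSON) key-value files holding input paths,
#' stage toggles and parameters, stimulus windows and the output directory.
#' Unknown keys are rejected; parameters are range-checked at use.
#'
#' @param path config file.
#' @param overrides named list merged over the file's values.
#' @return named list of class `pipeline_config`.
#' @export
read_config <- function(path, overrides = list()) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  cfg[names(overrides)] <- overrides
  unknown <- setdiff(names(cfg), known_config_keys)
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(layout = NULL, stabilise = FALSE, stabilise_radius = 10L,
                   zscore = TRUE, filter_width = NULL, temporal_width = NULL,
                   k = 50L, c = 50L, min_similarity = 0.5, seed = 0L,
                   windows = list(), divide = FALSE)
  for (key in names(defaults))
    if (is.null(cfg[[key]])) cfg[[key]] <- defaults[[key]]
  structure(cfg, class = "pipeline_config")
}

config_windows <- function(cfg) {
  lapply(cfg$windows, function(wd)
    stimulus_window(segment = wd$segment,
                    baseline = unlist(wd$baseline), onset = wd$onset))
}

load_input_movie <- function(cfg) {
  if (is.null(cfg$input)) stop("config must name an input movie")
  read_movie(cfg$input, layout = cfg$layout)
}

## shared preprocessing + decomposition for the map-side pipeline
map_branch <- function(cfg, movie) {
  shifts <- NULL
  if (isTRUE(cfg$stabilise)) {
    st <- stabilise(movie, radius = cfg$stabilise_radius)
    movie <- st$movie
    shifts <- st$shifts
  }
  if (!is.null(cfg$filter_width))
    movie <- spatial_gauss(movie, cfg$filter_width)
  if (!is.null(cfg$temporal_width))
    movie <- temporal_filter(movie, cfg$temporal_width)
  z <- if (isTRUE(cfg$zscore)) zscore(movie)$movie else movie
  k <- min(cfg$k, dim(z)[1L], dim(z)[2L])
  pc <- pca(z, k = k)
  fm <- cone_fitting(pca_scores(pc), c = cfg$c, seed = cfg$seed)
  rf <- refine(z, fm, min_similarity = cfg$min_similarity)
  list(movie = movie, zscored = z, pca = pc, model = fm, refined = rf,
       shifts = shifts)
}

write_manifest <- function(cfg, outdir, command, extra = list()) {
  manifest <- c(list(command = command,
                     package_version = as.character(
                       utils::packageVersion("conemap"))),
                unclass(cfg), extra)
  if (!is.null(cfg$input) && file.exists(cfg$input))
    manifest$input_md5 <- unname(tools::md5sum(cfg$input))
  manifest <- manifest[order(names(manifest))]
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

#' Pipeline commands
#'
#' The five pipeline entry points behind the command-line interface. Each
#' takes a validated [read_config] object (or, for `run_simulate`, a
#' [synthetic_spec]), writes its outputs into `output_dir` and a
#' `manifest.json` recording every parameter, the seed and the input
#' content hash, and returns the paths written (invisibly).
#'
#' * `run_map`: stabilise -> z-score -> PCA -> cone fitting -> refinement ->
#'   induced clustering; writes the glomerular map (TIFF + CSV), the
#'   refined model directory and the manifest.
#' * `run_timeseries`: same decomposition; the time-series branch then
#'   applies baseline fold change (when stimulus windows are given) to the
#'   stabilised movie and back-projects it onto the refined maps, writing
#'   full-length glomerular time series to CSV.
#' * `run_reconstruct`: writes the denoised low-rank movie (TIFF) and
#'   min-max scaled false-colour PNG previews.
#' * `run_simulate`: generates a synthetic movie + ground truth tables.
#' * `run_evaluate`: runs the noise-sweep benchmark and writes per-run and
#'   summary CSVs.
#'
#' @param cfg a `pipeline_config` (see [read_config]).
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
run_map <- function(cfg) {
  outdir <- cfg$output_dir %||% stop("config must name output_dir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  br <- map_branch(cfg, load_input_movie(cfg))
  map <- refined_label_map(br$refined)
  write_label_map(map, file.path(outdir, "glomerular_map.tif"))
  write_label_map(map, file.path(outdir, "glomerular_map.csv"))
  save_model(br$refined, file.path(outdir, "refined_model"))
  write_manifest(cfg, outdir, "map",
                 list(shifts = br$shifts,
                      n_signals = ncol(br$refined$T_hat)))
  invisible(outdir)
}

#' @rdname pipeline
#' @export
run_timeseries <- function(cfg) {
  outdir <- cfg$output_dir %||% stop("config must name output_dir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  br <- map_branch(cfg, load_input_movie(cfg))
  ts_movie <- br$movie
  if (length(cfg$windows) > 0L)
    ts_movie <- fold_change(ts_movie, config_windows(cfg),
                            divide = isTRUE(cfg$divide))
  T_full <- back_project(ts_movie, br$refined$S_hat)
  write_timeseries(T_full, file.path(outdir, "timeseries.csv"))
  write_manifest(cfg, outdir, "timeseries",
                 list(n_signals = ncol(T_full)))
  invisible(outdir)
}

#' @rdname pipeline
#' @export
run_reconstruct <- function(cfg) {
  outdir <- cfg$output_dir %||% stop("config must name output_dir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  br <- map_branch(cfg, load_input_movie(cfg))
  rec <- low_rank_movie(br$refined)
  write_movie(rec, file.path(outdir, "reconstruction.tif"))
  # false-colour previews of up to 6 evenly spaced frames, min-max scaled
  idx <- unique(round(seq(1L, dim(rec)[1L], length.out = min(6L,
                                                             dim(rec)[1L]))))
  pal <- grDevices::hcl.colors(256L, "Inferno")
  for (i in idx) {
    img <- get_frame(rec, i)
    rng <- range(img)
    sc <- if (rng[2L] > rng[1L]) (img - rng[1L]) / (rng[2L] - rng[1L])
          else img * 0
    rgb <- grDevices::col2rgb(pal[pmin(255L, floor(sc * 255)) + 1L]) / 255
    arr <- array(0, c(nrow(img), ncol(img), 3L))
    arr[, , 1L] <- matrix(rgb[1L, ], nrow(img))
    arr[, , 2L] <- matrix(rgb[2L, ], nrow(img))
    arr[, , 3L] <- matrix(rgb[3L, ], nrow(img))
    png::writePNG(arr, file.path(outdir, sprintf("frame_%04d.png", i)))
  }
  write_manifest(cfg, outdir, "reconstruct",
                 list(rank = ncol(br$refined$T_hat)))
  invisible(outdir)
}

#' @rdname pipeline
#' @param spec a [synthetic_spec] for `run_simulate`.
#' @param output_dir destination directory for `run_simulate`.
#' @export
run_simulate <- function(spec, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- generate_movie(spec)
  write_movie(gen$movie, file.path(output_dir, "movie.csv"))
  write_movie(gen$movie, file.path(output_dir, "movie.tif"))
  write_timeseries(gen$truth$U, file.path(output_dir, "sources.csv"),
                   ids = paste0("source_", seq_len(ncol(gen$truth$U))))
  write_label_map(truth_label_map(gen$truth),
                  file.path(output_dir, "truth_map.csv"))
  mask_df <- data.frame(
    pixel = unlist(gen$truth$masks),
    source = rep(seq_along(gen$truth$masks), lengths(gen$truth$masks)))
  utils::write.csv(mask_df, file.path(output_dir, "masks.csv"),
                   row.names = FALSE)
  cfg <- unclass(spec)
  cfg$centres <- NULL
  manifest <- c(list(command = "simulate"), cfg)
  jsonlite::write_json(manifest[order(names(manifest))],
                       file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(output_dir)
}

#' @rdname pipeline
#' @export
run_evaluate <- function(cfg) {
  outdir <- cfg$output_dir %||% stop("config must name output_dir")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- synthetic_spec(
    n_sources = cfg$n_sources %||% 16L, m = cfg$m %||% 400L,
    height = cfg$height %||% 60L, width = cfg$width %||% 60L,
    cluster_radius = cfg$cluster_radius %||% 8,
    source_kind = cfg$source_kind %||% "odours", seed = cfg$seed)
  sigmas <- unlist(cfg$sigmas %||% c(0.1, 0.5, 1, 2))
  reps <- cfg$reps %||% 5L
  sweep <- noise_sweep(spec, sigmas = sigmas, filter_width = NULL,
                       k = cfg$k, c = cfg$c,
                       min_similarity = cfg$min_similarity,
                       reps = reps, seed = cfg$seed)
  if (!is.null(cfg$filter_width)) {
    sweep <- rbind(sweep,
                   noise_sweep(spec, sigmas = sigmas,
                               filter_width = cfg$filter_width, k = cfg$k,
                               c = cfg$c,
                               min_similarity = cfg$min_similarity,
                               reps = reps, seed = cfg$seed))
  }
  utils::write.csv(sweep, file.path(outdir, "sweep.csv"), row.names = FALSE)
  utils::write.csv(summarise_sweep(sweep),
                   file.path(outdir, "sweep_summary.csv"), row.names = FALSE)
  write_manifest(cfg, outdir, "evaluate", list())
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Dispatches `map`, `timeseries`, `reconstruct`, `simulate` and `evaluate`
#' subcommands. Arguments: `--config <file>` (required), `--seed <int>` and
#' `--out <dir>` overrides. Returns (rather than calls `quit` with) the
#' exit status so it can be tested in-process: 0 on success, 2 on usage
#' errors, 1 on runtime failure; the launcher script passes the status to
#' `quit()`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return integer exit status, invisibly.
#' @export
cli_run <- function(args) {
  usage <- function(msg) {
    message(msg)
    message("usage: conemap <map|timeseries|reconstruct|simulate|evaluate> ",
            "--config <file> [--seed <int>] [--out <dir>]")
    invisible(2L)
  }
  if (length(args) < 1L) return(usage("missing subcommand"))
  cmd <- args[[1L]]
  if (!cmd %in% c("map", "timeseries", "reconstruct", "simulate", "evaluate"))
    return(usage(paste0("unknown subcommand '", cmd, "'")))
  opts <- list()
  i <- 2L
  while (i <= length(args)) {
    key <- args[[i]]
    if (!key %in% c("--config", "--seed", "--out") || i == length(args))
      return(usage(paste0("bad argument '", key, "'")))
    opts[[sub("^--", "", key)]] <- args[[i + 1L]]
    i <- i + 2L
  }
  if (is.null(opts$config)) return(usage("--config is required"))
  if (!file.exists(opts$config))
    return(usage(paste0("config file not found: ", opts$config)))
  overrides <- list()
  if (!is.null(opts$seed)) {
    seed <- suppressWarnings(as.integer(opts$seed))
    if (is.na(seed)) return(usage("--seed must be an integer"))
    overrides$seed <- seed
  }
  if (!is.null(opts$out)) overrides$output_dir <- opts$out
  cfg <- tryCatch(read_config(opts$config, overrides),
                  error = function(e) e)
  if (inherits(cfg, "error"))
    return(usage(paste0("invalid config: ", conditionMessage(cfg))))
  status <- tryCatch({
    if (cmd == "simulate") {
      spec <- synthetic_spec(
        n_sources = cfg$n_sources %||% 16L, m = cfg$m %||% 400L,
        height = cfg$height %||% 60L, width = cfg$width %||% 60L,
        cluster_radius = cfg$cluster_radius %||% 8,
        sigma_noise = cfg$sigma_noise %||% 0,
        source_kind = cfg$source_kind %||% "odours", seed = cfg$seed)
      run_simulate(spec, cfg$output_dir %||% stop("output_dir required"))
    } else {
      switch(cmd, map = run_map(cfg), timeseries = run_timeseries(cfg),
             reconstruct = run_reconstruct(cfg), evaluate = run_evaluate(cfg))
    }
    0L
  }, error = function(e) {
    message("error in '", cmd, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}
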