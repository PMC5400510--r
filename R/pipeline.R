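#' Read a pipeline configuration file
#'
#' The configuration is a YAML key-value file grouping the parameters of
#' every stage. Recognized keys (with defaults applied where omitted):
#'
#' ```yaml
#' template_id: ARS1_tpl
#' length_bp: 3800
#' acs_offset: 1700
#' orientation: forward
#' size_lo: 125
#' size_hi: 175
#' bandwidth_bp: 20
#' truncation_sd: 3
#' threshold: 2
#' min_separation: 120
#' pairing_window: 100
#' input_path: fragments.bed      # either this ...
#' input_format: bed3
#' simulate:                      # ... or this block
#'   preset: ISW2
#'   n: 50000
#'   fuzz_sd: 10
#'   background_frac: 0.1
#' seed: 1
#' ```
#'
#' Writing the parsed config back out with [yaml::write_yaml()] round-trips
#' losslessly.
#'
#' @param path Path to a YAML config file.
#' @return A named list with defaults filled in.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("Config file does not exist: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  fill_config_defaults(cfg)
}

pipeline_defaults <- function() {
  list(
    template_id = "ARS1_tpl",
    length_bp = 3800L,
    acs_offset = 1700L,
    orientation = "forward",
    size_lo = 125L,
    size_hi = 175L,
    bandwidth_bp = 20,
    truncation_sd = 3,
    threshold = 2,
    min_separation = 120L,
    pairing_window = 100L,
    seed = 1L
  )
}

fill_config_defaults <- function(cfg) {
  defaults <- pipeline_defaults()
  applied <- setdiff(names(defaults), names(cfg))
  if (length(applied) > 0L) {
    message("Config defaults applied: ", paste(applied, collapse = ", "))
  }
  utils::modifyList(defaults, cfg)
}

#' Run the full nucleosome-positioning pipeline
#'
#' Executes read-or-simulate, size selection, midpoint extraction, kernel
#' smoothing, depth normalization, and consensus peak calling from a single
#' configuration, writing the artifact set to `out_dir`:
#'
#' * `track.bedGraph` — the normalized dyad-density track,
#' * `peaks.tsv` — peak table with absolute and ACS-relative positions,
#' * `peaks.bed` — the same peaks as BED6,
#' * `run_info.yaml` — the complete parameter set (defaults included) and
#'   seed, stamping every run,
#' * `shifts.tsv` — only when `compare_peaks` is given: dyad shifts of this
#'   run's peaks relative to the reference peaks.
#'
#' Reruns with an identical config produce byte-identical peak tables. If a
#' stage fails, any partial outputs are removed.
#'
#' @param config A config list ([read_pipeline_config()]) or path to a YAML
#'   config file. Must contain either `input_path` or a `simulate` block.
#' @param out_dir Output directory (created if needed).
#' @param compare_peaks Optional reference peak tibble (or ACS-relative
#'   positions) to pair against for dyad-shift reporting.
#' @return Invisibly, a list with `track`, `peaks`, `shifts` (or `NULL`), and
#'   `paths` of the written artifacts.
#' @export
run_pipeline <- function(config, out_dir, compare_peaks = NULL) {
  if (is.character(config)) {
    config <- read_pipeline_config(config)
  } else {
    config <- fill_config_defaults(config)
  }
  has_input <- !is.null(config$input_path)
  has_sim <- !is.null(config$simulate)
  if (!has_input && !has_sim) {
    stop(
      "Config must provide `input_path` or a `simulate` block.",
      call. = FALSE
    )
  }
  coords <- template_coords(
    config$template_id, config$length_bp, config$acs_offset, config$orientation
  )
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    track = file.path(out_dir, "track.bedGraph"),
    peaks = file.path(out_dir, "peaks.tsv"),
    peaks_bed = file.path(out_dir, "peaks.bed"),
    run_info = file.path(out_dir, "run_info.yaml")
  )
  if (!is.null(compare_peaks)) {
    paths$shifts <- file.path(out_dir, "shifts.tsv")
  }
  ok <- FALSE
  on.exit({
    if (!ok) unlink(unlist(paths))
  })

  fragments <- if (has_input) {
    read_fragments(config$input_path, config$input_format %||% "bed3", coords)
  } else {
    sim <- config$simulate
    landscape <- make_landscape_preset(
      sim$preset, coords,
      seed = config$seed,
      fuzz_sd = sim$fuzz_sd %||% 10,
      spacing_bp = sim$spacing_bp %||% 165,
      background_frac = sim$background_frac %||% 0.1
    )
    simulate_mnase_library(
      landscape,
      n = sim$n,
      seed = config$seed,
      frag_len_mean = sim$frag_len_mean %||% 147,
      frag_len_sd = sim$frag_len_sd %||% 10,
      frag_len_bounds = unlist(sim$frag_len_bounds %||% c(100, 200))
    )
  }
  message("Pipeline: ", nrow(fragments), " fragments in.")
  track <- fragments |>
    filter_by_length(config$size_lo, config$size_hi) |>
    compute_midpoints() |>
    build_track(coords, config$bandwidth_bp, config$truncation_sd) |>
    normalize_track()
  message("Pipeline: ", track$n_midpoints, " midpoints after size selection.")
  peaks <- call_consensus_positions(
    track,
    threshold = config$threshold, min_separation = config$min_separation
  )
  message("Pipeline: ", nrow(peaks), " consensus peaks called.")

  write_track_bedgraph(track, coords, paths$track)
  readr::write_tsv(peaks, paths$peaks, progress = FALSE)
  write_peaks_bed6(peaks, coords, paths$peaks_bed)
  shifts <- NULL
  if (!is.null(compare_peaks)) {
    shifts <- pair_and_shift(compare_peaks, peaks, config$pairing_window)
    readr::write_tsv(shifts, paths$shifts, progress = FALSE)
  }
  yaml::write_yaml(config, paths$run_info)
  ok <- TRUE
  invisible(list(track = track, peaks = peaks, shifts = shifts, paths = paths))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
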