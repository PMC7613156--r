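#' Write the packaged fixtures to a directory
#'
#' Emits the morphology table CSV (cell-for-cell the packaged table), a
#' default JSON config for each experiment and the envelope export, and a
#' tiny scripted-engagement fixture (two capped agents on a head-on
#' course whose intercept time has a closed form) used by the test suite.
#' Regeneration is idempotent.
#'
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
generate_fixtures <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  p <- file.path(out_dir, "morphology.csv")
  write.csv(morphology_table(), p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  cfgs <- list(
    exp1 = list(
      experiment = "exp1", n_per_condition = 1e5, scale = 0.01,
      master_seed = 1
    ),
    exp2 = list(
      experiment = "exp2", n_samples = 1e6, scale = 0.01,
      master_seed = 2
    ),
    exp3 = list(
      experiment = "exp3", n_samples = 1e6, scale = 0.01,
      master_seed = 3
    ),
    envelope = list(
      experiment = "envelope", species = "Peregrine falcon (male)",
      speeds = c(1, 120, 0.5)
    )
  )
  for (nm in names(cfgs)) {
    p <- file.path(out_dir, paste0(nm, ".json"))
    jsonlite::write_json(cfgs[[nm]], p, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, p)
  }

  # head-on capped agents, 40 vs 20 m/s, 200 m apart, prey fleeing
  # directly away -> intercept at t = 200 / (40 - 20) = 10 s
  p <- file.path(out_dir, "scripted_headon.json")
  jsonlite::write_json(
    list(
      falcon = list(speed = 40, n_max = 0, rollacc_max = 0),
      prey = list(speed = 20, n_max = 0, rollacc_max = 0),
      separation = 200, expected_intercept_time = 10
    ),
    p,
    auto_unbox = TRUE, pretty = TRUE
  )
  paths <- c(paths, p)
  invisible(paths)
}

#' Echo a morphology list as JSON (provenance logging)
#'
#' @param morphs list of `stoopsim_morphology` (SI units).
#' @param path optional file to write to.
#' @return JSON string, invisibly when written to a file.
#' @export
morphology_to_json <- function(morphs, path = NULL) {
  x <- lapply(morphs, unclass)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Run an experiment pipeline from a JSON config file
#'
#' Executes the experiment named in the config, writes the per-condition
#' (or per-engagement) CSV and an echo of the resolved config next to it.
#' Deterministic given `master_seed`.
#'
#' @param path JSON config file (see [generate_fixtures()] for examples).
#' @param out_dir output directory.
#' @return invisibly, the result data.frame.
#' @export
run_from_config <- function(path, out_dir = dirname(path)) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg$experiment)) stop("config lacks field 'experiment'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(cfg$experiment,
    exp1 = run_experiment1(
      n_per_condition = cfg$n_per_condition %||% 1e5,
      scale = cfg$scale %||% 0.01, seed = cfg$master_seed %||% 1
    ),
    exp2 = run_experiment2(
      n_samples = cfg$n_samples %||% 1e6,
      scale = cfg$scale %||% 0.01, seed = cfg$master_seed %||% 2
    ),
    exp3 = run_experiment3(
      n_samples = cfg$n_samples %||% 1e6,
      scale = cfg$scale %||% 0.01, seed = cfg$master_seed %||% 3
    ),
    envelope = {
      m <- get_morphology(cfg$species %||% "Peregrine falcon (male)")
      sp <- cfg$speeds %||% c(1, 120, 0.5)
      performance_envelope(m, v = seq(sp[1], sp[2], by = sp[3]))$envelope
    },
    stop("unknown experiment '", cfg$experiment, "'")
  )
  base <- tools::file_path_sans_ext(basename(path))
  out_csv <- file.path(out_dir, paste0(base, "_results.csv"))
  write.csv(res, out_csv, row.names = FALSE)
  jsonlite::write_json(cfg, file.path(out_dir, paste0(base, "_config_echo.json")),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
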