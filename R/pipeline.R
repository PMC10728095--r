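.known_config_keys <- c(
  "params", "stages", "mode", "seed", "out_dir",
  "simulate", "sweep", "cohort", "sensitivity"
)

.known_stages <- c("simulate", "sweep", "cohort", "sensitivity")

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a path to a flat JSON file) with
#' fields `seed` (mandatory), `out_dir`, `stages` (subset of simulate /
#' sweep / cohort / sensitivity), `mode` (`"active"`, `"blocked"` or
#' `"both"`), optional `params` overrides, and per-stage option lists.
#' Unknown keys anywhere are rejected with a message listing all offenders.
#'
#' @param config list or JSON path.
#' @return The validated config list with defaults filled in.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  bad <- setdiff(names(config), .known_config_keys)
  if (!is.null(config$params)) {
    bad <- c(bad, setdiff(names(config$params), .par_order))
  }
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(unique(bad), collapse = ", "),
      call. = FALSE
    )
  }
  if (is.null(config$seed)) stop("config must set a seed", call. = FALSE)
  config$stages <- if (is.null(config$stages)) "simulate" else config$stages
  badst <- setdiff(config$stages, .known_stages)
  if (length(badst)) {
    stop("unknown stage(s): ", paste(badst, collapse = ", "), call. = FALSE)
  }
  config$mode <- if (is.null(config$mode)) "both" else config$mode
  if (!config$mode %in% c("active", "blocked", "both")) {
    stop("mode must be active, blocked or both", call. = FALSE)
  }
  config$out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  config
}

.cfg_modes <- function(config) {
  if (config$mode == "both") c("active", "blocked") else config$mode
}

#' Run the analysis pipeline
#'
#' Executes the selected stages in order (simulate, sweep, cohort,
#' sensitivity) from one configuration, writing CSV/JSON artifacts and a
#' manifest (files, seeds, package version, resolved configuration) to the
#' output directory. Per-stage seeds are derived deterministically from the
#' global seed so adding a stage never perturbs another stage's stream.
#'
#' @param config list or JSON path; see [validate_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pars <- do.call(baseline_params, as.list(config$params %||% list()))
  files <- character(0)
  seeds <- list(global = config$seed)
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  if ("simulate" %in% config$stages) {
    opts <- config$simulate %||% list()
    t_end <- opts$t_end %||% 150
    for (mode in .cfg_modes(config)) {
      tr <- integrate_tumor(pars, mode = mode, t_end = t_end)
      emit(tibble::as_tibble(tr), paste0("trajectory_", mode, ".csv"))
    }
  }

  if ("sweep" %in% config$stages) {
    opts <- config$sweep %||% list()
    seeds$sweep <- .substream_seed(config$seed, "sweep")
    sw <- bifurcation_sweep(
      pars,
      param1 = opts$param1 %||% "p_1",
      values1 = opts$values1 %||% seq(0, 1, length.out = 11),
      param2 = opts$param2 %||% "p_2",
      values2 = opts$values2 %||% seq(0, 1, length.out = 11),
      slice_param = opts$slice_param,
      slice_values = opts$slice_values,
      mode = if (config$mode == "both") "blocked" else config$mode,
      n_starts = opts$n_starts %||% 100
    )
    emit(sw, "sweep.csv")
    areas <- sweep_region_areas(sw)
    path <- file.path(config$out_dir, "sweep_areas.json")
    jsonlite::write_json(areas, path, dataframe = "rows", digits = NA)
    files <- c(files, path)
  }

  if ("cohort" %in% config$stages) {
    opts <- config$cohort %||% list()
    seeds$cohort <- .substream_seed(config$seed, "cohort")
    spec <- cohort_spec(n = opts$n %||% 30000, seed = seeds$cohort)
    cohort <- sample_cohort(spec)
    emit(cohort, "cohort.csv")
    result <- run_cohort(cohort,
      modes = .cfg_modes(config),
      days = opts$days %||% c(25, 150)
    )
    emit(tibble::as_tibble(result), "cohort_result.csv")
    probs <- outcome_probabilities(result)
    path <- file.path(config$out_dir, "outcome_probabilities.json")
    jsonlite::write_json(probs, path, dataframe = "rows", digits = NA)
    files <- c(files, path)
  }

  if ("sensitivity" %in% config$stages) {
    opts <- config$sensitivity %||% list()
    seeds$sensitivity <- .substream_seed(config$seed, "sensitivity")
    for (mode in .cfg_modes(config)) {
      rep <- global_sensitivity(
        mode = mode, n = opts$n %||% 2000,
        seed = seeds$sensitivity,
        metric = opts$metric %||% "day25_volume"
      )
      emit(tidy(rep), paste0("sensitivity_", mode, ".csv"))
    }
  }

  manifest <- list(
    package = "ctldyn",
    version = as.character(utils::packageVersion("ctldyn")),
    seeds = seeds,
    config = config,
    files = files
  )
  path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
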