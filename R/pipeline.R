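# End-to-end orchestration: simulate or load a mesh and per-setting maps,
# compute metrics, recommend a pacing setting, optionally simulate and
# analyse a cohort, and write everything (plus a manifest) to an output
# directory. Deterministic for a given configuration and seed.

#' Validate a pipeline configuration
#'
#' A configuration is a named list (or a YAML file containing one) with:
#' \describe{
#'   \item{seed}{integer, drives every stochastic stage (default 1).}
#'   \item{mesh}{either `list(path =, format =)` to load a mesh, or
#'     `list(n_subdiv =)` (plus optional semi-axes) to simulate one.}
#'   \item{maps}{either `list(presets = ..., bbb =)` to simulate the five
#'     pacing settings for one synthetic patient (`bbb` chooses the
#'     intrinsic preset), or a list of `list(setting =, path =)` entries to
#'     load maps from CSV.}
#'   \item{fractions}{activation fractions (subset of (0, 1], default
#'     0.7/0.8/0.9/1).}
#'   \item{qrs}{`list(source = "map_derived")` or
#'     `list(source = "supplied", qrs_ms =)`.}
#'   \item{patient_id}{label for the session (default "demo").}
#'   \item{cohort}{optional `list(n_patients =, prop_lbbb =)`; when present
#'     a synthetic cohort is simulated and analysed.}
#' }
#'
#' @param config a list or path to a YAML file.
#' @return the validated configuration list (class `pipeline_config`).
#' @export
pipeline_config <- function(config) {
  raw <- NULL
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      crt_stop(sprintf("config file not found: %s", config),
               "crt80_config_error")
    raw <- paste(readLines(config), collapse = "\n")
    config <- yaml::yaml.load(raw)
  }
  if (!is.list(config))
    crt_stop("config must be a list or a YAML file path", "crt80_config_error")
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  if (is.null(cfg$mesh))
    crt_stop("config is missing the 'mesh' section", "crt80_config_error")
  if (is.null(cfg$mesh$path) && is.null(cfg$mesh$n_subdiv))
    crt_stop("mesh section needs either 'path' or 'n_subdiv'",
             "crt80_config_error")
  if (!is.null(cfg$mesh$path) && !file.exists(mesh_probe_path(cfg$mesh)))
    crt_stop(sprintf("mesh file not found: %s", cfg$mesh$path),
             "crt80_config_error")
  cfg$fractions <- as.numeric(cfg$fractions %||% c(0.7, 0.8, 0.9, 1.0))
  if (any(cfg$fractions <= 0 | cfg$fractions > 1))
    crt_stop("fractions must lie in (0, 1]", "crt80_config_error")
  if (!0.8 %in% cfg$fractions)
    crt_stop("fractions must include 0.8", "crt80_config_error")
  cfg$qrs <- cfg$qrs %||% list(source = "map_derived")
  if (!cfg$qrs$source %in% c("map_derived", "supplied"))
    crt_stop("qrs$source must be 'map_derived' or 'supplied'",
             "crt80_config_error")
  if (cfg$qrs$source == "supplied" && is.null(cfg$qrs$qrs_ms))
    crt_stop("qrs$source = 'supplied' requires qrs$qrs_ms", "crt80_config_error")
  cfg$maps <- cfg$maps %||% list(presets = PACING_SETTINGS, bbb = "LBBB")
  cfg$patient_id <- cfg$patient_id %||% "demo"
  attr(cfg, "raw_yaml") <- raw
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

mesh_probe_path <- function(meshcfg) {
  fmt <- meshcfg$format %||%
    (if (grepl("\\.ply$", meshcfg$path)) "ply" else "csv")
  if (fmt == "csv") paste0(meshcfg$path, "_vertices.csv") else meshcfg$path
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load mesh -> maps -> metrics -> recommendation
#' (-> cohort simulation and analysis), writing `metrics.csv`,
#' `recommendation.json`, optionally `cohort.csv`, `cohort_analysis.json`
#' and `report.txt`, and a `manifest.json` from which the run is
#' reproducible (configuration, seed, versions, output checksums). Given
#' the same configuration and seed the outputs are byte-identical.
#'
#' @param config a [pipeline_config()] input (list or YAML path).
#' @param output_dir directory for artifacts (created if needed).
#' @param quiet suppress progress messages.
#' @return (invisibly) list with the output paths and in-memory results.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  cfg <- pipeline_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, crt80_error = function(e) {
      crt_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               class(e)[1L], stage = name)
    })
  }

  mesh <- stage("mesh", {
    if (!is.null(cfg$mesh$path)) {
      read_mesh(cfg$mesh$path, cfg$mesh$format %||% "auto")
    } else {
      biv_shell_mesh(n_subdiv = cfg$mesh$n_subdiv,
                     lv_axis = cfg$mesh$lv_axis %||% 45,
                     rv_axis = cfg$mesh$rv_axis %||% 30,
                     short_axis = cfg$mesh$short_axis %||% 35,
                     long_axis = cfg$mesh$long_axis %||% 60)
    }
  })
  say("mesh: %d vertices, %d triangles", nrow(mesh$vertices), nrow(mesh$triangles))

  maps <- stage("maps", {
    if (!is.null(cfg$maps$presets)) {
      prep <- mesh_prep(mesh)
      presets <- cfg$maps$presets
      out <- list()
      for (k in seq_along(presets)) {
        s <- presets[k]
        preset <- if (s == "INTRINSIC") (cfg$maps$bbb %||% "LBBB") else s
        out[[s]] <- preset_activation_map(mesh, preset,
                                          seed = cfg$seed + k, prep = prep)
      }
      out
    } else {
      out <- list()
      for (entry in cfg$maps) {
        out[[entry$setting]] <- read_activation_map(entry$path, mesh,
                                                    setting = entry$setting)
      }
      out
    }
  })
  say("maps: %s", paste(names(maps), collapse = ", "))

  metrics <- stage("metrics", {
    lapply(maps, function(m)
      chamber_metrics(m, fractions = cfg$fractions,
                      qrs_source = cfg$qrs$source,
                      qrs_ms = cfg$qrs$qrs_ms))
  })
  metrics_df <- do.call(rbind, lapply(metrics, as.data.frame))
  metrics_path <- file.path(output_dir, "metrics.csv")
  utils::write.csv(metrics_df, metrics_path, row.names = FALSE)

  rec <- NULL
  if ("INTRINSIC" %in% names(metrics) && length(metrics) >= 3L) {
    rec <- stage("recommend", {
      recommend_setting(pacing_session(cfg$patient_id, metrics))
    })
    jsonlite::write_json(
      list(patient = cfg$patient_id, recommended = rec$setting,
           criteria = rec$criteria, candidates = rec$rationale),
      file.path(output_dir, "recommendation.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("recommended setting: %s", rec$setting)
  }

  cohort <- analysis <- NULL
  if (!is.null(cfg$cohort)) {
    cohort <- stage("cohort", {
      simulate_cohort(mesh,
                      n_patients = cfg$cohort$n_patients %||% 30,
                      prop_lbbb = cfg$cohort$prop_lbbb %||% 2 / 3,
                      seed = cfg$seed)
    })
    write_cohort(cohort, file.path(output_dir, "cohort.csv"))
    analysis <- stage("analysis", analyze_cohort(cohort))
    jsonlite::write_json(
      list(ratio_tests = analysis$ratio_tests, slopes = analysis$slopes,
           response_models = lapply(analysis$response_models, function(m)
             list(method = m$method, r_squared = m$r_squared,
                  model_p = m$model_p, n_used = m$n_used,
                  coefficients = m$coefficients))),
      file.path(output_dir, "cohort_analysis.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rpt <- file.path(output_dir, "report.txt")
    sink(rpt); on.exit(sink(), add = TRUE)
    cat(sprintf("crt80 cohort report (n = %d, seed = %d)\n\n",
                nrow(cohort), cfg$seed))
    print(analysis)
    sink(); on.exit()
    say("cohort: n = %d analysed", nrow(cohort))
  }

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  outputs <- list.files(output_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "crt80",
    version = as.character(utils::packageVersion("crt80")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = unclass(cfg),
    config_md5 = md5_string(as.character(cfg_json)),
    outputs = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                              basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(output_dir = output_dir, mesh = mesh, maps = maps,
                 metrics = metrics, recommendation = rec,
                 cohort = cohort, analysis = analysis))
}

md5_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}
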