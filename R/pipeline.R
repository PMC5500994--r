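default_run_params <- function() {
  list(tile_size_m = 1, sd_threshold_m = 0.10, window_radius_m = 1,
       min_tree_area_m2 = 0.5, buffer_m = 1, max_buffer_m = 3,
       height_quantile = 1)
}

#' Read and validate a pipeline run configuration
#'
#' The configuration is a YAML file with fields `mode` (`"synthetic"` or
#' `"files"`), `seed`, an `orchard` block (any [orchard_config()] argument),
#' a `params` block (any analysis threshold: `tile_size_m`, `sd_threshold_m`,
#' `window_radius_m`, `min_tree_area_m2`, `buffer_m`), a `synthetic` block
#' ([simulate_orchard_series()] arguments) and, in files mode, an `inputs`
#' block mapping `date1`/`date2`/`date3` to DSM (and optional RGB) paths.
#'
#' @param path YAML file path.
#' @return A validated run-config list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  cfg$mode <- match.arg(cfg$mode %||% "synthetic", c("synthetic", "files"))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$params <- utils::modifyList(default_run_params(), cfg$params %||% list())
  for (p in c("tile_size_m", "sd_threshold_m", "window_radius_m",
              "min_tree_area_m2", "buffer_m"))
    if (cfg$params[[p]] <= 0) stop("parameter ", p, " must be positive")
  if (cfg$mode == "files") {
    if (is.null(cfg$inputs) || !length(cfg$inputs))
      stop("files mode requires an inputs block")
    for (d in names(cfg$inputs)) {
      if (is.null(cfg$inputs[[d]]$dsm)) stop("missing DSM path for ", d)
      if (!file.exists(cfg$inputs[[d]]$dsm))
        stop("DSM for ", d, " not found: ", cfg$inputs[[d]]$dsm)
    }
  }
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full multi-temporal pipeline
#'
#' Executes generate (or load) -> delineate -> feature extraction for every
#' date, then the date-pair comparisons (impact: date 2 vs 1; annual growth:
#' date 3 vs 2; restoration: date 3 vs 1), severity-class growth and QC
#' report, writing all outputs plus a reproducibility manifest (inputs,
#' parameter values, seeds, package version, per-stage tree counts) to
#' `out_dir`.  Outputs are deterministic for a fixed seed.
#'
#' @param config run-config list (see [read_run_config()]), or a path to a
#'   YAML config.
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir = "pipeline-out") {
  if (is.character(config)) config <- read_run_config(config)
  config <- validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pars <- config$params
  t0 <- proc.time()["elapsed"]
  log_stage <- function(...) message(sprintf("[%7.1fs] ", proc.time()["elapsed"] - t0), ...)

  ocfg <- do.call(orchard_config, config$orchard %||% list())

  scenes <- list(); truths <- NULL
  if (config$mode == "synthetic") {
    log_stage("generate: synthetic ", ocfg$n_rows, "x", ocfg$n_cols, " orchard")
    sim <- do.call(simulate_orchard_series,
                   c(list(config = ocfg, seed = config$seed),
                     config$synthetic %||% list()))
    for (d in names(sim$dates)) {
      scenes[[d]] <- sim$dates[[d]]$scene
      truths <- rbind(truths, sim$dates[[d]]$truth)
    }
    write.csv(truths, file.path(out_dir, "truth.csv"), row.names = FALSE)
  } else {
    for (d in names(config$inputs)) {
      log_stage("read: ", d)
      scenes[[d]] <- read_scene(config$inputs[[d]]$dsm, config$inputs[[d]]$rgb, d)
    }
  }

  records <- list(); masks <- list(); counts <- list()
  for (d in names(scenes)) {
    log_stage("delineate: ", d)
    masks[[d]] <- delineate(scenes[[d]], pars$tile_size_m, pars$sd_threshold_m,
                            pars$window_radius_m, pars$min_tree_area_m2)
    counts[[d]] <- masks[[d]]$n_trees
    log_stage("features: ", d, " (", masks[[d]]$n_trees, " trees)")
    records[[d]] <- extract_features(masks[[d]], scenes[[d]], ocfg,
                                     pars$buffer_m, pars$max_buffer_m,
                                     pars$height_quantile)
    write_tree_outputs(records[[d]], masks[[d]],
                       file.path(out_dir, paste0("trees_", d, ".geojson")),
                       file.path(out_dir, paste0("features_", d, ".csv")))
  }

  comparisons <- list()
  dn <- names(scenes)
  if (length(dn) >= 2) {
    combos <- list(impact = c(1, 2), growth = c(2, 3), restoration = c(1, 3))
    qc <- NULL
    for (cmp in names(combos)) {
      ij <- combos[[cmp]]
      if (max(ij) > length(dn)) next
      log_stage("compare: ", cmp, " (", dn[ij[2]], " vs ", dn[ij[1]], ")")
      m <- match_trees(records[[dn[ij[1]]]], records[[dn[ij[2]]]])
      ch <- change_table(m$pairs, cmp)
      comparisons[[cmp]] <- ch
      write.csv(ch, file.path(out_dir, paste0("changes_", cmp, ".csv")),
                row.names = FALSE)
      write.csv(summarize_change(ch),
                file.path(out_dir, paste0("summary_", cmp, ".csv")),
                row.names = FALSE)
      excl <- ch[!ch$use, c("row", "column", "tree_id")]
      if (nrow(excl)) qc <- rbind(qc, cbind(comparison = cmp, excl))
    }
    if (!is.null(comparisons$impact) && !is.null(comparisons$growth)) {
      m12 <- match_trees(records[[dn[1]]], records[[dn[2]]])
      m23 <- match_trees(records[[dn[2]]], records[[dn[3]]])
      write.csv(severity_class_growth(m12$pairs, m23$pairs),
                file.path(out_dir, "severity_class_growth.csv"),
                row.names = FALSE)
      export_level_maps(comparisons$impact, masks[[dn[1]]], "d_volume",
                        file.path(out_dir, "levels_impact_volume.geojson"))
    }
    write.csv(qc %||% data.frame(), file.path(out_dir, "qc_excluded.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package = "orchardcanopy",
    version = as.character(utils::packageVersion("orchardcanopy")),
    mode = config$mode,
    seed = config$seed,
    params = pars,
    orchard = config$orchard %||% list(),
    synthetic = config$synthetic %||% list(),
    inputs = config$inputs %||% list(),
    tree_counts = counts,
    outputs = list.files(out_dir))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_stage("done: outputs in ", out_dir)
  invisible(manifest)
}
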