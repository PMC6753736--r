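# Configuration I/O, summary emission and run manifests.

module_from_spec <- function(spec, mounting, bad) {
  if (is.null(spec)) {
    return(if (mounting == "table") planar_layout(6, 8, "table")
           else planar_layout(4, 6, "collimator"))
  }
  radius <- spec$radius %||% 0.3
  if (!is.null(spec$centers)) {
    cen <- do.call(rbind, lapply(spec$centers, as.numeric))
    args <- list(centers = cen, mounting = mounting, radius = radius)
    if (!is.null(spec$origin)) args$origin <- as.numeric(spec$origin)
    return(do.call(phantom_module, args))
  }
  layout <- spec$layout %||% "planar"
  if (!layout %in% c("planar", "spiral"))
    stop("config error: ", bad, ".layout must be 'planar' or 'spiral'")
  if (layout == "planar") {
    if (is.null(spec$n_balls) || is.null(spec$cube_edge))
      stop("config error: ", bad, " needs n_balls and cube_edge")
    args <- list(n_balls = spec$n_balls, cube_edge = spec$cube_edge,
                 mounting = mounting, radius = radius)
    if (!is.null(spec$max_per_plane)) args$max_per_plane <- spec$max_per_plane
    if (!is.null(spec$origin)) args$origin <- as.numeric(spec$origin)
    do.call(planar_layout, args)
  } else {
    if (is.null(spec$n_balls) || is.null(spec$cuboid))
      stop("config error: ", bad, " needs n_balls and cuboid")
    args <- list(n_balls = spec$n_balls, cuboid = as.numeric(spec$cuboid),
                 mounting = mounting, radius = radius)
    if (!is.null(spec$origin)) args$origin <- as.numeric(spec$origin)
    do.call(spiral_layout, args)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load an experiment configuration from a YAML file
#'
#' Fills in the nominal defaults (SAD 100 cm, SDD 180 cm, field 20 x 20 cm,
#' ball radius 0.3 cm, default phantom modules) for any field not given.
#' Angles are in degrees, sigma in mm, lengths in cm.
#'
#' @param path path to a YAML configuration file.
#' @return an [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  bad <- character(0)
  if (is.null(cfg$plan)) bad <- c(bad, "plan")
  if (is.null(cfg$sigma_mm)) bad <- c(bad, "sigma_mm")
  if (length(bad)) stop("config error: missing required keys: ",
                        paste(bad, collapse = ", "))
  if (cfg$sigma_mm < 0) stop("config error: sigma_mm must be >= 0")
  mc <- cfg$machine %||% list()
  machine <- machine_constants(
    SAD = mc$SAD %||% 100, SDD = mc$SDD %||% 180,
    field_size = as.numeric(mc$field_size %||% c(20, 20)),
    epid_size = as.numeric(mc$epid_size %||% c(43, 43)))
  ga <- cfg$plan$gantry_angles %||%
    gantry_angle_grid(cfg$plan$n_gantry %||%
                        stop("config error: plan needs gantry_angles or n_gantry"))
  ca <- cfg$plan$collimator_angles %||%
    collimator_angle_grid(cfg$plan$n_collimator %||%
                            stop("config error: plan needs collimator_angles or n_collimator"))
  plan <- test_plan(as.numeric(ga), as.numeric(ca), cfg$sigma_mm, machine)
  table <- module_from_spec(cfg$table_module, "table", "table_module")
  coll <- module_from_spec(cfg$collimator_module, "collimator",
                           "collimator_module")
  experiment_config(plan, table, coll,
                    n_replicates = cfg$n_replicates %||% 2L,
                    seed = cfg$seed %||% 1L,
                    include_sources = cfg$include_sources %||% TRUE)
}

#' Save an experiment configuration to YAML
#'
#' Writes the fully resolved configuration (explicit angle lists and marker
#' centers) so that [load_config()] round-trips to an identical
#' configuration.
#'
#' @param config an [experiment_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  mod_spec <- function(m) list(
    centers = lapply(seq_len(m$n), function(i) as.numeric(m$centers[i, ])),
    radius = m$radius, origin = as.numeric(m$origin))
  out <- list(
    plan = list(
      gantry_angles = as.numeric(unique(config$plan$pairs[, "psi"])),
      collimator_angles = as.numeric(unique(config$plan$pairs[, "theta"]))),
    sigma_mm = config$plan$sigma_mm,
    machine = list(SAD = config$plan$machine$SAD,
                   SDD = config$plan$machine$SDD,
                   field_size = config$plan$machine$field_size,
                   epid_size = config$plan$machine$epid_size),
    table_module = mod_spec(config$table),
    collimator_module = mod_spec(config$collimator),
    n_replicates = config$n_replicates,
    seed = config$seed,
    include_sources = config$include_sources)
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Write a summary table to CSV
#'
#' Stable column order, units column included, chi-squared confidence-limit
#' columns included.
#'
#' @param summary a summary data frame (from [run_experiment()]'s `summary`,
#'   possibly row-bound over configurations).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  if (!is.data.frame(summary) || nrow(summary) == 0L)
    stop("summary table is empty")
  need <- c("metric", "units", "sd", "ci_low", "ci_high")
  if (!all(need %in% names(summary)))
    stop("summary table must contain columns: ", paste(need, collapse = ", "))
  first <- intersect(c("label", "n_gantry", "n_collimator", "sigma_mm",
                       need, "n_values", "n_replicates"), names(summary))
  summary <- summary[, c(first, setdiff(names(summary), first)), drop = FALSE]
  utils::write.csv(summary, path, row.names = FALSE)
  invisible(path)
}

#' Write pooled error samples to CSV
#'
#' One row per pooled value (metric, value).
#'
#' @param result an `experiment_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(result, path) {
  stopifnot(inherits(result, "experiment_result"))
  df <- do.call(rbind, lapply(names(result$pooled), function(m)
    if (length(result$pooled[[m]]))
      data.frame(metric = m, value = result$pooled[[m]])))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Run manifest
#'
#' A reproducibility record: configuration hash, seed, package version,
#' timings and failure count.  Two runs with the same manifest hash and seed
#' produce identical outputs.
#'
#' @param config an [experiment_config()].
#' @param timings named numeric vector of per-stage timings (seconds).
#' @param n_failed failed-replicate count.
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config, timings = NULL, n_failed = 0L) {
  stopifnot(inherits(config, "experiment_config"))
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config, tmp, version = 2L)
  h <- unname(tools::md5sum(tmp))
  structure(list(config_hash = h, seed = config$seed,
                 package_version = as.character(utils::packageVersion("linacqa")),
                 created = format(Sys.time(), tz = "UTC"),
                 timings = timings, n_failed = n_failed),
            class = "run_manifest")
}
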