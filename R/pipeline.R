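#' @title Reproducible staged pipeline
#' @description Ties the stages together behind a validated configuration:
#'   simulate (synthetic landscape + records), qc, swd, fit, evaluate,
#'   project, refugia, gap.  Every stochastic step takes its seed from the
#'   config, artifacts are plain text (ASCII grids, CSV, JSON) and each
#'   stage records a manifest with input hashes so reruns are verifiably
#'   byte-identical.
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' @return named list of configuration values; see the vignette for the
#'   meaning and units of each entry.
#' @export
default_config <- function() {
  list(
    seed = 42,
    grid = list(n_rows = 60, n_cols = 60),
    years = 2000:2019,
    treeline_m = 2000,
    n_pa = 15, n_countries = 4,
    species = list(name = "synthetic alpine bird",
                   linear = c(bio1 = -1.5, lc321 = 0.8, lc332 = 0.5),
                   quadratic = c(bio1 = -0.5),
                   n_records = 4000),
    noise = list(p_bad_accuracy = 0.05, p_old_year = 0.05,
                 p_wrong_season = 0.05, p_bad_habitat = 0.05),
    season = c("05-15", "07-15"),
    qc = list(core_window = c("05-01", "07-31"),
              extended_windows = list(c("04-01", "04-30"),
                                      c("08-01", "08-31")),
              extended_min_breeding = "probable",
              min_year = 2000, max_accuracy_m = 1000),
    background = list(radius_m = 2000, n_points = 4000),
    partition = list(factors = c(4, 2), test_partition = 4),
    maxent = list(rm_grid = c(0.25, 0.5, 1, 2, 4),
                  iter_grid = c(240, 260, 300, 500),
                  n_perm = 10, tol = 1e-8, clamp = FALSE),
    threshold_q = 10,
    pa_filter = list(keep_categories = 1:4,
                     keep_designations = default_keep_designations()),
    out_dir = "refugium_out")
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills defaults, and rejects
#' unknown keys.
#'
#' @param config path to a YAML config file, or a named list.
#' @return validated config list.
#' @export
load_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  def <- default_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(def, config)
  stopifnot(is.numeric(cfg$seed), cfg$grid$n_rows >= 2,
            cfg$grid$n_cols >= 2, cfg$background$n_points >= 1,
            cfg$partition$test_partition %in% 1:4,
            cfg$threshold_q >= 0, cfg$threshold_q <= 100)
  cfg$species$linear <- unlist(cfg$species$linear)
  cfg$species$quadratic <- unlist(cfg$species$quadratic)
  cfg
}

build_landscape <- function(cfg) {
  synthetic_landscape(n_rows = cfg$grid$n_rows, n_cols = cfg$grid$n_cols,
                      seed = cfg$seed, years = cfg$years,
                      treeline_m = cfg$treeline_m, n_pa = cfg$n_pa,
                      n_countries = cfg$n_countries)
}

build_species <- function(cfg) {
  true_species(name = cfg$species$name, linear = cfg$species$linear,
               quadratic = cfg$species$quadratic,
               n_records = cfg$species$n_records,
               p_bad_accuracy = cfg$noise$p_bad_accuracy,
               p_old_year = cfg$noise$p_old_year,
               p_wrong_season = cfg$noise$p_wrong_season,
               p_bad_habitat = cfg$noise$p_bad_habitat)
}

stage_file <- function(cfg, ...) file.path(cfg$out_dir, ...)

require_artifact <- function(cfg, file, producer) {
  p <- stage_file(cfg, file)
  if (!file.exists(p))
    stop("missing artifact '", file, "': run stage '", producer,
         "' first")
  p
}

write_manifest <- function(cfg, stage, files) {
  paths <- vapply(files, function(f) stage_file(cfg, f), "")
  manifest <- list(stage = stage, seed = cfg$seed,
                   config_hash = unname(tools::md5sum(
                     stage_file(cfg, "config.yaml"))),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."),
                   files = as.list(stats::setNames(
                     unname(tools::md5sum(paths)), files)))
  jsonlite::write_json(manifest,
                       stage_file(cfg, paste0("manifest_", stage,
                                              ".json")),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (landscape rasters + raw occurrence records),
#' `qc` (filtered records + rejection log), `swd` (background points,
#' partitions, SWD table), `fit` (AICc-tuned maxent model + trace),
#' `evaluate` (train/test statistics), `project` (current + four future
#' suitability rasters), `refugia` (binary maps, refugia codes, change
#' summary), `gap` (PA overlay overall/per country, filtered variant),
#' or `all`.  Each stage requires its upstream artifacts and writes a
#' manifest with md5 hashes.
#'
#' @param stage stage name.
#' @param config YAML path or config list (see [load_config()]).
#' @return invisibly, the paths written by the stage.
#' @export
run_stage <- function(stage = c("all", "simulate", "qc", "swd", "fit",
                                "evaluate", "project", "refugia", "gap"),
                      config = list()) {
  stage <- match.arg(stage)
  cfg <- load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(cfg, stage_file(cfg, "config.yaml"))
  if (stage == "all") {
    out <- unlist(lapply(c("simulate", "qc", "swd", "fit", "evaluate",
                           "project", "refugia", "gap"),
                         run_stage, config = cfg))
    return(invisible(out))
  }
  fn <- get(paste0("stage_", stage), mode = "function")
  files <- fn(cfg)
  write_manifest(cfg, stage, files)
  invisible(vapply(files, function(f) stage_file(cfg, f), ""))
}

#' @rdname run_stage
#' @export
run_pipeline <- function(config = list()) run_stage("all", config)

stage_simulate <- function(cfg) {
  land <- build_landscape(cfg)
  sp <- build_species(cfg)
  recs <- simulate_occurrences(sp, land, n_records = cfg$species$n_records,
                               seed = cfg$seed + 10,
                               season = cfg$season)
  write_occurrences(recs, stage_file(cfg, "occurrences.csv"))
  write_ascii_grid(land$elevation, stage_file(cfg, "elevation.asc"))
  write_ascii_grid(land$country_raster, stage_file(cfg, "country.asc"))
  write_ascii_grid(land$pa_mask, stage_file(cfg, "pa_mask.asc"))
  utils::write.csv(land$pa_table, stage_file(cfg, "pa_table.csv"),
                   row.names = FALSE, quote = FALSE)
  c("occurrences.csv", "elevation.asc", "country.asc", "pa_mask.asc",
    "pa_table.csv")
}

stage_qc <- function(cfg) {
  require_artifact(cfg, "occurrences.csv", "simulate")
  recs <- read_occurrences(stage_file(cfg, "occurrences.csv"))
  rules <- species_rules(cfg$species$name,
                         core_window = unlist(cfg$qc$core_window),
                         extended_windows = cfg$qc$extended_windows,
                         extended_min_breeding =
                           cfg$qc$extended_min_breeding,
                         min_year = cfg$qc$min_year,
                         max_accuracy_m = cfg$qc$max_accuracy_m)
  res <- filter_records(recs, rules)
  write_occurrences(res$kept, stage_file(cfg, "records_kept.csv"))
  utils::write.csv(res$rejection_log,
                   stage_file(cfg, "rejection_log.csv"),
                   row.names = FALSE, quote = FALSE)
  c("records_kept.csv", "rejection_log.csv")
}

stage_swd <- function(cfg) {
  require_artifact(cfg, "records_kept.csv", "qc")
  land <- build_landscape(cfg)
  kept <- read_occurrences(stage_file(cfg, "records_kept.csv"))
  thin <- thin_to_cells(kept, land$grid)
  bg <- buffer_background(thin$presences,
                          radius_m = cfg$background$radius_m,
                          n_points = cfg$background$n_points,
                          grid = land$grid, seed = cfg$seed + 20)
  swd <- extract_swd(thin$presences, bg, land$predictors,
                     land$climate$bio1_by_year, land$grid,
                     factors = cfg$partition$factors)
  write_swd(swd, stage_file(cfg, "swd.csv"))
  c("swd.csv")
}

stage_fit <- function(cfg) {
  require_artifact(cfg, "swd.csv", "swd")
  swd <- read_swd(stage_file(cfg, "swd.csv"))
  parts <- split_train_test(swd, cfg$partition$test_partition)
  tuned <- tune_maxent(parts$train, rm_grid = cfg$maxent$rm_grid,
                       iter_grid = cfg$maxent$iter_grid,
                       seed = cfg$seed + 30,
                       n_perm = cfg$maxent$n_perm)
  write_maxent(tuned$model, stage_file(cfg, "model.json"))
  utils::write.csv(tuned$trace, stage_file(cfg, "tuning_trace.csv"),
                   row.names = FALSE, quote = TRUE)
  c("model.json", "tuning_trace.csv")
}

stage_evaluate <- function(cfg) {
  require_artifact(cfg, "model.json", "fit")
  require_artifact(cfg, "swd.csv", "swd")
  model <- read_maxent(stage_file(cfg, "model.json"))
  swd <- read_swd(stage_file(cfg, "swd.csv"))
  parts <- split_train_test(swd, cfg$partition$test_partition)
  rep <- evaluate(model, parts$train, parts$test)
  write_evaluation(rep, stage_file(cfg, "evaluation.json"))
  c("evaluation.json")
}

stage_project <- function(cfg) {
  require_artifact(cfg, "model.json", "fit")
  model <- read_maxent(stage_file(cfg, "model.json"))
  land <- build_landscape(cfg)
  futures <- generate_future(land$climate)
  cur <- project_suitability(model,
                             list(bio1 = land$climate$bio1_mean,
                                  bio7 = land$climate$bio7,
                                  bio12 = land$climate$bio12,
                                  bio15 = land$climate$bio15),
                             land$predictors,
                             clamp = cfg$maxent$clamp)
  write_ascii_grid(cur, stage_file(cfg, "suitability_current.asc"))
  files <- "suitability_current.asc"
  for (nm in names(futures)) {
    fut <- project_suitability(model, futures[[nm]], land$predictors,
                               clamp = cfg$maxent$clamp)
    f <- paste0("suitability_", gsub("[^A-Za-z0-9]", "_", nm), ".asc")
    write_ascii_grid(fut, stage_file(cfg, f))
    files <- c(files, f)
  }
  files
}

stage_refugia <- function(cfg) {
  require_artifact(cfg, "suitability_current.asc", "project")
  require_artifact(cfg, "model.json", "fit")
  require_artifact(cfg, "swd.csv", "swd")
  model <- read_maxent(stage_file(cfg, "model.json"))
  swd <- read_swd(stage_file(cfg, "swd.csv"))
  parts <- split_train_test(swd, cfg$partition$test_partition)
  tr_p <- parts$train[parts$train$class == "presence", , drop = FALSE]
  tau <- percentile_threshold(predict(model, tr_p, type = "cloglog"),
                              cfg$threshold_q)
  cur <- read_ascii_grid(stage_file(cfg, "suitability_current.asc"))
  fut_files <- setdiff(list.files(cfg$out_dir,
                                  pattern = "^suitability_.*\\.asc$"),
                       "suitability_current.asc")
  futs <- lapply(fut_files, function(f)
    read_ascii_grid(stage_file(cfg, f)))
  names(futs) <- sub("^suitability_(.*)\\.asc$", "\\1", fut_files)
  cur_bin <- binarize(cur, tau)
  fut_bin <- lapply(futs, binarize, tau = tau)
  ref <- classify_refugia(cur_bin, fut_bin, species = cfg$species$name)
  write_ascii_grid(ref, stage_file(cfg, "refugia.asc"))
  land <- build_landscape(cfg)
  cs <- change_summary(cur_bin, fut_bin, land$elevation)
  df <- as.data.frame(cs)
  df <- rbind(data.frame(condition = "current",
                         extent_km2 = attr(cs, "current_extent_km2"),
                         pct_change = 0,
                         mean_elev_m = attr(cs, "current_mean_elev_m"),
                         elev_shift_m = 0), df)
  utils::write.csv(df, stage_file(cfg, "change_summary.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(tau = tau,
                            mean_pct_change = attr(cs,
                                                   "mean_pct_change")),
                       stage_file(cfg, "threshold.json"),
                       auto_unbox = TRUE, digits = NA)
  c("refugia.asc", "change_summary.csv", "threshold.json")
}

stage_gap <- function(cfg) {
  require_artifact(cfg, "refugia.asc", "refugia")
  require_artifact(cfg, "pa_mask.asc", "simulate")
  ref <- read_ascii_grid(stage_file(cfg, "refugia.asc"))
  type1 <- raster_layer(ref$grid, "type1", ref$values == 1)
  pa <- read_ascii_grid(stage_file(cfg, "pa_mask.asc"))
  country <- read_ascii_grid(stage_file(cfg, "country.asc"))
  pa_table <- utils::read.csv(stage_file(cfg, "pa_table.csv"),
                              stringsAsFactors = FALSE)
  overall <- pa_overlay(type1, pa)
  percountry <- pa_per_country(type1, pa, country)
  pa_f <- filter_pa(pa, pa_table,
                    keep_categories = cfg$pa_filter$keep_categories,
                    keep_designations = cfg$pa_filter$keep_designations)
  overall_f <- pa_overlay(type1, pa_f)
  jsonlite::write_json(list(all_pas = overall, iucn_filtered = overall_f),
                       stage_file(cfg, "gap_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(percountry, stage_file(cfg, "gap_per_country.csv"),
                   row.names = FALSE, quote = FALSE)
  c("gap_summary.json", "gap_per_country.csv")
}
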