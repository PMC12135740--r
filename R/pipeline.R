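#' Default pipeline configuration
#'
#' Gathers every tunable constant of the analysis in one place (no
#' literals buried in stage code): the 5% deviation threshold and 11-beat
#' reference window, the 5% pause tolerance, the pAF detector settings,
#' the deceleration operationalisation, the 95% readability gate, the
#' 5-interval peak-HR rule, and the simulation block.
#'
#' @return nested named list of class `pipeline_config`.
#' @export
default_config <- function() {
  structure(list(
    detection = list(threshold = 0.05, window = 11L,
                     threshold_mode = "relative",
                     reference_statistic = "median"),
    pause = list(tolerance = 0.05),
    paf = list(min_beats = 12L, cv_threshold = 0.10, max_lag1 = 0.3,
               min_delta_frac = 0.5),
    deceleration = list(drop_bpm = 30, window_s = 60L, smooth_s = 10L,
                        min_peak_bpm = 120),
    morphology = list(wide_ratio = 1.25, baseline_beats = 10L),
    readability = list(weighting = "duration", inclusion_cutoff = 0.95),
    hr = list(peak_n = 5L),
    models = list(fixed_terms = c("cardiac", "type", "age", "level",
                                  "season", "duration_min", "hr_peak"),
                  random = "horse_id"),
    simulation = unclass(simulation_config()),
    seed = 1L
  ), class = "pipeline_config")
}

config_bounds <- list(
  "detection.threshold" = c(1e-6, 0.5),
  "detection.window" = c(3, 101),
  "pause.tolerance" = c(0, 0.5),
  "paf.min_beats" = c(4, 1000),
  "paf.cv_threshold" = c(0, 1),
  "paf.max_lag1" = c(0, 1),
  "paf.min_delta_frac" = c(0, 1),
  "deceleration.drop_bpm" = c(1, 200),
  "deceleration.window_s" = c(5, 600),
  "deceleration.smooth_s" = c(1, 120),
  "deceleration.min_peak_bpm" = c(40, 240),
  "morphology.wide_ratio" = c(1, 5),
  "morphology.baseline_beats" = c(3, 100),
  "readability.inclusion_cutoff" = c(0, 1),
  "hr.peak_n" = c(1, 100))

#' Validate (and complete) a pipeline configuration
#'
#' Unknown keys are rejected by name; numeric parameters are checked
#' against documented bounds; missing keys take their defaults.
#' @param cfg nested list (possibly partial).
#' @return completed `pipeline_config`.
#' @export
validate_config <- function(cfg) {
  def <- default_config()
  unknown_top <- setdiff(names(cfg), names(def))
  if (length(unknown_top))
    stop("unknown config key(s): ", paste(unknown_top, collapse = ", "),
         call. = FALSE)
  merged <- unclass(def)
  for (blk in names(cfg)) {
    if (!is.list(def[[blk]])) { merged[[blk]] <- cfg[[blk]]; next }
    unknown <- setdiff(names(cfg[[blk]]), names(def[[blk]]))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0(blk, ".", unknown), collapse = ", "), call. = FALSE)
    for (k in names(cfg[[blk]])) merged[[blk]][[k]] <- cfg[[blk]][[k]]
  }
  for (key in names(config_bounds)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    val <- merged[[parts[1]]][[parts[2]]]
    if (!is.numeric(val) || length(val) != 1 || is.na(val))
      stop("config ", key, " must be a single number", call. = FALSE)
    b <- config_bounds[[key]]
    if (val < b[1] || val > b[2])
      stop("config ", key, " = ", val, " outside bounds [", b[1], ", ",
           b[2], "]", call. = FALSE)
  }
  if (!merged$detection$threshold_mode %in% c("relative", "absolute_at_peak"))
    stop("config detection.threshold_mode must be 'relative' or ",
         "'absolute_at_peak'", call. = FALSE)
  if (!merged$detection$reference_statistic %in% c("median", "mean"))
    stop("config detection.reference_statistic must be 'median' or 'mean'",
         call. = FALSE)
  if (!merged$readability$weighting %in% c("duration", "beats"))
    stop("config readability.weighting must be 'duration' or 'beats'",
         call. = FALSE)
  if (!is.numeric(merged$seed))
    stop("config seed must be an integer", call. = FALSE)
  sim <- merged$simulation
  class(sim) <- NULL
  sim_norm <- do.call(simulation_config,
                      sim[names(sim) %in% names(formals(simulation_config))])
  merged$simulation <- unclass(sim_norm)
  structure(merged, class = "pipeline_config")
}

#' Load / save a pipeline configuration (YAML)
#'
#' Strict schema: unknown keys are listed in the error; numeric bounds
#' enforced. Load-dump-load is stable.
#' @param path YAML file path.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param cfg a `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  cfg <- unclass(cfg)
  # named atomic vectors lose their names as YAML sequences; emit a map
  if (!is.null(cfg$simulation$type_weights))
    cfg$simulation$type_weights <- as.list(cfg$simulation$type_weights)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Write the simulated cohort to disk
#'
#' One tachogram CSV and one ground-truth JSON per workout, a cohort
#' metadata CSV, and a manifest JSON echoing the configuration, seed and
#' format version.
#'
#' @param config a [simulation_config()] (or the `simulation` block of a
#'   pipeline config).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the metadata data.frame.
#' @export
simulate_to_dir <- function(config, out_dir) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config,
                      config[names(config) %in%
                               names(formals(simulation_config))])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- sample_cohort(config)
  meta_rows <- list()
  for (plan in cohort$plans) {
    horse <- cohort$horses[cohort$horses$horse_id == plan$horse_id, ]
    sim <- simulate_workout(horse, plan, config)
    write_tachogram(sim$tachogram,
                    file.path(out_dir, paste0(plan$workout_id, ".csv")))
    jsonlite::write_json(
      list(labels = sim$ground_truth$labels,
           ledger = sim$ground_truth$ledger),
      file.path(out_dir, paste0(plan$workout_id, "_truth.json")),
      auto_unbox = TRUE, digits = NA)
    meta_rows[[length(meta_rows) + 1]] <- meta_as_row(sim$tachogram$meta)
  }
  meta <- do.call(rbind, meta_rows)
  write_cohort_metadata(meta, file.path(out_dir, "cohort_metadata.csv"))
  jsonlite::write_json(list(config = unclass(config), seed = config$seed,
                            format_version = "1.0"),
                       file.path(out_dir, "simulation_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(meta)
}

#' Analyse a directory of tachogram CSVs
#'
#' @param dir directory holding `<workout_id>.csv` tachograms and a
#'   `cohort_metadata.csv`.
#' @param params a `pipeline_config`.
#' @param out_dir optional directory for per-workout events/profile JSON.
#' @return cohort results data.frame (one [summarize_workout()] row per
#'   workout).
#' @export
analyze_dir <- function(dir, params = default_config(), out_dir = NULL) {
  meta <- read_cohort_metadata(file.path(dir, "cohort_metadata.csv"))
  rows <- list()
  for (i in seq_len(nrow(meta))) {
    mrow <- meta[i, ]
    m <- workout_meta(mrow$horse_id, mrow$workout_id, mrow$type,
                      mrow$level, mrow$season, mrow$age, mrow$duration_min,
                      mrow$cardiac)
    t <- read_tachogram(file.path(dir, paste0(mrow$workout_id, ".csv")),
                        meta = m)
    an <- analyze_tachogram(t, params)
    rows[[i]] <- summarize_workout(
      t, an, inclusion_cutoff = params$readability$inclusion_cutoff,
      weighting = params$readability$weighting)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      jsonlite::write_json(
        list(events = an$events,
             profile = unclass(an$profile)[c("nPC", "arrhythmia",
                                             "arrhythmia_deceleration",
                                             "arrhythmia_complex")]),
        file.path(out_dir, paste0(mrow$workout_id, "_events.json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  do.call(rbind, rows)
}

#' Run the full pipeline
#'
#' simulate (optional) -> analyze -> summarize -> cohort tables; writes
#' all artefacts plus a reproducibility manifest with per-file checksums.
#' Re-running with an identical config and seed reproduces identical
#' checksums.
#'
#' @param config a `pipeline_config` (see [default_config()],
#'   [load_config()]).
#' @param out_dir output directory.
#' @param input_dir optional existing tachogram directory; when `NULL`
#'   the simulation block is run first.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config = default_config(), out_dir,
                         input_dir = NULL) {
  config <- validate_config(unclass(config))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- character(0)
  if (is.null(input_dir)) {
    input_dir <- file.path(out_dir, "simulated")
    sim_cfg <- config$simulation
    sim_cfg$seed <- config$seed
    simulate_to_dir(sim_cfg, input_dir)
    stages <- c(stages, "simulate")
  } else if (!dir.exists(input_dir)) {
    stop("input directory not found: ", input_dir, call. = FALSE)
  }
  results <- analyze_dir(input_dir, config,
                         out_dir = file.path(out_dir, "events"))
  stages <- c(stages, "analyze")
  write_results(results, file.path(out_dir, "workout_results.csv"))
  stages <- c(stages, "summarize")
  included <- results[results$included, ]
  summary_tab <- build_group_summary(results)
  utils::write.csv(summary_tab, file.path(out_dir, "group_summary.csv"),
                   row.names = FALSE, eol = "\n")
  assoc <- cohort_associations(included)
  utils::write.csv(assoc, file.path(out_dir, "associations.csv"),
                   row.names = FALSE, eol = "\n")
  models <- cohort_models(included, config)
  jsonlite::write_json(models, file.path(out_dir, "models.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  stages <- c(stages, "cohort")
  manifest <- list(
    config = unclass(config), seed = config$seed, format_version = "1.0",
    stages = stages,
    checksums = as.list(tools::md5sum(
      list.files(out_dir, pattern = "\\.(csv|json)$", full.names = TRUE))),
    timestamp = format(Sys.time(), tz = "UTC"))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  write_manifest(manifest, file.path(out_dir, "run_manifest.json"))
  invisible(manifest)
}

#' @rdname run_pipeline
#' @param manifest manifest list.
#' @param path JSON path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}

# Spearman screen of arrhythmia outcomes against covariates
cohort_associations <- function(results) {
  outcomes <- c("nPC", "arrhythmia", "arrhythmia_deceleration",
                "arrhythmia_complex")
  covars <- c("age", "level", "cardiac", "hr_peak", "duration_min",
              "season")
  out <- list()
  for (o in outcomes) for (v in covars) {
    y <- as.numeric(results[[o]]); x <- as.numeric(results[[v]])
    res <- tryCatch(spearman_assoc(x, y), error = function(e) NULL)
    if (is.null(res)) next
    out[[length(out) + 1]] <- data.frame(
      outcome = o, covariate = v, rho = res$rho, p_value = res$p_value,
      band = res$band)
  }
  do.call(rbind, out)
}

cohort_models <- function(results, config) {
  terms <- config$models$fixed_terms
  rnd <- config$models$random
  safe <- function(expr) tryCatch(suppressWarnings(expr),
                                  error = function(e)
                                    list(error = conditionMessage(e)))
  strip <- function(m) if (inherits(m, "model_result")) unclass(m) else m
  list(
    arrhythmia = strip(safe(fit_mixed_logistic(results, "arrhythmia",
                                               terms, rnd))),
    arrhythmia_deceleration = strip(safe(
      fit_mixed_logistic(results, "arrhythmia_deceleration", terms, rnd))),
    nPC = strip(safe(fit_mixed_poisson(results, "nPC", terms, rnd))))
}
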