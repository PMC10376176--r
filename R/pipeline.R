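#' Build and validate a pipeline configuration
#'
#' One object drives a full analysis run. Exactly one of `synthetic` /
#' `paths` must be supplied:
#' * `synthetic`: a list describing generated inputs — `grid` (arguments to
#'   [grid_spec()]), `n_layers`, optional `collinear_pairs`, `niche`
#'   (`intercept`, named `coefficients`), `n_presences`, and `scenarios`, a
#'   list of `list(period =, scenario =, deltas =)` entries fed to
#'   [make_future_stack()].
#' * `paths`: `occurrences` (delimited text), `layer_manifest` (see
#'   [read_env_stack()]), and `scenarios`, a list of
#'   `list(period =, scenario =, manifests =)` where multiple manifests per
#'   entry are averaged into one period stack.
#'
#' Defaults mirror standard ensemble-SDM practice: 1200 pseudo-absences, a
#' 70/30 train/test split repeated 10 times, predictor screening at
#' |r| < 0.8 and VIF < 10, and skill gates TSS > 0.7, AUC > 0.8.
#'
#' @param synthetic,paths Input description (exactly one non-NULL).
#' @param r_threshold,vif_threshold Predictor screening thresholds.
#' @param tss_gate,auc_gate Ensemble membership gates (strict).
#' @param n_pseudo_absences Pseudo-absence count. Default 1200.
#' @param train_fraction Training fraction. Default 0.7.
#' @param n_repetitions Split repetitions. Default 10.
#' @param learners Character vector of registered learner names.
#' @param weight_mode Ensemble weighting; see [combine()].
#' @param range_classes Classes counted as range in change analysis.
#' @param seed Integer master seed; all stage seeds derive from it.
#' @return A validated `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL, paths = NULL,
                            r_threshold = 0.8, vif_threshold = 10,
                            tss_gate = 0.7, auc_gate = 0.8,
                            n_pseudo_absences = 1200, train_fraction = 0.7,
                            n_repetitions = 10,
                            learners = c("GLM", "SRE"),
                            weight_mode = "mean_of_both",
                            range_classes = c("moderate", "high"),
                            seed = 1) {
  if (is.null(synthetic) == is.null(paths)) {
    rlang::abort("exactly one of 'synthetic' or 'paths' must be given")
  }
  stopifnot(
    r_threshold > 0, r_threshold <= 1,
    vif_threshold > 1,
    tss_gate >= -1, tss_gate <= 1, auc_gate >= 0, auc_gate <= 1,
    n_pseudo_absences >= 1,
    train_fraction > 0, train_fraction < 1,
    n_repetitions >= 1
  )
  if (length(learners) == 0) {
    rlang::abort("validation error: at least one learner required")
  }
  get_learners(learners) # errors early on unregistered names
  cfg <- list(
    synthetic = synthetic, paths = paths,
    r_threshold = r_threshold, vif_threshold = vif_threshold,
    tss_gate = tss_gate, auc_gate = auc_gate,
    n_pseudo_absences = n_pseudo_absences,
    train_fraction = train_fraction, n_repetitions = n_repetitions,
    learners = learners, weight_mode = weight_mode,
    range_classes = range_classes,
    seed = as.integer(seed)
  )
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of
#'   [pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$synthetic$niche$coefficients)) {
    raw$synthetic$niche$coefficients <-
      unlist(raw$synthetic$niche$coefficients)
  }
  do.call(pipeline_config, raw)
}

#' Run the full ensemble-SDM analysis
#'
#' Executes, in order: input construction (synthetic generation or file
#' reading), occurrence thinning, predictor screening, pseudo-absence
#' sampling, repeated stratified splits, per-learner model runs with
#' held-out evaluation, skill gating, weighted-average ensembling,
#' suitability classing with latitude-corrected areas, and per-scenario
#' loss/stable/gain change analysis against the current range. Every
#' intermediate table and raster is written under `out_dir` along with a
#' machine-readable run manifest; identical config + seed reproduces
#' identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created). `NULL` skips writing and only
#'   returns results in memory.
#' @return (Invisibly) a list: `stack`, `occurrences`, `selection`, `table`,
#'   `splits`, `runs`, `ensemble`, `class_map`, `areas`, `importance`,
#'   `changes` (scenario table), `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[ensdm] ", line)
    log_lines <<- c(log_lines, line)
  }
  seed <- config$seed
  stage_seed <- function(k) (seed * 101L + k) %% .Machine$integer.max

  # --- inputs -------------------------------------------------------------
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    spec <- do.call(grid_spec, syn$grid)
    stack <- make_env_stack(spec, syn$n_layers,
                            syn$collinear_pairs %||% list(),
                            seed = stage_seed(1L))
    truth <- niche_truth(syn$niche$intercept, unlist(syn$niche$coefficients))
    occ <- sample_occurrences(stack, truth, syn$n_presences,
                              seed = stage_seed(2L))
    scenarios <- purrr::map(syn$scenarios, function(sc) {
      list(period = sc$period, scenario = sc$scenario,
           stack = make_future_stack(stack, sc$deltas))
    })
    say("synthetic inputs: %d layers on %dx%d grid, %d presences, %d scenario(s)",
        syn$n_layers, spec$n_rows, spec$n_cols, nrow(occ), length(scenarios))
  } else {
    stack <- read_env_stack(config$paths$layer_manifest)
    spec <- stack$spec
    truth <- NULL
    occ <- read_occurrences(config$paths$occurrences)
    scenarios <- purrr::map(config$paths$scenarios, function(sc) {
      stacks <- purrr::map(sc$manifests, read_env_stack)
      list(period = sc$period, scenario = sc$scenario,
           stack = average_period_stacks(stacks))
    })
    say("read %d occurrence record(s) and %d layer(s)", nrow(occ),
        length(stack$layers))
  }

  # --- occurrence prep ----------------------------------------------------
  thinned <- thin_to_grid(occ, spec)
  say("thinning: %d -> %d record(s) (%d off-grid, %d collapsed)",
      nrow(occ), nrow(thinned), attr(thinned, "n_off_grid"),
      attr(thinned, "n_collapsed"))

  # --- predictor screening (full non-missing grid) ------------------------
  grid_vals <- extract_values(stack)
  grid_vals <- grid_vals[stats::complete.cases(grid_vals), ]
  selection <- select_variables(grid_vals, config$r_threshold,
                                config$vif_threshold)
  say("variable selection: kept %d of %d predictor(s)",
      length(selection$kept), length(stack$layers))
  model_stack <- env_stack(stack$layers[selection$kept], spec)

  # --- table + splits -----------------------------------------------------
  table <- sample_pseudo_absences(model_stack, thinned,
                                  n = config$n_pseudo_absences,
                                  seed = stage_seed(3L))
  say("table: %d presence(s), %d pseudo-absence(s)",
      sum(table$label == 1), sum(table$label == 0))
  splits <- split_train_test(table, config$train_fraction,
                             config$n_repetitions, seed = stage_seed(4L))

  # --- model runs ---------------------------------------------------------
  learners <- get_learners(config$learners)
  runs <- run_all(table, splits, learners, model_stack)
  say("runs: %d fitted, %d failed", length(runs),
      nrow(attr(runs, "failures")))

  # --- gate + ensemble ----------------------------------------------------
  retained <- gate_runs(runs, config$tss_gate, config$auc_gate)
  say("gating: retained %d of %d run(s)", length(retained), length(runs))
  ensemble <- combine(retained, table, config$weight_mode)
  say("ensemble: AUC %.3f, TSS %.3f, kappa %.3f, cutoff %.3f",
      ensemble$scores$auc, ensemble$scores$tss, ensemble$scores$kappa,
      ensemble$cutoff)

  # --- importance (ensemble-level, at table cells) ------------------------
  ens_predict <- function(d) {
    # weighted member predictions under each member's stored normalization
    member <- Map(function(run, w) {
      p <- learners[[run$learner]]$predict(run$fit, d)
      if (!is.null(run$norm_range) && run$norm_range > 0) {
        p <- pmin(1, pmax(0, (p - run$norm_min) / run$norm_range))
      } else if (!is.null(run$norm_range)) {
        p <- rep(0.5, length(p))
      }
      p * w
    }, ensemble$runs, ensemble$weights$weight)
    Reduce(`+`, member)
  }
  importance <- importance_table(ens_predict, table[selection$kept],
                                 seed = stage_seed(5L))

  # --- classing + change --------------------------------------------------
  cmap <- classify_suitability(ensemble$grid, ensemble$cutoff, spec)
  areas <- class_areas(cmap)
  current_range <- binary_range(cmap, config$range_classes)
  change_maps <- list()
  changes <- purrr::map(scenarios, function(sc) {
    fut_grid <- project_ensemble(ensemble, sc$stack, learners,
                                 predictors = selection$kept)
    fut_map <- classify_suitability(fut_grid, ensemble$cutoff, spec)
    cats <- change_matrix(current_range,
                          binary_range(fut_map, config$range_classes))
    change_maps[[paste(sc$period, sc$scenario, sep = "_")]] <<- cats
    summarize_change(cats, spec, period = sc$period, scenario = sc$scenario)
  })
  changes <- if (length(changes) > 0) scenario_table(changes) else NULL
  if (!is.null(changes)) {
    say("change analysis: %d scenario row(s)", nrow(changes))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("ensdm")),
    seed = seed,
    config = unclass(config),
    n_occurrences = nrow(occ),
    n_thinned = nrow(thinned),
    kept_predictors = selection$kept,
    n_runs = length(runs),
    n_retained = length(retained),
    ensemble_scores = as.list(ensemble$scores),
    cutoff = ensemble$cutoff
  )

  result <- list(
    stack = stack, truth = truth, occurrences = thinned,
    selection = selection, table = table, splits = splits, runs = runs,
    ensemble = ensemble, class_map = cmap, areas = areas,
    importance = importance, change_maps = change_maps, changes = changes,
    manifest = manifest, log = log_lines
  )
  if (!is.null(out_dir)) write_run_artifacts(result, config, out_dir)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_run_artifacts <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- result$class_map$spec
  readr::write_csv(result$occurrences, file.path(out_dir, "occurrences_thinned.csv"))
  readr::write_csv(tidy(result$selection), file.path(out_dir, "variable_selection.csv"))
  utils::write.csv(result$selection$correlation,
                   file.path(out_dir, "correlation_matrix.csv"))
  readr::write_csv(result$table, file.path(out_dir, "presence_absence_table.csv"))
  scores <- dplyr::bind_rows(
    scores_table(result$runs),
    dplyr::bind_cols(tibble::tibble(learner = "ENSEMBLE",
                                    repetition = NA_integer_),
                     result$ensemble$scores)
  )
  readr::write_csv(scores, file.path(out_dir, "model_scores.csv"))
  readr::write_csv(result$importance, file.path(out_dir, "variable_importance.csv"))
  jsonlite::write_json(
    list(weights = result$ensemble$weights,
         weight_mode = result$ensemble$weight_mode,
         cutoff = result$ensemble$cutoff),
    file.path(out_dir, "ensemble_weights.json"),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  write_asc(result$ensemble$grid, spec,
            file.path(out_dir, "ensemble_suitability.asc"))
  write_asc(result$class_map$classes, spec,
            file.path(out_dir, "suitability_classes.asc"))
  readr::write_csv(
    dplyr::mutate(result$areas,
                  area_1e4_km2 = round_half_up(.data$area_1e4_km2, 2)),
    file.path(out_dir, "class_areas.csv")
  )
  for (nm in names(result$change_maps)) {
    write_asc(result$change_maps[[nm]], spec,
              file.path(out_dir, paste0("change_", nm, ".asc")))
  }
  if (!is.null(result$changes)) {
    readr::write_csv(format_scenario_table(result$changes),
                     file.path(out_dir, "scenario_table.csv"))
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
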