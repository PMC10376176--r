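#' Gate single-model runs by skill
#'
#' Retains only runs whose held-out TSS and AUC both clear their gates,
#' with strict inequalities: a run scoring exactly at a gate is excluded.
#' An empty retention is reported (message), not an error — it only becomes
#' fatal at the combine step.
#'
#' @param runs `model_runs` from [run_all()].
#' @param tss_gate TSS gate (retain if TSS > gate). Default 0.7.
#' @param auc_gate AUC gate (retain if AUC > gate). Default 0.8.
#' @return The retained subset, still a `model_runs` list.
#' @export
gate_runs <- function(runs, tss_gate = 0.7, auc_gate = 0.8) {
  keep <- vapply(runs, function(r) {
    r$scores$tss > tss_gate && r$scores$auc > auc_gate
  }, logical(1))
  message(sprintf("gate_runs: retained %d of %d run(s) (TSS > %g, AUC > %g)",
                  sum(keep), length(runs), tss_gate, auc_gate))
  structure(unclass(runs)[keep], class = "model_runs",
            failures = attr(runs, "failures"))
}

#' Min-max normalize a run's suitability grid
#'
#' Rescales the run's grid predictions affinely so the non-missing cells
#' span `[0, 1]`; a constant grid maps to 0.5 everywhere with a warning.
#' The affine parameters are stored on the run (`norm_min`, `norm_range`)
#' so the identical rescaling can be re-applied when the fitted model is
#' projected onto a future stack.
#'
#' @param run A `model_run`.
#' @return The run with `grid` normalized and the affine recorded.
#' @export
normalize_predictions <- function(run) {
  stopifnot(inherits(run, "model_run"))
  v <- run$grid[!is.na(run$grid)]
  lo <- min(v)
  hi <- max(v)
  if (hi - lo == 0) {
    rlang::warn(sprintf("constant prediction grid (%s rep %d); normalized to 0.5",
                        run$learner, run$repetition))
    run$grid[!is.na(run$grid)] <- 0.5
    run$norm_min <- lo
    run$norm_range <- 0
  } else {
    run$grid <- (run$grid - lo) / (hi - lo)
    run$norm_min <- lo
    run$norm_range <- hi - lo
  }
  run
}

apply_normalization <- function(run, grid) {
  if (is.null(run$norm_range)) return(grid)
  if (run$norm_range == 0) {
    grid[!is.na(grid)] <- 0.5
    return(grid)
  }
  pmin(pmax((grid - run$norm_min) / run$norm_range, 0), 1)
}

#' Combine retained runs into a weighted-average ensemble
#'
#' Each retained run's grid is min-max normalized, then averaged with
#' weights proportional to its held-out skill: the AUC, the TSS, or (the
#' default) the mean of both — the higher a run's average AUC and TSS, the
#' greater its weight. Scores are shifted so their minimum is non-negative
#' before normalising weights to sum to 1 (TSS can be negative). The
#' ensemble is then re-scored against the full labelled table, and its
#' TSS-maximising cutoff becomes the suitable/unsuitable binarisation
#' threshold carried into habitat classing.
#'
#' @param retained Gated `model_runs` (see [gate_runs()]); must be
#'   non-empty.
#' @param table The labelled presence/pseudo-absence tibble the ensemble is
#'   re-evaluated on (grid values extracted at its cells).
#' @param weight_mode `"mean_of_both"` (default), `"auc"`, or `"tss"`.
#' @return An `ensemble_model`: `runs`, `weights` (tibble: learner,
#'   repetition, score, weight), `grid` (ensemble suitability matrix in
#'   `[0, 1]`), `scores` (one-row tibble), `cutoff`, `weight_mode`.
#' @export
combine <- function(retained, table,
                    weight_mode = c("mean_of_both", "auc", "tss")) {
  weight_mode <- match.arg(weight_mode)
  if (length(retained) == 0) {
    rlang::abort("ensemble error: no retained runs to combine")
  }
  score_of <- function(r) {
    switch(weight_mode,
           auc = r$scores$auc,
           tss = r$scores$tss,
           mean_of_both = (r$scores$auc + r$scores$tss) / 2)
  }
  raw <- vapply(retained, score_of, numeric(1))
  shifted <- if (min(raw) < 0) raw - min(raw) else raw
  weights <- if (sum(shifted) == 0) {
    rep(1 / length(shifted), length(shifted))
  } else {
    shifted / sum(shifted)
  }
  normed <- lapply(retained, normalize_predictions)
  grid <- Reduce(`+`, Map(function(r, w) r$grid * w, normed, weights))
  scores <- NULL
  cutoff <- NA_real_
  if (!is.null(table)) {
    loc <- tibble::tibble(row = table$row, col = table$col)
    pred <- grid[cbind(loc$row, loc$col)]
    ok <- !is.na(pred)
    bc <- best_cutoff(pred[ok], table$label[ok])
    scores <- bc$scores
    cutoff <- bc$cutoff
  }
  structure(
    list(
      runs = normed,
      weights = tibble::tibble(
        learner = vapply(retained, `[[`, character(1), "learner"),
        repetition = vapply(retained, `[[`, integer(1), "repetition"),
        score = raw,
        weight = weights
      ),
      grid = grid,
      spec = NULL,
      scores = scores,
      cutoff = cutoff,
      weight_mode = weight_mode
    ),
    class = "ensemble_model"
  )
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat(sprintf("<ensemble_model> %d member run(s), weight mode '%s'\n",
              nrow(x$weights), x$weight_mode))
  if (!is.null(x$scores)) {
    cat(sprintf("  AUC %.3f, TSS %.3f, kappa %.3f, cutoff %.3f\n",
                x$scores$auc, x$scores$tss, x$scores$kappa, x$cutoff))
  }
  invisible(x)
}

#' @rdname combine
#' @param x An `ensemble_model`.
#' @param ... Unused.
#' @return `tidy()`: the member weight tibble. `glance()`: one-row tibble of
#'   ensemble scores plus member count.
#' @export
tidy.ensemble_model <- function(x, ...) x$weights

#' @rdname combine
#' @export
glance.ensemble_model <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_members = nrow(x$weights),
                                  weight_mode = x$weight_mode),
                   x$scores)
}

#' Project an ensemble onto a (future) stack
#'
#' Re-predicts every member model on the given stack, re-applies each
#' member's stored min-max affine (fitted on the current grid, clipped to
#' `[0, 1]`) and combines with the fitted weights — so current and future
#' suitability share one scale and the current cutoff stays meaningful.
#'
#' @param ensemble An `ensemble_model` from [combine()].
#' @param stack An [env_stack()] aligned with the training stack.
#' @param learners The learner registry entries used to fit the members;
#'   default [default_learners()] plus anything registered.
#' @param predictors Predictor names used at fit time.
#' @return Suitability matrix in `[0, 1]`.
#' @export
project_ensemble <- function(ensemble, stack,
                             learners = get_learners(unique(
                               ensemble$weights$learner)),
                             predictors) {
  stopifnot(inherits(ensemble, "ensemble_model"), inherits(stack, "env_stack"))
  cc <- cell_centers(stack$spec)
  grid_data <- dplyr::bind_cols(cc, extract_values(stack, cc))
  complete <- stats::complete.cases(grid_data[predictors])
  grids <- Map(function(run, w) {
    lrn <- learners[[run$learner]]
    pred <- rep(NA_real_, nrow(grid_data))
    pred[complete] <- lrn$predict(run$fit, grid_data[complete, ])
    g <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
    g[cbind(grid_data$row, grid_data$col)] <- pred
    apply_normalization(run, g) * w
  }, ensemble$runs, ensemble$weights$weight)
  Reduce(`+`, grids)
}

#' Plot an ensemble suitability map
#'
#' @param object An `ensemble_model`.
#' @param spec The [grid_spec()] of the analysis grid.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ensemble_model <- function(object, spec, ...) {
  df <- grid_to_tibble(object$grid, spec, "suitability")
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$suitability)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Suitability")
}
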