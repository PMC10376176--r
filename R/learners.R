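#' Learner specifications and the learner registry
#'
#' Single models enter the pipeline through a uniform contract: a
#' `learner_spec` bundles a unique name, a fit function
#' `fit(train_data, predictors, ...)` returning a fitted object, and a
#' predict function `predict(fit, newdata)` returning suitabilities in
#' `[0, 1]`. The two native learners — logistic regression ([fit_glm()])
#' and the surface range envelope ([fit_sre()]) — are pre-registered;
#' additional learners (boosted trees, random forests, MARS, neural nets,
#' Maxent, ...) can be attached with [register_learner()] without touching
#' the pipeline.
#'
#' @param name Unique learner name (e.g. `"GLM"`).
#' @param fit Function `(data, predictors, ...)` -> fitted object. `data` is
#'   the training subset of the presence/pseudo-absence table.
#' @param predict Function `(fit, newdata)` -> numeric predictions in
#'   `[0, 1]`. Default calls `stats::predict()`.
#' @param hyper Named list of hyperparameters passed to `fit`.
#' @param native Flag marking the built-in learners.
#' @return A `learner_spec` object.
#' @export
learner_spec <- function(name, fit,
                         predict = function(object, newdata) {
                           stats::predict(object, newdata)
                         },
                         hyper = list(), native = FALSE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name),
            is.function(fit), is.function(predict))
  structure(list(name = name, fit = fit, predict = predict,
                 hyper = hyper, native = native),
            class = "learner_spec")
}

the_registry <- new.env(parent = emptyenv())

#' @rdname learner_spec
#' @param spec A `learner_spec` to register.
#' @param overwrite Replace an existing entry of the same name?
#' @export
register_learner <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "learner_spec"))
  if (!overwrite && spec$name %in% ls(the_registry)) {
    rlang::abort(paste0("learner already registered: ", spec$name))
  }
  assign(spec$name, spec, envir = the_registry)
  invisible(spec)
}

#' @rdname learner_spec
#' @param names Character vector of registered learner names.
#' @return `get_learners()`: a named list of `learner_spec`s.
#' @export
get_learners <- function(names) {
  missing_l <- setdiff(names, ls(the_registry))
  if (length(missing_l) > 0) {
    rlang::abort(paste0("unregistered learner(s): ",
                        paste(missing_l, collapse = ", ")))
  }
  stats::setNames(lapply(names, get, envir = the_registry), names)
}

#' @rdname learner_spec
#' @return `default_learners()`: the native `GLM` and `SRE` specs.
#' @export
default_learners <- function() get_learners(c("GLM", "SRE"))

register_native_learners <- function() {
  register_learner(learner_spec(
    "GLM",
    fit = function(data, predictors, ...) {
      fit_glm(data, predictors = predictors, ...)
    },
    native = TRUE
  ), overwrite = TRUE)
  register_learner(learner_spec(
    "SRE",
    fit = function(data, predictors, quantile = 0.025, ...) {
      fit_sre(data[data$label == 1, ], predictors = predictors,
              quantile = quantile)
    },
    native = TRUE
  ), overwrite = TRUE)
}

.onLoad <- function(libname, pkgname) {
  register_native_learners()
}

#' Fit every learner on every train/test repetition
#'
#' Runs each registered learner on each split, evaluates it on the held-out
#' rows (TSS-maximising cutoff, AUC, kappa), and predicts suitability over
#' the full grid. A failing learner run is recorded and skipped rather than
#' aborting the batch; the pipeline only errors if every run fails.
#'
#' @param table Presence/pseudo-absence tibble from
#'   [sample_pseudo_absences()].
#' @param splits Split assignments from [split_train_test()].
#' @param learners List of [learner_spec()]s (default [default_learners()]).
#' @param stack The [env_stack()] to predict over.
#' @param predictors Predictor columns; default the table's `predictors`
#'   attribute.
#' @return A `model_runs` list of `model_run` objects, each with `learner`,
#'   `repetition`, `fit`, `pred_test`, `test_labels`, `grid` (prediction
#'   matrix), `scores` (one-row tibble). Failures are attached as attribute
#'   `failures` (tibble: learner, repetition, message).
#' @export
run_all <- function(table, splits, learners = default_learners(), stack,
                    predictors = attr(table, "predictors")) {
  stopifnot(is.data.frame(table), length(learners) >= 1,
            inherits(stack, "env_stack"))
  if (is.null(predictors)) {
    rlang::abort("predictors not given and table carries no 'predictors' attribute")
  }
  cc <- cell_centers(stack$spec)
  grid_data <- dplyr::bind_cols(cc, extract_values(stack, cc))
  grid_complete <- stats::complete.cases(grid_data[predictors])
  reps <- sort(unique(splits$repetition))
  failures <- tibble::tibble(learner = character(), repetition = integer(),
                             message = character())
  runs <- list()
  for (lrn in learners) {
    for (rep_i in reps) {
      idx <- splits$row_index[splits$repetition == rep_i &
                                splits$set == "train"]
      test_idx <- splits$row_index[splits$repetition == rep_i &
                                     splits$set == "test"]
      run <- tryCatch({
        fit <- do.call(lrn$fit, c(list(table[idx, ], predictors), lrn$hyper))
        pred_test <- lrn$predict(fit, table[test_idx, ])
        if (any(pred_test < 0 | pred_test > 1, na.rm = TRUE)) {
          stop("learner predictions outside [0, 1]")
        }
        grid_pred <- rep(NA_real_, nrow(grid_data))
        grid_pred[grid_complete] <-
          lrn$predict(fit, grid_data[grid_complete, ])
        grid <- matrix(NA_real_, stack$spec$n_rows, stack$spec$n_cols)
        grid[cbind(grid_data$row, grid_data$col)] <- grid_pred
        bc <- best_cutoff(pred_test, table$label[test_idx])
        structure(
          list(learner = lrn$name, repetition = rep_i, fit = fit,
               pred_test = pred_test, test_labels = table$label[test_idx],
               grid = grid, scores = bc$scores),
          class = "model_run"
        )
      }, error = function(e) {
        failures <<- dplyr::add_row(failures, learner = lrn$name,
                                    repetition = as.integer(rep_i),
                                    message = conditionMessage(e))
        NULL
      })
      if (!is.null(run)) runs[[length(runs) + 1]] <- run
    }
  }
  if (length(runs) == 0) {
    rlang::abort("pipeline error: every learner run failed")
  }
  if (nrow(failures) > 0) {
    message(sprintf("run_all: %d run(s) failed and were skipped", nrow(failures)))
  }
  structure(runs, class = "model_runs", failures = failures)
}

#' @export
print.model_run <- function(x, ...) {
  cat(sprintf("<model_run> %s rep %d: AUC %.3f, TSS %.3f, kappa %.3f\n",
              x$learner, x$repetition, x$scores$auc, x$scores$tss,
              x$scores$kappa))
  invisible(x)
}

#' @export
print.model_runs <- function(x, ...) {
  cat(sprintf("<model_runs> %d run(s), %d failure(s)\n", length(x),
              nrow(attr(x, "failures"))))
  print(scores_table(x))
  invisible(x)
}

#' Per-run evaluation score table
#'
#' @param runs A `model_runs` list from [run_all()] (or any list of
#'   `model_run`s).
#' @return A tibble: `learner`, `repetition`, `auc`, `tss`, `kappa`,
#'   `cutoff`, `sensitivity`, `specificity`.
#' @export
scores_table <- function(runs) {
  purrr::map_dfr(runs, function(r) {
    dplyr::bind_cols(tibble::tibble(learner = r$learner,
                                    repetition = r$repetition),
                     r$scores)
  })
}
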