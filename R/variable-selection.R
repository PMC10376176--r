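#' Pearson correlation matrix of candidate predictors
#'
#' @param values Data frame or matrix of predictor samples (rows = samples,
#'   >= 3; no missing values).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(values) {
  m <- as.matrix(values)
  stopifnot(nrow(m) >= 3)
  if (anyNA(m)) rlang::abort("missing values in predictor matrix")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(paste0(
      "undefined correlation: zero-variance column(s): ",
      paste(colnames(m)[sds == 0], collapse = ", ")
    ))
  }
  stats::cor(m)
}

#' Variance inflation factor of one predictor
#'
#' `VIF = 1 / (1 - R^2)` where `R^2` comes from an ordinary least-squares
#' regression of the named column on all the other columns. A VIF of 1 means
#' the predictor is orthogonal to the rest; perfect collinearity is reported
#' as `Inf` rather than an error so screening loops can handle it.
#'
#' @param values Data frame or matrix (more rows than columns, >= 2 columns).
#' @param column Column name.
#' @return The VIF (>= 1, possibly `Inf`).
#' @export
vif <- function(values, column) {
  m <- as.matrix(values)
  stopifnot(ncol(m) >= 2, nrow(m) > ncol(m))
  if (!column %in% colnames(m)) {
    rlang::abort(paste0("unknown column: ", column))
  }
  y <- m[, column]
  x <- m[, setdiff(colnames(m), column), drop = FALSE]
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, x), y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) rlang::abort(paste0("zero-variance column: ", column))
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

vif_all <- function(m) {
  vapply(colnames(m), function(cl) vif(m, cl), numeric(1))
}

#' Screen predictors by pairwise correlation and VIF
#'
#' Iteratively eliminates collinear predictors until every retained pair has
#' `|r| < r_threshold` and every retained predictor has
#' `VIF < vif_threshold` (both strict: a value exactly at the threshold is
#' dropped). Each pass first resolves the worst-offending correlated pair —
#' dropping the member with the larger mean absolute correlation to all
#' other remaining predictors — then drops the largest VIF violator, and
#' repeats to a fixed point. Every drop is recorded with its reason and the
#' offending value.
#'
#' @param values Data frame or matrix of candidate predictors (>= 2 columns).
#' @param r_threshold Pairwise |Pearson r| bound. Default 0.8.
#' @param vif_threshold VIF bound. Default 10.
#' @return A `selection_report`: list with `kept` (ordered names), `dropped`
#'   (tibble: `layer`, `reason`, `value`), `correlation` (matrix over kept),
#'   `vif` (named vector over kept), and the thresholds.
#' @export
select_variables <- function(values, r_threshold = 0.8, vif_threshold = 10) {
  m <- as.matrix(values)
  stopifnot(ncol(m) >= 2)
  if (is.null(colnames(m))) colnames(m) <- paste0("V", seq_len(ncol(m)))
  dropped <- tibble::tibble(layer = character(), reason = character(),
                            value = numeric())
  drop_one <- function(layer, reason, value) {
    dropped <<- dplyr::add_row(dropped, layer = layer, reason = reason,
                               value = value)
    m <<- m[, setdiff(colnames(m), layer), drop = FALSE]
  }
  repeat {
    changed <- FALSE
    # correlation rule
    if (ncol(m) >= 2) {
      cm <- pearson_matrix(m)
      off <- abs(cm)
      diag(off) <- 0
      worst <- max(off)
      if (worst >= r_threshold) {
        idx <- which(off == worst, arr.ind = TRUE)[1, ]
        pair <- colnames(m)[idx]
        mean_abs <- rowMeans(abs(cm[pair, , drop = FALSE])) -
          1 / ncol(cm) # remove the unit diagonal contribution
        victim <- pair[which.max(mean_abs)]
        drop_one(victim, "correlation", cm[pair[1], pair[2]])
        changed <- TRUE
      }
    }
    # VIF rule
    if (ncol(m) >= 2 && nrow(m) > ncol(m)) {
      vifs <- vif_all(m)
      if (max(vifs) >= vif_threshold) {
        victim <- names(which.max(vifs))
        drop_one(victim, "vif", max(vifs))
        changed <- TRUE
      }
    }
    if (ncol(m) < 2) {
      rlang::abort("selection error: fewer than 2 predictors remain")
    }
    if (!changed) break
  }
  structure(
    list(
      kept = colnames(m),
      dropped = dropped,
      correlation = pearson_matrix(m),
      vif = vif_all(m),
      r_threshold = r_threshold,
      vif_threshold = vif_threshold
    ),
    class = "selection_report"
  )
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> kept %d predictor(s): %s\n",
              length(x$kept), paste(x$kept, collapse = ", ")))
  if (nrow(x$dropped) > 0) {
    cat(sprintf("dropped %d:\n", nrow(x$dropped)))
    print(x$dropped)
  }
  invisible(x)
}

#' @rdname select_variables
#' @param x A `selection_report`.
#' @param ... Unused.
#' @return `tidy()`: one row per candidate with `layer`, `status`
#'   (kept/dropped), `reason`, `value` (offending statistic for drops, final
#'   VIF for keeps).
#' @export
tidy.selection_report <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(layer = x$kept, status = "kept", reason = NA_character_,
                   value = unname(x$vif[x$kept])),
    dplyr::mutate(x$dropped, status = "dropped", .after = "layer")
  )
}

#' Permutation importance of a predictor for a fitted model
#'
#' Importance of a column is `1 - cor(pred, pred_permuted)` averaged over
#' `n_shuffles` random permutations of that column, clipped to `[0, 1]`: a
#' model whose predictions do not use the column scores 0, a model driven
#' entirely by it scores near 1. If either prediction vector is constant the
#' correlation is taken as 1 (importance 0).
#'
#' @param model A fitted learner with a `predict()` method returning values
#'   in `[0, 1]` (e.g. from [fit_glm()]), or any function
#'   `f(data) -> predictions`.
#' @param values Data frame of predictor samples.
#' @param column Column to permute.
#' @param n_shuffles Number of permutations to average. Default 5.
#' @param seed Integer seed.
#' @return A single importance in `[0, 1]`.
#' @export
permutation_importance <- function(model, values, column, n_shuffles = 5,
                                   seed) {
  values <- tibble::as_tibble(values)
  if (!column %in% names(values)) {
    rlang::abort(paste0("unknown column: ", column))
  }
  predict_fun <- if (is.function(model)) model else {
    function(d) stats::predict(model, d)
  }
  base_pred <- predict_fun(values)
  withr::with_seed(seed, {
    mean(vapply(seq_len(n_shuffles), function(i) {
      shuffled <- values
      shuffled[[column]] <- sample(shuffled[[column]])
      perm_pred <- predict_fun(shuffled)
      if (stats::sd(base_pred) == 0 || stats::sd(perm_pred) == 0) {
        return(0)
      }
      min(1, max(0, 1 - stats::cor(base_pred, perm_pred)))
    }, numeric(1)))
  })
}

#' Permutation-importance table over all predictors
#'
#' Applies [permutation_importance()] to every column and reports both the
#' raw `1 - r` importances and their normalisation to percentages summing
#' to 100 (the conventional "variable importance" table).
#'
#' @inheritParams permutation_importance
#' @param columns Columns to score; default all columns of `values`.
#' @return A tibble sorted by decreasing importance: `layer`, `importance`
#'   (raw), `importance_pct`.
#' @export
importance_table <- function(model, values, columns = names(values),
                             n_shuffles = 5, seed) {
  raw <- vapply(
    columns,
    function(cl) permutation_importance(model, values, cl, n_shuffles, seed),
    numeric(1)
  )
  total <- sum(raw)
  tibble::tibble(
    layer = columns,
    importance = unname(raw),
    importance_pct = if (total > 0) unname(100 * raw / total) else 0
  ) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}
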