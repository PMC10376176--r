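#' Environmental layer stacks
#'
#' An `env_stack` holds co-registered single-band environmental layers on one
#' lon/lat grid: a named list of numeric matrices (dimensions
#' `n_rows x n_cols` of the [grid_spec()], row 1 = southernmost band) plus
#' the grid spec itself. Missing data is `NA` and propagates through every
#' downstream operation.
#'
#' @param layers Named list of numeric matrices, all `n_rows x n_cols`.
#' @param spec The shared [grid_spec()].
#' @return An object of class `env_stack`.
#' @export
env_stack <- function(layers, spec) {
  stopifnot(inherits(spec, "grid_spec"), is.list(layers), length(layers) >= 1)
  nm <- names(layers)
  if (is.null(nm) || any(nm == "") || anyDuplicated(nm)) {
    rlang::abort("layers must have unique, non-empty names")
  }
  ok <- vapply(
    layers,
    function(m) is.matrix(m) && all(dim(m) == c(spec$n_rows, spec$n_cols)),
    logical(1)
  )
  if (!all(ok)) {
    rlang::abort(sprintf(
      "layer(s) %s do not match the grid spec (%d x %d)",
      paste(nm[!ok], collapse = ", "), spec$n_rows, spec$n_cols
    ))
  }
  structure(list(layers = layers, spec = spec), class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf(
    "<env_stack> %d layer(s) on a %d x %d grid: %s\n",
    length(x$layers), x$spec$n_rows, x$spec$n_cols,
    paste(names(x$layers), collapse = ", ")
  ))
  invisible(x)
}

#' @export
names.env_stack <- function(x) names(x$layers)

#' Extract layer values at grid cells
#'
#' @param stack An [env_stack()].
#' @param cells A tibble with `row` and `col` columns (e.g. from
#'   [locate_cells()] or [cell_centers()]); defaults to every cell.
#' @param layers Layer names to extract; default all.
#' @return A tibble, one row per requested cell, one column per layer.
#' @export
extract_values <- function(stack, cells = NULL, layers = names(stack$layers)) {
  stopifnot(inherits(stack, "env_stack"))
  if (is.null(cells)) cells <- cell_centers(stack$spec)
  missing_layers <- setdiff(layers, names(stack$layers))
  if (length(missing_layers) > 0) {
    rlang::abort(paste0(
      "unknown layer(s): ", paste(missing_layers, collapse = ", ")
    ))
  }
  idx <- cbind(cells$row, cells$col)
  out <- purrr::map(stack$layers[layers], function(m) m[idx])
  tibble::as_tibble(out)
}

#' Cells with complete predictor data
#'
#' @param stack An [env_stack()].
#' @return Logical matrix, `TRUE` where every layer is non-missing.
#' @export
complete_cells <- function(stack) {
  Reduce(`&`, lapply(stack$layers, function(m) !is.na(m)))
}

#' Cell-wise mean of aligned stacks
#'
#' Averages each layer across a list of stacks that share the same grid and
#' layer names — e.g. annual scenario stacks averaged into a mid-century or
#' end-of-century climatology.
#'
#' @param stacks List of [env_stack()] objects, all aligned.
#' @return An [env_stack()] of cell-wise arithmetic means.
#' @export
average_period_stacks <- function(stacks) {
  stopifnot(is.list(stacks), length(stacks) >= 1)
  ref <- stacks[[1]]
  stopifnot(inherits(ref, "env_stack"))
  for (s in stacks[-1]) {
    if (!inherits(s, "env_stack") ||
        !identical(unclass(s$spec), unclass(ref$spec)) ||
        !identical(names(s$layers), names(ref$layers))) {
      rlang::abort("all stacks must share one grid spec and one layer set")
    }
  }
  k <- length(stacks)
  layers <- purrr::map(names(ref$layers), function(nm) {
    Reduce(`+`, lapply(stacks, function(s) s$layers[[nm]])) / k
  })
  names(layers) <- names(ref$layers)
  env_stack(layers, ref$spec)
}

#' Plot an environmental stack
#'
#' One facet per layer, cells coloured by value.
#'
#' @param object An [env_stack()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.env_stack <- function(object, ...) {
  df <- stack_to_long(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~layer) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "value")
}

stack_to_long <- function(stack) {
  cc <- cell_centers(stack$spec)
  vals <- extract_values(stack, cc)
  dplyr::bind_cols(cc, vals) |>
    tidyr::pivot_longer(
      cols = dplyr::all_of(names(stack$layers)),
      names_to = "layer", values_to = "value"
    )
}

grid_to_tibble <- function(m, spec, value_name = "value") {
  cc <- cell_centers(spec)
  cc[[value_name]] <- m[cbind(cc$row, cc$col)]
  cc
}
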