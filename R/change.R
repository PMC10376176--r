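#' Binary range from a class map
#'
#' Collapses a suitability class map to a 0/1 range mask. The default
#' counts moderately and highly suitable cells as range — the standard
#' basis for range-change accounting — but any non-empty class subset can
#' be requested (e.g. all three suitable bands for a total-suitable mask).
#'
#' @param map A `class_map` from [classify_suitability()].
#' @param classes Character subset of
#'   `c("unsuitable", "low", "moderate", "high")`. Default
#'   `c("moderate", "high")`.
#' @return Binary matrix (1 in-range, 0 out, `NA` missing).
#' @export
binary_range <- function(map, classes = c("moderate", "high")) {
  stopifnot(inherits(map, "class_map"))
  if (length(classes) == 0) {
    rlang::abort("configuration error: empty class set")
  }
  bad <- setdiff(classes, suitability_class_names)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown class(es): ", paste(bad, collapse = ", ")))
  }
  codes <- match(classes, suitability_class_names) - 1L
  out <- matrix(NA_real_, nrow(map$classes), ncol(map$classes))
  ok <- !is.na(map$classes)
  out[ok] <- as.numeric(map$classes[ok] %in% codes)
  out
}

#' Per-cell loss/stable/gain change matrix
#'
#' Cross-tabulates current and future binary ranges cell-wise:
#' current 1 / future 0 is loss, 1/1 stable, 0/1 gain, 0/0 never suitable.
#'
#' @param current,future Binary matrices on the same grid (e.g. from
#'   [binary_range()]).
#' @return Integer matrix of category codes: 0 never, 1 loss, 2 stable,
#'   3 gain; `NA` where either input is missing.
#' @export
change_matrix <- function(current, future) {
  if (!all(dim(current) == dim(future))) {
    rlang::abort("alignment error: current and future grids differ in shape")
  }
  out <- matrix(NA_integer_, nrow(current), ncol(current))
  ok <- !is.na(current) & !is.na(future)
  out[ok & current == 1 & future == 0] <- 1L
  out[ok & current == 1 & future == 1] <- 2L
  out[ok & current == 0 & future == 1] <- 3L
  out[ok & current == 0 & future == 0] <- 0L
  out
}

change_category_names <- c("never", "loss", "stable", "gain")

#' Range-change summary from component areas
#'
#' The bookkeeping core of a range-change table row. Given loss, stable and
#' gain areas (any consistent unit; conventionally 10^4 km²) and the current
#' range area, derives:
#' * future suitable area = stable + gain
#' * species range change % = 100 x (gain - loss) / current
#' * percentage loss = 100 x loss / current
#' * percentage gain = 100 x gain / current
#'
#' `stable + loss` must equal the current area (they partition it); a
#' mismatch beyond `tolerance` errors.
#'
#' @param loss,stable,gain Component areas.
#' @param current Current (baseline) range area; must be > 0.
#' @param period,scenario Labels for the table row.
#' @param tolerance Allowed |stable + loss - current| (default 0.02,
#'   generous enough for inputs independently rounded to 2 decimals).
#' @return One-row tibble: `period`, `scenario`, `future_suitable`, `loss`,
#'   `stable`, `gain`, `species_range_change_pct`, `pct_loss`, `pct_gain`.
#' @export
range_change_stats <- function(loss, stable, gain, current,
                               period = NA_character_,
                               scenario = NA_character_,
                               tolerance = 0.02) {
  if (current <= 0) {
    rlang::abort("undefined percentage: current area must be > 0")
  }
  stopifnot(loss >= 0, stable >= 0, gain >= 0)
  if (abs(stable + loss - current) > tolerance) {
    rlang::abort(sprintf(
      "bookkeeping violation: stable + loss = %.6f but current = %.6f",
      stable + loss, current
    ))
  }
  tibble::tibble(
    period = period,
    scenario = scenario,
    future_suitable = stable + gain,
    loss = loss,
    stable = stable,
    gain = gain,
    species_range_change_pct = 100 * (gain - loss) / current,
    pct_loss = 100 * loss / current,
    pct_gain = 100 * gain / current
  )
}

#' Summarise a change matrix into a range-change table row
#'
#' Converts the per-cell loss/stable/gain categories into
#' latitude-corrected areas (10^4 km²) and the derived percentages.
#'
#' @param categories Change-category matrix from [change_matrix()].
#' @param spec The [grid_spec()].
#' @param period,scenario Labels for the row.
#' @return One-row tibble as in [range_change_stats()].
#' @export
summarize_change <- function(categories, spec, period = NA_character_,
                             scenario = NA_character_) {
  stopifnot(inherits(spec, "grid_spec"),
            all(dim(categories) == c(spec$n_rows, spec$n_cols)))
  cc <- cell_centers(spec)
  cat_v <- categories[cbind(cc$row, cc$col)]
  area <- cell_area_km2(cc$lat, spec) / 1e4
  area_of <- function(code) sum(area[!is.na(cat_v) & cat_v == code])
  loss <- area_of(1L)
  stable <- area_of(2L)
  gain <- area_of(3L)
  range_change_stats(loss, stable, gain, current = stable + loss,
                     period = period, scenario = scenario, tolerance = 1e-9)
}

#' Assemble and check a scenario range-change table
#'
#' Binds per-scenario summaries, orders rows by (period, scenario), and
#' verifies the internal identities of every row (future = stable + gain;
#' range change % = % gain - % loss) before the table is used or written.
#'
#' @param summaries A list of one-row summaries (or a tibble of rows) from
#'   [summarize_change()] / [range_change_stats()].
#' @return The checked, ordered tibble.
#' @export
scenario_table <- function(summaries) {
  tbl <- if (is.data.frame(summaries)) tibble::as_tibble(summaries) else {
    dplyr::bind_rows(summaries)
  }
  if (nrow(tbl) < 1) rlang::abort("at least one summary required")
  if (anyDuplicated(tbl[c("period", "scenario")])) {
    rlang::abort("duplicate (period, scenario) row")
  }
  stopifnot(
    all(abs(tbl$future_suitable - (tbl$stable + tbl$gain)) < 1e-9),
    all(abs(tbl$species_range_change_pct - (tbl$pct_gain - tbl$pct_loss))
        < 1e-9)
  )
  dplyr::arrange(tbl, .data$period, .data$scenario)
}

#' Plot a loss/stable/gain change map
#'
#' @param categories Change-category matrix from [change_matrix()].
#' @param spec The [grid_spec()].
#' @return A ggplot object.
#' @export
plot_change_map <- function(categories, spec) {
  df <- grid_to_tibble(categories, spec, "code")
  df$category <- factor(change_category_names[df$code + 1],
                        levels = change_category_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat,
                                   fill = .data$category)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(never = "grey92", loss = "#d73027", stable = "#4575b4",
                 gain = "#1a9850"),
      na.value = "white", drop = FALSE
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Range change")
}

#' Round a range-change table for presentation
#'
#' Applies half-up rounding to 2 decimals to the area and percentage
#' columns — the convention used when such tables are printed. Compute
#' first, round last: percentages are always derived from unrounded areas.
#'
#' @param tbl A [scenario_table()].
#' @param digits Decimal places. Default 2.
#' @return The rounded tibble.
#' @export
format_scenario_table <- function(tbl, digits = 2) {
  num <- intersect(c("future_suitable", "loss", "stable", "gain",
                     "species_range_change_pct", "pct_loss", "pct_gain"),
                   names(tbl))
  dplyr::mutate(tbl, dplyr::across(dplyr::all_of(num),
                                   ~round_half_up(.x, digits)))
}
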