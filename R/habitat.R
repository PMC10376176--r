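#' Class a suitability map into unsuitable/low/moderate/high
#'
#' Cells below the binarisation cutoff are unsuitable; the suitable range
#' `[cutoff, 1]` is divided into three equal-width bands for minimally
#' (low), moderately and highly suitable habitat. Intervals are
#' left-closed/right-open, with the top band closed at 1, so every
#' non-missing cell gets exactly one class.
#'
#' @param grid Suitability matrix in `[0, 1]` (`NA` = missing).
#' @param cutoff Binarisation threshold in `[0, 1)` (e.g. the ensemble's
#'   TSS-maximising cutoff).
#' @param spec The [grid_spec()] of the map.
#' @return A `class_map`: list with `classes` (integer matrix, 0 unsuitable,
#'   1 low, 2 moderate, 3 high, `NA` missing), `cutoff`, breaks `b1`, `b2`,
#'   and `spec`.
#' @export
classify_suitability <- function(grid, cutoff, spec) {
  if (cutoff < 0 || cutoff >= 1) {
    rlang::abort("configuration error: cutoff must be in [0, 1)")
  }
  stopifnot(inherits(spec, "grid_spec"),
            all(dim(grid) == c(spec$n_rows, spec$n_cols)))
  w <- (1 - cutoff) / 3
  b1 <- cutoff + w
  b2 <- cutoff + 2 * w
  cls <- matrix(NA_integer_, nrow(grid), ncol(grid))
  cls[grid < cutoff] <- 0L
  cls[grid >= cutoff & grid < b1] <- 1L
  cls[grid >= b1 & grid < b2] <- 2L
  cls[grid >= b2] <- 3L # top band closed at 1
  structure(list(classes = cls, cutoff = cutoff, b1 = b1, b2 = b2,
                 spec = spec),
            class = "class_map")
}

suitability_class_names <- c("unsuitable", "low", "moderate", "high")

#' @export
print.class_map <- function(x, ...) {
  counts <- table(factor(x$classes, levels = 0:3,
                         labels = suitability_class_names))
  cat(sprintf("<class_map> cutoff %.3f, breaks %.3f / %.3f\n",
              x$cutoff, x$b1, x$b2))
  print(counts)
  invisible(x)
}

#' Latitude-corrected class areas
#'
#' Sums the spherical area ([cell_area_km2()]) of the cells in each
#' suitability class. Areas are reported in units of 10^4 km² at full
#' precision; round only at presentation ([round_half_up()]).
#'
#' @param map A `class_map` from [classify_suitability()].
#' @return A tibble: `class` (factor unsuitable/low/moderate/high),
#'   `area_1e4_km2`.
#' @export
class_areas <- function(map) {
  stopifnot(inherits(map, "class_map"))
  cc <- cell_centers(map$spec)
  cls <- map$classes[cbind(cc$row, cc$col)]
  area <- cell_area_km2(cc$lat, map$spec) / 1e4
  tibble::tibble(
    class = factor(suitability_class_names, levels = suitability_class_names),
    area_1e4_km2 = vapply(0:3, function(k) sum(area[!is.na(cls) & cls == k]),
                          numeric(1))
  )
}

#' Plot a suitability class map
#'
#' @param object A `class_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.class_map <- function(object, ...) {
  df <- grid_to_tibble(object$classes, object$spec, "code")
  df$class <- factor(suitability_class_names[df$code + 1],
                     levels = suitability_class_names)
  ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(unsuitable = "grey90", low = "#fee08b",
                 moderate = "#fc8d59", high = "#d73027"),
      na.value = "white", drop = FALSE
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Suitability")
}
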