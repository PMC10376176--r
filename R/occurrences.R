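#' Read occurrence records from delimited text
#'
#' Reads presence coordinates (WGS84 decimal degrees) from a CSV/TSV file.
#' Rows with unparseable or out-of-bounds coordinates (|lon| > 180,
#' |lat| > 90) are dropped and counted; duplicated coordinates are retained
#' at this stage — de-duplication to the analysis grid is a separate,
#' explicit step ([thin_to_grid()]).
#'
#' @param path Path to a delimited text file.
#' @param lon_col,lat_col Column names holding longitude and latitude.
#'   Default `"lon"`, `"lat"`.
#' @param source_col Optional column carrying a provenance label; if absent
#'   the file name is used.
#' @param delim Field delimiter; `NULL` (default) auto-detects comma vs tab.
#' @return A tibble with columns `lon`, `lat`, `source`. The number of
#'   rejected rows is attached as attribute `n_rejected` and reported via
#'   a message.
#' @export
read_occurrences <- function(path, lon_col = "lon", lat_col = "lat",
                             source_col = NULL, delim = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("file not found: ", path))
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- tryCatch(
    readr::read_delim(path, delim = delim, show_col_types = FALSE,
                      progress = FALSE),
    error = function(e) rlang::abort(paste0("format error reading ", path,
                                            ": ", conditionMessage(e)))
  )
  for (col in c(lon_col, lat_col)) {
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("format error: column '%s' not found", col))
    }
  }
  lon <- suppressWarnings(as.numeric(raw[[lon_col]]))
  lat <- suppressWarnings(as.numeric(raw[[lat_col]]))
  src <- if (!is.null(source_col) && source_col %in% names(raw)) {
    as.character(raw[[source_col]])
  } else {
    rep(basename(path), nrow(raw))
  }
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    message(sprintf("read_occurrences: rejected %d out-of-bounds/unparseable row(s)",
                    n_rejected))
  }
  out <- tibble::tibble(lon = lon[ok], lat = lat[ok], source = src[ok])
  if (nrow(out) == 0) rlang::abort("empty-input error: no valid occurrence rows")
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Thin occurrences to one record per grid cell
#'
#' Collapses clustered records so each analysis cell contributes at most one
#' presence, removing the weight that opportunistic, spatially duplicated
#' sightings would otherwise carry. Within a cell the first record in input
#' order is kept (deterministic, auditable). Records outside the grid extent
#' are dropped and counted.
#'
#' @param occ Occurrence tibble (`lon`, `lat`, ...), e.g. from
#'   [read_occurrences()].
#' @param spec A [grid_spec()].
#' @return A tibble like `occ` with at most one row per cell, plus `row`,
#'   `col`, `cell_id` columns; attributes `n_off_grid` and `n_collapsed`
#'   report the drops. Thinning is idempotent.
#' @export
thin_to_grid <- function(occ, spec) {
  stopifnot(is.data.frame(occ), all(c("lon", "lat") %in% names(occ)))
  loc <- locate_cells(occ$lon, occ$lat, spec)
  on_grid <- !is.na(loc$cell_id)
  n_off <- sum(!on_grid)
  if (n_off > 0) {
    message(sprintf("thin_to_grid: dropped %d record(s) outside the grid", n_off))
  }
  occ <- tibble::as_tibble(occ)[setdiff(names(occ), c("row", "col", "cell_id"))]
  kept <- dplyr::bind_cols(occ[on_grid, ], loc[on_grid, ]) |>
    dplyr::distinct(.data$cell_id, .keep_all = TRUE)
  attr(kept, "n_off_grid") <- n_off
  attr(kept, "n_collapsed") <- sum(on_grid) - nrow(kept)
  kept
}

#' Build a labelled presence / pseudo-absence table
#'
#' Draws `n` pseudo-absence cells uniformly without replacement from the
#' grid cells that (a) carry complete predictor data and (b) contain no
#' presence, and binds them with the presences into the model-ready table.
#' Pseudo-absences stand in for the true absences that presence-only data
#' lack; a single draw is shared across all train/test repetitions.
#'
#' @param stack An [env_stack()] of candidate predictors.
#' @param presences Thinned occurrence tibble (one row per cell; run
#'   [thin_to_grid()] first).
#' @param n Number of pseudo-absences. Default 1200.
#' @param seed Integer seed (deterministic draw).
#' @return A tibble with columns `cell_id`, `row`, `col`, `lon`, `lat`,
#'   `label` (1 presence, 0 pseudo-absence) and one column per layer;
#'   attribute `predictors` holds the layer names.
#' @export
sample_pseudo_absences <- function(stack, presences, n = 1200, seed) {
  stopifnot(inherits(stack, "env_stack"), n >= 1)
  loc <- locate_cells(presences$lon, presences$lat, stack$spec)
  if (anyNA(loc$cell_id)) {
    rlang::abort("presences outside the grid; thin_to_grid() drops these first")
  }
  if (anyDuplicated(loc$cell_id)) {
    rlang::abort("multiple presences share a cell; run thin_to_grid() first")
  }
  cc <- cell_centers(stack$spec)
  complete <- complete_cells(stack)[cbind(cc$row, cc$col)]
  pres_vals <- extract_values(stack, loc)
  if (anyNA(pres_vals)) {
    rlang::abort("presence cell(s) have missing predictor data")
  }
  eligible <- which(complete & !(cc$cell_id %in% loc$cell_id))
  if (length(eligible) < n) {
    rlang::abort(sprintf(
      "sampling error: %d pseudo-absences requested but only %d eligible cells (short by %d)",
      n, length(eligible), n - length(eligible)
    ))
  }
  absent <- withr::with_seed(seed, sort(sample(eligible, n)))
  pres_tbl <- dplyr::bind_cols(
    loc["cell_id"], loc[c("row", "col")],
    tibble::tibble(lon = presences$lon, lat = presences$lat, label = 1L),
    pres_vals
  )
  abs_cells <- cc[absent, ]
  abs_tbl <- dplyr::bind_cols(
    abs_cells[c("cell_id", "row", "col", "lon", "lat")],
    tibble::tibble(label = 0L),
    extract_values(stack, abs_cells)
  )
  out <- dplyr::bind_rows(pres_tbl, abs_tbl)
  attr(out, "predictors") <- names(stack$layers)
  out
}

#' Stratified repeated train/test splits
#'
#' Assigns each table row to train or test, independently `n_repetitions`
#' times, stratified by label so each split preserves the class balance to
#' within one record per class.
#'
#' @param table Labelled table from [sample_pseudo_absences()] (any tibble
#'   with a binary `label` column works).
#' @param train_fraction Fraction of each class assigned to training.
#'   Default 0.7.
#' @param n_repetitions Number of independent splits. Default 10.
#' @param seed Integer seed.
#' @return A tibble with columns `repetition`, `row_index`, `set`
#'   (`"train"`/`"test"`); for every repetition the row indices partition
#'   `seq_len(nrow(table))`.
#' @export
split_train_test <- function(table, train_fraction = 0.7, n_repetitions = 10,
                             seed) {
  stopifnot(is.data.frame(table), "label" %in% names(table),
            train_fraction > 0, train_fraction < 1, n_repetitions >= 1)
  classes <- split(seq_len(nrow(table)), table$label)
  if (length(classes) < 2) rlang::abort("split error: table needs both classes")
  if (any(lengths(classes) < 2)) {
    rlang::abort("split error: each class needs at least 2 members")
  }
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_repetitions), function(rep_i) {
      train_idx <- unlist(lapply(classes, function(idx) {
        sample(idx, round(train_fraction * length(idx)))
      }), use.names = FALSE)
      tibble::tibble(
        repetition = rep_i,
        row_index = seq_len(nrow(table)),
        set = ifelse(seq_len(nrow(table)) %in% train_idx, "train", "test")
      )
    })
  })
}
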