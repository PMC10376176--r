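# Plain-text raster interchange: one ESRI ASCII grid (.asc) per layer plus a
# JSON manifest mapping layer name -> file. The .asc header is the standard
# six-line cell-registered form; rows are written north to south as the
# format requires, while env_stack matrices keep row 1 = southernmost.

#' Write a single layer as an ESRI ASCII grid
#'
#' @param m Numeric matrix (row 1 = southernmost band).
#' @param spec The [grid_spec()].
#' @param path Output file path (conventionally `.asc`).
#' @param nodata Value written for `NA` cells. Default `-9999`.
#' @return `path`, invisibly.
#' @export
write_asc <- function(m, spec, path, nodata = -9999) {
  stopifnot(inherits(spec, "grid_spec"),
            all(dim(m) == c(spec$n_rows, spec$n_cols)))
  header <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$lon_min),
    sprintf("yllcorner %.10g", spec$lat_min),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  m[is.na(m)] <- nodata
  rows <- apply(m[rev(seq_len(spec$n_rows)), , drop = FALSE], 1,
                function(r) paste(format(r, trim = TRUE, digits = 10),
                                  collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_asc()] or any conforming `.asc` file
#'   (corner- or centre-registered header).
#' @return A list with `values` (matrix, row 1 = southernmost) and `spec`
#'   (a [grid_spec()]).
#' @export
read_asc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (k in c("ncols", "nrows", "cellsize")) {
    if (is.null(hdr[[k]])) rlang::abort(sprintf("missing %s in .asc header", k))
  }
  cs <- hdr$cellsize
  lon_min <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - cs / 2
  lat_min <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - cs / 2
  body <- lines[i:length(lines)]
  vals <- as.numeric(unlist(strsplit(trimws(body), "\\s+")))
  n_rows <- as.integer(hdr$nrows)
  n_cols <- as.integer(hdr$ncols)
  if (length(vals) != n_rows * n_cols) {
    rlang::abort("grid body does not match declared dimensions")
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m <- m[rev(seq_len(n_rows)), , drop = FALSE] # north-first file -> south-first matrix
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(values = m, spec = grid_spec(n_rows, n_cols, lon_min, lat_min, cs))
}

#' Write a stack as per-layer ASCII grids plus a JSON manifest
#'
#' @param stack An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return Path to the manifest (`layers.json`), invisibly.
#' @export
write_env_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "env_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- purrr::imap_chr(stack$layers, function(m, nm) {
    f <- paste0(nm, ".asc")
    write_asc(m, stack$spec, file.path(dir, f))
    f
  })
  manifest <- file.path(dir, "layers.json")
  jsonlite::write_json(as.list(files), manifest, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read a stack from a layer manifest
#'
#' @param manifest Path to a `layers.json` written by [write_env_stack()]
#'   (layer name -> `.asc` file, paths relative to the manifest).
#' @return An [env_stack()].
#' @export
read_env_stack <- function(manifest) {
  files <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  grids <- purrr::map(files, function(f) read_asc(file.path(dir, f)))
  spec <- grids[[1]]$spec
  env_stack(purrr::map(grids, "values"), spec)
}
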