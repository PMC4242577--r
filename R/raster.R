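#' Regular lon/lat raster grid
#'
#' A minimal container for one environmental variable on a regular WGS84
#' decimal-degree grid, mirroring the ESRI ASCII grid layout: `values` is an
#' `n_rows x n_cols` matrix whose first row is the northernmost row, and
#' `x_origin`/`y_origin` give the lower-left corner of the extent. Cells equal
#' to `nodata_value` (stored as `NA` internally) are excluded from all
#' statistics.
#'
#' @param values Numeric matrix (`n_rows x n_cols`), row 1 = northern edge.
#'   `NA` marks missing cells.
#' @param x_origin,y_origin Lower-left corner of the grid, decimal degrees.
#' @param cell_size Cell edge length in decimal degrees; must be positive.
#' @param nodata_value Sentinel written to file for missing cells.
#' @return An object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(1:4, 2, 2), x_origin = 0, y_origin = 0,
#'                  cell_size = 0.5)
#' dim(g$values)
#' @export
raster_grid <- function(values, x_origin, y_origin, cell_size,
                        nodata_value = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  assert_that(is.numeric(cell_size) && length(cell_size) == 1 && cell_size > 0,
              "`cell_size` must be a single positive number")
  structure(
    list(values = values,
         n_rows = nrow(values), n_cols = ncol(values),
         x_origin = as.double(x_origin), y_origin = as.double(y_origin),
         cell_size = as.double(cell_size),
         nodata_value = as.double(nodata_value)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells, cell size %g deg\n",
              x$n_rows, x$n_cols, x$cell_size))
  cat(sprintf("  extent: lon [%g, %g], lat [%g, %g]; %d missing cells\n",
              x$x_origin, x$x_origin + x$n_cols * x$cell_size,
              x$y_origin, x$y_origin + x$n_rows * x$cell_size,
              sum(is.na(x$values))))
  invisible(x)
}

grid_y_top <- function(grid) grid$y_origin + grid$n_rows * grid$cell_size

same_geometry <- function(a, b, tol = 1e-9) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$x_origin - b$x_origin) < tol &&
    abs(a$y_origin - b$y_origin) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

#' Read an ESRI ASCII grid
#'
#' Parses the plain-text ESRI ASCII raster dialect (header keys `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, optional `NODATA_value`,
#' then `nrows` whitespace-separated data rows, northernmost first).
#'
#' @param path Path to the `.asc` file.
#' @return A [raster_grid].
#' @seealso [write_ascii_grid()]
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  header <- list()
  i <- 1L
  while (i <= length(lines) &&
         grepl("^[A-Za-z_]+\\s", trimws(lines[[i]]))) {
    parts <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    header[[tolower(parts[[1]])]] <- as.double(parts[[2]])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(header[[key]])) {
      abort(sprintf("malformed ESRI ASCII header in '%s': missing key '%s'",
                    path, key))
    }
  }
  nodata <- header[["nodata_value"]] %||% -9999
  n_rows <- as.integer(header$nrows)
  n_cols <- as.integer(header$ncols)
  data_lines <- lines[seq.int(i, length.out = length(lines) - i + 1L)]
  assert_that(length(data_lines) == n_rows,
              sprintf("expected %d data rows, found %d", n_rows,
                      length(data_lines)))
  rows <- lapply(seq_len(n_rows), function(r) {
    vals <- as.double(strsplit(trimws(data_lines[[r]]), "\\s+")[[1]])
    if (length(vals) != n_cols) {
      abort(sprintf("row %d has %d values, expected %d", r, length(vals),
                    n_cols))
    }
    vals
  })
  values <- do.call(rbind, rows)
  values[values == nodata] <- NA_real_
  raster_grid(values, header$xllcorner, header$yllcorner, header$cellsize,
              nodata_value = nodata)
}

#' Write an ESRI ASCII grid
#'
#' Inverse of [read_ascii_grid()]; finite values round-trip bit-identically
#' (written with full precision via `format(..., digits = 17)`).
#'
#' @param grid A [raster_grid].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- grid$nodata_value
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %s", format(grid$x_origin, digits = 17)),
    sprintf("yllcorner %s", format(grid$y_origin, digits = 17)),
    sprintf("cellsize %s", format(grid$cell_size, digits = 17)),
    sprintf("NODATA_value %s", format(grid$nodata_value, digits = 17))
  )
  body <- apply(vals, 1L, function(r) {
    paste(vapply(r, function(v) format(v, digits = 17), character(1)),
          collapse = " ")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Half-open pixel assignment: a point belongs to cell
# col = floor((x - x_origin)/cell_size) + 1,
# row = floor((y_top - y)/cell_size) + 1.
# Points on the east/south outer edge fall outside the grid.
cell_of <- function(grid, lon, lat) {
  col <- floor((lon - grid$x_origin) / grid$cell_size) + 1
  row <- floor((grid_y_top(grid) - lat) / grid$cell_size) + 1
  ok <- col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  list(row = as.integer(row), col = as.integer(col), inside = ok)
}

cell_center <- function(grid, row, col) {
  list(lon = grid$x_origin + (col - 0.5) * grid$cell_size,
       lat = grid_y_top(grid) - (row - 0.5) * grid$cell_size)
}

#' Thin occurrence records to one per grid cell
#'
#' Herbarium records are routinely deduplicated to the resolution of the
#' climate grid before niche modelling; this keeps the first record per
#' occupied pixel in input order (within each taxon), using half-open pixel
#' assignment.
#'
#' @param occ Tibble with columns `taxon`, `lon`, `lat` (decimal degrees).
#' @param grid [raster_grid] defining the pixel geometry; all points must lie
#'   inside its extent.
#' @return Tibble of the same shape with at most one record per occupied cell
#'   per taxon. Idempotent.
#' @export
thin_occurrences <- function(occ, grid) {
  occ <- as_tibble(occ)
  assert_that(all(c("taxon", "lon", "lat") %in% names(occ)),
              "`occ` needs columns taxon, lon, lat")
  assert_that(nrow(occ) >= 1, "`occ` must contain at least one record")
  cl <- cell_of(grid, occ$lon, occ$lat)
  if (any(!cl$inside)) {
    abort(sprintf("occurrence point(s) outside grid extent at row index %s",
                  paste(which(!cl$inside), collapse = ", ")))
  }
  occ %>%
    mutate(.cell = paste(.data$taxon, cl$row, cl$col)) %>%
    distinct(.data$.cell, .keep_all = TRUE) %>%
    select(-".cell")
}

#' Extract climate values at occurrence points
#'
#' @param stack Named list of [raster_grid]s sharing one geometry.
#' @param occ Tibble with `lon`, `lat` columns.
#' @return Tibble with one column per stack variable; rows align with `occ`.
#'   Points over missing cells yield `NA`.
#' @export
extract_climate <- function(stack, occ) {
  stopifnot(length(stack) >= 1)
  g1 <- stack[[1]]
  for (g in stack) assert_that(same_geometry(g1, g), "stack geometry mismatch")
  cl <- cell_of(g1, occ$lon, occ$lat)
  assert_that(all(cl$inside), "points outside stack extent")
  idx <- cbind(cl$row, cl$col)
  out <- lapply(stack, function(g) g$values[idx])
  as_tibble(out)
}

#' Climate table for every grid cell
#'
#' Flattens a climate stack into the background table used for niche
#' modelling: one row per cell with no missing variable.
#'
#' @inheritParams extract_climate
#' @param keep_coords Also return `lon`/`lat` cell-centre columns.
#' @return Tibble of cell values (complete cases only).
#' @export
background_table <- function(stack, keep_coords = FALSE) {
  g1 <- stack[[1]]
  for (g in stack) assert_that(same_geometry(g1, g), "stack geometry mismatch")
  vals <- lapply(stack, function(g) as.vector(g$values))
  out <- as_tibble(vals)
  rows <- rep(seq_len(g1$n_rows), times = g1$n_cols)
  cols <- rep(seq_len(g1$n_cols), each = g1$n_rows)
  if (keep_coords) {
    cc <- cell_center(g1, rows, cols)
    out$lon <- cc$lon
    out$lat <- cc$lat
  }
  out$.row <- rows
  out$.col <- cols
  out[stats::complete.cases(out[names(stack)]), ]
}
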