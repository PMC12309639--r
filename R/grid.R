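#' Gridded layer
#'
#' `grid_layer()` is the common currency of the hydrology, plume and coral
#' stages: a single-band regular raster stored as a numeric matrix with square
#' cells. No-data cells are `NA` in `values`. Rows index northing (row 1 is the
#' northern edge), columns index easting; cell centres sit at
#' `origin + (index - 0.5) * cell_size`.
#'
#' @param values numeric or integer matrix.
#' @param cell_size side length of a (square) cell in metres.
#' @param origin numeric length-2, `(x, y)` of the outer corner of cell
#'   `(1, 1)` (north-west corner of the grid), metres.
#' @param crs_label free-text coordinate-system label.
#' @return an object of class `grid_layer`.
#' @export
grid_layer <- function(values, cell_size, origin = c(0, 0),
                       crs_label = "local-metric") {
  values <- as.matrix(values)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("cell_size must be a single positive number (metres)")
  if (length(origin) != 2L) stop("origin must be length 2 (x, y)")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), crs_label = as.character(crs_label)),
    class = "grid_layer"
  )
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values
  cat(sprintf("<grid_layer> %d x %d cells, %.6g m cell, origin (%.6g, %.6g)\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2]))
  fin <- v[is.finite(v)]
  if (length(fin))
    cat(sprintf("  data cells: %d, range [%.6g, %.6g]\n", length(fin),
                min(fin), max(fin)))
  cat(sprintf("  no-data cells: %d\n", sum(is.na(v))))
  invisible(x)
}

is_grid_layer <- function(x) inherits(x, "grid_layer")

#' @export
dim.grid_layer <- function(x) dim(x$values)

stopifnot_same_shape <- function(...) {
  gs <- list(...)
  d <- dim(gs[[1]]$values)
  for (g in gs)
    if (!identical(dim(g$values), d)) stop("grids must share a common shape")
  invisible(TRUE)
}

#' Replace the value matrix of a grid, keeping its geometry
#' @param g a `grid_layer`.
#' @param values replacement matrix of identical shape.
#' @return a `grid_layer`.
#' @export
with_values <- function(g, values) {
  values <- as.matrix(values)
  if (!identical(dim(values), dim(g$values)))
    stop("replacement values must match grid shape")
  g$values <- values
  g
}

#' Cell-centre coordinates
#'
#' @param g a `grid_layer`.
#' @param rows,cols integer indices (1-based). Defaults to all cells.
#' @return data.frame with columns `row`, `col`, `x`, `y` (metres).
#' @export
cell_centers <- function(g, rows = NULL, cols = NULL) {
  if (is.null(rows)) {
    idx <- which(!is.na(g$values) | is.na(g$values))  # all cells
    rows <- row(g$values)[idx]; cols <- col(g$values)[idx]
  }
  data.frame(
    row = rows, col = cols,
    x = g$origin[1] + (cols - 0.5) * g$cell_size,
    y = g$origin[2] - (rows - 0.5) * g$cell_size
  )
}

#' Area of one cell in square kilometres
#' @param g a `grid_layer`.
#' @return scalar km^2.
#' @export
cell_area_km2 <- function(g) (g$cell_size / 1000)^2

# ---- ESRI ASCII grid I/O ------------------------------------------------
# Plain-text raster interchange; readable by QGIS/GDAL. The header stores the
# lower-left corner, so conversion from our upper-left origin happens here.

#' Write a grid as an ESRI ASCII raster (.asc)
#'
#' @param g a `grid_layer`.
#' @param path output file path.
#' @param digits significant digits written per cell.
#' @return `path`, invisibly.
#' @export
write_asc <- function(g, path, digits = 7) {
  v <- g$values
  nr <- nrow(v); nc <- ncol(v)
  nodata <- -9999
  yll <- g$origin[2] - nr * g$cell_size
  hdr <- c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %d", nodata)
  )
  m <- v
  m[is.na(m)] <- nodata
  body <- apply(m, 1, function(r) paste(formatC(r, digits = digits,
                                                format = "g"), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII raster (.asc) into a grid
#'
#' @param path file written by [write_asc()] or any GIS.
#' @param crs_label label to attach.
#' @return a `grid_layer`.
#' @export
read_asc <- function(path, crs_label = "local-metric") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  body <- lines[i:length(lines)]
  vals <- lapply(body, function(r) as.numeric(strsplit(trimws(r),
                                                       "[[:space:]]+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  origin <- c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize)
  grid_layer(m, hdr$cellsize, origin, crs_label)
}

# ---- neighbour bookkeeping ----------------------------------------------
# D8 neighbour order is fixed clockwise from east; this order is the
# tie-breaking order everywhere in the hydrology stage.
D8_DROW <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
D8_DCOL <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
D8_DIST <- sqrt(D8_DROW^2 + D8_DCOL^2)   # in cell units
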