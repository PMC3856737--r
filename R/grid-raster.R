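#' Rectangular grid raster in a local planar frame
#'
#' Minimal raster container used throughout the pipeline: a numeric matrix of
#' cell values together with the cell size (metres), the coordinates of the
#' lower-left corner and a nodata sentinel. Row 1 of the matrix is the
#' northernmost row (the ESRI ASCII file convention); cell centres are at
#' `(xll + (col - 0.5) * cell_size, yll + (nrow - row + 0.5) * cell_size)`.
#' No geodesy: coordinates are planar metres, which is how all distances in
#' the analysis are expressed.
#'
#' @param values numeric matrix (row 1 = northernmost row).
#' @param cell_size cell side length in metres, > 0.
#' @param xll,yll coordinates (m) of the lower-left corner of the grid.
#' @param nodata sentinel value marking missing cells (default -9999).
#' @return An object of class `grid_raster`.
#' @export
grid_raster <- function(values, cell_size, xll = 0, yll = 0, nodata = -9999) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (!is.numeric(values)) stop("'values' must be numeric")
  if (!is.numeric(cell_size) || length(cell_size) != 1 || cell_size <= 0)
    stop("'cell_size' must be a single positive number")
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         xll = as.numeric(xll), yll = as.numeric(yll),
         nodata = as.numeric(nodata)),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  cat(sprintf("<grid_raster> %d rows x %d cols, cell %g m, origin (%g, %g), nodata %g\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$xll, x$yll, x$nodata))
  invisible(x)
}

#' @export
dim.grid_raster <- function(x) dim(x$values)

#' Test whether two grids share shape, cell size and origin
#'
#' @param a,b `grid_raster` objects.
#' @param tol numeric tolerance on cell size and origin, in metres.
#' @return `TRUE`/`FALSE`.
#' @export
grids_congruent <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$cell_size - b$cell_size) < tol &&
    abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol
}

stopifnot_congruent <- function(a, b) {
  if (!grids_congruent(a, b))
    stop("grids are not congruent (shape, cell size and origin must match)")
}

#' Cell-centre coordinates of grid cells
#'
#' @param g a `grid_raster`.
#' @param rows,cols 1-based row/column indices (row 1 = northernmost).
#' @return A two-column matrix of x, y coordinates in metres.
#' @export
cell_centers <- function(g, rows, cols) {
  cbind(x = g$xll + (cols - 0.5) * g$cell_size,
        y = g$yll + (nrow(g$values) - rows + 0.5) * g$cell_size)
}

#' Read an ESRI ASCII grid
#'
#' Parses the six-line `ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value`
#' header (header keys case-insensitive, `xllcenter`/`yllcenter` accepted and
#' converted to corner coordinates) followed by `nrows` rows of `ncols` values,
#' northernmost row first.
#'
#' @param path file path.
#' @return A `grid_raster`.
#' @export
read_esri_ascii <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- list()
  i <- 0
  while (i < length(lines)) {
    parts <- strsplit(trimws(lines[i + 1]), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[a-zA-Z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- suppressWarnings(as.numeric(parts[2]))
      i <- i + 1
    } else break
  }
  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss))
    stop("malformed ESRI ASCII header: missing field(s) ", paste(miss, collapse = ", "))
  for (f in names(hdr)) if (is.na(hdr[[f]]))
    stop("malformed ESRI ASCII header: field '", f, "' is not numeric")
  ncols <- hdr$ncols; nrows <- hdr$nrows
  cell <- hdr$cellsize
  if (is.null(cell) || cell <= 0) stop("malformed ESRI ASCII header: cellsize must be > 0")
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner
         else if (!is.null(hdr$xllcenter)) hdr$xllcenter - cell / 2 else 0
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner
         else if (!is.null(hdr$yllcenter)) hdr$yllcenter - cell / 2 else 0
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines[-seq_len(i)]), "\\s+"))))
  if (anyNA(vals)) stop("malformed ESRI ASCII body: non-numeric cell value")
  if (length(vals) != nrows * ncols)
    stop(sprintf("malformed ESRI ASCII body: expected %d values (ncols x nrows), found %d",
                 nrows * ncols, length(vals)))
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  grid_raster(m, cell, xll, yll, nodata)
}

#' Write an ESRI ASCII grid
#'
#' Canonical formatting: lower-case header keys, values space-separated with
#' `format(..., scientific = FALSE)`, northernmost row first. Reading a file
#' written by this function reproduces it byte-identically.
#'
#' @param g a `grid_raster`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_esri_ascii <- function(g, path) {
  stopifnot(inherits(g, "grid_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(g$values)),
    sprintf("nrows %d", nrow(g$values)),
    sprintf("xllcorner %s", format(g$xll, scientific = FALSE)),
    sprintf("yllcorner %s", format(g$yll, scientific = FALSE)),
    sprintf("cellsize %s", format(g$cell_size, scientific = FALSE)),
    sprintf("NODATA_value %s", format(g$nodata, scientific = FALSE))
  ), con)
  body <- apply(g$values, 1, function(r)
    paste(format(r, scientific = FALSE, trim = TRUE), collapse = " "))
  writeLines(body, con)
  invisible(path)
}
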