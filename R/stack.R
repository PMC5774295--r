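## ClimateStack construction, accessors and point extraction.

#' Build a climate stack from aligned grids
#'
#' Member grids must share shape and georeferencing to within 1e-6 cell
#' widths. The stack's nodata mask is the union of member masks and is
#' applied to every member, so a cell missing in any variable is missing
#' everywhere.
#'
#' @param grids named list of [GridLayer-class] objects.
#' @param period period label, e.g. "present".
#' @return a [ClimateStack-class].
#' @export
buildStack <- function(grids, period) {
  if (length(grids) < 1) stop("at least one grid is required")
  if (is.null(names(grids)) || any(!nzchar(names(grids))))
    stop("grids must be a named list")
  ref <- grids[[1]]
  for (nm in names(grids)) {
    if (!sameGeometry(ref, grids[[nm]]))
      stop("alignment error: grid '", nm,
           "' does not share shape/transform with '", names(grids)[1], "'")
  }
  mask <- Reduce(`|`, lapply(grids, gridMask))
  grids <- lapply(grids, function(g) {
    v <- g@values; v[mask] <- NA_real_
    initialize(g, values = v, mask = mask)
  })
  new("ClimateStack", period = period, layers = grids)
}

#' Stack accessors
#'
#' @param stack a [ClimateStack-class].
#' @return `periodLabel`: the period label; `variableNames`: member names;
#'   `getLayer`: one member [GridLayer-class]; `stackMask`: the shared
#'   nodata mask; `nCells`: cell count.
#' @export
periodLabel <- function(stack) stack@period

#' @rdname periodLabel
#' @export
variableNames <- function(stack) names(stack@layers)

#' @rdname periodLabel
#' @param name variable name.
#' @export
getLayer <- function(stack, name) {
  if (!name %in% names(stack@layers))
    stop("variable '", name, "' not in stack '", stack@period, "'")
  stack@layers[[name]]
}

#' @rdname periodLabel
#' @export
stackMask <- function(stack) stack@layers[[1]]@mask

#' Cell values of a stack as a matrix
#'
#' @param stack a [ClimateStack-class].
#' @param variables variables to include (default all).
#' @param cells optional linear cell indices (column-major); default all.
#' @return numeric matrix, one row per cell, one column per variable.
#' @export
stackValues <- function(stack, variables = variableNames(stack),
                        cells = NULL) {
  cols <- lapply(variables, function(v) {
    vals <- getLayer(stack, v)@values
    if (is.null(cells)) as.vector(vals) else vals[cells]
  })
  m <- do.call(cbind, cols)
  colnames(m) <- variables
  m
}

#' Map projected points to linear cell indices
#'
#' @param grid a [GridLayer-class] (or other georeferenced map object).
#' @param x,y projected coordinates in metres.
#' @return integer vector of column-major cell indices; `NA` for points
#'   outside the grid extent.
#' @export
cellIndexAt <- function(grid, x, y) {
  d <- gridDim(grid); cs <- grid@cellSize
  col <- floor((x - grid@xll) / cs) + 1
  row <- d[1] - floor((y - grid@yll) / cs)
  ok <- col >= 1 & col <= d[2] & row >= 1 & row <= d[1]
  idx <- ifelse(ok, (col - 1) * d[1] + row, NA_integer_)
  as.integer(idx)
}

#' Extract stack values at point locations
#'
#' @param stack a [ClimateStack-class].
#' @param points data.frame with `x`, `y` columns (metres), or an
#'   [OccurrenceSet-class] / [BackgroundSet-class].
#' @param variables variables to extract (default all).
#' @return numeric matrix, one row per point; rows falling outside the
#'   grid or on masked cells are `NA`.
#' @export
extractValues <- function(stack, points, variables = variableNames(stack)) {
  if (is(points, "OccurrenceSet")) points <- points@points
  if (is(points, "BackgroundSet")) points <- points@points
  idx <- cellIndexAt(stack@layers[[1]], points$x, points$y)
  m <- matrix(NA_real_, length(idx), length(variables),
              dimnames = list(NULL, variables))
  ok <- !is.na(idx)
  if (any(ok)) m[ok, ] <- stackValues(stack, variables, cells = idx[ok])
  m
}

#' Read / write a period stack as one file per variable
#'
#' `readStackDir` loads every `<var>.asc` / `<var>.tif` in a directory into
#' a stack; `writeStackDir` writes one file per variable.
#'
#' @param dir directory holding one grid file per variable.
#' @param period period label.
#' @return a [ClimateStack-class] (`readStackDir`); invisibly `dir`
#'   (`writeStackDir`).
#' @export
readStackDir <- function(dir, period) {
  files <- sort(list.files(dir, pattern = "\\.(asc|txt|tif|tiff)$",
                           full.names = TRUE))
  if (!length(files)) stop("no grid files found in ", dir)
  grids <- lapply(files, readGrid)
  names(grids) <- tools::file_path_sans_ext(basename(files))
  buildStack(grids, period)
}

#' @rdname readStackDir
#' @param stack a [ClimateStack-class].
#' @param format `"ascii_grid"` or `"geotiff"`.
#' @export
writeStackDir <- function(stack, dir, format = "ascii_grid") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "geotiff") ".tif" else ".asc"
  for (nm in variableNames(stack))
    writeGrid(getLayer(stack, nm), file.path(dir, paste0(nm, ext)), format)
  invisible(dir)
}
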