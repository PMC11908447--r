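#' Planar raster grids
#'
#' All raster layers (ground elevation, tidal offset, rise rate, water mask,
#' hazard-zone membership) share one lightweight grid container: a numeric
#' matrix `values[ix, iy]` on a regular planar grid in meters, with `ix`
#' increasing eastward and `iy` increasing northward. Cell (ix, iy) has its
#' center at `origin + (c(ix, iy) - 0.5) * cellsize`. `NA` is nodata.
#'
#' @param values numeric matrix, indexed `[ix, iy]`.
#' @param origin numeric length-2, coordinates of the grid's lower-left corner (m).
#' @param cellsize cell edge length in meters.
#' @return an object of class `cp_grid`.
#' @export
cp_grid <- function(values, origin = c(0, 0), cellsize = 20) {
  if (!is.matrix(values)) abort("`values` must be a matrix")
  stopifnot_scalar_number(cellsize, "cellsize", lo = 1e-9)
  if (length(origin) != 2L || !is.numeric(origin)) {
    abort("`origin` must be a numeric vector of length 2")
  }
  structure(
    list(values = values, origin = as.numeric(origin), cellsize = cellsize,
         nx = nrow(values), ny = ncol(values)),
    class = "cp_grid"
  )
}

#' @export
print.cp_grid <- function(x, ...) {
  cat(sprintf("<cp_grid %d x %d cells, %.6g m cells, origin (%.6g, %.6g)>\n",
              x$nx, x$ny, x$cellsize, x$origin[1], x$origin[2]))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  values in [%.4g, %.4g], %d nodata cells\n",
              rng[1], rng[2], sum(is.na(x$values))))
  invisible(x)
}

# A grid with the same georeferencing but new values.
grid_like <- function(g, values) cp_grid(values, g$origin, g$cellsize)

#' Cell-center coordinates of a grid
#'
#' @param g a `cp_grid`.
#' @return list with vectors `x` (length nx) and `y` (length ny) of
#'   cell-center coordinates in meters.
#' @export
cell_centers <- function(g) {
  list(x = g$origin[1] + (seq_len(g$nx) - 0.5) * g$cellsize,
       y = g$origin[2] + (seq_len(g$ny) - 0.5) * g$cellsize)
}

# Linear cell index (ix + (iy-1)*nx) of points; NA outside the grid.
cell_index <- function(g, x, y) {
  ix <- floor((x - g$origin[1]) / g$cellsize) + 1
  iy <- floor((y - g$origin[2]) / g$cellsize) + 1
  ok <- ix >= 1 & ix <= g$nx & iy >= 1 & iy <= g$ny
  out <- rep(NA_integer_, length(x))
  out[ok] <- as.integer(ix[ok] + (iy[ok] - 1) * g$nx)
  out
}

# Logical matrix of cells whose center lies in [xmin,xmax) x [ymin,ymax).
rect_cell_mask <- function(g, xmin, xmax, ymin, ymax) {
  cc <- cell_centers(g)
  outer(cc$x >= xmin & cc$x < xmax, cc$y >= ymin & cc$y < ymax, `&`)
}

same_georef <- function(a, b) {
  a$nx == b$nx && a$ny == b$ny && a$cellsize == b$cellsize &&
    all(abs(a$origin - b$origin) < 1e-6)
}

check_coregistered <- function(..., what = "grids") {
  gs <- list(...)
  ref <- gs[[1]]
  for (g in gs[-1]) {
    if (!same_georef(ref, g)) {
      abort(sprintf(
        "%s are not co-registered: %dx%d @ %g m vs %dx%d @ %g m",
        what, ref$nx, ref$ny, ref$cellsize, g$nx, g$ny, g$cellsize))
    }
  }
  invisible(TRUE)
}

#' Inverse-distance interpolation of tide-gauge rise rates onto a grid
#'
#' Convenience interpolator producing a sea-level rise-rate surface (mm/yr)
#' from point gauge records; not intended to reproduce any agency product.
#'
#' @param gauges tibble with columns `x`, `y` (m) and `rate_mm_yr`.
#' @param template `cp_grid` defining the output georeferencing.
#' @param power inverse-distance weighting exponent.
#' @return a `cp_grid` of rates in mm/yr.
#' @export
interpolate_rise_rates <- function(gauges, template, power = 2) {
  if (nrow(gauges) == 0L) abort("no gauges supplied")
  cc <- cell_centers(template)
  vals <- matrix(0, template$nx, template$ny)
  wsum <- matrix(0, template$nx, template$ny)
  for (k in seq_len(nrow(gauges))) {
    dx <- outer(cc$x - gauges$x[k], rep(1, template$ny))
    dy <- outer(rep(1, template$nx), cc$y - gauges$y[k])
    d2 <- pmax(dx^2 + dy^2, template$cellsize^2 / 4)
    w <- d2^(-power / 2)
    vals <- vals + w * gauges$rate_mm_yr[k]
    wsum <- wsum + w
  }
  grid_like(template, vals / wsum)
}

#' Read and write grids as ESRI ASCII rasters
#'
#' Plain-text raster exchange format: a six-line header (ncols, nrows,
#' xllcorner, yllcorner, cellsize, NODATA_value) followed by rows of values
#' from the northernmost row down.
#'
#' @param g a `cp_grid`.
#' @param path file path (conventionally `.asc`).
#' @param nodata value written for `NA` cells.
#' @return `read_grid_asc` returns a `cp_grid`; `write_grid_asc` returns
#'   `path` invisibly.
#' @export
write_grid_asc <- function(g, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", g$nx),
    sprintf("nrows %d", g$ny),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2]),
    sprintf("cellsize %.10g", g$cellsize),
    sprintf("NODATA_value %.10g", nodata)
  ), con)
  v <- g$values
  v[is.na(v)] <- nodata
  for (iy in rev(seq_len(g$ny))) {
    writeLines(paste(formatC(v[, iy], format = "g", digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_grid_asc
#' @export
read_grid_asc <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1L)
  val <- as.numeric(vapply(hdr, `[`, "", 2L))
  names(val) <- tolower(key)
  nx <- as.integer(val[["ncols"]]); ny <- as.integer(val[["nrows"]])
  rows <- lapply(lines[7:(6 + ny)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- matrix(NA_real_, nx, ny)
  for (r in seq_len(ny)) m[, ny - r + 1L] <- rows[[r]]
  m[m == val[["nodata_value"]]] <- NA_real_
  cp_grid(m, origin = c(val[["xllcorner"]], val[["yllcorner"]]),
          cellsize = val[["cellsize"]])
}
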