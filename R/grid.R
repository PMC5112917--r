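#' Georeferenced isotope grid
#'
#' An `iso_grid` is a regular, north-up, geographic (WGS84) raster of isotope
#' values in per-mil (permil) units. It is the carrier for isoscapes (mean and
#' SD surfaces), per-bird likelihood surfaces, origin masks and origin-count
#' maps. Values are stored as a numeric matrix whose first row is the
#' northernmost row of cells; georeferencing is the longitude/latitude of the
#' grid's upper-left cell *corner* plus a square cell size in decimal degrees.
#'
#' @param values Numeric matrix of cell values (row 1 = northernmost row).
#'   `NA` entries are treated as nodata.
#' @param origin_lon,origin_lat Longitude and latitude (decimal degrees) of
#'   the upper-left corner of the upper-left cell.
#' @param cell_size Cell size in decimal degrees (square cells).
#' @param nodata Sentinel value used on write; internally nodata is `NA`.
#'
#' @return An object of class `iso_grid`.
#' @examples
#' g <- iso_grid(matrix(-60, 4, 5), origin_lon = -100, origin_lat = 48,
#'               cell_size = 0.5)
#' g
#' @export
iso_grid <- function(values, origin_lon, origin_lat, cell_size,
                     nodata = -9999) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0) {
    stop("`cell_size` must be a single positive number.", call. = FALSE)
  }
  values[!is.na(values) & values == nodata] <- NA_real_
  fin <- values[is.finite(values)]
  if (length(fin) && (any(fin < -500) || any(fin > 500))) {
    stop("Finite cell values must lie in [-500, 500] permil.", call. = FALSE)
  }
  structure(
    list(values = values, origin_lon = origin_lon, origin_lat = origin_lat,
         cell_size = cell_size, nodata = nodata, crs = "geographic WGS84"),
    class = "iso_grid"
  )
}

#' @export
print.iso_grid <- function(x, ...) {
  v <- x$values
  cat("<iso_grid> ", nrow(v), " x ", ncol(v), " cells @ ", x$cell_size,
      " deg (", x$crs, ")\n", sep = "")
  cat("  extent: lon [", x$origin_lon, ", ",
      x$origin_lon + ncol(v) * x$cell_size, "], lat [",
      x$origin_lat - nrow(v) * x$cell_size, ", ", x$origin_lat, "]\n",
      sep = "")
  fin <- v[is.finite(v)]
  if (length(fin)) {
    cat("  values: [", round(min(fin), 2), ", ", round(max(fin), 2),
        "] permil; ", sum(!is.finite(v)), " nodata cells\n", sep = "")
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

#' @export
dim.iso_grid <- function(x) dim(x$values)

# Cell-centre latitudes, north to south (one per row).
grid_lats <- function(grid) {
  n <- nrow(grid$values)
  grid$origin_lat - (seq_len(n) - 0.5) * grid$cell_size
}

# Cell-centre longitudes, west to east (one per column).
grid_lons <- function(grid) {
  n <- ncol(grid$values)
  grid$origin_lon + (seq_len(n) - 0.5) * grid$cell_size
}

#' Create an empty grid template over an extent
#'
#' @param extent Numeric vector `c(lat_min, lat_max, lon_min, lon_max)`.
#' @param cell_size Cell size in decimal degrees.
#' @return An `iso_grid` of `NA` cells covering the extent.
#' @export
grid_template <- function(extent, cell_size) {
  stopifnot(length(extent) == 4)
  lat_min <- extent[1]; lat_max <- extent[2]
  lon_min <- extent[3]; lon_max <- extent[4]
  if (lat_max <= lat_min || lon_max <= lon_min) {
    stop("Degenerate extent: need lat_max > lat_min and lon_max > lon_min.",
         call. = FALSE)
  }
  nr <- max(1L, ceiling((lat_max - lat_min) / cell_size))
  nc <- max(1L, ceiling((lon_max - lon_min) / cell_size))
  iso_grid(matrix(NA_real_, nr, nc), origin_lon = lon_min,
           origin_lat = lat_max, cell_size = cell_size)
}

#' Convert a grid to a tibble of cell centres
#'
#' @param x An `iso_grid`.
#' @param ... Unused.
#' @return A tibble with columns `lon`, `lat`, `value` (one row per cell).
#' @export
as_tibble.iso_grid <- function(x, ...) {
  lats <- grid_lats(x)
  lons <- grid_lons(x)
  tibble::tibble(
    lon = rep(lons, each = nrow(x$values)),
    lat = rep(lats, times = ncol(x$values)),
    value = as.vector(x$values)
  )
}

# Row/column of the cell containing each point; NA where outside the extent.
cell_index <- function(grid, lat, lon) {
  nr <- nrow(grid$values); nc <- ncol(grid$values)
  col <- floor((lon - grid$origin_lon) / grid$cell_size) + 1
  row <- floor((grid$origin_lat - lat) / grid$cell_size) + 1
  # points exactly on the south/east edge belong to the last cell
  col[lon == grid$origin_lon + nc * grid$cell_size] <- nc
  row[lat == grid$origin_lat - nr * grid$cell_size] <- nr
  outside <- row < 1 | row > nr | col < 1 | col > nc | !is.finite(lat) |
    !is.finite(lon)
  row[outside] <- NA_integer_
  col[outside] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Extract grid values at point locations
#'
#' Reads the value of the cell containing each point (nearest-cell rule, the
#' reproducible GIS default for reading rasters at collection sites).
#' Bilinear interpolation between the four surrounding cell centres is
#' available behind `method = "bilinear"`.
#'
#' @param grid An `iso_grid`.
#' @param points A data frame with columns `lat` and `lon` (decimal degrees).
#' @param method `"nearest"` (default) or `"bilinear"`.
#' @return A tibble with `lat`, `lon`, `value` and `flag` (`"ok"`,
#'   `"nodata"`, or `"outside"`); row order matches `points`.
#' @export
extract_at_points <- function(grid, points, method = c("nearest", "bilinear")) {
  method <- match.arg(method)
  stopifnot(is.data.frame(points), all(c("lat", "lon") %in% names(points)))
  lat <- points$lat; lon <- points$lon
  idx <- cell_index(grid, lat, lon)
  val <- rep(NA_real_, length(lat))
  inside <- !is.na(idx$row)
  if (method == "nearest") {
    val[inside] <- grid$values[cbind(idx$row[inside], idx$col[inside])]
  } else {
    val[inside] <- bilinear_at(grid, lat[inside], lon[inside])
  }
  flag <- dplyr::case_when(
    !inside ~ "outside",
    is.na(val) ~ "nodata",
    TRUE ~ "ok"
  )
  tibble::tibble(lat = lat, lon = lon, value = val, flag = flag)
}

bilinear_at <- function(grid, lat, lon) {
  lats <- grid_lats(grid); lons <- grid_lons(grid)
  nr <- length(lats); nc <- length(lons)
  # fractional position in cell-centre coordinates
  fx <- (lon - lons[1]) / grid$cell_size
  fy <- (lats[1] - lat) / grid$cell_size
  x0 <- pmin(pmax(floor(fx), 0), nc - 1); x1 <- pmin(x0 + 1, nc - 1)
  y0 <- pmin(pmax(floor(fy), 0), nr - 1); y1 <- pmin(y0 + 1, nr - 1)
  wx <- pmin(pmax(fx - x0, 0), 1); wy <- pmin(pmax(fy - y0, 0), 1)
  v00 <- grid$values[cbind(y0 + 1, x0 + 1)]
  v01 <- grid$values[cbind(y0 + 1, x1 + 1)]
  v10 <- grid$values[cbind(y1 + 1, x0 + 1)]
  v11 <- grid$values[cbind(y1 + 1, x1 + 1)]
  (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
}

#' Read a gridded isoscape from disk
#'
#' Supports the plain-text ESRI ASCII grid format (`.asc`), the portable
#' interchange format for single-band rasters. The `yllcorner`/`xllcorner`
#' lower-left-corner registration of the format is converted to this
#' package's upper-left-corner origin on read.
#'
#' @param path Path to the file.
#' @param format Raster format; only `"esri_ascii"` is supported.
#' @return An `iso_grid`.
#' @export
read_grid <- function(path, format = c("esri_ascii", "geotiff")) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported by this package; ",
         "use the ESRI ASCII grid format (plain text).", call. = FALSE)
  }
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) == 2) hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr))) {
    stop("Malformed ESRI ASCII header; need ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  n_hdr <- 5L + !is.null(hdr$nodata_value)
  vals <- scan(path, skip = n_hdr, quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc) {
    stop("Expected ", nr * nc, " cell values, found ", length(vals),
         call. = FALSE)
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  iso_grid(m, origin_lon = hdr$xllcorner,
           origin_lat = hdr$yllcorner + nr * hdr$cellsize,
           cell_size = hdr$cellsize, nodata = nodata)
}

#' Write a gridded isoscape to disk
#'
#' @param grid An `iso_grid`.
#' @param path Output path.
#' @param format Raster format; only `"esri_ascii"` is supported.
#' @param digits Significant digits written per cell (default preserves
#'   round-trip fidelity well below 1e-6 permil).
#' @return Invisibly, `path`.
#' @export
write_grid <- function(grid, path, format = c("esri_ascii", "geotiff"),
                       digits = 12) {
  format <- match.arg(format)
  if (format == "geotiff") {
    stop("GeoTIFF I/O is not supported by this package; ",
         "use the ESRI ASCII grid format (plain text).", call. = FALSE)
  }
  v <- grid$values
  nr <- nrow(v); nc <- ncol(v)
  hdr <- c(
    paste("ncols", nc),
    paste("nrows", nr),
    paste("xllcorner", format(grid$origin_lon, digits = 15)),
    paste("yllcorner", format(grid$origin_lat - nr * grid$cell_size,
                              digits = 15)),
    paste("cellsize", format(grid$cell_size, digits = 15)),
    paste("NODATA_value", format(grid$nodata, digits = 15))
  )
  out <- v
  out[!is.finite(out)] <- grid$nodata
  body <- apply(out, 1L, function(r) {
    paste(formatC(r, digits = digits, format = "g"), collapse = " ")
  })
  writeLines(c(hdr, body), path)
  invisible(path)
}

# TRUE when two grids share shape and georeferencing (to a small tolerance).
grids_aligned <- function(a, b, tol = 1e-9) {
  identical(dim(a$values), dim(b$values)) &&
    abs(a$origin_lon - b$origin_lon) < tol &&
    abs(a$origin_lat - b$origin_lat) < tol &&
    abs(a$cell_size - b$cell_size) < tol
}

stop_if_misaligned <- function(a, b, what = "grids") {
  if (!grids_aligned(a, b)) {
    stop("Misaligned ", what, ": shapes and georeferencing must match.",
         call. = FALSE)
  }
  invisible(TRUE)
}
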