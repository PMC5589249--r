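#' Define a raster grid specification
#'
#' A `grid_spec` describes the common analysis grid: a regular geographic
#' (longitude/latitude) lattice identified by its north-west corner, cell
#' size and dimensions. Row 1 is the northernmost row; cell centers sit at
#' `origin + (i - 0.5) * cell_size`. The default cell size of 2.5 arc-minutes
#' (1/24 degree, about 4.5 km at the equator) matches the resolution of the
#' bioclimatic layers the assessment is designed around.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Cell edge length in decimal degrees.
#' @param origin_lon,origin_lat Longitude/latitude of the north-west corner
#'   of the grid (degrees, WGS84).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size = 2.5 / 60,
                      origin_lon = -6, origin_lat = 16) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size = cell_size, origin_lon = origin_lon,
         origin_lat = origin_lat, crs = "EPSG:4326"),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.5f deg, NW corner (%.4f, %.4f)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

same_spec <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("n_rows", "n_cols", "cell_size",
                                "origin_lon", "origin_lat")],
                   unclass(b)[c("n_rows", "n_cols", "cell_size",
                                "origin_lon", "origin_lat")]))
}

#' Longitudes of cell centers (by column) and latitudes (by row)
#' @param spec A `grid_spec`.
#' @return Numeric vector of center coordinates.
#' @export
cell_center_lon <- function(spec) {
  spec$origin_lon + (seq_len(spec$n_cols) - 0.5) * spec$cell_size
}

#' @rdname cell_center_lon
#' @export
cell_center_lat <- function(spec) {
  spec$origin_lat - (seq_len(spec$n_rows) - 0.5) * spec$cell_size
}

#' Construct a raster layer on a grid
#'
#' A `grid_layer` couples a value matrix with a validity mask on a common
#' `grid_spec`. Values must be finite wherever the mask is `TRUE`; masked-out
#' cells are ignored by all downstream arithmetic and summaries.
#'
#' @param spec A `grid_spec`.
#' @param values Numeric matrix `n_rows x n_cols` (row 1 = north).
#' @param mask Logical matrix of the same shape; `TRUE` marks cells inside
#'   the study area. Defaults to all `TRUE`.
#' @return An object of class `grid_layer`.
#' @export
grid_layer <- function(spec, values, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  values <- as.matrix(values)
  if (!all(dim(values) == c(spec$n_rows, spec$n_cols)))
    stop("values shape does not match grid_spec")
  if (is.null(mask)) mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!all(dim(mask) == dim(values))) stop("mask shape does not match values")
  mask[is.na(mask)] <- FALSE
  if (any(!is.finite(values[mask])))
    stop("non-finite values inside the mask")
  structure(list(spec = spec, values = values, mask = mask),
            class = "grid_layer")
}

#' @export
print.grid_layer <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("grid_layer: %d x %d, %d masked-in cells, range [%.4g, %.4g]\n",
              x$spec$n_rows, x$spec$n_cols, sum(x$mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Construct an ordinal threat-class layer
#'
#' Codes are `0` = No threat, `1` = Low, `2` = Medium, `3` = High,
#' `4` = Very high.
#'
#' @param spec A `grid_spec`.
#' @param classes Integer matrix of codes in `0:4`.
#' @param mask Logical matrix; defaults to all `TRUE`.
#' @return An object of class `class_layer`.
#' @export
class_layer <- function(spec, classes, mask = NULL) {
  stopifnot(inherits(spec, "grid_spec"))
  classes <- as.matrix(classes)
  storage.mode(classes) <- "integer"
  if (!all(dim(classes) == c(spec$n_rows, spec$n_cols)))
    stop("classes shape does not match grid_spec")
  if (is.null(mask)) mask <- matrix(TRUE, spec$n_rows, spec$n_cols)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  if (any(is.na(classes[mask])) || any(classes[mask] < 0L | classes[mask] > 4L))
    stop("class codes must be in 0..4 on the mask")
  structure(list(spec = spec, classes = classes, mask = mask),
            class = "class_layer")
}

#' Threat-magnitude class labels, in code order 0..4
#' @export
threat_levels <- function() {
  c("No threat", "Low", "Medium", "High", "Very high")
}

#' @export
print.class_layer <- function(x, ...) {
  tab <- table(factor(x$classes[x$mask], levels = 0:4,
                      labels = threat_levels()))
  cat(sprintf("class_layer: %d x %d, %d masked-in cells\n",
              x$spec$n_rows, x$spec$n_cols, sum(x$mask)))
  print(tab)
  invisible(x)
}

#' Bilinear resampling onto a target grid
#'
#' Each target cell center takes the bilinear interpolation of the four
#' surrounding source cell centers. Target cells whose center falls outside
#' the source cell-center hull (where interpolation would become
#' extrapolation) are masked out, as are cells touching masked-out source
#' cells.
#'
#' @param source A `grid_layer`.
#' @param target A `grid_spec`.
#' @return A `grid_layer` on `target`.
#' @export
resample_bilinear <- function(source, target) {
  stopifnot(inherits(source, "grid_layer"), inherits(target, "grid_spec"))
  if (same_spec(source$spec, target)) return(source)
  src <- source$spec
  # extent overlap check (outer cell edges)
  s_w <- src$origin_lon; s_e <- s_w + src$n_cols * src$cell_size
  s_n <- src$origin_lat; s_s <- s_n - src$n_rows * src$cell_size
  t_w <- target$origin_lon; t_e <- t_w + target$n_cols * target$cell_size
  t_n <- target$origin_lat; t_s <- t_n - target$n_rows * target$cell_size
  if (t_w >= s_e || t_e <= s_w || t_s >= s_n || t_n <= s_s)
    stop("source and target grids do not overlap")

  tx <- cell_center_lon(target)   # length n_cols
  ty <- cell_center_lat(target)   # length n_rows, decreasing
  # fractional source index of each target center (1-based, cell centers)
  fx <- (tx - s_w) / src$cell_size + 0.5
  fy <- (s_n - ty) / src$cell_size + 0.5

  out <- matrix(NA_real_, target$n_rows, target$n_cols)
  ok  <- matrix(FALSE, target$n_rows, target$n_cols)

  j0 <- floor(fx); wx <- fx - j0
  i0 <- floor(fy); wy <- fy - i0
  valid_x <- j0 >= 1 & j0 + 1 <= src$n_cols
  valid_y <- i0 >= 1 & i0 + 1 <= src$n_rows

  V <- source$values; M <- source$mask
  for (i in which(valid_y)) {
    ii <- i0[i]
    for (j in which(valid_x)) {
      jj <- j0[j]
      if (M[ii, jj] && M[ii, jj + 1] && M[ii + 1, jj] && M[ii + 1, jj + 1]) {
        top <- V[ii, jj] * (1 - wx[j]) + V[ii, jj + 1] * wx[j]
        bot <- V[ii + 1, jj] * (1 - wx[j]) + V[ii + 1, jj + 1] * wx[j]
        out[i, j] <- top * (1 - wy[i]) + bot * wy[i]
        ok[i, j] <- TRUE
      }
    }
  }
  out[!ok] <- 0
  grid_layer(target, out, ok)
}

#' Min-max normalization of a layer over its mask
#'
#' Rescales masked-in values to `[0, 1]` as `(v - min) / (max - min)`. A
#' constant layer maps to all zeros (with a warning) so degenerate inputs
#' flow through the pipeline rather than erroring.
#'
#' @param layer A `grid_layer` with at least one masked-in cell.
#' @return A `grid_layer` with masked values in `[0, 1]`.
#' @export
normalize_minmax <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  v <- layer$values[layer$mask]
  if (length(v) == 0) stop("normalize_minmax: empty mask")
  lo <- min(v); hi <- max(v)
  out <- layer$values
  if (hi == lo) {
    warning("constant layer: normalized to all zeros")
    out[layer$mask] <- 0
  } else {
    out[layer$mask] <- (layer$values[layer$mask] - lo) / (hi - lo)
  }
  out[!layer$mask] <- 0
  grid_layer(layer$spec, out, layer$mask)
}

#' Element-wise square-root transform
#'
#' Used to deflate the heavy right skew of grazing-pressure and fire
#' frequency layers before normalization.
#'
#' @param layer A `grid_layer` with non-negative masked values.
#' @return A `grid_layer`.
#' @export
sqrt_transform <- function(layer) {
  stopifnot(inherits(layer, "grid_layer"))
  if (any(layer$values[layer$mask] < 0))
    stop("sqrt_transform: negative values")
  out <- layer$values
  out[layer$mask] <- sqrt(layer$values[layer$mask])
  grid_layer(layer$spec, out, layer$mask)
}

#' Point-in-cell index of lon/lat points on a grid
#'
#' Cell membership is half-open: `[west, east)` in longitude and
#' `(south, north]` in latitude, so a point on a shared edge belongs to
#' exactly one cell.
#'
#' @return Data frame with columns `row`, `col`, `inside`.
#' @keywords internal
point_cell_index <- function(lon, lat, spec) {
  col <- floor((lon - spec$origin_lon) / spec$cell_size) + 1
  row <- floor((spec$origin_lat - lat) / spec$cell_size) + 1
  # grid-top latitude belongs to row 1 under (south, north]
  row[lat == spec$origin_lat] <- 1
  inside <- col >= 1 & col <= spec$n_cols & row >= 1 & row <= spec$n_rows
  data.frame(row = as.integer(row), col = as.integer(col), inside = inside)
}

#' Rasterize points to per-cell weight sums
#'
#' Sums per-point weights (default 1) into the cell containing each point.
#' Points outside the grid are dropped with a message reporting the count.
#'
#' @param lon,lat Point coordinates (decimal degrees).
#' @param target A `grid_spec`.
#' @param weights Optional per-point weights; default 1.
#' @return A `grid_layer` of weight sums (0 where no points fell).
#' @export
rasterize_points <- function(lon, lat, target, weights = NULL) {
  stopifnot(inherits(target, "grid_spec"), length(lon) == length(lat))
  if (is.null(weights)) weights <- rep(1, length(lon))
  stopifnot(length(weights) == length(lon))
  idx <- point_cell_index(lon, lat, target)
  n_out <- sum(!idx$inside)
  if (n_out > 0)
    message(sprintf("rasterize_points: dropped %d point(s) outside the grid",
                    n_out))
  out <- matrix(0, target$n_rows, target$n_cols)
  keep <- which(idx$inside)
  for (k in keep) out[idx$row[k], idx$col[k]] <- out[idx$row[k], idx$col[k]] +
      weights[k]
  grid_layer(target, out)
}

#' Area of one grid cell in square kilometres
#'
#' In `"geodesic"` mode the east-west side shrinks with the cosine of
#' latitude: `(cell * 111.32 * cos(lat)) * (cell * 111.32)` km^2. In
#' `"nominal"` mode the cell side is taken as 4.5 km exactly, giving the
#' conventional 20.25 km^2 pixel used for site-level threats at 2.5
#' arc-minute resolution.
#'
#' @param spec A `grid_spec`.
#' @param latitude Latitude of the cell center in degrees (|lat| < 90).
#' @param mode `"geodesic"` or `"nominal"`.
#' @return Cell area in km^2.
#' @export
pixel_area_km2 <- function(spec, latitude = 0,
                           mode = c("geodesic", "nominal")) {
  mode <- match.arg(mode)
  if (mode == "nominal") return(4.5^2)
  stopifnot(abs(latitude) < 90)
  km_per_deg <- 111.32
  (spec$cell_size * km_per_deg * cos(latitude * pi / 180)) *
    (spec$cell_size * km_per_deg)
}

# ---- ESRI ASCII grid I/O -------------------------------------------------
# Plain-text raster exchange; masked-out cells are written as the nodata
# value. Class layers round-trip through the same format with integer codes.

#' Write a layer as an ESRI ASCII grid
#'
#' @param layer A `grid_layer` or `class_layer`.
#' @param path Output file path (.asc).
#' @param nodata Nodata marker written for masked-out cells.
#' @export
write_asc <- function(layer, path, nodata = -9999) {
  spec <- layer$spec
  vals <- if (inherits(layer, "class_layer")) layer$classes else layer$values
  vals[!layer$mask] <- nodata
  hdr <- c(
    sprintf("ncols %d", spec$n_cols),
    sprintf("nrows %d", spec$n_rows),
    sprintf("xllcorner %.10g", spec$origin_lon),
    sprintf("yllcorner %.10g", spec$origin_lat - spec$n_rows * spec$cell_size),
    sprintf("cellsize %.10g", spec$cell_size),
    sprintf("NODATA_value %g", nodata))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(format(vals, trim = TRUE, digits = 10, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Input file path.
#' @param as_class If `TRUE` return a `class_layer` (integer codes).
#' @return A `grid_layer` or `class_layer`; nodata cells are masked out.
#' @export
read_asc <- function(path, as_class = FALSE) {
  hdr_lines <- readLines(path, n = 6)
  kv <- strsplit(trimws(hdr_lines), "\\s+")
  hdr <- stats::setNames(as.numeric(vapply(kv, `[`, "", 2)),
                         tolower(vapply(kv, `[`, "", 1)))
  n_rows <- as.integer(hdr[["nrows"]]); n_cols <- as.integer(hdr[["ncols"]])
  spec <- grid_spec(n_rows, n_cols, cell_size = hdr[["cellsize"]],
                    origin_lon = hdr[["xllcorner"]],
                    origin_lat = hdr[["yllcorner"]] +
                      n_rows * hdr[["cellsize"]])
  vals <- matrix(scan(path, skip = 6, quiet = TRUE),
                 n_rows, n_cols, byrow = TRUE)
  mask <- vals != hdr[["nodata_value"]]
  vals[!mask] <- if (as_class) 0 else 0
  if (as_class) class_layer(spec, vals, mask) else grid_layer(spec, vals, mask)
}
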