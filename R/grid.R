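#' Raster grid container
#'
#' A `grid` is the unit of all raster math in fvcdyn: a 2-D numeric field with
#' an implicit nodata mask (cells stored as `NA`), a square cell size, and the
#' coordinates of the upper-left corner. Rows are stored top-down (row 1 is the
#' northernmost row), columns left-right, 0-based pixel indexing is never
#' exposed: all R-side indexing is the usual 1-based `[row, col]`.
#'
#' @param values numeric matrix; `NA` entries are nodata.
#' @param cell_size positive cell edge length (map units per cell).
#' @param origin numeric length-2, (x, y) of the upper-left corner.
#' @param band_label optional text label for the band.
#' @return an object of class `fvc_grid`.
#' @examples
#' g <- grid(matrix(runif(12), 3, 4), cell_size = 1000)
#' dim(grid_values(g))
#' @export
grid <- function(values, cell_size = 1, origin = c(0, 0), band_label = "") {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  stopifnot(is.matrix(values), is.numeric(cell_size), length(cell_size) == 1)
  if (!is.numeric(values) && !is.logical(values))
    stop("grid values must be numeric")
  if (cell_size <= 0) stop("cell_size must be > 0")
  if (length(origin) != 2) stop("origin must be (x, y)")
  storage.mode(values) <- "double"
  structure(
    list(values = values, cell_size = as.numeric(cell_size),
         origin = as.numeric(origin), band_label = as.character(band_label)),
    class = "fvc_grid")
}

#' @rdname grid
#' @param g a `fvc_grid`.
#' @export
grid_values <- function(g) g$values

#' @rdname grid
#' @export
grid_mask <- function(g) is.na(g$values)

#' @export
print.fvc_grid <- function(x, ...) {
  v <- x$values
  cat(sprintf("<fvc_grid %dx%d, cell %g, origin (%g, %g)%s>\n",
              nrow(v), ncol(v), x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$band_label)) paste0(" '", x$band_label, "'") else ""))
  cat(sprintf("  valid %d/%d, range [%s, %s]\n", sum(!is.na(v)), length(v),
              format(suppressWarnings(min(v, na.rm = TRUE))),
              format(suppressWarnings(max(v, na.rm = TRUE)))))
  invisible(x)
}

#' @export
dim.fvc_grid <- function(x) dim(x$values)

# Internal: error unless a and b share shape and geometry.
check_aligned <- function(a, b, what = "grids") {
  if (!identical(dim(a$values), dim(b$values)))
    stop(sprintf("%s are not co-registered: shapes %s vs %s", what,
                 paste(dim(a$values), collapse = "x"),
                 paste(dim(b$values), collapse = "x")))
  if (!isTRUE(all.equal(a$cell_size, b$cell_size)) ||
      !isTRUE(all.equal(a$origin, b$origin)))
    stop(sprintf("%s are not co-registered: geometry differs", what))
  invisible(TRUE)
}

# Internal: new grid with same geometry, different values.
grid_like <- function(g, values, band_label = g$band_label) {
  grid(values, cell_size = g$cell_size, origin = g$origin,
       band_label = band_label)
}

#' Time-ordered raster stack
#'
#' A `stack` holds co-registered annual grids as a rows x cols x years array
#' with strictly increasing integer year labels. It is the input to every
#' per-pixel time-series statistic (Theil-Sen, Mann-Kendall, Hurst, CV,
#' partial correlation).
#'
#' @param grids a list of co-registered `fvc_grid`s, or a 3-D array
#'   (rows x cols x years).
#' @param years integer vector of year labels, strictly increasing, one per
#'   layer.
#' @param cell_size,origin geometry, used when `grids` is an array.
#' @return an object of class `fvc_stack`.
#' @export
stack_grids <- function(grids, years, cell_size = 1, origin = c(0, 0)) {
  years <- as.integer(years)
  if (any(diff(years) <= 0)) stop("years must be strictly increasing")
  if (is.array(grids) && length(dim(grids)) == 3) {
    arr <- grids
  } else {
    stopifnot(is.list(grids), length(grids) >= 1)
    g1 <- grids[[1]]
    for (g in grids) check_aligned(g1, g, "stack layers")
    cell_size <- g1$cell_size
    origin <- g1$origin
    arr <- array(NA_real_, c(dim(g1$values), length(grids)))
    for (i in seq_along(grids)) arr[, , i] <- grids[[i]]$values
  }
  if (dim(arr)[3] != length(years))
    stop("number of layers must equal number of years")
  structure(list(values = arr, years = years,
                 cell_size = as.numeric(cell_size),
                 origin = as.numeric(origin)),
            class = "fvc_stack")
}

#' @rdname stack_grids
#' @param s a `fvc_stack`.
#' @param year a year label present in `s$years`.
#' @export
stack_layer <- function(s, year) {
  i <- match(as.integer(year), s$years)
  if (is.na(i)) stop("year not in stack: ", year)
  grid(s$values[, , i, drop = TRUE], s$cell_size, s$origin,
       band_label = as.character(year))
}

#' @rdname stack_grids
#' @export
stack_years <- function(s) s$years

#' @export
print.fvc_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<fvc_stack %dx%d, %d years %d-%d, cell %g>\n",
              d[1], d[2], d[3], min(x$years), max(x$years), x$cell_size))
  invisible(x)
}

#' Read and write ESRI ASCII grid rasters
#'
#' Plain-text single-band raster I/O. The ASCII grid header stores columns,
#' rows, lower-left corner, cell size and the nodata sentinel; fvcdyn converts
#' the lower-left corner to/from its internal upper-left origin. Round trips
#' preserve values, mask and geometry to full double precision.
#'
#' @param path file path.
#' @param nodata sentinel written for masked cells (default -9999). If a data
#'   value collides with the sentinel, `write_asc` stops.
#' @return `read_asc` returns a `fvc_grid`; `write_asc` returns `path`
#'   invisibly.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop("no such raster file: ", path)
  lines <- readLines(path, n = 6L)
  hdr <- list()
  nhdr <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                   "nodata_value")) {
      hdr[[key]] <- as.numeric(parts[2])
      nhdr <- nhdr + 1L
    } else break
  }
  for (k in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(hdr[[k]])) stop("malformed ASCII grid header in ", path)
  nodata <- if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value
  vals <- scan(path, what = double(), skip = nhdr, quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc)
    stop(sprintf("expected %d values, got %d in %s", nr * nc, length(vals),
                 path))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA_real_
  origin <- c(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize)
  grid(m, cell_size = hdr$cellsize, origin = origin)
}

#' @rdname read_asc
#' @param g a `fvc_grid`.
#' @export
write_asc <- function(g, path, nodata = -9999) {
  stopifnot(inherits(g, "fvc_grid"))
  v <- g$values
  if (any(v == nodata, na.rm = TRUE))
    stop("grid contains the nodata sentinel ", nodata,
         " as a data value; choose another sentinel")
  nr <- nrow(v); nc <- ncol(v)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", nc),
    sprintf("nrows %d", nr),
    sprintf("xllcorner %.10g", g$origin[1]),
    sprintf("yllcorner %.10g", g$origin[2] - nr * g$cell_size),
    sprintf("cellsize %.10g", g$cell_size),
    sprintf("NODATA_value %g", nodata)), con)
  v[is.na(v)] <- nodata
  for (i in seq_len(nr))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' QA bitmask filtering
#'
#' Masks cells of a value grid whose quality-assurance word fails a keep rule,
#' emulating cloud/snow/shadow removal with a detailed-QA bitfield. The rule is
#' user-supplied because retained bit combinations are product- and
#' study-specific.
#'
#' @param value a `fvc_grid` of data values.
#' @param qa a co-registered `fvc_grid` of integer QA words.
#' @param keep_rule function taking a vector of QA words, returning a logical
#'   vector: `TRUE` = keep the cell.
#' @return a `fvc_grid`: kept cells unchanged, others nodata.
#' @examples
#' v <- grid(matrix(1:9, 3))
#' q <- grid(matrix(c(0, 1, 2, 0, 1, 2, 0, 1, 2), 3))
#' qa_filter(v, q, function(w) bitwAnd(as.integer(w), 3L) == 0L)
#' @export
qa_filter <- function(value, qa, keep_rule) {
  check_aligned(value, qa, "value/qa grids")
  stopifnot(is.function(keep_rule))
  w <- qa$values
  keep <- rep(FALSE, length(w))
  ok <- !is.na(w)
  keep[ok] <- as.logical(keep_rule(w[ok]))
  out <- value$values
  out[!keep] <- NA_real_
  grid_like(value, matrix(out, nrow(out), ncol(out)))
}

#' Seasonal compositing
#'
#' Reduces a set of co-registered per-date grids (e.g. all June-August
#' composites of one year) to a single seasonal grid, per cell over the
#' unmasked observations. A cell is nodata only where no date has a valid
#' value.
#'
#' @param per_date_grids non-empty list of co-registered `fvc_grid`s.
#' @param reducer one of `"mean"`, `"max"`, `"median"`.
#' @return a `fvc_grid`.
#' @export
compose_season <- function(per_date_grids, reducer = c("mean", "max", "median")) {
  reducer <- match.arg(reducer)
  if (!is.list(per_date_grids) || length(per_date_grids) == 0)
    stop("per_date_grids must be a non-empty list of grids")
  g1 <- per_date_grids[[1]]
  for (g in per_date_grids) check_aligned(g1, g, "composite inputs")
  arr <- vapply(per_date_grids, function(g) g$values,
                matrix(0, nrow(g1$values), ncol(g1$values)))
  dim(arr) <- c(dim(g1$values), length(per_date_grids))
  f <- switch(reducer, mean = mean, max = max, median = stats::median)
  out <- apply(arr, c(1, 2), function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else f(x)
  })
  grid_like(g1, out)
}

#' Grading schemes
#'
#' A `grade_scheme` maps continuous values to ordered classes via strictly
#' increasing breakpoints. All intervals are lower-inclusive, upper-exclusive
#' (`[a, b)`); the bottom class is open below and the top class closed above.
#' `classify()` applies a scheme to a grid, returning an integer-coded
#' categorical grid carrying the labels as an attribute.
#'
#' @param breaks strictly increasing numeric thresholds (length k).
#' @param labels class names (length k + 1), ordered low to high.
#' @return `grade_scheme` returns a `grade_scheme` object.
#' @examples
#' classify(grid(matrix(c(0.05, 0.3, 0.65, 0.9), 2)), fvc_grades())
#' @export
grade_scheme <- function(breaks, labels) {
  breaks <- as.numeric(breaks)
  if (any(diff(breaks) <= 0)) stop("breaks must be strictly increasing")
  if (length(labels) != length(breaks) + 1)
    stop("need exactly length(breaks) + 1 labels")
  structure(list(breaks = breaks, labels = as.character(labels)),
            class = "grade_scheme")
}

#' @rdname grade_scheme
#' @param grid a `fvc_grid` of continuous values.
#' @param scheme a `grade_scheme`.
#' @export
classify <- function(grid, scheme) {
  stopifnot(inherits(grid, "fvc_grid"), inherits(scheme, "grade_scheme"))
  v <- grid$values
  if (any(is.nan(v)))
    stop("NaN among unmasked values; mask them explicitly before classifying")
  idx <- findInterval(v, scheme$breaks) + 1L
  out <- matrix(as.numeric(idx), nrow(v), ncol(v))
  out[is.na(v)] <- NA_real_
  g <- grid_like(grid, out, band_label = "class")
  attr(g, "labels") <- scheme$labels
  g
}

#' @rdname grade_scheme
#' @export
class_labels <- function(grid) attr(grid, "labels")

#' Five-level vegetation-cover grading
#'
#' The standard FVC grading used throughout the package, on the unit scale:
#' lowest (<0.10), low (0.10-0.30), medium (0.30-0.50), high (0.50-0.70),
#' highest (>0.70).
#'
#' @return a `grade_scheme`.
#' @export
fvc_grades <- function() {
  grade_scheme(c(0.10, 0.30, 0.50, 0.70),
               c("Lowest", "Low", "Medium", "High", "Highest"))
}

#' Five-level stability grading by coefficient of variation
#'
#' CV breaks 0.15 / 0.25 / 0.35 / 0.5 separating extremely insignificant,
#' insignificant, moderate, significant and extremely significant variation.
#'
#' @return a `grade_scheme`.
#' @export
cv_grades <- function() {
  grade_scheme(c(0.15, 0.25, 0.35, 0.5),
               c("Extremely insignificant", "Insignificant", "Moderate",
                 "Significant", "Extremely significant"))
}
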