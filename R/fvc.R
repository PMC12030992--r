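#' Dimidiate-pixel endmembers
#'
#' Fits the bare-soil and full-vegetation NDVI endmembers of the dimidiate
#' pixel model as low/high percentiles of the scene's unmasked NDVI values
#' (defaults: 5th and 95th). Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param ndvi a `fvc_grid` of NDVI values.
#' @param p_low,p_high percentiles in `[0, 100]`, `p_low < p_high`.
#' @return list with `ndvi_soil`, `ndvi_veg`, `p_low`, `p_high`, class
#'   `fvc_endmembers`.
#' @export
estimate_endmembers <- function(ndvi, p_low = 5, p_high = 95) {
  stopifnot(inherits(ndvi, "fvc_grid"))
  if (!(p_low >= 0 && p_low < p_high && p_high <= 100))
    stop("need 0 <= p_low < p_high <= 100")
  x <- ndvi$values[!is.na(ndvi$values)]
  if (length(unique(x)) < 2)
    stop("degenerate endmembers: fewer than 2 distinct unmasked NDVI values")
  qs <- stats::quantile(x, c(p_low, p_high) / 100, names = FALSE, type = 7)
  if (qs[1] >= qs[2])
    stop("degenerate endmembers: soil and vegetation percentiles coincide")
  structure(list(ndvi_soil = qs[1], ndvi_veg = qs[2],
                 p_low = p_low, p_high = p_high),
            class = "fvc_endmembers")
}

#' FVC inversion by the dimidiate pixel model
#'
#' Per cell, FVC = (NDVI - NDVI_soil) / (NDVI_veg - NDVI_soil), clamped to
#' `[0, 1]`: values below the soil endmember are bare ground, above the
#' vegetation endmember full cover. The mask propagates unchanged.
#'
#' @param ndvi a `fvc_grid` of NDVI.
#' @param em endmembers from [estimate_endmembers()] (or a list with
#'   `ndvi_soil` and `ndvi_veg`).
#' @return a `fvc_grid` of FVC in `[0, 1]`.
#' @export
invert_fvc <- function(ndvi, em) {
  stopifnot(inherits(ndvi, "fvc_grid"))
  soil <- em$ndvi_soil; veg <- em$ndvi_veg
  if (!(is.finite(soil) && is.finite(veg) && soil < veg))
    stop("invalid endmembers: need ndvi_soil < ndvi_veg")
  f <- (ndvi$values - soil) / (veg - soil)
  f <- pmin(pmax(f, 0), 1)
  grid_like(ndvi, matrix(f, nrow(ndvi$values), ncol(ndvi$values)),
            band_label = "FVC")
}

#' Class-area fractions of a categorical grid
#'
#' Fraction of the unmasked area in each class; fractions sum to 1.
#'
#' @param categorical a categorical `fvc_grid` as produced by [classify()].
#' @param labels class labels; defaults to the labels attached by
#'   [classify()].
#' @return data.frame with columns `class` and `fraction`.
#' @export
area_fractions <- function(categorical, labels = class_labels(categorical)) {
  v <- categorical$values[!is.na(categorical$values)]
  if (length(v) == 0) stop("empty domain: no unmasked cells")
  if (is.null(labels)) labels <- as.character(seq_len(max(v)))
  counts <- tabulate(as.integer(v), nbins = length(labels))
  data.frame(class = labels, fraction = counts / length(v),
             stringsAsFactors = FALSE)
}

#' FVC inversion of an NDVI stack
#'
#' Applies [estimate_endmembers()] + [invert_fvc()] across an annual NDVI
#' stack. Endmembers are fitted per year by default (each annual composite
#' gets its own 5th/95th percentiles); set `per_year = FALSE` to pool all
#' years into one endmember pair for sensitivity analysis.
#'
#' @param ndvi_stack a `fvc_stack` of annual NDVI composites.
#' @param per_year logical; fit endmembers per year (default) or pooled.
#' @param p_low,p_high endmember percentiles.
#' @return a `fvc_stack` of FVC with an `endmembers` attribute (one pair per
#'   year, or one pooled pair).
#' @export
fvc_stack <- function(ndvi_stack, per_year = TRUE, p_low = 5, p_high = 95) {
  stopifnot(inherits(ndvi_stack, "fvc_stack"))
  yrs <- ndvi_stack$years
  out <- array(NA_real_, dim(ndvi_stack$values))
  ems <- list()
  if (!per_year) {
    x <- ndvi_stack$values[!is.na(ndvi_stack$values)]
    if (length(unique(x)) < 2) stop("degenerate endmembers: constant stack")
    qs <- stats::quantile(x, c(p_low, p_high) / 100, names = FALSE)
    if (qs[1] >= qs[2]) stop("degenerate endmembers: percentiles coincide")
    pooled <- structure(list(ndvi_soil = qs[1], ndvi_veg = qs[2],
                             p_low = p_low, p_high = p_high),
                        class = "fvc_endmembers")
  }
  for (i in seq_along(yrs)) {
    g <- stack_layer(ndvi_stack, yrs[i])
    em <- if (per_year) estimate_endmembers(g, p_low, p_high) else pooled
    out[, , i] <- invert_fvc(g, em)$values
    ems[[as.character(yrs[i])]] <- em
  }
  s <- stack_grids(out, yrs, ndvi_stack$cell_size, ndvi_stack$origin)
  attr(s, "endmembers") <- if (per_year) ems else pooled
  s
}

#' Combined class-share change from a printed area-fraction table
#'
#' Accounting over a per-year class-share table (one row per cover or
#' stability grade, one percentage column per year or period): the summed
#' share of a set of grades in a given column, and the summed change of a set
#' of grades. If the table carries a `change` column it is used directly
#' (such columns are typically computed from unrounded shares); otherwise
#' change = last period minus first period.
#'
#' @param tab data.frame; first column the grade name, remaining numeric
#'   columns per-year (or per-period) percentages, optionally a column named
#'   `change` (case-insensitive).
#' @param classes character vector of grade names to combine.
#' @param period optional column name; when given, returns the summed share of
#'   `classes` in that column instead of the change.
#' @return a single number (percentage points).
#' @examples
#' tab <- data.frame(grade = c("a", "b"), y2000 = c(60, 40), y2024 = c(55, 45))
#' combined_share_change(tab, "b")            # +5
#' combined_share_change(tab, "b", "y2000")   # 40
#' @export
combined_share_change <- function(tab, classes, period = NULL) {
  stopifnot(is.data.frame(tab), ncol(tab) >= 3 || !is.null(period))
  rows <- tab[[1]] %in% classes
  if (sum(rows) != length(classes))
    stop("classes not all present in table: ",
         paste(setdiff(classes, tab[[1]]), collapse = ", "))
  if (!is.null(period)) {
    if (!period %in% names(tab)) stop("no such column: ", period)
    return(sum(tab[rows, period]))
  }
  chg <- which(tolower(names(tab)) == "change")
  if (length(chg) == 1) return(sum(tab[rows, chg[1]]))
  num <- which(vapply(tab, is.numeric, logical(1)))
  sum(tab[rows, num[length(num)]]) - sum(tab[rows, num[1]])
}
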