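#' Coefficient of variation of a series
#'
#' Sample standard deviation (n-1 denominator) divided by the mean. Undefined
#' (returned as `NA`) when the mean is zero or negative, or with fewer than
#' two valid points.
#'
#' @param x numeric series; `NA`s dropped.
#' @return the CV, or `NA`.
#' @examples
#' cv_series(c(1, 3))  # ~0.707
#' @export
cv_series <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (m <= 0) return(NA_real_)
  stats::sd(x) / m
}

#' Stability analysis of a stack by coefficient of variation
#'
#' Per-pixel CV of the annual values within each period, graded into the five
#' stability classes of [cv_grades()]. Pixels with a nonpositive temporal
#' mean or fewer than 2 valid years in a period are masked.
#'
#' @param s a `fvc_stack`.
#' @param periods list of `c(start, end)` year pairs; default one period
#'   spanning the whole stack.
#' @return list of one result per period, each with `cv` and `cv_class`
#'   grids and the `period`.
#' @export
cv_stack <- function(s, periods = NULL) {
  stopifnot(inherits(s, "fvc_stack"))
  if (is.null(periods)) periods <- list(range(s$years))
  d <- dim(s$values)
  lapply(periods, function(p) {
    stopifnot(length(p) == 2)
    sel <- s$years >= p[1] & s$years <= p[2]
    if (sum(sel) < 2)
      stop(sprintf("period %d-%d covers fewer than 2 stack years", p[1], p[2]))
    flat <- matrix(s$values[, , sel, drop = FALSE], d[1] * d[2], sum(sel))
    cv <- apply(flat, 1, cv_series)
    cvg <- grid(matrix(cv, d[1], d[2]), s$cell_size, s$origin, "CV")
    list(cv = cvg, cv_class = classify(cvg, cv_grades()),
         period = as.integer(p))
  })
}

#' Per-zone class-area fractions
#'
#' Cross-tabulates a categorical grid against a zone-label grid: for each
#' zone, the fraction of its unmasked cells in each class (rows sum to 1).
#' Zones with no jointly valid cells are flagged empty.
#'
#' @param categorical a categorical `fvc_grid` (e.g. from [classify()]).
#' @param zones a co-registered `fvc_grid` of integer zone labels.
#' @param labels class labels; defaults to those attached to `categorical`.
#' @return data.frame: `zone`, one column per class, `n` (cell count),
#'   `empty` flag.
#' @export
zonal_fractions <- function(categorical, zones,
                            labels = class_labels(categorical)) {
  check_aligned(categorical, zones, "class/zone grids")
  cv <- categorical$values; zv <- zones$values
  if (is.null(labels)) labels <- as.character(seq_len(max(cv, na.rm = TRUE)))
  zl <- sort(unique(zv[!is.na(zv)]))
  out <- do.call(rbind, lapply(zl, function(z) {
    sel <- !is.na(zv) & zv == z & !is.na(cv)
    n <- sum(sel)
    fr <- if (n > 0) tabulate(as.integer(cv[sel]), length(labels)) / n
          else rep(NA_real_, length(labels))
    d <- as.data.frame(as.list(stats::setNames(fr, labels)),
                       check.names = FALSE)
    cbind(data.frame(zone = z), d, data.frame(n = n, empty = n == 0))
  }))
  rownames(out) <- NULL
  out
}

#' Pearson correlation with validity checks
#'
#' Sample correlation coefficient over pairwise-complete observations,
#' requiring at least 3 pairs and nonzero variance in both variables
#' (returns `NA` otherwise).
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation, or `NA`.
#' @export
pearson <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' First-order partial correlation
#'
#' Pearson correlation of x and y with the linear effect of a control z
#' removed: r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#' Significance by the two-sided t test, t = r sqrt((n-3)/(1-r^2)) on n-3
#' degrees of freedom.
#'
#' @param x,y,z numeric vectors; rows with any `NA` are dropped pairwise.
#' @return list with `r` (partial correlation), `t`, `p`, `n`.
#' @examples
#' set.seed(1); z <- rnorm(50)
#' partial_corr(z + rnorm(50), z + rnorm(50), z)$r
#' @export
partial_corr <- function(x, y, z) {
  ok <- stats::complete.cases(x, y, z)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete observations")
  rxy <- suppressWarnings(stats::cor(x, y))
  rxz <- suppressWarnings(stats::cor(x, z))
  ryz <- suppressWarnings(stats::cor(y, z))
  if (anyNA(c(rxy, rxz, ryz)))
    stop("zero variance in one of the inputs")
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("degenerate control: |cor with z| = 1")
  r <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
  r <- max(-1, min(1, r))
  tt <- if (abs(r) < 1) r * sqrt((n - 3) / (1 - r^2)) else sign(r) * Inf
  list(r = r, t = tt, p = 2 * stats::pt(-abs(tt), df = n - 3), n = n)
}

#' Pixelwise partial correlation of vegetation with two climate drivers
#'
#' For each pixel, the partial correlation of the FVC series with temperature
#' controlling precipitation, and with precipitation controlling temperature,
#' over the common years of three co-registered stacks. Pixels use
#' pairwise-complete years; those with fewer than `min_years` complete years,
#' or with a constant series among the three, are masked.
#'
#' @param fvc,temp,precip co-registered `fvc_stack`s over identical years.
#' @param alpha significance level for the masks (default 0.05).
#' @param min_years minimum complete years per pixel (default 10).
#' @return list of two results (`temp`, `precip`), each with grids `r`, `t`,
#'   `p` and logical significance matrix `sig` (p < alpha).
#' @export
partial_corr_maps <- function(fvc, temp, precip, alpha = 0.05,
                              min_years = 10) {
  stopifnot(inherits(fvc, "fvc_stack"), inherits(temp, "fvc_stack"),
            inherits(precip, "fvc_stack"))
  if (!identical(fvc$years, temp$years) ||
      !identical(fvc$years, precip$years))
    stop("stacks must cover identical years")
  if (!identical(dim(fvc$values), dim(temp$values)) ||
      !identical(dim(fvc$values), dim(precip$values)))
    stop("stacks are not co-registered")
  d <- dim(fvc$values)
  np <- d[1] * d[2]
  f <- matrix(fvc$values, np, d[3])
  tm <- matrix(temp$values, np, d[3])
  pr <- matrix(precip$values, np, d[3])
  one <- function(yv, zv) {
    res <- matrix(NA_real_, np, 3)
    for (i in seq_len(np)) {
      ok <- stats::complete.cases(f[i, ], yv[i, ], zv[i, ])
      if (sum(ok) < max(4, min_years)) next
      pc <- tryCatch(partial_corr(f[i, ok], yv[i, ok], zv[i, ok]),
                     error = function(e) NULL)
      if (!is.null(pc)) res[i, ] <- c(pc$r, pc$t, pc$p)
    }
    g <- function(j, lab) grid(matrix(res[, j], d[1], d[2]),
                               fvc$cell_size, fvc$origin, lab)
    list(r = g(1, "partial r"), t = g(2, "t"), p = g(3, "p"),
         sig = matrix(res[, 3] < alpha, d[1], d[2]))
  }
  list(temp = one(tm, pr), precip = one(pr, tm))
}
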