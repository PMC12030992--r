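#' Aggregate a pixel grid to square analysis units
#'
#' Blocks the grid into square units of `unit_size` map units on a side
#' (e.g. 15 km units over 1 km pixels) and takes the mean of unmasked pixels
#' per unit. Partial units at the right/bottom edge are kept. Units whose
#' fraction of valid pixels falls below `min_valid` are masked.
#'
#' @param g a `fvc_grid`.
#' @param unit_size unit edge length in the grid's map units; must be at
#'   least `cell_size`.
#' @param min_valid minimum valid-pixel fraction per unit (default 0.5).
#' @return a `fvc_grid` of unit means (cell size = `unit_size`) with a
#'   `valid_fraction` matrix attribute.
#' @export
aggregate_units <- function(g, unit_size, min_valid = 0.5) {
  stopifnot(inherits(g, "fvc_grid"))
  k <- unit_size / g$cell_size
  if (k < 1) stop("unit_size must be at least one pixel")
  k <- as.integer(round(k))
  v <- g$values
  ri <- (seq_len(nrow(v)) - 1L) %/% k + 1L
  ci <- (seq_len(ncol(v)) - 1L) %/% k + 1L
  nr <- max(ri); nc <- max(ci)
  idx <- (rep(ci, each = nrow(v)) - 1L) * nr + rep(ri, ncol(v))
  npix <- tabulate(idx, nr * nc)
  ok <- !is.na(v)
  nval <- tabulate(idx[ok], nr * nc)
  sums <- rep(0, nr * nc)
  tp <- tapply(v[ok], idx[ok], sum)
  sums[as.integer(names(tp))] <- tp
  means <- ifelse(nval > 0, sums / nval, NA_real_)
  vf <- nval / npix
  means[vf < min_valid] <- NA_real_
  out <- grid(matrix(means, nr, nc), cell_size = g$cell_size * k,
              origin = g$origin, band_label = "unit mean")
  attr(out, "valid_fraction") <- matrix(vf, nr, nc)
  out
}

# Internal: sparse contiguity neighbour list for a regular lattice restricted
# to valid units. Returns list(i, j, w) of row-standardized weights.
lattice_weights <- function(valid, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  nr <- nrow(valid); nc <- ncol(valid)
  steps <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (contiguity == "queen")
    steps <- rbind(steps, c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  id <- matrix(NA_integer_, nr, nc)
  id[valid] <- seq_len(sum(valid))
  ii <- integer(); jj <- integer()
  pos <- which(valid, arr.ind = TRUE)
  for (s in seq_len(nrow(steps))) {
    r2 <- pos[, 1] + steps[s, 1]; c2 <- pos[, 2] + steps[s, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    ok[ok] <- valid[cbind(r2[ok], c2[ok])]
    ii <- c(ii, id[pos[ok, , drop = FALSE]])
    jj <- c(jj, id[cbind(r2[ok], c2[ok])])
  }
  deg <- tabulate(ii, sum(valid))
  list(i = ii, j = jj, w = 1 / deg[ii], n = sum(valid), deg = deg)
}

#' Global Moran's I of a unit lattice
#'
#' Spatial autocorrelation of unit means under binary contiguity weights
#' (queen by default), row-standardized. Expectation E(I) = -1/(N-1);
#' variance under the randomization assumption; Z = (I - E(I)) / sd(I).
#' Isolated units (no valid neighbour) are dropped.
#'
#' @param lattice a `fvc_grid` of unit values, e.g. from
#'   [aggregate_units()].
#' @param contiguity `"queen"` (default) or `"rook"`.
#' @return list with `i` (Moran's I), `e_i`, `var_i`, `z`, `n_units`.
#' @export
morans_i <- function(lattice, contiguity = c("queen", "rook")) {
  contiguity <- match.arg(contiguity)
  v <- lattice$values
  valid <- !is.na(v)
  W0 <- lattice_weights(valid, contiguity)
  # drop isolates, rebuilding weights on the connected subset
  if (any(W0$deg == 0)) {
    keep <- matrix(FALSE, nrow(v), ncol(v))
    keep[valid][W0$deg > 0] <- TRUE
    valid <- keep
    W0 <- lattice_weights(valid, contiguity)
  }
  n <- W0$n
  if (n < 9) stop("need at least 9 valid units for Moran's I")
  x <- v[valid]
  z <- x - mean(x)
  s2 <- sum(z^2)
  if (s2 == 0) stop("constant lattice: Moran's I undefined")
  W <- sum(W0$w)
  num <- sum(W0$w * z[W0$i] * z[W0$j])
  I <- (n / W) * (num / s2)
  # randomization moments (row-standardized weights)
  key1 <- paste(W0$i, W0$j); key2 <- paste(W0$j, W0$i)
  wrev <- W0$w[match(key1, key2)]  # w_ji matched to each stored w_ij
  wrev[is.na(wrev)] <- 0
  S1 <- 0.5 * sum((W0$w + wrev)^2)
  ro_out <- rep(0, n); ro_in <- rep(0, n)
  for (e in seq_along(W0$i)) {
    ro_out[W0$i[e]] <- ro_out[W0$i[e]] + W0$w[e]
    ro_in[W0$j[e]] <- ro_in[W0$j[e]] + W0$w[e]
  }
  S2 <- sum((ro_out + ro_in)^2)
  b2 <- n * sum(z^4) / (sum(z^2))^2
  EI <- -1 / (n - 1)
  varI <- (n * ((n^2 - 3 * n + 3) * S1 - n * S2 + 3 * W^2) -
             b2 * ((n^2 - n) * S1 - 2 * n * S2 + 6 * W^2)) /
    ((n - 1) * (n - 2) * (n - 3) * W^2) - EI^2
  list(i = I, e_i = EI, var_i = varI, z = (I - EI) / sqrt(varI), n_units = n)
}

#' Coefficient of variation over the valid units of a lattice
#'
#' Identical to [cv_series()] applied to the flattened valid unit values.
#'
#' @param lattice a `fvc_grid` of unit values.
#' @return the unit CV, or `NA`.
#' @export
unit_cv <- function(lattice) cv_series(as.vector(lattice$values))

#' Multi-scale spatial-structure scan
#'
#' Aggregates a pixel grid to each candidate unit size, computing global
#' Moran's I (with Z) and the unit CV per scale. A recommended scale is the
#' one maximizing the sum of within-scan ranks of I and CV among scales whose
#' Z exceeds `z_min`; ties go to the smaller unit. If no scale is significant
#' the table is returned with no recommendation.
#'
#' @param g a `fvc_grid`.
#' @param scales numeric unit sizes (map units), at least 2 unless a single
#'   scale is being checked.
#' @param min_valid,contiguity passed to [aggregate_units()] / [morans_i()].
#' @param z_min significance gate for the recommendation (default 1.96).
#' @return list with `table` (data.frame: scale, moran_i, e_i, var_i, z,
#'   unit_cv, n_units) and `recommended` (a scale, or `NA`).
#' @export
scale_scan <- function(g, scales, min_valid = 0.5, contiguity = "queen",
                       z_min = 1.96) {
  stopifnot(length(scales) >= 1)
  rows <- lapply(scales, function(sc) {
    lat <- aggregate_units(g, sc, min_valid = min_valid)
    m <- morans_i(lat, contiguity)
    data.frame(scale = sc, moran_i = m$i, e_i = m$e_i, var_i = m$var_i,
               z = m$z, unit_cv = unit_cv(lat), n_units = m$n_units)
  })
  tab <- do.call(rbind, rows)
  sig <- tab$z > z_min
  recommended <- NA_real_
  if (any(sig)) {
    score <- rank(tab$moran_i) + rank(tab$unit_cv)
    score[!sig] <- -Inf
    best <- which(score == max(score))
    recommended <- min(tab$scale[best])
  }
  list(table = tab, recommended = recommended)
}
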