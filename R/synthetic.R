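#' Fractional Gaussian noise by circulant embedding
#'
#' Exact simulation of stationary fractional Gaussian noise with Hurst
#' parameter `h` via Davies-Harte circulant embedding of the fGn
#' autocovariance gamma(k) = ((k+1)^{2H} - 2 k^{2H} + |k-1|^{2H}) / 2.
#' h = 0.5 gives white noise. Deterministic under a fixed seed.
#'
#' @param n series length.
#' @param h Hurst parameter in (0, 1).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`, unit marginal variance.
#' @examples
#' gen_fgn(256, 0.8, seed = 1)[1:5]
#' @export
gen_fgn <- function(n, h, seed = NULL) {
  if (!(h > 0 && h < 1)) stop("h must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  if (abs(h - 0.5) < 1e-12) return(stats::rnorm(n))
  k <- 0:n
  gam <- 0.5 * (abs(k + 1)^(2 * h) - 2 * abs(k)^(2 * h) + abs(k - 1)^(2 * h))
  row <- c(gam, rev(gam[2:n]))              # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  lam[lam < 0 & lam > -1e-9] <- 0
  if (any(lam < 0))
    stop("circulant embedding not nonnegative definite for h = ", h)
  m <- 2L * n
  V <- complex(m)
  V[1] <- sqrt(lam[1]) * stats::rnorm(1)
  V[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  k <- 2:n
  u <- stats::rnorm(n - 1); w <- stats::rnorm(n - 1)
  V[k] <- sqrt(lam[k] / 2) * complex(real = u, imaginary = w)
  V[m + 2 - k] <- Conj(V[k])
  x <- Re(stats::fft(V)) / sqrt(m)
  x[seq_len(n)]
}

#' Synthetic annual FVC stack with known trend and persistence
#'
#' Per pixel, series = baseline + slope * (year - first year) + noise_sd *
#' fGn(h), clipped to `[0, 1]`. Defaults mirror an arid-region frame: 25
#' annual layers (2000-2024) around a baseline mean of 0.226. The planted
#' slope field and h are returned as ground truth. If clipping touches more
#' than 1% of values a warning asks for a tamer configuration.
#'
#' @param shape `c(rows, cols)`.
#' @param years integer years (default 2000:2024).
#' @param baseline scalar or matrix of per-pixel intercepts (default 0.226).
#' @param slope_field scalar or matrix of trends in FVC/yr (default 0).
#' @param noise_sd interannual noise SD (default 0.02).
#' @param h Hurst parameter of the noise (default 0.5).
#' @param seed integer seed.
#' @param cell_size,origin geometry of the produced stack.
#' @return list with `stack` (a `fvc_stack`) and `truth` (list: slope_field
#'   matrix, h, baseline matrix).
#' @export
gen_fvc_stack <- function(shape = c(20, 20), years = 2000:2024,
                          baseline = 0.226, slope_field = 0,
                          noise_sd = 0.02, h = 0.5, seed = 1,
                          cell_size = 1, origin = c(0, 0)) {
  stopifnot(noise_sd >= 0)
  set.seed(seed)
  nr <- shape[1]; nc <- shape[2]; ny <- length(years)
  bl <- if (is.matrix(baseline)) baseline else matrix(baseline, nr, nc)
  sl <- if (is.matrix(slope_field)) slope_field else matrix(slope_field, nr, nc)
  arr <- array(NA_real_, c(nr, nc, ny))
  t0 <- years - years[1]
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    eps <- if (noise_sd > 0) noise_sd * gen_fgn(ny, h) else rep(0, ny)
    arr[i, j, ] <- bl[i, j] + sl[i, j] * t0 + eps
  }
  clipped <- mean(arr < 0 | arr > 1)
  if (clipped > 0.01)
    warning(sprintf("%.1f%% of generated values clipped to [0,1]; consider a tamer configuration",
                    100 * clipped))
  arr <- pmin(pmax(arr, 0), 1)
  list(stack = stack_grids(arr, years, cell_size, origin),
       truth = list(slope_field = sl, h = h, baseline = bl))
}

#' Synthetic NDVI scene from a known cover field
#'
#' NDVI = soil + cover * (veg - soil) + Gaussian noise, the generative
#' inverse of the dimidiate pixel model, so [invert_fvc()] with the true
#' endmembers recovers `cover_field` exactly at zero noise.
#'
#' @param cover_field matrix of true FVC in `[0, 1]`.
#' @param soil,veg endmember NDVI values, `soil < veg`.
#' @param noise_sd additive NDVI noise SD (default 0).
#' @param seed integer seed.
#' @param cell_size,origin geometry.
#' @return list with `ndvi` (a `fvc_grid`) and `truth` (the cover matrix and
#'   endmembers).
#' @export
gen_ndvi_scene <- function(cover_field, soil = 0.05, veg = 0.85,
                           noise_sd = 0, seed = 1, cell_size = 1,
                           origin = c(0, 0)) {
  stopifnot(is.matrix(cover_field), soil < veg)
  if (any(cover_field < 0 | cover_field > 1, na.rm = TRUE))
    stop("cover_field must lie in [0, 1]")
  set.seed(seed)
  ndvi <- soil + cover_field * (veg - soil)
  if (noise_sd > 0)
    ndvi <- ndvi + matrix(stats::rnorm(length(ndvi), sd = noise_sd),
                          nrow(ndvi), ncol(ndvi))
  list(ndvi = grid(ndvi, cell_size, origin, "NDVI"),
       truth = list(cover = cover_field, soil = soil, veg = veg))
}

#' Synthetic factor table with analytic q
#'
#' Draws unit responses from a stratified normal design: stratum labels in
#' the given fractions (largest-remainder rounding to exact counts), y ~
#' Normal(stratum mean, within-SD). The analytic explanatory power
#' q* = SSB / (SSB + SSW) follows from the spec moments:
#' SSB = sum f_h (mu_h - mu)^2, SSW = sum f_h sigma_h^2.
#'
#' @param n_units number of units.
#' @param strata_spec data.frame with columns `fraction`, `mean`, `sd`;
#'   fractions must sum to 1.
#' @param seed integer seed.
#' @return list with `table` (data.frame unit_id, y, stratum), `q_true`.
#' @export
gen_factor_table <- function(n_units, strata_spec, seed = 1) {
  stopifnot(is.data.frame(strata_spec),
            all(c("fraction", "mean", "sd") %in% names(strata_spec)))
  f <- strata_spec$fraction
  if (abs(sum(f) - 1) > 1e-9) stop("stratum fractions must sum to 1")
  set.seed(seed)
  raw <- f * n_units
  counts <- floor(raw)
  rem <- n_units - sum(counts)
  if (rem > 0) {
    add <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  lab <- rep(seq_along(f), counts)
  y <- stats::rnorm(n_units, mean = strata_spec$mean[lab],
                    sd = strata_spec$sd[lab])
  mu <- sum(f * strata_spec$mean)
  ssb <- sum(f * (strata_spec$mean - mu)^2)
  ssw <- sum(f * strata_spec$sd^2)
  list(table = data.frame(unit_id = seq_len(n_units), y = y, stratum = lab),
       q_true = ssb / (ssb + ssw))
}

#' Synthetic co-varying FVC / temperature / precipitation stacks
#'
#' Per pixel, an annual trivariate normal series (FVC, temperature,
#' precipitation) drawn from a supplied 3x3 covariance; the true first-order
#' partial correlations are computed from that covariance in closed form and
#' returned as ground truth. Deterministic under a fixed seed.
#'
#' @param shape `c(rows, cols)`.
#' @param years integer years (default 2000:2024).
#' @param cov_mat symmetric positive-definite 3x3 covariance, variable order
#'   (fvc, temp, precip).
#' @param means length-3 means (default c(0.226, 8, 150)).
#' @param seed integer seed.
#' @param cell_size,origin geometry.
#' @return list with stacks `fvc`, `temp`, `precip` and `truth` (partial
#'   correlations `r_fvc_temp.precip`, `r_fvc_precip.temp`).
#' @export
gen_climate_stacks <- function(shape = c(10, 10), years = 2000:2024,
                               cov_mat, means = c(0.226, 8, 150), seed = 1,
                               cell_size = 1, origin = c(0, 0)) {
  stopifnot(is.matrix(cov_mat), all(dim(cov_mat) == 3))
  if (max(abs(cov_mat - t(cov_mat))) > 1e-12)
    stop("covariance must be symmetric")
  ev <- eigen(cov_mat, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("covariance must be positive-definite")
  set.seed(seed)
  R <- chol(cov_mat)
  nr <- shape[1]; nc <- shape[2]; ny <- length(years)
  np <- nr * nc
  arr <- array(NA_real_, c(np, ny, 3))
  for (i in seq_len(np)) {
    zz <- matrix(stats::rnorm(ny * 3), ny, 3) %*% R
    arr[i, , ] <- sweep(zz, 2, means, "+")
  }
  mk <- function(k) stack_grids(array(arr[, , k], c(nr, nc, ny)), years,
                                cell_size, origin)
  cr <- stats::cov2cor(cov_mat)
  pcor <- function(a, b, c.) (cr[a, b] - cr[a, c.] * cr[b, c.]) /
    sqrt((1 - cr[a, c.]^2) * (1 - cr[b, c.]^2))
  list(fvc = mk(1), temp = mk(2), precip = mk(3),
       truth = list(r_fvc_temp.precip = pcor(1, 2, 3),
                    r_fvc_precip.temp = pcor(1, 3, 2)))
}
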