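#' Theil-Sen slope of a time series
#'
#' Median of all pairwise slopes (x_j - x_i) / (t_j - t_i), i < j, using the
#' year labels in the denominator. Robust to outliers; an even number of
#' pairwise slopes takes the mean of the two central values (the usual sample
#' median).
#'
#' @param x numeric series values; `NA`s are dropped together with their
#'   years.
#' @param years numeric time labels, same length as `x`; defaults to
#'   `seq_along(x)`.
#' @return the slope (units of x per year), or `NA` with fewer than 2 valid
#'   points.
#' @examples
#' sen_slope(c(0, 0, 1), 1:3)  # 0.5
#' @export
sen_slope <- function(x, years = seq_along(x)) {
  ok <- !is.na(x)
  x <- x[ok]; t <- years[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  dx <- outer(x, x, "-")
  dt <- outer(t, t, "-")
  stats::median(dx[lower.tri(dx)] / dt[lower.tri(dt)])
}

#' Mann-Kendall trend test
#'
#' Nonparametric monotone-trend test: S is the sum of signs of all forward
#' differences, its variance under the null is n(n-1)(2n+5)/18 (no tie
#' correction by default; set `tie_correction = TRUE` to subtract the usual
#' tie term), and Z applies the three-branch continuity correction
#' (S-1)/sd for S > 0, 0 for S = 0, (S+1)/sd for S < 0.
#'
#' @param x numeric series; `NA`s dropped.
#' @param min_n minimum valid observations (default 4); fewer returns `NA`s.
#' @param tie_correction subtract the tie-group term from var(S)?
#' @return list with `s`, `var_s`, `z`.
#' @examples
#' mk_test(c(1, 2, 3))$s  # 3
#' @export
mk_test <- function(x, min_n = 4, tie_correction = FALSE) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < max(2, min_n))
    return(list(s = NA_real_, var_s = NA_real_, z = NA_real_))
  d <- sign(outer(x, x, "-"))
  s <- sum(d[lower.tri(d)])  # lower.tri entries are sign(x_later - x_earlier)
  v <- n * (n - 1) * (2 * n + 5) / 18
  if (tie_correction) {
    tj <- table(x)
    tj <- tj[tj > 1]
    if (length(tj))
      v <- v - sum(tj * (tj - 1) * (2 * tj + 5)) / 18
  }
  z <- if (s > 0) (s - 1) / sqrt(v) else if (s < 0) (s + 1) / sqrt(v) else 0
  list(s = s, var_s = v, z = z)
}

#' Five-class trend grading from slope and Mann-Kendall Z
#'
#' beta > `beta_thresh` with |Z| > `z_thresh` is a significant increase,
#' with |Z| <= `z_thresh` a slight increase; symmetric for decreases;
#' |beta| <= `beta_thresh` is basically unchanged. Default thresholds:
#' 0.0005 FVC/yr and 2.58 (99% two-sided normal).
#'
#' @param beta a `fvc_grid` of Theil-Sen slopes.
#' @param z a co-registered `fvc_grid` of MK Z scores.
#' @param beta_thresh,z_thresh classification thresholds.
#' @return categorical `fvc_grid` with labels from [trend_labels()].
#' @export
classify_trend <- function(beta, z, beta_thresh = 0.0005, z_thresh = 2.58) {
  check_aligned(beta, z, "beta/z grids")
  b <- beta$values; zz <- abs(z$values)
  out <- matrix(NA_real_, nrow(b), ncol(b))
  ok <- !is.na(b) & !is.na(zz)
  out[ok] <- 3  # Basically unchanged
  out[ok & b >  beta_thresh & zz >  z_thresh] <- 5
  out[ok & b >  beta_thresh & zz <= z_thresh] <- 4
  out[ok & b < -beta_thresh & zz <= z_thresh] <- 2
  out[ok & b < -beta_thresh & zz >  z_thresh] <- 1
  g <- grid_like(beta, out, band_label = "trend class")
  attr(g, "labels") <- trend_labels()
  g
}

#' @rdname classify_trend
#' @export
trend_labels <- function() {
  c("Significant decrease", "Slight decrease", "Basically unchanged",
    "Slight increase", "Significant increase")
}

#' Rescaled-range (R/S) Hurst exponent
#'
#' For each window length m the series is split into floor(n/m) contiguous
#' non-overlapping subseries (tail remainder dropped). Per subseries the
#' cumulative deviation from the subseries mean gives the range R, and the
#' population standard deviation gives S; subseries with S = 0 are dropped.
#' The mean R/S per window is regressed on log(m): H is the OLS slope of
#' log(R/S) on log(m), the intercept is log(c) of the power law R/S = c m^H.
#'
#' By default the series values themselves are treated as the increments; set
#' `differenced = TRUE` to use first differences instead.
#'
#' @param x numeric series; `NA`s dropped (the series must still be
#'   contiguous in time for the cumulative sums to be meaningful).
#' @param windows integer window lengths; default all m in `[3, floor(n/2)]`.
#'   At least 3 distinct usable windows are required.
#' @param min_n minimum series length (default 8).
#' @param differenced analyse first differences instead of values.
#' @return list with `h`, `log_c`, `fit_r2`, `windows`, `rs` (mean R/S per
#'   window), or `NA`s when the series is too short.
#' @examples
#' set.seed(1)
#' hurst_rs(rnorm(64))$h
#' @export
hurst_rs <- function(x, windows = NULL, min_n = 8, differenced = FALSE) {
  x <- x[!is.na(x)]
  if (differenced) x <- diff(x)
  n <- length(x)
  empty <- list(h = NA_real_, log_c = NA_real_, fit_r2 = NA_real_,
                windows = integer(), rs = numeric())
  if (n < max(6, min_n)) return(empty)
  if (is.null(windows)) windows <- 3:max(3, n %/% 2)
  windows <- sort(unique(as.integer(windows)))
  windows <- windows[windows >= 2 & windows <= n]
  rs <- vapply(windows, function(m) {
    k <- n %/% m
    sub <- matrix(x[seq_len(k * m)], nrow = m)
    dev <- sweep(sub, 2, colMeans(sub))
    cum <- apply(dev, 2, cumsum)
    if (k == 1) cum <- matrix(cum, nrow = m)
    r <- apply(cum, 2, function(v) max(v) - min(v))
    s <- sqrt(colMeans(dev^2))
    keep <- s > 0
    if (!any(keep)) return(NA_real_)
    mean(r[keep] / s[keep])
  }, numeric(1))
  keep <- is.finite(rs) & rs > 0
  if (sum(keep) < 3)
    stop("insufficient variation: fewer than 3 usable R/S windows")
  lm_m <- log(windows[keep]); lm_rs <- log(rs[keep])
  fit <- stats::lm.fit(cbind(1, lm_m), lm_rs)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((lm_rs - mean(lm_rs))^2)
  list(h = unname(fit$coefficients[2]), log_c = unname(fit$coefficients[1]),
       fit_r2 = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       windows = windows[keep], rs = rs[keep])
}

#' Future-trend classification from trend class and Hurst exponent
#'
#' Combines the five-class Sen+MK trend grade with persistence: increase
#' classes with H below the threshold map to continued improvement and above
#' it to improvement-to-degradation; decrease classes symmetrically; basically
#' unchanged cells stay basically unchanged, as does H exactly at the
#' threshold. The default mapping is deliberately a plain lookup so the
#' H-direction convention can be swapped via `mapping`.
#'
#' @param trend_class categorical `fvc_grid` from [classify_trend()].
#' @param h a co-registered `fvc_grid` of Hurst exponents.
#' @param h_thresh persistence threshold (default 0.5).
#' @param mapping named character vector keyed `"increase_low"`,
#'   `"increase_high"`, `"decrease_low"`, `"decrease_high"` (low/high =
#'   H below/above threshold) giving future labels.
#' @return categorical `fvc_grid` with labels from [future_labels()].
#' @export
classify_future <- function(trend_class, h, h_thresh = 0.5,
                            mapping = c(increase_low = "Continued improvement",
                                        increase_high = "Improvement to degradation",
                                        decrease_low = "Continued degradation",
                                        decrease_high = "Degradation to improvement")) {
  check_aligned(trend_class, h, "trend/hurst grids")
  labs <- future_labels()
  need <- c("increase_low", "increase_high", "decrease_low", "decrease_high")
  if (!all(need %in% names(mapping)) || !all(mapping[need] %in% labs))
    stop("mapping must assign the four increase/decrease x H cases to known labels")
  tc <- trend_class$values; hv <- h$values
  if (any(!is.na(tc) & !(tc %in% 1:5))) stop("unknown trend class codes")
  code <- stats::setNames(seq_along(labs), labs)
  out <- matrix(NA_real_, nrow(tc), ncol(tc))
  ok <- !is.na(tc) & !is.na(hv)
  out[ok] <- code[["Basically unchanged"]]
  inc <- ok & tc >= 4; dec <- ok & tc <= 2
  out[inc & hv < h_thresh] <- code[[mapping[["increase_low"]]]]
  out[inc & hv > h_thresh] <- code[[mapping[["increase_high"]]]]
  out[dec & hv < h_thresh] <- code[[mapping[["decrease_low"]]]]
  out[dec & hv > h_thresh] <- code[[mapping[["decrease_high"]]]]
  g <- grid_like(trend_class, out, band_label = "future class")
  attr(g, "labels") <- labs
  g
}

#' @rdname classify_future
#' @export
future_labels <- function() {
  c("Continued improvement", "Improvement to degradation",
    "Basically unchanged", "Continued degradation",
    "Degradation to improvement")
}

#' Per-pixel trend analysis of a stack
#'
#' Applies [sen_slope()] and [mk_test()] to every pixel series of a stack and
#' grades the result with [classify_trend()]. Pixels with fewer than `min_n`
#' valid years are masked.
#'
#' @param s a `fvc_stack`.
#' @param beta_thresh,z_thresh grading thresholds, see [classify_trend()].
#' @param min_n minimum valid years per pixel for the MK test (default 4).
#' @return list with grids `beta`, `s_stat`, `var_s`, `z`, `trend_class`.
#' @export
trend_stack <- function(s, beta_thresh = 0.0005, z_thresh = 2.58, min_n = 4) {
  stopifnot(inherits(s, "fvc_stack"))
  d <- dim(s$values)
  flat <- matrix(s$values, d[1] * d[2], d[3])
  beta <- apply(flat, 1, sen_slope, years = s$years)
  mk <- apply(flat, 1, function(v) unlist(mk_test(v, min_n = min_n)))
  g <- function(v, lab) grid(matrix(v, d[1], d[2]), s$cell_size, s$origin, lab)
  bg <- g(beta, "sen slope"); zg <- g(mk["z", ], "MK z")
  list(beta = bg, s_stat = g(mk["s", ], "MK S"),
       var_s = g(mk["var_s", ], "MK var"), z = zg,
       trend_class = classify_trend(bg, zg, beta_thresh, z_thresh))
}

#' Per-pixel Hurst exponent of a stack
#'
#' @param s a `fvc_stack`.
#' @param windows window lengths passed to [hurst_rs()].
#' @param min_n minimum valid years per pixel (default 8).
#' @return list with grids `h`, `log_c`, `fit_r2`.
#' @export
hurst_stack <- function(s, windows = NULL, min_n = 8) {
  stopifnot(inherits(s, "fvc_stack"))
  d <- dim(s$values)
  flat <- matrix(s$values, d[1] * d[2], d[3])
  res <- apply(flat, 1, function(v) {
    out <- tryCatch(hurst_rs(v, windows = windows, min_n = min_n),
                    error = function(e) NULL)
    if (is.null(out)) c(NA_real_, NA_real_, NA_real_)
    else c(out$h, out$log_c, out$fit_r2)
  })
  g <- function(v, lab) grid(matrix(v, d[1], d[2]), s$cell_size, s$origin, lab)
  list(h = g(res[1, ], "hurst"), log_c = g(res[2, ], "log c"),
       fit_r2 = g(res[3, ], "fit r2"))
}
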