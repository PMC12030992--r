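#' Compare two co-registered raster products
#'
#' Agreement metrics between two grids over their jointly valid cells:
#' MAE and RMSE (also converted to similarities as 1 - error / data_range,
#' natural for proportions on `[0, 1]`), R-squared as the squared Pearson
#' correlation, mean local SSIM (11x11 Gaussian window, sigma 1.5, constants
#' C1 = (0.01 L)^2, C2 = (0.03 L)^2 with L = `data_range`), and PSNR =
#' 10 log10(L^2 / MSE) in dB. Values at cells not valid in both grids never
#' influence any metric: SSIM windows renormalize their Gaussian weights over
#' the jointly valid cells.
#'
#' @param a,b co-registered `fvc_grid`s.
#' @param data_range dynamic range L of the data (default 1 for FVC).
#' @return list: `mae`, `rmse`, `mae_similarity`, `rmse_similarity`, `r2`
#'   (`NA` if either input has zero variance), `ssim`, `psnr` (`Inf` when
#'   MSE = 0), `n_valid`.
#' @export
compare_products <- function(a, b, data_range = 1.0) {
  check_aligned(a, b, "products")
  ok <- !is.na(a$values) & !is.na(b$values)
  n <- sum(ok)
  if (n < 9) stop("insufficient overlap: fewer than 9 jointly valid cells")
  x <- a$values[ok]; y <- b$values[ok]
  err <- x - y
  mae <- mean(abs(err)); mse <- mean(err^2); rmse <- sqrt(mse)
  r2 <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
        else stats::cor(x, y)^2
  psnr <- if (mse == 0) Inf else 10 * log10(data_range^2 / mse)
  list(mae = mae, rmse = rmse,
       mae_similarity = 1 - mae / data_range,
       rmse_similarity = 1 - rmse / data_range,
       r2 = r2,
       ssim = ssim(a, b, data_range = data_range),
       psnr = psnr, n_valid = n)
}

#' Structural similarity index of two grids
#'
#' Mean local SSIM with a Gaussian window (default 11x11, sigma 1.5) and the
#' reference constants C1 = (0.01 L)^2, C2 = (0.03 L)^2. Local means,
#' variances and covariance use Gaussian weights renormalized over jointly
#' valid cells, and the final mean is over jointly valid pixels, so masked
#' cells never contribute.
#'
#' @param a,b co-registered `fvc_grid`s.
#' @param data_range dynamic range L.
#' @param window odd window size (default 11).
#' @param sigma Gaussian sigma (default 1.5).
#' @return mean SSIM in `[-1, 1]`.
#' @export
ssim <- function(a, b, data_range = 1.0, window = 11, sigma = 1.5) {
  check_aligned(a, b, "products")
  stopifnot(window %% 2 == 1)
  x <- a$values; y <- b$values
  ok <- !is.na(x) & !is.na(y)
  if (!any(ok)) stop("no jointly valid cells")
  m <- matrix(0, nrow(x), ncol(x)); m[ok] <- 1
  x0 <- x; y0 <- y; x0[!ok] <- 0; y0[!ok] <- 0
  half <- (window - 1) / 2
  g1 <- exp(-((-half:half)^2) / (2 * sigma^2))
  g1 <- g1 / sum(g1)
  conv <- function(z) gauss_blur(z, g1)
  wsum <- conv(m)
  mu_x <- conv(x0) / wsum
  mu_y <- conv(y0) / wsum
  exx <- conv(x0^2) / wsum
  eyy <- conv(y0^2) / wsum
  exy <- conv(x0 * y0) / wsum
  var_x <- pmax(exx - mu_x^2, 0)
  var_y <- pmax(eyy - mu_y^2, 0)
  cov_xy <- exy - mu_x * mu_y
  c1 <- (0.01 * data_range)^2; c2 <- (0.03 * data_range)^2
  s <- ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
  mean(s[ok])
}

# Separable Gaussian convolution with zero padding (the mask-renormalization
# in ssim() cancels the padding).
gauss_blur <- function(z, g1) {
  half <- (length(g1) - 1) / 2
  nr <- nrow(z); nc <- ncol(z)
  pad_conv <- function(mat) {
    # convolve each column with g1
    p <- rbind(matrix(0, half, ncol(mat)), mat, matrix(0, half, ncol(mat)))
    out <- matrix(0, nrow(mat), ncol(mat))
    for (s in seq_along(g1))
      out <- out + g1[s] * p[s:(s + nrow(mat) - 1), , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(z))))
}
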