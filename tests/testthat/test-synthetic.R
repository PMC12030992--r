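test_that("fGn generator is seeded, bounded and matches the fGn autocovariance", {
  expect_equal(gen_fgn(128, 0.7, seed = 3), gen_fgn(128, 0.7, seed = 3))
  expect_error(gen_fgn(64, 1.2), "in \\(0, 1\\)")
  expect_error(gen_fgn(64, 0), "in \\(0, 1\\)")
  # white-noise limit: lag-1 autocorrelation near 0
  x5 <- gen_fgn(4096, 0.5, seed = 11)
  expect_lt(abs(acf(x5, plot = FALSE)$acf[2]), 0.05)
  # persistent case: lag-1 autocorrelation near 2^(2H-1) - 1
  x8 <- gen_fgn(4096, 0.8, seed = 11)
  expect_lt(abs(acf(x8, plot = FALSE)$acf[2] - (2^0.6 - 1)), 0.05)
  expect_lt(abs(var(x8) - 1), 0.2)
})

test_that("FVC stack generator plants exact trends and returns its truth", {
  slopes <- matrix(seq(-0.002, 0.004, length.out = 9), 3)
  sim <- gen_fvc_stack(shape = c(3, 3), slope_field = slopes, noise_sd = 0,
                       baseline = 0.5, seed = 2)
  expect_equal(sim$truth$slope_field, slopes)
  d <- dim(sim$stack$values)
  expect_equal(d, c(3L, 3L, 25L))
  for (i in 1:3) for (j in 1:3)
    expect_equal(sen_slope(sim$stack$values[i, j, ], 2000:2024),
                 slopes[i, j], tolerance = 1e-12)
  # determinism and clipping warning
  s1 <- gen_fvc_stack(shape = c(4, 4), seed = 9)
  s2 <- gen_fvc_stack(shape = c(4, 4), seed = 9)
  expect_equal(s1$stack$values, s2$stack$values)
  expect_warning(gen_fvc_stack(shape = c(4, 4), baseline = 0.99,
                               noise_sd = 0.2, seed = 1), "clipped")
})

test_that("NDVI scene generator inverts exactly and propagates noise as expected", {
  cover <- matrix(runif(900, 0.02, 0.98), 30)
  clean <- gen_ndvi_scene(cover, soil = 0.05, veg = 0.85, noise_sd = 0)
  rec <- invert_fvc(clean$ndvi, list(ndvi_soil = 0.05, ndvi_veg = 0.85))
  expect_equal(rec$values, cover, tolerance = 1e-12)
  # RMSE of recovered cover ~ noise/(veg-soil)
  noisy <- gen_ndvi_scene(cover, soil = 0.05, veg = 0.85, noise_sd = 0.01,
                          seed = 8)
  recn <- invert_fvc(noisy$ndvi, list(ndvi_soil = 0.05, ndvi_veg = 0.85))
  rmse <- sqrt(mean((recn$values - cover)^2))
  expect_lt(rmse, 0.02)
  flat <- gen_ndvi_scene(matrix(0.5, 5, 5), noise_sd = 0)
  expect_error(estimate_endmembers(flat$ndvi), "degenerate")
  expect_error(gen_ndvi_scene(matrix(1.5, 2, 2)), "\\[0, 1\\]")
  expect_error(gen_ndvi_scene(cover, soil = 0.9, veg = 0.1), "soil < veg")
})

test_that("factor-table generator hits its analytic q in the limiting cases", {
  spec0 <- data.frame(fraction = c(0.5, 0.5), mean = c(0, 3), sd = c(0, 0))
  t0 <- gen_factor_table(500, spec0, seed = 1)
  expect_equal(factor_q(t0$table$y, t0$table$stratum), 1)
  expect_equal(t0$q_true, 1)
  # equal means: q is near zero (small positive finite-sample bias)
  spec_null <- data.frame(fraction = c(0.4, 0.6), mean = c(1, 1), sd = c(1, 1))
  qs <- vapply(1:10, function(s) {
    tt <- gen_factor_table(2000, spec_null, seed = s)
    factor_q(tt$table$y, tt$table$stratum)
  }, numeric(1))
  expect_lt(mean(qs), 2 / 2000 * 4)
  expect_equal(gen_factor_table(100, spec_null, seed = 2)$q_true, 0)
  expect_error(gen_factor_table(10, data.frame(fraction = c(0.5, 0.6),
                                               mean = 0:1, sd = 1)),
               "sum to 1")
  # stratum counts follow the fractions exactly
  spec3 <- data.frame(fraction = c(0.2, 0.3, 0.5), mean = 1:3, sd = 0.1)
  t3 <- gen_factor_table(10, spec3, seed = 3)
  expect_equal(as.integer(table(t3$table$stratum)), c(2L, 3L, 5L))
})

test_that("climate-stack generator honours its covariance ground truth", {
  cv <- matrix(c(1, 0.5, 0.2,
                 0.5, 1, 0.1,
                 0.2, 0.1, 1), 3, 3)
  sim <- gen_climate_stacks(shape = c(5, 5), cov_mat = cv, seed = 5)
  sim2 <- gen_climate_stacks(shape = c(5, 5), cov_mat = cv, seed = 5)
  expect_equal(sim$fvc$values, sim2$fvc$values)
  r <- stats::cov2cor(cv)
  expect_equal(sim$truth$r_fvc_temp.precip,
               (r[1, 2] - r[1, 3] * r[2, 3]) /
                 sqrt((1 - r[1, 3]^2) * (1 - r[2, 3]^2)))
  bad <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  expect_error(gen_climate_stacks(cov_mat = bad), "positive-definite")
  # conditional independence plants a zero partial correlation
  ind <- diag(3); ind[1, 3] <- ind[3, 1] <- 0.6; ind[2, 3] <- ind[3, 2] <- 0.0
  simi <- gen_climate_stacks(shape = c(12, 12), cov_mat = ind, seed = 6)
  expect_equal(simi$truth$r_fvc_temp.precip,
               stats::cov2cor(ind)[1, 2] / sqrt(1 - 0.36), tolerance = 1e-12)
  maps <- partial_corr_maps(simi$fvc, simi$temp, simi$precip)
  expect_lt(abs(mean(maps$temp$r$values, na.rm = TRUE)), 0.08)
})
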