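test_that("Theil-Sen slope matches hand cases and the brute-force oracle", {
  expect_equal(sen_slope(c(1, 2, 3, 4), 1:4), 1.0)
  expect_equal(sen_slope(c(0, 0, 1), 1:3), 0.5)  # pairwise slopes 0, .5, 1
  expect_equal(sen_slope(rep(2.2, 6)), 0)
  expect_true(is.na(sen_slope(c(3, NA), 1:2)))
  set.seed(21)
  for (n in c(5, 11, 30)) {
    x <- rnorm(n); yr <- sort(sample(1990:2030, n))
    expect_equal(sen_slope(x, yr), sen_bruteforce(x, yr))
  }
  # irregular year spacing uses the year difference in the denominator
  expect_equal(sen_slope(c(0, 4), c(2000, 2004)), 1)
})

test_that("Mann-Kendall statistic, variance and Z match direct evaluation", {
  r <- mk_test(c(1, 2, 3), min_n = 3)
  expect_equal(r$s, 3)
  expect_equal(r$var_s, 3 * 2 * 11 / 18)
  expect_equal(r$z, 2 / sqrt(11 / 3), tolerance = 1e-10)
  n <- 12
  expect_equal(mk_test(seq_len(n))$s, n * (n - 1) / 2)
  expect_equal(mk_test(rnorm(10) * 0 + 1:10)$var_s, 125)
  flat <- mk_test(rep(5, 8))
  expect_equal(flat$s, 0)
  expect_equal(flat$z, 0)
  expect_true(is.na(mk_test(c(1, 2, 3))$s))  # below default minimum
})

test_that("Sen and MK obey symmetry and invariance properties", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(15)
    expect_equal(mk_test(rev(x))$s, -mk_test(x)$s)
    expect_equal(sen_slope(x + 7), sen_slope(x))
    expect_equal(mk_test(x + 7)$s, mk_test(x)$s)
    expect_equal(sen_slope(3 * x), 3 * sen_slope(x))
  }
})

test_that("trend grading applies the slope and |Z| thresholds", {
  g <- function(b, z) {
    tc <- classify_trend(grid(matrix(b, 1)), grid(matrix(z, 1)))
    trend_labels()[tc$values[1, 1]]
  }
  expect_equal(g(0.001, 3.0), "Significant increase")
  expect_equal(g(0.001, 2.0), "Slight increase")
  expect_equal(g(0.0004, 5.0), "Basically unchanged")
  expect_equal(g(-0.001, -3.0), "Significant decrease")  # |Z| is used
  expect_equal(g(-0.001, 2.0), "Slight decrease")
  expect_equal(g(0.0005, 9.9), "Basically unchanged")    # threshold inclusive
})

test_that("R/S statistic matches the hand-computed subseries value", {
  # windows of 3 over a repeated [1,2,3] block: every subseries has
  # deviations (-1,0,1), cumulative (-1,-1,0), R = 1, S = sqrt(2/3)
  x <- rep(c(1, 2, 3), 5)
  out <- hurst_rs(x, windows = c(2, 3, 5))
  expect_equal(out$rs[out$windows == 3], 1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_error(hurst_rs(rep(1, 40)), "insufficient variation")
  short <- hurst_rs(c(1, 2, 3))
  expect_true(is.na(short$h))
})

test_that("R/S Hurst estimate tracks white-noise persistence", {
  set.seed(5)
  est <- vapply(1:12, function(i) hurst_rs(gen_fgn(512, 0.5, seed = 100 + i),
                                           windows = 2^(4:8))$h, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("future classification follows the trend x persistence lookup", {
  g <- function(code, h) {
    tc <- grid(matrix(code, 1)); attr(tc, "labels") <- trend_labels()
    fc <- classify_future(tc, grid(matrix(h, 1)))
    future_labels()[fc$values[1, 1]]
  }
  expect_equal(g(4, 0.3), "Continued improvement")     # slight increase
  expect_equal(g(1, 0.7), "Degradation to improvement") # significant decrease
  expect_equal(g(5, 0.7), "Improvement to degradation")
  expect_equal(g(2, 0.3), "Continued degradation")
  expect_equal(g(3, 0.9), "Basically unchanged")        # unchanged stays
  expect_equal(g(5, 0.5), "Basically unchanged")        # tie rule at H = 0.5
  bad <- grid(matrix(7, 1)); attr(bad, "labels") <- trend_labels()
  expect_error(classify_future(bad, grid(matrix(0.4, 1))), "unknown trend")
})

test_that("stackwise trend analysis recovers noise-free planted slopes", {
  slopes <- matrix(c(0.004, 0, -0.003, 0.001), 2)
  sim <- gen_fvc_stack(shape = c(2, 2), slope_field = slopes,
                       noise_sd = 0, baseline = 0.4)
  tr <- trend_stack(sim$stack)
  expect_equal(tr$beta$values, slopes, tolerance = 1e-12)
  cls <- tr$trend_class$values
  expect_equal(trend_labels()[cls[1, 1]], "Significant increase")
  expect_equal(trend_labels()[cls[1, 2]], "Significant decrease")
  expect_equal(trend_labels()[cls[2, 1]], "Basically unchanged")
})
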