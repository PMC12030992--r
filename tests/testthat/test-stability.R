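test_that("CV is sd/mean with n-1, scale-invariant, shift-sensitive", {
  expect_equal(cv_series(c(2, 2, 2)), 0)
  expect_equal(cv_series(c(1, 3)), sqrt(2) / 2)
  x <- runif(20, 1, 2)
  expect_equal(cv_series(5 * x), cv_series(x))
  expect_false(isTRUE(all.equal(cv_series(x + 3), cv_series(x))))
  expect_true(is.na(cv_series(c(-1, 1))))  # zero mean undefined
  expect_true(is.na(cv_series(3)))
})

test_that("stackwise CV grades stability periods correctly", {
  arr <- array(0.3, c(2, 2, 25))
  s <- stack_grids(arr, 2000:2024)
  res <- cv_stack(s)[[1]]
  expect_equal(res$cv$values, matrix(0, 2, 2))
  expect_equal(class_labels(res$cv_class)[res$cv_class$values[1, 1]],
               "Extremely insignificant")
  # grade boundaries of the CV scheme
  cg <- classify(toy_grid(c(0.2, 0.6, 0.1, 0.4), nr = 2), cv_grades())
  labs <- class_labels(cg)[cg$values]
  expect_equal(labs, c("Insignificant", "Extremely significant",
                       "Extremely insignificant", "Significant"))
  expect_error(cv_stack(s, periods = list(c(1990, 1991))), "fewer than 2")
  # multi-period split returns one result per period
  two <- cv_stack(s, periods = list(c(2000, 2012), c(2013, 2024)))
  expect_length(two, 2)
  expect_equal(two[[2]]$period, c(2013L, 2024L))
})

test_that("zonal class fractions match per-zone counting", {
  cg <- classify(grid(matrix(runif(64), 8)), fvc_grades())
  one <- zonal_fractions(cg, grid(matrix(1, 8, 8)))
  expect_equal(unlist(one[1, 2:6], use.names = FALSE),
               area_fractions(cg)$fraction)
  # two uniform zones -> identity rows
  zc <- classify(grid(matrix(rep(c(0.05, 0.95), each = 32), 8)), fvc_grades())
  zz <- grid(matrix(rep(c(1, 2), each = 32), 8))
  fr <- zonal_fractions(zc, zz)
  expect_equal(fr$Lowest, c(1, 0))
  expect_equal(fr$Highest, c(0, 1))
  # random grid vs brute-force per-zone counting
  set.seed(9)
  cm <- matrix(sample(1:5, 64, TRUE), 8)
  zm <- matrix(sample(1:2, 64, TRUE), 8)
  cgr <- grid(cm); attr(cgr, "labels") <- paste0("c", 1:5)
  fr2 <- zonal_fractions(cgr, grid(zm))
  for (z in 1:2) for (k in 1:5)
    expect_equal(fr2[fr2$zone == z, paste0("c", k)],
                 sum(cm == k & zm == z) / sum(zm == z))
  expect_equal(rowSums(fr2[, paste0("c", 1:5)]), c(1, 1))
})

test_that("partial correlation matches its closed form and reduces to Pearson", {
  expect_equal(pearson(1:3, c(1, 3, 2)), 0.5)
  expect_equal(pearson(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson(1:10, -(1:10)), -1)
  expect_true(is.na(pearson(1:10, rep(2, 10))))

  set.seed(14)
  x <- rnorm(40); y <- rnorm(40); z <- rnorm(40)
  pc <- partial_corr(x, y, z)
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  expect_equal(pc$r, (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2)))
  expect_equal(pc$p, 2 * pt(-abs(pc$t), df = 37))
  # orthogonal control leaves the Pearson correlation untouched
  zc <- rep(c(-1, 1), 20)
  xo <- rep(c(1, 1, -1, -1), 10)
  expect_equal(partial_corr(xo, xo + 0 * zc, zc)$r, 1)
  expect_error(partial_corr(1:5, c(2, 1, 4, 3, 5), 1:5 * 2), "degenerate")
})

test_that("large-sample partial correlation recovers a planted value", {
  # trivariate normal with partial r(x,y|z) = 0.3 by construction
  n <- 10000
  set.seed(31)
  z <- rnorm(n)
  x <- 0.6 * z + sqrt(1 - 0.36) * rnorm(n)
  r <- 0.3
  e <- rnorm(n)
  y <- 0.6 * z + sqrt(1 - 0.36) * (r * ((x - 0.6 * z) / sqrt(0.64)) +
                                     sqrt(1 - r^2) * e)
  expect_lt(abs(partial_corr(x, y, z)$r - 0.3), 0.03)
})

test_that("pixelwise partial-correlation maps separate driver from bystander", {
  cov3 <- diag(c(0.02^2, 1, 20^2))
  cov3[1, 2] <- cov3[2, 1] <- 0.7 * 0.02 * 1  # FVC-temp correlation 0.7
  sim <- gen_climate_stacks(shape = c(8, 8), cov_mat = cov3, seed = 4)
  maps <- partial_corr_maps(sim$fvc, sim$temp, sim$precip)
  expect_gt(mean(maps$temp$sig & maps$temp$r$values > 0, na.rm = TRUE), 0.8)
  expect_lt(abs(mean(maps$precip$r$values, na.rm = TRUE)), 0.1)
  # swapping the climate stacks swaps the two maps
  sw <- partial_corr_maps(sim$fvc, sim$precip, sim$temp)
  expect_equal(sw$precip$r$values, maps$temp$r$values)
  # constant control at a pixel is masked, not an error
  tmp <- sim$temp; tmp$values[1, 1, ] <- 5
  m2 <- partial_corr_maps(sim$fvc, tmp, sim$precip)
  expect_true(is.na(m2$temp$r$values[1, 1]))
})
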