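test_that("discretization methods produce the documented breaks", {
  eq <- discretize(seq(0, 100, by = 1), "equal_interval", 4)
  expect_equal(eq$breaks, c(25, 50, 75))
  qt <- discretize(1:8, "quantile", 4)
  expect_equal(unname(table(qt$labels)), rep(2L, 4), ignore_attr = TRUE)
  expect_error(discretize(rep(3, 10), "equal_interval", 4), "constant column")
  expect_error(discretize(c(1, 1, 2, 2), "quantile", 4), "distinct")
  # std_dev breaks sit symmetric around the mean in half-SD steps
  x <- rnorm(500)
  sd4 <- discretize(x, "std_dev", 4)
  expect_equal(sd4$breaks, mean(x) + 0.5 * sd(x) * c(-1, 0, 1))
  # geometric bins span the range and every value is labeled
  gx <- rlnorm(500)
  ge <- discretize(gx, "geometric", 5)
  expect_true(all(ge$labels >= 1 & ge$labels <= ge$L))
  expect_true(all(ge$breaks > min(gx) & ge$breaks < max(gx)))
})

test_that("q statistic equals the group-by oracle and its closed-form cases", {
  expect_equal(factor_q(c(1, 2, 3, 4), c(1, 1, 2, 2)), 0.8)
  # internally constant strata explain everything
  expect_equal(factor_q(c(2, 2, 7, 7, 7), c(1, 1, 2, 2, 2)), 1)
  set.seed(18)
  for (n in c(50, 1000, 10000)) {
    y <- rnorm(n)
    h <- sample(1:6, n, TRUE)
    expect_equal(factor_q(y, h), q_bruteforce(y, h), tolerance = 1e-10)
    expect_gte(factor_q(y, h), 0)
    expect_lte(factor_q(y, h), 1)
  }
  expect_error(factor_q(c(1, 2), c(1, 1)), "at least 2")
  expect_error(factor_q(rep(1, 10), rep(1:2, 5)), "SST is zero")
})

test_that("interaction typing covers the five cases with exact boundaries", {
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.8), "Nonlinear-enhanced")
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.65), "Bivariable-enhanced")
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.7), "Independent")
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.35), "Uni-variable-weaken")
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.2), "Nonlinear-weaken")
  # equality with the larger single q stays on the weaken side
  expect_equal(fvcdyn:::interaction_type(0.3, 0.4, 0.4), "Uni-variable-weaken")
  # typing is exhaustive over random admissible triples
  set.seed(4)
  for (i in 1:200) {
    q1 <- runif(1); q2 <- runif(1); q12 <- runif(1)
    expect_true(fvcdyn:::interaction_type(q1, q2, q12) %in%
                  c("Nonlinear-weaken", "Uni-variable-weaken",
                    "Bivariable-enhanced", "Independent",
                    "Nonlinear-enhanced"))
  }
})

test_that("interaction overlay behaves on constructed stratifications", {
  set.seed(26)
  n <- 400
  h1 <- sample(1:3, n, TRUE); h2 <- sample(1:3, n, TRUE)
  y <- rnorm(n, mean = h1)
  # identical second factor: overlay q equals the single q
  same <- interaction_q(y, h1, h1)
  expect_equal(same$q12, same$q1)
  expect_equal(same$type, "Uni-variable-weaken")
  # response driven by the XOR of two factors: only the overlay explains it
  a <- sample(0:1, n, TRUE); b <- sample(0:1, n, TRUE)
  yx <- ifelse(xor(a, b), 5, 0) + rnorm(n, sd = 0.1)
  xi <- interaction_q(yx, a + 1, b + 1)
  expect_lt(max(xi$q1, xi$q2), 0.1)
  expect_gt(xi$q12, 0.9)
  expect_equal(xi$type, "Nonlinear-enhanced")
  expect_error(interaction_q(y, rep(1, n), rep(1, n)), "at least 2")
})

test_that("risk detector flags mean differences via Welch t", {
  y <- c(rnorm(20, 0, 1), rnorm(20, 0, 1))
  h <- rep(1:2, each = 20)
  same <- risk_detect(c(1:5, 1:5), rep(1:2, each = 5))
  expect_equal(same$t[1, 2], 0)
  expect_false(same$sig[1, 2])
  jit <- risk_detect(c(rnorm(4, 0, 1e-6), rnorm(4, 1, 1e-6)),
                     rep(1:2, each = 4))
  expect_true(jit$sig[1, 2])
  expect_equal(jit$best_stratum, 2L)
  # Welch t on {1,2,3} vs {2,4,6} matches the direct formula
  rd <- risk_detect(c(1, 2, 3, 2, 4, 6), rep(1:2, each = 3))
  tt <- (mean(c(1, 2, 3)) - mean(c(2, 4, 6))) /
    sqrt(var(c(1, 2, 3)) / 3 + var(c(2, 4, 6)) / 3)
  expect_equal(rd$t[1, 2], tt)
  # singleton strata are excluded, not fatal
  s1 <- risk_detect(c(1, 5, 6, 7), c(1, 2, 2, 2))
  expect_true(is.na(s1$sig[1, 2]))
})

test_that("ecological detector compares within-strata variance sums", {
  set.seed(33)
  y <- rnorm(60)
  h <- sample(1:3, 60, TRUE)
  same <- ecological_detect(y, h, h)
  expect_equal(same$f, 1)
  expect_false(same$significant)
  # construct SSW1 = 2 * SSW2 exactly: y symmetric around group means
  y2 <- c(-1, 1, -sqrt(2), sqrt(2))
  hA <- c(1, 1, 2, 2)   # SSW = 2 + 4 = 6... choose directly:
  # factor A groups {(-1,1)},{(-r2,r2)}: SSW_A = 2 + 4 = 6
  # factor B groups {(-1,-r2)},{(1,r2)}: means -(1+r2)/2,(1+r2)/2
  hB <- c(1, 2, 1, 2)
  sswA <- 6
  sswB <- sum((c(-1, -sqrt(2)) - mean(c(-1, -sqrt(2))))^2) * 2
  eco <- ecological_detect(y2, hA, hB)
  expect_equal(eco$f, sswA / sswB)
  # strong signal case: one factor explains y almost perfectly
  hs <- rep(1:3, each = 30)
  ys <- hs * 10 + rnorm(90, sd = 0.1)
  hr <- sample(1:3, 90, TRUE)
  expect_true(ecological_detect(ys, hs, hr)$significant)
})

test_that("optimal discretization recovers planted step structure", {
  set.seed(41)
  x <- runif(600)
  # steps planted at the empirical tertiles so a 3-bin quantile partition
  # can separate them exactly
  steps <- findInterval(x, quantile(x, c(1 / 3, 2 / 3), type = 7)) + 1
  y <- c(0, 5, 10)[steps] + rnorm(600, sd = 0.05)
  best <- optimal_discretization(y, x, k_range = 3:6)
  expect_gt(best$q, 0.99)
  # independent response: low q everywhere
  y0 <- rnorm(1000)
  x0 <- runif(1000)
  expect_lt(optimal_discretization(y0, x0)$q, 0.05)
  single <- optimal_discretization(y, x, methods = "quantile", k_range = 4)
  expect_equal(single$partition$method, "quantile")
  expect_equal(single$partition$k, 4L)
})

test_that("full detector run enumerates pairs and ranks the planted driver", {
  set.seed(55)
  n <- 600
  drv <- sample(1:4, n, TRUE)
  tab <- data.frame(
    unit_id = 1:n,
    y = drv * 1.0 + rnorm(n, sd = 0.8),
    driver = factor(letters[drv]),
    bystander = runif(n),
    noisecat = factor(sample(c("u", "v", "w"), n, TRUE)))
  res <- run_geodetector(tab, k_range = 3:5)
  expect_equal(nrow(res$interactions), choose(3, 2))
  expect_equal(names(res$q)[1], "driver")
  expect_gt(res$q["driver"], res$q["bystander"])
  # 15 factors enumerate 105 unordered pairs
  big <- data.frame(y = rnorm(300))
  for (k in 1:15) big[[paste0("f", k)]] <- factor(sample(1:3, 300, TRUE))
  resb <- run_geodetector(big)
  expect_equal(nrow(resb$interactions), 105)
  expect_equal(nrow(resb$ecological), 105)
  two <- run_geodetector(tab, factors = c("driver", "bystander"),
                         k_range = 3:4)
  expect_equal(nrow(two$interactions), 1)
})

test_that("zonal detector recovers each zone's own dominant factor", {
  set.seed(66)
  mk_zone <- function(n, dominant) {
    a <- sample(1:3, n, TRUE); b <- sample(1:3, n, TRUE)
    y <- if (dominant == "a") a + rnorm(n, sd = 0.3) else b + rnorm(n, sd = 0.3)
    data.frame(y = y, fa = factor(a), fb = factor(b))
  }
  tab <- rbind(cbind(mk_zone(150, "a"), zone = 1),
               cbind(mk_zone(150, "b"), zone = 2))
  zr <- zonal_geodetector(tab, anchor = "fa", min_units = 30)
  expect_equal(names(zr$zones[["1"]]$q)[1], "fa")
  expect_equal(names(zr$zones[["2"]]$q)[1], "fb")
  # one zone reduces to a plain run
  one <- zonal_geodetector(cbind(mk_zone(120, "a"), zone = 7), min_units = 30)
  plain <- run_geodetector(mk_zone(120, "a"))
  expect_equal(unname(zr$zones[["1"]]$q["fa"]),
               unname(run_geodetector(tab[tab$zone == 1,
                                          c("y", "fa", "fb")])$q["fa"]))
  expect_equal(names(one$zones), "7")
  # top interactions are sorted descending by overlay q
  ti <- zr$top_interactions
  for (z in unique(ti$zone))
    expect_false(is.unsorted(rev(ti$q12[ti$zone == z])))
  expect_warning(zonal_geodetector(cbind(mk_zone(10, "a"), zone = 3)),
                 "skipped")
})
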