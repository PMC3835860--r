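test_that("concentration normalization follows the 0.2 m depth convention", {
  expect_identical(areal_concentration(0, 100), 0)
  expect_equal(areal_concentration(180, 180), 0.2)          # 900 m^2 swept
  expect_equal(areal_concentration(403, 180), 403 / 900)    # 0.4478 m^-2
  # areal and volumetric forms are locked together: conc_m2 = 0.2 * conc_m3
  cnt <- c(0, 3, 57, 403); vol <- c(120, 95, 180, 180)
  expect_equal(areal_concentration(cnt, vol),
               0.2 * volumetric_concentration(cnt, vol))
  expect_error(areal_concentration(10, 0), "volume")
  expect_error(areal_concentration(-1, 10), "count")
})

test_that("zooplankton preservation correction multiplies by 1.20", {
  expect_identical(zoop_corrected_mass(0), 0)
  expect_equal(zoop_corrected_mass(100), 120)
  expect_equal(zoop_corrected_mass(250), 300)
  expect_error(zoop_corrected_mass(-5), ">= 0")
})

test_that("removal equivalents invert the plastic:plankton ratio", {
  r <- removal_equivalents(1.0)
  expect_equal(r$zoop_removed_mg_per_g, 1000)
  r <- removal_equivalents(1.368)
  expect_equal(round(r$zoop_removed_mg_per_g), 731)
  expect_equal(r$carbon_removed_mg_per_g, r$zoop_removed_mg_per_g * 0.40)
  expect_equal(r$carbon_removed_mg_per_g, 292.4, tolerance = 1e-3)
  expect_error(removal_equivalents(0), "positive")
  expect_error(removal_equivalents(-1), "positive")
})

test_that("summaries use interpolated percentiles and a seeded bootstrap", {
  s <- summarize_values(c(5, 5, 5, 5), seed = 1)
  expect_equal(s$median, 5)
  expect_equal(s$cv_percent, 0)
  expect_equal(s$boot_ci_lo, 5)
  expect_equal(s$boot_ci_hi, 5)

  s <- summarize_values(1:100, seed = 1)
  expect_equal(s$median, 50.5)
  expect_equal(s$p5, 5.95)
  expect_equal(s$p95, 95.05)
  expect_true(s$boot_ci_lo <= s$median && s$median <= s$boot_ci_hi)

  # CV of an exponential is 100% up to MC error
  set.seed(2)
  s <- summarize_values(rexp(1e4, 1.44), seed = 3)
  expect_lt(abs(s$cv_percent - 100), 5)

  # seeded bootstrap reproduces
  set.seed(7); x <- rnorm(30)
  expect_identical(summarize_values(x, seed = 9)$boot_ci_lo,
                   summarize_values(x, seed = 9)$boot_ci_lo)
  expect_error(summarize_values(numeric(0)), "at least one")
})

test_that("anomalies are centred on zero", {
  expect_equal(anomaly(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(anomaly(rep(4, 6)), rep(0, 6))
  set.seed(4)
  expect_equal(mean(anomaly(rexp(50))), 0)
})

test_that("Spearman correlation matches hand-ranked cases", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, rev(1:10))$rho, -1)
  # ranks of y = (2,1,4,3,5): sum d^2 = 4 -> rho = 1 - 24/120 = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5))$rho, 0.8)
  expect_error(spearman_rho(1:4, 1:5), "lengths differ")
})

test_that("rank tests reproduce enumerable cases and hold their size", {
  # disjoint samples: U = 0 in one orientation, 9 in the other
  res <- rank_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$mann_whitney$U, 0)
  res2 <- rank_tests(list(a = c(4, 5, 6), b = c(1, 2, 3)))
  expect_equal(res2$mann_whitney$U, 9)

  # identical groups: H ~ 0, p ~ 1
  g <- list(a = c(1, 5, 9, 2), b = c(1, 5, 9, 2), c = c(1, 5, 9, 2))
  res <- rank_tests(g)
  expect_lt(res$kruskal$statistic, 1e-8)
  expect_gt(res$kruskal$p, 0.999)
  expect_true(is.matrix(res$pairwise_p))

  expect_error(rank_tests(list(a = 1:3)), ">= 2")
  expect_error(rank_tests(list(a = 1:3, b = numeric(0))), "non-empty")

  # empirical size ~ alpha on null simulations
  set.seed(10)
  rej <- 0L
  for (i in 1:1000) {
    p <- rank_tests(list(a = rexp(30), b = rexp(30)))$mann_whitney$p
    if (p < 0.05) rej <- rej + 1L
  }
  expect_lt(abs(rej / 1000 - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("Theil-Sen regression is exact on lines and robust to outliers", {
  ts <- theil_sen(1:10, 2 * (1:10) + 1)
  expect_equal(ts$slope, 2)
  expect_equal(ts$intercept, 1)

  # slopes {1, 2.5, 4} -> median 2.5
  expect_equal(theil_sen(c(0, 1, 2), c(0, 1, 5))$slope, 2.5)

  # one outlier among 20 collinear points leaves the slope unchanged
  x <- 1:20; y <- 3 * x - 2; y[7] <- y[7] + 500
  expect_equal(theil_sen(x, y)$slope, 3)

  # slope invariant to adding a constant to y
  set.seed(6); x <- rnorm(15); y <- rnorm(15)
  expect_equal(theil_sen(x, y)$slope, theil_sen(x, y + 100)$slope)

  expect_error(theil_sen(rep(2, 5), 1:5), "identical")
})

test_that("per-tow ratios use the corrected zooplankton mass", {
  tows <- data.frame(plastic_dry_mg = c(120, 0), zoop_dry_mg_raw = c(100, 50))
  expect_equal(plastic_plankton_ratio(tows), c(1, 0))
})
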