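test_that("uniform detection has a closed-form likelihood and ESW = W", {
  edges <- distance_bin_edges()
  cnt <- c(5L, 18L, 22L, 41L, 39L, 120L)
  fit <- fit_detection(cnt, edges, family = "uniform")
  expect_equal(fit$loglik,
               dmultinom(cnt, prob = diff(edges) / 600, log = TRUE))
  expect_equal(fit$aic, -2 * fit$loglik)   # zero parameters
  expect_equal(fit$esw_m, 600)
  expect_equal(esw(fit), 600)
})

test_that("half-normal ESW matches the closed form and is monotone in sigma", {
  mk <- function(sigma) structure(
    list(family = "half_normal", params = c(sigma = sigma),
         truncation_W_m = 600), class = "detection_fit")
  for (sigma in c(50, 100, 150, 400)) {
    expect_equal(esw(mk(sigma)), esw_halfnormal_closed(sigma, 600),
                 tolerance = 1e-6)
  }
  expect_equal(esw(mk(100)), 125.33, tolerance = 1e-4)
  eswv <- vapply(c(30, 60, 120, 240, 480), function(s) esw(mk(s)),
                 numeric(1))
  expect_true(all(diff(eswv) > 0))
})

test_that("detection fits recover generating parameters and families", {
  edges <- distance_bin_edges()
  # half-normal truth sigma = 150 m, ~2000 detections, several seeds
  for (s in 1:3) {
    cfg <- one_group_config(300, 150, rep(10, 4), seed = s)
    v <- gen_sightings(cfg)
    cnt <- closed_bin_counts(v$sightings)
    fit <- fit_detection(cnt, edges, family = "half_normal")
    expect_gt(sum(cnt), 1500)
    expect_lt(abs(fit$params[["sigma"]] / 150 - 1), 0.10)
    expect_equal(fit$aic, 2 - 2 * fit$loglik)
  }

  # AIC prefers the generating family: uniform truth vs half-normal truth
  set.seed(21)
  cnt_u <- as.integer(rmultinom(1, 5000, diff(edges) / 600))
  expect_identical(select_detection(cnt_u, edges)$family, "uniform")
  x <- abs(rnorm(30000, 0, 120)); x <- x[x < 600][1:5000]
  cnt_h <- as.integer(table(cut(x, edges, include.lowest = TRUE)))
  expect_identical(select_detection(cnt_h, edges)$family, "half_normal")

  # guard rails
  expect_error(fit_detection(c(1L, 0L, 0L, 0L, 0L, 0L), edges), "at least")
  degen <- fit_detection(c(50L, 0L, 0L, 0L, 0L, 0L), edges,
                         family = "uniform")
  expect_true(degen$flagged)
})

test_that("correction factors standardize densities to the widest strip", {
  edges <- distance_bin_edges()
  mk <- function(sigma) {
    f <- structure(list(family = "half_normal", params = c(sigma = sigma),
                        truncation_W_m = 600), class = "detection_fit")
    f$esw_m <- esw(f)
    f
  }
  # same ESW in every group: CF = 1, density = n / (L ESW)
  fits <- list(a = mk(100), b = mk(100))
  d <- densities(fits, c(a = 40, b = 80), L_km = 100)
  expect_equal(d$cf, c(1, 1))
  expect_equal(d$density_per_km2, c(40, 80) / (100 * fits$a$esw_m / 1000))

  # ESW 100 m and 200 m -> CFs 2 and 1
  f100 <- structure(list(family = "uniform", params = numeric(0),
                         truncation_W_m = 100, esw_m = 100),
                    class = "detection_fit")
  f200 <- structure(list(family = "uniform", params = numeric(0),
                         truncation_W_m = 100, esw_m = 200),
                    class = "detection_fit")
  d <- densities(list(narrow = f100, wide = f200),
                 c(narrow = 10, wide = 10), L_km = 50)
  expect_equal(d$cf[d$group == "narrow"], 2)
  expect_equal(d$cf[d$group == "wide"], 1)
  # widest group: corrected density equals its uncorrected density
  expect_equal(d$corrected_n[d$group == "wide"], 10)
  # algebraic identity: density = n / (L ESW_g)
  expect_equal(d$density_per_km2, c(10, 10) / (50 * c(100, 200) / 1000))

  # uniform detection over full truncation reduces to count / (L W)
  fu <- fit_detection(c(5L, 18L, 22L, 41L, 39L, 120L), edges, "uniform")
  du <- densities(list(all = fu), c(all = 245), L_km = 120)
  expect_equal(du$density_per_km2, 245 / (120 * 0.6))
})

test_that("segment bootstrap is reproducible and collapses for identical data", {
  cfg <- one_group_config(120, 150, rep(4, 20), seed = 14)
  v <- gen_sightings(cfg)
  ci1 <- bootstrap_density_ci(v$sightings, v$segments, B = 150, seed = 5)
  ci2 <- bootstrap_density_ci(v$sightings, v$segments, B = 150, seed = 5)
  expect_identical(ci1, ci2)
  expect_lt(ci1$ci_lo, ci1$density_per_km2)
  expect_gt(ci1$ci_hi, ci1$density_per_km2)
  expect_warning(
    bootstrap_density_ci(v$sightings, v$segments, B = 50, seed = 1),
    "noisy")

  # identical segments shrink the interval relative to heterogeneous ones:
  # duplicate one segment's sightings across all segment ids
  s1 <- v$sightings[v$sightings$segment_id == v$segments$segment_id[1], ]
  clones <- do.call(rbind, lapply(v$segments$segment_id, function(id) {
    s <- s1; s$segment_id <- id; s
  }))
  ci_clone <- bootstrap_density_ci(clones, v$segments, B = 150, seed = 5)
  expect_lt(ci_clone$ci_hi - ci_clone$ci_lo, 1e-8)
})
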