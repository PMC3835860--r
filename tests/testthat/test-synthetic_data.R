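test_that("tow generation is deterministic under a fixed seed", {
  cfg <- field_config(n_stations = 25, seed = 7)
  expect_identical(gen_tows(cfg), gen_tows(cfg))

  cfg2 <- field_config(n_stations = 25, seed = 8)
  expect_false(identical(gen_tows(cfg), gen_tows(cfg2)))
})

test_that("nugget-only field recovers the exponential marginal", {
  cfg <- field_config(n_stations = 5000, track_spacing_km = 1,
                      spatial_range_km = 0, wind_decay_per_ms = 0,
                      marginal_rate = 1.44, seed = 42)
  tw <- gen_tows(cfg)
  conc <- areal_concentration(tw$count, tw$volume_m3)

  # analytic mean 1/rate within 3 standard errors (SD of exp = 1/rate)
  se <- (1 / 1.44) / sqrt(5000)
  expect_lt(abs(mean(conc) - 1 / 1.44), 3 * se)

  # SD of exponential = 1/rate = 0.694; SE(SD) ~ sigma * sqrt(2/n)
  se_sd <- (1 / 1.44) * sqrt(2 / 5000)
  expect_lt(abs(sd(conc) - 1 / 1.44), 3 * se_sd)

  # KS: the latent surface concentration is exactly exponential
  ks <- suppressWarnings(ks.test(tw$conc_surface_m2, pexp, 1.44))
  expect_gt(ks$p.value, 0.01)
})

test_that("surface availability is non-increasing in wind speed", {
  cfg <- field_config(n_stations = 4000, track_spacing_km = 1,
                      spatial_range_km = 0, wind_decay_per_ms = 0.3,
                      seed = 11)
  tw <- gen_tows(cfg)
  # mean concentration drops from calm to windy conditions
  calm <- tw$conc_surface_m2[tw$wind_ms < cfg$wind_mean_ms]
  windy <- tw$conc_surface_m2[tw$wind_ms > cfg$wind_mean_ms + 2]
  expect_gt(mean(calm), mean(windy))
  expect_lt(cor(tw$wind_ms, tw$conc_surface_m2, method = "spearman"), 0)
  # with the decay switched off the association vanishes by construction
  cfg0 <- field_config(n_stations = 4000, track_spacing_km = 1,
                       spatial_range_km = 0, wind_decay_per_ms = 0,
                       seed = 11)
  tw0 <- gen_tows(cfg0)
  expect_lt(abs(cor(tw0$wind_ms, tw0$conc_surface_m2)), 3 / sqrt(4000))
})

test_that("sightings respect conservation and bin arithmetic", {
  cfg <- one_group_config(80, 150, rep(5, 8), seed = 3)
  v <- gen_sightings(cfg)
  gen <- attr(v$sightings, "n_generated")
  expect_gte(sum(gen$n_generated), nrow(v$sightings))
  expect_identical(sum(closed_bin_counts(v$sightings)),
                   nrow(v$sightings))
  # reproducible
  v2 <- gen_sightings(cfg)
  expect_identical(closed_bin_counts(v$sightings),
                   closed_bin_counts(v2$sightings))
})

test_that("zero density yields zero sightings; flat detection fills bins by width", {
  cfg0 <- sighting_config(
    groups = data.frame(size_class = "small", color_class = "white",
                        density_per_km2 = 0, hn_sigma_m = 100),
    segment_lengths_km = c(5, 5), seed = 1)
  expect_identical(nrow(gen_sightings(cfg0)$sightings), 0L)

  # sigma >> bin span: retention ~uniform, counts ~ bin widths (multinomial)
  cfg <- one_group_config(400, 1e6, rep(10, 10), seed = 9)
  v <- gen_sightings(cfg)
  cnt <- closed_bin_counts(v$sightings)
  p <- diff(distance_bin_edges()) / 600
  gof <- suppressWarnings(chisq.test(cnt, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("particle areas are exponential at the configured scale", {
  expect_identical(gen_particles(0), numeric(0))
  expect_error(gen_particles(-1), "non-negative")
  a <- gen_particles(1e4, area_rate = 100, seed = 5)
  expect_identical(a, gen_particles(1e4, area_rate = 100, seed = 5))
  # mean area ~ 0.01 cm^2 within 3 SE
  expect_lt(abs(mean(a) - 0.01), 3 * 0.01 / sqrt(1e4))
})

test_that("invalid generator configurations are rejected", {
  expect_error(field_config(marginal_rate = 0), "marginal_rate")
  expect_error(field_config(marginal_rate = -2), "marginal_rate")
  expect_error(field_config(spatial_range_km = -1), "spatial_range_km")
  expect_error(field_config(n_stations = 1), "n_stations")
  expect_error(sighting_config(segment_lengths_km = numeric(0)), "segment")
  expect_error(
    sighting_config(groups = data.frame(size_class = "small",
                                        color_class = "white",
                                        density_per_km2 = -1,
                                        hn_sigma_m = 10)),
    "densities")
})
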