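# Independent Mann-Whitney U oracle: hand-computed rank-sum statistic with
# tie-corrected normal approximation and continuity correction. Kept free of
# stats::wilcox.test so it can cross-check the package's Monte Carlo power.
oracle_ranksum_p <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  ties <- table(r)
  sig2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- U - mu
  z <- sign(z) * max(abs(z) - 0.5, 0) / sqrt(sig2)
  2 * stats::pnorm(-abs(z))
}

# closed-form half-normal ESW: sigma * sqrt(pi/2) * erf(W / (sigma sqrt(2)))
esw_halfnormal_closed <- function(sigma, W) {
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  sigma * sqrt(pi / 2) * erf(W / (sigma * sqrt(2)))
}

# scattered coordinates for variogram tests (degrees around 30N, 140W)
scatter_coords <- function(n, seed) {
  set.seed(seed)
  list(lat = stats::runif(n, 30, 33), lon = stats::runif(n, -142, -138))
}

# equally spaced track coordinates with a given spacing in km
track_coords <- function(n, spacing_km) {
  list(lat = 30 + (seq_len(n) - 1) * spacing_km / 111.1949,
       lon = rep(-140, n))
}

# one-group sighting configuration used across distance-sampling tests
one_group_config <- function(density, sigma, lengths_km, seed) {
  sighting_config(
    groups = data.frame(size_class = "medium", color_class = "white",
                        density_per_km2 = density, hn_sigma_m = sigma),
    segment_lengths_km = lengths_km, seed = seed)
}

closed_bin_counts <- function(sightings, edges = distance_bin_edges()) {
  labels <- distance_bin_labels(edges, open_top = FALSE)
  as.integer(table(factor(sightings$distance_bin, levels = labels)))
}
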