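#' Configuration for a synthetic surface-debris field
#'
#' Describes a one-dimensional track of surface net-tow stations over a
#' latent debris concentration field. The field is a Gaussian copula: a
#' stationary Gaussian process with squared-exponential correlation is
#' transformed through its normal scores so that the marginal concentration
#' is exactly exponential with rate `marginal_rate` (particles per square
#' metre are right-skewed in surface surveys, and an exponential fit with
#' rate 1.44 describes combined-survey microplastic concentrations).
#' Surface availability decreases with wind speed: mixing pushes buoyant
#' particles below the depth a surface net samples, so the observed surface
#' concentration is the latent concentration times
#' `exp(-wind_decay_per_ms * max(0, wind - wind_mean_ms))`.
#'
#' @param n_stations Number of tow stations along the track (>= 2).
#' @param track_spacing_km Distance between consecutive stations, km.
#' @param marginal_rate Exponential rate of the marginal concentration,
#'   1/(particles m^-2). Default 1.44.
#' @param spatial_range_km Range of the squared-exponential correlation of
#'   the latent Gaussian field, km. `0` gives a pure-nugget (white noise)
#'   field.
#' @param wind_mean_ms,wind_sd_ms Mean and standard deviation of the true
#'   wind speed at tow time, m s^-1.
#' @param wind_decay_per_ms Surface-availability decay per m s^-1 of wind
#'   above the mean; `0` disables the wind effect.
#' @param tow_length_m Length of one tow, m. With the 0.86 m net mouth this
#'   sets the surface area swept per tow.
#' @param particle_mass_mg Mean dry mass of one plastic particle, mg.
#' @param zoop_median_mg,zoop_sdlog Median (mg) and log-scale SD of the
#'   lognormal zooplankton dry biomass per tow.
#' @param seed Optional integer seed; fixed seed gives identical tables.
#'
#' @return An object of class `field_config`.
#' @seealso [gen_tows()]
#' @export
field_config <- function(n_stations = 119L,
                         track_spacing_km = 18,
                         marginal_rate = 1.44,
                         spatial_range_km = 0,
                         wind_mean_ms = 6,
                         wind_sd_ms = 2,
                         wind_decay_per_ms = 0.1,
                         tow_length_m = 780,
                         particle_mass_mg = 1,
                         zoop_median_mg = 300,
                         zoop_sdlog = 0.8,
                         seed = NULL) {
  if (!is.numeric(marginal_rate) || marginal_rate <= 0)
    stop("`marginal_rate` must be > 0", call. = FALSE)
  if (spatial_range_km < 0)
    stop("`spatial_range_km` must be >= 0", call. = FALSE)
  if (n_stations < 2)
    stop("`n_stations` must be >= 2", call. = FALSE)
  if (track_spacing_km <= 0 || tow_length_m <= 0)
    stop("track spacing and tow length must be positive", call. = FALSE)
  if (wind_sd_ms < 0 || wind_decay_per_ms < 0)
    stop("wind parameters must be non-negative", call. = FALSE)
  structure(list(
    n_stations = as.integer(n_stations),
    track_spacing_km = track_spacing_km,
    marginal_rate = marginal_rate,
    spatial_range_km = spatial_range_km,
    wind_mean_ms = wind_mean_ms,
    wind_sd_ms = wind_sd_ms,
    wind_decay_per_ms = wind_decay_per_ms,
    tow_length_m = tow_length_m,
    particle_mass_mg = particle_mass_mg,
    zoop_median_mg = zoop_median_mg,
    zoop_sdlog = zoop_sdlog,
    seed = seed
  ), class = "field_config")
}

#' Simulate a stationary Gaussian process along a 1-D track
#'
#' Draws one realization of a zero-mean, unit-variance Gaussian process at
#' `n` equally spaced points with squared-exponential correlation
#' `exp(-(h / range_km)^2)`. A range of zero returns white noise. Uses the
#' current RNG state unless `seed` is given.
#'
#' @param n Number of points.
#' @param spacing_km Spacing between points, km.
#' @param range_km Correlation range, km (0 = white noise).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @export
sim_gp_track <- function(n, spacing_km, range_km, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  if (range_km <= 0) return(stats::rnorm(n))
  x <- (seq_len(n) - 1) * spacing_km
  h <- abs(outer(x, x, "-"))
  C <- exp(-(h / range_km)^2)
  diag(C) <- diag(C) + 1e-8  # numerical jitter for the Cholesky
  R <- chol(C)
  drop(crossprod(R, stats::rnorm(n)))
}

#' Generate synthetic surface net-tow records
#'
#' Simulates `n_stations` manta tows along a 1-D meridional track. The
#' latent concentration field is the Gaussian copula described in
#' [field_config()]; the observed surface concentration applies the wind
#' availability decay; particle counts are Poisson given concentration times
#' swept surface area. Dry plastic mass is the sum of per-particle
#' exponential masses, and zooplankton dry biomass is lognormal.
#'
#' @param config A [field_config()].
#' @return A data frame with one row per tow: `tow_id`, `lat`, `lon`,
#'   `gear`, `volume_m3`, `count`, `conc_surface_m2` (latent observed
#'   concentration, particles m^-2, before Poisson counting),
#'   `plastic_dry_mg`, `zoop_dry_mg_raw`, `wind_ms`, `region`, `diel`.
#' @examples
#' tows <- gen_tows(field_config(n_stations = 10, seed = 1))
#' tows$count
#' @export
gen_tows <- function(config) {
  if (!inherits(config, "field_config"))
    stop("`config` must be a field_config", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_stations

  z <- sim_gp_track(n, config$track_spacing_km, config$spatial_range_km)
  conc_true <- stats::qexp(stats::pnorm(z), rate = config$marginal_rate)

  wind <- pmax(stats::rnorm(n, config$wind_mean_ms, config$wind_sd_ms), 0)
  avail <- exp(-config$wind_decay_per_ms * pmax(0, wind - config$wind_mean_ms))
  conc_surface <- conc_true * avail

  area_m2 <- config$tow_length_m * 0.86  # manta mouth width 0.86 m
  volume_m3 <- area_m2 * 0.2             # mouth depth 0.2 m
  count <- stats::rpois(n, conc_surface * area_m2)

  plastic <- numeric(n)
  pos <- count > 0
  if (any(pos))
    plastic[pos] <- stats::rgamma(sum(pos), shape = count[pos],
                                  rate = 1 / config$particle_mass_mg)
  zoop <- stats::rlnorm(n, meanlog = log(config$zoop_median_mg),
                        sdlog = config$zoop_sdlog)

  lat <- 30 + (seq_len(n) - 1) * config$track_spacing_km / 111.1949
  data.frame(
    tow_id = sprintf("T%04d", seq_len(n)),
    lat = lat,
    lon = rep(-140, n),
    gear = rep("manta", n),
    volume_m3 = rep(volume_m3, n),
    count = count,
    conc_surface_m2 = conc_surface,
    plastic_dry_mg = plastic,
    zoop_dry_mg_raw = zoop,
    wind_ms = wind,
    region = rep("NPSG", n),
    diel = rep_len(c("D", "C", "N"), n),
    stringsAsFactors = FALSE
  )
}

#' Default perpendicular-distance bin edges (m)
#'
#' The seven observation bins used for shipboard debris sightings:
#' 0-10, 10-50, 50-100, 100-200, 200-300, 300-600 m and an open `>600 m`
#' bin. Only the closed edges are returned; the open bin is handled by its
#' label.
#'
#' @return Numeric vector `c(0, 10, 50, 100, 200, 300, 600)`.
#' @export
distance_bin_edges <- function() c(0, 10, 50, 100, 200, 300, 600)

#' Labels for distance bins given their closed edges
#'
#' @param edges Strictly increasing numeric edges, first element 0.
#' @param open_top Append the open `">last"` label?
#' @return Character vector of bin labels such as `"0-10"`, `">600"`.
#' @export
distance_bin_labels <- function(edges = distance_bin_edges(),
                                open_top = TRUE) {
  if (any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  lab <- paste0(edges[-length(edges)], "-", edges[-1])
  if (open_top) lab <- c(lab, paste0(">", edges[length(edges)]))
  lab
}

#' Debris size and color classes
#'
#' @return Character vectors of the three size classes (`small` 2-10 cm,
#'   `medium` 10-30 cm, `large` >30 cm) and three color classes.
#' @name debris_classes
NULL

#' @rdname debris_classes
#' @export
size_classes <- function() c("small", "medium", "large")

#' @rdname debris_classes
#' @export
color_classes <- function() c("white", "high-vis", "low-vis")

#' Configuration for synthetic visual debris sightings
#'
#' Describes the true state of macrodebris along surveyed transect segments:
#' a true density per km^2 and a half-normal detection scale for each of the
#' nine debris groups (3 size classes x 3 color classes). Detection from the
#' trackline decays as `g(x) = exp(-x^2 / (2 sigma^2))` in perpendicular
#' distance `x`; larger and more visible items have larger `sigma`. The
#' observer surveys one side of the trackline and records each detection in
#' a distance bin.
#'
#' @param groups Data frame with columns `size_class`, `color_class`,
#'   `density_per_km2`, `hn_sigma_m`. Defaults give a dense small class and
#'   sparse large class with sigma increasing in size and visibility.
#' @param segment_lengths_km Lengths of the surveyed segments, km.
#' @param bin_edges_m Closed distance-bin edges, m (default the standard
#'   seven-bin scheme truncated at 600 m).
#' @param seed Optional integer seed.
#' @return An object of class `sighting_config`.
#' @export
sighting_config <- function(groups = default_sighting_groups(),
                            segment_lengths_km = rep(10, 12),
                            bin_edges_m = distance_bin_edges(),
                            seed = NULL) {
  req <- c("size_class", "color_class", "density_per_km2", "hn_sigma_m")
  if (!all(req %in% names(groups)))
    stop("`groups` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  if (any(groups$density_per_km2 < 0))
    stop("densities must be >= 0", call. = FALSE)
  if (any(groups$hn_sigma_m <= 0))
    stop("half-normal sigma must be > 0", call. = FALSE)
  if (any(diff(bin_edges_m) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (length(segment_lengths_km) < 1)
    stop("at least one transect segment is required", call. = FALSE)
  if (any(segment_lengths_km <= 0))
    stop("segment lengths must be positive", call. = FALSE)
  structure(list(
    groups = groups,
    segment_lengths_km = segment_lengths_km,
    bin_edges_m = bin_edges_m,
    seed = seed
  ), class = "sighting_config")
}

#' @rdname sighting_config
#' @export
default_sighting_groups <- function() {
  g <- expand.grid(size_class = size_classes(),
                   color_class = color_classes(),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base_density <- c(small = 60, medium = 12, large = 3)
  base_sigma <- c(small = 60, medium = 150, large = 300)
  vis <- c(white = 1.2, `high-vis` = 1.1, `low-vis` = 0.8)
  g$density_per_km2 <- base_density[g$size_class] / 3
  g$hn_sigma_m <- base_sigma[g$size_class] * vis[g$color_class]
  rownames(g) <- NULL
  g
}

# diameter bounds (cm) for a size class; open large class capped at cap_cm
.size_class_bounds <- function(size_class, cap_cm = 100) {
  lo <- c(small = 2, medium = 10, large = 30)
  hi <- c(small = 10, medium = 30, large = cap_cm)
  cbind(lo = lo[size_class], hi = hi[size_class])
}

#' Generate synthetic visual sightings and transect segments
#'
#' For each transect segment and debris group, the number of items truly
#' present in the one-sided strip out to the truncation distance (the last
#' closed bin edge) is Poisson with mean `density_per_km2 * length_km *
#' W_km`; each item gets a uniform perpendicular distance on `[0, W]` and is
#' detected with probability `exp(-x^2 / (2 sigma^2))`. Detected items are
#' assigned to distance bins, mimicking bin-at-observation-time protocols.
#' Items beyond the truncation distance are not modelled (detection at the
#' horizon is not half-normal), so the open top bin is always empty here.
#'
#' @param config A [sighting_config()].
#' @return A list with `sightings` (one row per detected item: `sighting_id`,
#'   `segment_id`, `size_class`, `color_class`, `distance_bin`,
#'   `diameter_cm`) and `segments` (`segment_id`, `length_km`). The
#'   `sightings` element carries an attribute `n_generated`, a data frame of
#'   per-group item counts before detection thinning.
#' @export
gen_sightings <- function(config) {
  if (!inherits(config, "sighting_config"))
    stop("`config` must be a sighting_config", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  edges <- config$bin_edges_m
  W_m <- edges[length(edges)]
  W_km <- W_m / 1000
  labels <- distance_bin_labels(edges, open_top = FALSE)
  segs <- data.frame(
    segment_id = sprintf("S%03d", seq_along(config$segment_lengths_km)),
    length_km = config$segment_lengths_km,
    stringsAsFactors = FALSE
  )

  out <- vector("list", nrow(segs) * nrow(config$groups))
  gen <- config$groups[, c("size_class", "color_class")]
  gen$n_generated <- 0L
  k <- 0L
  for (si in seq_len(nrow(segs))) {
    for (gi in seq_len(nrow(config$groups))) {
      grp <- config$groups[gi, ]
      n_true <- stats::rpois(1, grp$density_per_km2 * segs$length_km[si] * W_km)
      gen$n_generated[gi] <- gen$n_generated[gi] + n_true
      if (n_true == 0) next
      x <- stats::runif(n_true, 0, W_m)
      detected <- stats::runif(n_true) < exp(-x^2 / (2 * grp$hn_sigma_m^2))
      x <- x[detected]
      if (length(x) == 0) next
      bnd <- .size_class_bounds(grp$size_class)
      k <- k + 1L
      out[[k]] <- data.frame(
        segment_id = segs$segment_id[si],
        size_class = grp$size_class,
        color_class = grp$color_class,
        distance_bin = as.character(cut(x, edges, labels = labels,
                                        include.lowest = TRUE)),
        diameter_cm = stats::runif(length(x), bnd[, "lo"], bnd[, "hi"]),
        stringsAsFactors = FALSE
      )
    }
  }
  sightings <- if (k > 0) do.call(rbind, out[seq_len(k)]) else
    data.frame(segment_id = character(), size_class = character(),
               color_class = character(), distance_bin = character(),
               diameter_cm = numeric(), stringsAsFactors = FALSE)
  if (nrow(sightings) > 0)
    sightings <- cbind(sighting_id = sprintf("V%05d", seq_len(nrow(sightings))),
                       sightings, stringsAsFactors = FALSE)
  else
    sightings <- cbind(sighting_id = character(), sightings)
  attr(sightings, "n_generated") <- gen
  attr(sightings, "truncation_m") <- W_m
  list(sightings = sightings, segments = segs)
}

#' Generate synthetic net-collected particle cross-sectional areas
#'
#' Particle areas are exponential with rate `area_rate`, reproducing the
#' strong small-size skew of net-collected microplastic; the default rate of
#' 100 cm^-2 puts the modal histogram bin near 0.01 cm^2.
#'
#' @param n Number of particles (>= 0).
#' @param area_rate Exponential rate, 1/cm^2.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` particle areas in cm^2.
#' @export
gen_particles <- function(n, area_rate = 100, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1 || n < 0)
    stop("`n` must be a single non-negative number", call. = FALSE)
  if (area_rate <= 0) stop("`area_rate` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) return(numeric(0))
  stats::rexp(as.integer(n), rate = area_rate)
}
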