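#' Cross-sectional area of a visually sized debris item
#'
#' Visually observed objects are sized by their larger dimension and
#' assumed circular, so the cross-sectional area is `pi d^2 / 4`.
#'
#' @param diameter_cm Diameter, cm (> 0). Vectorized.
#' @return Area in cm^2.
#' @export
circle_area <- function(diameter_cm) {
  if (any(diameter_cm <= 0))
    stop("`diameter_cm` must be > 0", call. = FALSE)
  pi * diameter_cm^2 / 4
}

#' Default log-spaced area bin edges for the size spectrum
#'
#' @param n_bins Number of bins; default 15.
#' @return Edges in cm^2, log-spaced over `10^-3` to `10^4`.
#' @export
spectrum_bin_edges <- function(n_bins = 15) {
  10^seq(-3, 4, length.out = n_bins + 1)
}

#' Combined micro/macro debris size-frequency spectrum
#'
#' Bins net-collected microdebris (measured per-particle areas) and
#' visually assessed macrodebris (diameters converted through
#' [circle_area()]) on a common cross-sectional-area axis, in consistent
#' per-m^2 density units. Each bin reports the numeric density and its
#' share of the total cross-sectional area; the area fractions sum to 1
#' whenever any debris is present.
#'
#' @param micro Data frame with `area_cm2` and `density_per_m2` (the
#'   numeric density each particle represents, e.g. `1 / area sampled`);
#'   may be `NULL` or empty.
#' @param macro Data frame with `diameter_cm` and `density_per_m2`; may be
#'   `NULL` or empty.
#' @param bin_edges_cm2 Strictly increasing area bin edges, cm^2.
#' @return Data frame of class `size_spectrum`: `bin_lo_cm2`, `bin_hi_cm2`,
#'   `numeric_density_per_m2`, `area_fraction`.
#' @export
build_spectrum <- function(micro = NULL, macro = NULL,
                           bin_edges_cm2 = spectrum_bin_edges()) {
  if (any(diff(bin_edges_cm2) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  areas <- numeric(0); dens <- numeric(0)
  if (!is.null(micro) && nrow(micro) > 0) {
    if (!all(c("area_cm2", "density_per_m2") %in% names(micro)))
      stop("`micro` needs columns area_cm2, density_per_m2", call. = FALSE)
    areas <- c(areas, micro$area_cm2)
    dens <- c(dens, micro$density_per_m2)
  }
  if (!is.null(macro) && nrow(macro) > 0) {
    if (!all(c("diameter_cm", "density_per_m2") %in% names(macro)))
      stop("`macro` needs columns diameter_cm, density_per_m2", call. = FALSE)
    areas <- c(areas, circle_area(macro$diameter_cm))
    dens <- c(dens, macro$density_per_m2)
  }
  if (any(dens < 0)) stop("densities must be >= 0", call. = FALSE)

  nb <- length(bin_edges_cm2) - 1
  out <- data.frame(bin_lo_cm2 = bin_edges_cm2[-length(bin_edges_cm2)],
                    bin_hi_cm2 = bin_edges_cm2[-1],
                    numeric_density_per_m2 = 0,
                    area_fraction = 0)
  if (length(areas)) {
    bin <- cut(areas, bin_edges_cm2, labels = FALSE, include.lowest = TRUE)
    keep <- !is.na(bin)
    bin <- bin[keep]; a <- areas[keep]; d <- dens[keep]
    num <- tapply(d, factor(bin, levels = seq_len(nb)), sum, default = 0)
    area_w <- tapply(d * a, factor(bin, levels = seq_len(nb)), sum,
                     default = 0)
    out$numeric_density_per_m2 <- as.numeric(num)
    total_area <- sum(area_w)
    if (total_area > 0) out$area_fraction <- as.numeric(area_w) / total_area
  }
  class(out) <- c("size_spectrum", "data.frame")
  out
}

#' Fraction of the ocean surface physically covered by plastic
#'
#' @param total_debris_area_m2 Summed two-dimensional debris area, m^2
#'   (>= 0).
#' @param surveyed_area_km2 Total area surveyed, km^2 (> 0).
#' @return Coverage in percent: `100 * area_m2 / (surveyed_km2 * 1e6)`.
#' @examples
#' coverage_percent(22.9, 94.4)  # ~2.43e-5 %
#' @export
coverage_percent <- function(total_debris_area_m2, surveyed_area_km2) {
  if (any(surveyed_area_km2 <= 0))
    stop("`surveyed_area_km2` must be > 0", call. = FALSE)
  if (any(total_debris_area_m2 < 0))
    stop("debris area must be >= 0", call. = FALSE)
  100 * total_debris_area_m2 / (surveyed_area_km2 * 1e6)
}

#' Ocean-coverage bounds from size-class counts
#'
#' Visual size classes only bound each item's diameter (small 2-10 cm,
#' medium 10-30 cm, large > 30 cm), so coverage is reported as a range: the
#' minimum assumes every item sits at its class's lower diameter bound, the
#' maximum at its upper bound, with the open large class capped at
#' `large_cap_cm`.
#'
#' @param counts Named vector or list with elements `small`, `medium`,
#'   `large` (counts >= 0).
#' @param surveyed_area_km2 Area surveyed, km^2 (> 0).
#' @param large_cap_cm Upper diameter cap for the open large class, cm;
#'   must exceed 30. Default 100.
#' @return List with `min_percent` and `max_percent`.
#' @export
class_bound_coverage <- function(counts, surveyed_area_km2,
                                 large_cap_cm = 100) {
  if (large_cap_cm <= 30)
    stop("`large_cap_cm` must exceed the 30 cm class boundary", call. = FALSE)
  counts <- unlist(counts)[c("small", "medium", "large")]
  if (any(is.na(counts)))
    stop("`counts` needs elements small, medium, large", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  lo_d <- c(small = 2, medium = 10, large = 30)
  hi_d <- c(small = 10, medium = 30, large = large_cap_cm)
  # cm^2 -> m^2: / 1e4
  min_area_m2 <- sum(counts * circle_area(lo_d)) / 1e4
  max_area_m2 <- sum(counts * circle_area(hi_d)) / 1e4
  list(min_percent = coverage_percent(min_area_m2, surveyed_area_km2),
       max_percent = coverage_percent(max_area_m2, surveyed_area_km2))
}
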