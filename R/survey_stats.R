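#' Areal and volumetric concentration from a surface net tow
#'
#' A manta net samples the two-dimensional air-sea interface, so
#' concentrations are preferentially expressed per square metre of sea
#' surface. The flowmeter records a filtered volume; the depth sampled is
#' taken to be the 0.2 m vertical dimension of the net mouth, so the surface
#' area swept is `volume_m3 / 0.2` and the areal concentration is
#' `count / (volume_m3 / 0.2)`. The two forms satisfy
#' `conc_m2 == 0.2 * conc_m3` exactly.
#'
#' @param count Particle count (>= 0). Vectorized.
#' @param volume_m3 Filtered water volume, m^3 (> 0). Vectorized.
#' @param depth_m Sampled depth, m; default the 0.2 m mouth dimension.
#' @return `areal_concentration()`: particles m^-2.
#'   `volumetric_concentration()`: particles m^-3.
#' @examples
#' areal_concentration(180, 180)  # 0.2 particles per m^2
#' @export
areal_concentration <- function(count, volume_m3, depth_m = 0.2) {
  .check_conc_args(count, volume_m3)
  count / (volume_m3 / depth_m)
}

#' @rdname areal_concentration
#' @export
volumetric_concentration <- function(count, volume_m3) {
  .check_conc_args(count, volume_m3)
  count / volume_m3
}

.check_conc_args <- function(count, volume_m3) {
  if (any(volume_m3 <= 0)) stop("`volume_m3` must be > 0", call. = FALSE)
  if (any(count < 0)) stop("`count` must be >= 0", call. = FALSE)
  invisible(NULL)
}

#' Preservation-corrected zooplankton dry mass
#'
#' Formalin preservation dissolves part of the biomass before weighing; a
#' 20% correction factor compensates, i.e. measured mass times 1.20.
#'
#' @param raw_mg Measured dry mass, mg (>= 0). Vectorized.
#' @return Corrected dry mass, mg.
#' @export
zoop_corrected_mass <- function(raw_mg) {
  if (any(raw_mg < 0)) stop("`raw_mg` must be >= 0", call. = FALSE)
  raw_mg * 1.20
}

#' Zooplankton removal equivalent of a plastic:plankton ratio
#'
#' Given the ratio of microplastic dry mass to zooplankton dry mass in the
#' neuston, any scheme that filters the surface layer removes
#' `1000 / ratio` mg of dry zooplankton biomass for each gram of plastic it
#' removes, and `carbon_fraction` of that as carbon. At the North Pacific
#' Subtropical Gyre median ratio of 1.368 this is about 731 mg of
#' zooplankton (and 292.4 mg carbon at a 0.40 carbon fraction) per gram of
#' plastic.
#'
#' @param ratio Plastic dry mass / zooplankton dry mass (> 0).
#' @param carbon_fraction Carbon content as a fraction of zooplankton dry
#'   mass; default 0.40.
#' @return An object of class `ratio_result`: `ratio`,
#'   `zoop_removed_mg_per_g`, `carbon_removed_mg_per_g`, `carbon_fraction`.
#' @examples
#' removal_equivalents(1.368)
#' @export
removal_equivalents <- function(ratio, carbon_fraction = 0.40) {
  if (!is.numeric(ratio) || length(ratio) != 1 || ratio <= 0)
    stop("`ratio` must be a single positive number", call. = FALSE)
  if (carbon_fraction < 0 || carbon_fraction > 1)
    stop("`carbon_fraction` must be in [0, 1]", call. = FALSE)
  zoop <- 1000 / ratio
  structure(list(
    ratio = ratio,
    zoop_removed_mg_per_g = zoop,
    carbon_removed_mg_per_g = zoop * carbon_fraction,
    carbon_fraction = carbon_fraction
  ), class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  cat("Plastic:plankton removal equivalents\n")
  cat(sprintf("  dry-mass ratio:        %.3f\n", x$ratio))
  cat(sprintf("  zooplankton removed:   %.1f mg per g plastic\n",
              x$zoop_removed_mg_per_g))
  cat(sprintf("  carbon removed:        %.1f mg per g plastic (fraction %.2f)\n",
              x$carbon_removed_mg_per_g, x$carbon_fraction))
  invisible(x)
}

#' Robust summary of a skewed sample with a bootstrap CI of the median
#'
#' Concentration data from surface tows are strongly right-skewed, so the
#' summary is built around order statistics: median, 5th and 95th
#' percentiles (linear interpolation, type 7), the coefficient of variation
#' in percent, and a percentile-bootstrap confidence interval for the
#' median.
#'
#' @param x Numeric sample, `n >= 1` (bootstrap needs `n >= 2`).
#' @param B Bootstrap resamples; default 1000.
#' @param conf Confidence level; default 0.95.
#' @param seed Optional integer seed for the bootstrap.
#' @return An object of class `summary_stats`: `median`, `p5`, `p95`,
#'   `max`, `cv_percent`, `boot_ci_lo`, `boot_ci_hi`, `n`.
#' @export
summarize_values <- function(x, B = 1000, conf = 0.95, seed = NULL) {
  x <- x[!is.na(x)]
  if (length(x) < 1) stop("`x` must contain at least one value", call. = FALSE)
  q <- stats::quantile(x, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  cv <- if (mean(x) == 0) NA_real_ else 100 * stats::sd(x) / mean(x)
  ci <- c(NA_real_, NA_real_)
  if (length(x) >= 2) {
    if (!is.null(seed)) set.seed(seed)
    meds <- vapply(seq_len(B), function(i)
      stats::median(sample(x, replace = TRUE)), numeric(1))
    ci <- stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          type = 7, names = FALSE)
  }
  structure(list(
    median = q[2], p5 = q[1], p95 = q[3], max = max(x),
    cv_percent = cv, boot_ci_lo = ci[1], boot_ci_hi = ci[2],
    n = length(x)
  ), class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d  median = %.4g [boot CI %.4g, %.4g]\n",
              x$n, x$median, x$boot_ci_lo, x$boot_ci_hi))
  cat(sprintf("p5 = %.4g  p95 = %.4g  max = %.4g  CV = %.1f%%\n",
              x$p5, x$p95, x$max, x$cv_percent))
  invisible(x)
}

#' Anomalies about the series mean
#'
#' Subtracts the overall mean, as used to compare particle-concentration
#' anomalies with wind-speed anomalies; the output sums to zero.
#'
#' @param x Numeric vector, `n >= 1`.
#' @return `x - mean(x)`.
#' @export
anomaly <- function(x) {
  if (length(x) < 1) stop("`x` must be non-empty", call. = FALSE)
  x - mean(x)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`. Ties get average
#'   ranks.
#' @return List with `rho` and `p` (two-sided).
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 3) stop("need n >= 3", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value)
}

#' Nonparametric comparisons of concentration groups
#'
#' For two groups, the Mann-Whitney U test (normal approximation with tie
#' and continuity correction); for any number of groups, the Kruskal-Wallis
#' test; and pairwise post-hoc rank-sum comparisons with Holm family-wise
#' adjustment (a simpler procedure with the same decision structure as the
#' Nemenyi-Damico-Wolfe-Dunn joint-ranking test).
#'
#' @param groups Named list of numeric vectors, at least two, none empty.
#' @return List with `kruskal` (`statistic`, `p`), `mann_whitney`
#'   (`U`, `p`; only when exactly two groups), and `pairwise_p` (matrix of
#'   Holm-adjusted p-values; only when more than two groups).
#' @export
rank_tests <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("`groups` must be a list of >= 2 numeric vectors", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all groups must be non-empty", call. = FALSE)
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))

  kw <- stats::kruskal.test(values, g)
  out <- list(kruskal = list(statistic = unname(kw$statistic),
                             p = kw$p.value))
  if (length(groups) == 2) {
    w <- suppressWarnings(stats::wilcox.test(groups[[1]], groups[[2]],
                                             exact = FALSE, correct = TRUE))
    out$mann_whitney <- list(U = unname(w$statistic), p = w$p.value)
  } else {
    pw <- suppressWarnings(stats::pairwise.wilcox.test(
      values, g, p.adjust.method = "holm", exact = FALSE))
    out$pairwise_p <- pw$p.value
  }
  out
}

#' Theil-Sen single-median regression line
#'
#' The slope is the median of all pairwise slopes over point pairs with
#' distinct x, and the intercept the median of `y - slope * x`; robust to
#' outliers in skewed survey data.
#'
#' @param x,y Numeric vectors of equal length, `n >= 2`, with at least two
#'   distinct `x`.
#' @return List with `slope` and `intercept`.
#' @export
theil_sen <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` lengths differ", call. = FALSE)
  if (length(x) < 2) stop("need n >= 2", call. = FALSE)
  ij <- utils::combn(length(x), 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- dx != 0
  if (!any(keep)) stop("all `x` values are identical", call. = FALSE)
  slopes <- (y[ij[2, ]] - y[ij[1, ]])[keep] / dx[keep]
  slope <- stats::median(slopes)
  list(slope = slope, intercept = stats::median(y - slope * x))
}

#' Per-tow plastic-to-plankton dry-mass ratios
#'
#' Divides the microplastic dry mass of each tow by its
#' preservation-corrected zooplankton dry mass (see
#' [zoop_corrected_mass()]).
#'
#' @param tows Tow data frame with columns `plastic_dry_mg` and
#'   `zoop_dry_mg_raw`.
#' @return Numeric vector of ratios, one per tow.
#' @export
plastic_plankton_ratio <- function(tows) {
  req <- c("plastic_dry_mg", "zoop_dry_mg_raw")
  if (!all(req %in% names(tows)))
    stop("`tows` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  zoop <- zoop_corrected_mass(tows$zoop_dry_mg_raw)
  if (any(zoop <= 0)) stop("zooplankton mass must be > 0", call. = FALSE)
  tows$plastic_dry_mg / zoop
}
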