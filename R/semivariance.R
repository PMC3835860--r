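#' Pairwise great-circle distances between sample locations
#'
#' Station coordinates are geographic (decimal degrees, WGS84), so pairwise
#' separations are computed as haversine great-circle distances on a sphere
#' of radius 6371 km. At basin scales this differs materially from planar
#' distance on raw degrees.
#'
#' @param lat,lon Numeric vectors of equal length (degrees), `n >= 2`.
#' @return Symmetric `n x n` matrix of distances in km.
#' @examples
#' pairwise_distances(c(0, 0), c(0, 1))[1, 2]  # ~111.19 km
#' @export
pairwise_distances <- function(lat, lon) {
  if (length(lat) != length(lon))
    stop("`lat` and `lon` lengths differ", call. = FALSE)
  if (length(lat) < 2) stop("need at least 2 points", call. = FALSE)
  if (any(!is.finite(lat)) || any(!is.finite(lon)) ||
      any(abs(lat) > 90) || any(abs(lon) > 360))
    stop("invalid coordinates", call. = FALSE)
  m <- geosphere::distm(cbind(lon, lat),
                        fun = function(p1, p2)
                          geosphere::distHaversine(p1, p2, r = 6371000))
  m / 1000
}

#' Empirical semivariogram (classical or robust)
#'
#' Bins all unordered location pairs by separation distance and computes the
#' empirical semivariance per bin. The classical estimator is
#' \deqn{\hat\gamma(h) = \frac{1}{2|N(h)|} \sum_{N(h)} (z_i - z_j)^2,}
#' which is sensitive to the strong skew of concentration data. The robust
#' Cressie-Hawkins estimator is based on square-rooted absolute differences,
#' \deqn{\hat\gamma(h) = \frac{\big(\frac{1}{|N(h)|}\sum_{N(h)}
#'   |z_i - z_j|^{1/2}\big)^4}{2\,(0.457 + 0.494/|N(h)|)}.}
#' Bins containing no pairs are omitted.
#'
#' @param values Numeric measurements `z_i`, one per location.
#' @param lat,lon Coordinates in decimal degrees.
#' @param bin_edges_km Optional distance-bin edges (km). Default: `n_bins`
#'   equal-width bins from 0 to half the maximum pairwise distance.
#' @param estimator `"robust"` (default) or `"classical"`.
#' @param n_bins Number of default bins; default 15.
#' @return A data frame of class `semivariogram` with columns
#'   `bin_center_km`, `gamma`, `n_pairs`; attributes `estimator` and
#'   `bin_edges_km`.
#' @export
empirical_semivariogram <- function(values, lat, lon,
                                    bin_edges_km = NULL,
                                    estimator = c("robust", "classical"),
                                    n_bins = 15) {
  estimator <- match.arg(estimator)
  if (length(values) != length(lat))
    stop("`values` and coordinates lengths differ", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  d <- pairwise_distances(lat, lon)
  lt <- lower.tri(d)
  h <- d[lt]
  dz <- outer(values, values, "-")[lt]

  if (is.null(bin_edges_km))
    bin_edges_km <- seq(0, max(h) / 2, length.out = n_bins + 1)
  if (any(diff(bin_edges_km) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)

  bins <- cut(h, bin_edges_km, include.lowest = TRUE)
  keep <- !is.na(bins)
  if (!any(keep)) stop("no pairs fall within the bin edges", call. = FALSE)
  h <- h[keep]; dz <- dz[keep]; bins <- droplevels(bins[keep])

  centers <- (bin_edges_km[-1] + bin_edges_km[-length(bin_edges_km)]) / 2
  names(centers) <- levels(cut(centers, bin_edges_km, include.lowest = TRUE))

  gam <- tapply(dz, bins, function(v) {
    m <- length(v)
    if (estimator == "classical") sum(v^2) / (2 * m)
    else mean(sqrt(abs(v)))^4 / (2 * (0.457 + 0.494 / m))
  })
  npairs <- as.integer(table(bins))

  out <- data.frame(
    bin_center_km = unname(centers[names(gam)]),
    gamma = as.numeric(gam),
    n_pairs = npairs
  )
  out <- out[order(out$bin_center_km), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("semivariogram", "data.frame"),
            estimator = estimator, bin_edges_km = bin_edges_km)
}

#' Fit a linear or Gaussian model to an empirical semivariogram
#'
#' Weighted least squares with the per-bin pair counts as weights. The
#' linear family is `gamma(h) = a + b h` (the slope may be negative). The
#' Gaussian family is `gamma(h) = tau2 + sigma2 (1 - exp(-(h/phi)^2))` with
#' nugget `tau2 >= 0`, partial sill `sigma2 >= 0` and range parameter
#' `phi > 0`; under this parameterization the practical range (where the
#' model reaches ~95% of the sill) is `phi * sqrt(3)` and is reported
#' alongside `phi`. The Gaussian fit is multi-started over `phi` to avoid
#' local minima.
#'
#' @param emp A [empirical_semivariogram()] result, or any data frame with
#'   `bin_center_km`, `gamma`, `n_pairs`.
#' @param family `"linear"` or `"gaussian"`.
#' @return An object of class `variogram_model`: `family`, `params`
#'   (named vector), `objective` (weighted SSE), `fitted`, and for the
#'   Gaussian family `practical_range_km`.
#' @export
fit_variogram <- function(emp, family = c("linear", "gaussian")) {
  family <- match.arg(family)
  req <- c("bin_center_km", "gamma", "n_pairs")
  if (!all(req %in% names(emp)))
    stop("`emp` needs columns ", paste(req, collapse = ", "), call. = FALSE)
  h <- emp$bin_center_km; g <- emp$gamma; w <- emp$n_pairs
  min_bins <- if (family == "linear") 3 else 4
  if (length(h) < min_bins)
    stop("need at least ", min_bins, " bins for the ", family, " family",
         call. = FALSE)

  if (family == "linear") {
    fit <- stats::lm(g ~ h, weights = w)
    co <- stats::coef(fit)
    params <- c(intercept = unname(co[1]), slope = unname(co[2]))
    fitted <- unname(stats::fitted(fit))
    obj <- sum(w * (g - fitted)^2)
    return(structure(list(family = family, params = params,
                          objective = obj, fitted = fitted,
                          bin_center_km = h),
                     class = "variogram_model"))
  }

  model <- function(p, h) p[1] + p[2] * (1 - exp(-(h / p[3])^2))
  obj_fn <- function(p) sum(w * (g - model(p, h))^2)
  tau0 <- max(min(g), 0)
  sill0 <- max(max(g) - min(g), 1e-8 + 0.1 * abs(max(g)))
  phi_starts <- stats::quantile(h, c(0.1, 0.25, 0.5, 0.75, 0.9), names = FALSE)
  phi_starts <- unique(pmax(phi_starts, 1e-6))
  best <- NULL
  for (phi0 in phi_starts) {
    res <- try(stats::optim(c(tau0, sill0, phi0), obj_fn,
                            method = "L-BFGS-B",
                            lower = c(0, 0, 1e-6),
                            upper = c(Inf, Inf, 50 * max(h)),
                            control = list(factr = 1e4, maxit = 500)),
               silent = TRUE)
    if (inherits(res, "try-error")) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("Gaussian variogram fit failed to converge from every start; ",
         "check the empirical semivariogram for degenerate bins",
         call. = FALSE)
  params <- c(tau2 = best$par[1], sigma2 = best$par[2], phi = best$par[3])
  structure(list(family = family, params = params,
                 objective = best$value,
                 fitted = model(best$par, h),
                 bin_center_km = h,
                 practical_range_km = best$par[3] * sqrt(3)),
            class = "variogram_model")
}

#' Evaluate a fitted variogram model at new distances
#'
#' @param object A `variogram_model`.
#' @param h Distances (km).
#' @param ... Unused.
#' @return Model semivariance at `h`.
#' @export
predict.variogram_model <- function(object, h, ...) {
  p <- object$params
  if (object$family == "linear") p["intercept"] + p["slope"] * h
  else p["tau2"] + p["sigma2"] * (1 - exp(-(h / p["phi"])^2))
}

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("Variogram model: %s\n", x$family))
  print(round(x$params, 6))
  if (!is.null(x$practical_range_km))
    cat(sprintf("practical range: %.3f km\n", x$practical_range_km))
  cat(sprintf("weighted SSE: %.6g\n", x$objective))
  invisible(x)
}
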