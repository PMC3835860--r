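# Detection functions g(x): probability of detecting an item at
# perpendicular distance x from the trackline.
.g_fun <- function(family, params) {
  switch(family,
    uniform = function(x) rep(1, length(x)),
    half_normal = function(x) exp(-x^2 / (2 * params[["sigma"]]^2)),
    hazard_rate = function(x) {
      g <- 1 - exp(-(x / params[["scale"]])^(-params[["shape"]]))
      g[x == 0] <- 1
      g
    },
    stop("unknown detection family: ", family, call. = FALSE))
}

# integral of g over [a, b]; closed form where available
.g_integral <- function(family, params, a, b) {
  if (family == "uniform") return(b - a)
  if (family == "half_normal") {
    s <- params[["sigma"]]
    return(s * sqrt(2 * pi) * (stats::pnorm(b / s) - stats::pnorm(a / s)))
  }
  g <- .g_fun(family, params)
  mapply(function(lo, hi)
    stats::integrate(g, lo, hi, rel.tol = 1e-9)$value, a, b)
}

# multinomial cell probabilities over the closed bins, given g
.bin_probs <- function(family, params, edges) {
  ints <- .g_integral(family, params,
                      edges[-length(edges)], edges[-1])
  ints / sum(ints)
}

.n_params <- c(uniform = 0L, half_normal = 1L, hazard_rate = 2L)

#' Fit a detection function to binned perpendicular distances
#'
#' Maximizes the multinomial log-likelihood of the per-bin sighting counts,
#' with cell probabilities proportional to the integral of the detection
#' function `g(x)` over each bin (items are assumed uniformly distributed
#' in perpendicular distance out to the truncation distance `W`, the last
#' closed bin edge). Supported families: `uniform` (`g = 1`, 0 parameters),
#' `half_normal` (`g = exp(-x^2/2\sigma^2)`, 1 parameter) and
#' `hazard_rate` (`g = 1 - exp(-(x/s)^{-b})`, 2 parameters). The open
#' `>W` bin, if present in the data, must be dropped before fitting: an
#' unbounded bin has no finite integral for a uniform detection function.
#'
#' Optimization is on the log-parameter scale: golden-section search for the
#' half-normal, bounded quasi-Newton (L-BFGS-B) from a fixed grid of
#' restarts for the hazard-rate.
#'
#' @param counts Integer sighting counts per closed bin
#'   (`length(edges) - 1` values).
#' @param bin_edges_m Strictly increasing closed bin edges, m; last edge is
#'   the truncation distance `W`. Default [distance_bin_edges()].
#' @param family Detection family.
#' @param min_count Minimum total count required to fit; default 10.
#' @return An object of class `detection_fit`: `family`, `params`,
#'   `loglik`, `aic` (`2k - 2 loglik`), `esw_m`, `truncation_W_m`,
#'   `counts`, `bin_edges_m`, `flagged` (TRUE when all counts fall in a
#'   single bin, a degenerate configuration).
#' @export
fit_detection <- function(counts,
                          bin_edges_m = distance_bin_edges(),
                          family = c("half_normal", "uniform", "hazard_rate"),
                          min_count = 10) {
  family <- match.arg(family)
  edges <- bin_edges_m
  if (any(diff(edges) <= 0))
    stop("bin edges must be strictly increasing", call. = FALSE)
  if (length(counts) != length(edges) - 1)
    stop("`counts` must have one value per closed bin", call. = FALSE)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  n <- sum(counts)
  if (n < min_count)
    stop("need at least ", min_count, " sightings within the truncation ",
         "distance to fit a detection function", call. = FALSE)
  W <- edges[length(edges)]
  flagged <- sum(counts > 0) == 1

  loglik_for <- function(params) {
    p <- .bin_probs(family, params, edges)
    # probabilities underflow at extreme parameters; keep the surface finite
    if (any(!is.finite(p)) || any(p <= 0 & counts > 0)) return(-1e10)
    stats::dmultinom(counts, prob = p, log = TRUE)
  }

  if (family == "uniform") {
    params <- numeric(0)
    ll <- loglik_for(params)
  } else if (family == "half_normal") {
    opt <- stats::optimize(function(ls) -loglik_for(c(sigma = exp(ls))),
                           interval = log(c(W / 1000, W * 100)),
                           tol = 1e-9)
    params <- c(sigma = exp(opt$minimum))
    ll <- -opt$objective
  } else {
    starts <- expand.grid(scale = W * c(0.05, 0.15, 0.4, 0.8),
                          shape = c(1.5, 3, 6))
    best <- NULL
    for (i in seq_len(nrow(starts))) {
      res <- try(stats::optim(
        log(as.numeric(starts[i, ])),
        function(lp) -loglik_for(c(scale = exp(lp[1]), shape = exp(lp[2]))),
        method = "L-BFGS-B",
        lower = log(c(W / 1e4, 0.2)), upper = log(c(W * 100, 50)),
        control = list(factr = 1e4, maxit = 500)), silent = TRUE)
      if (inherits(res, "try-error")) next
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (is.null(best))
      stop("hazard-rate fit failed to converge from every start",
           call. = FALSE)
    params <- c(scale = exp(best$par[1]), shape = exp(best$par[2]))
    ll <- -best$value
  }

  k <- .n_params[[family]]
  fit <- structure(list(
    family = family, params = params, loglik = ll,
    aic = 2 * k - 2 * ll,
    esw_m = NA_real_, truncation_W_m = W,
    counts = counts, bin_edges_m = edges, flagged = flagged
  ), class = "detection_fit")
  fit$esw_m <- esw(fit)
  fit
}

#' @export
print.detection_fit <- function(x, ...) {
  cat(sprintf("Detection fit: %s (W = %g m)%s\n", x$family,
              x$truncation_W_m,
              if (x$flagged) "  [flagged: degenerate counts]" else ""))
  if (length(x$params))
    cat("  params:", paste(names(x$params),
                           signif(x$params, 5), sep = " = ",
                           collapse = ", "), "\n")
  cat(sprintf("  loglik = %.3f  AIC = %.3f  ESW = %.2f m\n",
              x$loglik, x$aic, x$esw_m))
  invisible(x)
}

#' Effective strip width of a fitted detection function
#'
#' The ESW is the width of a perfectly detected strip with the same
#' expected sighting count as the fitted decaying detection function:
#' `ESW = integral of g(x) dx from 0 to W`, computed by adaptive quadrature
#' at relative tolerance 1e-8. For a uniform `g` the ESW equals the
#' truncation distance `W`; for a half-normal it equals
#' `sigma * sqrt(pi/2) * erf(W / (sigma * sqrt(2)))`.
#'
#' @param fit A [fit_detection()] result.
#' @return ESW in metres, in `(0, W]`.
#' @export
esw <- function(fit) {
  if (!inherits(fit, "detection_fit"))
    stop("`fit` must be a detection_fit", call. = FALSE)
  g <- .g_fun(fit$family, fit$params)
  stats::integrate(g, 0, fit$truncation_W_m, rel.tol = 1e-8)$value
}

#' Fit several detection families and select by AIC
#'
#' @inheritParams fit_detection
#' @param families Character vector of families to try.
#' @return The best `detection_fit` (minimum AIC), with an `aic_table`
#'   attribute (data frame of family, AIC, ESW).
#' @export
select_detection <- function(counts,
                             bin_edges_m = distance_bin_edges(),
                             families = c("uniform", "half_normal",
                                          "hazard_rate"),
                             min_count = 10) {
  fits <- lapply(families, function(f)
    fit_detection(counts, bin_edges_m, family = f, min_count = min_count))
  aics <- vapply(fits, function(f) f$aic, numeric(1))
  best <- fits[[which.min(aics)]]
  attr(best, "aic_table") <- data.frame(
    family = families, aic = aics,
    esw_m = vapply(fits, function(f) f$esw_m, numeric(1)))
  best
}

#' Group densities standardized to the widest effective strip width
#'
#' Each debris group's correction factor is
#' `CF_g = ESW_max / ESW_g`, standardizing its apparent density to the group
#' with the widest ESW. The corrected number of sightings is
#' `n_g * CF_g`, and the density is the corrected count divided by the
#' effective area surveyed (survey distance times the maximum ESW,
#' one-sided), which is algebraically `n_g / (L * ESW_g)`.
#'
#' @param fits Named list of `detection_fit` objects, one per group; all
#'   must share the same truncation distance.
#' @param counts Named vector of sighting counts per group (same names).
#' @param L_km Total survey track length, km (> 0).
#' @return Data frame of class `group_density`: `group`, `esw_m`, `cf`,
#'   `n`, `corrected_n`, `density_per_km2`.
#' @export
densities <- function(fits, counts, L_km) {
  if (L_km <= 0) stop("`L_km` must be > 0", call. = FALSE)
  if (is.null(names(fits)) || !all(names(fits) %in% names(counts)))
    stop("`fits` and `counts` must share group names", call. = FALSE)
  W <- vapply(fits, function(f) f$truncation_W_m, numeric(1))
  if (length(unique(W)) != 1)
    stop("all groups must share the truncation distance", call. = FALSE)
  eswv <- vapply(fits, function(f) f$esw_m, numeric(1))
  if (any(eswv <= 0)) stop("zero effective strip width", call. = FALSE)
  counts <- counts[names(fits)]
  esw_max <- max(eswv)
  cf <- esw_max / eswv
  corrected <- counts * cf
  dens <- corrected / (L_km * esw_max / 1000)  # ESW m -> km, one-sided
  out <- data.frame(group = names(fits), esw_m = eswv, cf = cf,
                    n = as.numeric(counts), corrected_n = corrected,
                    density_per_km2 = dens, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("group_density", "data.frame")
  out
}

# tabulate sightings of one group into closed-bin counts
.bin_counts <- function(distance_bin, edges) {
  labels <- distance_bin_labels(edges, open_top = FALSE)
  tab <- table(factor(distance_bin, levels = labels))
  as.integer(tab)
}

#' Bootstrap confidence intervals for group densities
#'
#' Resamples transect segments with replacement, re-tabulates the sightings
#' attached to the sampled segments (with multiplicity), refits the
#' detection function per group, recomputes densities, and returns
#' percentile confidence intervals.
#'
#' @param sightings Data frame with `segment_id`, `size_class`,
#'   `color_class`, `distance_bin` (labels from [distance_bin_labels()];
#'   any open-bin rows are dropped).
#' @param segments Data frame with `segment_id`, `length_km`; `>= 2` rows.
#' @param bin_edges_m Closed bin edges, m.
#' @param family Detection family used in each replicate.
#' @param group_cols Columns defining a debris group.
#' @param B Bootstrap replicates; fewer than 100 triggers a warning.
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @param min_count Minimum per-group count for refitting; replicates where
#'   a group cannot be refitted are dropped for that group.
#' @return Data frame: `group`, `density_per_km2` (point estimate),
#'   `ci_lo`, `ci_hi`, `n_boot_used`.
#' @export
bootstrap_density_ci <- function(sightings, segments,
                                 bin_edges_m = distance_bin_edges(),
                                 family = "half_normal",
                                 group_cols = c("size_class", "color_class"),
                                 B = 500, conf = 0.95, seed = NULL,
                                 min_count = 10) {
  if (nrow(segments) < 2)
    stop("need at least 2 segments to bootstrap", call. = FALSE)
  if (B < 100) warning("B < 100 bootstrap replicates; intervals are noisy")
  if (!is.null(seed)) set.seed(seed)

  labels_closed <- distance_bin_labels(bin_edges_m, open_top = FALSE)
  s <- sightings[sightings$distance_bin %in% labels_closed, , drop = FALSE]
  grp <- interaction(s[group_cols], drop = TRUE, sep = ":")
  groups <- levels(grp)

  point <- .density_from_tables(s, grp, groups, segments$length_km,
                                bin_edges_m, family, min_count)

  boot <- matrix(NA_real_, nrow = B, ncol = length(groups),
                 dimnames = list(NULL, groups))
  for (b in seq_len(B)) {
    idx <- sample(nrow(segments), replace = TRUE)
    L_b <- sum(segments$length_km[idx])
    pieces <- lapply(idx, function(i)
      which(s$segment_id == segments$segment_id[i]))
    rows <- unlist(pieces)
    sb <- s[rows, , drop = FALSE]
    gb <- factor(as.character(grp)[rows], levels = groups)
    boot[b, ] <- .density_from_tables(sb, gb, groups, NULL, bin_edges_m,
                                      family, min_count, L_km = L_b)
  }
  alpha <- (1 - conf) / 2
  ci <- t(apply(boot, 2, function(col) {
    col <- col[is.finite(col)]
    if (length(col) < 2) return(c(NA_real_, NA_real_, 0))
    c(stats::quantile(col, c(alpha, 1 - alpha), names = FALSE), length(col))
  }))
  data.frame(group = groups,
             density_per_km2 = point,
             ci_lo = ci[, 1], ci_hi = ci[, 2],
             n_boot_used = as.integer(ci[, 3]),
             stringsAsFactors = FALSE)
}

# densities for each group from a sightings table; returns named vector
.density_from_tables <- function(s, grp, groups, lengths_km, edges, family,
                                 min_count, L_km = NULL) {
  if (is.null(L_km)) L_km <- sum(lengths_km)
  out <- stats::setNames(rep(NA_real_, length(groups)), groups)
  for (g in groups) {
    cnt <- .bin_counts(s$distance_bin[grp == g], edges)
    if (sum(cnt) < min_count) next
    fit <- try(fit_detection(cnt, edges, family = family,
                             min_count = min_count), silent = TRUE)
    if (inherits(fit, "try-error")) next
    out[g] <- sum(cnt) / (L_km * fit$esw_m / 1000)
  }
  out
}
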