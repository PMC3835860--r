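# derive a reproducible per-cell seed below 2^31 from a master seed
.cell_seed <- function(master, index) {
  as.integer((as.numeric(master) + 100003 * as.numeric(index)) %% 2147483647)
}

#' Monte Carlo power of the Mann-Whitney U test for abundance change
#'
#' Estimates the power to detect a multiplicative increase in right-skewed
#' concentration data. For each `(factor, n)` cell, both groups are drawn by
#' resampling the empirical base sample with replacement; the treatment
#' group is multiplied by the factor of increase; a two-sided Mann-Whitney
#' U test (normal approximation with tie and continuity correction) is run
#' at level `alpha`; power is the fraction of `reps` simulations with
#' `p < alpha`. A master seed spawns an independent substream per cell, so
#' each cell is reproducible in isolation.
#'
#' @param base Numeric base sample of concentrations (`n >= 2`).
#' @param factors Multiplicative factors of increase (> 0), e.g. 1.2 for a
#'   20% increase.
#' @param n_values Per-group sample sizes.
#' @param reps Simulations per cell; default 1000, minimum 100.
#' @param alpha Test level in (0, 1); default 0.05.
#' @param seed Optional master seed.
#' @return Data frame of class `power_result`: `factor`, `n`, `power`,
#'   `mc_se` (`sqrt(power (1 - power) / reps)`).
#' @export
mc_power <- function(base, factors, n_values, reps = 1000, alpha = 0.05,
                     seed = NULL) {
  base <- base[!is.na(base)]
  if (length(base) < 2) stop("`base` must have n >= 2", call. = FALSE)
  if (any(factors <= 0)) stop("factors must be > 0", call. = FALSE)
  if (reps < 100) stop("`reps` must be >= 100", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)

  grid <- expand.grid(factor = factors, n = n_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$power <- NA_real_
  for (i in seq_len(nrow(grid))) {
    if (!is.null(seed)) set.seed(.cell_seed(seed, i))
    f <- grid$factor[i]; n <- grid$n[i]
    rej <- 0L
    for (r in seq_len(reps)) {
      a <- sample(base, n, replace = TRUE)
      b <- sample(base, n, replace = TRUE) * f
      p <- suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
      if (p < alpha) rej <- rej + 1L
    }
    grid$power[i] <- rej / reps
  }
  grid$mc_se <- sqrt(grid$power * (1 - grid$power) / reps)
  class(grid) <- c("power_result", "data.frame")
  attr(grid, "reps") <- reps
  attr(grid, "alpha") <- alpha
  grid
}

#' Smallest sample size reaching a target power
#'
#' Runs [mc_power()] for one factor over a grid of sample sizes, smooths
#' the power-vs-n curve by isotonic regression (power is monotone in n up
#' to Monte Carlo jitter, and a raw threshold crossing is seed-sensitive),
#' and returns the smallest grid n whose smoothed power reaches the target.
#'
#' @param base Numeric base sample.
#' @param factor Single multiplicative factor of increase.
#' @param target_power Target power in `(alpha, 1)`.
#' @param n_grid Increasing grid of per-group sample sizes.
#' @inheritParams mc_power
#' @return List of class `sample_size_result`: `n` (NA if the target is not
#'   attained on the grid), `attained` (logical), `grid` (data frame with
#'   raw and isotonic-smoothed power).
#' @export
sample_size_for_power <- function(base, factor, target_power = 0.8,
                                  n_grid = seq(10, 500, by = 10),
                                  reps = 1000, alpha = 0.05, seed = NULL) {
  if (target_power <= alpha || target_power >= 1)
    stop("`target_power` must be in (alpha, 1)", call. = FALSE)
  n_grid <- sort(unique(n_grid))
  res <- mc_power(base, factor, n_grid, reps = reps, alpha = alpha,
                  seed = seed)
  iso <- stats::isoreg(res$n, res$power)
  res$power_iso <- iso$yf[order(order(res$n))]
  hit <- which(res$power_iso >= target_power)
  structure(list(
    n = if (length(hit)) res$n[min(hit)] else NA_integer_,
    attained = length(hit) > 0,
    target_power = target_power,
    factor = factor,
    grid = as.data.frame(res)
  ), class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  if (x$attained)
    cat(sprintf("n = %d per group reaches power %.2f at factor %.2f\n",
                x$n, x$target_power, x$factor))
  else
    cat(sprintf("target power %.2f not attained on the grid at factor %.2f\n",
                x$target_power, x$factor))
  invisible(x)
}

#' Sampling-adequacy curve for exponential concentration data
#'
#' Evaluates how the variability of a sample statistic stabilizes with
#' effort when concentrations follow an exponential distribution: for every
#' sample size `n` in `n_values` and each of `sets_per_n` independent sets,
#' draws `n` exponential(rate) deviates and records the sample standard
#' deviation. With the defaults (`n = 2..1000`, 5 sets) this generates
#' 4995 simulated datasets; at large `n` the SD converges to `1/rate`.
#'
#' @param rate Exponential rate, default 1.44 (1/(particles m^-2)).
#' @param n_values Sample sizes; default `2:1000`.
#' @param sets_per_n Independent sets per sample size; default 5.
#' @param seed Optional integer seed.
#' @return Data frame of class `adequacy_curve` with columns `n`, `set`,
#'   `sd`; attribute `rate`.
#' @export
adequacy_curve <- function(rate = 1.44, n_values = 2:1000, sets_per_n = 5,
                           seed = NULL) {
  if (rate <= 0) stop("`rate` must be > 0", call. = FALSE)
  if (any(n_values < 2)) stop("sample sizes must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(set = seq_len(sets_per_n), n = n_values,
                      KEEP.OUT.ATTRS = FALSE)[, c("n", "set")]
  grid$sd <- vapply(grid$n, function(n) stats::sd(stats::rexp(n, rate)),
                    numeric(1))
  rownames(grid) <- NULL
  class(grid) <- c("adequacy_curve", "data.frame")
  attr(grid, "rate") <- rate
  grid
}

#' Maximum-likelihood exponential rate of a concentration sample
#'
#' The MLE of the exponential rate is the reciprocal of the sample mean.
#'
#' @param values Non-negative values, `n >= 2`, positive mean.
#' @return The fitted rate (1/units of `values`).
#' @export
fit_exponential_rate <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need n >= 2", call. = FALSE)
  if (any(values < 0)) stop("values must be >= 0", call. = FALSE)
  m <- mean(values)
  if (m <= 0) stop("mean must be > 0 to fit an exponential rate",
                   call. = FALSE)
  1 / m
}
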