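#' Configuration of the synthetic weekly injury-count generator
#'
#' Describes a weekly count series of the kind the decomposition pipeline
#' targets: about fifteen years of weekly samples with a piecewise-linear
#' long-run trend, a dominant seasonal cycle of about half a year
#' (26 weeks; 17 weeks for the minor-cause analogue), and autocorrelated
#' (red, AR(1)) noise on top.  Default magnitudes give strictly positive
#' counts of a few hundred per week.
#'
#' @param n_weeks Series length (default 780 weekly samples, ~15 years).
#' @param base_level Mean level of the counts (default 300).
#' @param trend_segments List of `c(start_week, slope_per_week)` pairs with
#'   strictly increasing start weeks, the first at week 1; each slope
#'   applies from its start week to the next segment's start.  Default:
#'   rise to week 280, fall to week 348, mild rise thereafter.
#' @param seasonal_period Dominant cycle length in weeks (default 26).
#' @param seasonal_amplitude Amplitude of the dominant cycle (default 40).
#' @param secondary_period Optional second cycle length (default `NULL`).
#' @param secondary_amplitude Amplitude of the second cycle (default 0).
#' @param ar1_coefficient AR(1) coefficient of the noise, in `[0, 1)`
#'   (default 0.6).
#' @param noise_sd Innovation standard deviation of the AR(1) noise
#'   (default 15).
#' @param integer_counts Round the series to whole counts? (default FALSE)
#' @param seed Integer seed (default 1).
#' @return Object of class `"synthetic_series_config"`.
#' @export
synthetic_series_config <- function(n_weeks = 780L, base_level = 300,
                                    trend_segments = list(c(1, 0.35),
                                                          c(280, -0.8),
                                                          c(348, 0.15)),
                                    seasonal_period = 26L,
                                    seasonal_amplitude = 40,
                                    secondary_period = NULL,
                                    secondary_amplitude = 0,
                                    ar1_coefficient = 0.6, noise_sd = 15,
                                    integer_counts = FALSE, seed = 1L) {
  stopifnot(n_weeks >= 3L, base_level > 0, seasonal_period >= 1L,
            seasonal_amplitude >= 0, noise_sd >= 0,
            ar1_coefficient >= 0, ar1_coefficient < 1)
  starts <- vapply(trend_segments, `[`, numeric(1), 1L)
  if (length(starts) == 0L || starts[1L] != 1 || is.unsorted(starts, strictly = TRUE)) {
    stop("`trend_segments` must start at week 1 with strictly increasing start weeks",
         call. = FALSE)
  }
  structure(list(n_weeks = as.integer(n_weeks), base_level = base_level,
                 trend_segments = trend_segments,
                 seasonal_period = as.integer(seasonal_period),
                 seasonal_amplitude = seasonal_amplitude,
                 secondary_period = secondary_period,
                 secondary_amplitude = secondary_amplitude,
                 ar1_coefficient = ar1_coefficient, noise_sd = noise_sd,
                 integer_counts = integer_counts, seed = as.integer(seed)),
            class = "synthetic_series_config")
}

# deterministic part: base + continuous piecewise-linear trend + seasonality
synthetic_deterministic <- function(cfg) {
  t <- seq_len(cfg$n_weeks)
  starts <- vapply(cfg$trend_segments, `[`, numeric(1), 1L)
  slopes <- vapply(cfg$trend_segments, `[`, numeric(1), 2L)
  trend <- numeric(cfg$n_weeks)
  level <- 0
  bounds <- c(starts, cfg$n_weeks + 1L)
  for (s in seq_along(starts)) {
    span <- t >= bounds[s] & t < bounds[s + 1L]
    trend[span] <- level + slopes[s] * (t[span] - starts[s])
    level <- level + slopes[s] * (bounds[s + 1L] - starts[s])
  }
  seas <- cfg$seasonal_amplitude * sin(2 * pi * t / cfg$seasonal_period)
  if (!is.null(cfg$secondary_period) && cfg$secondary_amplitude > 0) {
    seas <- seas + cfg$secondary_amplitude *
      sin(2 * pi * t / cfg$secondary_period)
  }
  cfg$base_level + trend + seas
}

# stationary AR(1) noise, seeded; marginal sd = noise_sd / sqrt(1 - a^2)
synthetic_noise <- function(cfg) {
  if (cfg$noise_sd == 0) return(numeric(cfg$n_weeks))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(cfg$seed)
  innov <- stats::rnorm(cfg$n_weeks, 0, cfg$noise_sd)
  e <- numeric(cfg$n_weeks)
  a <- cfg$ar1_coefficient
  e[1L] <- innov[1L] / sqrt(1 - a^2)
  for (t in seq_len(cfg$n_weeks - 1L)) e[t + 1L] <- a * e[t] + innov[t + 1L]
  e
}

#' Generate a synthetic weekly injury-count series
#'
#' Sums the deterministic structure (base level, piecewise-linear trend,
#' seasonal sinusoids) and seeded AR(1) noise described by the
#' configuration, clamps at zero, and optionally rounds to integer counts.
#' Identical configurations (including seed) give identical series.
#'
#' @param cfg A [synthetic_series_config()].
#' @return Numeric series of length `n_weeks`.
#' @examples
#' x <- generate_injury_series(synthetic_series_config(seed = 7))
#' @export
generate_injury_series <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_series_config"))
  x <- synthetic_deterministic(cfg) + synthetic_noise(cfg)
  x <- pmax(x, 0)
  if (cfg$integer_counts) x <- round(x)
  x
}

#' Generate the series' two ground-truth components separately
#'
#' Returns the additive parts of [generate_injury_series()] before clamping
#' and rounding: `c_L` is the smooth deterministic part (trend plus
#' seasonality) and `c_H` the zero-mean AR(1) noise.  Useful for testing
#' forecasting stages with a known decomposition, bypassing MSVD/SWT.
#'
#' @param cfg A [synthetic_series_config()].
#' @return List with `c_L` and `c_H`, whose sum equals the unclamped series
#'   for the same configuration.
#' @export
generate_component_pair <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_series_config"))
  list(c_L = synthetic_deterministic(cfg), c_H = synthetic_noise(cfg))
}

#' Generate a noisy linear multi-output regression fixture
#'
#' Draws a full-rank regressor matrix and a true coefficient matrix, and
#' forms targets `z %*% t(beta_true)` plus optional white noise — the
#' standard recovery fixture for the MIMO-AR least-squares fit.
#'
#' @param rows Number of rows (> 2P).
#' @param P Lags per component (z has 2P columns).
#' @param tau Number of outputs.
#' @param noise_sd Standard deviation of additive target noise (default 0).
#' @param seed Integer seed.
#' @return List with `reg` (a `"regressor_set"` with `z` and `targets`) and
#'   `beta_true` (`tau x 2P`).
#' @export
generate_linear_mimo_fixture <- function(rows, P, tau, noise_sd = 0,
                                         seed = 1L) {
  stopifnot(rows > 2L * P, P >= 1L, tau >= 1L, noise_sd >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  z <- matrix(stats::rnorm(rows * 2L * P), rows, 2L * P)
  beta_true <- matrix(stats::rnorm(tau * 2L * P), tau, 2L * P)
  targets <- z %*% t(beta_true)
  if (noise_sd > 0) {
    targets <- targets + matrix(stats::rnorm(rows * tau, 0, noise_sd),
                                rows, tau)
  }
  reg <- structure(list(z = z, targets = targets, row_index = seq_len(rows),
                        P = P, tau = tau),
                   class = "regressor_set")
  list(reg = reg, beta_true = beta_true)
}
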