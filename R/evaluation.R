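check_pair <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2L) stop("need at least 2 observations", call. = FALSE)
  if (!all(is.finite(observed)) || !all(is.finite(predicted))) {
    stop("non-finite values in metric inputs", call. = FALSE)
  }
  invisible(NULL)
}

#' Normalised root mean square error
#'
#' RMSE divided by the mean of the observations; reported on the natural
#' scale (multiply by 100 to quote a percentage).
#'
#' @param observed,predicted Equal-length numeric vectors; `mean(observed)`
#'   must be nonzero.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(observed, predicted) {
  check_pair(observed, predicted)
  xbar <- mean(observed)
  if (xbar == 0) stop("nRMSE undefined: mean of observations is zero",
                      call. = FALSE)
  sqrt(mean((observed - predicted)^2)) / xbar
}

#' Sum of absolute errors and of absolute deviations
#'
#' The two building blocks of the absolute-value skill scores:
#' `SAE = sum(|predicted - observed|)` and
#' `SAD = sum(|observed - mean(observed)|)`.
#'
#' @inheritParams nrmse
#' @return Named list with `SAE` and `SAD`.
#' @export
sae_sad <- function(observed, predicted) {
  check_pair(observed, predicted)
  list(SAE = sum(abs(predicted - observed)),
       SAD = sum(abs(observed - mean(observed))))
}

#' Modified Nash-Sutcliffe efficiency
#'
#' `1 - SAE/SAD`: the absolute-value form of the Nash-Sutcliffe score,
#' less sensitive to extremes than the squared form.  Equals 1 for a
#' perfect forecast and 0 for the mean predictor; unbounded below.
#'
#' @inheritParams nrmse
#' @return Scalar <= 1.
#' @export
mnse <- function(observed, predicted) {
  s <- sae_sad(observed, predicted)
  if (s$SAD == 0) stop("mNSE undefined: observations are constant (SAD = 0)",
                       call. = FALSE)
  1 - s$SAE / s$SAD
}

#' Modified index of agreement
#'
#' Two-branch absolute-value index: `1 - SAE/(2 SAD)` when `SAE <= 2 SAD`,
#' otherwise `2 SAD / SAE - 1`; the `2 SAD` term balances the number of
#' deviations in numerator and denominator, and the two branches meet
#' continuously at 0.  Range `(-1, 1]`, 1 only for a perfect forecast.
#'
#' @inheritParams nrmse
#' @return Scalar in `(-1, 1]`.
#' @export
mia <- function(observed, predicted) {
  s <- sae_sad(observed, predicted)
  if (s$SAD == 0) stop("mIA undefined: observations are constant (SAD = 0)",
                       call. = FALSE)
  if (s$SAE <= 2 * s$SAD) 1 - s$SAE / (2 * s$SAD) else 2 * s$SAD / s$SAE - 1
}

#' Per-horizon forecast evaluation table
#'
#' Evaluates each forecast horizon (column) with nRMSE, mNSE and mIA and
#' appends the customary summary rows: Min, Max, and means over horizons
#' 1-8, 1-13 and 1-tau (each mean only when tau reaches that range).
#' Values are kept on the natural scale; use `percent = TRUE` in
#' [format_horizon_metrics()] or `print()` to report x100.
#'
#' @param observed,predicted Matrices of equal shape: rows are forecast
#'   origins, columns horizons `1..tau`.
#' @return Object of class `"horizon_metrics"`: list with `per_horizon`
#'   (data frame: horizon, nrmse, mnse, mia) and `summary` (data frame:
#'   label, nrmse, mnse, mia).
#' @export
evaluate_horizons <- function(observed, predicted) {
  if (is.null(dim(observed))) observed <- matrix(observed, ncol = 1L)
  if (is.null(dim(predicted))) predicted <- matrix(predicted, ncol = 1L)
  if (!all(dim(observed) == dim(predicted))) {
    stop("`observed` and `predicted` must have identical shape", call. = FALSE)
  }
  tau <- ncol(observed)
  per <- data.frame(
    horizon = seq_len(tau),
    nrmse = vapply(seq_len(tau), function(h) nrmse(observed[, h], predicted[, h]),
                   numeric(1)),
    mnse = vapply(seq_len(tau), function(h) mnse(observed[, h], predicted[, h]),
                  numeric(1)),
    mia = vapply(seq_len(tau), function(h) mia(observed[, h], predicted[, h]),
                 numeric(1))
  )
  agg <- function(label, rows, fun) {
    data.frame(label = label, nrmse = fun(per$nrmse[rows]),
               mnse = fun(per$mnse[rows]), mia = fun(per$mia[rows]))
  }
  summ <- rbind(agg("Min", seq_len(tau), min), agg("Max", seq_len(tau), max))
  if (tau > 8L) summ <- rbind(summ, agg("Mean 1-8", 1:8, mean))
  if (tau > 13L) summ <- rbind(summ, agg("Mean 1-13", 1:13, mean))
  summ <- rbind(summ, agg(sprintf("Mean 1-%d", tau), seq_len(tau), mean))
  structure(list(per_horizon = per, summary = summ, tau = tau),
            class = "horizon_metrics")
}

#' Format a horizon metrics table for reporting
#'
#' @param x `"horizon_metrics"` object.
#' @param percent Multiply metrics by 100 (the conventional reporting
#'   scale)? Default TRUE.
#' @param digits Significant digits (default 4).
#' @return Data frame combining per-horizon and summary rows, first column
#'   `horizon` holding the horizon number or summary label.
#' @export
format_horizon_metrics <- function(x, percent = TRUE, digits = 4L) {
  stopifnot(inherits(x, "horizon_metrics"))
  f <- if (percent) 100 else 1
  per <- data.frame(horizon = as.character(x$per_horizon$horizon),
                    nrmse = signif(f * x$per_horizon$nrmse, digits),
                    mnse = signif(f * x$per_horizon$mnse, digits),
                    mia = signif(f * x$per_horizon$mia, digits))
  summ <- data.frame(horizon = x$summary$label,
                     nrmse = signif(f * x$summary$nrmse, digits),
                     mnse = signif(f * x$summary$mnse, digits),
                     mia = signif(f * x$summary$mia, digits))
  rbind(per, summ)
}

#' @export
print.horizon_metrics <- function(x, percent = TRUE, ...) {
  cat(sprintf("Forecast skill per horizon (tau = %d)%s\n", x$tau,
              if (percent) ", in percent" else ""))
  print(format_horizon_metrics(x, percent = percent), row.names = FALSE)
  invisible(x)
}

#' Fourier power spectrum with an AR(1) red-noise background
#'
#' Periodogram of the mean-removed series over the positive frequencies
#' below Nyquist, with a theoretical AR(1) ("red noise") background
#' spectrum whose lag-1 coefficient is estimated from the series and whose
#' level is scaled to the mean periodogram power.  A peak is flagged
#' significant when its power exceeds the background times the chi-squared
#' (2 d.o.f.) quantile at the chosen confidence, the standard red-noise
#' significance convention.
#'
#' @param x Numeric series, length >= 32.
#' @param confidence Significance level in (0, 1), default 0.95.
#' @return Object of class `"fps"`: list with `table` (data frame:
#'   `k`, `frequency` (cycles/sample), `period` (samples), `power`,
#'   `background`, `threshold`, `significant`), `dominant_period` (rounded
#'   period of the highest-power peak, ties toward the longer period),
#'   `dominant_significant`, `ar1`, `confidence`, `n`.
#' @export
fourier_power_spectrum <- function(x, confidence = 0.95) {
  x <- check_series(x, min_length = 32L)
  if (!(confidence > 0 && confidence < 1)) {
    stop("`confidence` must lie in (0, 1)", call. = FALSE)
  }
  n <- length(x)
  xc <- x - mean(x)
  ft <- stats::fft(xc)
  kmax <- floor((n - 1) / 2)           # positive frequencies below Nyquist
  k <- seq_len(kmax)
  power <- Mod(ft[k + 1L])^2 / n

  # lag-1 autocorrelation for the red-noise null
  v0 <- sum(xc^2)
  alpha <- if (v0 > 0) sum(xc[-1L] * xc[-n]) / v0 else 0
  alpha <- min(max(alpha, 0), 0.999)   # red noise: clamp to [0, 1)
  shape <- (1 - alpha^2) / (1 + alpha^2 - 2 * alpha * cos(2 * pi * k / n))
  background <- mean(power) * shape / mean(shape)
  threshold <- background * stats::qchisq(confidence, df = 2) / 2
  significant <- power > threshold

  if (all(power == 0)) {
    dominant <- NA_integer_
    dom_sig <- FALSE
  } else {
    kd <- which.max(power)             # ties resolve to the lowest k
    dominant <- as.integer(round(n / k[kd]))
    dom_sig <- significant[kd]
  }
  structure(list(
    table = data.frame(k = k, frequency = k / n, period = n / k,
                       power = power, background = background,
                       threshold = threshold, significant = significant),
    dominant_period = dominant, dominant_significant = dom_sig,
    ar1 = alpha, confidence = confidence, n = n),
    class = "fps")
}

#' @export
print.fps <- function(x, ...) {
  cat(sprintf("Fourier power spectrum (N = %d, AR(1) alpha = %.3f)\n",
              x$n, x$ar1))
  cat(sprintf("  dominant period: %s samples (%ssignificant at %g%%)\n",
              x$dominant_period, if (x$dominant_significant) "" else "not ",
              100 * x$confidence))
  cat(sprintf("  %d of %d frequencies above the red-noise threshold\n",
              sum(x$table$significant), nrow(x$table)))
  invisible(x)
}

#' Select the autoregressive lag order from the spectrum
#'
#' Returns the rounded period (in sampling units) of the highest-power
#' spectral peak; for a weekly series this is the number of weeks of the
#' dominant cycle and serves as the lag order P of the forecasting models.
#' A message notes whether the peak clears the red-noise significance
#' threshold.
#'
#' @param spec `"fps"` object from [fourier_power_spectrum()].
#' @return Positive integer lag order.
#' @export
select_lag_order <- function(spec) {
  stopifnot(inherits(spec, "fps"))
  if (is.na(spec$dominant_period)) {
    stop("spectrum has no finite peak (constant series?)", call. = FALSE)
  }
  if (!spec$dominant_significant) {
    message(sprintf(
      "dominant period %d is below the %g%% red-noise threshold",
      spec$dominant_period, 100 * spec$confidence))
  }
  max(1L, spec$dominant_period)
}

#' Relative gain of one metric sequence over another
#'
#' Default convention: `100 * (mean(a) - mean(b)) / mean(b)`, the percentage
#' improvement of the mean score of method a over method b across horizons.
#' The per-horizon convention computes the percentage gain at each horizon
#' and averages those instead; the two differ whenever b varies across
#' horizons, and both are reported by the comparison pipeline since neither
#' is canonical.
#'
#' @param a,b Equal-length numeric vectors of per-horizon scores.
#' @param type `"mean"` (default) or `"per_horizon"`.
#' @return Scalar percentage gain.
#' @export
relative_gain <- function(a, b, type = c("mean", "per_horizon")) {
  type <- match.arg(type)
  if (length(a) != length(b)) stop("`a` and `b` must have equal length",
                                   call. = FALSE)
  if (type == "mean") {
    mb <- mean(b)
    if (mb == 0) stop("mean of `b` is zero; gain undefined", call. = FALSE)
    100 * (mean(a) - mb) / mb
  } else {
    if (any(b == 0)) stop("`b` contains zeros; per-horizon gain undefined",
                          call. = FALSE)
    mean(100 * (a - b) / b)
  }
}
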