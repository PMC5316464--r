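#' Read a univariate weekly series from CSV
#'
#' Accepts a single-column CSV of values, or a two-column CSV whose first
#' column holds ISO-8601 dates and whose second holds the values; a header
#' row is detected automatically.
#'
#' @param path CSV file path.
#' @return Numeric series; when dates are present they are attached as the
#'   `"dates"` attribute.
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) == 0L) stop("empty CSV", call. = FALSE)
  # headerless single column comes back with the first value as the name
  first_as_num <- suppressWarnings(as.numeric(names(df)[ncol(df)]))
  if (!is.na(first_as_num)) {
    df <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  }
  vals <- suppressWarnings(as.numeric(df[[ncol(df)]]))
  if (anyNA(vals)) stop("non-numeric values in the series column", call. = FALSE)
  if (ncol(df) >= 2L) {
    dates <- tryCatch(as.Date(df[[1L]]), error = function(e) NULL)
    if (!is.null(dates) && !anyNA(dates)) attr(vals, "dates") <- dates
  }
  vals
}

#' Write decomposition components to CSV
#'
#' Three columns: time index, low-frequency component, high-frequency
#' component — the interchange format shared by the MSVD and SWT paths.
#'
#' @param c_L,c_H Component series.
#' @param path Output CSV path.
#' @export
write_components_csv <- function(c_L, c_H, path) {
  utils::write.csv(data.frame(index = seq_along(c_L), c_L = c_L, c_H = c_H),
                   path, row.names = FALSE)
}

#' Split a series into low/high-frequency components by the chosen method
#'
#' Dispatches to [msvd()] (`"msvd"`), [swt_components()] (`"swt"`), or the
#' trivial split `c_L = x, c_H = 0` (`"none"`, i.e. forecast the raw series).
#'
#' @param x Numeric series.
#' @param method `"msvd"`, `"swt"` or `"none"`.
#' @param msvd_tol,msvd_max_levels MSVD stopping parameters.
#' @param J,wavelet SWT depth and Daubechies filter.
#' @return List with `c_L`, `c_H`, and `detail` (the full method object,
#'   `NULL` for `"none"`).
#' @export
decompose_series <- function(x, method = c("msvd", "swt", "none"),
                             msvd_tol = 1e-4, msvd_max_levels = 32L,
                             J = 3L, wavelet = "db2") {
  method <- match.arg(method)
  switch(method,
    msvd = {
      d <- msvd(x, tol = msvd_tol, max_levels = msvd_max_levels)
      list(c_L = d$c_L, c_H = d$c_H, detail = d)
    },
    swt = {
      d <- swt_components(x, J = J, wavelet = wavelet)
      list(c_L = d$c_L, c_H = d$c_H, detail = d)
    },
    none = list(c_L = as.numeric(x), c_H = numeric(length(x)), detail = NULL)
  )
}

build_z_rows <- function(c_L, c_H, ns, P) {
  z <- matrix(0, length(ns), 2L * P)
  for (k in seq_len(P)) {
    z[, k] <- c_L[ns - k + 1L]
    z[, P + k] <- c_H[ns - k + 1L]
  }
  z
}

#' Run the full decomposition-and-forecast experiment
#'
#' The end-to-end protocol: decompose the series into low/high-frequency
#' components, pick the lag order from the Fourier power spectrum (unless
#' given), build the 2P-lag regressors with tau-horizon targets, split
#' 70/30 chronologically, fit the chosen model on the training block, and
#' evaluate per-horizon skill on the test block.
#'
#' Two leakage modes are provided.  In `"full"` mode the components are
#' extracted from the full series before splitting — the conventional
#' protocol, but the test-period component values then reflect observations
#' from the test period itself (a warning notes this once).  In `"causal"`
#' mode the training regressors come from a decomposition of the training
#' window only, and each test row's regressors come from a fresh
#' decomposition of the series up to that row's forecast origin, so no
#' future observation ever enters a regressor.
#'
#' @param x Numeric series (weekly counts).
#' @param method Decomposition: `"msvd"` (default), `"swt"`, or `"none"`.
#' @param model `"mimo_ar"` (default) or `"mimo_ann"`.
#' @param P Lag order per component; `NULL` (default) selects it as the
#'   dominant spectral period via [select_lag_order()].
#' @param tau Largest forecast horizon (default 14).
#' @param train_fraction Chronological training share (default 0.70).
#' @param leakage `"full"` (default) or `"causal"`; see Details.
#' @param msvd_tol,msvd_max_levels,J,wavelet Decomposition parameters.
#' @param epochs,runs Perceptron training budget (defaults 500, 10).
#' @param seed Seed for the perceptron restarts (ignored by the
#'   deterministic AR path).
#' @param confidence Red-noise confidence for spectral lag selection.
#' @param output_dir If non-`NULL`, writes `components.csv`,
#'   `predictions.csv`, `metrics.csv` (percent scale), `delta_r.csv` (MSVD
#'   only), and `manifest.txt` there.
#' @return Object of class `"forecast_experiment"`: list with `metrics`
#'   (a [evaluate_horizons()] table), `predictions` / `observed` (test
#'   matrices), `decomposition`, `model_fit`, `P`, `tau`, `config`.
#' @export
run_experiment <- function(x, method = c("msvd", "swt", "none"),
                           model = c("mimo_ar", "mimo_ann"),
                           P = NULL, tau = 14L, train_fraction = 0.7,
                           leakage = c("full", "causal"),
                           msvd_tol = 1e-4, msvd_max_levels = 32L,
                           J = 3L, wavelet = "db2",
                           epochs = 500L, runs = 10L, seed = 1L,
                           confidence = 0.95, output_dir = NULL) {
  method <- match.arg(method)
  model <- match.arg(model)
  leakage <- match.arg(leakage)
  x <- check_series(x)
  n <- length(x)

  if (is.null(P)) {
    spec_input <- if (leakage == "causal") x[seq_len(floor(train_fraction * n))]
                  else x
    P <- select_lag_order(fourier_power_spectrum(spec_input,
                                                 confidence = confidence))
  }
  P <- as.integer(P)
  tau <- as.integer(tau)

  rows <- P:(n - tau)
  if (length(rows) < 2L) {
    stop("series too short for the requested P and tau", call. = FALSE)
  }
  ntr <- floor(train_fraction * length(rows))
  train_ns <- rows[seq_len(ntr)]
  test_ns <- rows[seq(ntr + 1L, length(rows))]
  targets_at <- function(ns) {
    tg <- matrix(0, length(ns), tau)
    for (h in seq_len(tau)) tg[, h] <- x[ns + h]
    tg
  }

  dec_full <- NULL
  if (leakage == "full") {
    warning("components are extracted from the full series before splitting; ",
            "test-period regressors reflect test-period observations ",
            "(use leakage = \"causal\" to avoid this)", call. = FALSE)
    dec_full <- decompose_series(x, method, msvd_tol, msvd_max_levels, J,
                                 wavelet)
    z_train <- build_z_rows(dec_full$c_L, dec_full$c_H, train_ns, P)
    z_test <- build_z_rows(dec_full$c_L, dec_full$c_H, test_ns, P)
  } else {
    dec_full <- decompose_series(x[seq_len(max(train_ns))], method,
                                 msvd_tol, msvd_max_levels, J, wavelet)
    z_train <- build_z_rows(dec_full$c_L, dec_full$c_H, train_ns, P)
    z_test <- matrix(0, length(test_ns), 2L * P)
    for (r in seq_along(test_ns)) {
      d_r <- decompose_series(x[seq_len(test_ns[r])], method,
                              msvd_tol, msvd_max_levels, J, wavelet)
      z_test[r, ] <- build_z_rows(d_r$c_L, d_r$c_H, test_ns[r], P)
    }
  }

  reg_train <- structure(list(z = z_train, targets = targets_at(train_ns),
                              row_index = train_ns, P = P, tau = tau),
                         class = "regressor_set")
  fit <- switch(model,
    mimo_ar = fit_mimo_ar(reg_train),
    mimo_ann = train_mlp_lm(reg_train, epochs = epochs, runs = runs,
                            seed = seed))
  observed <- targets_at(test_ns)
  predicted <- predict(fit, z_test)
  metrics <- evaluate_horizons(observed, predicted)

  config <- list(method = method, model = model, P = P, tau = tau,
                 train_fraction = train_fraction, leakage = leakage,
                 msvd_tol = msvd_tol, msvd_max_levels = msvd_max_levels,
                 J = J, wavelet = wavelet, epochs = epochs, runs = runs,
                 seed = seed, confidence = confidence, n = n)
  out <- structure(list(metrics = metrics, predictions = predicted,
                        observed = observed, test_index = test_ns,
                        decomposition = dec_full, model_fit = fit,
                        P = P, tau = tau, config = config),
                   class = "forecast_experiment")
  if (!is.null(output_dir)) write_experiment(out, x, output_dir)
  out
}

write_experiment <- function(exp, x, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(data.frame(index = seq_along(x), x = x),
                   file.path(output_dir, "input_series.csv"),
                   row.names = FALSE)
  write_components_csv(exp$decomposition$c_L, exp$decomposition$c_H,
                       file.path(output_dir, "components.csv"))
  tau <- exp$tau
  long <- data.frame(
    origin = rep(exp$test_index, times = tau),
    horizon = rep(seq_len(tau), each = length(exp$test_index)),
    observed = as.vector(exp$observed),
    predicted = as.vector(exp$predictions))
  utils::write.csv(long, file.path(output_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(format_horizon_metrics(exp$metrics),
                   file.path(output_dir, "metrics.csv"), row.names = FALSE)
  if (exp$config$method == "msvd" && !is.null(exp$decomposition$detail)) {
    d <- exp$decomposition$detail
    utils::write.csv(
      data.frame(level = seq_along(d$R), R = d$R,
                 delta_R = c(d$delta_R, NA)[seq_along(d$R)]),
      file.path(output_dir, "delta_r.csv"), row.names = FALSE)
  }
  checksum <- unname(tools::md5sum(file.path(output_dir, "input_series.csv")))
  cfg <- exp$config
  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("msvdcast"))),
    sprintf("input_md5: %s", checksum),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    vapply(names(cfg), function(k) sprintf("%s: %s", k,
                                           paste(format(cfg[[k]]), collapse = " ")),
           character(1)))
  writeLines(manifest, file.path(output_dir, "manifest.txt"))
  invisible(NULL)
}

#' @export
print.forecast_experiment <- function(x, ...) {
  cat(sprintf("Forecast experiment: %s + %s, P = %d, tau = %d, %s mode\n",
              toupper(x$config$method), toupper(x$config$model), x$P, x$tau,
              x$config$leakage))
  print(x$metrics)
  invisible(x)
}

#' Compare decomposition/model combinations on one series
#'
#' Runs several experiment variants that share the input series, the lag
#' order, the split and the horizon range, and tabulates their per-horizon
#' metrics side by side together with relative-gain summaries (both the
#' mean-of-scores and per-horizon conventions) of the first variant over
#' each of the others.
#'
#' @param x Numeric series.
#' @param variants Character vector naming the variants to run; supported:
#'   `"msvd_ar"`, `"swt_ar"`, `"swt_ann"`, `"none_ar"`.
#' @param gain_range Horizons over which gains are averaged (default
#'   `1:min(13, tau)`).
#' @param ... Passed to [run_experiment()] (e.g. `P`, `tau`, `seed`,
#'   `leakage`).
#' @return Object of class `"method_comparison"`: list with `table` (wide
#'   data frame: horizon, then nrmse/mnse/mia per variant), `gains` (data
#'   frame: baseline, metric, convention, gain in percent), `experiments`.
#' @export
compare_methods <- function(x, variants = c("msvd_ar", "swt_ar", "swt_ann"),
                            gain_range = NULL, ...) {
  known <- list(msvd_ar = list(method = "msvd", model = "mimo_ar"),
                swt_ar = list(method = "swt", model = "mimo_ar"),
                swt_ann = list(method = "swt", model = "mimo_ann"),
                none_ar = list(method = "none", model = "mimo_ar"))
  bad <- setdiff(variants, names(known))
  if (length(bad) > 0L) {
    stop(sprintf("unknown variant(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  exps <- lapply(variants, function(v) {
    do.call(run_experiment,
            c(list(x = x, method = known[[v]]$method,
                   model = known[[v]]$model), list(...)))
  })
  names(exps) <- variants
  taus <- vapply(exps, function(e) e$tau, integer(1))
  if (length(unique(taus)) != 1L) {
    stop("variants ended with different tau; pass `tau` explicitly",
         call. = FALSE)
  }
  tau <- taus[1L]
  tab <- data.frame(horizon = seq_len(tau))
  for (v in variants) {
    per <- exps[[v]]$metrics$per_horizon
    tab[[paste0(v, "_nrmse")]] <- per$nrmse
    tab[[paste0(v, "_mnse")]] <- per$mnse
    tab[[paste0(v, "_mia")]] <- per$mia
  }
  if (is.null(gain_range)) gain_range <- seq_len(min(13L, tau))
  gains <- NULL
  ref <- exps[[1L]]$metrics$per_horizon
  for (v in variants[-1L]) {
    per <- exps[[v]]$metrics$per_horizon
    for (metric in c("nrmse", "mnse", "mia")) {
      for (conv in c("mean", "per_horizon")) {
        g <- relative_gain(ref[[metric]][gain_range],
                           per[[metric]][gain_range], type = conv)
        gains <- rbind(gains, data.frame(
          baseline = v, metric = metric, convention = conv, gain = g))
      }
    }
  }
  structure(list(table = tab, gains = gains, experiments = exps,
                 reference = variants[1L], gain_range = gain_range),
            class = "method_comparison")
}

#' @export
print.method_comparison <- function(x, ...) {
  cat(sprintf("Method comparison (reference: %s; gains over horizons %d-%d)\n",
              x$reference, min(x$gain_range), max(x$gain_range)))
  print(utils::head(x$table), row.names = FALSE)
  cat("...\nRelative gains of the reference over each baseline (%):\n")
  print(x$gains, row.names = FALSE)
  invisible(x)
}
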