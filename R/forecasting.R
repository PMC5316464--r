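#' Build the lagged regressor matrix and multi-horizon targets
#'
#' For each usable time index `n = P .. N - tau` the regressor row collects
#' the P most recent values of the low-frequency component and the P most
#' recent values of the high-frequency component,
#' `[c_L(n), ..., c_L(n-P+1), c_H(n), ..., c_H(n-P+1)]` (2P columns), and the
#' target row holds the observed series at the next `tau` steps,
#' `[x(n+1), ..., x(n+tau)]`, so one multi-output model predicts all horizons
#' jointly (the MIMO strategy, which avoids the error accumulation of
#' recursive one-step forecasting).
#'
#' @param c_L,c_H Low- and high-frequency component series, length N each.
#' @param x Observed series, length N.
#' @param P Lag order (per component), >= 1.
#' @param tau Largest forecast horizon, >= 1.
#' @return Object of class `"regressor_set"`: list with `z`
#'   (`(N-P-tau+1) x 2P` matrix), `targets` (`(N-P-tau+1) x tau`),
#'   `row_index` (the time index n of each row), `P`, `tau`.
#' @export
build_regressors <- function(c_L, c_H, x, P, tau) {
  n <- length(x)
  if (length(c_L) != n || length(c_H) != n) {
    stop("`c_L`, `c_H` and `x` must share the same length", call. = FALSE)
  }
  stopifnot(P >= 1L, tau >= 1L)
  if (n < P + tau) {
    stop(sprintf("series of length %d too short for P = %d, tau = %d (need >= %d)",
                 n, P, tau, P + tau), call. = FALSE)
  }
  rows <- P:(n - tau)
  lag_block <- function(s) {
    out <- matrix(0, length(rows), P)
    for (k in seq_len(P)) out[, k] <- s[rows - k + 1L]
    out
  }
  z <- cbind(lag_block(c_L), lag_block(c_H))
  targets <- matrix(0, length(rows), tau)
  for (h in seq_len(tau)) targets[, h] <- x[rows + h]
  structure(list(z = z, targets = targets, row_index = rows, P = P, tau = tau),
            class = "regressor_set")
}

#' Chronological train/test split of a regressor set
#'
#' Splits the rows in time order, training block first: the first
#' `floor(train_fraction * rows)` rows train the model, the remainder test
#' it.  No shuffling; the last training index always precedes the first
#' test index.
#'
#' @param reg A `"regressor_set"`.
#' @param train_fraction Fraction in (0, 1); default 0.70.
#' @return List with `train` and `test` regressor sets.
#' @export
split_regressors <- function(reg, train_fraction = 0.7) {
  stopifnot(inherits(reg, "regressor_set"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stop("`train_fraction` must lie strictly between 0 and 1", call. = FALSE)
  }
  m <- nrow(reg$z)
  if (m < 2L) stop("need at least 2 rows to split", call. = FALSE)
  ntr <- floor(train_fraction * m)
  take <- function(i) {
    structure(list(z = reg$z[i, , drop = FALSE],
                   targets = reg$targets[i, , drop = FALSE],
                   row_index = reg$row_index[i], P = reg$P, tau = reg$tau),
              class = "regressor_set")
  }
  list(train = take(seq_len(ntr)), test = take(seq(ntr + 1L, m)))
}

#' Moore-Penrose pseudoinverse
#'
#' SVD-based pseudoinverse with the usual singular-value cutoff
#' `max(dim) * eps * max(d)`.
#'
#' @param A Numeric matrix.
#' @return The pseudoinverse of `A`.
#' @keywords internal
pinv <- function(A) {
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  pos <- s$d > tol
  if (!any(pos)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, pos, drop = FALSE] %*%
    (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Fit the linear MIMO autoregression
#'
#' Estimates the `tau x 2P` coefficient matrix `beta` of the multi-output
#' linear model `x_hat = beta %*% t(z)` as the minimum-norm least-squares
#' solution via the Moore-Penrose pseudoinverse,
#' `t(beta) = pinv(z) %*% targets`.  Deterministic; rank-deficient regressor
#' matrices are handled by the pseudoinverse without error.
#'
#' @param reg Training `"regressor_set"`.
#' @param intercept Add a constant column to `z`? Off by default (the model
#'   has no intercept term; components are typically far from zero-mean, so
#'   enable only deliberately).
#' @return Object of class `"mimo_ar"`: list with `beta` (`tau x 2P`,
#'   plus one column when `intercept`), `P`, `tau`, `intercept`.
#' @export
fit_mimo_ar <- function(reg, intercept = FALSE) {
  stopifnot(inherits(reg, "regressor_set"))
  if (nrow(reg$z) < 1L) stop("empty regressor set", call. = FALSE)
  if (!all(is.finite(reg$z)) || !all(is.finite(reg$targets))) {
    stop("regressors/targets contain non-finite values", call. = FALSE)
  }
  z <- if (intercept) cbind(reg$z, 1) else reg$z
  beta <- t(pinv(z) %*% reg$targets)
  structure(list(beta = beta, P = reg$P, tau = reg$tau, intercept = intercept),
            class = "mimo_ar")
}

#' Predict from a fitted MIMO autoregression
#'
#' @param object `"mimo_ar"` model.
#' @param z Regressor matrix (or `"regressor_set"`) with `2P` columns.
#' @param ... Unused.
#' @return Matrix of predictions, rows x tau.
#' @export
predict.mimo_ar <- function(object, z, ...) {
  if (inherits(z, "regressor_set")) z <- z$z
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (object$intercept) z <- cbind(z, 1)
  if (ncol(z) != ncol(object$beta)) {
    stop(sprintf("`z` has %d columns; model expects %d (= 2P%s)",
                 ncol(z), ncol(object$beta),
                 if (object$intercept) " + intercept" else ""), call. = FALSE)
  }
  z %*% t(object$beta)
}

#' Initialise a three-layer sigmoid perceptron
#'
#' Network with `2P` inputs (the lagged component values), `Q` hidden nodes
#' with logistic-sigmoid activation, and `tau` linear outputs (one per
#' horizon).  The hidden size follows `Q = round(log2(N_train))`, the usual
#' scaling of hidden width with training-set size; weights start from a
#' small symmetric uniform distribution, reproducibly per seed.
#'
#' @param n_inputs Number of inputs (2P).
#' @param n_train Training-set size (rows), >= 2.
#' @param tau Number of outputs.
#' @param seed Integer seed for the weight draw.
#' @param Q Optional explicit hidden size, overriding the log2 rule.
#' @return Object of class `"mimo_mlp"`: `w` (`n_inputs x Q`), `b`
#'   (`Q x tau`), `Q`; untrained (no standardisation attached yet).
#' @export
init_mlp <- function(n_inputs, n_train, tau, seed = 1L, Q = NULL) {
  stopifnot(n_train >= 2L, n_inputs >= 1L, tau >= 1L)
  if (is.null(Q)) Q <- max(1L, as.integer(round(log2(n_train))))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  w <- matrix(stats::runif(n_inputs * Q, -0.5, 0.5), n_inputs, Q)
  b <- matrix(stats::runif(Q * tau, -0.5, 0.5), Q, tau)
  structure(list(w = w, b = b, Q = Q, center = NULL, scale = NULL),
            class = "mimo_mlp")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

mlp_forward <- function(w, b, z) {
  y <- 1 / (1 + exp(-(z %*% w)))    # logistic hidden layer
  list(pred = y %*% b, hidden = y)
}

#' Predict from a trained perceptron
#'
#' Deterministic forward pass: hidden activations
#' `Y = sigmoid(z %*% w)`, predictions `Y %*% b`.  Inputs are standardised
#' with the training-set statistics stored in the model, when present.
#'
#' @param object `"mimo_mlp"` model.
#' @param z Regressor matrix (or `"regressor_set"`).
#' @param ... Unused.
#' @return Matrix of predictions, rows x tau.
#' @export
predict.mimo_mlp <- function(object, z, ...) {
  if (inherits(z, "regressor_set")) z <- z$z
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  if (ncol(z) != nrow(object$w)) {
    stop(sprintf("`z` has %d columns; model expects %d", ncol(z),
                 nrow(object$w)), call. = FALSE)
  }
  if (!is.null(object$center)) {
    z <- sweep(sweep(z, 2L, object$center), 2L, object$scale, `/`)
  }
  mlp_forward(object$w, object$b, z)$pred
}

# analytic Jacobian of vec(pred) w.r.t. theta = c(vec(w), vec(b))
mlp_jacobian <- function(w, b, z, hidden) {
  m <- nrow(z); p <- nrow(w); Q <- ncol(w); tau <- ncol(b)
  npar <- p * Q + Q * tau
  Jm <- matrix(0, m * tau, npar)
  dY <- hidden * (1 - hidden)          # m x Q
  for (h in seq_len(tau)) {
    rr <- (h - 1L) * m + seq_len(m)
    # d pred[, h] / d w[i, j] = b[j, h] * dY[, j] * z[, i]
    for (j in seq_len(Q)) {
      cols <- (j - 1L) * p + seq_len(p)
      Jm[rr, cols] <- (b[j, h] * dY[, j]) * z
    }
    # d pred[, h] / d b[j, h] = hidden[, j]
    Jm[rr, p * Q + (h - 1L) * Q + seq_len(Q)] <- hidden
  }
  Jm
}

#' Train the perceptron by Levenberg-Marquardt
#'
#' Full-batch Levenberg-Marquardt on the sum-of-squares error over all
#' horizons: at each iteration the damped normal equations
#' `(J'J + lambda I) delta = J'r` are solved for the step over all weights
#' jointly; the damping is divided by `damping_factor` on an accepted step
#' and multiplied by it on a rejected one, so the accepted-step error
#' sequence is non-increasing.  The optimisation restarts `runs` times from
#' fresh seeded initialisations (seeds `seed + 0 .. seed + runs - 1`) and
#' the model with the lowest training error is returned, with the per-run
#' error curves attached.  Inputs are standardised per column with
#' training-set statistics by default (sigmoid saturation control); the
#' statistics travel with the model and are reapplied at prediction time.
#'
#' @param reg Training `"regressor_set"`.
#' @param epochs Maximum accepted iterations per run (default 500).
#' @param runs Number of random restarts (default 10).
#' @param seed Base seed.
#' @param Q Hidden size; default `round(log2(nrow))`.
#' @param standardize Standardise inputs with training statistics
#'   (default TRUE).
#' @param damping_init,damping_factor,damping_max Levenberg-Marquardt
#'   damping schedule (defaults 1e-3, 10, 1e10).
#' @param mse_tol Stop a run early once training MSE falls below this
#'   (default 1e-12, effectively off).
#' @return `"mimo_mlp"` model of the best run, with a `report` element:
#'   per-run final MSE, accepted-error curves, best run index.
#' @export
train_mlp_lm <- function(reg, epochs = 500L, runs = 10L, seed = 1L, Q = NULL,
                         standardize = TRUE, damping_init = 1e-3,
                         damping_factor = 10, damping_max = 1e10,
                         mse_tol = 1e-12) {
  stopifnot(inherits(reg, "regressor_set"), epochs >= 1L, runs >= 1L)
  z_raw <- reg$z
  targets <- reg$targets
  m <- nrow(z_raw)
  if (standardize) {
    center <- colMeans(z_raw)
    scale <- apply(z_raw, 2L, stats::sd)
    scale[scale == 0 | !is.finite(scale)] <- 1
    z <- sweep(sweep(z_raw, 2L, center), 2L, scale, `/`)
  } else {
    center <- NULL; scale <- NULL
    z <- z_raw
  }

  run_one <- function(run_seed) {
    model <- init_mlp(ncol(z), m, reg$tau, seed = run_seed, Q = Q)
    w <- model$w; b <- model$b
    p <- nrow(w); Qn <- ncol(w); tau <- ncol(b)
    fw <- mlp_forward(w, b, z)
    r <- as.vector(targets - fw$pred)
    sse <- sum(r^2)
    lambda <- damping_init
    curve <- numeric(0)
    accepted <- 0L
    while (accepted < epochs) {
      if (!is.finite(sse)) return(NULL)
      if (sse / (m * tau) < mse_tol) break
      Jm <- mlp_jacobian(w, b, z, fw$hidden)
      g <- crossprod(Jm, r)
      JtJ <- crossprod(Jm)
      improved <- FALSE
      while (lambda <= damping_max) {
        step <- tryCatch(
          solve(JtJ + diag(lambda, ncol(JtJ)), g),
          error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          w_new <- w + matrix(step[seq_len(p * Qn)], p, Qn)
          b_new <- b + matrix(step[p * Qn + seq_len(Qn * tau)], Qn, tau)
          fw_new <- mlp_forward(w_new, b_new, z)
          r_new <- as.vector(targets - fw_new$pred)
          sse_new <- sum(r_new^2)
          if (is.finite(sse_new) && sse_new < sse) {
            w <- w_new; b <- b_new; fw <- fw_new; r <- r_new; sse <- sse_new
            lambda <- max(lambda / damping_factor, .Machine$double.xmin)
            improved <- TRUE
            break
          }
        }
        lambda <- lambda * damping_factor
      }
      if (!improved) break                 # damping exhausted: local optimum
      accepted <- accepted + 1L
      curve[accepted] <- sse / (m * tau)
    }
    list(w = w, b = b, mse = sse / (m * tau), curve = curve)
  }

  results <- vector("list", runs)
  for (k in seq_len(runs)) {
    res <- run_one(seed + k - 1L)
    if (is.null(res)) {
      warning(sprintf("run %d aborted on non-finite training error", k),
              call. = FALSE)
    }
    results[[k]] <- res
  }
  ok <- !vapply(results, is.null, logical(1))
  if (!any(ok)) stop("all training runs diverged", call. = FALSE)
  mses <- vapply(results, function(r) if (is.null(r)) Inf else r$mse,
                 numeric(1))
  best <- which.min(mses)
  out <- results[[best]]
  structure(list(w = out$w, b = out$b, Q = ncol(out$w),
                 center = center, scale = scale,
                 report = list(final_mse = mses, best_run = best,
                               curves = lapply(results, function(r) r$curve))),
            class = "mimo_mlp")
}

#' @export
print.mimo_ar <- function(x, ...) {
  cat(sprintf("MIMO-AR model: tau = %d horizons, P = %d lags per component%s\n",
              x$tau, x$P, if (x$intercept) " (+ intercept)" else ""))
  invisible(x)
}

#' @export
print.mimo_mlp <- function(x, ...) {
  cat(sprintf("MIMO perceptron: %d inputs -> %d sigmoid hidden -> %d linear outputs\n",
              nrow(x$w), x$Q, ncol(x$b)))
  if (!is.null(x$report)) {
    cat(sprintf("  best of %d runs, training MSE %.4g\n",
                length(x$report$final_mse), min(x$report$final_mse)))
  }
  invisible(x)
}
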